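#' Kabsch least-squares rigid superposition
#'
#' Optimal proper rotation (det = +1) and translation minimizing the RMSD
#' between two corresponding point sets, via SVD of the covariance matrix.
#'
#' @param coords_ref,coords_mobile numeric n x 3 matrices of corresponding
#'   points (n >= 3, not collinear).
#' @return list with `rotation` (3x3), `translation` (length 3) such that
#'   `mobile %*% t(rotation) + translation` superposes onto the reference,
#'   and the resulting `rmsd`.
#' @export
kabsch_superpose <- function(coords_ref, coords_mobile) {
  A <- as.matrix(coords_ref); B <- as.matrix(coords_mobile)
  stopifnot(ncol(A) == 3, ncol(B) == 3)
  if (nrow(A) != nrow(B)) stop("point counts differ")
  if (nrow(A) < 3) stop("need at least 3 points for superposition")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- t(Bc) %*% Ac
  sv <- svd(H)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate (collinear) point set; rotation is not determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- Bc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Ac)^2)))
  list(rotation = R, translation = as.numeric(ca - (cb %*% t(R))),
       rmsd = rmsd)
}

rmsd_plain <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# paired coordinates for shared residues/atoms, in reference order; uses
# one point per residue (CA) or all shared heavy atoms
match_atoms <- function(ref, mod, res_keys = NULL, atom_set = "CA") {
  if (atom_set == "CA") {
    ra <- ref$atoms[ref$atoms$elety == "CA", ]
    ma <- mod$atoms[mod$atoms$elety == "CA", ]
    keys <- intersect(ra$res_key, ma$res_key)
    if (!is.null(res_keys)) keys <- intersect(keys, res_keys)
    if (length(keys) == 0L)
      stop("no common CA atoms between model and reference")
    ia <- match(keys, ra$res_key); im <- match(keys, ma$res_key)
  } else {
    ra <- ref$atoms; ma <- mod$atoms
    ra$akey <- paste(ra$res_key, ra$elety)
    ma$akey <- paste(ma$res_key, ma$elety)
    if (!is.null(res_keys)) {
      ra <- ra[ra$res_key %in% res_keys, ]
      ma <- ma[ma$res_key %in% res_keys, ]
    }
    keys <- intersect(ra$akey, ma$akey)
    if (length(keys) == 0L)
      stop("no common atoms between model and reference")
    ia <- match(keys, ra$akey); im <- match(keys, ma$akey)
  }
  list(ref = as.matrix(ra[ia, c("x", "y", "z")]),
       mod = as.matrix(ma[im, c("x", "y", "z")]),
       keys = keys)
}

#' Interface residues of a reference complex
#'
#' Residues of either partner within `dist` Angstrom (minimum heavy-atom
#' distance) of any residue of the other partner.
#'
#' @param ref_a,ref_b the two partners posed as the reference complex.
#' @param dist interface criterion in Angstrom (default 5).
#' @return list with residue-key vectors `a` and `b`.
#' @export
interface_residues <- function(ref_a, ref_b, dist = 5) {
  ct <- find_contacts(ref_a, ref_b, dist)$pairs
  list(a = unique(ct$res_a), b = unique(ct$res_b))
}

#' CAPRI-style assessment of a docking model
#'
#' Ligand RMSD: the model is superposed on the reference over the larger
#' partner's (the receptor, by residue count, ties by heavy-atom count)
#' C-alpha atoms, and the RMSD is measured over the smaller partner's
#' C-alphas. Interface RMSD: interface residues are those within 5 Angstrom
#' of the other partner in the reference; the model's interface C-alphas are
#' best-fit superposed on the reference's and the residual RMSD reported. A
#' model is acceptable when ligand RMSD < 10 and interface RMSD < 4 Angstrom
#' (strict inequalities).
#'
#' @param model_a,model_b the two partners posed as in the docking model.
#' @param ref_a,ref_b the same partners posed as the reference complex.
#' @param interface_dist interface criterion (default 5 Angstrom).
#' @param atom_set `"CA"` (default for protein structures), `"heavy"` (all
#'   shared heavy atoms, used e.g. for pseudo-atom toys without C-alphas) or
#'   `"auto"` (CA when both partners have them, else heavy).
#' @return list of class `eval_result`: `lrmsd`, `irmsd`, `acceptable`,
#'   `receptor` (`"a"` or `"b"`).
#' @export
evaluate_model <- function(model_a, model_b, ref_a, ref_b,
                           interface_dist = 5,
                           atom_set = c("auto", "CA", "heavy")) {
  atom_set <- match.arg(atom_set)
  if (atom_set == "auto")
    atom_set <- if (any(ref_a$atoms$elety == "CA") &&
                    any(ref_b$atoms$elety == "CA")) "CA" else "heavy"
  size <- function(s) c(nrow(s$residues), nrow(s$atoms))
  a_big <- {
    sa <- size(ref_a); sb <- size(ref_b)
    sa[1] > sb[1] || (sa[1] == sb[1] && sa[2] >= sb[2])
  }
  rec_ref <- if (a_big) ref_a else ref_b
  lig_ref <- if (a_big) ref_b else ref_a
  rec_mod <- if (a_big) model_a else model_b
  lig_mod <- if (a_big) model_b else model_a

  rec <- match_atoms(rec_ref, rec_mod, atom_set = atom_set)
  fit <- kabsch_superpose(rec$ref, rec$mod)
  lig <- match_atoms(lig_ref, lig_mod, atom_set = atom_set)
  lig_moved <- sweep(lig$mod %*% t(fit$rotation), 2, -fit$translation, `-`)
  lrmsd <- rmsd_plain(lig$ref, lig_moved)

  iface <- interface_residues(ref_a, ref_b, interface_dist)
  ia <- match_atoms(ref_a, model_a, iface$a, atom_set)
  ib <- match_atoms(ref_b, model_b, iface$b, atom_set)
  irmsd <- kabsch_superpose(rbind(ia$ref, ib$ref), rbind(ia$mod, ib$mod))$rmsd

  structure(list(lrmsd = lrmsd, irmsd = irmsd,
                 acceptable = acceptable_model(lrmsd, irmsd),
                 receptor = if (a_big) "a" else "b"),
            class = "eval_result")
}

#' Acceptability of a docking model
#'
#' A model is acceptable when the ligand RMSD is less than 10 Angstrom AND
#' the interface RMSD is less than 4 Angstrom (both strict).
#'
#' @param lrmsd,irmsd ligand and interface RMSD in Angstrom (vectorized).
#' @return logical vector.
#' @export
acceptable_model <- function(lrmsd, irmsd) lrmsd < 10 & irmsd < 4

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result: ligand rmsd %.2f, interface rmsd %.2f -> %s>\n",
              x$lrmsd, x$irmsd,
              if (x$acceptable) "acceptable" else "not acceptable"))
  invisible(x)
}

#' Gain in acceptable models from constrained docking
#'
#' The gain of a set of complexes is the total number of acceptable models
#' obtained with constraints divided by the total without constraints. Given
#' a table with several retention columns (e.g. 500/1000/2000/5000 retained
#' models), a per-column gain and their mean are returned.
#'
#' @param counts data.frame with columns `constrained`, `unconstrained` and
#'   optionally a grouping column named by `by` (one gain per group).
#' @param by optional name of the grouping column.
#' @return if `by` is `NULL`, the scalar gain; otherwise a named numeric
#'   vector of per-group gains with the across-group `mean` and `sd` as
#'   attributes.
#' @export
compute_gain <- function(counts, by = NULL) {
  g1 <- function(d) {
    u <- sum(d$unconstrained)
    if (u <= 0) stop("gain undefined: zero unconstrained acceptable models")
    sum(d$constrained) / u
  }
  if (is.null(by)) return(g1(counts))
  groups <- split(counts, counts[[by]])
  g <- vapply(groups, g1, numeric(1))
  attr(g, "mean") <- mean(g)
  attr(g, "sd") <- sd(g)
  g
}

#' Acceptable-model counts of the 28-complex docking benchmark
#'
#' Per-complex counts of acceptable models from constrained (100 predicted
#' contacts, 1%-per-constraint sampling) and unconstrained rigid-body docking
#' runs over a 28-complex test benchmark, for bound and unbound partner
#' structures and four model-retention totals. Distributed with the package
#' as a plain-text table so the gain statistics can be recomputed with
#' [compute_gain()].
#'
#' @return data.frame with columns `complex`, `setting` (`bound`/`unbound`),
#'   `total` (500/1000/2000/5000), `constrained`, `unconstrained`.
#' @export
benchmark_counts <- function() {
  path <- system.file("extdata", "benchmark_model_counts.csv",
                      package = "condock", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
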