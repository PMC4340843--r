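#' van der Waals radii used for surface areas and grid digitization
#'
#' Standard heavy-atom radii: C 1.7, N 1.55, O 1.52, S 1.8, P 1.8 Angstrom.
#' Elements outside the table fall back to 1.7 Angstrom with a warning; an
#' empty element symbol is an error.
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii (Angstrom).
#' @export
vdw_radius <- function(element) {
  tab <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8)
  element <- toupper(element)
  if (any(is.na(element) | element == ""))
    stop("atom with empty element symbol; cannot assign a vdW radius")
  r <- tab[element]
  if (anyNA(r)) {
    unk <- unique(element[is.na(r)])
    warning("no vdW radius for element(s) ", paste(unk, collapse = ", "),
            "; using 1.7 Angstrom")
    r[is.na(r)] <- 1.7
  }
  unname(r)
}

# deterministic quasi-uniform points on the unit sphere (golden-spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue solvent-accessible surface area
#'
#' Rolling-probe (Shrake-Rupley) point-sampling SASA over heavy atoms only.
#' Each atom is covered with `n_sphere_points` quasi-uniform test points at
#' radius vdW + probe; points falling inside any other atom's expanded sphere
#' are buried. Atom areas are summed per residue; the side-chain area sums
#' over all atoms except the backbone N, CA, C, O (so glycine's side-chain
#' area is 0).
#'
#' @param s a `dock_structure`.
#' @param probe_radius probe radius in Angstrom (default 1.4, a water probe).
#' @param n_sphere_points test points per atom (default 960).
#' @return An object of class `residue_areas`: data.frame with `res_key`,
#'   `chain`, `resno`, `icode`, `resname`, `area_full`, `area_side` (Angstrom^2).
#' @export
compute_residue_areas <- function(s, probe_radius = 1.4, n_sphere_points = 960) {
  stopifnot(inherits(s, "dock_structure"), probe_radius > 0,
            n_sphere_points >= 1)
  at <- s$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rr <- vdw_radius(at$element) + probe_radius
  pts <- sphere_points(n_sphere_points)
  n <- nrow(xyz)
  areas <- numeric(n)
  maxr <- max(rr)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (rr[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (rr[i] + rr[nb])^2]
    p <- pts * rr[i]
    p <- sweep(p, 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj >= rr[j]^2
    }
    areas[i] <- 4 * pi * rr[i]^2 * sum(acc) / n_sphere_points
  }
  backbone <- at$elety %in% c("N", "CA", "C", "O")
  full <- tapply(areas, at$res_key, sum)
  side <- tapply(areas * !backbone, at$res_key, sum)
  res <- s$residues
  out <- data.frame(res, area_full = as.numeric(full[res$res_key]),
                    area_side = as.numeric(side[res$res_key]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("residue_areas", "data.frame")
  out
}

#' Select candidate surface residues by exposed area
#'
#' A residue is a candidate for contact prediction when its full-residue
#' exposed area is strictly greater than the cutoff. The default cutoff of
#' 38 Angstrom^2 trades off the number of candidate pairs against the risk of
#' losing all true contacts in small-interface complexes (see
#' [select_area_cutoff()]).
#'
#' @param areas a `residue_areas` object.
#' @param cutoff area threshold in Angstrom^2 (default 38).
#' @return character vector of candidate residue keys, in residue order.
#' @export
select_surface_residues <- function(areas, cutoff = 38) {
  stopifnot(cutoff >= 0)
  areas$res_key[areas$area_full > cutoff]
}

#' Choose the surface-area cutoff from a training survey
#'
#' Scores each cutoff on a grid by the product of two indicators over the
#' training complexes: (mean number of potential contacts) / (minimum number
#' of surviving true contacts over complexes), times the fraction of true
#' contacts lost in the complex that has the fewest true contacts overall.
#' A cutoff at which some complex retains zero true contacts scores +Inf.
#' Returns the grid cutoff minimizing the product; ties go to the smaller
#' cutoff (which keeps more true contacts).
#'
#' @param survey list of complexes, each a list with numeric vectors
#'   `potential` and `surviving` (one value per grid cutoff) and scalar
#'   `total_true` (true contacts with no area filtering).
#' @param cutoff_grid numeric vector of cutoffs (Angstrom^2); default
#'   integers 0..60.
#' @return the selected cutoff (scalar); the per-cutoff scores are attached
#'   as attribute `"scores"`.
#' @export
select_area_cutoff <- function(survey, cutoff_grid = 0:60) {
  stopifnot(length(survey) >= 1, length(cutoff_grid) >= 1)
  ng <- length(cutoff_grid)
  pot <- vapply(survey, function(cx) as.numeric(cx$potential), numeric(ng))
  sur <- vapply(survey, function(cx) as.numeric(cx$surviving), numeric(ng))
  if (ng == 1L) { pot <- matrix(pot, 1); sur <- matrix(sur, 1) }
  total <- vapply(survey, function(cx) as.numeric(cx$total_true), numeric(1))
  jstar <- which.min(total)
  scores <- vapply(seq_len(ng), function(g) {
    smin <- min(sur[g, ])
    if (smin <= 0) return(Inf)
    ratio <- mean(pot[g, ]) / smin
    frac_lost <- (total[jstar] - sur[g, jstar]) / total[jstar]
    ratio * frac_lost
  }, numeric(1))
  best <- which(scores == min(scores))
  out <- cutoff_grid[best[which.min(cutoff_grid[best])]]
  attr(out, "scores") <- setNames(scores, cutoff_grid)
  out
}

#' Survey candidate counts and true-contact survival over a cutoff grid
#'
#' Convenience builder of the input to [select_area_cutoff()] from prepared
#' complexes.
#'
#' @param complexes list; each element a list with `areas_a`, `areas_b`
#'   (`residue_areas` of the two partners) and `contacts` (true inter-partner
#'   `contact_set`).
#' @param cutoff_grid numeric vector of cutoffs.
#' @return list suitable for [select_area_cutoff()].
#' @export
survey_area_cutoffs <- function(complexes, cutoff_grid = 0:60) {
  lapply(complexes, function(cx) {
    truth <- cx$contacts$pairs
    pot <- numeric(length(cutoff_grid))
    sur <- numeric(length(cutoff_grid))
    for (g in seq_along(cutoff_grid)) {
      ca <- select_surface_residues(cx$areas_a, cutoff_grid[g])
      cb <- select_surface_residues(cx$areas_b, cutoff_grid[g])
      pot[g] <- length(ca) * length(cb)
      sur[g] <- sum(truth$res_a %in% ca & truth$res_b %in% cb)
    }
    list(potential = pot, surviving = sur, total_true = nrow(truth))
  })
}
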