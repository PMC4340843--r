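#' Generate a toy two-partner complex with known contacts
#'
#' Builds two solid pseudo-protein partners facing each other across an
#' interface. Each residue is a dense cube of carbon pseudo-atoms (3 x 3 x 3
#' at 1 Angstrom spacing) on a 4.5 Angstrom residue lattice, so the partners
#' are packed like real protein cores: any placement that tries to
#' interpenetrate or interdigitate them brings some atom pair well inside
#' the core-clash range and is rejected by a hard-core docking grid. The interface
#' is corrugated: every interface site carries a seeded lateral depth offset
#' shared by the two partners, and the designated contact sites protrude so
#' their closest atom pairs sit exactly `contact_dist` Angstrom apart
#' (default 4.5, inside the 5 Angstrom criterion) while all remaining sites
#' are recessed beyond it. Inter-partner atom pairs stay above ~3.9 Angstrom
#' (well above the 2 Angstrom interpenetration floor, and above the ~3.4
#' Angstrom limit at which 1.7 Angstrom vdW cores could share a 1 Angstrom
#' grid cell), so a hard-core docking grid is clash-free at the true pose.
#' Deterministic for a given seed.
#'
#' @param n_res residue count per partner (length-2 vector or scalar); up to
#'   9 residues per depth layer.
#' @param atoms_per_res atoms per residue (default 27, the dense cube;
#'   fewer takes a subset, more adds jittered interior atoms).
#' @param n_contacts number of designated true-contact residue pairs (at
#'   most `min(9, n_res)`).
#' @param contact_dist distance of the designated closest atom pairs
#'   (Angstrom, in (4, 5]).
#' @param seed RNG seed.
#' @return list with `a`, `b` (`dock_structure`s posed in complex),
#'   `contacts` (ground-truth inter-partner `contact_set` at 5 Angstrom,
#'   computed by [find_contacts()]) and `spec` (the generating parameters).
#' @export
make_toy_complex <- function(n_res = c(8, 8), atoms_per_res = 27,
                             n_contacts = 3, contact_dist = 4.5, seed = 1) {
  if (length(n_res) == 1L) n_res <- rep(n_res, 2)
  stopifnot(contact_dist > 4, contact_dist <= 5, atoms_per_res >= 1)
  if (n_contacts > min(n_res))
    stop("infeasible: more designated contacts than residues per partner")
  if (n_contacts > 9)
    stop("infeasible: at most 9 interface sites per layer")
  aa3 <- bio3d::aa123(strsplit(AA20, "")[[1]])
  cube <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  # corners first so small atoms_per_res still spans the residue volume
  cube <- cube[order(-rowSums(abs(cube)), cube[, 1], cube[, 2], cube[, 3]), ]
  with_seed(seed, {
    px <- runif(9, -0.75, 0.75) # shared corrugation depth per interface site
    build <- function(n, chain, side) {
      resnames <- sample(aa3, n, replace = TRUE)
      at <- list()
      for (r in seq_len(n)) {
        site <- (r - 1L) %% 9L
        layer <- (r - 1L) %/% 9L
        recess <- if (layer == 0L && r <= n_contacts) 0 else 1
        depth <- contact_dist / 2 + 1 + recess + 4 * layer
        ctr <- c(px[site + 1L] + side * depth,
                 4.5 * (site %/% 3L), 4.5 * (site %% 3L))
        xyz <- cube[seq_len(min(atoms_per_res, 27L)), , drop = FALSE]
        if (atoms_per_res > 27L) {
          extra <- matrix(runif(3 * (atoms_per_res - 27L), -0.5, 0.5),
                          ncol = 3)
          xyz <- rbind(xyz, extra)
        }
        xyz <- sweep(xyz, 2, ctr, `+`)
        at[[r]] <- data.frame(
          chain = chain, resno = r, icode = "", resname = resnames[r],
          elety = paste0("C", seq_len(nrow(xyz))), element = "C",
          x = round(xyz[, 1], 3), y = round(xyz[, 2], 3),
          z = round(xyz[, 3], 3), occ = 1, stringsAsFactors = FALSE)
      }
      atoms <- do.call(rbind, at)
      atoms$res_key <- residue_key(atoms$chain, atoms$resno, atoms$icode)
      res <- atoms[!duplicated(atoms$res_key),
                   c("chain", "resno", "icode", "resname", "res_key")]
      rownames(res) <- rownames(atoms) <- NULL
      structure(list(id = paste0("toy_", chain), atoms = atoms,
                     residues = res),
                class = "dock_structure")
    }
    a <- build(n_res[1], "A", -1)
    b <- build(n_res[2], "B", +1)
    list(a = a, b = b, contacts = find_contacts(a, b, 5),
         spec = list(n_res = n_res, atoms_per_res = atoms_per_res,
                     n_contacts = n_contacts, contact_dist = contact_dist,
                     seed = seed))
  })
}

#' Generate paired alignments with planted coevolution signal
#'
#' Emulates the statistical structure contact prediction exploits: for each
#' synthetic organism both chains are mutated jointly — designated
#' contact-pair columns co-substitute with probability `coevolution` (to a
#' correlated amino-acid pair via a fixed bijection), all other columns
#' mutate independently at `sub_rate`; gaps replace non-query letters at
#' `gap_rate`. Query rows are the structures' sequences, ungapped, so they
#' degap exactly to the chains.
#'
#' @param toy a toy complex from [make_toy_complex()] (or any list with `a`,
#'   `b` structures and `contacts`).
#' @param n_org number of non-query organisms.
#' @param sub_rate independent substitution probability per column.
#' @param coevolution probability that a designated contact column pair
#'   co-substitutes (0 disables the planted signal).
#' @param gap_rate per-cell gap probability in non-query rows.
#' @param seed RNG seed.
#' @param corrupt `"none"` (default), `"ragged"` (FASTA text of alignment A
#'   gets a truncated row) or `"all_gap_column"` (the first contact column of
#'   A is fully gapped in non-query rows).
#' @return list with `aln_a`, `aln_b` (`msa_alignment`), `paired`
#'   (`paired_alignment`), `fasta_a`, `fasta_b` (aligned-FASTA text), and
#'   `contact_cols` (matrix of designated column pairs).
#' @export
make_synthetic_alignments <- function(toy, n_org = 30, sub_rate = 0.1,
                                      coevolution = 0.8, gap_rate = 0.05,
                                      seed = 1,
                                      corrupt = c("none", "ragged",
                                                  "all_gap_column")) {
  corrupt <- match.arg(corrupt)
  aa <- strsplit(AA20, "")[[1]]
  partner <- setNames(aa[c(seq_along(aa)[-1], 1)], aa) # fixed bijection
  seq_a <- strsplit(structure_sequence(toy$a), "")[[1]]
  seq_b <- strsplit(structure_sequence(toy$b), "")[[1]]
  truth <- toy$contacts$pairs
  col_a <- toy$a$residues$resno[match(truth$res_a, toy$a$residues$res_key)]
  col_b <- toy$b$residues$resno[match(truth$res_b, toy$b$residues$res_key)]
  with_seed(seed, {
    rows_a <- matrix(rep(seq_a, n_org), nrow = n_org, byrow = TRUE)
    rows_b <- matrix(rep(seq_b, n_org), nrow = n_org, byrow = TRUE)
    for (o in seq_len(n_org)) {
      sub <- function(x) sample(aa, 1)
      mut_a <- runif(length(seq_a)) < sub_rate
      mut_b <- runif(length(seq_b)) < sub_rate
      rows_a[o, mut_a] <- vapply(which(mut_a), sub, character(1))
      rows_b[o, mut_b] <- vapply(which(mut_b), sub, character(1))
      co <- runif(nrow(truth)) < coevolution
      for (m in which(co)) {
        r <- sample(aa, 1)
        rows_a[o, col_a[m]] <- r
        rows_b[o, col_b[m]] <- partner[[r]]
      }
      rows_a[o, runif(length(seq_a)) < gap_rate] <- "-"
      rows_b[o, runif(length(seq_b)) < gap_rate] <- "-"
    }
    if (corrupt == "all_gap_column" && nrow(truth) > 0)
      rows_a[, col_a[1]] <- "-"
    orgs <- sprintf("Synthorg %03d", seq_len(n_org))
    fasta <- function(qseq, rows, tag) {
      heads <- c(sprintf(">%s|query OS=Reference organism OX=0", tag),
                 sprintf(">%s|h%03d OS=%s OX=%d", tag, seq_len(n_org), orgs,
                         seq_len(n_org)))
      seqs <- c(paste(qseq, collapse = ""),
                apply(rows, 1, paste, collapse = ""))
      paste(rbind(heads, seqs), collapse = "\n")
    }
    fa <- fasta(seq_a, rows_a, "A")
    fb <- fasta(seq_b, rows_b, "B")
    if (corrupt == "ragged") {
      ln <- strsplit(fa, "\n")[[1]]
      ln[4] <- substr(ln[4], 1, nchar(ln[4]) - 1L)
      fa <- paste(ln, collapse = "\n")
      return(list(fasta_a = fa, fasta_b = fb))
    }
    aln_a <- parse_alignment(fa, "fasta")
    aln_b <- parse_alignment(fb, "fasta")
    list(aln_a = aln_a, aln_b = aln_b,
         paired = pair_rows_by_organism(aln_a, aln_b),
         fasta_a = fa, fasta_b = fb,
         contact_cols = cbind(a = col_a, b = col_b))
  })
}

#' Generate a labelled synthetic feature table
#'
#' Negative (non-contact) pairs draw every feature from a standard normal;
#' positive (contact) pairs are shifted by `mean_shift` standard deviations
#' on the informative features only. The positive count is
#' `round(prevalence * n_pairs)`.
#'
#' @param n_pairs number of candidate pairs.
#' @param n_features number of features.
#' @param informative indices of informative features.
#' @param mean_shift class-mean shift (in SD units) on informative features.
#' @param prevalence fraction of positive pairs (in (0, 1)).
#' @param seed RNG seed.
#' @return list with `x` (matrix, columns `f1..fn`) and `y` (logical labels).
#' @export
make_feature_table <- function(n_pairs, n_features = 20,
                               informative = integer(0), mean_shift = 1,
                               prevalence = 0.01, seed = 1) {
  stopifnot(prevalence > 0, prevalence < 1)
  with_seed(seed, {
    n_pos <- round(prevalence * n_pairs)
    y <- c(rep(TRUE, n_pos), rep(FALSE, n_pairs - n_pos))
    x <- matrix(rnorm(n_pairs * n_features), n_pairs, n_features,
                dimnames = list(NULL, paste0("f", seq_len(n_features))))
    if (n_pos > 0 && length(informative) > 0)
      x[y, informative] <- x[y, informative] + mean_shift
    list(x = x, y = y)
  })
}

#' Generate a multi-complex collection of synthetic feature tables
#'
#' Convenience wrapper over [make_feature_table()] producing the per-complex
#' named list consumed by [cross_validate()] and [beam_forward_search()];
#' complex k uses sub-seed `seed * 1000 + k`.
#'
#' @param n_complexes number of complexes.
#' @param pairs_per_complex candidate pairs per complex.
#' @inheritParams make_feature_table
#' @return named list of `list(x, y)` tables.
#' @export
make_feature_tables <- function(n_complexes, pairs_per_complex,
                                n_features = 20, informative = integer(0),
                                mean_shift = 1, prevalence = 0.01, seed = 1) {
  out <- lapply(seq_len(n_complexes), function(k)
    make_feature_table(pairs_per_complex, n_features, informative,
                       mean_shift, prevalence, seed = seed * 1000 + k))
  names(out) <- sprintf("cx%02d", seq_len(n_complexes))
  out
}
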