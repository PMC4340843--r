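#' Amino-acid substitution and pair-score tables
#'
#' `gonnet_matrix()` loads the packaged Gonnet 250 substitution matrix
#' (20x20, one-decimal log-odds units, symmetric), used for the conservation
#' descriptors. `default_pair_tables()` returns the four residue-pair score
#' tables used by the interaction descriptors: two volume-normalized contact
#' scores and all-atom / alpha-carbon contact propensities. The packaged pair
#' tables are SYNTHETIC stand-ins built deterministically from the
#' Kyte-Doolittle hydropathy scale, side-chain charges and mean residue
#' volumes; substitute literature tables via `load_score_matrix()` wherever
#' exact published propensities are required.
#'
#' @return `gonnet_matrix()`: a 20x20 numeric matrix with one-letter
#'   dimnames. `default_pair_tables()`: named list of four such matrices
#'   (`contact_vol1`, `contact_vol2`, `prop_all_atom`, `prop_calpha`).
#' @export
gonnet_matrix <- function() {
  path <- system.file("extdata", "gonnet250.tsv", package = "condock",
                      mustWork = TRUE)
  load_score_matrix(path)
}

#' @rdname gonnet_matrix
#' @param path TSV file: header row of 20 one-letter codes (first column
#'   `aa`), then 20 rows of scores.
#' @export
load_score_matrix <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  stopifnot(nrow(m) == 20, ncol(m) == 20,
            all(rownames(m) == colnames(m)))
  m
}

# physical scales used to synthesize the fallback pair tables
aa_scales <- function() {
  aa <- strsplit(AA20, "")[[1]]
  hyd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
           E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
           M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
           Y = -1.3, V = 4.2)
  vol <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5, Q = 143.8,
           E = 138.4, G = 60.1, H = 153.2, I = 166.7, L = 166.7, K = 168.6,
           M = 162.9, F = 189.9, P = 112.7, S = 89.0, T = 116.1, W = 227.8,
           Y = 193.6, V = 140.0)
  chg <- c(A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0,
           H = 0.5, I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 0,
           T = 0, W = 0, Y = 0, V = 0)
  list(aa = aa, hyd = hyd[aa], vol = vol[aa], chg = chg[aa])
}

#' @rdname gonnet_matrix
#' @export
default_pair_tables <- function() {
  s <- aa_scales()
  h <- s$hyd; v <- s$vol; q <- s$chg
  cv1 <- outer(h, h) / outer(v, v)^(1 / 3) * 10
  cv2 <- (-outer(q, q) + 0.1 * outer(h, h, `+`)) / (outer(v, v, `+`) / 200)
  pa <- outer(h, h, `+`) / 2
  pc <- outer(v, v, pmin) / outer(v, v, pmax) + 0.2 * (outer(h, h) > 0)
  tabs <- list(contact_vol1 = cv1, contact_vol2 = cv2,
               prop_all_atom = pa, prop_calpha = pc)
  lapply(tabs, function(m) { dimnames(m) <- list(s$aa, s$aa); m })
}

#' Names of the 17 registered base descriptors
#'
#' The descriptor set is a registry: max/min full-residue and side-chain
#' exposed areas (`area_full_*`, `area_side_*`); max/min per-residue Gonnet
#' substitution scores and the same relative to the chain average
#' (`subst_*`, `subst_rel_*`); four residue-pair interaction scores averaged
#' over matched alignment rows (`contact_vol1`, `contact_vol2`,
#' `prop_all_atom`, `prop_calpha`); max/min column gap fraction
#' (`gap_frac_*`); max/min column gap count over the alignment's total gap
#' count (`gap_share_*`); and the pairwise co-occurrence log-odds score
#' (`cooccur`). Each base descriptor additionally yields `_a2o` and `_a2a`
#' neighborhood aggregates, for 51 features in total.
#'
#' @return character vector of descriptor names.
#' @export
descriptor_registry <- function() {
  c("area_full_max", "area_full_min", "area_side_max", "area_side_min",
    "subst_max", "subst_min", "subst_rel_max", "subst_rel_min",
    "contact_vol1", "contact_vol2", "prop_all_atom", "prop_calpha",
    "gap_frac_max", "gap_frac_min", "gap_share_max", "gap_share_min",
    "cooccur")
}

#' Assemble the inputs of the descriptor computation for one complex
#'
#' Collects, for the candidate residues of both partners, their alignment
#' columns, query amino acids, exposed areas, and the matched alignment rows,
#' so that [compute_base_descriptors()] can work from plain lookups.
#'
#' @param cand_a,cand_b candidate residue keys per partner.
#' @param pa a `paired_alignment` (queries mapped to the two chains).
#' @param struct_a,struct_b the partner structures.
#' @param areas_a,areas_b `residue_areas` for the partners.
#' @param chain_a,chain_b chain ids the alignments describe (default: first
#'   chain of each structure).
#' @param gonnet substitution matrix (default [gonnet_matrix()]).
#' @param pair_tables named list of four 20x20 pair tables (default
#'   [default_pair_tables()]).
#' @return an opaque context list consumed by [compute_base_descriptors()].
#' @export
descriptor_context <- function(cand_a, cand_b, pa, struct_a, struct_b,
                               areas_a, areas_b,
                               chain_a = NULL, chain_b = NULL,
                               gonnet = gonnet_matrix(),
                               pair_tables = default_pair_tables()) {
  stopifnot(inherits(pa, "paired_alignment"))
  side <- function(aln, rows, struct, areas, chain, cand) {
    chain <- chain %||% struct$residues$chain[1]
    seq <- structure_sequence(struct, chain)
    cols <- map_query_columns(aln, seq)
    ch_res <- struct$residues$res_key[struct$residues$chain == chain]
    idx <- match(cand, ch_res)
    if (anyNA(idx))
      stop("candidate residue(s) not in chain ", chain, ": ",
           paste(cand[is.na(idx)], collapse = ", "))
    mat <- do.call(rbind, strsplit(aln$seqs[rows], ""))
    list(cand = cand, col = cols[idx],
         qaa = strsplit(seq, "")[[1]][idx],
         area_full = areas$area_full[match(cand, areas$res_key)],
         area_side = areas$area_side[match(cand, areas$res_key)],
         all_cols = cols, all_qaa = strsplit(seq, "")[[1]],
         mat = mat)
  }
  list(a = side(pa$a, pa$pairs[, 1], struct_a, areas_a, chain_a, cand_a),
       b = side(pa$b, pa$pairs[, 2], struct_b, areas_b, chain_b, cand_b),
       gonnet = gonnet, tables = pair_tables)
}

# mean Gonnet score of the query aa against the column's amino acids over
# matched rows (gaps / non-standard letters skipped); NaN if nothing usable
subst_scores <- function(mat, cols, qaa, gonnet) {
  aa_ok <- rownames(gonnet)
  vapply(seq_along(cols), function(k) {
    col <- mat[, cols[k]]
    col <- col[col %in% aa_ok]
    if (length(col) == 0L || !(qaa[k] %in% aa_ok)) return(NaN)
    mean(gonnet[qaa[k], col])
  }, numeric(1))
}

#' Compute the 17 base descriptors for every candidate pair
#'
#' Per pair (a, b): max/min exposed areas (full residue and side-chain);
#' max/min per-residue substitution scores, where a residue's score is the
#' mean Gonnet score between its query amino acid and the amino acids in the
#' same column across matched rows (gaps skipped), and the same scores minus
#' the chain-average substitution score; four pair-table scores, each the
#' mean of `table[aa_a, aa_b]` over matched row pairs (rows with a gap in
#' either column skipped); max/min column gap fraction; max/min column gap
#' share (column gap count over the alignment's total gap count, matched rows
#' only); and the co-occurrence log-odds of the query amino-acid pair versus
#' the product of column marginals, with +1 pseudocounts.
#'
#' Descriptors that cannot be computed (e.g. a column entirely gapped in the
#' matched rows) are `NaN` and are imputed downstream with the training mean.
#'
#' @param ctx a context from [descriptor_context()].
#' @return named list of 17 numeric matrices (candidates of A x candidates
#'   of B), in [descriptor_registry()] order.
#' @export
compute_base_descriptors <- function(ctx) {
  A <- ctx$a; B <- ctx$b
  na <- length(A$cand); nb <- length(B$cand)
  pmax_ <- function(u, v) outer(u, v, pmax)
  pmin_ <- function(u, v) outer(u, v, pmin)

  sub_a <- subst_scores(A$mat, A$col, A$qaa, ctx$gonnet)
  sub_b <- subst_scores(B$mat, B$col, B$qaa, ctx$gonnet)
  prot_a <- mean(subst_scores(A$mat, A$all_cols, A$all_qaa, ctx$gonnet),
                 na.rm = TRUE)
  prot_b <- mean(subst_scores(B$mat, B$all_cols, B$all_qaa, ctx$gonnet),
                 na.rm = TRUE)

  gapf <- function(mat, cols) colMeans(mat[, cols, drop = FALSE] == "-")
  gf_a <- gapf(A$mat, A$col); gf_b <- gapf(B$mat, B$col)
  tot_gap_a <- sum(A$mat == "-"); tot_gap_b <- sum(B$mat == "-")
  gs <- function(mat, cols, tot)
    if (tot == 0) rep(0, length(cols)) else
      colSums(mat[, cols, drop = FALSE] == "-") / tot
  gs_a <- gs(A$mat, A$col, tot_gap_a); gs_b <- gs(B$mat, B$col, tot_gap_b)

  aa_ok <- rownames(ctx$gonnet)
  pair_mats <- lapply(ctx$tables, function(x) matrix(NaN, na, nb))
  cooc <- matrix(NaN, na, nb)
  for (i in seq_len(na)) {
    ca <- A$mat[, A$col[i]]
    for (j in seq_len(nb)) {
      cb <- B$mat[, B$col[j]]
      ok <- ca %in% aa_ok & cb %in% aa_ok
      if (any(ok)) {
        for (t in names(pair_mats))
          pair_mats[[t]][i, j] <- mean(ctx$tables[[t]][cbind(ca[ok], cb[ok])])
        n <- sum(ok)
        c_ab <- sum(ca[ok] == A$qaa[i] & cb[ok] == B$qaa[j])
        c_a <- sum(ca[ok] == A$qaa[i]); c_b <- sum(cb[ok] == B$qaa[j])
        cooc[i, j] <- log(((c_ab + 1) / (n + 1)) /
                            (((c_a + 1) / (n + 1)) * ((c_b + 1) / (n + 1))))
      }
    }
  }

  out <- list(
    area_full_max = pmax_(A$area_full, B$area_full),
    area_full_min = pmin_(A$area_full, B$area_full),
    area_side_max = pmax_(A$area_side, B$area_side),
    area_side_min = pmin_(A$area_side, B$area_side),
    subst_max = pmax_(sub_a, sub_b),
    subst_min = pmin_(sub_a, sub_b),
    subst_rel_max = pmax_(sub_a - prot_a, sub_b - prot_b),
    subst_rel_min = pmin_(sub_a - prot_a, sub_b - prot_b),
    contact_vol1 = pair_mats$contact_vol1,
    contact_vol2 = pair_mats$contact_vol2,
    prop_all_atom = pair_mats$prop_all_atom,
    prop_calpha = pair_mats$prop_calpha,
    gap_frac_max = pmax_(gf_a, gf_b),
    gap_frac_min = pmin_(gf_a, gf_b),
    gap_share_max = pmax_(gs_a, gs_b),
    gap_share_min = pmin_(gs_a, gs_b),
    cooccur = cooc)
  lapply(out, function(m) {
    dimnames(m) <- list(A$cand, B$cand)
    m
  })
}

#' Aggregate base descriptors over spatial neighborhoods
#'
#' For pair (a, b) and base descriptor D, the "all to one" aggregate is the
#' mean of D over the distinct pairs `{(a', b): a' in N(a)} U {(a, b'): b' in
#' N(b)}`, and the "all to all" aggregate is the mean over `N(a) x N(b)`.
#' Neighborhoods include the residue itself, so singleton neighborhoods
#' degenerate to the base value.
#'
#' @param base named list of base-descriptor matrices from
#'   [compute_base_descriptors()].
#' @param nbr_a,nbr_b neighborhood maps (from [build_neighborhoods()]) for
#'   the candidates indexing the matrix rows / columns.
#' @return list with elements `a2o` and `a2a`, each a named list of matrices
#'   parallel to `base`.
#' @export
aggregate_neighborhood <- function(base, nbr_a, nbr_b) {
  m1 <- base[[1]]
  ra <- rownames(m1); rb <- colnames(m1)
  ia <- lapply(nbr_a[ra], function(v) match(v, ra))
  ib <- lapply(nbr_b[rb], function(v) match(v, rb))
  if (any(vapply(c(ia, ib), anyNA, logical(1))))
    stop("neighborhood member outside the candidate set")
  na <- length(ra); nb <- length(rb)
  a2o <- a2a <- lapply(base, function(m) matrix(NA_real_, na, nb,
                                                dimnames = dimnames(m)))
  for (i in seq_len(na)) {
    Ni <- ia[[i]]
    for (j in seq_len(nb)) {
      Nj <- ib[[j]]
      one <- unique(rbind(cbind(Ni, j), cbind(i, Nj)))
      all_ <- as.matrix(expand.grid(Ni, Nj))
      for (d in names(base)) {
        a2o[[d]][i, j] <- mean(base[[d]][one], na.rm = FALSE)
        a2a[[d]][i, j] <- mean(base[[d]][all_], na.rm = FALSE)
      }
    }
  }
  list(a2o = a2o, a2a = a2a)
}

#' Fit / apply the [-1, 1] feature scaler
#'
#' Maps each feature linearly so the training data spans \[-1, 1\]:
#' `x -> 2 (x - min) / (max - min) - 1`. Test values outside the training
#' range are NOT clipped; constant training features map to 0.
#'
#' @param x numeric matrix or data.frame of training features.
#' @return `fit_feature_scaler()`: object of class `feature_scaler` (per
#'   feature min and max). `apply_feature_scaler()`: scaled matrix.
#' @export
fit_feature_scaler <- function(x) {
  x <- as.matrix(x)
  structure(list(min = apply(x, 2, min, na.rm = TRUE),
                 max = apply(x, 2, max, na.rm = TRUE),
                 names = colnames(x)),
            class = "feature_scaler")
}

#' @rdname fit_feature_scaler
#' @param scaler a `feature_scaler`.
#' @param newdata matrix/data.frame with the same columns as the training
#'   data.
#' @export
apply_feature_scaler <- function(scaler, newdata) {
  x <- as.matrix(newdata)
  rng <- scaler$max - scaler$min
  out <- sweep(sweep(x, 2, scaler$min), 2, ifelse(rng == 0, 1, rng), `/`)
  out <- 2 * out - 1
  out[, rng == 0] <- 0
  out
}

#' Build the labelled feature table for one complex
#'
#' End-to-end glue: computes exposed areas (unless given), selects surface
#' candidates at `cutoff`, builds intra-protein neighborhoods, computes the
#' 17 base descriptors for all candidate pairs plus their `_a2o` / `_a2a`
#' aggregates (51 features), and labels each pair by the true-contact
#' criterion if the partners are posed as the reference complex.
#'
#' @inheritParams descriptor_context
#' @param aln_a,aln_b `msa_alignment` objects for the two partners.
#' @param cutoff surface-area candidate cutoff (Angstrom^2, default 38).
#' @param contact_dist true-contact distance criterion (Angstrom, default 5).
#' @param label if `TRUE` (default) the structures are assumed posed in the
#'   reference complex and pairs are labelled via [find_contacts()];
#'   `FALSE` leaves labels `NA`.
#' @param impute replace `NaN` descriptor values by the column mean over the
#'   table (default `TRUE`); the affected columns are recorded in attribute
#'   `"imputed"`.
#' @return data.frame: `res_a`, `res_b`, `label`, then 51 feature columns.
#'   Attribute `"imputed"` lists imputed feature names.
#' @export
build_feature_table <- function(struct_a, struct_b, aln_a, aln_b,
                                areas_a = NULL, areas_b = NULL,
                                cutoff = 38, contact_dist = 5,
                                chain_a = NULL, chain_b = NULL,
                                label = TRUE, impute = TRUE,
                                gonnet = gonnet_matrix(),
                                pair_tables = default_pair_tables()) {
  areas_a <- areas_a %||% compute_residue_areas(struct_a)
  areas_b <- areas_b %||% compute_residue_areas(struct_b)
  cand_a <- select_surface_residues(areas_a, cutoff)
  cand_b <- select_surface_residues(areas_b, cutoff)
  if (length(cand_a) == 0L || length(cand_b) == 0L)
    stop("no candidate surface residues at cutoff ", cutoff)
  nbr_a <- build_neighborhoods(cand_a, find_contacts(struct_a, max_dist = contact_dist))
  nbr_b <- build_neighborhoods(cand_b, find_contacts(struct_b, max_dist = contact_dist))
  pa <- pair_rows_by_organism(aln_a, aln_b)
  ctx <- descriptor_context(cand_a, cand_b, pa, struct_a, struct_b,
                            areas_a, areas_b, chain_a, chain_b,
                            gonnet, pair_tables)
  base <- compute_base_descriptors(ctx)
  agg <- aggregate_neighborhood(base, nbr_a, nbr_b)

  grid <- expand.grid(ia = seq_along(cand_a), ib = seq_along(cand_b))
  feat <- list()
  for (d in names(base)) {
    feat[[d]] <- base[[d]][cbind(grid$ia, grid$ib)]
    feat[[paste0(d, "_a2o")]] <- agg$a2o[[d]][cbind(grid$ia, grid$ib)]
    feat[[paste0(d, "_a2a")]] <- agg$a2a[[d]][cbind(grid$ia, grid$ib)]
  }
  out <- data.frame(res_a = cand_a[grid$ia], res_b = cand_b[grid$ib],
                    stringsAsFactors = FALSE)
  if (label) {
    truth <- find_contacts(struct_a, struct_b, contact_dist)$pairs
    out$label <- paste(out$res_a, out$res_b) %in%
      paste(truth$res_a, truth$res_b)
  } else out$label <- NA
  out <- cbind(out, as.data.frame(feat))
  imputed <- character(0)
  if (impute) {
    for (cn in names(feat)) {
      bad <- !is.finite(out[[cn]])
      if (any(bad)) {
        imputed <- c(imputed, cn)
        fill <- mean(out[[cn]][!bad])
        out[[cn]][bad] <- if (is.finite(fill)) fill else 0
      }
    }
  }
  attr(out, "imputed") <- imputed
  out
}
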