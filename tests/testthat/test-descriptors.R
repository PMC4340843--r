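# two 2-residue partners with controllable alignments
mini_ctx <- function(fa, fb, area_a = c(50, 60), area_b = c(45, 70),
                     cand_a = c("A:1:", "A:2:"), cand_b = c("B:1:", "B:2:")) {
  sa <- make_structure(rbind(atom_row("A", 1, "CA", 0, 0, 0, "ALA"),
                             atom_row("A", 2, "CA", 4, 0, 0, "GLY")))
  sb <- make_structure(rbind(atom_row("B", 1, "CA", 0, 8, 0, "TRP"),
                             atom_row("B", 2, "CA", 4, 8, 0, "CYS")))
  areas_a <- data.frame(sa$residues, area_full = area_a,
                        area_side = area_a / 2)
  areas_b <- data.frame(sb$residues, area_full = area_b,
                        area_side = area_b / 2)
  pa <- pair_rows_by_organism(parse_alignment(fa, "fasta"),
                              parse_alignment(fb, "fasta"))
  descriptor_context(cand_a, cand_b, pa, sa, sb, areas_a, areas_b)
}

test_that("query-only alignments give Gonnet self-scores for D5/D6", {
  ctx <- suppressWarnings(mini_ctx(">qa OS=Q\nAG\n", ">qb OS=Q\nWC\n"))
  d <- compute_base_descriptors(ctx)
  G <- gonnet_matrix()
  # pair (A:1 [A], B:1 [W]): single matched row -> self substitution scores
  expect_equal(d$subst_max[1, 1], max(G["A", "A"], G["W", "W"]))
  expect_equal(d$subst_min[1, 1], min(G["A", "A"], G["W", "W"]))
  expect_equal(d$area_full_max[1, 1], 50)
  expect_equal(d$area_full_min[1, 1], 45)
  expect_equal(d$area_side_max[2, 2], 35)
})

test_that("substitution scores are the hand-computed column means", {
  # organism rows make column 1 of A hold {A (query), A, G}
  fa <- ">qa OS=Q\nAG\n>h1 OS=O1\nAG\n>h2 OS=O2\nGG\n"
  fb <- ">qb OS=Q\nWC\n>h1 OS=O1\nWC\n>h2 OS=O2\nWC\n"
  ctx <- mini_ctx(fa, fb)
  d <- compute_base_descriptors(ctx)
  G <- gonnet_matrix()
  sc_a1 <- mean(c(G["A", "A"], G["A", "A"], G["A", "G"]))
  sc_b1 <- G["W", "W"]
  expect_equal(d$subst_max[1, 1], max(sc_a1, sc_b1))
  expect_equal(d$subst_min[1, 1], min(sc_a1, sc_b1))
  # relative scores subtract each chain's average residue score
  sc_a2 <- G["G", "G"]
  prot_a <- mean(c(sc_a1, sc_a2))
  expect_equal(d$subst_rel_max[1, 1] + d$subst_rel_min[1, 1],
               (sc_a1 - prot_a) + (sc_b1 - mean(c(sc_b1, G["C", "C"]))))
})

test_that("pair-table scores average over matched rows, skipping gaps", {
  fa <- ">qa OS=Q\nAG\n>h1 OS=O1\nCG\n>h2 OS=O2\n-G\n"
  fb <- ">qb OS=Q\nWC\n>h1 OS=O1\nYC\n>h2 OS=O2\nWC\n"
  ctx <- mini_ctx(fa, fb)
  d <- compute_base_descriptors(ctx)
  tt <- default_pair_tables()$contact_vol1
  # pair (A1, B1): rows (A,W), (C,Y) — the gapped third row is skipped
  expect_equal(d$contact_vol1[1, 1], mean(c(tt["A", "W"], tt["C", "Y"])))
})

test_that("gap descriptors hit their boundary cases", {
  fa <- ">qa OS=Q\nAG\n>h1 OS=O1\n-G\n>h2 OS=O2\n-G\n"
  fb <- ">qb OS=Q\nWC\n>h1 OS=O1\nWC\n>h2 OS=O2\nWC\n"
  ctx <- mini_ctx(fa, fb)
  d <- compute_base_descriptors(ctx)
  # column 1 of A is gapped in 2 of 3 matched rows
  expect_equal(d$gap_frac_max[1, 1], 2 / 3)
  expect_equal(d$gap_frac_min[1, 1], 0)
  expect_equal(d$gap_share_max[1, 1], 1)   # all of A's gaps sit in column 1
  # an all-gap column (including the query row is impossible, but the
  # non-query rows can be) still yields finite gap stats and NaN pair scores
  ctx2 <- mini_ctx(">qa OS=Q\nAG\n>h1 OS=O1\n-G\n",
                   ">qb OS=Q\nWC\n>h1 OS=O1\n-C\n")
  d2 <- compute_base_descriptors(ctx2)
  expect_equal(d2$gap_frac_max[1, 1], 0.5)
})

test_that("an unalignable descriptor is NaN and gets imputed downstream", {
  # a non-standard residue (sequence letter X) has no substitution score
  toy <- make_toy_complex(n_res = c(4, 4), n_contacts = 2, seed = 8)
  toy$a$residues$resname[4] <- "UNK"
  toy$a$atoms$resname[toy$a$atoms$resno == 4] <- "UNK"
  syn <- make_synthetic_alignments(toy, n_org = 4, gap_rate = 0, seed = 8)
  ft <- build_feature_table(toy$a, toy$b, syn$aln_a, syn$aln_b, cutoff = 0)
  expect_true(all(is.finite(as.matrix(ft[, -(1:3)]))))
  expect_true(length(attr(ft, "imputed")) > 0)
  ft_raw <- build_feature_table(toy$a, toy$b, syn$aln_a, syn$aln_b,
                                cutoff = 0, impute = FALSE)
  expect_true(any(!is.finite(as.matrix(ft_raw[, -(1:3)]))))
})

test_that("the all-gap-column corruption gaps a contact column fully", {
  toy <- make_toy_complex(n_res = c(4, 4), n_contacts = 2, seed = 8)
  syn <- make_synthetic_alignments(toy, n_org = 5, gap_rate = 0, seed = 8,
                                   corrupt = "all_gap_column")
  col <- syn$contact_cols[1, "a"]
  rows <- syn$paired$pairs[, 1]
  chars <- substr(syn$aln_a$seqs[rows], col, col)
  expect_true(all(chars[-1] == "-"))  # every non-query matched row gapped
})

test_that("neighborhood aggregation reproduces hand means and brute force", {
  base <- list(D = matrix(c(1, 3, 5, 7), 2, 2,
                          dimnames = list(c("a", "a2"), c("b", "b2"))))
  # singletons: both aggregates equal the base value
  nbr1 <- list(a = "a", a2 = "a2"); nbr2 <- list(b = "b", b2 = "b2")
  agg <- aggregate_neighborhood(base, nbr1, nbr2)
  expect_equal(agg$a2o$D, base$D)
  expect_equal(agg$a2a$D, base$D)
  # N(a) = {a, a2}, N(b) = {b}: D(a,b)=1, D(a2,b)=3 -> both aggregates 2
  nbrA <- list(a = c("a", "a2"), a2 = "a2")
  agg2 <- aggregate_neighborhood(base, nbrA, nbr2)
  expect_equal(agg2$a2o$D["a", "b"], 2)
  expect_equal(agg2$a2a$D["a", "b"], 2)
})

test_that("aggregates match an exhaustive double loop on random toys", {
  set.seed(13)
  for (rep in 1:3) {
    na <- 5; nb <- 4
    ra <- paste0("a", 1:na); rb <- paste0("b", 1:nb)
    M <- matrix(rnorm(na * nb), na, nb, dimnames = list(ra, rb))
    nbrA <- setNames(lapply(ra, function(r)
      unique(c(r, sample(ra, sample(0:3, 1))))), ra)
    nbrB <- setNames(lapply(rb, function(r)
      unique(c(r, sample(rb, sample(0:2, 1))))), rb)
    # symmetrize to honest neighborhoods
    for (r1 in ra) for (r2 in ra)
      if (r2 %in% nbrA[[r1]]) nbrA[[r2]] <- unique(c(nbrA[[r2]], r1))
    for (r1 in rb) for (r2 in rb)
      if (r2 %in% nbrB[[r1]]) nbrB[[r2]] <- unique(c(nbrB[[r2]], r1))
    agg <- aggregate_neighborhood(list(D = M), nbrA, nbrB)
    for (i in seq_len(na)) for (j in seq_len(nb)) {
      Ni <- nbrA[[ra[i]]]; Nj <- nbrB[[rb[j]]]
      one <- unique(rbind(cbind(match(Ni, ra), j),
                          cbind(i, match(Nj, rb))))
      vals_one <- apply(one, 1, function(p) M[p[1], p[2]])
      vals_all <- as.vector(M[match(Ni, ra), match(Nj, rb), drop = FALSE])
      expect_equal(agg$a2o$D[i, j], mean(vals_one))
      expect_equal(agg$a2a$D[i, j], mean(vals_all))
    }
  }
})

test_that("feature scaling maps training range to [-1, 1] without clipping", {
  x <- cbind(f1 = c(0, 10, 5), f2 = c(3, 3, 3))
  sc <- fit_feature_scaler(x)
  got <- apply_feature_scaler(sc, x)
  expect_equal(got[, "f1"], c(-1, 1, 0))
  expect_equal(got[, "f2"], c(0, 0, 0))  # constant feature -> 0
  expect_equal(unname(apply_feature_scaler(sc, cbind(f1 = 15, f2 = 3))[, "f1"]),
               2)  # outside the training range, unclipped
})

test_that("scaling then unscaling is the identity for varying features", {
  set.seed(3)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("u", "v", "w")))
  sc <- fit_feature_scaler(x)
  y <- apply_feature_scaler(sc, x)
  back <- sweep(sweep((y + 1) / 2, 2, sc$max - sc$min, `*`), 2, sc$min, `+`)
  expect_equal(back, x, tolerance = 1e-12)
})

test_that("descriptors ignore alignment row order and unmatched rows", {
  fa <- ">qa OS=Q\nAG\n>h1 OS=O1\nCG\n>h2 OS=O2\nGG\n"
  fb <- ">qb OS=Q\nWC\n>h1 OS=O1\nYC\n>h2 OS=O2\nWC\n"
  d1 <- compute_base_descriptors(mini_ctx(fa, fb))
  # swap the two homolog rows of A, and add an unmatched organism to B
  fa2 <- ">qa OS=Q\nAG\n>h2 OS=O2\nGG\n>h1 OS=O1\nCG\n"
  fb2 <- paste0(fb, ">x OS=Nowhere\nMM\n")
  d2 <- compute_base_descriptors(mini_ctx(fa2, fb2))
  for (nm in names(d1)) expect_equal(d2[[nm]], d1[[nm]], label = nm)
})

test_that("the packaged Gonnet matrix is symmetric with the expected scale", {
  G <- gonnet_matrix()
  expect_equal(G, t(G))
  expect_equal(unname(diag(G)["C" == rownames(G)]), 11.5)
  expect_true(all(diag(G) > 0))
  tabs <- default_pair_tables()
  expect_equal(length(tabs), 4L)
  for (tt in tabs) expect_equal(tt, t(tt))
})
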