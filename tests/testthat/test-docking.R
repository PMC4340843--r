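test_that("digitization matches a per-cell center test for one atom", {
  s <- make_structure(atom_row("A", 1, "C1", 0.3, -0.2, 0.7))
  g <- digitize(s, resolution = 1, surface_margin = 1.5)
  # oracle: count lattice centers within r of the atom
  centers <- as.matrix(expand.grid(x = seq(-6.5, 6.5, 1),
                                   y = seq(-6.5, 6.5, 1),
                                   z = seq(-6.5, 6.5, 1)))
  d <- sqrt(rowSums(sweep(centers, 2, c(0.3, -0.2, 0.7))^2))
  expect_equal(nrow(g$core), sum(d <= 1.7))
  expect_equal(nrow(g$surface), sum(d > 1.7 & d <= 3.2))
  # the atom's own cell is core
  own <- floor(c(0.3, -0.2, 0.7) / 1 - g$origin)
  expect_true(any(g$core[, 1] == own[1] & g$core[, 2] == own[2] &
                    g$core[, 3] == own[3]))
})

test_that("zero surface margin leaves an empty surface layer", {
  s <- make_structure(atom_row("A", 1, "C1", 0, 0, 0))
  g <- digitize(s, surface_margin = 0)
  expect_equal(nrow(g$surface), 0L)
  expect_gt(nrow(g$core), 0L)
})

test_that("translating a structure by one cell shifts the lattice sets", {
  toy <- make_toy_complex(n_res = c(2, 2), n_contacts = 1, seed = 4)
  g1 <- digitize(toy$a)
  s2 <- toy$a
  s2$atoms$x <- s2$atoms$x + 1
  g2 <- digitize(s2)
  shift <- round((g1$origin - g2$origin) / g1$resolution) + c(1, 0, 0)
  moved <- sweep(g1$core, 2, -shift, `-`)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_setequal(key(moved), key(g2$core))
})

test_that("the translational scan equals brute-force enumeration", {
  toy <- make_toy_complex(n_res = c(2, 2), n_contacts = 1, seed = 6)
  g_a <- digitize(toy$a); g_b <- digitize(toy$b)
  got <- search_translations(g_a, g_b, core_overlap_tol = 0)
  want <- brute_scan(g_a, g_b, core_tol = 0)
  key <- function(tx, ty, tz) paste(tx, ty, tz)
  got_k <- key(got$tx, got$ty, got$tz)
  want_k <- key(want[, "tx"], want[, "ty"], want[, "tz"])
  expect_setequal(got_k, want_k)
  expect_equal(got$score[match(want_k, got_k)], unname(want[, "score"]))
})

test_that("an empty allowed region yields no translations", {
  toy <- make_toy_complex(n_res = c(2, 2), n_contacts = 1, seed = 4)
  g_a <- digitize(toy$a); g_b <- digitize(toy$b)
  st <- search_translations(g_a, g_b, region = matrix(0L, 0, 3))
  expect_equal(nrow(st), 0L)
})

test_that("region-restricted scores agree with the unrestricted scan", {
  toy <- make_toy_complex(n_res = c(3, 3), n_contacts = 2, seed = 9)
  g_a <- digitize(toy$a); g_b <- digitize(toy$b)
  full <- search_translations(g_a, g_b)
  region <- as.matrix(full[seq(1, nrow(full), by = 7), c("tx", "ty", "tz")])
  sub <- search_translations(g_a, g_b, region = region)
  key <- function(d) paste(d$tx, d$ty, d$tz)
  m <- match(key(sub), key(full))
  expect_true(!anyNA(m))
  expect_equal(sub$score, full$score[m])
})

test_that("surface scores are symmetric under swapping the partners", {
  toy <- make_toy_complex(n_res = c(2, 3), n_contacts = 1, seed = 10)
  g_a <- digitize(toy$a); g_b <- digitize(toy$b)
  ab <- search_translations(g_a, g_b)
  ba <- search_translations(g_b, g_a)
  key <- function(tx, ty, tz) paste(tx, ty, tz)
  m <- match(key(-ab$tx, -ab$ty, -ab$tz), key(ba$tx, ba$ty, ba$tz))
  expect_true(!anyNA(m))
  expect_equal(ba$score[m], ab$score)
})

test_that("single-atom constraint regions are exact lattice balls", {
  sa <- make_structure(atom_row("A", 1, "C1", 0, 0, 0))
  sb <- make_structure(atom_row("B", 1, "C1", 10, 0, 0))
  g_a <- digitize(sa); g_b <- digitize(sb)
  cn <- list(res_a = "A:1:", res_b = "B:1:", max_dist = 5)
  region <- prune_with_constraint(cn, sa, sb, g_a, g_b, slack = 0)
  # oracle: translations whose cartesian offset keeps the atoms within 5
  shift <- g_a$origin - g_b$origin
  d0 <- c(0, 0, 0) - c(10, 0, 0)
  ok <- sqrt(rowSums(sweep(sweep(region, 2, -shift, `-`), 2, d0)^2))
  expect_true(all(ok <= 5 + 1e-9))
  # region volume grows with max_dist
  r2 <- prune_with_constraint(list(res_a = "A:1:", res_b = "B:1:",
                                   max_dist = 8), sa, sb, g_a, g_b,
                              slack = 0)
  expect_gt(nrow(r2), nrow(region))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_true(all(key(region) %in% key(r2)))   # nesting
})

test_that("pruning is sound: no exactly-satisfying translation is lost", {
  for (seed in 1:10) {
    toy <- make_toy_complex(n_res = c(2, 2), n_contacts = 1, seed = seed)
    g_a <- digitize(toy$a); g_b <- digitize(toy$b)
    cn <- list(res_a = toy$contacts$pairs$res_a[1],
               res_b = toy$contacts$pairs$res_b[1], max_dist = 5)
    region <- prune_with_constraint(cn, toy$a, toy$b, g_a, g_b, slack = 3)
    want <- brute_constraint_translations(cn, toy$a, toy$b, g_a, g_b)
    key <- paste(region[, 1], region[, 2], region[, 3])
    expect_true(all(want %in% key))
  }
})

test_that("constrained models satisfy their constraint and scan fewer cells", {
  toy <- make_toy_complex(seed = 15)
  cn <- data.frame(res_a = toy$contacts$pairs$res_a[1],
                   res_b = toy$contacts$pairs$res_b[1], max_dist = 5)
  res <- run_constrained_docking(toy$a, toy$b, constraints = cn,
                                 models_per_constraint = 8)
  expect_gt(nrow(res$models), 0)
  for (i in seq_len(nrow(res$models))) {
    sb <- apply_dock_model(toy$b, res, i)
    d <- find_contacts(toy$a, sb, 5)$pairs
    hit <- d$res_a == cn$res_a & d$res_b == cn$res_b
    expect_true(any(hit))
  }
  # the constraint scans no more translations than the unconstrained run
  g_a <- digitize(toy$a); g_b <- digitize(toy$b)
  constrained <- search_translations(
    g_a, g_b, prune_with_constraint(as.list(cn[1, ]), toy$a, toy$b,
                                    g_a, g_b))
  full <- search_translations(g_a, g_b)
  expect_lte(nrow(constrained), nrow(full))
})

test_that("a true-contact constraint recovers the planted pose", {
  hits <- 0
  for (seed in 1:5) {
    toy <- make_toy_complex(seed = seed)
    cn <- data.frame(res_a = "A:1:", res_b = "B:1:", max_dist = 5)
    res <- run_constrained_docking(toy$a, toy$b, constraints = cn,
                                   models_per_constraint = 50)
    g_a <- digitize(toy$a); g_b <- digitize(toy$b)
    t_true <- round((g_b$origin - g_a$origin) / 1)
    m <- res$models
    d <- pmax(abs(m$tx - t_true[1]), abs(m$ty - t_true[2]),
              abs(m$tz - t_true[3]))
    hits <- hits + any(d <= 2)
  }
  expect_gte(hits, 4)
})

test_that("cross-constraint sampling uses largest-remainder quotas", {
  mk_models <- function(k, n_each) {
    data.table::rbindlist(lapply(seq_len(k), function(ci)
      data.table::data.table(constraint = sprintf("c%03d", ci),
                             rot = 1L, tx = seq_len(n_each) + 100L * ci,
                             ty = 0L, tz = 0L, score = n_each:1)))
  }
  m100 <- mk_models(100, 12)
  s500 <- sample_across_constraints(m100, 500)
  expect_true(all(attr(s500, "quota") == 5))
  expect_equal(nrow(s500), 500L)
  s1000 <- sample_across_constraints(m100, 1000)
  expect_true(all(attr(s1000, "quota") == 10))
  q <- attr(sample_across_constraints(mk_models(3, 10), 10), "quota")
  expect_equal(unname(q), c(4, 3, 3))
  expect_error(sample_across_constraints(mk_models(3, 5), 2), "smaller")
})

test_that("duplicate placements collapse to a single retained model", {
  m <- data.table::data.table(
    constraint = c("c1", "c1", "c2", "c2"),
    rot = 1L, tx = c(1L, 2L, 1L, 3L), ty = 0L, tz = 0L,
    score = c(9, 8, 9, 7))
  out <- sample_across_constraints(m, 4)
  expect_equal(nrow(out), 3L)   # (1,0,0) kept once
  expect_equal(sort(out$tx), c(1L, 2L, 3L))
})

test_that("rotation generators are well-formed", {
  rots <- rotation_grid(step_deg = 90)
  expect_true(all(vapply(rots, function(R)
    abs(det(R) - 1) < 1e-9 && max(abs(crossprod(R) - diag(3))) < 1e-9,
    logical(1))))
  expect_equal(rots[[1]], diag(3))
  rnd <- random_rotations(5, seed = 3)
  expect_true(all(vapply(rnd, function(R)
    abs(det(R) - 1) < 1e-9 && max(abs(crossprod(R) - diag(3))) < 1e-9,
    logical(1))))
  expect_equal(random_rotations(5, seed = 3), rnd)  # seeded determinism
})
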