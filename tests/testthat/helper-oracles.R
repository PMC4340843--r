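# Independent oracles and tiny fixture builders used across the suite.
# These deliberately avoid the package's own code paths wherever they check
# one: brute-force loops, closed forms, and literal formula transcriptions.

# one PDB ATOM line with full control over the fields
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, elem = "C", alt = "", icode = "") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), alt,
          resname, chain, resno, ifelse(icode == "", " ", icode),
          x, y, z, occ, 0, elem)
}

# ad-hoc structure straight from an atom table (bypasses the PDB parser)
make_structure <- function(atoms, id = "fixture") {
  atoms$icode <- atoms$icode %||% ""
  atoms$occ <- atoms$occ %||% 1
  atoms$res_key <- condock::residue_key(atoms$chain, atoms$resno, atoms$icode)
  res <- atoms[!duplicated(atoms$res_key),
               c("chain", "resno", "icode", "resname", "res_key")]
  rownames(res) <- rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, residues = res),
            class = "dock_structure")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

atom_row <- function(chain, resno, elety, x, y, z, resname = "ALA",
                     element = "C") {
  data.frame(chain = chain, resno = resno, icode = "", resname = resname,
             elety = elety, element = element, x = x, y = y, z = z, occ = 1,
             stringsAsFactors = FALSE)
}

# O(n^2) residue-contact oracle: plain double loop over residue pairs
brute_contacts <- function(s_a, s_b, max_dist) {
  out <- list()
  for (ra in s_a$residues$res_key) for (rb in s_b$residues$res_key) {
    pa <- condock::structure_coords(s_a, ra)
    pb <- condock::structure_coords(s_b, rb)
    dmin <- Inf
    for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb)))
      dmin <- min(dmin, sqrt(sum((pa[i, ] - pb[j, ])^2)))
    if (dmin <= max_dist) out[[length(out) + 1L]] <- c(ra, rb)
  }
  if (length(out) == 0L) return(character(0))
  sort(vapply(out, paste, character(1), collapse = " "))
}

# independent Shrake-Rupley with its own (random, seeded) sphere points
brute_sasa_atom <- function(xyz, radii, probe, n_pts = 9600, seed = 99) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n_pts), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  n <- nrow(xyz)
  rr <- radii + probe
  vapply(seq_len(n), function(i) {
    p <- sweep(u * rr[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_pts)
    for (j in seq_len(n)[-i]) {
      dj <- rowSums(sweep(p, 2, xyz[j, ])^2)
      acc <- acc & dj >= rr[j]^2
    }
    4 * pi * rr[i]^2 * mean(acc)
  }, numeric(1))
}

# literal transcription of the extended R-precision definition
rprec_literal <- function(labels_in_rank_order) {
  lab <- as.integer(labels_in_rank_order)
  R <- sum(lab)
  highestTrue <- min(which(lab == 1))
  if (highestTrue <= R) sum(lab[1:R]) / R else 1 - highestTrue / R
}

# brute-force NBC score: recompute histogram probabilities from scratch with
# the model's edges and raw training data, then take the log product ratio
brute_nbc_score <- function(x_row, train_x, train_y, model) {
  pk <- c(mean(!train_y), mean(train_y))
  ll <- numeric(2)
  for (k in 1:2) {
    cls <- c(FALSE, TRUE)[k]
    xk <- train_x[train_y == cls, , drop = FALSE]
    nb <- model$n_bins[k]
    prod_log <- log(pk[k])
    for (i in seq_len(ncol(train_x))) {
      e <- model$edges[[k]][, i]
      cnt <- integer(nb)
      for (v in xk[, i]) {
        b <- max(1, min(nb, findInterval(v, e)))
        cnt[b] <- cnt[b] + 1L
      }
      b <- max(1, min(nb, findInterval(x_row[i], e)))
      prod_log <- prod_log + log((cnt[b] + 1) / (nrow(xk) + nb))
    }
    ll[k] <- prod_log
  }
  ll[2] - ll[1]
}

# greedy forward selection (beam of 1), written independently
greedy_forward <- function(tables, max_size, n_folds, seed) {
  pool <- colnames(tables[[1]]$x)
  chosen <- character(0)
  out <- list()
  for (s in seq_len(max_size)) {
    cand <- setdiff(pool, chosen)
    scores <- vapply(cand, function(f)
      as.numeric(condock::cross_validate(tables, n_folds = n_folds,
                                         features = sort(c(chosen, f)),
                                         seed = seed)), numeric(1))
    best <- cand[order(-scores, cand)][1]
    chosen <- sort(c(chosen, best))
    out[[s]] <- list(subset = chosen, score = max(scores))
  }
  out
}

# all surface-overlap scores by explicit per-translation set intersection
brute_scan <- function(g_a, g_b, core_tol = 0) {
  enc <- function(m) (m[, 1] + 1024) + 2048 * (m[, 2] + 1024) +
    2048^2 * (m[, 3] + 1024)
  sa <- enc(g_a$surface); sb <- enc(g_b$surface)
  ca <- enc(g_a$core); cb <- enc(g_b$core)
  az <- rbind(g_a$core, g_a$surface); bz <- rbind(g_b$core, g_b$surface)
  rng <- lapply(1:3, function(d)
    (min(az[, d]) - max(bz[, d])):(max(az[, d]) - min(bz[, d])))
  out <- list()
  for (tx in rng[[1]]) for (ty in rng[[2]]) for (tz in rng[[3]]) {
    off <- tx + 2048 * ty + 2048^2 * tz
    co <- sum((cb + off) %in% ca)
    if (co > core_tol) next
    sc <- sum((sb + off) %in% sa)
    out[[length(out) + 1L]] <- c(tx, ty, tz, sc, co)
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("tx", "ty", "tz", "score", "core_overlap")
  m
}

# lattice translations exactly satisfying a residue-distance constraint:
# union of lattice balls around every atom-pair difference
brute_constraint_translations <- function(cn, s_a, s_b_rot, g_a, g_b) {
  pa <- condock::structure_coords(s_a, cn$res_a)
  pb <- condock::structure_coords(s_b_rot, cn$res_b)
  res <- g_a$resolution
  shift <- g_a$origin - g_b$origin
  keys <- vector("list", nrow(pa) * nrow(pb))
  n <- 0L
  rad <- cn$max_dist / res
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb))) {
    d <- pa[i, ] - pb[j, ]
    ctr <- (d - shift) / res
    g <- as.matrix(expand.grid(
      ceiling(ctr[1] - rad):floor(ctr[1] + rad),
      ceiling(ctr[2] - rad):floor(ctr[2] + rad),
      ceiling(ctr[3] - rad):floor(ctr[3] + rad)))
    t_cart <- sweep(g * res, 2, -shift, `-`)
    ok <- sqrt(rowSums(sweep(t_cart, 2, d)^2)) <= cn$max_dist
    n <- n + 1L
    keys[[n]] <- paste(g[ok, 1], g[ok, 2], g[ok, 3])
  }
  unique(unlist(keys))
}
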