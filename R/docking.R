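# cell-key encoding: integer cells (i, j, k) packed into one double so that
# key differences are themselves packed translations (|component| < 1024)
.KB <- 2048
cell_encode <- function(ijk) {
  (ijk[, 1] + 1024) + .KB * (ijk[, 2] + 1024) + .KB^2 * (ijk[, 3] + 1024)
}
diff_decode <- function(d) {
  dk <- round(d / .KB^2); r <- d - dk * .KB^2
  dj <- round(r / .KB);   di <- r - dj * .KB
  cbind(di, dj, dk)
}

#' Digitize a structure onto a cubic grid
#'
#' BiGGER-style digitization: core cells are those whose center lies within
#' the vdW radius of any heavy atom; surface cells lie within vdW +
#' `surface_margin` but are not core. Cell `(i, j, k)` has its center at
#' `origin + (i + 0.5) * resolution` per axis.
#'
#' @param s a `dock_structure`.
#' @param resolution cell edge in Angstrom (default 1).
#' @param surface_margin thickness of the surface layer in Angstrom
#'   (default 1.5).
#' @return object of class `dock_grid`: `resolution`, `origin`, integer cell
#'   matrices `core` and `surface`.
#' @export
digitize <- function(s, resolution = 1, surface_margin = 1.5) {
  stopifnot(inherits(s, "dock_structure"), resolution > 0,
            surface_margin >= 0)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  r_core <- vdw_radius(s$atoms$element)
  r_out <- r_core + surface_margin
  origin <- floor((apply(xyz, 2, min) - max(r_out)) / resolution - 1) * resolution
  cells <- list(); dmin <- list()
  for (a in seq_len(nrow(xyz))) {
    lo <- floor((xyz[a, ] - r_out[a] - origin) / resolution - 0.5)
    hi <- ceiling((xyz[a, ] + r_out[a] - origin) / resolution - 0.5)
    g <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    ctr <- sweep((g + 0.5) * resolution, 2, -origin, `-`)
    d <- sqrt(rowSums((ctr - matrix(xyz[a, ], nrow(g), 3, byrow = TRUE))^2))
    keep <- d <= r_out[a]
    cells[[a]] <- g[keep, , drop = FALSE]
    dmin[[a]] <- ifelse(d[keep] <= r_core[a], 0, 1) # 0 = core, 1 = surface
  }
  allc <- do.call(rbind, cells)
  lvl <- unlist(dmin)
  key <- cell_encode(allc)
  # a cell touched by several atoms is core if core for any atom
  ord <- order(key, lvl)
  first <- !duplicated(key[ord])
  allc <- allc[ord, , drop = FALSE][first, , drop = FALSE]
  lvl <- lvl[ord][first]
  structure(list(resolution = resolution, origin = origin,
                 core = allc[lvl == 0, , drop = FALSE],
                 surface = allc[lvl == 1, , drop = FALSE]),
            class = "dock_grid")
}

#' @export
print.dock_grid <- function(x, ...) {
  cat(sprintf("<dock_grid: %g Angstrom cells, %d core, %d surface>\n",
              x$resolution, nrow(x$core), nrow(x$surface)))
  invisible(x)
}

# Cartesian translation applied to the ligand for lattice translation t
lattice_to_cartesian <- function(g_a, g_b, t) {
  sweep(t * g_a$resolution, 2, g_b$origin - g_a$origin, `-`)
}

#' Scan lattice translations of the ligand grid over the receptor grid
#'
#' Enumerates ligand translations (all translations where the two grids'
#' bounding boxes can intersect, or only `region` if given) and scores each
#' by the number of overlapping surface-surface cell pairs; translations with
#' more than `core_overlap_tol` core-core overlaps are discarded. The scan is
#' a cross-correlation: every (surface A, surface B) cell pair votes for the
#' translation that superimposes them.
#'
#' @param g_a,g_b `dock_grid`s of receptor and (rotated) ligand; resolutions
#'   must match.
#' @param region optional integer matrix of allowed translations (columns
#'   tx, ty, tz), e.g. from [prune_with_constraint()].
#' @param core_overlap_tol maximum tolerated core-core cell overlaps
#'   (default 0, hard core).
#' @return data.table with `tx`, `ty`, `tz`, `score`, `core_overlap`,
#'   ordered by decreasing score then (tz, ty, tx).
#' @export
search_translations <- function(g_a, g_b, region = NULL, core_overlap_tol = 0) {
  stopifnot(inherits(g_a, "dock_grid"), inherits(g_b, "dock_grid"),
            isTRUE(all.equal(g_a$resolution, g_b$resolution)))
  tab <- function(ka, kb) {
    if (length(ka) == 0L || length(kb) == 0L)
      return(data.table(dkey = numeric(0), n = integer(0)))
    d <- as.vector(outer(ka, kb, `-`))
    data.table(dkey = d)[, list(n = .N), by = "dkey"]
  }
  surf <- tab(cell_encode(g_a$surface), cell_encode(g_b$surface))
  core <- tab(cell_encode(rbind(g_a$core)), cell_encode(rbind(g_b$core)))
  if (is.null(region)) {
    az <- rbind(g_a$core, g_a$surface); bz <- rbind(g_b$core, g_b$surface)
    rng <- lapply(1:3, function(d)
      (min(az[, d]) - max(bz[, d])):(max(az[, d]) - min(bz[, d])))
    region <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  } else {
    region <- as.matrix(region)
    if (nrow(region) == 0L)
      return(data.table(tx = integer(0), ty = integer(0), tz = integer(0),
                        score = integer(0), core_overlap = integer(0)))
  }
  rkey <- cell_encode(region) - cell_encode(matrix(0L, 1, 3))[1]
  sc <- surf$n[match(rkey, surf$dkey)]
  co <- core$n[match(rkey, core$dkey)]
  out <- data.table(tx = region[, 1], ty = region[, 2], tz = region[, 3],
                    score = ifelse(is.na(sc), 0L, sc),
                    core_overlap = ifelse(is.na(co), 0L, co))
  score <- core_overlap <- tz <- ty <- tx <- NULL
  out <- out[core_overlap <= core_overlap_tol]
  setorder(out, -score, tz, ty, tx)
  out
}

#' Translation region allowed by a residue-contact constraint
#'
#' A constraint requires one residue of each partner to come within
#' `max_dist` Angstrom. For a fixed ligand rotation, every translation that
#' can satisfy the constraint must place the ligand residue's centroid within
#' `max_dist + rho_a + rho_b + slack` of the receptor residue's centroid
#' (rho = centroid-to-farthest-atom radius of each residue), so the returned
#' lattice ball is a guaranteed superset of all exactly-satisfying
#' translations: pruning with it is sound.
#'
#' @param constraint list/row with `res_a`, `res_b`, `max_dist`.
#' @param s_a receptor structure; `s_b_rot` the ligand structure already
#'   rotated as docked.
#' @param g_a,g_b the corresponding `dock_grid`s.
#' @param slack extra radius in Angstrom absorbing grid discretization
#'   (default 3).
#' @return integer matrix of allowed translations (columns tx, ty, tz).
#' @export
prune_with_constraint <- function(constraint, s_a, s_b_rot, g_a, g_b,
                                  slack = 3) {
  stopifnot(slack >= 0, constraint$max_dist > 0)
  pa <- structure_coords(s_a, res_keys = constraint$res_a)
  pb <- structure_coords(s_b_rot, res_keys = constraint$res_b)
  if (nrow(pa) == 0L) stop("constraint residue not found in receptor: ",
                           constraint$res_a)
  if (nrow(pb) == 0L) stop("constraint residue not found in ligand: ",
                           constraint$res_b)
  ca <- colMeans(pa); cb <- colMeans(pb)
  rho_a <- if (nrow(pa) == 1L) 0 else max(sqrt(rowSums(sweep(pa, 2, ca)^2)))
  rho_b <- if (nrow(pb) == 1L) 0 else max(sqrt(rowSums(sweep(pb, 2, cb)^2)))
  D <- constraint$max_dist + rho_a + rho_b + slack
  res <- g_a$resolution
  # want |d0 - t_cart| <= D with t_cart = t*res - (origin_b - origin_a)
  d0 <- ca - cb
  center <- (d0 + (g_b$origin - g_a$origin)) / res
  rad <- D / res
  rng <- lapply(1:3, function(d) ceiling(center[d] - rad):floor(center[d] + rad))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  keep <- rowSums(sweep(g, 2, center)^2) <= rad^2
  m <- g[keep, , drop = FALSE]
  colnames(m) <- c("tx", "ty", "tz")
  m
}

#' Euler-grid and random rotation sampling
#'
#' `rotation_grid()` builds a deterministic ZYZ Euler-angle grid (identity
#' first); `random_rotations()` draws uniform random rotations from
#' normalized quaternions.
#'
#' @param step_deg Euler step in degrees (default 24).
#' @return list of 3x3 rotation matrices.
#' @export
rotation_grid <- function(step_deg = 24) {
  ang <- function(to) seq(0, to - step_deg, by = step_deg) * pi / 180
  rots <- list()
  for (a in ang(360)) for (b in c(seq(0, 180, by = step_deg) * pi / 180))
    for (g in ang(360)) {
      if (b %in% c(0, pi) && g > 0) next # gimbal-redundant
      rots[[length(rots) + 1L]] <- euler_zyz(a, b, g)
    }
  rots
}

euler_zyz <- function(a, b, g) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
  rz(a) %*% ry(b) %*% rz(g)
}

#' @rdname rotation_grid
#' @param n number of rotations.
#' @param seed RNG seed.
#' @export
random_rotations <- function(n, seed = 1) {
  with_seed(seed, lapply(seq_len(n), function(i) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    quat_to_rot(q)
  }))
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3)
}

rot_to_quat <- function(R) {
  w <- sqrt(max(0, 1 + R[1, 1] + R[2, 2] + R[3, 3])) / 2
  if (w > 1e-8) {
    c(w, (R[2, 3] - R[3, 2]) / (4 * w) * -1,
      (R[3, 1] - R[1, 3]) / (4 * w) * -1,
      (R[1, 2] - R[2, 1]) / (4 * w) * -1)
  } else {
    x <- sqrt(max(0, 1 + R[1, 1] - R[2, 2] - R[3, 3])) / 2
    c(w, x, (R[1, 2] + R[2, 1]) / (4 * x), (R[1, 3] + R[3, 1]) / (4 * x))
  }
}

#' Rotate a structure about its heavy-atom centroid
#'
#' @param s a `dock_structure`.
#' @param rotation 3x3 rotation matrix.
#' @return rotated `dock_structure`.
#' @export
rotate_structure <- function(s, rotation) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  new <- sweep(sweep(xyz, 2, ctr) %*% t(rotation), 2, -ctr, `-`)
  s$atoms[, c("x", "y", "z")] <- new
  s
}

translate_structure <- function(s, t_cart) {
  s$atoms$x <- s$atoms$x + t_cart[1]
  s$atoms$y <- s$atoms$y + t_cart[2]
  s$atoms$z <- s$atoms$z + t_cart[3]
  s
}

#' Constraint-pruned rigid-body docking
#'
#' For each sampled ligand rotation and each constraint, scans only the
#' translations allowed by the constraint's pruning region, verifies the
#' constraint exactly (minimum heavy-atom distance between the two residues
#' at the placed geometry), and keeps the `models_per_constraint` best
#' placements per constraint by surface-contact score (ties: rotation index,
#' then tz, ty, tx). Without constraints, performs the unrestricted scan and
#' keeps the `top_k` best placements overall.
#'
#' @param s_a,s_b receptor and ligand structures.
#' @param constraints data.frame with columns `res_a`, `res_b` and optional
#'   `max_dist` (default 5 Angstrom contact criterion), or `NULL` for an
#'   unconstrained run.
#' @param rotations list of 3x3 rotation matrices (default: identity only).
#' @param models_per_constraint models kept per constraint (default 10).
#' @param top_k models kept in an unconstrained run (default 100).
#' @param resolution,surface_margin grid parameters (see [digitize()]).
#' @param core_overlap_tol tolerated core-core overlaps (default 0).
#' @param slack pruning slack in Angstrom (default 3): widens only the
#'   pruning region, absorbing grid and rotation discretization; candidate
#'   placements are then verified against the constraint's own `max_dist`
#'   exactly.
#' @return object of class `dock_models`: `models` data.table (`constraint`,
#'   `rot`, `tx`, `ty`, `tz`, `cx`, `cy`, `cz`, `score`), the `rotations`
#'   list and the grid configuration.
#' @export
run_constrained_docking <- function(s_a, s_b, constraints = NULL,
                                    rotations = list(diag(3)),
                                    models_per_constraint = 10, top_k = 100,
                                    resolution = 1, surface_margin = 1.5,
                                    core_overlap_tol = 0, slack = 3) {
  g_a <- digitize(s_a, resolution, surface_margin)
  if (!is.null(constraints)) {
    constraints <- as.data.frame(constraints)
    if (is.null(constraints$max_dist)) constraints$max_dist <- 5
    if (is.null(constraints$id))
      constraints$id <- paste0("c", seq_len(nrow(constraints)))
  }
  acc <- list()
  for (ri in seq_along(rotations)) {
    sb_rot <- rotate_structure(s_b, rotations[[ri]])
    g_b <- digitize(sb_rot, resolution, surface_margin)
    if (is.null(constraints)) {
      st <- search_translations(g_a, g_b, NULL, core_overlap_tol)
      st <- head(st, top_k)
      if (nrow(st) > 0) { st$rot <- ri; st$constraint <- NA_character_
        acc[[length(acc) + 1L]] <- st }
      next
    }
    for (ci in seq_len(nrow(constraints))) {
      cn <- constraints[ci, ]
      region <- prune_with_constraint(cn, s_a, sb_rot, g_a, g_b, slack)
      st <- search_translations(g_a, g_b, region, core_overlap_tol)
      if (nrow(st) == 0L) next
      # exact verification: residue-residue min atom distance at placement
      pa <- structure_coords(s_a, res_keys = cn$res_a)
      pb <- structure_coords(sb_rot, res_keys = cn$res_b)
      tc <- lattice_to_cartesian(g_a, g_b, as.matrix(st[, c("tx", "ty", "tz")]))
      ok <- vapply(seq_len(nrow(st)), function(m) {
        pbm <- sweep(pb, 2, -tc[m, ], `-`)
        d2 <- outer(rowSums(pa^2), rowSums(pbm^2), `+`) - 2 * pa %*% t(pbm)
        sqrt(max(0, min(d2))) <= cn$max_dist
      }, logical(1))
      st <- st[ok]
      st <- head(st, models_per_constraint)
      if (nrow(st) > 0) { st$rot <- ri; st$constraint <- cn$id
        acc[[length(acc) + 1L]] <- st }
    }
  }
  models <- rbindlist(acc)
  if (nrow(models) > 0) {
    score <- rot <- tz <- ty <- tx <- constraint <- NULL
    setorder(models, constraint, -score, rot, tz, ty, tx, na.last = TRUE)
    if (is.null(constraints)) {
      models <- head(models[order(-models$score, models$rot, models$tz,
                                  models$ty, models$tx)], top_k)
    } else {
      models <- models[, head(.SD, models_per_constraint), by = constraint]
    }
    # cartesian translation per model (depends on the rotation's grid origin)
    cart <- matrix(NA_real_, nrow(models), 3)
    for (ri in unique(models$rot)) {
      sel <- which(models$rot == ri)
      g_b <- digitize(rotate_structure(s_b, rotations[[ri]]),
                      resolution, surface_margin)
      cart[sel, ] <- lattice_to_cartesian(
        g_a, g_b, as.matrix(models[sel, c("tx", "ty", "tz")]))
    }
    models$cx <- cart[, 1]; models$cy <- cart[, 2]; models$cz <- cart[, 3]
  }
  structure(list(models = models, rotations = rotations,
                 resolution = resolution, surface_margin = surface_margin,
                 constraints = constraints),
            class = "dock_models")
}

#' @export
print.dock_models <- function(x, ...) {
  cat(sprintf("<dock_models: %d models, %d rotation(s), %s>\n",
              nrow(x$models), length(x$rotations),
              if (is.null(x$constraints)) "unconstrained"
              else sprintf("%d constraint(s)", nrow(x$constraints))))
  invisible(x)
}

#' Realize one docking model as a posed ligand structure
#'
#' @param s_b the original ligand structure.
#' @param result a `dock_models` object.
#' @param i model row index.
#' @return the ligand `dock_structure` rotated and translated as docked.
#' @export
apply_dock_model <- function(s_b, result, i) {
  m <- result$models[i, ]
  sb <- rotate_structure(s_b, result$rotations[[m$rot]])
  translate_structure(sb, c(m$cx, m$cy, m$cz))
}

#' Sample a balanced model set across constraints
#'
#' Retains the same number of models from each constraint (total /
#' constraints, largest-remainder rounding: with 100 constraints and a total
#' of 500 this is 5 models per constraint; 1000 gives 10). Identical
#' placements arising under several constraints are deduplicated, keeping the
#' first (highest-score) provenance.
#'
#' @param result a `dock_models` object from a constrained run, or its
#'   `models` data.table (ranked within each constraint).
#' @param total total number of models to retain.
#' @return data.table of retained models; per-constraint quotas in attribute
#'   `"quota"`.
#' @export
sample_across_constraints <- function(result, total) {
  models <- if (inherits(result, "dock_models")) result$models else
    as.data.table(result)
  ids <- unique(models$constraint)
  k <- length(ids)
  if (k == 0L) stop("no constrained models to sample from")
  if (total < k)
    stop(sprintf("total (%d) smaller than the number of constraints (%d)",
                 total, k))
  base <- total %/% k
  quota <- setNames(rep(base, k), ids)
  rem <- total - base * k
  if (rem > 0) quota[seq_len(rem)] <- quota[seq_len(rem)] + 1L
  kept <- rbindlist(lapply(ids, function(id)
    head(models[models$constraint == id, ], quota[[id]])))
  dup <- duplicated(kept[, c("rot", "tx", "ty", "tz")])
  out <- kept[!dup]
  attr(out, "quota") <- quota
  out
}
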