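#' Rice rule for histogram bin counts
#'
#' Twice the cube root of the number of values, rounded half away from zero,
#' never below 1. With the candidate-pair counts typical of a docking
#' training set this gives on the order of 200 bins for the non-contact class
#' and 30 for the (much rarer) contact class.
#'
#' @param n_values number of values (>= 1).
#' @return integer bin count.
#' @export
#' @examples
#' rice_bin_count(1e6)  # 200
#' rice_bin_count(3375) # 30
rice_bin_count <- function(n_values) {
  stopifnot(n_values >= 1)
  max(1L, as.integer(round_half_up(2 * n_values^(1 / 3))))
}

#' Equal-width discretization edges
#'
#' `n_bins + 1` edges spanning `[min(values), max(values)]` with equal
#' widths. A degenerate all-equal input is expanded by a small epsilon so a
#' single zero-width bin still contains all the values.
#'
#' @param values numeric vector (non-empty).
#' @param n_bins number of intervals (>= 1).
#' @return numeric vector of `n_bins + 1` strictly increasing edges.
#' @export
ewd_edges <- function(values, n_bins) {
  stopifnot(length(values) >= 1, n_bins >= 1)
  mn <- min(values); mx <- max(values)
  if (mx - mn <= 0) {
    eps <- max(1e-9, abs(mn) * 1e-9)
    mn <- mn - eps; mx <- mx + eps
  }
  seq(mn, mx, length.out = n_bins + 1)
}

# bin index with boundary clamping (values at/above the last edge fall in
# the last bin; below the first edge, in the first)
ewd_bin <- function(values, edges) {
  n <- length(edges) - 1L
  pmin(pmax(findInterval(values, edges), 1L), n)
}

#' Train the Naive Bayes contact classifier
#'
#' Binary NBC with per-class equal-width discretization of each feature. The
#' bin count of class k is the Rice rule on that class's sample size, so the
#' sparse contact class gets coarser histograms than the abundant non-contact
#' class. Conditional probabilities use +1 Laplace smoothing,
#' `(count + 1) / (N_k + n_k)`, keeping every log finite; priors are the
#' pooled class frequencies. Everything is stored as natural logs.
#'
#' @param x numeric feature matrix (rows = candidate pairs).
#' @param y binary labels (logical or 0/1): `TRUE`/1 = contact.
#' @param feature_names optional names (default: colnames of `x`).
#' @return object of class `nbc_model`: `log_prior` (length 2: non-contact,
#'   contact), `n_bins`, per-class `edges` and `log_prob` lists (one matrix
#'   per class, bins x features), `features`.
#' @export
nbc_train <- function(x, y, feature_names = NULL) {
  x <- as.matrix(x)
  y <- as.logical(y)
  stopifnot(nrow(x) == length(y), !anyNA(y))
  if (length(unique(y)) < 2L)
    stop("training data contains a single class; both contact and ",
         "non-contact examples are required")
  feature_names <- feature_names %||% colnames(x) %||%
    paste0("f", seq_len(ncol(x)))
  classes <- c(FALSE, TRUE)
  n_bins <- integer(2)
  edges <- log_prob <- vector("list", 2)
  for (k in 1:2) {
    xk <- x[y == classes[k], , drop = FALSE]
    nk <- nrow(xk)
    n_bins[k] <- rice_bin_count(nk)
    e <- matrix(NA_real_, n_bins[k] + 1L, ncol(x))
    lp <- matrix(NA_real_, n_bins[k], ncol(x))
    for (i in seq_len(ncol(x))) {
      e[, i] <- ewd_edges(xk[, i], n_bins[k])
      counts <- tabulate(ewd_bin(xk[, i], e[, i]), nbins = n_bins[k])
      lp[, i] <- log((counts + 1) / (nk + n_bins[k]))
    }
    edges[[k]] <- e
    log_prob[[k]] <- lp
  }
  structure(list(log_prior = log(c(sum(!y), sum(y)) / length(y)),
                 n_bins = n_bins, edges = edges, log_prob = log_prob,
                 features = feature_names),
            class = "nbc_model")
}

#' @export
print.nbc_model <- function(x, ...) {
  cat(sprintf(
    "<nbc_model: %d features; %d/%d bins (non-contact/contact); priors %.4g/%.4g>\n",
    length(x$features), x$n_bins[1], x$n_bins[2],
    exp(x$log_prior[1]), exp(x$log_prior[2])))
  invisible(x)
}

#' Score candidate pairs with a trained classifier
#'
#' The contact score is the difference of unnormalized log posteriors,
#' `S(x) = [log p(C1) + sum_i log p(x_i|C1)] - [log p(C0) + sum_i log
#' p(x_i|C0)]`; sums of logs are used instead of probability products to
#' avoid round-off. Values outside a class's training range are clamped into
#' the boundary bin.
#'
#' @param model an `nbc_model`.
#' @param x numeric matrix (or vector for a single pair) with the model's
#'   feature count.
#' @return numeric vector of scores S, one per row.
#' @export
nbc_score <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$features))
    stop(sprintf("feature dimension mismatch: model has %d, input has %d",
                 length(model$features), ncol(x)))
  ll <- matrix(0, nrow(x), 2)
  for (k in 1:2) {
    acc <- rep(model$log_prior[k], nrow(x))
    for (i in seq_len(ncol(x))) {
      b <- ewd_bin(x[, i], model$edges[[k]][, i])
      acc <- acc + model$log_prob[[k]][b, i]
    }
    ll[, k] <- acc
  }
  ll[, 2] - ll[, 1]
}

#' Rank candidate pairs of a complex by contact score
#'
#' Deterministic ordering: decreasing score, ties broken by the residue-pair
#' identifiers `(res_a, res_b)`.
#'
#' @param scores numeric scores.
#' @param res_a,res_b residue identifiers parallel to `scores` (optional but
#'   recommended for reproducible tie-breaks).
#' @param labels optional true-contact labels.
#' @return data.frame ordered by rank: `rank`, `res_a`, `res_b`, `score`,
#'   `label`.
#' @export
rank_contacts <- function(scores, res_a = NULL, res_b = NULL, labels = NULL) {
  n <- length(scores)
  res_a <- res_a %||% as.character(seq_len(n))
  res_b <- res_b %||% rep("", n)
  ord <- order(-scores, res_a, res_b)
  data.frame(rank = seq_len(n), res_a = res_a[ord], res_b = res_b[ord],
             score = scores[ord],
             label = if (is.null(labels)) NA else labels[ord],
             stringsAsFactors = FALSE)
}

#' R-precision of a ranking, extended below zero
#'
#' With R true contacts, the usual R-precision is the fraction of true
#' contacts among the top R ranked candidates. When not even one true contact
#' ranks within the top R, this returns `1 - highestTrue / R` instead (a
#' negative value measuring by how far the classifier missed), where
#' `highestTrue` is the rank of the best-ranked true contact.
#'
#' @param ranking a data.frame from [rank_contacts()] with known `label`, or
#'   a logical vector of labels already in rank order.
#' @return numeric scalar (can be negative; 1 is perfect).
#' @export
r_precision <- function(ranking) {
  lab <- if (is.data.frame(ranking)) as.logical(ranking$label)
  else as.logical(ranking)
  if (anyNA(lab)) stop("ranking has missing labels")
  R <- sum(lab)
  if (R < 1) stop("R-precision undefined: ranking contains no true contacts")
  highest <- which(lab)[1]
  if (highest <= R) sum(lab[seq_len(R)]) / R else 1 - highest / R
}

#' Complex-level cross-validation of the classifier
#'
#' Folds partition complexes, never candidate pairs: all pairs of a held-out
#' complex are scored by a model trained on the pooled pairs of the other
#' folds, and the per-complex R-precision values are macro-averaged. Fold
#' assignment is a seeded shuffle of the (sorted) complex ids, so the result
#' does not depend on input order.
#'
#' @param tables named list of complexes, each a list with `x` (feature
#'   matrix) and `y` (labels).
#' @param n_folds number of folds (default 5).
#' @param features optional feature subset (indices or names) to train on.
#' @param seed RNG seed for the fold shuffle (default 75).
#' @return mean R-precision; per-complex values in attribute `"per_complex"`,
#'   fold assignment in `"folds"`.
#' @export
cross_validate <- function(tables, n_folds = 5, features = NULL, seed = 75) {
  stopifnot(n_folds >= 2)
  ids <- sort(names(tables) %||% as.character(seq_along(tables)))
  if (is.null(names(tables))) names(tables) <- ids
  if (length(ids) < n_folds)
    stop("fewer complexes (", length(ids), ") than folds (", n_folds, ")")
  shuffled <- with_seed(seed, sample(ids))
  fold_of <- setNames(rep(seq_len(n_folds), length.out = length(ids)),
                      shuffled)
  sel <- function(x) if (is.null(features)) x else x[, features, drop = FALSE]
  rp <- setNames(rep(NA_real_, length(ids)), ids)
  for (f in seq_len(n_folds)) {
    test_ids <- names(fold_of)[fold_of == f]
    train_ids <- setdiff(ids, test_ids)
    xtr <- do.call(rbind, lapply(tables[train_ids], function(t) sel(as.matrix(t$x))))
    ytr <- unlist(lapply(tables[train_ids], function(t) as.logical(t$y)))
    model <- nbc_train(xtr, ytr)
    for (id in test_ids) {
      tb <- tables[[id]]
      if (sum(tb$y) < 1) next
      s <- nbc_score(model, sel(as.matrix(tb$x)))
      rp[id] <- r_precision(rank_contacts(s, labels = as.logical(tb$y)))
    }
  }
  if (anyNA(rp)) {
    warning("complex(es) without true contacts skipped: ",
            paste(names(rp)[is.na(rp)], collapse = ", "))
  }
  out <- mean(rp, na.rm = TRUE)
  attr(out, "per_complex") <- rp
  attr(out, "folds") <- fold_of
  attr(out, "seed") <- seed
  out
}

#' Serialize / restore a trained classifier as JSON
#'
#' @param model an `nbc_model`.
#' @param path file to write / read.
#' @return `write_nbc_model()`: the path, invisibly. `read_nbc_model()`: the
#'   model.
#' @export
write_nbc_model <- function(model, path) {
  obj <- list(log_prior = model$log_prior, n_bins = model$n_bins,
              edges = lapply(model$edges, as.data.frame),
              log_prob = lapply(model$log_prob, as.data.frame),
              features = model$features)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_nbc_model
#' @export
read_nbc_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(list(log_prior = obj$log_prior,
                 n_bins = as.integer(obj$n_bins),
                 edges = lapply(obj$edges, as.matrix),
                 log_prob = lapply(obj$log_prob, as.matrix),
                 features = obj$features),
            class = "nbc_model")
}
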