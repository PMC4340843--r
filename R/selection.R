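#' Forward sequential feature search with a beam of retained subsets
#'
#' Evaluates every single feature by cross-validated mean R-precision,
#' retains the best `beam_n` subsets, then repeatedly extends every retained
#' subset by every unused feature, deduplicates (subsets are order-
#' insensitive), re-evaluates and again retains the top `beam_n`, up to
#' `max_size` features. With `beam_n = 1` this reduces to classic greedy
#' forward selection; with `beam_n` at least the number of subsets of each
#' size it is exhaustive.
#'
#' @param tables per-complex feature tables as in [cross_validate()].
#' @param beam_n number of subsets retained per size (default 10).
#' @param max_size largest subset size to explore.
#' @param n_folds,seed cross-validation configuration (the same folds are
#'   used for every subset).
#' @param feature_pool optional subset of feature names/indices to search
#'   over (default: all columns of the first table).
#' @param verbose print progress per size.
#' @return object of class `search_trajectory`: list with `sizes` (per size:
#'   `subsets` list and `scores`, sorted by decreasing score, ties broken by
#'   lexicographic subset order), `best_subset`, `best_score`.
#' @export
beam_forward_search <- function(tables, beam_n = 10, max_size = 45,
                                n_folds = 5, seed = 75,
                                feature_pool = NULL, verbose = FALSE) {
  stopifnot(beam_n >= 1)
  pool <- feature_pool %||% colnames(as.matrix(tables[[1]]$x))
  if (is.null(pool)) pool <- seq_len(ncol(as.matrix(tables[[1]]$x)))
  if (length(pool) == 0L) stop("empty feature pool")
  max_size <- min(max_size, length(pool))
  cache <- new.env(parent = emptyenv())
  evaluate <- function(subset) {
    key <- paste(subset, collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- as.numeric(cross_validate(tables, n_folds = n_folds,
                                   features = subset, seed = seed))
    cache[[key]] <- v
    v
  }
  rank_subsets <- function(subsets, scores) {
    lex <- vapply(subsets, function(s) paste(s, collapse = "\r"), character(1))
    order(-scores, lex)
  }
  frontier <- lapply(pool, function(f) f)
  sizes <- vector("list", max_size)
  for (s in seq_len(max_size)) {
    if (s > 1) {
      ext <- list()
      for (sub in frontier)
        for (f in setdiff(pool, sub))
          ext[[length(ext) + 1L]] <- sort(c(sub, f))
      keys <- vapply(ext, function(x) paste(x, collapse = "\r"), character(1))
      frontier <- ext[!duplicated(keys)]
    }
    scores <- vapply(frontier, evaluate, numeric(1))
    ord <- rank_subsets(frontier, scores)
    keep <- ord[seq_len(min(beam_n, length(ord)))]
    sizes[[s]] <- list(subsets = frontier[keep], scores = scores[keep])
    frontier <- frontier[keep]
    if (verbose)
      message(sprintf("size %d: best %.4f (%s)", s, sizes[[s]]$scores[1],
                      paste(sizes[[s]]$subsets[[1]], collapse = ",")))
  }
  best_per_size <- vapply(sizes, function(z) z$scores[1], numeric(1))
  best_s <- which(best_per_size == max(best_per_size))[1] # ties: smaller size
  structure(list(sizes = sizes,
                 best_subset = sizes[[best_s]]$subsets[[1]],
                 best_score = best_per_size[best_s]),
            class = "search_trajectory")
}

#' @export
print.search_trajectory <- function(x, ...) {
  cat(sprintf("<search_trajectory: sizes 1..%d; best %.4f with {%s}>\n",
              length(x$sizes), x$best_score,
              paste(x$best_subset, collapse = ", ")))
  invisible(x)
}
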