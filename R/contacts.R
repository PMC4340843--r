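#' Find residue contacts by minimum heavy-atom distance
#'
#' Two residues are in contact when their closest heavy atoms are at most
#' `max_dist` Angstrom apart (measured between atom centers). With one
#' structure, computes intra-protein contacts (self pairs excluded, each pair
#' stored once under the canonical residue order); with two structures,
#' inter-protein contacts with partner A always on the left.
#'
#' @param s_a a `dock_structure`.
#' @param s_b a second `dock_structure`, or `NULL` for intra-protein contacts
#'   within `s_a`.
#' @param max_dist distance criterion in Angstrom (default 5, the CAPRI
#'   contact criterion).
#' @return An object of class `contact_set`: list with `pairs` (data.frame
#'   `res_a`, `res_b`, `min_dist`), `max_dist`, and `intra` flag.
#' @export
find_contacts <- function(s_a, s_b = NULL, max_dist = 5) {
  stopifnot(inherits(s_a, "dock_structure"), max_dist > 0)
  intra <- is.null(s_b)
  if (intra) s_b <- s_a else stopifnot(inherits(s_b, "dock_structure"))
  xa <- as.matrix(s_a$atoms[, c("x", "y", "z")])
  xb <- as.matrix(s_b$atoms[, c("x", "y", "z")])
  ka <- s_a$atoms$res_key
  kb <- s_b$atoms$res_key
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= max_dist^2, arr.ind = TRUE)
  dt <- data.table(res_a = ka[hit[, 1]], res_b = kb[hit[, 2]],
                   d = sqrt(d2[hit]))
  if (intra) {
    ord <- match(dt$res_a, s_a$residues$res_key) <
      match(dt$res_b, s_a$residues$res_key)
    keep <- dt$res_a != dt$res_b
    dt <- dt[keep]
    ord <- ord[keep]
    tmp <- dt$res_a
    dt[!ord, c("res_a", "res_b") := list(res_b, tmp[!ord])]
  }
  res_a <- res_b <- d <- NULL # NSE bindings
  pairs <- if (nrow(dt) == 0L)
    data.table(res_a = character(0), res_b = character(0),
               min_dist = numeric(0))
  else dt[, list(min_dist = min(d)), by = list(res_a, res_b)]
  setorder(pairs, res_a, res_b)
  structure(list(pairs = as.data.frame(pairs), max_dist = max_dist,
                 intra = intra),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("<contact_set: %d %s pairs at <= %g Angstrom>\n",
              nrow(x$pairs), if (x$intra) "intra-protein" else "inter-protein",
              x$max_dist))
  invisible(x)
}

#' Build spatial neighborhoods over candidate surface residues
#'
#' The neighborhood of a candidate residue is the residue itself plus all
#' residues of the candidate set that are in contact with it (intra-protein
#' contacts at the 5 Angstrom heavy-atom criterion). Non-candidate contacts
#' are ignored.
#'
#' @param candidates character vector of candidate residue keys.
#' @param intra_contacts an intra-protein `contact_set` of the same structure.
#' @return named list: for each candidate, the character vector of
#'   neighborhood member keys (the residue first, then contacting candidates).
#' @export
build_neighborhoods <- function(candidates, intra_contacts) {
  stopifnot(inherits(intra_contacts, "contact_set"), intra_contacts$intra)
  if (anyDuplicated(candidates)) stop("duplicate candidate residues")
  p <- intra_contacts$pairs
  keep <- p$res_a %in% candidates & p$res_b %in% candidates
  p <- p[keep, , drop = FALSE]
  adj <- split(c(p$res_b, p$res_a), c(p$res_a, p$res_b))
  out <- lapply(candidates, function(r) unique(c(r, adj[[r]])))
  names(out) <- candidates
  out
}
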