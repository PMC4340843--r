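#' Parse a multiple sequence alignment
#'
#' Reads an aligned FASTA or Clustal alignment (via Biostrings) and extracts
#' an organism tag from each header: first a `OS=...` UniProt-style field,
#' else a trailing `[...]` bracket, else the full header.
#'
#' @param text character scalar/vector of alignment text, or a file path.
#' @param format `"fasta"` (aligned FASTA) or `"clustal"`.
#' @param query index of the query row (the row matching the structure's
#'   chain sequence); default 1.
#' @param organism_regex optional custom regex with one capture group applied
#'   to headers before the default rules.
#' @return An object of class `msa_alignment`: list with `headers`,
#'   `organisms`, `seqs` (uppercase gapped sequences, `-` gaps), `query`,
#'   `ncol`.
#' @export
parse_alignment <- function(text, format = c("fasta", "clustal"), query = 1L,
                            organism_regex = NULL) {
  format <- match.arg(format)
  path <- if (length(text) == 1L && !grepl("[\n>]", text) && file.exists(text))
    text else {
    tf <- tempfile(fileext = if (format == "fasta") ".fasta" else ".aln")
    writeLines(if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
               else text, tf)
    tf
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    if (length(ss) == 0L) stop("empty alignment")
    headers <- names(ss)
    seqs <- toupper(as.character(ss))
  } else {
    ma <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    headers <- rownames(ma)
    seqs <- toupper(as.character(ma))
    if (length(seqs) == 0L) stop("empty alignment")
  }
  seqs <- gsub("\\.", "-", seqs)
  len <- unname(nchar(seqs))
  if (len[1] == 0L) stop("empty alignment: zero-width sequences")
  if (length(unique(len)) != 1L) {
    bad <- which(len != len[1])[1]
    stop(sprintf("ragged alignment: row '%s' has length %d, expected %d",
                 headers[bad], len[bad], len[1]))
  }
  stopifnot(query >= 1, query <= length(seqs))
  structure(list(headers = headers,
                 organisms = extract_organism(headers, organism_regex),
                 seqs = unname(seqs), query = as.integer(query),
                 ncol = len[1]),
            class = "msa_alignment")
}

extract_organism <- function(headers, organism_regex = NULL) {
  vapply(headers, function(h) {
    if (!is.null(organism_regex)) {
      m <- regmatches(h, regexec(organism_regex, h, perl = TRUE))[[1]]
      if (length(m) >= 2) return(m[2])
    }
    m <- regmatches(h, regexec("OS=(.*?)(?: [A-Z]{2}=|$)", h, perl = TRUE))[[1]]
    if (length(m) >= 2) return(m[2])
    m <- regmatches(h, regexec("\\[([^][]+)\\][^][]*$", h))[[1]]
    if (length(m) >= 2) return(m[2])
    h
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat(sprintf("<msa_alignment: %d rows x %d columns, query row %d>\n",
              length(x$seqs), x$ncol, x$query))
  invisible(x)
}

# identity of row i to the query: matching ungapped positions / ungapped
# query length
row_identity <- function(aln, i) {
  q <- strsplit(aln$seqs[aln$query], "")[[1]]
  r <- strsplit(aln$seqs[i], "")[[1]]
  qn <- q != "-"
  if (!any(qn)) return(0)
  sum(qn & r == q) / sum(qn)
}

#' Pair alignment rows across two partners by source organism
#'
#' Rows are matched when the same organism tag appears in both alignments;
#' when an organism has several rows in one alignment, the row with the
#' highest ungapped identity to that alignment's query is used (ties: first
#' row). The two query rows are always matched to each other. Unmatched rows
#' are dropped from the pairing (but remain in the alignments).
#'
#' @param a,b `msa_alignment` objects for the two partners.
#' @return An object of class `paired_alignment`: list with `a`, `b`, and
#'   `pairs`, an integer matrix with columns `row_a`, `row_b` (first row =
#'   the query pair).
#' @export
pair_rows_by_organism <- function(a, b) {
  stopifnot(inherits(a, "msa_alignment"), inherits(b, "msa_alignment"))
  pick <- function(aln, org) {
    rows <- setdiff(which(aln$organisms == org), aln$query)
    if (length(rows) == 0L) return(NA_integer_)
    ident <- vapply(rows, function(i) row_identity(aln, i), numeric(1))
    rows[which.max(ident)]
  }
  common <- intersect(unique(a$organisms[-a$query]),
                      unique(b$organisms[-b$query]))
  ra <- vapply(common, function(o) pick(a, o), integer(1))
  rb <- vapply(common, function(o) pick(b, o), integer(1))
  ok <- !is.na(ra) & !is.na(rb)
  pairs <- cbind(row_a = c(a$query, ra[ok]), row_b = c(b$query, rb[ok]))
  rownames(pairs) <- NULL
  if (nrow(pairs) == 1L)
    warning("no organism common to both alignments besides the queries")
  structure(list(a = a, b = b, pairs = pairs), class = "paired_alignment")
}

#' @export
print.paired_alignment <- function(x, ...) {
  cat(sprintf("<paired_alignment: %d matched row pairs>\n", nrow(x$pairs)))
  invisible(x)
}

#' Map structure residues to alignment columns
#'
#' The degapped query row must equal the chain sequence (positions holding
#' `X` on either side compare equal). The k-th non-gap query position maps to
#' its alignment column.
#'
#' @param a an `msa_alignment`.
#' @param chain_sequence one-letter sequence of the structure's chain.
#' @return integer vector: for residue k of the chain, the 1-based alignment
#'   column.
#' @export
map_query_columns <- function(a, chain_sequence) {
  q <- strsplit(a$seqs[a$query], "")[[1]]
  cols <- which(q != "-")
  s <- strsplit(toupper(chain_sequence), "")[[1]]
  if (length(cols) != length(s))
    stop(sprintf("query row has %d residues but chain sequence has %d",
                 length(cols), length(s)))
  qa <- q[cols]
  mism <- which(qa != s & qa != "X" & s != "X")
  if (length(mism) > 0L)
    stop(sprintf(
      "query/chain sequence mismatch at position %d: query '%s' vs chain '%s'",
      mism[1], qa[mism[1]], s[mism[1]]))
  cols
}
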