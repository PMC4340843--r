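#' Parse a PDB-format structure
#'
#' Reads ATOM records from PDB text into a heavy-atom structure. Hydrogens
#' (element H or D) are removed; alternate locations are resolved
#' deterministically by keeping, per atom, the altloc with the highest
#' occupancy (ties: first in file); residues keep their file order.
#'
#' @param pdb_text character scalar (possibly multi-line) or character vector
#'   of lines in PDB format.
#' @param id identifier stored on the structure.
#' @param include_het also read HETATM records (default `FALSE`).
#' @return An object of class `dock_structure`: a list with `id`, an `atoms`
#'   data.frame (`chain`, `resno`, `icode`, `resname`, `elety`, `element`,
#'   `x`, `y`, `z`, `occ`, `res_key`) and a `residues` data.frame in file
#'   order (`chain`, `resno`, `icode`, `resname`, `res_key`).
#' @export
#' @examples
#' pdb <- "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C"
#' s <- parse_structure(pdb)
#' nrow(s$atoms)
parse_structure <- function(pdb_text, id = "structure", include_het = FALSE) {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE))
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]] else pdb_text
  rec_types <- if (include_het) c("ATOM  ", "HETATM") else "ATOM  "
  is_atom <- substr(lines, 1, 6) %in% rec_types
  atom_lines <- lines[is_atom]
  atom_lineno <- which(is_atom)
  if (length(atom_lines) == 0L)
    stop("empty structure: no ", if (include_het) "ATOM/HETATM" else "ATOM",
         " records found")
  # validate fixed-column records before handing off to the reader
  bad <- which(nchar(atom_lines) < 54)
  if (length(bad) == 0L) {
    coords <- suppressWarnings(cbind(
      as.numeric(substr(atom_lines, 31, 38)),
      as.numeric(substr(atom_lines, 39, 46)),
      as.numeric(substr(atom_lines, 47, 54))))
    bad <- which(!is.finite(rowSums(coords)))
  }
  if (length(bad) > 0L)
    stop(sprintf("malformed PDB ATOM record at line %d: %s",
                 atom_lineno[bad[1]], atom_lines[bad[1]]))

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- suppressWarnings(bio3d::read.pdb(tf, verbose = FALSE, hex = FALSE))
  at <- pdb$atom
  if (!include_het) at <- at[at$type == "ATOM", , drop = FALSE]

  element <- toupper(trimws(at$elesy))
  guess <- toupper(substr(gsub("^[0-9]+", "", trimws(at$elety)), 1, 1))
  element[is.na(element) | element == ""] <- guess[is.na(element) | element == ""]
  at$element <- element
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0L) stop("empty structure: no heavy atoms after hydrogen filtering")

  at$icode <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  at$chain <- ifelse(is.na(at$chain), "", at$chain)
  at$occ <- ifelse(is.na(at$o), 1, at$o)
  # altloc resolution: highest occupancy, then first occurrence
  key <- paste(at$chain, at$resno, at$icode, at$elety, sep = "\r")
  ord <- order(match(key, unique(key)), -at$occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$icode, at$elety, sep = "\r")), ,
           drop = FALSE]
  # restore file order
  at <- at[order(as.integer(rownames(at))), , drop = FALSE]

  atoms <- data.frame(
    chain = at$chain, resno = at$resno, icode = at$icode,
    resname = at$resid, elety = trimws(at$elety), element = at$element,
    x = at$x, y = at$y, z = at$z, occ = at$occ,
    stringsAsFactors = FALSE)
  atoms$res_key <- residue_key(atoms$chain, atoms$resno, atoms$icode)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in structure")
  res <- atoms[!duplicated(atoms$res_key),
               c("chain", "resno", "icode", "resname", "res_key")]
  rownames(res) <- NULL
  structure(list(id = id, atoms = atoms, residues = res),
            class = "dock_structure")
}

#' Canonical residue identifier
#'
#' @param chain,resno,icode chain id, residue number, insertion code.
#' @return character vector `"chain:resno:icode"`.
#' @export
residue_key <- function(chain, resno, icode = "") {
  paste(chain, resno, icode, sep = ":")
}

#' @export
print.dock_structure <- function(x, ...) {
  cat(sprintf("<dock_structure %s: %d chains, %d residues, %d heavy atoms>\n",
              x$id, length(unique(x$residues$chain)), nrow(x$residues),
              nrow(x$atoms)))
  invisible(x)
}

#' Heavy-atom coordinates of a structure
#'
#' @param s a `dock_structure`.
#' @param res_keys optional residue keys to restrict to.
#' @param elety optional atom-name filter (e.g. `"CA"`).
#' @return numeric matrix with columns x, y, z.
#' @export
structure_coords <- function(s, res_keys = NULL, elety = NULL) {
  at <- s$atoms
  if (!is.null(res_keys)) at <- at[at$res_key %in% res_keys, , drop = FALSE]
  if (!is.null(elety)) at <- at[at$elety %in% elety, , drop = FALSE]
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- at$res_key
  m
}

#' One-letter amino-acid sequence of a chain
#'
#' @param s a `dock_structure`.
#' @param chain chain id (default: first chain).
#' @return character scalar; unknown residue names become `"X"`.
#' @export
structure_sequence <- function(s, chain = NULL) {
  chain <- chain %||% s$residues$chain[1]
  rn <- s$residues$resname[s$residues$chain == chain]
  aa <- bio3d::aa321(rn)
  aa[is.na(aa) | !aa %in% strsplit(AA20, "")[[1]]] <- "X"
  paste(aa, collapse = "")
}

AA20 <- "ARNDCQEGHILKMFPSTWYV"

#' Write a structure as PDB text
#'
#' Minimal deterministic PDB writer (ATOM records + TER/END), used mainly by
#' the synthetic fixture generators so that identical seeds give byte-identical
#' files.
#'
#' @param s a `dock_structure`.
#' @return character scalar of PDB text.
#' @export
as_pdb_text <- function(s) {
  at <- s$atoms
  name <- ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), name, at$resname, at$chain, at$resno,
    ifelse(at$icode == "", " ", at$icode), at$x, at$y, at$z, at$occ, 0,
    at$element)
  paste(c(lines, "TER", "END", ""), collapse = "\n")
}
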