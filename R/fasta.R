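#' Amino-acid sequence sets
#'
#' Sequence sets are represented as a named character vector of upper-case
#' residue strings (20 standard residues plus `X`), with an optional
#' `descriptions` attribute carrying FASTA description lines. IDs must be
#' unique and sequences non-empty.
#'
#' @param x Named character vector of residue strings.
#' @param descriptions Optional character vector of description lines,
#'   recycled against `x`.
#' @return An object of class `"aa_sequences"`.
#' @examples
#' aa_sequences(c(s1 = "ACDE", s2 = "ACDF"))
#' @export
aa_sequences <- function(x, descriptions = NULL) {
  if (!is.character(x) || length(x) == 0L)
    stop("`x` must be a non-empty character vector of sequences")
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("every sequence needs a non-empty id (names of `x`)")
  dup <- unique(names(x)[duplicated(names(x))])
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  x <- toupper(x)
  if (any(!nzchar(x)))
    stop("empty sequence(s): ", paste(names(x)[!nzchar(x)], collapse = ", "))
  ok <- vapply(strsplit(x, ""), function(ch) all(ch %in% AA_EXTENDED), TRUE)
  if (any(!ok))
    stop("illegal residue character(s) in record(s): ",
         paste(names(x)[!ok], collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", length(x))
  attr(x, "descriptions") <- rep_len(as.character(descriptions), length(x))
  class(x) <- "aa_sequences"
  x
}

#' @export
`[.aa_sequences` <- function(x, i) {
  d <- attr(x, "descriptions")
  y <- unclass(x)[i]
  aa_sequences(y, if (is.null(d)) NULL else d[i])
}

#' @export
print.aa_sequences <- function(x, ...) {
  cat(sprintf("aa_sequences: %d sequence(s), lengths %d-%d\n",
              length(x), min(nchar(x)), max(nchar(x))))
  show <- head(seq_along(x), 6L)
  for (i in show) {
    s <- unclass(x)[[i]]
    cat(sprintf("  %-20s %s%s\n", names(x)[i],
                substr(s, 1, 50), if (nchar(s) > 50) "..." else ""))
  }
  if (length(x) > 6L) cat(sprintf("  ... and %d more\n", length(x) - 6L))
  invisible(x)
}

#' Read and write FASTA files
#'
#' `read_fasta()` reads an amino-acid FASTA file (any line wrapping) into an
#' [aa_sequences] object, preserving record order; `write_fasta()` writes one
#' back wrapped at 60 columns. Duplicate IDs and residue characters outside
#' the 20-letter alphabet (plus `X`, and `-` when `gapped = TRUE`) are errors.
#'
#' @param path File path.
#' @param gapped Allow `-` gap characters (aligned FASTA) on read.
#' @return `read_fasta()`: an [aa_sequences] object (with gaps retained when
#'   `gapped = TRUE`); `write_fasta()`: `path`, invisibly.
#' @export
read_fasta <- function(path, gapped = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  full <- names(ss)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  if (gapped) {
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
      stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
    ok <- vapply(strsplit(seqs, ""),
                 function(ch) all(ch %in% c(AA_EXTENDED, GAP_CHAR)), TRUE)
    if (any(!ok))
      stop("illegal residue character(s) in record(s): ",
           paste(ids[!ok], collapse = ", "))
    attr(seqs, "descriptions") <- desc
    class(seqs) <- "aa_sequences"
    return(seqs)
  }
  aa_sequences(seqs, desc)
}

#' @rdname read_fasta
#' @param x An [aa_sequences] object (or named character vector).
#' @export
write_fasta <- function(x, path) {
  if (!inherits(x, "aa_sequences")) x <- aa_sequences(x)
  desc <- attr(x, "descriptions")
  nm <- ifelse(nzchar(desc), paste(names(x), desc), names(x))
  ss <- Biostrings::AAStringSet(setNames(gsub("-", "-", unclass(x)), NULL))
  names(ss) <- nm
  Biostrings::writeXStringSet(ss, filepath = path, width = 60L)
  invisible(path)
}

#' Multiple sequence alignments
#'
#' An alignment is a character matrix of single residues (rows = sequences,
#' identified by rownames; columns = alignment columns) in which `-` marks a
#' gap. De-gapping any row reproduces the corresponding input sequence.
#'
#' @param x Named character vector of equal-length gapped strings, or a
#'   character matrix of single characters with rownames.
#' @return An object of class `"aa_alignment"` (character matrix).
#' @examples
#' aln <- as_alignment(c(a = "AC-E", b = "ACDE"))
#' alignment_strings(aln)
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else {
    if (is.null(names(x))) stop("gapped strings must be named")
    if (length(unique(nchar(x))) != 1L)
      stop("alignment rows must all have equal length")
    m <- do.call(rbind, strsplit(toupper(unname(x)), ""))
    rownames(m) <- names(x)
  }
  if (is.null(rownames(m))) stop("alignment needs rownames (sequence ids)")
  bad <- !(m %in% c(AA_EXTENDED, GAP_CHAR))
  if (any(bad)) stop("illegal characters in alignment")
  class(m) <- c("aa_alignment", class(m))
  m
}

#' @rdname as_alignment
#' @param aln An `aa_alignment`.
#' @export
alignment_strings <- function(aln) {
  apply(unclass(aln), 1L, paste0, collapse = "")
}

#' @rdname as_alignment
#' @export
degap <- function(aln) {
  s <- gsub("-", "", alignment_strings(aln), fixed = TRUE)
  aa_sequences(s)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("aa_alignment: %d sequences x %d columns\n", nrow(x), ncol(x)))
  s <- alignment_strings(x)
  for (i in head(seq_along(s), 8L))
    cat(sprintf("  %-20s %s%s\n", names(s)[i], substr(s[i], 1, 50),
                if (nchar(s[i]) > 50) "..." else ""))
  if (length(s) > 8L) cat(sprintf("  ... and %d more\n", length(s) - 8L))
  invisible(x)
}
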