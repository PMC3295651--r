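#' Pairwise global alignment with affine gaps
#'
#' Needleman–Wunsch/Gotoh global alignment of two protein sequences under a
#' substitution matrix with affine gap penalties
#' (`gap_open + (k - 1) * gap_extend` for a gap of length `k`). Traceback
#' tie-breaks are fixed (aligned pair preferred over a gap in the first
#' sequence, preferred over a gap in the second) so results are reproducible.
#'
#' @param a,b Single sequences: named length-1 character vectors or
#'   [aa_sequences] of length 1.
#' @param matrix A [substitution_matrix]; default [blosum62()].
#' @return A list of class `"pairwise_alignment"` with elements `alignment`
#'   (two-row [as_alignment] matrix), `score` (optimal global score) and
#'   `identity` (fraction identical over columns with no gap in either row).
#' @examples
#' pairwise_global_align(c(a = "ACDE"), c(b = "ACE"))
#' @export
pairwise_global_align <- function(a, b, matrix = blosum62()) {
  a <- .as_single_seq(a, "a"); b <- .as_single_seq(b, "b")
  if (!inherits(matrix, "substitution_matrix"))
    stop("`matrix` must be a substitution_matrix")
  ca <- strsplit(unclass(a)[[1]], "")[[1]]
  cb <- strsplit(unclass(b)[[1]], "")[[1]]
  S <- matrix$scores[ca, cb, drop = FALSE]
  res <- gotoh_align_cpp(S, matrix$gap_open, matrix$gap_extend)
  ra <- ifelse(res$ai > 0, ca[pmax(res$ai, 1L)], GAP_CHAR)
  rb <- ifelse(res$bi > 0, cb[pmax(res$bi, 1L)], GAP_CHAR)
  m <- rbind(ra, rb)
  rownames(m) <- c(names(a), names(b))
  aln <- as_alignment(m)
  structure(list(alignment = aln, score = res$score,
                 identity = percent_identity(ra, rb)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment: score %.1f, identity %.1f%%\n",
              x$score, 100 * x$identity))
  print(x$alignment)
  invisible(x)
}

.as_single_seq <- function(x, arg) {
  if (inherits(x, "aa_sequences")) {
    if (length(x) != 1L) stop("`", arg, "` must be a single sequence")
    return(x)
  }
  if (is.character(x) && length(x) == 1L) {
    if (is.null(names(x))) names(x) <- arg
    return(aa_sequences(x))
  }
  stop("`", arg, "` must be a single named sequence")
}

#' Percent identity between two aligned rows
#'
#' Fraction of identical residues over the columns in which neither row has a
#' gap. Columns with a gap in either row are excluded from the denominator.
#'
#' @param row_a,row_b Equal-length gapped strings or character vectors.
#' @return Fraction in `[0, 1]`.
#' @examples
#' percent_identity("AC-E", "ACDE")  # 1: three comparable columns, all equal
#' @export
percent_identity <- function(row_a, row_b) {
  if (is.character(row_a) && length(row_a) == 1L) row_a <- strsplit(row_a, "")[[1]]
  if (is.character(row_b) && length(row_b) == 1L) row_b <- strsplit(row_b, "")[[1]]
  if (length(row_a) != length(row_b))
    stop("aligned rows must have equal length")
  comp <- row_a != GAP_CHAR & row_b != GAP_CHAR
  if (!any(comp)) stop("no comparable (gap-free) columns between the rows")
  sum(row_a[comp] == row_b[comp]) / sum(comp)
}

#' UPGMA guide tree from pairwise alignment identities
#'
#' Builds the guide tree that orders profile merges in [progressive_msa()]:
#' all-against-all pairwise global alignments give identity fractions, the
#' distance `1 - identity` is clustered by UPGMA (average linkage). Only the
#' merge order matters downstream, so the uncorrected identity distance is
#' used.
#'
#' @inheritParams progressive_msa
#' @return An object of class `"guide_tree"`: the [stats::hclust] tree with a
#'   `distances` attribute (the `dist` object used).
#' @export
build_guide_tree <- function(records, matrix = blosum62()) {
  if (!inherits(records, "aa_sequences")) records <- aa_sequences(records)
  n <- length(records)
  if (n < 2L) stop("need at least 2 sequences to build a guide tree")
  D <- stats::dist(seq_len(n))  # placeholder structure, overwritten below
  dm <- matrix(0, n, n, dimnames = list(names(records), names(records)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pw <- pairwise_global_align(records[i], records[j], matrix)
    dm[i, j] <- dm[j, i] <- 1 - pw$identity
  }
  D <- as.dist(dm)
  hc <- hclust(D, method = "average")
  attr(hc, "distances") <- D
  class(hc) <- c("guide_tree", class(hc))
  hc
}

#' @export
print.guide_tree <- function(x, ...) {
  cat(sprintf("UPGMA guide tree over %d sequences\n",
              length(x$labels)))
  invisible(x)
}

#' Progressive multiple sequence alignment
#'
#' Hierarchical-clustering-guided progressive alignment: a UPGMA guide tree
#' from pairwise identities fixes the merge order, and at each merge the two
#' sub-alignments are aligned profile-to-profile with the same affine-gap
#' Gotoh kernel as the pairwise aligner. Profile column scores are the mean
#' substitution score over all non-gap residue pairs between the two columns;
#' gaps, once inserted, are never removed ("once a gap, always a gap"). For
#' two sequences the result is exactly the pairwise global alignment.
#'
#' @param records An [aa_sequences] object (>= 2 sequences).
#' @param matrix A [substitution_matrix]; default [blosum62()].
#' @param guide Optional precomputed [build_guide_tree()] result.
#' @return An [as_alignment] matrix with rows in input order.
#' @examples
#' recs <- aa_sequences(c(a = "ACDEFG", b = "ACEFG", c = "ACDEFG"))
#' progressive_msa(recs)
#' @export
progressive_msa <- function(records, matrix = blosum62(), guide = NULL) {
  if (!inherits(records, "aa_sequences")) records <- aa_sequences(records)
  n <- length(records)
  if (n < 2L) stop("need at least 2 sequences for an alignment")
  if (is.null(guide)) guide <- build_guide_tree(records, matrix)
  blocks <- lapply(seq_len(n), function(i) {
    m <- matrix(strsplit(unclass(records)[[i]], "")[[1]], nrow = 1)
    rownames(m) <- names(records)[i]
    m
  })
  merged <- vector("list", n - 1L)
  pick <- function(k) if (k < 0) blocks[[-k]] else merged[[k]]
  for (s in seq_len(nrow(guide$merge))) {
    A <- pick(guide$merge[s, 1L]); B <- pick(guide$merge[s, 2L])
    merged[[s]] <- .align_profiles(A, B, matrix)
  }
  out <- merged[[n - 1L]]
  out <- out[names(records), , drop = FALSE]
  as_alignment(out)
}

# Mean-of-pairs column score matrix between two profiles (char matrices).
.profile_col_scores <- function(A, B, scores) {
  ca <- .profile_counts(A); cb <- .profile_counts(B)
  na <- colSums(ca); nb <- colSums(cb)
  S <- crossprod(ca, scores %*% cb)
  denom <- outer(na, nb)
  S <- ifelse(denom > 0, S / denom, 0)
  S
}

.profile_counts <- function(A) {
  L <- ncol(A)
  cnt <- matrix(0L, nrow = length(AA_EXTENDED), ncol = L,
                dimnames = list(AA_EXTENDED, NULL))
  for (r in AA_EXTENDED) cnt[r, ] <- colSums(A == r)
  cnt
}

.align_profiles <- function(A, B, matrix) {
  S <- .profile_col_scores(A, B, matrix$scores)
  res <- gotoh_align_cpp(S, matrix$gap_open, matrix$gap_extend)
  expand <- function(M, idx) {
    out <- matrix(GAP_CHAR, nrow = nrow(M), ncol = length(idx),
                  dimnames = list(rownames(M), NULL))
    out[, idx > 0] <- M[, idx[idx > 0], drop = FALSE]
    out
  }
  rbind(expand(A, res$ai), expand(B, res$bi))
}

#' Sum-of-pairs score of an alignment
#'
#' Scores a multiple alignment as the sum over all sequence pairs of their
#' induced pairwise alignment scores (substitution scores over residue pairs,
#' affine gap penalties per pairwise gap run; columns gapped in both rows of a
#' pair are ignored). Used to compare alignments of the same sequences.
#'
#' @param aln An [as_alignment] matrix.
#' @param matrix A [substitution_matrix].
#' @return Numeric sum-of-pairs score.
#' @export
sum_of_pairs_score <- function(aln, matrix = blosum62()) {
  m <- unclass(aln)
  n <- nrow(m)
  total <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ri <- m[i, ]; rj <- m[j, ]
    keep <- !(ri == GAP_CHAR & rj == GAP_CHAR)
    ri <- ri[keep]; rj <- rj[keep]
    both <- ri != GAP_CHAR & rj != GAP_CHAR
    total <- total + sum(matrix$scores[cbind(ri[both], rj[both])])
    for (g in list(ri == GAP_CHAR, rj == GAP_CHAR)) {
      if (any(g)) {
        runs <- rle(g)
        lens <- runs$lengths[runs$values]
        total <- total + sum(matrix$gap_open + (lens - 1) * matrix$gap_extend)
      }
    }
  }
  total
}
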