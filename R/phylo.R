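#' Observed proportion-of-differences (p) distance matrix
#'
#' For every pair of aligned rows, the fraction of differing residues over
#' the comparable columns. With `deletion = "pairwise"` a column is comparable
#' for a pair when neither row has a gap there; with `"complete"` all columns
#' containing any gap are removed before any pair is compared.
#'
#' @param aln An [as_alignment] matrix (>= 2 rows).
#' @param deletion Gap treatment, `"pairwise"` (default) or `"complete"`.
#' @return Symmetric numeric matrix of p-distances with zero diagonal and
#'   taxon dimnames.
#' @examples
#' aln <- as_alignment(c(a = "ACDE", b = "ACDF"))
#' p_distance_matrix(aln)
#' @export
p_distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- unclass(aln)
  if (nrow(m) < 2L) stop("need at least 2 aligned sequences")
  if (deletion == "complete") {
    keep <- colSums(m == GAP_CHAR) == 0L
    if (!any(keep)) stop("complete deletion removed every column")
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- m[i, ] != GAP_CHAR & m[j, ] != GAP_CHAR
    if (!any(comp))
      stop(sprintf("no comparable columns between '%s' and '%s'",
                   rownames(m)[i], rownames(m)[j]))
    D[i, j] <- D[j, i] <- sum(m[i, comp] != m[j, comp]) / sum(comp)
  }
  D
}

#' Jukes-Cantor distance correction
#'
#' Corrects an observed proportion of differing sites for multiple hits under
#' the equal-rates Jukes-Cantor model. For `states = "aa20"` (default) the
#' 20-state amino-acid generalisation is used,
#' \deqn{d = -\frac{19}{20}\,\ln\!\left(1 - \frac{20}{19}\,p\right),}
#' and for `states = "nt4"` the classical 4-state nucleotide form
#' (factors 3/4, 4/3). Distances are undefined at or beyond the saturation
#' point `p >= (s - 1)/s`.
#'
#' @param p Observed proportion(s) of differing sites, in `[0, (s-1)/s)`.
#' @param states `"aa20"` or `"nt4"`.
#' @return Corrected distance(s), substitutions per site.
#' @examples
#' jc_correct(0.5)          # 0.70985...
#' jc_correct(0.5, "nt4")   # 0.82396...
#' @export
jc_correct <- function(p, states = c("aa20", "nt4")) {
  states <- match.arg(states)
  b <- if (states == "aa20") 19 / 20 else 3 / 4
  if (any(!is.finite(p)) || any(p < 0))
    stop("p must be finite and >= 0")
  if (any(p >= b))
    stop(sprintf("saturated distance: p >= %g, Jukes-Cantor undefined", b))
  -b * log(1 - p / b)
}

#' @rdname jc_correct
#' @param D A symmetric p-distance matrix (from [p_distance_matrix()]).
#' @export
jc_distance_matrix <- function(D, states = c("aa20", "nt4")) {
  states <- match.arg(states)
  out <- D
  out[] <- 0
  off <- row(D) != col(D)
  out[off] <- jc_correct(D[off], states)
  out
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the standard Q-criterion. At equal Q the
#' pair whose (sorted) representative taxon names are lexicographically
#' smallest is joined, so the output is deterministic on degenerate inputs.
#' Negative branch lengths produced by the three-point/NJ formulas are
#' clamped to zero with the deficit moved onto the sister branch, preserving
#' the path length between the joined pair. The result is an unrooted binary
#' tree (basal trifurcation) as an [ape::read.tree] `"phylo"` object.
#'
#' @param D Symmetric distance matrix with taxon dimnames (>= 3 taxa), or a
#'   `dist` object.
#' @return An unrooted `"phylo"` tree.
#' @examples
#' D <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' nj_tree(D)
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (is.null(rownames(D))) stop("distance matrix needs taxon dimnames")
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  if (any(!is.finite(D)) || any(D < 0))
    stop("distances must be finite and non-negative")
  frag <- rownames(D)
  rep_name <- rownames(D)

  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  bl <- function(x) sprintf("%.15g", x)

  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      paste(sort(c(rep_name[ij[1]], rep_name[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    l <- clamp_pair(li, lj)
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], bl(l[1]), frag[j], bl(l[2]))
    new_rep <- min(rep_name[i], rep_name[j])
    dk <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2
    dk <- pmax(dk, 0)
    D2 <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D2, dk), c(dk, 0))
    frag <- c(frag[-c(i, j)], new_frag)
    rep_name <- c(rep_name[-c(i, j)], new_rep)
    rownames(D) <- colnames(D) <- rep_name
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ls <- pmax(c(l1, l2, l3), 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], bl(ls[1]),
                 frag[2], bl(ls[2]), frag[3], bl(ls[3]))
  newick_read(nwk)
}

#' Column-bootstrap supports for the NJ tree
#'
#' Runs the full distance pipeline (p-distance, Jukes-Cantor correction,
#' neighbor joining) on the input alignment, then on `B` column resamples
#' (columns drawn with replacement). The support of an internal edge of the
#' point-estimate tree is 100 times the fraction of successful replicate
#' trees containing the same bipartition. Replicates in which any pairwise
#' distance saturates are dropped, counted, and reported in a warning.
#'
#' @param aln An [as_alignment] matrix.
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Optional integer seed for the column resampling.
#' @param deletion,states Passed to [p_distance_matrix()] and [jc_correct()].
#' @return The point-estimate `"phylo"` tree with `node.label` set to the
#'   supports (in `[0, 100]`, `NA` on the basal node) and attributes
#'   `bootstrap_B` and `bootstrap_dropped`.
#' @export
bootstrap_support <- function(aln, B = 100L, seed = NULL,
                              deletion = "pairwise", states = "aa20") {
  if (B < 1L) stop("need B >= 1 bootstrap replicates")
  pipeline <- function(a) {
    nj_tree(jc_distance_matrix(p_distance_matrix(a, deletion), states))
  }
  point <- pipeline(aln)
  m <- unclass(aln)
  reps <- .with_seed(seed, {
    lapply(seq_len(B), function(b) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      tryCatch(pipeline(as_alignment(m[, cols, drop = FALSE])),
               error = function(e) NULL)
    })
  })
  ok <- !vapply(reps, is.null, TRUE)
  if (any(!ok))
    warning(sprintf("%d of %d bootstrap replicates dropped (saturated or degenerate distances)",
                    sum(!ok), B))
  if (!any(ok)) stop("all bootstrap replicates failed")
  rep_splits <- lapply(reps[ok], tree_bipartitions)
  pp <- ape::prop.part(point)
  labs <- attr(pp, "labels")
  ntip <- length(labs)
  supports <- rep(NA_real_, point$Nnode)
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    split <- .canonical_split(side, labs)
    supports[k] <- 100 * mean(vapply(rep_splits, function(s) split %in% s, TRUE))
  }
  point$node.label <- supports
  attr(point, "bootstrap_B") <- as.integer(B)
  attr(point, "bootstrap_dropped") <- sum(!ok)
  point
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Canonical string labels for every internal edge's leaf-set split: each
#' split is represented by the side not containing the alphabetically first
#' taxon, with its members sorted and joined by `|`.
#'
#' @param tree A `"phylo"` tree.
#' @return Character vector of canonical split labels.
#' @export
tree_bipartitions <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  ntip <- length(labs)
  out <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    out <- c(out, .canonical_split(side, labs))
  }
  unique(out)
}

.canonical_split <- function(side, labs) {
  anchor <- min(labs)
  if (anchor %in% side) side <- setdiff(labs, side)
  paste(sort(side), collapse = "|")
}

#' Newick serialization
#'
#' Thin wrappers around [ape::write.tree()] / [ape::read.tree()] that
#' round-trip trees with branch lengths and internal-node (support) labels,
#' and turn malformed input into an informative error.
#'
#' @param tree A `"phylo"` tree.
#' @return `newick_write()`: a single Newick string. `newick_read()`: a
#'   `"phylo"` tree.
#' @examples
#' tr <- newick_read("(A:1,B:2,(C:3,D:4)95:1);")
#' newick_write(tr)
#' @export
newick_write <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  ape::write.tree(tree)
}

#' @rdname newick_write
#' @param text A Newick string.
#' @export
newick_read <- function(text) {
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) stop("malformed Newick string: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick string (unbalanced parentheses or empty input): ",
         substr(text, 1, 60), call. = FALSE)
  if (!is.null(tr$node.label)) {
    lab <- suppressWarnings(as.numeric(tr$node.label))
    if (!all(is.na(lab))) tr$node.label <- lab
  }
  tr
}
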