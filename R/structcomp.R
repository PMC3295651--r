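#' Structure models
#'
#' A minimal atomic-coordinate container: a data frame of atoms with columns
#' `type` (`ATOM`/`HETATM`), `chain`, `resno`, `insert`, `resid` (residue
#' name), `elety` (atom name), `element` and `x,y,z` (angstroms). The
#' `(chain, resno, insert, elety)` tuple identifies an atom uniquely.
#'
#' @param atoms Data frame with the columns above (`insert`, `element`,
#'   `type`, `chain` optional; defaults `""`, guessed from `elety`, `"ATOM"`,
#'   `"A"`).
#' @return An object of class `"structure_model"`.
#' @export
structure_model <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  for (col in c("resno", "resid", "elety", "x", "y", "z"))
    if (is.null(atoms[[col]])) stop("atoms need column '", col, "'")
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$element))
    atoms$element <- substr(gsub("[0-9]", "", atoms$elety), 1, 1)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite atom coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate atoms (chain/resno/insert/name): ",
         paste(head(unique(key[duplicated(key)]), 3), collapse = "; "))
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  at <- x$atoms
  cat(sprintf("structure_model: %d atoms, %d residues, chain(s) %s\n",
              nrow(at), length(unique(paste(at$chain, at$resno, at$insert))),
              paste(unique(at$chain), collapse = ",")))
  invisible(x)
}

#' Read and write PDB-format coordinates
#'
#' `read_structure()` parses ATOM/HETATM records of a PDB file (first model;
#' for duplicated altloc atoms, conformer `A` is retained; insertion codes
#' preserved) into a [structure_model]; `write_structure()` writes one back.
#' Parsing is delegated to \pkg{bio3d}.
#'
#' @param path PDB file path.
#' @param model Model number to read (default 1).
#' @return `read_structure()`: a [structure_model]; `write_structure()`:
#'   `path`, invisibly.
#' @export
read_structure <- function(path, model = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = model > 1L,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no ATOM records in ", path)
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  structure_model(data.frame(
    type = at$type, chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert), resid = at$resid,
    elety = at$elety,
    element = if (!is.null(at$elesy)) at$elesy else NA_character_,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE))
}

#' @rdname read_structure
#' @param x A [structure_model].
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "structure_model"))
  at <- x$atoms
  bio3d::write.pdb(file = path,
                   type = at$type, resno = at$resno, resid = at$resid,
                   chain = at$chain, insert = ifelse(nzchar(at$insert),
                                                     at$insert, ""),
                   elety = at$elety, elesy = at$element,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))))
  invisible(path)
}

#' Lobe/domain definitions for a bilobed SBP fold
#'
#' Residue-number sets for the N-terminal and C-terminal lobes (and
#' optionally the connecting hinge) of a two-domain solute-binding protein.
#' The sets must be disjoint.
#'
#' @param N_lobe,C_lobe,hinge Integer vectors of residue numbers (ranges may
#'   be given as e.g. `c(1:137)`).
#' @return An object of class `"domain_definition"`.
#' @export
domain_definition <- function(N_lobe, C_lobe, hinge = integer(0)) {
  N_lobe <- as.integer(N_lobe); C_lobe <- as.integer(C_lobe)
  hinge <- as.integer(hinge)
  if (length(intersect(N_lobe, C_lobe)) || length(intersect(N_lobe, hinge)) ||
      length(intersect(C_lobe, hinge)))
    stop("lobe/hinge residue ranges must be disjoint")
  structure(list(N_lobe = N_lobe, C_lobe = C_lobe, hinge = hinge),
            class = "domain_definition")
}

#' C-alpha coordinates of selected residues
#'
#' @param x A [structure_model].
#' @param resno Optional residue numbers to keep (in this order).
#' @param chain Optional chain id.
#' @return Numeric matrix (n x 3) with resno rownames.
#' @export
ca_coords <- function(x, resno = NULL, chain = NULL) {
  at <- x$atoms
  at <- at[at$elety == "CA" & at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain == chain, , drop = FALSE]
  if (!is.null(resno)) {
    idx <- match(resno, at$resno)
    if (any(is.na(idx)))
      stop("missing C-alpha atoms for residue(s): ",
           paste(resno[is.na(idx)], collapse = ", "))
    at <- at[idx, , drop = FALSE]
  }
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- at$resno
  m
}

#' Kabsch least-squares superposition
#'
#' Optimal rigid-body superposition of paired coordinate sets: the rotation
#' and translation minimising the RMSD of `moving` onto `fixed`, with the
#' reflection case corrected to a proper rotation (det = +1). Coordinates are
#' rows; the aligned set is `moving %*% rotation + translation` (row-wise).
#'
#' @param fixed,moving Paired n x 3 coordinate matrices (n >= 3,
#'   non-collinear).
#' @return A list of class `"superposition"`: `rotation` (3 x 3 proper
#'   orthogonal), `translation` (length-3), `rmsd`, `n`, and `aligned` (the
#'   transformed `moving` set).
#' @examples
#' p <- matrix(rnorm(30), 10)
#' kabsch_superpose(p, p)$rmsd
#' @export
kabsch_superpose <- function(fixed, moving) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  if (!all(dim(fixed) == dim(moving)) || ncol(fixed) != 3L)
    stop("need paired n x 3 coordinate matrices")
  n <- nrow(fixed)
  if (n < 3L) stop("need at least 3 paired points")
  cf <- colMeans(fixed); cm <- colMeans(moving)
  P <- sweep(moving, 2L, cm); Q <- sweep(fixed, 2L, cf)
  for (M in list(P, Q)) {
    sv <- svd(M, nu = 0, nv = 0)$d
    if (sv[2] <= 1e-8 * max(sv[1], 1e-12))
      stop("degenerate (collinear) point set")
  }
  C <- crossprod(P, Q)               # 3 x 3
  sv <- svd(C)
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aligned <- P %*% R
  rmsd <- sqrt(mean(rowSums((aligned - Q)^2)))
  aligned <- sweep(aligned, 2L, cf, "+")
  structure(list(rotation = R, translation = cf - as.numeric(cm %*% R),
                 rmsd = rmsd, n = n, aligned = aligned),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition of %d paired atoms: rmsd %.4f A, rotation %.2f deg\n",
              x$n, x$rmsd, rotation_angle(x$rotation)))
  invisible(x)
}

#' Rotation angle of a rotation matrix
#'
#' @param R A 3 x 3 proper rotation matrix.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Inter-domain hinge-opening angle
#'
#' Measures the rigid-body rotation of the N lobe between two conformations
#' of a bilobed solute-binding protein (the Venus-flytrap opening). Structure
#' `b` is first superposed onto structure `a` using the paired C-lobe
#' C-alpha atoms; the rotation that then optimally superposes the
#' (C-lobe-aligned) N lobe of `b` onto the N lobe of `a` is extracted and its
#' angle returned.
#'
#' @param a,b [structure_model] objects.
#' @param domains A [domain_definition()] in the residue numbering of `a`.
#' @param pairing Optional data frame with columns `resno_a`, `resno_b`
#'   giving the residue correspondence; by default residues are paired by
#'   equal residue number.
#' @return Hinge angle in degrees, with attributes `c_lobe_rmsd`,
#'   `n_lobe_rmsd` and `n_pairs` (per lobe).
#' @export
hinge_angle <- function(a, b, domains, pairing = NULL) {
  stopifnot(inherits(a, "structure_model"), inherits(b, "structure_model"),
            inherits(domains, "domain_definition"))
  if (is.null(pairing)) {
    common <- intersect(a$atoms$resno[a$atoms$elety == "CA"],
                        b$atoms$resno[b$atoms$elety == "CA"])
    pairing <- data.frame(resno_a = common, resno_b = common)
  }
  lobe_pairs <- function(lobe) {
    sel <- pairing[pairing$resno_a %in% lobe, , drop = FALSE]
    if (nrow(sel) < 3L)
      stop("fewer than 3 paired C-alpha atoms in lobe")
    list(a = ca_coords(a, sel$resno_a), b = ca_coords(b, sel$resno_b))
  }
  cp <- lobe_pairs(domains$C_lobe)
  np <- lobe_pairs(domains$N_lobe)
  sup_c <- kabsch_superpose(cp$a, cp$b)
  # apply the C-lobe transform to b's N-lobe atoms
  nb_aligned <- sweep(np$b %*% sup_c$rotation, 2L, sup_c$translation, "+")
  sup_n <- kabsch_superpose(np$a, nb_aligned)
  ang <- rotation_angle(sup_n$rotation)
  attr(ang, "c_lobe_rmsd") <- sup_c$rmsd
  attr(ang, "n_lobe_rmsd") <- sup_n$rmsd
  attr(ang, "n_pairs") <- c(N = nrow(np$a), C = nrow(cp$a))
  ang
}

#' Residue pairing from a pairwise sequence alignment
#'
#' Aligns the (C-alpha) sequences of two structures and returns the
#' ungapped aligned residue-number pairs, for use as the `pairing` argument
#' of [hinge_angle()] between paralogous structures.
#'
#' @param a,b [structure_model] objects.
#' @param matrix A [substitution_matrix].
#' @return Data frame with columns `resno_a`, `resno_b`.
#' @export
pair_residues_by_alignment <- function(a, b, matrix = blosum62()) {
  seq_of <- function(x, nm) {
    at <- x$atoms[x$atoms$elety == "CA" & x$atoms$type == "ATOM", ]
    list(seq = setNames(paste0(.aa3to1(at$resid), collapse = ""), nm),
         resno = at$resno)
  }
  sa <- seq_of(a, "a"); sb <- seq_of(b, "b")
  pw <- pairwise_global_align(sa$seq, sb$seq, matrix)
  m <- unclass(pw$alignment)
  ia <- cumsum(m[1, ] != GAP_CHAR); ib <- cumsum(m[2, ] != GAP_CHAR)
  both <- m[1, ] != GAP_CHAR & m[2, ] != GAP_CHAR
  data.frame(resno_a = sa$resno[ia[both]], resno_b = sb$resno[ib[both]])
}
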