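# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (direct recursion / bisection / closed forms).

# Exhaustive global-alignment score by enumerating every alignment (as a
# move sequence: M = aligned pair, A = gap in a, B = gap in b) and scoring
# affine gap runs post hoc. Feasible for sequences up to ~6 residues.
enum_align_best <- function(a, b, mat) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  go <- mat$gap_open; ge <- mat$gap_extend
  score_moves <- function(moves) {
    i <- 0L; j <- 0L; s <- 0
    for (mv in moves) {
      if (mv == "M") {
        i <- i + 1L; j <- j + 1L
        s <- s + mat$scores[ca[i], cb[j]]
      } else if (mv == "A") j <- j + 1L else i <- i + 1L
    }
    r <- rle(moves)
    for (k in seq_along(r$values))
      if (r$values[k] != "M")
        s <- s + go + (r$lengths[k] - 1) * ge
    s
  }
  best <- -Inf
  rec <- function(i, j, moves) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score_moves(moves))
      return(invisible(NULL))
    }
    if (i <= length(ca) && j <= length(cb)) rec(i + 1L, j + 1L, c(moves, "M"))
    if (i <= length(ca)) rec(i + 1L, j, c(moves, "B"))
    if (j <= length(cb)) rec(i, j + 1L, c(moves, "A"))
  }
  rec(1L, 1L, character(0))
  best
}

# Exhaustive 3-way sum-of-pairs optimum under LINEAR gap costs (every gap
# column costs `gap` against a residue, gap-gap pairs cost 0), by memoised
# recursion over (i, j, k). Used with a linear-gap substitution matrix
# (gap_open == gap_extend) so progressive alignments are comparable.
enum3_best <- function(sa, sb, sc, mat, gap) {
  A <- strsplit(sa, "")[[1]]; B <- strsplit(sb, "")[[1]]
  C <- strsplit(sc, "")[[1]]
  S <- mat$scores
  memo <- new.env(hash = TRUE, parent = emptyenv())
  pair <- function(x, y) {
    if (is.na(x) && is.na(y)) 0
    else if (is.na(x) || is.na(y)) gap
    else S[x, y]
  }
  rec <- function(i, j, k) {
    if (i == 0L && j == 0L && k == 0L) return(0)
    key <- paste(i, j, k)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    for (da in 0:1) for (db in 0:1) for (dc in 0:1) {
      if (da + db + dc == 0L) next
      if ((da && i == 0L) || (db && j == 0L) || (dc && k == 0L)) next
      x <- if (da) A[i] else NA
      y <- if (db) B[j] else NA
      z <- if (dc) C[k] else NA
      col <- pair(x, y) + pair(x, z) + pair(y, z)
      best <- max(best, col + rec(i - da, j - db, k - dc))
    }
    memo[[key]] <- best
    best
  }
  rec(length(A), length(B), length(C))
}

# Rodrigues rotation matrix, independent of the package internals.
oracle_rotation <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# One-site ITC heats with the bound complex found by bisection on the
# mass-action equation (free ligand xf solves xf + n*M*xf/(Kd+xf) = X).
oracle_itc_heats <- function(n, Kd, dH, volumes, V0, M0, X0,
                             displacement = TRUE) {
  m <- M0; x <- 0; Qprev <- 0
  q <- numeric(length(volumes))
  for (i in seq_along(volumes)) {
    dil <- 1 - volumes[i] / V0
    m <- m * dil
    x <- x * dil + X0 * volumes[i] / V0
    if (x <= 0) {
      mx <- 0
    } else {
      f <- function(xf) xf + n * m * xf / (Kd + xf) - x
      lo <- 0; hi <- x
      for (it in 1:200) {
        mid <- (lo + hi) / 2
        if (f(mid) > 0) hi <- mid else lo <- mid
      }
      mx <- x - (lo + hi) / 2
    }
    Q <- dH * V0 * mx
    q[i] <- Q - Qprev +
      if (displacement) (volumes[i] / V0) * (Q + Qprev) / 2 else 0
    Qprev <- Q
  }
  list(q = q, Q_final = Qprev, MX_final = mx)
}

# Small fixed-format PDB writer for parser tests (independent of bio3d).
pdb_lines <- function(df) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          df$type, seq_len(nrow(df)),
          paste0(" ", df$elety), if (is.null(df$alt)) "" else df$alt,
          df$resid, df$chain, df$resno, "", df$x, df$y, df$z, 1, 0,
          df$element)
}

# Consensus sequence carrying a clade signature on a fixed scaffold.
signature_scaffold <- function(spec, length_out = 540, fill = "A") {
  s <- rep(fill, length_out)
  s[as.integer(names(spec))] <- spec
  paste0(s, collapse = "")
}
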