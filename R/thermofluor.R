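#' Melt curves
#'
#' A thermal-shift (thermofluor) melt curve: fluorescence versus temperature
#' on a strictly increasing grid of at least 10 points, labelled with the
#' protein and (optionally) the ligand present.
#'
#' @param temperature Temperatures in degrees C, strictly increasing.
#' @param fluorescence Fluorescence readings (arbitrary units), same length.
#' @param protein,ligand Labels; an apo curve has `ligand = ""`.
#' @return An object of class `"melt_curve"`.
#' @export
melt_curve <- function(temperature, fluorescence, protein = "", ligand = "") {
  temperature <- as.numeric(temperature)
  fluorescence <- as.numeric(fluorescence)
  if (length(temperature) != length(fluorescence))
    stop("temperature and fluorescence must have equal length")
  if (length(temperature) < 10L)
    stop("need at least 10 points in a melt curve")
  if (any(diff(temperature) <= 0))
    stop("temperature grid must be strictly increasing")
  if (any(!is.finite(temperature)) || any(!is.finite(fluorescence)))
    stop("non-finite values in melt curve")
  structure(list(temperature = temperature, fluorescence = fluorescence,
                 protein = as.character(protein),
                 ligand = as.character(ligand)),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("melt_curve '%s'%s: %d points, %.1f-%.1f degC\n", x$protein,
              if (nzchar(x$ligand)) paste0(" + ", x$ligand) else " (apo)",
              length(x$temperature), min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' Melt-curve CSV input/output
#'
#' Curves are stored as two-column CSV with header
#' `temperature_C,fluorescence`; protein/ligand labels travel in leading
#' comment lines (`# protein=`, `# ligand=`). Values round-trip exactly.
#'
#' @param path CSV file path.
#' @return `read_melt_csv()`: a [melt_curve]; `write_melt_csv()`: `path`,
#'   invisibly.
#' @export
read_melt_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (length(hit)) sub(paste0("^#\\s*", key, "="), "", hit[1]) else ""
  }
  tab <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"))
  if (!all(c("temperature_C", "fluorescence") %in% names(tab)))
    stop("melt CSV needs header temperature_C,fluorescence: ", path)
  melt_curve(tab$temperature_C, tab$fluorescence, get("protein"),
             get("ligand"))
}

#' @rdname read_melt_csv
#' @param curve A [melt_curve].
#' @export
write_melt_csv <- function(curve, path) {
  stopifnot(inherits(curve, "melt_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# protein=%s", curve$protein),
               sprintf("# ligand=%s", curve$ligand),
               "temperature_C,fluorescence",
               sprintf("%.17g,%.17g", curve$temperature,
                       curve$fluorescence)), con)
  invisible(path)
}

#' Melting temperature from the first derivative
#'
#' Extracts the apparent melting temperature of a thermofluor curve as the
#' signed extremum of the first derivative of (optionally moving-average
#' smoothed) fluorescence with respect to temperature, refined to sub-grid
#' precision by parabolic interpolation through the extremum and its two
#' neighbours. With `derivative_sign = 1` (default, for dye-binding curves
#' in which fluorescence rises on unfolding) the maximum of dF/dT is used;
#' with `-1` the minimum, matching instruments that export an inverted
#' derivative. A curve whose derivative extremum does not stand out from the
#' noise floor (or a flat curve) raises a "no transition" error.
#'
#' @param curve A [melt_curve] (or anything accepted by [melt_curve()]).
#' @param smoothing_window Moving-average width in points (odd; default 5;
#'   1 disables smoothing).
#' @param derivative_sign `+1` or `-1` (see above).
#' @param window Optional `c(lo, hi)` temperature scan window in degrees C;
#'   default: the full grid.
#' @return An object of class `"tm_fit"` with elements `Tm` (degrees C),
#'   `derivative_extremum` (signed dF/dT at the peak), `flags` (character;
#'   e.g. `"edge"` when the extremum sits on the window boundary), plus the
#'   smoothed curve and derivative used.
#' @examples
#' cv <- simulate_melt_curve(Tm = 60)
#' extract_tm(cv)$Tm
#' @export
extract_tm <- function(curve, smoothing_window = 5L, derivative_sign = 1,
                       window = NULL) {
  stopifnot(inherits(curve, "melt_curve"))
  if (!derivative_sign %in% c(-1, 1))
    stop("derivative_sign must be +1 or -1")
  w <- as.integer(smoothing_window)
  if (w < 1L || w %% 2L == 0L) stop("smoothing_window must be odd and >= 1")
  Tg <- curve$temperature
  f <- .movavg(curve$fluorescence, w)
  n <- length(Tg)
  d <- numeric(n)
  d[1] <- (f[2] - f[1]) / (Tg[2] - Tg[1])
  d[n] <- (f[n] - f[n - 1]) / (Tg[n] - Tg[n - 1])
  i <- 2:(n - 1)
  d[i] <- (f[i + 1] - f[i - 1]) / (Tg[i + 1] - Tg[i - 1])
  if (is.null(window)) window <- range(Tg)
  in_win <- which(Tg >= window[1] & Tg <= window[2])
  if (length(in_win) < 3L) stop("scan window contains fewer than 3 points")
  sd_ <- derivative_sign * d
  peak_rel <- which.max(sd_[in_win])
  peak <- in_win[peak_rel]
  base <- median(sd_[in_win])
  noise <- mad(sd_[in_win])
  if (!(sd_[peak] > base) ||
      (noise > 0 && (sd_[peak] - base) < 5 * noise))
    stop("no transition: derivative extremum indistinct from the noise floor")
  flags <- character(0)
  if (peak == in_win[1] || peak == in_win[length(in_win)]) {
    flags <- c(flags, "edge")
    Tm <- Tg[peak]
  } else {
    Tm <- .parabolic_vertex(Tg[(peak - 1):(peak + 1)],
                            sd_[(peak - 1):(peak + 1)])
    if (!is.finite(Tm) || Tm < Tg[peak - 1] || Tm > Tg[peak + 1]) {
      flags <- c(flags, "interpolation-fallback")
      Tm <- Tg[peak]
    }
  }
  structure(list(Tm = Tm, derivative_extremum = d[peak],
                 derivative_sign = derivative_sign, flags = flags,
                 protein = curve$protein, ligand = curve$ligand,
                 temperature = Tg, smoothed = f, derivative = d,
                 window = window),
            class = "tm_fit")
}

.movavg <- function(x, w) {
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Vertex abscissa of the parabola through three (x, y) points.
.parabolic_vertex <- function(x, y) {
  X <- cbind(1, x, x^2)
  cf <- unname(solve(X, y))
  if (abs(cf[3]) < .Machine$double.eps) return(NA_real_)
  -cf[2] / (2 * cf[3])
}

#' @export
print.tm_fit <- function(x, ...) {
  cat(sprintf("Tm = %.2f degC (%s%s)%s\n", x$Tm, x$protein,
              if (nzchar(x$ligand)) paste0(" + ", x$ligand) else ", apo",
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

#' @export
coef.tm_fit <- function(object, ...) c(Tm = object$Tm)

#' @export
plot.tm_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$temperature, x$smoothed, type = "l", xlab = "temperature (degC)",
       ylab = "fluorescence (AU)", ...)
  graphics::abline(v = x$Tm, lty = 2)
  plot(x$temperature, x$derivative_sign * x$derivative, type = "l",
       xlab = "temperature (degC)", ylab = "signed dF/dT")
  graphics::abline(v = x$Tm, lty = 2)
  invisible(x)
}

#' Ligand-induced melting-temperature shift
#'
#' `delta_tm()` is the apparent Tm of the liganded (holo) sample minus that
#' of the apo sample, in degrees C; destabilisation keeps its negative sign.
#'
#' @param apo,holo [extract_tm()] fits (or plain Tm values).
#' @return Numeric shift in degrees C.
#' @export
delta_tm <- function(apo, holo) {
  tm <- function(x) if (inherits(x, "tm_fit")) x$Tm else as.numeric(x)
  tm(holo) - tm(apo)
}

#' Delta-Tm screening table with a significance threshold
#'
#' Builds the ligand-by-protein table of apparent Tm shifts from apo and
#' holo melt curves. Replicate curves of the same protein/ligand pair are
#' averaged at the Tm level. Shifts with `|dTm| < threshold` are masked as
#' not significant (shown as a dash); the comparison is inclusive, so a
#' shift exactly at the threshold is reported. Rows are ordered by
#' descending mean significant shift.
#'
#' @param apo_curves List of apo [melt_curve]s (one or more per protein;
#'   `ligand` must be `""`).
#' @param holo_curves List of liganded [melt_curve]s.
#' @param threshold Significance threshold in degrees C (default 1.5).
#' @param ... Passed to [extract_tm()].
#' @return An object of class `"shift_table"`: list with `delta` (numeric
#'   ligand x protein matrix), `significant` (logical matrix), `apo_tm`
#'   (named vector) and `threshold`.
#' @export
build_shift_table <- function(apo_curves, holo_curves, threshold = 1.5, ...) {
  stopifnot(is.list(apo_curves))
  if (inherits(apo_curves, "melt_curve")) apo_curves <- list(apo_curves)
  if (inherits(holo_curves, "melt_curve")) holo_curves <- list(holo_curves)
  tm_of <- function(cv) extract_tm(cv, ...)$Tm
  apo_prot <- vapply(apo_curves, function(c) c$protein, "")
  apo_tms <- vapply(apo_curves, tm_of, 0)
  apo_tm <- tapply(apo_tms, apo_prot, mean)
  if (length(holo_curves) == 0L) {
    empty <- matrix(numeric(0), nrow = 0, ncol = length(apo_tm),
                    dimnames = list(NULL, names(apo_tm)))
    return(structure(list(delta = empty, significant = empty > 0,
                          apo_tm = apo_tm, threshold = threshold),
                     class = "shift_table"))
  }
  hp <- vapply(holo_curves, function(c) c$protein, "")
  hl <- vapply(holo_curves, function(c) c$ligand, "")
  if (any(!nzchar(hl))) stop("holo curves must carry a ligand label")
  missing_apo <- setdiff(unique(hp), names(apo_tm))
  if (length(missing_apo))
    stop("missing apo reference for protein(s): ",
         paste(missing_apo, collapse = ", "))
  htm <- vapply(holo_curves, tm_of, 0)
  agg <- tapply(htm, list(hl, hp), mean)
  prots <- sort(unique(c(names(apo_tm), hp)))
  delta <- matrix(NA_real_, nrow = nrow(agg), ncol = length(prots),
                  dimnames = list(rownames(agg), prots))
  for (p in colnames(agg))
    delta[, p] <- agg[, p] - apo_tm[[p]]
  signif <- !is.na(delta) & abs(delta) >= threshold
  ord <- order(-apply(ifelse(signif, delta, NA), 1L,
                      function(r) if (all(is.na(r))) -Inf else
                        mean(r, na.rm = TRUE)))
  structure(list(delta = delta[ord, , drop = FALSE],
                 significant = signif[ord, , drop = FALSE],
                 apo_tm = apo_tm, threshold = threshold),
            class = "shift_table")
}

#' @export
print.shift_table <- function(x, ...) {
  cat(sprintf("delta-Tm shift table (threshold %.1f degC; '-' = not significant)\n",
              x$threshold))
  print.data.frame(as.data.frame(format(x)), right = TRUE)
  invisible(x)
}

#' @export
format.shift_table <- function(x, digits = 1, ...) {
  out <- ifelse(x$significant & !is.na(x$delta),
                formatC(x$delta, format = "f", digits = digits), "-")
  dimnames(out) <- dimnames(x$delta)
  out
}

#' @rdname build_shift_table
#' @param x A `shift_table`.
#' @param path Output CSV path.
#' @export
write_shift_table <- function(x, path) {
  stopifnot(inherits(x, "shift_table"))
  tab <- as.data.frame(format(x), stringsAsFactors = FALSE)
  tab <- cbind(ligand = rownames(tab), tab)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
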