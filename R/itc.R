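#' Titration series
#'
#' Per-injection integrated heats of an isothermal titration calorimetry
#' (ITC) experiment in a perfusion (overfill) cell, with the metadata needed
#' for fitting: cell volume, initial cell (macromolecule) concentration and
#' syringe (ligand) concentration. Internal units are litres, molar and
#' calories; the CSV interface uses the instrument-style uL/uM/ucal.
#'
#' @param volumes Injection volumes in litres (> 0, >= 5 injections).
#' @param heats Observed integrated heats in calories, one per injection.
#' @param V0 Active cell volume in litres.
#' @param M0 Initial cell protein concentration, molar.
#' @param X0 Syringe ligand concentration, molar.
#' @param temperature Temperature in kelvin (default 310.15, i.e. 37 C).
#' @param first_injection_excluded Default handling of the customary small
#'   first injection when fitting (default `TRUE`).
#' @return An object of class `"titration_series"`.
#' @export
titration_series <- function(volumes, heats, V0, M0, X0,
                             temperature = 310.15,
                             first_injection_excluded = TRUE) {
  volumes <- as.numeric(volumes); heats <- as.numeric(heats)
  if (length(volumes) < 5L) stop("need at least 5 injections")
  if (length(heats) != length(volumes))
    stop("heats and volumes must have equal length")
  if (any(volumes <= 0)) stop("injection volumes must be positive")
  .check_scalar(V0, "V0", lower = 0, strict_lower = TRUE)
  .check_scalar(M0, "M0", lower = 0, strict_lower = TRUE)
  .check_scalar(X0, "X0", lower = 0)
  if (any(!is.finite(heats))) stop("non-finite heats")
  structure(list(volumes = volumes, heats = heats, V0 = V0, M0 = M0,
                 X0 = X0, temperature = temperature,
                 first_injection_excluded = isTRUE(first_injection_excluded)),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("titration_series: %d injections, V0 %.3g mL, M0 %.3g uM, X0 %.3g uM\n",
              length(x$volumes), x$V0 * 1e3, x$M0 * 1e6, x$X0 * 1e6))
  invisible(x)
}

#' Molar ratio (total ligand / total protein in the cell) per injection
#' @param series A [titration_series].
#' @return Numeric vector.
#' @export
molar_ratio <- function(series) {
  tot <- .cell_totals(series$volumes, series$V0, series$M0, series$X0)
  tot$X / tot$M
}

# Perfusion-cell running totals after each injection: each injection of
# volume v displaces the fraction v/V0 of the current cell content.
.cell_totals <- function(volumes, V0, M0, X0) {
  k <- length(volumes)
  M <- numeric(k); X <- numeric(k)
  m <- M0; x <- 0
  for (i in seq_len(k)) {
    dil <- 1 - volumes[i] / V0
    if (dil <= 0) stop("injection volume exceeds the cell volume")
    m <- m * dil
    x <- x * dil + X0 * volumes[i] / V0
    M[i] <- m; X[i] <- x
  }
  list(M = M, X = X)
}

#' Forward one-site ITC binding model
#'
#' Predicts the per-injection integrated heats of a one-site binding
#' isotherm in a perfusion cell. After injection \eqn{i} the running total
#' concentrations \eqn{M_i} (protein) and \eqn{X_i} (ligand) follow the
#' perfusion dilution \eqn{M_i = M_{i-1}(1 - v_i/V_0)},
#' \eqn{X_i = X_{i-1}(1 - v_i/V_0) + X_0 v_i/V_0}. The bound-complex
#' concentration is the exact mass-action root
#' \deqn{[MX]_i = \tfrac12\left[(nM_i + X_i + K_d) -
#'   \sqrt{(nM_i + X_i + K_d)^2 - 4 n M_i X_i}\right],}
#' the cumulative heat is \eqn{Q_i = \Delta H\, V_0\, [MX]_i}, and the
#' injection heat includes the displaced-volume correction
#' \eqn{q_i = Q_i - Q_{i-1} + (v_i/V_0)(Q_i + Q_{i-1})/2}.
#'
#' @param n Stoichiometry (sites per protein).
#' @param Kd Dissociation constant, molar (> 0).
#' @param dH Binding enthalpy, calories per mole of ligand.
#' @param volumes Injection volumes, litres.
#' @param V0,M0,X0 Cell volume (L), cell protein (M), syringe ligand (M).
#' @param series Alternatively, a [titration_series] supplying
#'   `volumes`/`V0`/`M0`/`X0`.
#' @return Numeric vector of per-injection heats in calories.
#' @examples
#' forward_one_site(1, 2.1e-6, -1e4, volumes = rep(1e-5, 25),
#'                  V0 = 1.4e-3, M0 = 2e-5, X0 = 3e-4)
#' @export
forward_one_site <- function(n, Kd, dH, volumes = series$volumes,
                             V0 = series$V0, M0 = series$M0, X0 = series$X0,
                             series = NULL) {
  .check_scalar(n, "n", lower = 0, strict_lower = TRUE)
  .check_scalar(Kd, "Kd", lower = 0, strict_lower = TRUE)
  .check_scalar(dH, "dH")
  tot <- .cell_totals(volumes, V0, M0, X0)
  b <- n * tot$M + tot$X + Kd
  disc <- b^2 - 4 * n * tot$M * tot$X
  if (any(disc < 0)) stop("internal error: negative discriminant")
  MX <- (b - sqrt(disc)) / 2
  Q <- dH * V0 * MX
  Qprev <- c(0, Q[-length(Q)])
  Q - Qprev + (volumes / V0) * (Q + Qprev) / 2
}

#' ITC series CSV input/output
#'
#' Series are stored as CSV with header
#' `injection_index,volume_uL,heat_ucal`, preceded by comment metadata lines
#' `# V0_mL=`, `# M0_uM=`, `# X0_uM=`, `# temp_C=`. Values round-trip
#' exactly.
#'
#' @param path CSV file path.
#' @return `read_itc_csv()`: a [titration_series]; `write_itc_csv()`:
#'   `path`, invisibly.
#' @export
read_itc_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (!length(hit)) stop("missing metadata '", key, "' in ", path)
    as.numeric(sub(paste0("^#\\s*", key, "="), "", hit[1]))
  }
  tab <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"))
  need <- c("injection_index", "volume_uL", "heat_ucal")
  if (!all(need %in% names(tab)))
    stop("ITC CSV needs header ", paste(need, collapse = ","), ": ", path)
  tab <- tab[order(tab$injection_index), ]
  titration_series(tab$volume_uL * 1e-6, tab$heat_ucal * 1e-6,
                   V0 = get("V0_mL") * 1e-3, M0 = get("M0_uM") * 1e-6,
                   X0 = get("X0_uM") * 1e-6,
                   temperature = get("temp_C") + 273.15)
}

#' @rdname read_itc_csv
#' @param series A [titration_series].
#' @export
write_itc_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# V0_mL=%.17g", series$V0 * 1e3),
               sprintf("# M0_uM=%.17g", series$M0 * 1e6),
               sprintf("# X0_uM=%.17g", series$X0 * 1e6),
               sprintf("# temp_C=%.17g", series$temperature - 273.15),
               "injection_index,volume_uL,heat_ucal",
               sprintf("%d,%.17g,%.17g", seq_along(series$volumes),
                       series$volumes * 1e6, series$heats * 1e6)), con)
  invisible(path)
}

#' Fit the one-site binding model to a titration series
#'
#' Least-squares fit of the forward one-site model (see
#' [forward_one_site()]) to observed injection heats. The optimisation is
#' over `(n, log Ka, dH)` so the association constant stays positive, using
#' Levenberg-Marquardt (\pkg{minpack.lm}) from the heuristic initial guess
#' plus a fixed fan of perturbed starts (+/- 50 percent) to guard against
#' shallow minima; the best converged start wins. The customary small first
#' injection is excluded by default. Parameter standard errors come from the
#' Jacobian at the optimum; the Kd error is propagated from log Ka. A fit
#' whose residual standard deviation exceeds `lack_of_fit_tol` times the
#' largest observed heat magnitude is flagged (lack of fit, e.g. a
#' multi-site process).
#'
#' @param series A [titration_series].
#' @param initial Optional named list/vector with starting `n`, `Kd`, `dH`.
#' @param exclude_first Drop the first injection (default: the series'
#'   `first_injection_excluded` flag).
#' @param offset Also fit a constant per-injection heat offset (nuisance
#'   parameter for residual heats of dilution).
#' @param n_starts Number of starts (default 5: the heuristic start plus 4
#'   fixed perturbations).
#' @param lack_of_fit_tol Residual-sd threshold as a fraction of the largest
#'   heat magnitude (default 0.05).
#' @return An object of class `"itc_fit"`; see [coef.itc_fit()],
#'   [summary.itc_fit()], [predict.itc_fit()], [residuals.itc_fit()],
#'   [plot.itc_fit()].
#' @examples
#' s <- simulate_itc(Kd = 2.1e-6, dH = -1e4, M0 = 2e-5, X0 = 3e-4, seed = 1)
#' fit_one_site(s)
#' @export
fit_one_site <- function(series, initial = NULL, exclude_first = NULL,
                         offset = FALSE, n_starts = 5L,
                         lack_of_fit_tol = 0.05) {
  stopifnot(inherits(series, "titration_series"))
  if (is.null(exclude_first)) exclude_first <- series$first_injection_excluded
  use <- seq_along(series$heats)
  if (exclude_first) use <- use[-1L]
  if (length(use) < 5L) stop("fewer than 5 usable injections")
  q_obs <- series$heats[use]
  if (max(abs(q_obs)) <= 0) stop("no binding detected: all heats are zero")

  model_q <- function(par) {
    q <- forward_one_site(par[["n"]], exp(-par[["logKa"]]), par[["dH"]],
                          series = series)[use]
    if (offset) q <- q + par[["q0"]]
    q
  }
  resid_fn <- function(par) q_obs - model_q(par)

  start0 <- .itc_start(series, use, initial, offset)
  fac <- c(1, 0.5, 1.5, 0.75, 1.25, 0.6, 1.4)[seq_len(max(1L, n_starts))]
  fits <- list()
  for (f in fac) {
    st <- start0
    st[["n"]] <- start0[["n"]] * f
    st[["dH"]] <- start0[["dH"]] * f
    st[["logKa"]] <- start0[["logKa"]] + log(f)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  if (!length(fits))
    stop("one-site fit failed to converge from any start")
  rss <- vapply(fits, function(f) sum(f$fvec^2), 0)
  best <- fits[[which.min(rss)]]
  par <- best$par
  k <- length(q_obs); p <- length(par)
  dof <- max(k - p, 1L)
  sigma <- sqrt(sum(best$fvec^2) / dof)
  covm <- tryCatch({
    h <- best$hessian
    sigma^2 * solve(h)
  }, error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(covm), 0))
  names(se) <- names(par)
  Kd <- exp(-par[["logKa"]])
  coefs <- c(n = par[["n"]], Kd = Kd, dH = par[["dH"]])
  ses <- c(n = se[["n"]], Kd = Kd * se[["logKa"]], dH = se[["dH"]])
  if (offset) { coefs <- c(coefs, q0 = par[["q0"]]); ses <- c(ses, q0 = se[["q0"]]) }
  fitted <- model_q(par)
  lack <- sigma > lack_of_fit_tol * max(abs(q_obs))
  if (lack)
    warning(sprintf("lack of fit: residual sd %.3g exceeds %.0f%% of the largest heat",
                    sigma, 100 * lack_of_fit_tol))
  structure(list(coefficients = coefs, se = ses, Ka = 1 / Kd,
                 rss = sum(best$fvec^2), sigma = sigma, df = dof,
                 residuals = q_obs - fitted, fitted = fitted,
                 used = use, series = series, offset = offset,
                 lack_of_fit = lack, info = best$info,
                 message = best$message, n_starts = length(fits)),
            class = "itc_fit")
}

# Heuristic starting values: n = 1; dH from the first usable heat per mole
# injected; Kd placed an order of magnitude below the cell concentration.
.itc_start <- function(series, use, initial, offset) {
  v1 <- series$volumes[use[1]]
  dH0 <- series$heats[use[1]] / max(series$X0 * v1, 1e-30)
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -1e4
  st <- list(n = 1, logKa = -log(max(series$M0 / 10, 1e-12)), dH = dH0)
  if (!is.null(initial)) {
    initial <- as.list(initial)
    if (!is.null(initial$n)) st$n <- initial$n
    if (!is.null(initial$Kd)) st$logKa <- -log(initial$Kd)
    if (!is.null(initial$dH)) st$dH <- initial$dH
  }
  if (offset) st$q0 <- 0
  st
}

#' @export
print.itc_fit <- function(x, ...) {
  cf <- coef(x)
  cat("One-site ITC fit\n")
  cat(sprintf("  n   = %.3f +/- %.3f\n", cf[["n"]], x$se[["n"]]))
  cat(sprintf("  Kd  = %.4g M (%.4g uM) +/- %.2g uM\n", cf[["Kd"]],
              cf[["Kd"]] * 1e6, x$se[["Kd"]] * 1e6))
  cat(sprintf("  dH  = %.4g cal/mol +/- %.2g\n", cf[["dH"]], x$se[["dH"]]))
  if (x$offset) cat(sprintf("  q0  = %.3g cal\n", cf[["q0"]]))
  cat(sprintf("  residual sd %.3g cal on %d df%s\n", x$sigma, x$df,
              if (x$lack_of_fit) "  [lack-of-fit flag]" else ""))
  invisible(x)
}

#' @export
#' @rdname fit_one_site
#' @param object,x An `itc_fit`.
#' @param ... Unused.
coef.itc_fit <- function(object, ...) object$coefficients

#' @export
#' @rdname fit_one_site
summary.itc_fit <- function(object, ...) {
  tab <- data.frame(estimate = coef(object), std_error = object$se)
  structure(list(coefficients = tab, sigma = object$sigma,
                 rss = object$rss, df = object$df,
                 lack_of_fit = object$lack_of_fit), class = "summary.itc_fit")
}

#' @export
print.summary.itc_fit <- function(x, ...) {
  print(x$coefficients, digits = 4)
  cat(sprintf("residual sd %.3g on %d df; RSS %.3g%s\n", x$sigma, x$df,
              x$rss, if (x$lack_of_fit) "  [lack-of-fit flag]" else ""))
  invisible(x)
}

#' @export
#' @rdname fit_one_site
#' @param newdata Optional [titration_series] to predict heats for (all of
#'   its injections); by default the fitted heats of the injections used in
#'   the fit are returned.
predict.itc_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  cf <- coef(object)
  q <- forward_one_site(cf[["n"]], cf[["Kd"]], cf[["dH"]], series = newdata)
  if (object$offset) q <- q + cf[["q0"]]
  q
}

#' @export
#' @rdname fit_one_site
residuals.itc_fit <- function(object, ...) object$residuals

#' @export
#' @rdname fit_one_site
plot.itc_fit <- function(x, ...) {
  mr <- molar_ratio(x$series)[x$used]
  moles <- x$series$X0 * x$series$volumes[x$used]
  obs <- x$series$heats[x$used] / moles / 1000  # kcal per mole of injectant
  fit <- x$fitted / moles / 1000
  plot(mr, obs, xlab = "molar ratio (ligand/protein)",
       ylab = "kcal per mole of injectant", ...)
  graphics::lines(mr, fit)
  invisible(x)
}

#' @export
#' @rdname fit_one_site
#' @param nsim,seed See [stats::simulate()].
simulate.itc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  cf <- coef(object)
  .with_seed(seed, {
    q <- predict(object)
    as.data.frame(replicate(nsim, q + rnorm(length(q), 0, object$sigma)))
  })
}

#' Equilibrium fractional occupancy at a given free-ligand level
#'
#' Single-site occupancy `L / (Kd + L)` under the ligand-excess
#' approximation (free ligand approximately equal to total), appropriate for
#' reading off e.g. how much of a weak binder is complexed at an assay's
#' ligand concentration.
#'
#' @param L Ligand concentration, molar (>= 0).
#' @param Kd Dissociation constant, molar (> 0).
#' @return Occupancy in `[0, 1]`.
#' @examples
#' fraction_bound(500e-6, 655e-6)  # 0.4329
#' @export
fraction_bound <- function(L, Kd) {
  if (any(L < 0)) stop("L must be >= 0")
  if (any(Kd <= 0)) stop("Kd must be > 0")
  L / (Kd + L)
}
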