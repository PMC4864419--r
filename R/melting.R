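# Two-state bimolecular duplex melting by DSC.
#
# Model: non-self-complementary A + B <=> AB with total strand
# concentration CT (mol strands / L, equal strand amounts). With alpha the
# duplex fraction and K(T) the van't Hoff association constant anchored at
# alpha(Tm) = 1/2 (so K(Tm) = 4/CT), mass action gives
#   K (1 - alpha)^2 CT / 2 = alpha,
# solved in closed form per temperature. The excess heat capacity is
#   dCp(T) = -dH d(alpha)/dT (+ baseline),
# whose area over the transition equals the melting enthalpy.

R_GAS <- 8.314462618e-3  # kJ mol^-1 K^-1

# duplex fraction alpha(T) for the anchored bimolecular two-state model
two_state_alpha <- function(T_C, tm_C, dh, ct) {
  TK <- T_C + 273.15; TmK <- tm_C + 273.15
  # K anchored at alpha = 1/2: K(Tm) = 4/CT; dH > 0 for melting so the
  # association constant decreases with temperature
  K <- (4 / ct) * exp((dh / R_GAS) * (1 / TK - 1 / TmK))
  kap <- K * ct / 2
  # kap a^2 - (2 kap + 1) a + kap = 0 ; physical root in [0, 1]
  a <- ((2 * kap + 1) - sqrt((2 * kap + 1)^2 - 4 * kap^2)) / (2 * kap)
  pmin(pmax(a, 0), 1)
}

#' Default total strand concentration
#'
#' Strand molarity corresponding to a duplex load of `mg_ml` mg/ml for the
#' given duplex spec (0.9 mg/ml of the reference decamer by default).
#'
#' @param spec A [duplex_spec()] (default the PT-free decamer).
#' @param mg_ml Duplex mass concentration, mg/ml.
#' @return Total strand concentration, mol/L.
#' @export
default_ct <- function(spec = decamer_spec(), mg_ml = 0.9) {
  # average nucleotide residue masses (Na+ free acid form, g/mol)
  mass <- c(A = 313.2, C = 289.2, G = 329.2, T = 304.2)
  m1 <- sum(mass[spec$strand1$base]) + 18
  m2 <- sum(mass[spec$strand2$base]) + 18
  duplex_molar <- mg_ml / (m1 + m2)   # (g/L) / (g/mol) = mol/L
  2 * duplex_molar                    # two strands per duplex
}

#' Simulate a DSC excess-heat-capacity curve
#'
#' Two-state bimolecular melting with van't Hoff temperature dependence
#' anchored at `alpha(Tm) = 1/2`, a linear baseline, and optional Gaussian
#' noise.
#'
#' @param tm Melting temperature, degrees C.
#' @param dh Melting enthalpy, kJ/mol.
#' @param ct Total strand concentration, mol/L.
#' @param grid Temperature grid, degrees C (strictly increasing, must cover
#'   `tm`).
#' @param baseline Length-2 numeric (intercept, slope) of the linear
#'   baseline in kJ mol^-1 K^-1 (slope per degree C).
#' @param noise_sd Gaussian noise standard deviation (same units as dCp).
#' @param seed Integer seed (reproducible noise); `NULL` leaves the RNG
#'   state alone.
#' @return Object of class `dsc_curve`: data frame with columns `T_C` and
#'   `dCp`, attributes `ct` and `truth`.
#' @examples
#' curve <- simulate_dsc_curve(76.55, 300, seed = 1)
#' @export
simulate_dsc_curve <- function(tm, dh, ct = default_ct(),
                               grid = seq(25, 95, by = 0.2),
                               baseline = c(0, 0), noise_sd = 0, seed = NULL) {
  if (dh <= 0) stop("dh must be positive")
  if (!(min(grid) < tm && tm < max(grid)))
    stop("temperature grid must cover Tm")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be increasing")
  a <- two_state_alpha(grid, tm, dh, ct)
  # dCp = -dH dalpha/dT, centered finite differences on the grid
  dadT <- numeric(length(grid))
  dadT[-c(1L, length(grid))] <-
    (a[-(1:2)] - a[-((length(a) - 1L):length(a))]) /
    (grid[-(1:2)] - grid[-((length(grid) - 1L):length(grid))])
  dadT[1L] <- (a[2L] - a[1L]) / (grid[2L] - grid[1L])
  dadT[length(grid)] <- (a[length(a)] - a[length(a) - 1L]) /
    (grid[length(grid)] - grid[length(grid) - 1L])
  dcp <- -dh * dadT + baseline[1L] + baseline[2L] * (grid - grid[1L])
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      set.seed(seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    }
    dcp <- dcp + stats::rnorm(length(grid), 0, noise_sd)
  }
  structure(data.frame(T_C = grid, dCp = dcp),
            class = c("dsc_curve", "data.frame"),
            ct = ct, truth = list(tm = tm, dh = dh, baseline = baseline,
                                  noise_sd = noise_sd, seed = seed))
}

#' @export
print.dsc_curve <- function(x, ...) {
  cat(sprintf("DSC curve: %d points, %.1f-%.1f C, peak %.2f kJ/mol/K at %.2f C\n",
              nrow(x), min(x$T_C), max(x$T_C), max(x$dCp),
              x$T_C[which.max(x$dCp)]))
  invisible(x)
}

#' @export
plot.dsc_curve <- function(x, ...) {
  graphics::plot(x$T_C, x$dCp, type = "l", xlab = "Temperature (°C)",
                 ylab = expression(Delta * C[p] ~ "(kJ" ~ mol^-1 ~ K^-1 * ")"),
                 ...)
  invisible(x)
}

#' Calorimetric enthalpy and entropy by area integration
#'
#' Trapezoidal integrals of the baseline-subtracted excess heat capacity:
#' `dH_cal = integral dCp dT` and `dS = integral (dCp / T) dT` with
#' temperatures in kelvin for the entropy.
#'
#' @param curve A `dsc_curve` (or data frame with `T_C`, `dCp`),
#'   baseline-subtracted.
#' @return `integrate_enthalpy`: kJ/mol; `integrate_entropy`:
#'   kJ mol^-1 K^-1.
#' @export
integrate_enthalpy <- function(curve) {
  check_grid(curve)
  trapz(curve$T_C, curve$dCp)
}

#' @rdname integrate_enthalpy
#' @export
integrate_entropy <- function(curve) {
  check_grid(curve)
  trapz(curve$T_C, curve$dCp / (curve$T_C + 273.15))
}

check_grid <- function(curve) {
  if (is.unsorted(curve$T_C, strictly = TRUE))
    stop("temperature grid must be strictly increasing")
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1L) + y[-1L]) / 2)

# peak detection; errors when the curve is not single-peaked. Two local
# maxima count as separate peaks only when the smoothed curve dips to less
# than half the smaller maximum between them (a true valley, not noise).
find_peaks <- function(curve, min_frac = 0.5) {
  y <- stats::filter(curve$dCp, rep(1 / 5, 5), sides = 2)
  y[is.na(y)] <- curve$dCp[is.na(y)]
  ymax <- max(y)
  if (ymax <= 0) stop("no melting peak detected")
  is_peak <- which(diff(sign(diff(y))) == -2) + 1L
  big <- is_peak[y[is_peak] >= min_frac * ymax]
  if (length(big) > 1L) {
    for (k in seq_len(length(big) - 1L)) {
      valley <- min(y[big[k]:big[k + 1L]])
      if (valley < 0.5 * min(y[big[k]], y[big[k + 1L]]))
        stop("multiple peaks detected: not a two-state transition")
    }
  }
  curve$T_C[which.max(y)]
}

#' Fit the two-state bimolecular melting model to a DSC curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the
#' [simulate_dsc_curve()] model with a linear baseline and amplitude scale,
#' initialized at the curve maximum. Also reports the model-free area
#' integrals (`dh_cal`, `ds_cal`) over the baseline-subtracted curve.
#'
#' @param curve A `dsc_curve`.
#' @param ct Total strand concentration, mol/L (default: curve attribute,
#'   else [default_ct()]).
#' @return Object of class `melt_fit`: list with `tm` (degrees C), `dh_vh`
#'   (van't Hoff enthalpy, kJ/mol), `scale`, `baseline`, `dh_cal`,
#'   `ds_cal`, `fitted`, `residuals`, `rss`, `curve`.
#' @examples
#' curve <- simulate_dsc_curve(76.55, 300, seed = 1)
#' fit <- fit_two_state(curve)
#' coef(fit)
#' @export
fit_two_state <- function(curve, ct = NULL) {
  check_grid(curve)
  if (is.null(ct)) ct <- attr(curve, "ct") %||% default_ct()
  tm0 <- find_peaks(curve)
  model_dcp <- function(tm, dh, b0, b1, scale) {
    sim <- simulate_dsc_curve(tm, dh, ct, grid = curve$T_C,
                              baseline = c(0, 0), noise_sd = 0)
    scale * sim$dCp + b0 + b1 * (curve$T_C - curve$T_C[1L])
  }
  df <- data.frame(T_C = curve$T_C, dCp = curve$dCp)
  fit <- minpack.lm::nlsLM(
    dCp ~ model_dcp(tm, dh, b0, b1, scale),
    data = df,
    start = list(tm = tm0, dh = 300, b0 = 0, b1 = 0, scale = 1),
    lower = c(min(curve$T_C), 10, -Inf, -Inf, 0.01),
    upper = c(max(curve$T_C), 2000, Inf, Inf, 100),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$convInfo$isConv) stop("two-state fit did not converge")
  cf <- stats::coef(fit)
  base <- cf[["b0"]] + cf[["b1"]] * (curve$T_C - curve$T_C[1L])
  sub <- curve
  sub$dCp <- curve$dCp - base
  structure(list(tm = cf[["tm"]], dh_vh = cf[["dh"]],
                 scale = cf[["scale"]],
                 baseline = c(cf[["b0"]], cf[["b1"]]),
                 dh_cal = integrate_enthalpy(sub),
                 ds_cal = integrate_entropy(sub),
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit),
                 rss = sum(stats::residuals(fit)^2),
                 ct = ct, curve = curve, nls = fit),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("Two-state bimolecular melting fit\n")
  cat(sprintf("  Tm     = %.2f C\n", x$tm))
  cat(sprintf("  dH_vH  = %.1f kJ/mol (fitted)\n", x$dh_vh))
  cat(sprintf("  dH_cal = %.1f kJ/mol (area)\n", x$dh_cal))
  cat(sprintf("  dS     = %.4f kJ/mol/K (area of dCp/T)\n", x$ds_cal))
  cat(sprintf("  RSS    = %.4g\n", x$rss))
  invisible(x)
}

#' @export
summary.melt_fit <- function(object, ...) {
  s <- summary(object$nls)
  cat("Two-state bimolecular melting fit (", length(object$residuals),
      " points)\n\n", sep = "")
  stats::printCoefmat(s$coefficients)
  cat(sprintf("\nArea integrals: dH_cal = %.1f kJ/mol, dS = %.4f kJ/mol/K\n",
              object$dh_cal, object$ds_cal))
  invisible(s)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(tm = object$tm, dh_vh = object$dh_vh,
    dh_cal = object$dh_cal, ds_cal = object$ds_cal)
}

#' @export
residuals.melt_fit <- function(object, ...) object$residuals

#' @export
plot.melt_fit <- function(x, ...) {
  graphics::plot(x$curve$T_C, x$curve$dCp, pch = 16, cex = 0.4,
                 xlab = "Temperature (°C)",
                 ylab = expression(Delta * C[p] ~ "(kJ" ~ mol^-1 ~ K^-1 * ")"),
                 ...)
  graphics::lines(x$curve$T_C, x$fitted, col = 2, lwd = 2)
  graphics::abline(v = x$tm, lty = 3)
  invisible(x)
}

#' @export
simulate.melt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  out <- lapply(seq_len(nsim), function(k)
    simulate_dsc_curve(object$tm, object$dh_vh, object$ct,
                       grid = object$curve$T_C,
                       baseline = object$baseline,
                       noise_sd = stats::sd(object$residuals),
                       seed = if (is.null(seed)) NULL else seed + k - 1L))
  if (nsim == 1L) out[[1L]] else out
}
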