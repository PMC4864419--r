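# Karplus-based interconversion of vicinal J-couplings, deoxyribose
# pseudorotation and backbone torsion restraints.
#
# Conventions: angles in degrees; pseudorotation phase P in [0, 360) with
# S-type (C2'-endo, B-DNA) sugars at P ~ 90-270 and N-type (C3'-endo) near
# P ~ 0-36; pucker amplitude phi_m in degrees (real sugars ~ 30-45).

#' Karplus parameter set
#'
#' Coefficients of `3J(theta) = A cos^2(theta) + B cos(theta) + C` (Hz).
#' Defaults: proton-proton set A = 10.2, B = -0.8, C = 0; proton-phosphorus
#' set A = 15.3, B = -6.2, C = 1.5 (configurable; the classic generalized
#' coefficients for deoxyribose HH and H3'-P couplings).
#'
#' @param A,B,C Coefficients in Hz (A > 0).
#' @param label Free-text label ("HH" or "HP").
#' @return Object of class `karplus_params`.
#' @export
karplus_params <- function(A, B, C, label = "custom") {
  stopifnot(is.numeric(A), A > 0)
  structure(list(A = A, B = B, C = C, label = label),
            class = "karplus_params")
}

#' @rdname karplus_params
#' @export
karplus_hh <- function() karplus_params(10.2, -0.8, 0, "HH")

#' @rdname karplus_params
#' @export
karplus_hp <- function() karplus_params(15.3, -6.2, 1.5, "HP")

#' @export
print.karplus_params <- function(x, ...) {
  cat(sprintf("Karplus set [%s]: J(theta) = %.2f cos^2 + %.2f cos + %.2f Hz\n",
              x$label, x$A, x$B, x$C))
  invisible(x)
}

#' Evaluate the Karplus relationship
#'
#' @param theta Dihedral angle(s), degrees.
#' @param params A [karplus_params()].
#' @return 3J coupling(s) in Hz.
#' @examples
#' karplus_j(180, karplus_hh())  # 11.0
#' @export
karplus_j <- function(theta, params = karplus_hh()) {
  ct <- cos(deg2rad(theta))
  params$A * ct^2 + params$B * ct + params$C
}

#' Endocyclic torsions from pseudorotation
#'
#' `nu_j = phi_m * cos(P + 144 (j - 2))`, j = 0..4.
#'
#' @param P Pseudorotation phase, degrees.
#' @param phi_m Pucker amplitude, degrees.
#' @return Named numeric vector nu0..nu4 (degrees).
#' @export
pucker_to_endocyclic <- function(P, phi_m) {
  nu <- phi_m * cos(deg2rad(P + 144 * ((0:4) - 2)))
  names(nu) <- paste0("nu", 0:4)
  nu
}

#' Pseudorotation from endocyclic torsions
#'
#' Inverts [pucker_to_endocyclic()]:
#' `tan(P) = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72))`,
#' `phi_m = nu2 / cos(P)`, with quadrant handling via `atan2`.
#'
#' @param nu Numeric vector of the five endocyclic torsions nu0..nu4
#'   (degrees).
#' @return List with `P` (degrees in [0, 360)), `phi_m` (degrees) and
#'   `degenerate` (TRUE for a planar ring, where the phase is undefined).
#' @export
endocyclic_to_pucker <- function(nu) {
  stopifnot(length(nu) == 5L, all(is.finite(nu)))
  num <- (nu[5L] + nu[2L]) - (nu[4L] + nu[1L])
  den <- 2 * nu[3L] * (sin(deg2rad(36)) + sin(deg2rad(72)))
  if (abs(den) < 1e-9 && abs(num) < 1e-9)
    return(list(P = NA_real_, phi_m = 0, degenerate = TRUE))
  P <- rad2deg(atan2(num, den)) %% 360
  phi_m <- if (abs(cos(deg2rad(P))) < 1e-9)
    num / (2 * sin(deg2rad(P)) * (sin(deg2rad(36)) + sin(deg2rad(72))))
  else nu[3L] / cos(deg2rad(P))
  list(P = unname(P), phi_m = unname(phi_m), degenerate = FALSE)
}

# Empirical linear relations between the proton-proton dihedrals of the
# deoxyribose and the endocyclic torsions nu1/nu2 (standard deoxyribose
# geometry; configurable through `phase_relations`).
default_phase_relations <- function() {
  list("H1'H2'"  = function(nu1) 121.4 + 1.03 * nu1,
       "H1'H2''" = function(nu1) 0.9 + 1.02 * nu1,
       "H2'H3'"  = function(nu2) 2.4 + 1.06 * nu2,
       "H2''H3'" = function(nu2) 122.9 + 1.06 * nu2)
}

#' Predict sugar proton-proton couplings from the pucker state
#'
#' Computes the four H-H dihedrals from nu1/nu2 via the configured phase
#' relations, then applies the Karplus equation.
#'
#' @param P,phi_m Pseudorotation phase and amplitude, degrees.
#' @param params HH Karplus set.
#' @param phase_relations List of four functions mapping nu1 (first two) or
#'   nu2 (last two) to the corresponding H-H dihedral.
#' @return Named numeric vector of couplings (Hz):
#'   `J_H1'H2'`, `J_H1'H2''`, `J_H2'H3'`, `J_H2''H3'`.
#' @export
predict_sugar_couplings <- function(P, phi_m, params = karplus_hh(),
                                    phase_relations = default_phase_relations()) {
  nu <- pucker_to_endocyclic(P, phi_m)
  th <- c(phase_relations[["H1'H2'"]](nu[2L]),
          phase_relations[["H1'H2''"]](nu[2L]),
          phase_relations[["H2'H3'"]](nu[3L]),
          phase_relations[["H2''H3'"]](nu[3L]))
  j <- karplus_j(th, params)
  names(j) <- c("J_H1'H2'", "J_H1'H2''", "J_H2'H3'", "J_H2''H3'")
  j
}

#' Estimate the sugar pucker from measured couplings
#'
#' Deterministic grid search over P in [0, 360) (1 degree steps) and phi_m
#' in (20, 50) (0.5 degree steps) minimizing the sum of squared deviations
#' between predicted and observed couplings. At least two of the four H-H
#' couplings must be present.
#'
#' @param couplings Named numeric vector using the names of
#'   [predict_sugar_couplings()] output (missing couplings `NA` or absent).
#' @param params HH Karplus set.
#' @param phase_relations See [predict_sugar_couplings()].
#' @return Object of class `pucker_fit`: list with `P`, `phi_m`, `rss`
#'   (residual sum of squares, Hz^2), `n_obs`, and `observed`.
#' @examples
#' j <- predict_sugar_couplings(160, 36)
#' fit <- estimate_pucker(j)
#' fit$P   # ~160
#' @export
estimate_pucker <- function(couplings, params = karplus_hh(),
                            phase_relations = default_phase_relations()) {
  nm <- c("J_H1'H2'", "J_H1'H2''", "J_H2'H3'", "J_H2''H3'")
  obs <- couplings[intersect(names(couplings), nm)]
  obs <- obs[!is.na(obs)]
  if (length(obs) < 2L)
    stop("at least two sugar couplings are required")
  Ps <- seq(0, 359, by = 1)
  phis <- seq(20.5, 49.5, by = 0.5)
  best <- list(rss = Inf)
  for (phi in phis) {
    # vectorized over P for speed
    nu1 <- phi * cos(deg2rad(Ps - 144))
    nu2 <- phi * cos(deg2rad(Ps))
    pred <- rbind(
      "J_H1'H2'"  = karplus_j(phase_relations[["H1'H2'"]](nu1), params),
      "J_H1'H2''" = karplus_j(phase_relations[["H1'H2''"]](nu1), params),
      "J_H2'H3'"  = karplus_j(phase_relations[["H2'H3'"]](nu2), params),
      "J_H2''H3'" = karplus_j(phase_relations[["H2''H3'"]](nu2), params))
    rss <- colSums((pred[names(obs), , drop = FALSE] - obs)^2)
    i <- which.min(rss)
    if (rss[i] < best$rss)
      best <- list(P = Ps[i], phi_m = phi, rss = unname(rss[i]))
  }
  structure(c(best, list(n_obs = length(obs), observed = obs,
                         params = params)),
            class = "pucker_fit")
}

#' @export
print.pucker_fit <- function(x, ...) {
  cat(sprintf("Sugar pucker fit: P = %.1f deg, phi_m = %.1f deg (%s-type)\n",
              x$P, x$phi_m, if (x$P >= 90 && x$P < 270) "S" else "N"))
  cat(sprintf("  %d couplings, residual = %.3f Hz^2\n", x$n_obs, x$rss))
  invisible(x)
}

#' @export
coef.pucker_fit <- function(object, ...) {
  c(P = object$P, phi_m = object$phi_m)
}

#' Backbone torsion restraint helpers
#'
#' `epsilon_from_j` inverts the HP Karplus curve for the H3'-C3'-O3'-P
#' dihedral and applies the 120 degree shift relating it to epsilon
#' (C4'-C3'-O3'-P); the inversion branch lying in the B-DNA trans/-gauche
#' epsilon region (-210 to -120, i.e. 150..240 equivalent) is selected.
#' `zeta_from_epsilon` applies the linear BI-form epsilon-zeta correlation
#' (zeta = epsilon + delta_BI, default +90, so epsilon - zeta = -90).
#' `beta_classify` maps the small 3J(P-H5') values typical of B-DNA
#' (2-5 Hz) onto a trans beta restraint (180 deg).
#'
#' @param J Measured coupling, Hz.
#' @param params HP Karplus set.
#' @param shift Shift applied to the H3'-P dihedral to obtain epsilon
#'   (default -120; +120 exposed for the alternative convention).
#' @param width Half-width of the emitted restraint, degrees.
#' @return `epsilon_from_j`: list `center`, `width`, `lower`, `upper`
#'   (degrees, in (-180, 180]).
#' @export
epsilon_from_j <- function(J, params = karplus_hp(), shift = -120,
                           width = 30) {
  if (!is.finite(J) || J < 0) stop("J must be non-negative")
  A <- params$A; B <- params$B; C <- params$C
  jmax <- max(karplus_j(seq(0, 180, 0.5), params))
  if (J > jmax + 1e-9) stop("J = ", J, " Hz exceeds the Karplus maximum (",
                            round(jmax, 2), " Hz)")
  # solve A c^2 + B c + (C - J) = 0 for c = cos(theta)
  disc <- B^2 - 4 * A * (C - J)
  roots <- (-B + c(1, -1) * sqrt(max(disc, 0))) / (2 * A)
  roots <- roots[abs(roots) <= 1 + 1e-9]
  thetas <- rad2deg(acos(pmin(1, pmax(-1, roots))))
  cand <- c(thetas, -thetas)                    # J is even in theta
  eps <- wrap_angle(cand + shift)
  in_b <- eps[eps >= 150 | eps <= -120]         # B-DNA epsilon region
  center <- if (length(in_b)) in_b[which.max(abs(in_b))] else eps[1L]
  list(center = center, width = width,
       lower = wrap_angle(center - width), upper = wrap_angle(center + width))
}

#' @rdname epsilon_from_j
#' @param epsilon Epsilon torsion, degrees.
#' @param delta_bi Linear offset of the BI epsilon-zeta correlation
#'   (default +90).
#' @export
zeta_from_epsilon <- function(epsilon, delta_bi = 90, width = 30) {
  if (!is.finite(epsilon)) stop("epsilon must be finite")
  if (!(epsilon >= 150 || epsilon <= -120))
    stop("epsilon = ", epsilon, " outside the B-DNA range")
  center <- wrap_angle(epsilon + delta_bi)
  list(center = center, width = width,
       lower = wrap_angle(center - width), upper = wrap_angle(center + width))
}

#' @rdname epsilon_from_j
#' @param J_PH5 Measured 3J(P-H5') coupling, Hz.
#' @export
beta_classify <- function(J_PH5, width = 30) {
  if (!is.finite(J_PH5) || J_PH5 < 0) stop("J must be non-negative")
  if (J_PH5 >= 2 && J_PH5 <= 5)
    list(center = 180, width = width, lower = 180 - width,
         upper = wrap_angle(180 + width))
  else "unclassified"
}

# wrap into (-180, 180]
wrap_angle <- function(x) {
  y <- ((x + 180) %% 360) - 180
  ifelse(y == -180, 180, y)
}

#' Read a coupling table and report per-residue puckers
#'
#' @param path CSV with columns `residue`, `J_name`, `value_Hz`, where
#'   `J_name` uses the names of [predict_sugar_couplings()] output.
#' @param params HH Karplus set.
#' @return Data frame: residue, P, phi_m, rss, type ("S"/"N").
#' @export
pucker_report <- function(path, params = karplus_hh()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue", "J_name", "value_Hz")
  if (!all(need %in% names(tab))) stop("coupling table needs columns: ",
                                       paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$residue), function(g) {
    j <- stats::setNames(g$value_Hz, g$J_name)
    fit <- estimate_pucker(j, params)
    data.frame(residue = g$residue[1L], P = fit$P, phi_m = fit$phi_m,
               rss = fit$rss,
               type = if (fit$P >= 90 && fit$P < 270) "S" else "N",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$residue), , drop = FALSE]
}
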