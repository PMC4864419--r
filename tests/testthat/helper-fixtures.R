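# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture_template <- function(pt = "none") {
  key <- paste0("tmpl_", pt)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- build_bform_template(decamer_spec(pt))
  .fixtures[[key]]
}

fixture_spec <- function(pt = "none") decamer_spec(pt)

# independent distance helper (does not reuse package internals)
dist3 <- function(a, b) sqrt(sum((a - b)^2))

# random rigid transform of a structure model (for invariance tests)
random_rigid <- function(model, seed) {
  set.seed(seed)
  ang <- stats::runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3, 3)
  Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                 sin(ang[2]), 0, cos(ang[2])), 3, 3)
  Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0,
                 -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, 3)
  R <- Rx %*% Ry %*% Rz
  t <- stats::runif(3, -20, 20)
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% R
  model$x <- xyz[, 1] + t[1]
  model$y <- xyz[, 2] + t[2]
  model$z <- xyz[, 3] + t[3]
  model
}
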