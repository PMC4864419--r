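# Seeded synthetic-data generation: NOE peak tables, coupling sets,
# coordinate ensembles and DSC curves with the statistical structure each
# analysis stage assumes, so the whole pipeline runs offline.

#' Synthetic-data configuration
#'
#' @param seed Integer seed driving every stochastic generator.
#' @param noe_cutoff Proton-pair distance cutoff for synthetic NOE peaks, A
#'   (default 6).
#' @param volume_noise Fractional (lognormal) volume noise sd (default 0.1).
#' @param coupling_noise Gaussian coupling noise sd, Hz (default 0.5).
#' @param n_models Ensemble size (default 20).
#' @param jitter_sd Isotropic per-coordinate jitter sd, A (default 0.1).
#' @param dsc List of DSC parameters (tm, dh, ct, noise_sd).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1, noe_cutoff = 6, volume_noise = 0.1,
                         coupling_noise = 0.5, n_models = 20,
                         jitter_sd = 0.1,
                         dsc = list(tm = 76.55, dh = 300, ct = default_ct(),
                                    noise_sd = 0)) {
  stopifnot(noe_cutoff <= 8, volume_noise >= 0, coupling_noise >= 0,
            jitter_sd >= 0)
  structure(list(seed = as.integer(seed), noe_cutoff = noe_cutoff,
                 volume_noise = volume_noise,
                 coupling_noise = coupling_noise,
                 n_models = as.integer(n_models), jitter_sd = jitter_sd,
                 dsc = dsc),
            class = "synth_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  expr
}

#' Synthesize an NOE peak table from a structure model
#'
#' Inverts the ISPA calibration: every proton pair closer than the cutoff
#' gets volume `(d_ref / d)^6 * V_ref`, multiplied by lognormal noise. The
#' cytosine H5-H6 reference pairs are included, so
#' [noe_restraints()] can self-calibrate. Exchangeable protons (imino/amino)
#' are flagged.
#'
#' @param model A `structure_model` with hydrogens.
#' @param cfg A [synth_config()].
#' @param v_ref Reference volume (arbitrary units, default 1000).
#' @param d_ref Reference distance (default 2.45 A).
#' @param d_min Minimum proton-pair distance retained (default 1.95 A);
#'   geminal pairs below it are trivial and are excluded, as in real peak
#'   lists.
#' @param mixing_times Mixing times (ms) of the non-exchangeable NOESY
#'   build-up series; one peak row is emitted per mixing time with
#'   independent noise, and the downstream calibration averages over them.
#' @return Data frame usable by [noe_restraints()].
#' @export
synth_noe_table <- function(model, cfg = synth_config(), v_ref = 1000,
                            d_ref = 2.45,
                            mixing_times = c(50, 100, 150, 200, 250),
                            d_min = 1.95) {
  h <- model[model$element == "H", , drop = FALSE]
  if (nrow(h) == 0L) stop("model has no hydrogens")
  exch_atoms <- c("H1", "H3", "H21", "H22", "H41", "H42", "H61", "H62")
  xyz <- model_xyz(h)
  n <- nrow(h)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    d <- sqrt(rowSums((xyz[(i + 1L):n, , drop = FALSE] -
                       matrix(xyz[i, ], n - i, 3L, byrow = TRUE))^2))
    sel <- which(d <= cfg$noe_cutoff & d >= d_min)
    for (s in sel) {
      j <- i + s
      rows[[length(rows) + 1L]] <- data.frame(
        res_a = h$resno[i], atom_a = h$atom[i],
        res_b = h$resno[j], atom_b = h$atom[j],
        dist = d[s],
        exchangeable = h$atom[i] %in% exch_atoms | h$atom[j] %in% exch_atoms,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  # exchangeable peaks: one row, two-mixing-time protocol (close contacts
  # appear at 50 ms, weak ones only at 200 ms); non-exchangeable peaks:
  # one row per mixing time of the build-up series
  exch <- tab[tab$exchangeable, , drop = FALSE]
  exch$mixing_time_ms <- ifelse(exch$dist <= 4.0, 50, 200)
  nonx <- tab[!tab$exchangeable, , drop = FALSE]
  nonx <- nonx[rep(seq_len(nrow(nonx)), each = length(mixing_times)), ,
               drop = FALSE]
  nonx$mixing_time_ms <- rep(mixing_times, length.out = nrow(nonx))
  tab <- rbind(exch, nonx)
  noise <- if (cfg$volume_noise > 0)
    with_seed(cfg$seed, exp(stats::rnorm(nrow(tab), 0, cfg$volume_noise)))
  else rep(1, nrow(tab))
  tab$volume <- (d_ref / tab$dist)^6 * v_ref * noise
  tab$class <- NA_character_
  tab$dist <- NULL
  rownames(tab) <- NULL
  tab
}

#' Synthesize per-residue sugar couplings from a structure model
#'
#' Forward route: coordinate pucker ([pucker_from_coords()]) ->
#' [predict_sugar_couplings()] -> Gaussian noise.
#'
#' @param model A `structure_model`.
#' @param cfg A [synth_config()].
#' @param params HH Karplus set.
#' @return Data frame: residue, J_name, value_Hz.
#' @export
synth_couplings <- function(model, cfg = synth_config(),
                            params = karplus_hh()) {
  res <- sort(unique(model$resno))
  rows <- list()
  for (r in res) {
    pk <- pucker_from_coords(model, r)
    if (isTRUE(pk$degenerate)) stop("degenerate sugar ring at residue ", r)
    j <- predict_sugar_couplings(pk$P, pk$phi_m, params)
    rows[[length(rows) + 1L]] <- data.frame(
      residue = r, J_name = names(j), value_Hz = unname(j),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (cfg$coupling_noise > 0)
    tab$value_Hz <- tab$value_Hz +
      with_seed(cfg$seed + 1L,
                stats::rnorm(nrow(tab), 0, cfg$coupling_noise))
  rownames(tab) <- NULL
  tab
}

#' Synthesize a coordinate ensemble by isotropic jitter
#'
#' Model 1 is the unperturbed input; models 2..n add independent Gaussian
#' jitter to every coordinate. A crude emulation of an NMR ensemble
#' (uncorrelated per-atom scatter), sufficient for RMSD and distance
#' statistics.
#'
#' @param model A `structure_model`.
#' @param cfg A [synth_config()] (fields `n_models`, `jitter_sd`, `seed`).
#' @param source Label for the ensemble.
#' @return A [structure_ensemble()].
#' @export
synth_ensemble <- function(model, cfg = synth_config(), source = "synthetic") {
  n <- cfg$n_models
  if (n < 2L) stop("ensemble size must be at least 2")
  models <- with_seed(cfg$seed + 2L, {
    lapply(seq_len(n), function(k) {
      m <- model
      if (k > 1L && cfg$jitter_sd > 0) {
        m$x <- m$x + stats::rnorm(nrow(m), 0, cfg$jitter_sd)
        m$y <- m$y + stats::rnorm(nrow(m), 0, cfg$jitter_sd)
        m$z <- m$z + stats::rnorm(nrow(m), 0, cfg$jitter_sd)
      }
      attr(m, "model") <- k
      m
    })
  })
  structure_ensemble(models, source = source)
}
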