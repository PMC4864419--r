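# Quantitative geometry on multi-model structure ensembles: least-squares
# superposition, pairwise and cross-ensemble RMSD, ensemble-averaged atom
# distances, groove localization, and coordinate-based sugar puckers.

#' Construct an ensemble from structure models
#'
#' @param models List of `structure_model` objects with identical atom
#'   inventory (same chain/residue/atom triples in the same order).
#' @param source Free-text label.
#' @return Object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(models, source = "") {
  stopifnot(is.list(models), length(models) >= 1L)
  key <- function(m) paste(m$chain, m$resno, m$atom)
  k1 <- key(models[[1L]])
  for (i in seq_along(models)) {
    if (!identical(key(models[[i]]), k1))
      stop("model ", i, " has a different atom inventory")
  }
  structure(list(models = models, source = source),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("structure_ensemble", if (nzchar(x$source)) paste0("[", x$source, "]"),
      ": ", length(x$models), " models, ", nrow(x$models[[1L]]),
      " atoms each\n", sep = "")
  invisible(x)
}

#' @export
length.structure_ensemble <- function(x) length(x$models)

# Atom selections. "backbone" follows the phosphodiester backbone
# convention {P, O1P/O2P (or S1P/S2P), O5', C5', C4', C3', O3'}; "heavy"
# excludes hydrogens; "all" keeps everything.
selection_mask <- function(model, selection = c("backbone", "heavy", "all"),
                           exclude_terminal = FALSE) {
  selection <- match.arg(selection)
  keep <- switch(selection,
    backbone = model$atom %in% c("P", "O1P", "O2P", "S1P", "S2P",
                                 "O5'", "C5'", "C4'", "C3'", "O3'"),
    heavy = model$element != "H",
    all = rep(TRUE, nrow(model)))
  if (exclude_terminal) {
    res <- sort(unique(model$resno))
    n <- length(res) / 2L
    term <- c(res[1L], res[n], res[n + 1L], res[2L * n])
    keep <- keep & !(model$resno %in% term)
  }
  keep
}

model_xyz <- function(model) as.matrix(model[, c("x", "y", "z")])

#' Least-squares rigid superposition
#'
#' Kabsch algorithm: finds the proper rotation + translation minimizing the
#' RMSD of the selected atoms of `mobile` onto `reference`, and applies it
#' to all atoms of `mobile`.
#'
#' @param mobile,reference `structure_model`s with matching selections.
#' @param selection `"backbone"`, `"heavy"` or `"all"`.
#' @param exclude_terminal Drop the terminal residue of each strand from
#'   the fit (end fraying).
#' @return List: `model` (transformed mobile), `rmsd` (over the selection),
#'   `R`, `t`.
#' @export
superpose <- function(mobile, reference, selection = "backbone",
                      exclude_terminal = FALSE) {
  mm <- selection_mask(mobile, selection, exclude_terminal)
  mr <- selection_mask(reference, selection, exclude_terminal)
  xm <- model_xyz(mobile)[mm, , drop = FALSE]
  xr <- model_xyz(reference)[mr, , drop = FALSE]
  if (nrow(xm) != nrow(xr)) stop("selections do not match 1:1")
  if (nrow(xm) < 3L) stop("at least 3 atoms are required")
  fit <- kabsch(xm, xr)
  out <- mobile
  xyz <- model_xyz(mobile) %*% fit$R
  xyz <- sweep(xyz, 2L, -fit$t)
  out$x <- xyz[, 1L]; out$y <- xyz[, 2L]; out$z <- xyz[, 3L]
  sel_fit <- sweep(xm %*% fit$R, 2L, -fit$t)
  list(model = out, rmsd = rmsd_xyz(sel_fit, xr), R = fit$R, t = fit$t)
}

#' Average pairwise RMSD of an ensemble
#'
#' Superposes every unordered model pair on the selection and reports the
#' mean and standard deviation of the pairwise RMSDs, plus the full
#' symmetric matrix.
#'
#' @param ensemble A [structure_ensemble()].
#' @inheritParams superpose
#' @return Object of class `rmsd_report`: list with `selection`, `mean`,
#'   `sd`, and `matrix`.
#' @export
average_pairwise_rmsd <- function(ensemble, selection = "backbone",
                                  exclude_terminal = FALSE) {
  n <- length(ensemble)
  if (n < 2L) stop("at least 2 models are required")
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- superpose(ensemble$models[[j]], ensemble$models[[i]],
                   selection, exclude_terminal)$rmsd
    m[i, j] <- r; m[j, i] <- r
  }
  vals <- m[upper.tri(m)]
  structure(list(selection = selection, mean = mean(vals),
                 sd = stats::sd(vals), matrix = m),
            class = "rmsd_report")
}

#' @export
print.rmsd_report <- function(x, ...) {
  cat(sprintf("Average pairwise RMSD (%s): %.3f +/- %.3f A over %d models\n",
              x$selection, x$mean, x$sd, nrow(x$matrix)))
  invisible(x)
}

# Mean structure after iterative superposition onto the evolving mean.
mean_structure <- function(ensemble, selection, exclude_terminal,
                           max_iter = 10L, tol = 1e-6) {
  ref <- ensemble$models[[1L]]
  for (it in seq_len(max_iter)) {
    fitted <- lapply(ensemble$models, function(m)
      superpose(m, ref, selection, exclude_terminal)$model)
    avg <- fitted[[1L]]
    xyz <- Reduce(`+`, lapply(fitted, model_xyz)) / length(fitted)
    delta <- max(abs(xyz - model_xyz(avg)))
    avg$x <- xyz[, 1L]; avg$y <- xyz[, 2L]; avg$z <- xyz[, 3L]
    ref <- avg
    if (delta < tol) break
  }
  ref
}

# Map atom inventories between two models, pairing phosphorothioate sulfurs
# with the corresponding oxygens (S1P <-> O1P, S2P <-> O2P).
map_selection <- function(a, b, selection, exclude_terminal) {
  canon <- function(m) {
    at <- m$atom
    at[at == "S1P"] <- "O1P"; at[at == "S2P"] <- "O2P"
    paste(m$chain, m$resno, at)
  }
  ka <- canon(a); kb <- canon(b)
  ma <- selection_mask(a, selection, exclude_terminal)
  mb <- selection_mask(b, selection, exclude_terminal)
  shared <- intersect(ka[ma], kb[mb])
  if (length(shared) < 3L) stop("selections cannot be mapped")
  list(ia = match(shared, ka), ib = match(shared, kb))
}

#' RMSD between two ensembles
#'
#' Superposes representatives of two ensembles on a shared heavy-atom
#' selection (phosphorothioate sulfurs are mapped onto the corresponding
#' phosphate oxygens by position) and reports the RMSD. Mode
#' `"mean-structure"` (default) compares the iteratively superposed mean
#' structures; mode `"model1"` compares the first models.
#'
#' @param ensemble_a,ensemble_b [structure_ensemble()]s.
#' @param selection Atom selection (default "heavy").
#' @param mode `"mean-structure"` or `"model1"`.
#' @param exclude_terminal Drop terminal residues (default TRUE; end
#'   fraying dominates otherwise).
#' @return RMSD in A.
#' @export
cross_ensemble_rmsd <- function(ensemble_a, ensemble_b, selection = "heavy",
                                mode = c("mean-structure", "model1"),
                                exclude_terminal = TRUE) {
  mode <- match.arg(mode)
  a <- if (mode == "mean-structure")
    mean_structure(ensemble_a, selection, exclude_terminal)
  else ensemble_a$models[[1L]]
  b <- if (mode == "mean-structure")
    mean_structure(ensemble_b, selection, exclude_terminal)
  else ensemble_b$models[[1L]]
  idx <- map_selection(a, b, selection, exclude_terminal)
  xa <- model_xyz(a)[idx$ia, , drop = FALSE]
  xb <- model_xyz(b)[idx$ib, , drop = FALSE]
  fit <- kabsch(xa, xb)
  rmsd_xyz(sweep(xa %*% fit$R, 2L, -fit$t), xb)
}

#' Ensemble-averaged atom-atom distance
#'
#' Euclidean distance between two atoms in every model; when several
#' symmetric site pairs are given, the mean pools all of them.
#'
#' @param ensemble A [structure_ensemble()].
#' @param pairs List of atom-pair specs, each
#'   `list(res_a, atom_a, res_b, atom_b)` (or a single such spec).
#' @return Object of class `distance_stat`: list with `mean`, `sd`,
#'   `per_model` (matrix models x pairs), `pairs`.
#' @examples
#' # d <- ensemble_distance(ens, list(list(2, "H2''", 3, "O2P"),
#' #                                  list(16, "H2''", 17, "O2P")))
#' @export
ensemble_distance <- function(ensemble, pairs) {
  if (!is.null(pairs$res_a) || (length(pairs) == 4L && !is.list(pairs[[1L]])))
    pairs <- list(pairs)
  pairs <- lapply(pairs, function(p) {
    if (is.null(names(p))) names(p) <- c("res_a", "atom_a", "res_b", "atom_b")
    as.list(p)
  })
  per <- sapply(pairs, function(p) {
    vapply(ensemble$models, function(m) {
      vnorm(atom_xyz(m, p$res_a, p$atom_a) - atom_xyz(m, p$res_b, p$atom_b))
    }, numeric(1L))
  })
  per <- matrix(per, nrow = length(ensemble))
  structure(list(mean = mean(per), sd = stats::sd(as.numeric(per)),
                 per_pair_mean = colMeans(per), per_model = per,
                 pairs = pairs),
            class = "distance_stat")
}

#' @export
print.distance_stat <- function(x, ...) {
  cat(sprintf("Ensemble distance: %.2f +/- %.2f A (%d models, %d site pair%s)\n",
              x$mean, x$sd, nrow(x$per_model), ncol(x$per_model),
              if (ncol(x$per_model) > 1L) "s pooled" else ""))
  invisible(x)
}

# Best-fit helix axis through the base-pair C1'-C1' midpoints: returns a
# point and a unit direction.
helix_axis <- function(model) {
  res <- sort(unique(model$resno))
  n <- length(res) / 2L
  mids <- t(vapply(seq_len(n), function(j) {
    (atom_xyz(model, j, "C1'") + atom_xyz(model, 2L * n + 1L - j, "C1'")) / 2
  }, numeric(3L)))
  cen <- colMeans(mids)
  sv <- svd(sweep(mids, 2L, cen))
  list(point = cen, dir = sv$v[, 1L])
}

axial_distance <- function(p, axis) {
  v <- p - axis$point
  vnorm(v - sum(v * axis$dir) * axis$dir)
}

# Major- and minor-groove edge atoms per base type.
groove_edge_atoms <- function(base) {
  if (base %in% c("A", "G"))
    list(major = c("O6", "N6", "N7"), minor = c("N3", "C2", "N2"))
  else
    list(major = c("O4", "N4", "C5"), minor = c("O2"))
}

#' Groove localization of an atom
#'
#' Labels an atom `major`, `minor`, or `exterior`. The atom is compared
#' against the base-edge atom sets of all residues: if its minimum distance
#' to the major-groove edge set beats the minor-groove set by more than
#' `margin` it is `major` (and vice versa). Atoms whose distance from the
#' helix axis exceeds the mean phosphorus axial distance are `exterior`
#' (checked first); ties fall back to the larger-margin label.
#'
#' @param model A duplex `structure_model`.
#' @param resno,atom The atom to classify.
#' @param margin Classification margin in A (default 0.5).
#' @param exterior_margin Allowance above the mean phosphorus axial
#'   distance before an atom counts as exterior (default 1.0 A; the
#'   phosphate substituents themselves sit at about the phosphorus
#'   radius).
#' @return Object of class `groove_assignment`: list with `label`,
#'   `margin` (achieved, A), `d_major`, `d_minor`, `axial`.
#' @export
groove_assign <- function(model, resno, atom, margin = 0.5,
                          exterior_margin = 1.0) {
  p <- atom_xyz(model, resno, atom)
  axis <- helix_axis(model)
  res <- sort(unique(model$resno))
  dmaj <- Inf; dmin <- Inf
  for (r in res) {
    base <- sub("^D|^RS|^SS", "", model$resname[model$resno == r][1L])
    base <- substr(base, nchar(base), nchar(base))
    if (base == "G" && grepl("SG$", model$resname[model$resno == r][1L]))
      base <- "G"
    edges <- groove_edge_atoms(base)
    for (a in edges$major) {
      i <- which(model$resno == r & model$atom == a)
      if (length(i)) dmaj <- min(dmaj, vnorm(p - as.numeric(model[i, c("x", "y", "z")])))
    }
    for (a in edges$minor) {
      i <- which(model$resno == r & model$atom == a)
      if (length(i)) dmin <- min(dmin, vnorm(p - as.numeric(model[i, c("x", "y", "z")])))
    }
  }
  p_rad <- mean(vapply(which(model$atom == "P"), function(i)
    axial_distance(as.numeric(model[i, c("x", "y", "z")]), axis), numeric(1L)))
  axial <- axial_distance(p, axis)
  label <- if (axial > p_rad + exterior_margin) "exterior"
           else if (dmaj < dmin - margin) "major"
           else if (dmin < dmaj - margin) "minor"
           else "exterior"
  structure(list(label = label, margin = abs(dmaj - dmin),
                 d_major = dmaj, d_minor = dmin, axial = axial,
                 p_radius = p_rad),
            class = "groove_assignment")
}

#' @export
print.groove_assignment <- function(x, ...) {
  cat(sprintf("Groove assignment: %s (d_major %.2f, d_minor %.2f, axial %.2f A)\n",
              x$label, x$d_major, x$d_minor, x$axial))
  invisible(x)
}

#' Sugar pucker from coordinates
#'
#' Computes the five endocyclic torsions from the ring atom coordinates
#' (nu0: C4'-O4'-C1'-C2' ... nu4: C3'-C4'-O4'-C1') and converts them to the
#' pseudorotation phase and amplitude.
#'
#' @param model A `structure_model`.
#' @param resno Residue number.
#' @return List: `P`, `phi_m`, `nu` (the five torsions), `type`
#'   (`"S"`/`"N"`), `degenerate`.
#' @export
pucker_from_coords <- function(model, resno) {
  g <- function(a) atom_xyz(model, resno, a)
  ring <- list(c("C4'", "O4'", "C1'", "C2'"),
               c("O4'", "C1'", "C2'", "C3'"),
               c("C1'", "C2'", "C3'", "C4'"),
               c("C2'", "C3'", "C4'", "O4'"),
               c("C3'", "C4'", "O4'", "C1'"))
  nu <- vapply(ring, function(q)
    point_torsion(g(q[1L]), g(q[2L]), g(q[3L]), g(q[4L])), numeric(1L))
  pk <- endocyclic_to_pucker(nu)
  if (pk$degenerate) return(c(pk, list(nu = nu, type = NA_character_)))
  c(pk, list(nu = nu, type = if (pk$P >= 90 && pk$P < 270) "S" else "N"))
}
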