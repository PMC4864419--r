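# NOE-derived distance restraints and Watson-Crick restraints.
#
# NOESY cross-peak volumes are converted to distances through the isolated
# spin pair approximation (ISPA) against the cytosine H5-H6 reference
# (2.45 A), binned into the standard strong/medium/weak classes, and written
# as XPLOR/CNS-dialect "assign" statements.

#' ISPA distance calibration
#'
#' Isolated spin pair approximation: NOE volume scales as d^-6, so
#' `d = reference_distance * (reference_volume / volume)^(1/6)`. The
#' cytosine H5-H6 intra-base distance (2.45 A) is the conventional
#' calibration reference.
#'
#' @param volume Cross-peak volume(s), arbitrary units, > 0.
#' @param reference_volume Volume of the reference peak (same units), > 0.
#' @param reference_distance Reference distance in A (default 2.45).
#' @return Calibrated distance(s) in A.
#' @examples
#' calibrate_distance(100, 100)        # 2.45
#' calibrate_distance(100 / 64, 100)   # 4.90
#' @export
calibrate_distance <- function(volume, reference_volume,
                               reference_distance = 2.45) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volume must be positive")
  if (any(!is.finite(reference_volume)) || any(reference_volume <= 0))
    stop("reference_volume must be positive")
  reference_distance * (reference_volume / volume)^(1 / 6)
}

# Distance bounds per NOE intensity class. Non-exchangeable protons use the
# 1.8-2.9 / 1.8-3.5 / 1.8-6.0 A bins; exchangeable protons the wider
# 1.8-4.0 / 1.8-5.0 / 1.8-8.0 A bins.
noe_bounds <- function(class, exchangeable) {
  upper <- if (exchangeable) c(strong = 4.0, medium = 5.0, weak = 8.0)
           else c(strong = 2.9, medium = 3.5, weak = 6.0)
  c(1.8, unname(upper[class]))
}

#' Classify an NOE peak into a distance restraint
#'
#' An explicit intensity class takes precedence; otherwise a calibrated
#' distance is thresholded (strong <= 2.9 A, medium <= 3.5 A, else weak).
#' Exchangeable-proton peaks without an explicit class are classified from
#' the mixing-time pattern: strong if observed at 50 ms with volume at least
#' `exch_strong_frac` of the reference volume, medium if observed at 50 ms
#' below that, weak if observed only at 200 ms or longer.
#'
#' @param peak One-row data frame (or list) with fields `res_a`, `atom_a`,
#'   `res_b`, `atom_b`, `exchangeable`, and optionally `class`,
#'   `mixing_time_ms`, `volume`.
#' @param calibrated_distance Calibrated distance in A, or `NA` if
#'   unavailable.
#' @param reference_volume Reference volume, used only for the exchangeable
#'   strong/medium split.
#' @param exch_strong_frac Volume fraction of the reference separating
#'   strong from medium exchangeable peaks at 50 ms (default 0.5).
#' @return One-row data frame: a distance restraint with columns `res_a`,
#'   `atom_a`, `res_b`, `atom_b`, `lower`, `upper`, `class`, `exchangeable`,
#'   `pseudoatom`.
#' @export
classify_noe <- function(peak, calibrated_distance = NA,
                         reference_volume = NA, exch_strong_frac = 0.5) {
  peak <- as.list(peak)
  exch <- isTRUE(as.logical(peak$exchangeable))
  cls <- peak$class
  if (is.null(cls) || is.na(cls) || !nzchar(cls) || cls == "unset") {
    if (exch) {
      mt <- peak$mixing_time_ms
      if (is.null(mt) || is.na(mt))
        stop("unclassifiable exchangeable peak: no class and no mixing time")
      if (mt <= 50) {
        cls <- if (!is.na(reference_volume) && !is.null(peak$volume) &&
                   peak$volume >= exch_strong_frac * reference_volume)
          "strong" else "medium"
      } else if (mt >= 200) cls <- "weak"
      else stop("unclassifiable exchangeable peak at ", mt, " ms")
    } else {
      if (is.na(calibrated_distance))
        stop("unclassifiable peak: no class and no calibrated distance")
      cls <- if (calibrated_distance <= 2.9) "strong"
             else if (calibrated_distance <= 3.5) "medium" else "weak"
    }
  }
  if (!cls %in% c("strong", "medium", "weak"))
    stop("unknown NOE class '", cls, "'")
  b <- noe_bounds(cls, exch)
  data.frame(res_a = peak$res_a, atom_a = peak$atom_a,
             res_b = peak$res_b, atom_b = peak$atom_b,
             lower = b[1L], upper = b[2L], class = cls,
             exchangeable = exch, pseudoatom = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build distance restraints from an NOE peak table
#'
#' Calibrates every non-exchangeable peak against the reference volume
#' (ISPA) and classifies all peaks into distance restraints. Peaks of the
#' same proton pair recorded at several mixing times (the NOESY build-up
#' series) are pooled: their calibrated distances are averaged and a single
#' restraint is emitted, using the reference volume measured at the same
#' mixing time when available.
#'
#' @param peaks Data frame with columns `res_a`, `atom_a`, `res_b`,
#'   `atom_b`, `volume`, `mixing_time_ms`, `exchangeable` and optionally
#'   `class`.
#' @param reference_volume Volume of the cytosine H5-H6 reference peak. If
#'   `NULL`, taken from the peak flagged by `atom_a == "H5"`, `atom_b ==
#'   "H6"` (or vice versa) within one residue, at the shortest mixing time.
#' @param reference_distance Reference distance (default 2.45 A).
#' @inheritParams classify_noe
#' @return Data frame of distance restraints (one row per peak).
#' @export
noe_restraints <- function(peaks, reference_volume = NULL,
                           reference_distance = 2.45,
                           exch_strong_frac = 0.5) {
  stopifnot(is.data.frame(peaks), nrow(peaks) > 0L)
  is_ref <- peaks$res_a == peaks$res_b &
    ((peaks$atom_a == "H5" & peaks$atom_b == "H6") |
     (peaks$atom_a == "H6" & peaks$atom_b == "H5"))
  ref_by_mt <- NULL
  if (is.null(reference_volume)) {
    ref <- peaks[is_ref, , drop = FALSE]
    if (nrow(ref) == 0L)
      stop("no cytosine H5-H6 reference peak found; supply reference_volume")
    # mean reference volume per mixing time, pooled over reference pairs
    ref_by_mt <- tapply(ref$volume, ref$mixing_time_ms, mean)
    reference_volume <- mean(ref$volume)
  }
  ref_for <- function(mt) {
    if (!is.null(ref_by_mt) && as.character(mt) %in% names(ref_by_mt))
      ref_by_mt[[as.character(mt)]] else reference_volume
  }
  pair_key <- paste(peaks$res_a, peaks$atom_a, peaks$res_b, peaks$atom_b,
                    peaks$exchangeable)
  out <- lapply(split(seq_len(nrow(peaks)), pair_key), function(idx) {
    g <- peaks[idx, , drop = FALSE]
    p <- g[1L, , drop = FALSE]
    if (!isTRUE(as.logical(p$exchangeable)) && all(!is.na(g$volume))) {
      d <- mean(vapply(seq_len(nrow(g)), function(k)
        calibrate_distance(g$volume[k], ref_for(g$mixing_time_ms[k]),
                           reference_distance), numeric(1L)))
    } else d <- NA
    classify_noe(p, d, ref_for(p$mixing_time_ms), exch_strong_frac)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pseudoatom correction for degenerate proton groups
#'
#' Distances to unresolved proton groups (methyls, degenerate methylenes)
#' are referred to a pseudoatom at the group centre; the upper bound is
#' widened by a correction (default +1.0 A for methyls). Pseudoatom names
#' follow the XPLOR convention of an `M`/`Q` prefix (e.g. `M7`, `Q5'`).
#'
#' @param restraint One-row distance-restraint data frame.
#' @param group `"methyl"` or `"degenerate"`.
#' @param correction Upper-bound increment in A (default 1.0).
#' @return The corrected restraint (flag `pseudoatom` set).
#' @export
pseudoatom_correction <- function(restraint, group = c("methyl", "degenerate"),
                                  correction = 1.0) {
  group <- match.arg(group)
  is_pseudo <- function(a) grepl("^[MQ]", a)
  if (!is_pseudo(restraint$atom_a) && !is_pseudo(restraint$atom_b))
    stop("restraint does not target a degenerate proton group ",
         "(pseudoatom names start with M or Q)")
  restraint$upper <- restraint$upper + correction
  restraint$pseudoatom <- TRUE
  restraint
}

#' Watson-Crick hydrogen-bond and planarity restraints
#'
#' Emits, for every base pair of the spec, the standard Watson-Crick
#' hydrogen-bond restraints (three for G.C, two for A.T) with heavy-heavy
#' target 2.8-3.0 A and hydrogen-acceptor target 1.8-2.0 A, plus one
#' planarity group per pair.
#'
#' @param spec A [duplex_spec()].
#' @param heavy Heavy-atom (donor-acceptor) bounds, length-2 (default
#'   c(2.8, 3.0)).
#' @param hydrogen Hydrogen-acceptor bounds (default c(1.8, 2.0)).
#' @return List with `hbonds` (data frame: res_donor, donor, hydrogen,
#'   res_acceptor, acceptor, heavy_lo, heavy_hi, h_lo, h_hi) and
#'   `planarity` (list of residue-number pairs).
#' @examples
#' wc <- generate_wc_restraints(decamer_spec())
#' nrow(wc$hbonds)  # 29 = 9 GC x 3 + 1 AT x 2
#' @export
generate_wc_restraints <- function(spec, heavy = c(2.8, 3.0),
                                   hydrogen = c(1.8, 2.0)) {
  stopifnot(inherits(spec, "duplex_spec"))
  n <- nrow(spec$strand1)
  rows <- list(); planarity <- list()
  for (j in seq_len(n)) {
    r1 <- spec$pairing$res1[j]; r2 <- spec$pairing$res2[j]
    b1 <- residue_base(spec, r1); b2 <- residue_base(spec, r2)
    pur <- if (b1 %in% c("A", "G")) b1 else b2
    pyr <- if (b1 %in% c("C", "T")) b1 else b2
    res_of <- function(side) {
      if ((side == "pur") == (b1 == pur)) r1 else r2
    }
    bonds <- wc_bond_table(pur, pyr)
    for (k in seq_len(nrow(bonds))) {
      rows[[length(rows) + 1L]] <- data.frame(
        res_donor = res_of(bonds$d_res[k]), donor = bonds$donor[k],
        hydrogen = bonds$hydrogen[k],
        res_acceptor = res_of(bonds$a_res[k]), acceptor = bonds$acceptor[k],
        heavy_lo = heavy[1L], heavy_hi = heavy[2L],
        h_lo = hydrogen[1L], h_hi = hydrogen[2L],
        stringsAsFactors = FALSE)
    }
    planarity[[j]] <- c(r1, r2)
  }
  list(hbonds = do.call(rbind, rows), planarity = planarity)
}

#' Fraction of restraints satisfied by a structure model
#'
#' @param model A `structure_model`.
#' @param restraints Distance-restraint data frame (from [noe_restraints()]
#'   or [classify_noe()]).
#' @return List: `fraction` satisfied, logical vector `satisfied`, numeric
#'   vector `distance`.
#' @export
check_restraints <- function(model, restraints) {
  d <- vapply(seq_len(nrow(restraints)), function(i) {
    a <- atom_xyz(model, restraints$res_a[i], restraints$atom_a[i])
    b <- atom_xyz(model, restraints$res_b[i], restraints$atom_b[i])
    vnorm(a - b)
  }, numeric(1L))
  ok <- d >= restraints$lower & d <= restraints$upper
  list(fraction = mean(ok), satisfied = ok, distance = d)
}

#' Fraction of Watson-Crick restraints satisfied by a model
#'
#' @param model A `structure_model`.
#' @param wc Output of [generate_wc_restraints()].
#' @return Fraction of hydrogen bonds whose heavy-heavy and
#'   hydrogen-acceptor distances both fall inside their target windows.
#' @export
check_wc_restraints <- function(model, wc) {
  hb <- wc$hbonds
  ok <- vapply(seq_len(nrow(hb)), function(i) {
    dd <- vnorm(atom_xyz(model, hb$res_donor[i], hb$donor[i]) -
                atom_xyz(model, hb$res_acceptor[i], hb$acceptor[i]))
    dh <- vnorm(atom_xyz(model, hb$res_donor[i], hb$hydrogen[i]) -
                atom_xyz(model, hb$res_acceptor[i], hb$acceptor[i]))
    dd >= hb$heavy_lo[i] && dd <= hb$heavy_hi[i] &&
      dh >= hb$h_lo[i] && dh <= hb$h_hi[i]
  }, logical(1L))
  mean(ok)
}

#' Restraint bookkeeping in the style of NMR structure statistics tables
#'
#' @param restraints Distance-restraint data frame.
#' @param n_bp Number of base pairs (strand 1 residues are 1..n_bp,
#'   strand 2 residues n_bp+1..2*n_bp).
#' @return Named list: total, intra-residue, inter-residue, sequential
#'   (same strand, |i-j| = 1) and non-sequential counts. Inter-strand
#'   contacts count as inter-residue non-sequential.
#' @export
restraint_summary <- function(restraints, n_bp) {
  same_res <- restraints$res_a == restraints$res_b
  strand <- function(r) ifelse(r <= n_bp, 1L, 2L)
  same_strand <- strand(restraints$res_a) == strand(restraints$res_b)
  seq1 <- !same_res & same_strand &
    abs(restraints$res_a - restraints$res_b) == 1L
  list(total = nrow(restraints),
       intra_residue = sum(same_res),
       inter_residue = sum(!same_res),
       sequential = sum(seq1),
       non_sequential = sum(!same_res & !seq1))
}

#' Write distance restraints as XPLOR/CNS assign statements
#'
#' Encoding: `assign (resid I and name A) (resid J and name B) d dminus
#' dplus` with `d` = upper bound, `dminus` = upper - lower, `dplus` = 0, so
#' the allowed interval is `[d - dminus, d + dplus]`. Class and flags are
#' kept in a trailing comment so the matching reader round-trips exactly.
#'
#' @param restraints Nonempty distance-restraint data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_restraint_table <- function(restraints, path) {
  if (!is.data.frame(restraints) || nrow(restraints) == 0L)
    stop("empty restraint list")
  lines <- vapply(seq_len(nrow(restraints)), function(i) {
    r <- restraints[i, ]
    sprintf("assign (resid %d and name %s) (resid %d and name %s) %.4f %.4f %.4f ! class=%s exch=%s pseudo=%s",
            r$res_a, r$atom_a, r$res_b, r$atom_b,
            r$upper, r$upper - r$lower, 0,
            r$class, r$exchangeable, r$pseudoatom)
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read an XPLOR/CNS-dialect distance restraint table
#'
#' Inverse of [write_restraint_table()].
#'
#' @param path File of `assign` statements.
#' @return Distance-restraint data frame.
#' @export
read_restraint_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[grepl("^\\s*assign", lines)]
  if (length(lines) == 0L) stop("no assign statements in ", path)
  pat <- paste0("^\\s*assign\\s*\\(resid\\s+(\\d+)\\s+and\\s+name\\s+(\\S+)\\)",
                "\\s*\\(resid\\s+(\\d+)\\s+and\\s+name\\s+(\\S+)\\)",
                "\\s+([0-9.eE+-]+)\\s+([0-9.eE+-]+)\\s+([0-9.eE+-]+)",
                "(\\s*!\\s*class=(\\S+)\\s+exch=(\\S+)\\s+pseudo=(\\S+))?")
  m <- regmatches(lines, regexec(pat, lines))
  out <- lapply(m, function(g) {
    if (length(g) == 0L) stop("unparsable assign line")
    d <- as.numeric(g[6L]); dminus <- as.numeric(g[7L]); dplus <- as.numeric(g[8L])
    data.frame(res_a = as.integer(g[2L]), atom_a = g[3L],
               res_b = as.integer(g[4L]), atom_b = g[5L],
               lower = d - dminus, upper = d + dplus,
               class = if (nzchar(g[10L])) g[10L] else NA_character_,
               exchangeable = identical(g[11L], "TRUE"),
               pseudoatom = identical(g[12L], "TRUE"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
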