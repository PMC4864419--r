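# Idealized B-form duplex template generation.
#
# The builder is base-pair centric: planar base geometries are positioned as
# Watson-Crick pairs by least-squares satisfaction of the hydrogen-bond
# distance targets, pairs are stacked with fiber-like helical symmetry
# (rise 3.38 A, twist 36 deg/bp), and each deoxyribose + 5'-phosphate is
# grown from its glycosidic attachment by internal-coordinate (NeRF)
# construction with canonical B-DNA torsions and a C2'-endo (S-type) sugar.
# Residues are rigid copies; the template is an idealized starting model,
# not an energy-minimized structure.

#' Default geometric parameters of the B-form template generator
#'
#' @return Named list: helical rise (A) and twist (deg) per base pair, sugar
#'   pseudorotation phase/amplitude (deg), glycosidic torsion chi (deg),
#'   backbone torsions (deg), P-S bond length used for phosphorothioate
#'   substitution (A), and the displacement of the helix axis from the
#'   base-pair C1'-C1' midpoint (A).
#' @export
bform_params <- function() {
  list(rise = 3.38, twist = 36,
       pucker_P = 162, pucker_amp = 36,
       chi = -105, gamma = 54, beta = 174, alpha = -63,
       c2_branch = -119, gly_tilt = 8, axis_shift = -2,
       p_s_bond = 1.98)
}

# ---- planar base geometries --------------------------------------------

# Planar base geometries (angstroms, base plane z = 0): idealized
# N-glycosylated bases from force-field-optimized small-molecule models,
# projected onto the ring plane. C1' marks the glycosidic attachment point.
.base_tables <- list(
  G = data.frame(
    atom = c("N9", "C1'", "C8", "C4", "N7", "C5", "C6", "N1", "C2", "N3", "O6", "N2", "H1", "H21", "H22", "H8"),
    x = c(-1.4645, -1.8559, -2.3032, -0.1857, -1.6384, -0.3187, 0.8909, 2.0339, 2.0342, 0.9514, 0.9496, 3.2528, 2.9014, 3.9723, 3.1823, -3.3816),
    y = c(-1.1465, -2.5308, -0.0627, -0.6722, 1.0762, 0.6983, 1.4911, 0.7024, -0.6783, -1.4082, 2.7167, -1.2758, 1.2079, -0.8228, -2.2689, -0.1571),
    stringsAsFactors = FALSE),
  A = data.frame(
    atom = c("N9", "C1'", "C8", "C4", "N7", "C5", "C6", "N1", "C2", "N3", "N6", "H61", "H62", "H2", "H8"),
    x = c(-1.5017, -1.9279, -2.3093, -0.2050, -1.6122, -0.2920, 0.9225, 2.0786, 2.0084, 0.9108, 0.9965, 1.8774, 0.1469, 2.9623, -3.3902),
    y = c(-1.1170, -2.4908, -0.0132, -0.6871, 1.1046, 0.6957, 1.4019, 0.6996, -0.6502, -1.4343, 2.7894, 3.1232, 3.2361, -1.1703, -0.0770),
    stringsAsFactors = FALSE),
  C = data.frame(
    atom = c("N1", "C1'", "C6", "C2", "O2", "N3", "C4", "C5", "H6", "N4", "H41", "H42", "H5"),
    x = c(-0.3245, -0.6688, -1.3334, 1.0240, 1.9194, 1.3249, 0.3705, -1.0616, -2.3496, 0.7393, 1.7253, 0.1488, -1.8223),
    y = c(1.3094, 2.7207, 0.3755, 0.9344, 1.7760, -0.4079, -1.2837, -0.9277, 0.7179, -2.6009, -2.7072, -3.2300, -1.6747),
    stringsAsFactors = FALSE),
  T = data.frame(
    atom = c("N1", "C1'", "C6", "C2", "O2", "N3", "C4", "C5", "H6", "O4", "H3", "C7"),
    x = c(-0.5882, -1.1797, 0.7869, -1.4161, -2.6441, -0.7723, 0.5779, 1.4119, 1.3474, 1.0741, -1.3565, 2.8946),
    y = c(-1.2277, -2.5576, -1.1159, -0.1129, -0.1565, 1.0962, 1.2928, 0.0676, -2.0472, 2.4142, 1.9168, 0.2411),
    stringsAsFactors = FALSE)
)

# Base geometry in its local frame (z = 0 plane). Thymine methyl hydrogens
# are added synthetically: one in plane, two displaced +-0.5 A out of plane.
base_geometry <- function(base) {
  tab <- .base_tables[[base]]
  if (is.null(tab)) stop("unknown base: ", base)
  g <- cbind(tab, z = 0)
  if (base == "T") {
    c5 <- unlist(tab[tab$atom == "C5", c("x", "y")], use.names = FALSE)
    c7 <- unlist(tab[tab$atom == "C7", c("x", "y")], use.names = FALSE)
    d <- unit2(c7 - c5)
    hm <- data.frame(
      atom = c("H71", "H72", "H73"),
      x = c(c7[1L] + 1.08 * d[1L], c7[1L] - 0.36 * d[1L] + 0.9 * d[2L],
            c7[1L] - 0.36 * d[1L] - 0.9 * d[2L]),
      y = c(c7[2L] + 1.08 * d[2L], c7[2L] - 0.36 * d[2L] - 0.9 * d[1L],
            c7[2L] - 0.36 * d[2L] + 0.9 * d[1L]),
      z = c(0, 0.5, -0.5),
      stringsAsFactors = FALSE)
    g <- rbind(g, hm)
  }
  g
}

unit2 <- function(v) v / sqrt(sum(v * v))

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

# Watson-Crick hydrogen-bond atom triples (donor heavy, hydrogen, acceptor
# heavy) listed from the purine side.
wc_bond_table <- function(pur, pyr) {
  if (pur == "G" && pyr == "C") {
    data.frame(
      d_res = c("pyr", "pur", "pur"),
      donor = c("N4", "N1", "N2"),
      hydrogen = c("H41", "H1", "H21"),
      a_res = c("pur", "pyr", "pyr"),
      acceptor = c("O6", "N3", "O2"),
      stringsAsFactors = FALSE)
  } else if (pur == "A" && pyr == "T") {
    data.frame(
      d_res = c("pur", "pyr"),
      donor = c("N6", "N3"),
      hydrogen = c("H61", "H3"),
      a_res = c("pyr", "pur"),
      acceptor = c("O4", "N1"),
      stringsAsFactors = FALSE)
  } else stop("not a Watson-Crick purine/pyrimidine combination")
}

# Orient a planar base into its canonical frame: Watson-Crick edge centroid
# along +x and the minor-groove marker atom (purine N3, pyrimidine O2) at
# y < 0. The second condition fixes which face is "up" (a proper flip about
# the x axis when needed), so every base presents the same handedness to the
# pairing step.
orient_wc <- function(geom, base) {
  wc_atoms <- switch(base, G = c("O6", "N1", "N2"), A = c("N6", "N1"),
                     C = c("N4", "N3", "O2"), T = c("O4", "N3"))
  minor_marker <- if (base %in% c("A", "G")) "N3" else "O2"
  xyz <- as.matrix(geom[, c("x", "y", "z")])
  cen <- colMeans(xyz[geom$atom %in% c("N1", "C2", "N3", "C4", "C5", "C6"), ,
                      drop = FALSE])
  wc <- colMeans(xyz[geom$atom %in% wc_atoms, , drop = FALSE])
  d <- unit2((wc - cen)[1:2])
  th <- -atan2(d[2L], d[1L]) * 180 / pi
  xyz <- sweep(xyz, 2L, cen)
  xyz[, 1:2] <- xyz[, 1:2] %*% t(rot2(th))
  if (xyz[geom$atom == minor_marker, 2L] > 0)
    xyz <- xyz %*% diag(c(1, -1, -1))
  geom$x <- xyz[, 1L]; geom$y <- xyz[, 2L]; geom$z <- xyz[, 3L]
  geom
}

# ---- residue construction ----------------------------------------------

# Two substituent directions completing an approximately tetrahedral centre
# whose bonds to u1 and u2 (unit vectors from the centre) are known.
tetra_pair <- function(centre, n1, n2) {
  u1 <- unit(n1 - centre); u2 <- unit(n2 - centre)
  m <- unit(-(u1 + u2)); n <- unit(cross3(u1, u2))
  xi <- deg2rad(54.75)
  list(m * cos(xi) + n * sin(xi), m * cos(xi) - n * sin(xi))
}

# Of the two tetra_pair directions, the one pointing to the same side as
# `ref` relative to the plane through `centre` spanned by the bonds.
side_of <- function(dirs, centre, n1, n2, ref) {
  nrm <- cross3(unit(n1 - centre), unit(n2 - centre))
  s <- sign(sum(nrm * (ref - centre)))
  if (sign(sum(nrm * dirs[[1L]])) == s) list(same = dirs[[1L]], opp = dirs[[2L]])
  else list(same = dirs[[2L]], opp = dirs[[1L]])
}

# Grow deoxyribose + 5'-phosphate from the base frame. The ring is built by
# NeRF from the glycosidic torsion chi and the endocyclic torsions nu1/nu2
# of the configured pseudorotation state; exocyclic substituents complete
# tetrahedral centres, with C5' (and H2'') on the base face of the sugar and
# O3' on the opposite face, as in beta-D-deoxyribonucleotides.
# `base3d` is a matrix of base atom coordinates (rows named by atom).
build_sugar_phosphate <- function(base3d, base, par, with_phosphate = TRUE) {
  nu <- par$pucker_amp * cos(deg2rad(par$pucker_P + 144 * ((0:4) - 2)))
  gly_n <- if (base %in% c("A", "G")) "N9" else "N1"
  gly_c <- if (base %in% c("A", "G")) "C4" else "C2"
  A <- base3d[gly_c, ]; B <- base3d[gly_n, ]; C1 <- base3d["C1'", ]
  chi <- par$chi
  out <- list()
  out[["O4'"]] <- place_atom(A, B, C1, 1.42, 108.2, chi)
  out[["C2'"]] <- place_atom(A, B, C1, 1.53, 114.0, chi + par$c2_branch)
  out[["C3'"]] <- place_atom(out[["O4'"]], C1, out[["C2'"]], 1.525, 102.5,
                             nu[2L])
  out[["C4'"]] <- place_atom(C1, out[["C2'"]], out[["C3'"]], 1.52, 102.5,
                             nu[3L])
  # H1' completes C1' (bonds: N, O4', C2')
  d <- tetra_pair(C1, out[["O4'"]], out[["C2'"]])
  h1 <- side_of(d, C1, out[["O4'"]], out[["C2'"]], B)
  out[["H1'"]] <- C1 + 1.09 * h1$opp
  # C2' hydrogens: H2' on the base face, H2'' on the other (H2'' ends up
  # close to H1', the C2'-endo signature)
  d <- tetra_pair(out[["C2'"]], C1, out[["C3'"]])
  h2 <- side_of(d, out[["C2'"]], C1, out[["C3'"]], B)
  out[["H2''"]] <- out[["C2'"]] + 1.09 * h2$opp
  out[["H2'"]] <- out[["C2'"]] + 1.09 * h2$same
  # O3' and C5' on the base face (beta-D configuration at C3'/C4',
  # verified against the stereocentre signs of beta-D-deoxyribonucleosides)
  d <- tetra_pair(out[["C3'"]], out[["C2'"]], out[["C4'"]])
  o3 <- side_of(d, out[["C3'"]], out[["C2'"]], out[["C4'"]], B)
  out[["O3'"]] <- out[["C3'"]] + 1.42 * o3$same
  out[["H3'"]] <- out[["C3'"]] + 1.09 * o3$opp
  d <- tetra_pair(out[["C4'"]], out[["C3'"]], out[["O4'"]])
  c5 <- side_of(d, out[["C4'"]], out[["C3'"]], out[["O4'"]], B)
  out[["C5'"]] <- out[["C4'"]] + 1.51 * c5$same
  out[["H4'"]] <- out[["C4'"]] + 1.09 * c5$opp
  out[["O5'"]] <- place_atom(out[["C3'"]], out[["C4'"]], out[["C5'"]],
                             1.44, 110.5, par$gamma)
  d <- tetra_pair(out[["C5'"]], out[["C4'"]], out[["O5'"]])
  out[["H5'"]] <- out[["C5'"]] + 1.09 * d[[1L]]
  out[["H5''"]] <- out[["C5'"]] + 1.09 * d[[2L]]
  if (with_phosphate) {
    out[["P"]] <- place_atom(out[["C4'"]], out[["C5'"]], out[["O5'"]],
                             1.59, 119.0, par$beta)
    out[["O1P"]] <- place_atom(out[["C5'"]], out[["O5'"]], out[["P"]],
                               1.48, 108.0, par$alpha + 120)
    out[["O2P"]] <- place_atom(out[["C5'"]], out[["O5'"]], out[["P"]],
                               1.48, 108.0, par$alpha - 120)
  }
  do.call(rbind, out)
}

# Build one Watson-Crick pair (residue of strand 1 + partner) in the pair
# frame: helix axis along z through the origin, C1'-C1' direction along y,
# base plane z = 0. Returns list of two coordinate matrices (rows = atoms).
build_pair_unit <- function(base1, par) {
  base2 <- wc_complement(base1)
  g1 <- glycosidic_tilt(orient_wc(base_geometry(base1), base1), par$gly_tilt)
  g2 <- glycosidic_tilt(orient_wc(base_geometry(base2), base2), par$gly_tilt)
  m1 <- as.matrix(g1[, c("x", "y", "z")]); rownames(m1) <- g1$atom
  m2 <- as.matrix(g2[, c("x", "y", "z")]); rownames(m2) <- g2$atom
  # flip the partner over (proper rotation about y) so its WC edge faces -x
  m2 <- m2 %*% diag(c(-1, 1, -1))

  pur <- if (base1 %in% c("A", "G")) base1 else base2
  pyr <- if (base1 %in% c("C", "T")) base1 else base2
  bonds <- wc_bond_table(pur, pyr)
  pick <- function(side) if ((side == "pur") == (base1 == pur)) 1L else 2L

  # partner-side atoms of each bond and their targets: the base1-side heavy
  # atom displaced 2.90 A along +x (hydrogen bonds roughly parallel to x)
  p2_atoms <- character(nrow(bonds)); p1_atoms <- character(nrow(bonds))
  for (k in seq_len(nrow(bonds))) {
    if (pick(bonds$d_res[k]) == 2L) {
      p2_atoms[k] <- bonds$donor[k]; p1_atoms[k] <- bonds$acceptor[k]
    } else {
      p2_atoms[k] <- bonds$acceptor[k]; p1_atoms[k] <- bonds$donor[k]
    }
  }
  targets <- m1[p1_atoms, 1:2, drop = FALSE]
  targets[, 1L] <- targets[, 1L] + 2.90
  # closed-form 2D rigid alignment (proper rotation) of the partner's bond
  # atoms onto the targets, then a small refinement with H-acceptor terms
  src <- m2[p2_atoms, 1:2, drop = FALSE]
  cs <- colMeans(src); ct <- colMeans(targets)
  h <- crossprod(sweep(src, 2L, cs), sweep(targets, 2L, ct))
  sv <- svd(h)
  R2 <- sv$u %*% diag(c(1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$v)
  th0 <- atan2(R2[1L, 2L], R2[1L, 1L]) * 180 / pi
  t0 <- ct - as.numeric(cs %*% R2)

  objective <- function(p) {
    R <- diag(3); R[1:2, 1:2] <- rot2(p[3L])
    mm2 <- m2 %*% t(R); mm2[, 1L] <- mm2[, 1L] + p[1L]; mm2[, 2L] <- mm2[, 2L] + p[2L]
    err <- 0
    for (k in seq_len(nrow(bonds))) {
      don <- if (pick(bonds$d_res[k]) == 1L) m1[bonds$donor[k], ] else mm2[bonds$donor[k], ]
      hyd <- if (pick(bonds$d_res[k]) == 1L) m1[bonds$hydrogen[k], ] else mm2[bonds$hydrogen[k], ]
      acc <- if (pick(bonds$a_res[k]) == 1L) m1[bonds$acceptor[k], ] else mm2[bonds$acceptor[k], ]
      err <- err + (vnorm(don - acc) - 2.90)^2 + (vnorm(hyd - acc) - 1.90)^2
    }
    err
  }
  fit <- stats::optim(c(t0[1L], t0[2L], th0), objective,
                      method = "BFGS", control = list(maxit = 500))
  R <- diag(3); R[1:2, 1:2] <- rot2(fit$par[3L])
  m2 <- m2 %*% t(R); m2[, 1L] <- m2[, 1L] + fit$par[1L]
  m2[, 2L] <- m2[, 2L] + fit$par[2L]

  # grow sugars/phosphates, then move the pair into the helix frame
  s1 <- build_sugar_phosphate(m1, base1, par)
  s2 <- build_sugar_phosphate(m2, base2, par)
  res1 <- rbind(m1, s1); res2 <- rbind(m2, s2)

  c1a <- res1["C1'", ]; c1b <- res2["C1'", ]
  mid <- (c1a + c1b) / 2
  v <- unit(c1b - c1a)
  th <- atan2(v[1L], v[2L]) * 180 / pi   # rotate C1'->C1' onto +y
  Rz <- rotation_matrix(c(0, 0, 1), th)
  shift <- function(m) {
    nm <- rownames(m)
    m <- sweep(m, 2L, mid) %*% t(Rz)
    m[, 1L] <- m[, 1L] - par$axis_shift
    rownames(m) <- nm
    m
  }
  list(res1 = shift(res1), res2 = shift(res2))
}

# Rotate the glycosidic C1' about its base nitrogen, in the base plane,
# toward the minor-groove side (canonical frame), emulating the lambda
# inclination of the glycosidic bonds in Watson-Crick pairs.
glycosidic_tilt <- function(geom, tilt) {
  nn <- if (any(geom$atom == "N9")) "N9" else "N1"
  N <- unlist(geom[geom$atom == nn, c("x", "y")], use.names = FALSE)
  C1 <- unlist(geom[geom$atom == "C1'", c("x", "y")], use.names = FALSE)
  geom[geom$atom == "C1'", c("x", "y")] <-
    as.list(N + as.numeric(rot2(tilt) %*% (C1 - N)))
  geom
}

# ---- public builders ---------------------------------------------------

#' Build an idealized all-atom B-form duplex template
#'
#' Generates an all-atom (hydrogens included, PDB v3 names) B-form model of
#' the duplex described by `spec`, with fiber-like helical symmetry and
#' C2'-endo sugars, and applies any stereospecific phosphorothioate
#' substitutions in the spec via [apply_pt_modification()].
#'
#' 5'-terminal residues carry a 5'-OH (no phosphate group). The template is
#' an idealized rigid-nucleotide starting model: base pairs satisfy their
#' Watson-Crick hydrogen-bond targets by construction, and backbone
#' continuity is approximate (consecutive intra-strand P-P spacings near
#' 7 A), as appropriate for restraint bookkeeping, geometry statistics and
#' synthetic-data generation rather than energetics.
#'
#' @param spec A [duplex_spec()].
#' @param par Geometry parameters, see [bform_params()].
#' @return A `structure_model`: data frame with columns `atom`, `element`,
#'   `resno`, `resname`, `chain`, `x`, `y`, `z` and attribute `model` = 1.
#' @examples
#' tmpl <- build_bform_template(decamer_spec("Rp"))
#' subset(tmpl, resno == 3 & atom %in% c("P", "S2P"))
#' @export
build_bform_template <- function(spec, par = bform_params()) {
  stopifnot(inherits(spec, "duplex_spec"))
  n <- nrow(spec$strand1)
  if (n == 0L) stop("empty spec")
  rows <- vector("list", 2L * n)
  pair_cache <- new.env(parent = emptyenv())
  for (j in seq_len(n)) {
    b1 <- spec$strand1$base[j]
    unit_pair <- if (!is.null(pair_cache[[b1]])) pair_cache[[b1]] else
      (pair_cache[[b1]] <- build_pair_unit(b1, par))
    Rz <- rotation_matrix(c(0, 0, 1), par$twist * (j - 1L))
    dz <- c(0, 0, par$rise * (j - 1L))
    place <- function(m) sweep(m %*% t(Rz), 2L, -dz)
    r1 <- place(unit_pair$res1); r2 <- place(unit_pair$res2)
    res1 <- j; res2 <- 2L * n + 1L - j
    rows[[res1]] <- model_rows(r1, res1, paste0("D", b1), "A")
    rows[[res2]] <- model_rows(r2, res2, paste0("D", wc_complement(b1)), "B")
  }
  # strip 5'-phosphates of the 5'-terminal residues (1 and n+1)
  model <- do.call(rbind, rows)
  drop <- model$resno %in% c(1L, n + 1L) & model$atom %in% c("P", "O1P", "O2P")
  model <- model[!drop, , drop = FALSE]
  rownames(model) <- NULL
  model <- as_structure_model(model, model_index = 1L)
  if (nrow(spec$pt_sites)) {
    for (k in seq_len(nrow(spec$pt_sites))) {
      model <- apply_pt_modification(model, spec$pt_sites$resno[k],
                                     spec$pt_sites$chirality[k],
                                     p_s_bond = par$p_s_bond)
    }
  }
  model
}

model_rows <- function(m, resno, resname, chain) {
  data.frame(atom = rownames(m),
             element = atom_element(rownames(m)),
             resno = resno, resname = resname, chain = chain,
             x = m[, 1L], y = m[, 2L], z = m[, 3L],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Infer element from a PDB v3 atom name
#' @param name Character vector of atom names.
#' @return Character vector of element symbols.
#' @keywords internal
atom_element <- function(name) {
  toupper(substr(gsub("^[0-9']+", "", name), 1L, 1L))
}

as_structure_model <- function(df, model_index = 1L) {
  need <- c("atom", "element", "resno", "resname", "chain", "x", "y", "z")
  stopifnot(all(need %in% names(df)))
  key <- paste(df$chain, df$resno, df$atom)
  if (anyDuplicated(key)) stop("duplicate (chain, residue, atom) triple")
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("non-finite coordinates")
  structure(df[, need], class = c("structure_model", "data.frame"),
            model = model_index)
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model: ", length(unique(x$resno)), " residues, ",
      nrow(x), " atoms (model ", attr(x, "model") %||% 1L, ")\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coordinates of one atom of a structure model
#'
#' @param model A `structure_model`.
#' @param resno Residue number (continuous duplex numbering).
#' @param atom Atom name (canonical dialect, e.g. `"H2''"`, `"O2P"`).
#' @return Numeric length-3 xyz vector.
#' @export
atom_xyz <- function(model, resno, atom) {
  i <- which(model$resno == resno & model$atom == atom)
  if (length(i) != 1L)
    stop("atom ", atom, " of residue ", resno,
         if (length(i)) " is ambiguous" else " not found")
  as.numeric(model[i, c("x", "y", "z")])
}

#' Apply a stereospecific phosphorothioate substitution
#'
#' Replaces one non-bridging phosphate oxygen of the residue's 5'-phosphate
#' by sulfur: Rp chirality substitutes O2P (renamed S2P), Sp substitutes O1P
#' (renamed S1P). The sulfur is placed along the original P-O bond direction
#' at the configured P-S bond length; every other atom is untouched. The
#' residue is renamed RSG/SSG (modified guanine residue types).
#'
#' Applying the same substitution twice is an error (the target oxygen is
#' already gone), never a silent double substitution.
#'
#' @param model A `structure_model`.
#' @param resno Residue to modify (must carry P, O1P, O2P).
#' @param chirality `"Rp"` or `"Sp"`.
#' @param p_s_bond P-S bond length in A (default 1.98, standard
#'   phosphorothioate geometry).
#' @return The modified `structure_model`.
#' @export
apply_pt_modification <- function(model, resno, chirality, p_s_bond = 1.98) {
  if (!chirality %in% c("Rp", "Sp"))
    stop("chirality must be 'Rp' or 'Sp'")
  target <- if (chirality == "Rp") "O2P" else "O1P"
  i <- which(model$resno == resno & model$atom == target)
  ip <- which(model$resno == resno & model$atom == "P")
  if (length(ip) != 1L)
    stop("residue ", resno, " has no phosphate (P) atom")
  if (length(i) != 1L)
    stop("residue ", resno, " has no ", target,
         " atom (already substituted or missing phosphate oxygens)")
  p <- as.numeric(model[ip, c("x", "y", "z")])
  o <- as.numeric(model[i, c("x", "y", "z")])
  s <- p + p_s_bond * unit(o - p)
  model$atom[i] <- sub("O", "S", target)
  model$element[i] <- "S"
  model[i, c("x", "y", "z")] <- as.list(s)
  model$resname[model$resno == resno] <- if (chirality == "Rp") "RSG" else "SSG"
  model
}
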