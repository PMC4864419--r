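# File formats: multi-MODEL PDB ensembles (reading through bio3d, writing
# in fixed-column PDB v3), chemical-shift tables (CSV and a read-only
# NMR-STAR shift-loop subset), and XPLOR-style topology/parameter stubs for
# the phosphorothioate residues.

#' Normalize atom-name dialects
#'
#' Canonical internal names follow the O1P/O2P, H2'/H2'' convention;
#' readers accept the OP1/OP2, H2'1/H2'2, 1H2' and C5M dialects.
#'
#' @param x Character vector of atom names.
#' @return Normalized names.
#' @export
normalize_atom_name <- function(x) {
  x <- trimws(x)
  map <- c(OP1 = "O1P", OP2 = "O2P", SP1 = "S1P", SP2 = "S2P",
           C5M = "C7", O1P = "O1P", O2P = "O2P")
  hit <- x %in% names(map)
  x[hit] <- map[x[hit]]
  # trailing-digit prime dialects: H2'1 -> H2', H2'2 -> H2''
  x <- sub("^([A-Z]+\\d?)'1$", "\\1'", x)
  x <- sub("^([A-Z]+\\d?)'2$", "\\1''", x)
  # leading-digit dialects: 1H2' -> H2', 2H2' -> H2'', 2H5' -> H5''
  lead <- grepl("^[123][A-Z]", x)
  x[lead] <- ifelse(substr(x[lead], 1L, 1L) == "1",
                    substring(x[lead], 2L),
                    paste0(substring(x[lead], 2L), "'"))
  # quote-as-doubleprime dialect
  gsub('"', "''", x, fixed = TRUE)
}

#' Read a multi-MODEL PDB file as a structure ensemble
#'
#' Atom names are dialect-normalized; every model must share the atom
#' inventory of the first.
#'
#' @param path PDB file with MODEL/ENDMDL records (a single-model file
#'   yields a one-model ensemble).
#' @return A [structure_ensemble()].
#' @export
read_pdb_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nm <- normalize_atom_name(at$elety)
  elem <- ifelse(!is.na(at$elesy) & nzchar(trimws(at$elesy)),
                 toupper(trimws(at$elesy)), atom_element(nm))
  n_models <- nrow(pdb$xyz)
  models <- lapply(seq_len(n_models), function(k) {
    xyz <- matrix(pdb$xyz[k, ], ncol = 3L, byrow = TRUE)
    as_structure_model(data.frame(
      atom = nm, element = elem, resno = at$resno, resname = at$resid,
      chain = at$chain, x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      stringsAsFactors = FALSE), model_index = k)
  })
  structure_ensemble(models, source = basename(path))
}

#' Write a structure ensemble (or single model) as multi-MODEL PDB
#'
#' @param x A [structure_ensemble()] or `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(x, path) {
  if (inherits(x, "structure_model"))
    x <- structure_ensemble(list(x))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(x$models)) {
    m <- x$models[[k]]
    writeLines(sprintf("MODEL     %4d", k), con)
    nm <- ifelse(nchar(m$atom) < 4L, paste0(" ", m$atom), m$atom)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(m)), nm, m$resname, m$chain, m$resno,
      m$x, m$y, m$z, 1, 0, m$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a chemical-shift table
#'
#' CSV dialect: columns `residue`, `atom`, `nucleus`, `ppm`. NMR-STAR
#' dialect: the `_Atom_chem_shift` loop of an NMR-STAR 3.x file (read-only
#' subset; columns Comp_index_ID/Seq_ID, Atom_ID, Atom_type, Val).
#'
#' @param path Input file.
#' @param dialect `"csv"` or `"nmrstar"` (default guessed from the
#'   extension: `.str` -> NMR-STAR).
#' @param offset Added to the file's residue numbering to map it onto the
#'   spec's continuous 1..2n scheme (default 0).
#' @return Data frame of class `shift_table`: residue, atom, nucleus, ppm.
#' @export
read_shift_table <- function(path, dialect = NULL, offset = 0) {
  if (is.null(dialect))
    dialect <- if (grepl("\\.str$", path, ignore.case = TRUE)) "nmrstar"
               else "csv"
  dialect <- match.arg(dialect, c("csv", "nmrstar"))
  tab <- if (dialect == "csv") {
    x <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("residue", "atom", "nucleus", "ppm")
    if (!all(need %in% names(x)))
      stop("shift CSV needs columns: ", paste(need, collapse = ", "))
    x[, need]
  } else read_star_shifts(path)
  tab$residue <- tab$residue + offset
  tab$atom <- normalize_atom_name(tab$atom)
  if (any(!is.finite(tab$ppm))) stop("non-finite chemical shift")
  class(tab) <- c("shift_table", "data.frame")
  tab
}

# minimal NMR-STAR 3.x chemical-shift loop parser
read_star_shifts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  li <- grep("^\\s*loop_\\s*$", lines)
  if (!length(li)) stop("no loop_ found in ", path)
  for (start in li) {
    i <- start + 1L
    tags <- character()
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1L
    }
    if (!any(grepl("_Atom_chem_shift", tags))) next
    cols <- sub("^_Atom_chem_shift\\.", "", tags)
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "stop_" || startsWith(ln, "save_")) break
      if (nzchar(ln) && !startsWith(ln, "#"))
        rows[[length(rows) + 1L]] <- scan(text = ln, what = "character",
                                          quiet = TRUE)
      i <- i + 1L
    }
    tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(tab) <- cols
    rescol <- intersect(c("Comp_index_ID", "Seq_ID"), cols)[1L]
    if (is.na(rescol)) stop("no residue-number tag in shift loop")
    return(data.frame(residue = as.integer(tab[[rescol]]),
                      atom = tab$Atom_ID,
                      nucleus = paste0(ifelse(tab$Atom_type == "H", "1", "31"),
                                       tab$Atom_type),
                      ppm = as.numeric(tab$Val),
                      stringsAsFactors = FALSE))
  }
  stop("no _Atom_chem_shift loop found in ", path)
}

#' Write a shift table as CSV
#'
#' @param tab A `shift_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab)[, c("residue", "atom", "nucleus", "ppm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Chemical-shift differences between two tables
#'
#' Per-atom `delta = modified - reference` on the intersection of
#' (residue, atom, nucleus) keys, with atoms beyond a threshold flagged.
#'
#' @param modified,reference `shift_table`s.
#' @param threshold Flagging threshold in ppm (default 0.2; protons in
#'   unperturbed duplex positions typically shift less than this).
#' @return Data frame: residue, atom, nucleus, ppm_modified,
#'   ppm_reference, delta, flagged.
#' @export
shift_delta <- function(modified, reference, threshold = 0.2) {
  key <- function(t) paste(t$residue, t$atom, t$nucleus)
  shared <- intersect(key(modified), key(reference))
  if (!length(shared)) stop("no overlapping atoms between the shift tables")
  im <- match(shared, key(modified)); ir <- match(shared, key(reference))
  out <- data.frame(residue = modified$residue[im],
                    atom = modified$atom[im],
                    nucleus = modified$nucleus[im],
                    ppm_modified = modified$ppm[im],
                    ppm_reference = reference$ppm[ir],
                    stringsAsFactors = FALSE)
  out$delta <- out$ppm_modified - out$ppm_reference
  out$flagged <- abs(out$delta) > threshold
  out[order(out$residue, out$atom), , drop = FALSE]
}

#' Write XPLOR-style topology/parameter stubs for the PT residues
#'
#' Plain-text residue topology and parameter entries for the
#' phosphorothioate guanine residue types RSG (Rp: O2P replaced by S2P) and
#' SSG (Sp: O1P replaced by S1P). Masses, bond and angle values are
#' documented package defaults (standard phosphorothioate geometry), not
#' fitted force-field constants.
#'
#' @param path Output path.
#' @param p_s_bond P-S bond length, A (default 1.98).
#' @return `path`, invisibly.
#' @export
write_pt_topology <- function(path, p_s_bond = 1.98) {
  lines <- c(
    "! Topology/parameter stub for phosphorothioate guanine residues",
    "! RSG: Rp (O2P -> S2P); SSG: Sp (O1P -> S1P). Values are package",
    "! defaults for idealized geometry.",
    "MASS S2P 32.060", "MASS S1P 32.060", "",
    "RESIdue RSG", "  GROUp", "  ATOM P    TYPE P    CHARge  1.20 END",
    "  ATOM S2P  TYPE S2P  CHARge -0.90 END",
    "  ATOM O1P  TYPE O1P  CHARge -0.70 END",
    "  BOND P S2P", "  BOND P O1P", "END", "",
    "RESIdue SSG", "  GROUp", "  ATOM P    TYPE P    CHARge  1.20 END",
    "  ATOM S1P  TYPE S1P  CHARge -0.90 END",
    "  ATOM O2P  TYPE O2P  CHARge -0.70 END",
    "  BOND P S1P", "  BOND P O2P", "END", "",
    sprintf("BOND P    S2P   500.0 %.3f", p_s_bond),
    sprintf("BOND P    S1P   500.0 %.3f", p_s_bond),
    "ANGLe O5' P    S2P   80.0 108.0",
    "ANGLe O5' P    S1P   80.0 108.0",
    "ANGLe O3' P    S2P   80.0 108.0",
    "ANGLe O3' P    S1P   80.0 108.0")
  writeLines(lines, path)
  invisible(path)
}
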