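#' Specify a phosphorothioate-modified DNA duplex
#'
#' Builds a validated description of a Watson-Crick DNA duplex with optional
#' stereospecific phosphorothioate (PT) sites. Residues are numbered
#' continuously: strand 1 runs 1..n (5'->3', chain A), strand 2 runs
#' n+1..2n (5'->3', chain B), so residue i of strand 1 pairs with residue
#' 2n+1-i of strand 2.
#'
#' A PT site replaces one non-bridging oxygen of a backbone phosphate by
#' sulfur and is chiral at phosphorus (Rp or Sp). Because the substituted
#' phosphate is the residue's 5'-phosphate, a PT site cannot sit on the
#' 5'-terminal residue of either strand.
#'
#' @param seq1 Strand 1 sequence, 5'->3' (characters from ACGT).
#' @param seq2 Strand 2 sequence, 5'->3'; `rev(seq2)` must be the
#'   Watson-Crick complement of `seq1`.
#' @param pt List of PT sites, each `list(residue =, chirality =)` or a
#'   two-element vector `c(residue, "Rp"|"Sp")`; residue in continuous
#'   numbering.
#' @return An object of class `duplex_spec`: list with `strand1`, `strand2`
#'   (data frames of base/residue number), `pt_sites` (data frame of
#'   residue/chirality), and `pairing` (data frame res1/res2).
#' @examples
#' spec <- duplex_spec("CGGCCGCCGA", "TCGGCGGCCG",
#'                     pt = list(c(3, "Rp"), c(17, "Rp")))
#' spec
#' @export
duplex_spec <- function(seq1, seq2, pt = list()) {
  s1 <- toupper(strsplit(seq1, "")[[1L]])
  s2 <- toupper(strsplit(seq2, "")[[1L]])
  if (length(s1) == 0L) stop("empty sequence")
  if (length(s1) != length(s2)) stop("strands must have equal length")
  if (!all(s1 %in% c("A", "C", "G", "T")) || !all(s2 %in% c("A", "C", "G", "T")))
    stop("sequences must contain only A, C, G, T")
  comp <- wc_complement(rev(s2))
  if (!identical(comp, s1))
    stop("strands are not Watson-Crick complementary (seq2 reversed must complement seq1)")
  n <- length(s1)
  strand1 <- data.frame(base = s1, resno = seq_len(n), stringsAsFactors = FALSE)
  strand2 <- data.frame(base = s2, resno = n + seq_len(n), stringsAsFactors = FALSE)
  pairing <- data.frame(res1 = seq_len(n), res2 = 2L * n + 1L - seq_len(n))

  pt_sites <- data.frame(resno = integer(0), chirality = character(0),
                         stringsAsFactors = FALSE)
  for (site in pt) {
    site <- unlist(site, use.names = FALSE)
    if (length(site) != 2L) stop("each pt site must be (residue, chirality)")
    resno <- as.integer(site[1L]); chir <- as.character(site[2L])
    if (!chir %in% c("Rp", "Sp"))
      stop("chirality must be 'Rp' or 'Sp', got '", chir, "'")
    if (is.na(resno) || resno < 1L || resno > 2L * n)
      stop("pt residue ", site[1L], " outside 1..", 2L * n)
    if (resno == 1L || resno == n + 1L)
      stop("residue ", resno, " is 5'-terminal and has no 5'-phosphate; ",
           "PT modification impossible there")
    pt_sites <- rbind(pt_sites,
                      data.frame(resno = resno, chirality = chir,
                                 stringsAsFactors = FALSE))
  }
  if (anyDuplicated(pt_sites$resno)) stop("duplicate PT site")
  structure(list(strand1 = strand1, strand2 = strand2,
                 pt_sites = pt_sites, pairing = pairing),
            class = "duplex_spec")
}

wc_complement <- function(bases) {
  map <- c(A = "T", T = "A", G = "C", C = "G")
  unname(map[bases])
}

#' @export
print.duplex_spec <- function(x, ...) {
  n <- nrow(x$strand1)
  cat("DNA duplex specification (", n, " bp)\n", sep = "")
  cat("  strand 1 (A, 1-", n, "):   5'-", paste(x$strand1$base, collapse = ""),
      "-3'\n", sep = "")
  cat("  strand 2 (B, ", n + 1L, "-", 2L * n, "): 5'-",
      paste(x$strand2$base, collapse = ""), "-3'\n", sep = "")
  if (nrow(x$pt_sites)) {
    cat("  PT sites: ",
        paste(sprintf("%s%d (%s)", residue_base(x, x$pt_sites$resno),
                      x$pt_sites$resno, x$pt_sites$chirality),
              collapse = ", "), "\n", sep = "")
  } else cat("  PT sites: none (PT-free)\n")
  invisible(x)
}

# Base letter of a residue in continuous numbering (vectorized).
residue_base <- function(spec, resno) {
  n <- nrow(spec$strand1)
  vapply(resno, function(r) {
    if (r <= n) spec$strand1$base[r] else spec$strand2$base[r - n]
  }, character(1L))
}

# Chain id ("A"/"B") for continuous residue numbers.
residue_chain <- function(spec, resno) {
  ifelse(resno <= nrow(spec$strand1), "A", "B")
}

#' The decamer duplex studied by the package's reference analyses
#'
#' Convenience constructor for the d(CGGCCGCCGA).d(TCGGCGGCCG) decamer from
#' the gene of *Streptomyces lividans* in which physiological PT modification
#' occurs, with PT sites (when present) on the 5'-phosphates of G3 and G17.
#'
#' @param pt One of "none", "Rp" (both sites Rp) or "Sp" (both sites Sp).
#' @return A [duplex_spec()].
#' @examples
#' decamer_spec("Rp")
#' @export
decamer_spec <- function(pt = c("none", "Rp", "Sp")) {
  pt <- match.arg(pt)
  mods <- switch(pt,
                 none = list(),
                 Rp = list(c(3, "Rp"), c(17, "Rp")),
                 Sp = list(c(3, "Sp"), c(17, "Sp")))
  duplex_spec("CGGCCGCCGA", "TCGGCGGCCG", pt = mods)
}
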