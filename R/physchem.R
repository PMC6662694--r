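#' Fauchère–Pliška side-chain hydrophobicity scale
#'
#' Unitless octanol/water side-chain transfer hydrophobicities for the 20
#' canonical amino acids (Fauchère & Pliška 1983), the scale used by the
#' HeliQuest web server. This is the default scale for
#' [mean_hydrophobicity()] and [hydrophobic_moment()].
#'
#' @format Named numeric vector of length 20; names are one-letter codes.
#' @export
fauchere_pliska <- c(
  A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
  Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
  L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
  S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22
)

#' Construct a peptide sequence with terminal chemistry
#'
#' @param residues One-letter amino-acid string or character vector
#'   (canonical 20 only).
#' @param id Text label.
#' @param n_term_free Logical; free (protonated) N-terminal amine.
#' @param c_term_amidated Logical; C-terminal amide (neutral) rather than
#'   free carboxylate.
#' @return An object of class `peptide_sequence`.
#' @examples
#' aurein <- peptide_sequence("GLFDIVKKVVGAFGSL", id = "aurein2.5",
#'                            c_term_amidated = TRUE)
#' net_charge(aurein)
#' @export
peptide_sequence <- function(residues, id = "peptide",
                             n_term_free = TRUE, c_term_amidated = FALSE) {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(residues)
  if (length(residues) < 1L)
    stop("peptide must contain at least one residue")
  bad <- setdiff(residues, names(fauchere_pliska))
  if (length(bad))
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  structure(
    list(id = id, residues = residues,
         n_term_free = isTRUE(n_term_free),
         c_term_amidated = isTRUE(c_term_amidated)),
    class = "peptide_sequence")
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat(sprintf("<peptide_sequence> %s: %s (%d aa)%s%s\n",
              x$id, paste(x$residues, collapse = ""), length(x$residues),
              if (x$n_term_free) "" else ", N-term blocked",
              if (x$c_term_amidated) ", C-term amidated" else ""))
  invisible(x)
}

as_peptide <- function(seq) {
  if (inherits(seq, "peptide_sequence")) seq else peptide_sequence(seq)
}

#' Net charge at neutral pH
#'
#' Side-chain charges at pH 7 (K, R = +1; D, E = -1; H = 0) plus +1 for a
#' free N-terminal amine and -1 for a free C-terminal carboxylate (0 when
#' amidated). This termini-aware convention reproduces the charges HeliQuest
#' reports for C-terminally amidated peptides.
#'
#' @param seq A `peptide_sequence` or one-letter string (string input
#'   assumes free N-terminus and free acid C-terminus).
#' @return Integer net charge in elementary-charge units.
#' @export
net_charge <- function(seq) {
  seq <- as_peptide(seq)
  side <- c(K = 1, R = 1, D = -1, E = -1)
  q <- sum(side[seq$residues], na.rm = TRUE)
  q <- q + as.integer(seq$n_term_free)
  if (!seq$c_term_amidated) q <- q - 1L
  as.integer(q)
}

check_scale <- function(scale) {
  if (!is.numeric(scale) || is.null(names(scale)))
    stop("scale must be a named numeric vector")
  missing <- setdiff(names(fauchere_pliska), names(scale))
  if (length(missing))
    stop("scale missing residue(s): ", paste(missing, collapse = ", "))
  scale
}

#' Mean hydrophobicity H
#'
#' Arithmetic mean of per-residue hydrophobicities, H = (1/N) sum H_i.
#'
#' @inheritParams net_charge
#' @param scale Named numeric hydrophobicity scale covering the canonical 20
#'   residues; default [fauchere_pliska].
#' @return Unitless mean hydrophobicity.
#' @export
mean_hydrophobicity <- function(seq, scale = fauchere_pliska) {
  seq <- as_peptide(seq)
  scale <- check_scale(scale)
  mean(scale[seq$residues])
}

#' Helical hydrophobic moment muH
#'
#' Magnitude of the vector sum of residue hydrophobicities placed at
#' `delta`-degree increments around the helix axis, normalized by length:
#' muH = (1/N) * |sum_i H_i (cos(i*delta), sin(i*delta))|, i = 0..N-1.
#' With the default delta = 100 degrees (ideal alpha-helix) and the
#' Fauchère–Pliška scale this is the HeliQuest hydrophobic moment.
#'
#' @inheritParams mean_hydrophobicity
#' @param delta Angular increment per residue, degrees (default 100).
#' @return Unitless hydrophobic moment (>= 0).
#' @export
hydrophobic_moment <- function(seq, scale = fauchere_pliska, delta = 100) {
  seq <- as_peptide(seq)
  scale <- check_scale(scale)
  h <- scale[seq$residues]
  a <- (seq_along(h) - 1) * delta * pi / 180
  sqrt(sum(h * cos(a))^2 + sum(h * sin(a))^2) / length(h)
}

#' Per-sequence physico-chemical profile
#'
#' @inheritParams mean_hydrophobicity
#' @param delta Helical angular increment, degrees.
#' @return A one-row data.frame: id, length, charge, H (3 dp), muH (3 dp).
#' @export
physchem_profile <- function(seq, scale = fauchere_pliska, delta = 100) {
  seq <- as_peptide(seq)
  data.frame(
    id = seq$id,
    length = length(seq$residues),
    charge = net_charge(seq),
    H = round(mean_hydrophobicity(seq, scale), 3),
    muH = round(hydrophobic_moment(seq, scale, delta), 3),
    stringsAsFactors = FALSE)
}

#' Physico-chemical report for a FASTA file
#'
#' Reads peptide sequences from FASTA and tabulates charge, H and muH for
#' each. All sequences are treated as C-terminally amidated when
#' `c_term_amidated = TRUE` (the study peptides are amidated).
#'
#' @param fasta_file Path to a FASTA file of amino-acid sequences.
#' @param c_term_amidated Logical, applied to every sequence.
#' @inheritParams physchem_profile
#' @return data.frame with one row per sequence.
#' @export
physchem_report <- function(fasta_file, c_term_amidated = TRUE,
                            scale = fauchere_pliska, delta = 100) {
  aln <- bio3d::read.fasta(fasta_file)
  rows <- lapply(seq_len(nrow(aln$ali)), function(i) {
    res <- aln$ali[i, aln$ali[i, ] != "-"]
    physchem_profile(
      peptide_sequence(res, id = aln$id[i],
                       c_term_amidated = c_term_amidated),
      scale = scale, delta = delta)
  })
  do.call(rbind, rows)
}
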