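# Average residue masses (Da) for the 20 standard amino acids, and the
# Bjellqvist pK set used for the isoelectric point.  Average (not
# monoisotopic) masses match the convention of the usual web calculators.
AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

# Bjellqvist pK values: N/C termini plus ionizable side chains.
PK_NTERM <- 7.5
PK_CTERM <- 3.55
PK_SIDE_POS <- c(K = 10.0, R = 12.0, H = 5.98)
PK_SIDE_NEG <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)

#' Translate a coding sequence
#'
#' Standard genetic code.  The CDS must start with ATG, end with a stop
#' codon, and contain no internal stop; the returned protein excludes
#' the stop codon.
#'
#' @param cds DNA sequence (character scalar), length divisible by 3.
#' @return Amino-acid sequence (leading residue M).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) stop("cds length not divisible by 3")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) stop("invalid codon at codon index ", which(is.na(aa))[[1L]])
  if (aa[[1L]] != "M") stop("cds does not start with ATG")
  if (aa[[length(aa)]] != "*") stop("cds does not end with a stop codon")
  internal <- which(aa[-length(aa)] == "*")
  if (length(internal)) stop("internal stop at codon index ", internal[[1L]])
  paste(aa[-length(aa)], collapse = "")
}

#' Derive the mature protein from a precursor
#'
#' Removes the N-terminal signal peptide (supplied as an annotation, in
#' residues) from the precursor.
#'
#' @param protein Precursor amino-acid sequence.
#' @param sp_len Signal-peptide length, `0 <= sp_len < nchar(protein)`.
#' @return Mature-protein sequence of length `nchar(protein) - sp_len`.
#' @export
derive_mature <- function(protein, sp_len) {
  if (is.na(sp_len) || sp_len < 0L) stop("sp_len must be a non-negative integer")
  if (sp_len >= nchar(protein))
    stop("sp_len (", sp_len, ") >= protein length (", nchar(protein), ")")
  substring(protein, sp_len + 1L)
}

#' Molecular weight of a protein
#'
#' Sum of average residue masses plus one water, in Daltons.
#'
#' @param sequence Amino-acid sequence (standard 20 residues).
#' @return Molecular weight in Da.
#' @export
molecular_weight <- function(sequence) {
  if (!nchar(sequence)) stop("empty sequence")
  res <- strsplit(toupper(sequence), "")[[1L]]
  unknown <- setdiff(res, names(AA_RESIDUE_MASS))
  if (length(unknown)) stop("unknown residue: ", unknown[[1L]])
  sum(AA_RESIDUE_MASS[res]) + WATER_MASS
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus, and the
#' ionizable side chains (D, E, C, Y negative; H, K, R positive), using
#' the Bjellqvist pK set documented in the package source.  The model is
#' composition-only: permuting the sequence does not change the charge.
#'
#' @param sequence Amino-acid sequence.
#' @param ph pH value.
#' @return Net charge in elementary charge units.
#' @export
net_charge <- function(sequence, ph) {
  res <- strsplit(toupper(sequence), "")[[1L]]
  pos <- 1 / (1 + 10^(ph - PK_NTERM)) +
    sum(vapply(names(PK_SIDE_POS), function(a)
      sum(res == a) / (1 + 10^(ph - PK_SIDE_POS[[a]])), 1))
  neg <- 1 / (1 + 10^(PK_CTERM - ph)) +
    sum(vapply(names(PK_SIDE_NEG), function(a)
      sum(res == a) / (1 + 10^(PK_SIDE_NEG[[a]] - ph)), 1))
  pos - neg
}

#' Isoelectric point of a protein
#'
#' pH at which the modelled net charge ([net_charge()]) is zero, found
#' by bisection on \[0, 14\].  The charge is strictly decreasing in pH,
#' so the root is unique.
#'
#' @param sequence Amino-acid sequence.
#' @param tol Bisection tolerance on pH.
#' @return Isoelectric point (pH units).
#' @export
isoelectric_point <- function(sequence, tol = 1e-3) {
  if (!nchar(sequence)) stop("empty sequence")
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical property table for mature proteins
#'
#' Convenience wrapper applying [derive_mature()], [molecular_weight()]
#' and [isoelectric_point()] across a set of precursor records.
#'
#' @param proteins Named character vector of precursor sequences.
#' @param sp_len Integer vector of signal-peptide lengths (recycled).
#' @return Data frame: `gene_id`, `mp_len`, `mw` (2 dp), `pi` (2 dp).
#' @export
protein_features <- function(proteins, sp_len) {
  sp_len <- rep_len(sp_len, length(proteins))
  mats <- mapply(derive_mature, proteins, sp_len)
  data.frame(
    gene_id = names(proteins),
    mp_len = nchar(mats),
    mw = round(vapply(mats, molecular_weight, 1), 2L),
    pi = round(vapply(mats, isoelectric_point, 1), 2L),
    row.names = NULL, stringsAsFactors = FALSE)
}
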