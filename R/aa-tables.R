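# Genetic-code and amino-acid reference tables.
#
# The mini-cell models a configurable subset of amino acids explicitly (the
# remainder of the proteome is lumped); these tables cover the full standard
# code so that toy specs outside the default subset (e.g. Met-initiated,
# uncleaved peptides) also work.

# codon -> one-letter amino acid, standard code, DNA alphabet
.GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L", CTA = "L",
  CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M", GTT = "V", GTC = "V",
  GTA = "V", GTG = "V", TCT = "S", TCC = "S", TCA = "S", TCG = "S", CCT = "P",
  CCC = "P", CCA = "P", CCG = "P", ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", CAT = "H",
  CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E", TGT = "C", TGC = "C", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R",
  AGG = "R", GGT = "G", GGC = "G", GGA = "G", GGG = "G",
  TAA = "*", TAG = "*", TGA = "*"
)

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.START_CODON <- "ATG"

# three-letter names used for species ids (lower case)
.AA_NAME <- c(
  A = "ala", R = "arg", N = "asn", D = "asp", C = "cys", Q = "gln", E = "glu",
  G = "gly", H = "his", I = "ile", L = "leu", K = "lys", M = "met", F = "phe",
  P = "pro", S = "ser", T = "thr", W = "trp", Y = "tyr", V = "val"
)

# monoisotopic-ish average residue masses (g/mol), used for molecular weight
# of a peptide: sum(residues) + water
.AA_RESIDUE_MASS <- c(
  A = 71.08, R = 156.19, N = 114.10, D = 115.09, C = 103.14, E = 129.12,
  Q = 128.13, G = 57.05, H = 137.14, I = 113.16, L = 113.16, K = 128.17,
  M = 131.19, F = 147.18, P = 97.12, S = 87.08, T = 101.10, W = 186.21,
  Y = 163.18, V = 99.13
)

# carbon atoms per residue (for elemental bookkeeping of lumped precursors)
.AA_CARBON <- c(
  A = 3, R = 6, N = 4, D = 4, C = 3, E = 5, Q = 5, G = 2, H = 6, I = 6,
  L = 6, K = 6, M = 5, F = 9, P = 5, S = 3, T = 4, W = 11, Y = 9, V = 5
)

codons_for <- function(aa) {
  names(.GENETIC_CODE)[.GENETIC_CODE == aa]
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) abort(sprintf("sequence length %d is not a multiple of 3", n))
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Translate a protein-coding nucleotide sequence
#'
#' Translates a DNA coding sequence (start codon through stop codon) into its
#' one-letter amino-acid sequence. The stop codon is dropped; if
#' `cleave_start` is `TRUE` the initiator residue is excised (N-terminal
#' methionine excision), so the returned sequence is the mature product.
#'
#' @param sequence Coding DNA string over `A`,`C`,`G`,`T`.
#' @param cleave_start Excise the initiator residue from the product?
#' @return A single string of one-letter amino-acid codes.
#' @export
translate_cds <- function(sequence, cleave_start = FALSE) {
  codons <- split_codons(toupper(sequence))
  if (codons[1] != .START_CODON) abort("sequence does not begin with a start codon")
  if (!tail(codons, 1) %in% .STOP_CODONS) abort("sequence does not end with a stop codon")
  body <- codons[-length(codons)]
  aa <- unname(.GENETIC_CODE[body])
  if (anyNA(aa)) abort("sequence contains an unknown codon")
  if (any(aa[-1] == "*")) abort("sequence contains an internal stop codon")
  if (cleave_start) aa <- aa[-1]
  paste(aa, collapse = "")
}

# counts of one-letter amino acids in a peptide string, over `alphabet`
aa_counts <- function(peptide, alphabet = NULL) {
  chars <- strsplit(peptide, "")[[1]]
  if (is.null(alphabet)) alphabet <- sort(unique(chars))
  vapply(alphabet, function(a) sum(chars == a), integer(1))
}

#' Molecular weight of a peptide
#'
#' @param peptide One-letter amino-acid string.
#' @return Molecular weight in g/mol (residue masses plus one water).
#' @export
peptide_mw <- function(peptide) {
  chars <- strsplit(peptide, "")[[1]]
  m <- .AA_RESIDUE_MASS[chars]
  if (anyNA(m)) abort("peptide contains an unknown residue code")
  sum(m) + 18.02
}

# nucleotide counts (A, C, G, T) of a DNA string
nt_counts <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  vapply(c("A", "C", "G", "T"), function(n) sum(chars == n), integer(1))
}
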