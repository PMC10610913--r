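#' Display order of amino-acid substitutions in enrichment matrices
#'
#' Row order used for all substitution-by-position matrices: arginine first,
#' tryptophan last, grouping charged, polar, special, hydrophobic and aromatic
#' residues.
#' @export
AA_DISPLAY_ORDER <- c("R", "H", "K", "D", "E", "S", "T", "N", "Q", "C",
                      "G", "P", "A", "V", "I", "L", "M", "F", "Y", "W")

#' Stop-codon symbol used as the 21st substitution
#' @export
STOP_CHAR <- "*"

# Representative codon per amino acid for reverse translation. Third base is
# A/T wherever the code allows (only Met and Trp force G), so that a WT gene
# built from this table differs from every NNS single-codon substitution and
# synonymous library members are unambiguous at the nucleotide level.
REP_CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT")

#' Construct a validated coding sequence
#'
#' A coding sequence pairs a DNA string with its translation under the
#' standard genetic code. The DNA must be a multiple of 3 nt, contain only
#' A/C/G/T, and encode no internal stop codon. Residues are numbered 1-based
#' with position 1 the initiator methionine.
#'
#' @param name identifier for the sequence.
#' @param nt DNA string (coding strand, no terminal stop codon required).
#' @return An object of class \code{coding_sequence} with fields \code{name},
#'   \code{nt} and \code{aa} (the translated protein).
#' @examples
#' cds <- coding_sequence("toy", "ATGGCTTAC")
#' cds$aa  # "MAY"
#' @export
coding_sequence <- function(name, nt) {
  nt <- toupper(as.character(nt))
  if (!grepl("^[ACGT]+$", nt))
    stop("coding sequence contains non-ACGT characters")
  if (nchar(nt) %% 3L != 0L)
    stop("coding sequence length must be divisible by 3")
  aa <- translate_nt(nt)
  if (grepl("\\*", substr(aa, 1L, nchar(aa))))
    stop("coding sequence contains an internal stop codon")
  structure(list(name = name, nt = nt, aa = aa), class = "coding_sequence")
}

# Translate a DNA string under the standard genetic code; stops rendered "*".
translate_nt <- function(nt) {
  aa <- Biostrings::translate(Biostrings::DNAString(nt),
                              genetic.code = Biostrings::GENETIC_CODE,
                              no.init.codon = TRUE)
  as.character(aa)
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("coding_sequence '%s': %d nt, %d aa\n",
              x$name, nchar(x$nt), nchar(x$aa)))
  invisible(x)
}

#' Read a coding sequence from a FASTA file
#'
#' @param path FASTA file with a single record.
#' @param name optional name override (defaults to the FASTA header).
#' @return A \code{coding_sequence}.
#' @export
read_cds_fasta <- function(path, name = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L)
    stop("expected exactly one FASTA record, found ", length(set))
  coding_sequence(if (is.null(name)) names(set)[1L] else name,
                  as.character(set[[1L]]))
}

#' Reverse-translate a protein to a representative DNA sequence
#'
#' Uses one fixed codon per amino acid (third base A/T except Met/Trp), so
#' the result is deterministic and every NNS single-codon substitution of it
#' differs from the template except at Met/Trp positions.
#'
#' @param aa protein string (one-letter codes, no stops).
#' @return DNA string of length \code{3 * nchar(aa)}.
#' @export
reverse_translate <- function(aa) {
  res <- strsplit(aa, "")[[1L]]
  bad <- setdiff(res, names(REP_CODON))
  if (length(bad))
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  paste(REP_CODON[res], collapse = "")
}

#' The 140-residue human alpha-synuclein sequence (UniProt P37840)
#'
#' Returns the wild-type alpha-synuclein coding sequence used as the default
#' reference for the screen. The protein sequence is the canonical human one;
#' the DNA is a synthetic representative reverse-translation (the analysis is
#' invariant to the wild-type codon choice at the protein level), shipped in
#' \code{inst/extdata/asyn_cds_synthetic.fasta}.
#'
#' @return A \code{coding_sequence} named \code{"aSyn"}.
#' @export
asyn_cds <- function() {
  path <- system.file("extdata", "asyn_cds_synthetic.fasta",
                      package = "aggscan", mustWork = TRUE)
  read_cds_fasta(path, name = "aSyn")
}
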