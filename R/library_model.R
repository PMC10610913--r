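#' All 32 NNS codons
#'
#' NNS degenerate codons: N = A/C/G/T at the first two positions, S = G/C at
#' the third. The set encodes all 20 amino acids plus the TAG stop.
#' @return Character vector of 32 codons.
#' @export
nns_codons <- function() {
  n <- c("A", "C", "G", "T")
  s <- c("G", "C")
  as.vector(outer(outer(n, n, paste0), s, paste0))
}

#' Enumerate the NNS single-codon saturation library
#'
#' Substitutes every codon in \code{mutable_range} of the wild-type coding
#' sequence with each of the 32 NNS codons, translates each variant gene, and
#' collapses the codon-level library to protein-level variants. Variants whose
#' substituted codon encodes the wild-type residue are flagged synonymous;
#' during counting their reads are pooled into the wild-type reference.
#'
#' @param wt a \code{coding_sequence}.
#' @param mutable_range integer vector \code{c(first, last)} of residue
#'   positions to mutagenize (inclusive, 1-based). Defaults to 2..length,
#'   leaving the initiator Met untouched.
#' @return An object of class \code{variant_db} with components:
#'   \describe{
#'     \item{wt}{the wild-type \code{coding_sequence}}
#'     \item{mutable_range}{the range used}
#'     \item{codon_variants}{data.frame, one row per (position, NNS codon):
#'       \code{position}, \code{codon}, \code{product}, \code{is_wt_codon},
#'       \code{is_synonymous}, \code{gene_nt}}
#'     \item{protein_variants}{data.frame keyed by (position, substitution)
#'       over non-wild-type products: \code{position}, \code{wt_aa},
#'       \code{substitution}, \code{n_codons}}
#'   }
#' @examples
#' db <- enumerate_nns(coding_sequence("toy", "ATGGCT"), c(2, 2))
#' nrow(db$protein_variants)  # 20: 19 missense + stop
#' @export
enumerate_nns <- function(wt, mutable_range = NULL) {
  stopifnot(inherits(wt, "coding_sequence"))
  n_aa <- nchar(wt$aa)
  if (is.null(mutable_range)) mutable_range <- c(2L, n_aa)
  mutable_range <- as.integer(mutable_range)
  if (length(mutable_range) != 2L || mutable_range[1L] > mutable_range[2L] ||
      mutable_range[1L] < 1L || mutable_range[2L] > n_aa)
    stop("mutable_range must lie within [1, ", n_aa, "]")

  positions <- seq.int(mutable_range[1L], mutable_range[2L])
  codons <- nns_codons()
  wt_res <- strsplit(wt$aa, "")[[1L]]

  # genetic-code products of the 32 NNS codons, computed once
  products <- vapply(codons, function(cd) {
    p <- Biostrings::GENETIC_CODE[[cd]]
    if (p == "*") STOP_CHAR else p
  }, character(1L))

  grid_pos <- rep(positions, each = length(codons))
  grid_codon <- rep(codons, times = length(positions))
  grid_prod <- rep(products, times = length(positions))

  wt_codon <- substring(wt$nt, (grid_pos - 1L) * 3L + 1L, grid_pos * 3L)
  gene_nt <- paste0(substring(wt$nt, 1L, (grid_pos - 1L) * 3L),
                    grid_codon,
                    substring(wt$nt, grid_pos * 3L + 1L, nchar(wt$nt)))

  codon_variants <- data.frame(
    position = grid_pos,
    codon = grid_codon,
    product = grid_prod,
    is_wt_codon = grid_codon == wt_codon,
    is_synonymous = grid_prod == wt_res[grid_pos],
    gene_nt = gene_nt,
    stringsAsFactors = FALSE)

  nonwt <- codon_variants[!codon_variants$is_synonymous, , drop = FALSE]
  key <- paste(nonwt$position, nonwt$product)
  agg <- nonwt[!duplicated(key), c("position", "product")]
  agg$n_codons <- as.integer(table(key)[paste(agg$position, agg$product)])
  protein_variants <- data.frame(
    position = agg$position,
    wt_aa = wt_res[agg$position],
    substitution = agg$product,
    n_codons = agg$n_codons,
    stringsAsFactors = FALSE)
  protein_variants <- protein_variants[order(protein_variants$position,
                                             protein_variants$substitution), ]
  rownames(protein_variants) <- NULL

  structure(list(wt = wt,
                 mutable_range = mutable_range,
                 codon_variants = codon_variants,
                 protein_variants = protein_variants),
            class = "variant_db")
}

#' @export
print.variant_db <- function(x, ...) {
  cat(sprintf(paste0("variant_db for '%s': positions %d-%d, %d codon ",
                     "variants, %d non-WT protein variants\n"),
              x$wt$name, x$mutable_range[1L], x$mutable_range[2L],
              nrow(x$codon_variants), nrow(x$protein_variants)))
  invisible(x)
}

#' Canonical variant name
#'
#' Formats a (position, substitution) key as wild-type residue, position,
#' substitution, e.g. \code{"E13K"}; stop variants use \code{"*"}
#' (\code{"K10*"}). Synonymous keys are rendered with the substitution equal
#' to the wild type, e.g. \code{"A30A"}.
#'
#' @param db a \code{variant_db} (supplies the wild-type residues).
#' @param position residue position(s).
#' @param substitution amino-acid one-letter code(s) or \code{"*"}.
#' @return Character vector of names.
#' @export
variant_name <- function(db, position, substitution) {
  wt_res <- strsplit(db$wt$aa, "")[[1L]]
  if (any(position < 1L | position > length(wt_res)))
    stop("position outside the coding sequence")
  if (!all(substitution %in% c(AA_DISPLAY_ORDER, STOP_CHAR)))
    stop("invalid substitution symbol")
  paste0(wt_res[position], position, substitution)
}

#' Parse a canonical variant name
#'
#' Inverse of \code{\link{variant_name}}: validates the wild-type residue
#' against the database and returns the key.
#'
#' @param db a \code{variant_db}.
#' @param name variant string such as \code{"E13K"} or \code{"Q79*"}.
#' @return data.frame with columns \code{position}, \code{substitution}.
#' @export
parse_variant <- function(db, name) {
  m <- regmatches(name, regexec("^([A-Y])([0-9]+)([A-Y*])$", name))
  bad <- vapply(m, length, integer(1L)) != 4L
  if (any(bad)) stop("unparseable variant name(s): ",
                     paste(name[bad], collapse = ", "))
  wt_aa <- vapply(m, `[`, character(1L), 2L)
  pos <- as.integer(vapply(m, `[`, character(1L), 3L))
  sub <- vapply(m, `[`, character(1L), 4L)
  wt_res <- strsplit(db$wt$aa, "")[[1L]]
  if (any(pos < 1L | pos > length(wt_res)))
    stop("position outside the coding sequence")
  if (any(wt_res[pos] != wt_aa))
    stop("wild-type residue mismatch in variant name")
  data.frame(position = pos, substitution = sub, stringsAsFactors = FALSE)
}

#' Write the protein-variant database as TSV
#'
#' One row per (position, substitution) with the number of encoding codons.
#'
#' @param db a \code{variant_db}.
#' @param path output file.
#' @export
write_variant_db <- function(db, path) {
  pv <- db$protein_variants
  pv$variant <- variant_name(db, pv$position, pv$substitution)
  utils::write.table(pv[, c("variant", "position", "wt_aa", "substitution",
                            "n_codons")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
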