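#' Default amplicon anchor sequences
#'
#' Constant flanks expected around the gene region in merged amplicon reads:
#' the 5' anchor ends immediately before the initiator ATG-containing codon 1
#' and the 3' anchor (start of the fluorophore linker in the fusion
#' construct) begins immediately after the final codon.
#' @return Named character vector with elements \code{five} and \code{three}.
#' @export
default_anchors <- function() {
  c(five = "GCTAGCGCCGCCACC", three = "GGAGGCTCAGGCGGA")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Trim merged reads to the gene region
#'
#' Extracts the substring strictly between the 5' and 3' anchors. Reads in
#' which either anchor is absent are tried as reverse complements; reads
#' where the extracted region does not have the expected length (indels,
#' truncations) are rejected. Rejected reads are returned as \code{NA} and
#' later counted as unmatched.
#'
#' @param reads character vector of merged read sequences.
#' @param anchors named vector as from \code{\link{default_anchors}}.
#' @param expected_length required gene-region length in nt (e.g. 420 for a
#'   140-codon gene); \code{NULL} disables the length check.
#' @return Character vector, same length as \code{reads}, gene region or
#'   \code{NA}.
#' @export
trim_to_gene <- function(reads, anchors = default_anchors(),
                         expected_length = NULL) {
  extract <- function(x) {
    i5 <- regexpr(anchors[["five"]], x, fixed = TRUE)
    i3 <- regexpr(anchors[["three"]], x, fixed = TRUE)
    start <- ifelse(i5 > 0L, i5 + nchar(anchors[["five"]]), NA_integer_)
    end <- ifelse(i3 > 0L, i3 - 1L, NA_integer_)
    out <- rep(NA_character_, length(x))
    ok <- !is.na(start) & !is.na(end) & end >= start
    out[ok] <- substring(x[ok], start[ok], end[ok])
    out
  }
  out <- extract(reads)
  retry <- which(is.na(out) & nzchar(reads))
  if (length(retry))
    out[retry] <- extract(revcomp(reads[retry]))
  if (!is.null(expected_length))
    out[!is.na(out) & nchar(out) != expected_length] <- NA_character_
  out
}

#' Read a sorted-pool FASTQ into a read set
#'
#' Base qualities are parsed but not used by the counting step (matching is
#' exact); they are retained only so that realistic inputs round-trip.
#'
#' @param path FASTQ file (optionally gzip-compressed).
#' @param pool_label one of \code{"input_library"}, \code{"fret_pos"},
#'   \code{"fret_neg"} (free-form labels are allowed).
#' @return List with \code{pool_label} and \code{reads} (character vector).
#' @export
read_pool_fastq <- function(path, pool_label) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  list(pool_label = pool_label, reads = as.character(set))
}

#' Count reads against the variant database by exact matching
#'
#' Each gene-region read increments exactly one bucket: the wild-type count
#' if it equals the wild-type gene or any synonymous NNS codon variant
#' (synonymous counts are combined into the reference), the matching
#' non-wild-type protein variant otherwise, or unmatched if it is no library
#' member (sequencing errors, indels, multi-mutants).
#'
#' @param reads character vector of gene-region sequences (\code{NA} entries,
#'   e.g. from \code{\link{trim_to_gene}}, count as unmatched).
#' @param db a \code{variant_db}.
#' @param pool_label label stored on the table.
#' @return Object of class \code{count_table}: \code{pool_label},
#'   \code{counts} (data.frame position/substitution/count covering every
#'   database key), \code{wt_count}, \code{unmatched}, \code{total}.
#' @export
count_reads <- function(reads, db, pool_label = "pool") {
  if (length(reads) == 0L) stop("empty read set")
  cv <- db$codon_variants
  # nucleotide sequences that collapse to the wild-type protein
  wt_genes <- unique(c(db$wt$nt, cv$gene_nt[cv$is_synonymous]))
  nonsyn <- cv[!cv$is_synonymous, , drop = FALSE]

  wt_hit <- !is.na(reads) & reads %in% wt_genes
  idx <- match(reads, nonsyn$gene_nt)
  idx[wt_hit] <- NA_integer_

  pv <- db$protein_variants
  pv_key <- paste(pv$position, pv$substitution)
  hit_key <- paste(nonsyn$position[idx[!is.na(idx)]],
                   nonsyn$product[idx[!is.na(idx)]])
  tab <- table(factor(hit_key, levels = pv_key))
  counts <- data.frame(position = pv$position,
                       substitution = pv$substitution,
                       count = as.integer(tab),
                       stringsAsFactors = FALSE)
  wt_count <- sum(wt_hit)
  matched <- wt_count + sum(!is.na(idx))
  structure(list(pool_label = pool_label,
                 counts = counts,
                 wt_count = wt_count,
                 unmatched = length(reads) - matched,
                 total = length(reads)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table '%s': %d reads (%d WT, %d variant, %d unmatched)\n",
              x$pool_label, x$total, x$wt_count,
              sum(x$counts$count), x$unmatched))
  invisible(x)
}

#' Per-variant frequencies within a pool
#'
#' Frequencies are relative abundances among recognized alleles: the
#' denominator is the matched read count (wild type plus all variants),
#' excluding unmatched reads, so that enrichment ratios are invariant to
#' pool-specific junk rates.
#'
#' @param ct a \code{count_table}.
#' @return List with \code{freq} (data.frame position/substitution/count/f)
#'   and \code{wt_f}; frequencies sum to 1 with the wild type included.
#' @export
pool_frequencies <- function(ct) {
  matched <- ct$total - ct$unmatched
  if (matched <= 0L)
    stop("no reads matched the variant database in pool '", ct$pool_label,
         "'; check anchors and reference sequence")
  freq <- ct$counts
  freq$f <- freq$count / matched
  list(freq = freq, wt_f = ct$wt_count / matched)
}

#' Write / read a count table as TSV
#'
#' The TSV lists every variant key plus \code{WT} and \code{unmatched}
#' sentinel rows, so the table round-trips exactly.
#' @param ct a \code{count_table}.
#' @param path file path.
#' @export
write_count_table <- function(ct, path) {
  df <- data.frame(variant = paste0(ct$counts$substitution, "@",
                                    ct$counts$position),
                   position = ct$counts$position,
                   substitution = ct$counts$substitution,
                   count = ct$counts$count,
                   stringsAsFactors = FALSE)
  df <- rbind(df,
              data.frame(variant = "WT", position = NA, substitution = "WT",
                         count = ct$wt_count),
              data.frame(variant = "unmatched", position = NA,
                         substitution = "unmatched", count = ct$unmatched))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pool=", ct$pool_label), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  header <- readLines(path, n = 1L)
  pool <- sub("^# pool=", "", header)
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  wt <- df$count[df$substitution == "WT"]
  unm <- df$count[df$substitution == "unmatched"]
  body <- df[!df$substitution %in% c("WT", "unmatched"), ]
  structure(list(pool_label = pool,
                 counts = data.frame(position = as.integer(body$position),
                                     substitution = body$substitution,
                                     count = as.integer(body$count),
                                     stringsAsFactors = FALSE),
                 wt_count = as.integer(wt),
                 unmatched = as.integer(unm),
                 total = as.integer(wt + unm + sum(body$count))),
            class = "count_table")
}
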