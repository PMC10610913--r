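#' Relative enrichment of a variant versus wild type
#'
#' RE = log10(f_sel / f_inlib) - log10(f_wt_sel / f_wt_inlib): the log10 fold
#' change of a variant's selected-versus-input frequency ratio relative to
#' the wild-type ratio. Positive values mean the variant is over-represented
#' in the selected pool relative to wild type. Vectorized over the first two
#' arguments; any non-positive frequency yields \code{NA} (no pseudocount is
#' applied here).
#'
#' @param f_sel,f_inlib variant frequency in the selected pool / input
#'   library.
#' @param f_wt_sel,f_wt_inlib wild-type frequencies in the same pools.
#' @return Numeric vector of RE values (log10 units).
#' @examples
#' relative_enrichment(0.002, 0.001, 0.01, 0.01)  # log10(2)
#' @export
relative_enrichment <- function(f_sel, f_inlib, f_wt_sel, f_wt_inlib) {
  if (any(c(f_wt_sel, f_wt_inlib) <= 0))
    stop("wild-type frequency must be positive in both pools")
  re <- log10(f_sel / f_inlib) - log10(f_wt_sel / f_wt_inlib)
  re[!is.finite(re) | f_sel <= 0 | f_inlib <= 0] <- NA_real_
  re
}

#' Score every library variant against the input pool
#'
#' Joins a selected-pool count table with the input-library table and
#' computes RE per protein variant. Variants absent from the input library
#' are flagged \code{missing_absent}; variants seen in the input fewer than
#' \code{min_input_count} times, or never seen in the selected pool, are
#' flagged \code{missing_low_count} (not detected sufficiently for an
#' accurate count). Only \code{scored} records carry an RE value.
#'
#' @param sel_ct selected-pool \code{count_table} (e.g. FRET-positive).
#' @param in_ct input-library \code{count_table}.
#' @param db a \code{variant_db}.
#' @param min_input_count minimum input reads for scoring (default 10, which
#'   keeps the Poisson component of the RE noise below ~0.15 log10 units).
#' @param pseudocount optional count added to every allele in both pools
#'   before frequencies are formed (default 0: none).
#' @return data.frame with one row per database key: \code{position},
#'   \code{wt_aa}, \code{substitution}, \code{count_sel}, \code{count_in},
#'   \code{f_sel}, \code{f_in}, \code{re}, \code{status}.
#' @export
enrichment_records <- function(sel_ct, in_ct, db, min_input_count = 10L,
                               pseudocount = 0) {
  pv <- db$protein_variants
  key <- function(ct) paste(ct$counts$position, ct$counts$substitution)
  pk <- paste(pv$position, pv$substitution)
  c_sel <- ct_counts(sel_ct, key, pk)
  c_in <- ct_counts(in_ct, key, pk)

  m_sel <- sel_ct$total - sel_ct$unmatched
  m_in <- in_ct$total - in_ct$unmatched
  if (m_sel <= 0L || m_in <= 0L) stop("a pool has no matched reads")

  n_alleles <- nrow(pv) + 1L  # variants + WT
  f_sel <- (c_sel + pseudocount) / (m_sel + pseudocount * n_alleles)
  f_in <- (c_in + pseudocount) / (m_in + pseudocount * n_alleles)
  f_wt_sel <- (sel_ct$wt_count + pseudocount) /
    (m_sel + pseudocount * n_alleles)
  f_wt_in <- (in_ct$wt_count + pseudocount) / (m_in + pseudocount * n_alleles)

  status <- rep("scored", nrow(pv))
  status[c_in + pseudocount < min_input_count] <- "missing_low_count"
  status[f_sel <= 0] <- "missing_low_count"
  status[c_in + pseudocount <= 0] <- "missing_absent"

  re <- relative_enrichment(f_sel, f_in, f_wt_sel, f_wt_in)
  re[status != "scored"] <- NA_real_

  data.frame(position = pv$position, wt_aa = pv$wt_aa,
             substitution = pv$substitution,
             count_sel = c_sel, count_in = c_in,
             f_sel = f_sel, f_in = f_in, re = re, status = status,
             stringsAsFactors = FALSE)
}

ct_counts <- function(ct, key, pk) {
  idx <- match(pk, key(ct))
  if (anyNA(idx)) stop("count table does not cover the variant database")
  ct$counts$count[idx]
}

#' Build the substitution-by-position enrichment matrix
#'
#' Arranges scored RE values on a 20-row grid (rows in the fixed display
#' order \code{AA_DISPLAY_ORDER}, columns the mutable positions). Wild-type
#' cells are flagged distinctly from missing cells; stop-codon variants are
#' kept in a separate row outside the display matrix.
#'
#' @param records output of \code{\link{enrichment_records}}.
#' @param db a \code{variant_db}.
#' @return Object of class \code{enrichment_matrix}: \code{values} (20 x P
#'   numeric), \code{mask} (20 x P character: \code{"scored"}, \code{"wt"},
#'   \code{"missing_low_count"}, \code{"missing_absent"}), \code{positions},
#'   \code{stop_re}, \code{stop_status} (named by position), \code{wt_aa}.
#' @export
build_matrix <- function(records, db) {
  if (anyDuplicated(paste(records$position, records$substitution)))
    stop("duplicate (position, substitution) records")
  positions <- seq.int(db$mutable_range[1L], db$mutable_range[2L])
  wt_res <- strsplit(db$wt$aa, "")[[1L]]

  values <- matrix(NA_real_, nrow = length(AA_DISPLAY_ORDER),
                   ncol = length(positions),
                   dimnames = list(AA_DISPLAY_ORDER, positions))
  mask <- matrix("missing_absent", nrow = nrow(values), ncol = ncol(values),
                 dimnames = dimnames(values))
  for (p in seq_along(positions))
    mask[wt_res[positions[p]], p] <- "wt"

  mis <- records[records$substitution != STOP_CHAR, ]
  ri <- match(mis$substitution, AA_DISPLAY_ORDER)
  ci <- match(mis$position, positions)
  keep <- !is.na(ri) & !is.na(ci)
  idx <- cbind(ri[keep], ci[keep])
  values[idx] <- mis$re[keep]
  mask[idx] <- mis$status[keep]

  stops <- records[records$substitution == STOP_CHAR, ]
  stop_re <- stats::setNames(stops$re, stops$position)
  stop_status <- stats::setNames(stops$status, stops$position)

  structure(list(values = values, mask = mask, positions = positions,
                 stop_re = stop_re, stop_status = stop_status,
                 wt_aa = wt_res[positions]),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf(paste0("enrichment_matrix: %d substitutions x %d positions ",
                     "(%d scored, %d missing), %d stop variants\n"),
              nrow(x$values), ncol(x$values), sum(x$mask == "scored"),
              sum(x$mask %in% c("missing_low_count", "missing_absent")),
              length(x$stop_re)))
  invisible(x)
}

#' Stop-codon false-discovery estimate for the screen
#'
#' Stop variants truncate the protein upstream of the fluorophore, so they
#' cannot genuinely produce FRET; any apparent enrichment of stops in the
#' FRET-positive pool measures sorting/technical error. Two estimators:
#' \describe{
#'   \item{\code{positive_re}}{fraction of scored stop variants with RE > 0
#'     (stops that look spuriously enriched).}
#'   \item{\code{gate_leakage}}{the pooled stop enrichment ratio
#'     (sum f_sel / sum f_in over stop variants) multiplied by the fraction
#'     of sorted cells falling in the positive gate; this estimates the
#'     per-cell probability that a non-aggregating cell is mis-sorted into
#'     the positive gate, the sorter error rate itself. Requires
#'     \code{frac_pos} (known from the sort statistics).}
#' }
#'
#' @param records output of \code{\link{enrichment_records}} for the
#'   FRET-positive versus input comparison.
#' @param method \code{"positive_re"} (default) or \code{"gate_leakage"}.
#' @param frac_pos fraction of sorted cells in the positive gate (needed for
#'   \code{gate_leakage}).
#' @return The estimate (a fraction), with attribute \code{n_stops}.
#' @export
stop_codon_fdr <- function(records, method = c("positive_re", "gate_leakage"),
                           frac_pos = NULL) {
  method <- match.arg(method)
  stops <- records[records$substitution == STOP_CHAR, ]
  if (method == "positive_re") {
    scored <- stops[stops$status == "scored", ]
    if (nrow(scored) == 0L)
      stop("no scored stop variants; cannot estimate FDR")
    out <- mean(scored$re > 0)
    n <- nrow(scored)
  } else {
    if (is.null(frac_pos))
      stop("gate_leakage estimator needs frac_pos (positive-gate cell fraction)")
    use <- stops[stops$count_in > 0, ]
    if (nrow(use) == 0L)
      stop("no stop variants observed in the input library")
    out <- sum(use$f_sel) / sum(use$f_in) * frac_pos
    n <- nrow(use)
  }
  attr(out, "n_stops") <- n
  out
}

#' Serialize an enrichment matrix in heatmap layout
#'
#' 20 rows in the fixed substitution display order, one column per position;
#' cells hold the RE value, \code{"NA"} for cells not detected sufficiently
#' for an accurate count, and \code{"WT"} for wild-type cells. The format
#' round-trips through \code{\link{read_matrix_tsv}} (missing-cell subtype is
#' carried in a trailing comment block).
#'
#' @param mat an \code{enrichment_matrix}.
#' @param path output TSV.
#' @export
write_matrix_tsv <- function(mat, path) {
  cells <- matrix(as.character(signif(mat$values, 10)),
                  nrow = nrow(mat$values), dimnames = dimnames(mat$values))
  cells[mat$mask %in% c("missing_low_count", "missing_absent")] <- "NA"
  cells[mat$mask == "wt"] <- "WT"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("substitution", colnames(mat$values)), collapse = "\t"),
             con)
  for (i in seq_len(nrow(cells)))
    writeLines(paste(c(rownames(cells)[i], cells[i, ]), collapse = "\t"), con)
  # stop row and missing-subtype annotations as comment lines
  writeLines(paste0("#stop_re\t", paste(names(mat$stop_re), collapse = ",")),
             con)
  writeLines(paste0("#stop_val\t",
                    paste(as.character(signif(mat$stop_re, 10)),
                          collapse = ",")), con)
  writeLines(paste0("#stop_status\t", paste(mat$stop_status, collapse = ",")),
             con)
  low <- which(mat$mask == "missing_low_count")
  writeLines(paste0("#low_count_cells\t", paste(low, collapse = ",")), con)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  com <- grepl("^#", lines)
  body <- utils::read.delim(text = lines[!com], check.names = FALSE,
                            colClasses = "character", na.strings = NULL)
  positions <- as.integer(colnames(body)[-1L])
  cells <- as.matrix(body[, -1L, drop = FALSE])
  rownames(cells) <- body$substitution

  values <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                    dimnames = list(rownames(cells),
                                                    positions)))
  mask <- matrix("scored", nrow = nrow(cells), ncol = ncol(cells),
                 dimnames = dimnames(values))
  mask[cells == "NA"] <- "missing_absent"
  mask[cells == "WT"] <- "wt"

  meta <- function(tag) {
    ln <- lines[startsWith(lines, paste0("#", tag, "\t"))]
    strsplit(sub("^#[^\t]+\t", "", ln), ",")[[1L]]
  }
  low <- suppressWarnings(as.integer(meta("low_count_cells")))
  low <- low[!is.na(low)]
  mask[low] <- "missing_low_count"
  stop_pos <- meta("stop_re")
  stop_re <- stats::setNames(suppressWarnings(as.numeric(meta("stop_val"))),
                             stop_pos)
  stop_status <- stats::setNames(meta("stop_status"), stop_pos)

  wt_aa <- rownames(cells)[apply(mask == "wt", 2L, function(z)
    if (any(z)) which(z)[1L] else NA_integer_)]
  structure(list(values = values, mask = mask, positions = positions,
                 stop_re = stop_re, stop_status = stop_status, wt_aa = wt_aa),
            class = "enrichment_matrix")
}
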