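#' Per-residue median enrichment
#'
#' Collapses the enrichment matrix to one number per position: the median RE
#' over scored missense cells (missing cells and stop-codon variants are
#' excluded; even counts average the two central values). Positions with no
#' scored cell are dropped from the map.
#'
#' @param mat an \code{enrichment_matrix}.
#' @return Named numeric vector, names = positions.
#' @export
residue_medians <- function(mat) {
  med <- vapply(seq_along(mat$positions), function(j) {
    v <- mat$values[mat$mask[, j] == "scored", j]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }, numeric(1L))
  names(med) <- mat$positions
  med[!is.na(med)]
}

#' Otsu threshold for a bimodal set of values
#'
#' Classical histogram Otsu thresholding: the values are binned into
#' \code{bins} equal-width bins over their range and the bin edge maximizing
#' the between-class variance (equivalently minimizing the pooled
#' within-class variance) is returned. Ties are resolved by averaging the
#' maximizing edges. Deterministic for a fixed bin count.
#'
#' @param values numeric vector with at least two distinct values.
#' @param bins histogram bin count (default 256, the classical
#'   image-processing choice).
#' @return The threshold (same units as \code{values}).
#' @export
otsu_threshold <- function(values, bins = 256L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    stop("Otsu thresholding needs at least two distinct values")
  rng <- range(values)
  edges <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  h <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE),
                     bins), nbins = bins)
  p <- h / sum(h)
  centers <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  w0 <- cumsum(p)                       # class {<= edge k+1}
  mu <- cumsum(p * centers)
  mu_t <- mu[bins]
  # between-class variance at each interior cut (after bin k)
  k <- seq_len(bins - 1L)
  valid <- w0[k] > 0 & w0[k] < 1
  sigma_b <- rep(-Inf, bins - 1L)
  sigma_b[valid] <- (mu_t * w0[k][valid] - mu[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  best <- which(sigma_b == max(sigma_b))
  mean(edges[best + 1L])
}

#' Classify inhibitory residues from median enrichment
#'
#' Residues whose median RE is less than or equal to the threshold are
#' classified inhibitory (substitutions there deplete seeding); the
#' comparison is inclusive. Consecutive inhibitory residues are merged into
#' maximal intervals.
#'
#' @param medians named numeric vector from \code{\link{residue_medians}}.
#' @param threshold cut-off in log10 units; defaults to
#'   \code{otsu_threshold(medians)}.
#' @param bins passed to \code{\link{otsu_threshold}} when the threshold is
#'   computed here.
#' @return Object of class \code{residue_classification}: \code{medians},
#'   \code{threshold}, \code{inhibitory} (sorted positions), \code{intervals}
#'   (2-column matrix start/end).
#' @export
classify_residues <- function(medians, threshold = NULL, bins = 256L) {
  if (length(medians) == 0L) stop("empty median map")
  if (is.null(threshold)) threshold <- otsu_threshold(medians, bins = bins)
  inhibitory <- sort(as.integer(names(medians)[medians <= threshold]))
  structure(list(medians = medians, threshold = threshold,
                 inhibitory = inhibitory,
                 intervals = runs_to_intervals(inhibitory)),
            class = "residue_classification")
}

runs_to_intervals <- function(pos) {
  if (length(pos) == 0L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  breaks <- c(0L, which(diff(pos) > 1L), length(pos))
  starts <- pos[breaks[-length(breaks)] + 1L]
  ends <- pos[breaks[-1L]]
  matrix(c(starts, ends), ncol = 2L,
         dimnames = list(NULL, c("start", "end")))
}

#' @export
print.residue_classification <- function(x, ...) {
  cat(sprintf("residue_classification: threshold %.4f, %d inhibitory residues\n",
              x$threshold, length(x$inhibitory)))
  cat(" ", format_intervals(x$intervals), "\n")
  invisible(x)
}

#' Render / parse residue intervals in report style
#'
#' Runs are rendered \code{"29 to 30"}, isolated residues as plain numbers,
#' joined by commas: \code{"2, 27, 29 to 30, 33"}. \code{parse_intervals}
#' inverts the rendering back to the full residue set.
#'
#' @param intervals 2-column start/end matrix.
#' @return A single string; for \code{parse_intervals}, a sorted integer
#'   vector of residues.
#' @export
format_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) return("")
  paste(ifelse(intervals[, 1L] == intervals[, 2L],
               as.character(intervals[, 1L]),
               paste(intervals[, 1L], "to", intervals[, 2L])),
        collapse = ", ")
}

#' @rdname format_intervals
#' @param text rendered interval string.
#' @export
parse_intervals <- function(text) {
  if (!nzchar(trimws(text))) return(integer(0))
  parts <- trimws(strsplit(text, ",")[[1L]])
  out <- lapply(parts, function(p) {
    if (grepl(" to ", p)) {
      ab <- as.integer(strsplit(p, " to ")[[1L]])
      seq.int(ab[1L], ab[2L])
    } else as.integer(p)
  })
  sort(unique(unlist(out)))
}

#' Extract one substitution's per-position profile
#'
#' Returns the enrichment-matrix row for a single substitution (e.g. the
#' proline or arginine row, the classic aggregation gatekeepers), with
#' masked cells propagated as \code{NA}.
#'
#' @param mat an \code{enrichment_matrix}.
#' @param substitution one-letter amino-acid code present in the display
#'   alphabet.
#' @return Named numeric vector over positions (\code{NA} = missing or WT).
#' @export
gatekeeper_profile <- function(mat, substitution) {
  if (!substitution %in% rownames(mat$values))
    stop("unknown substitution '", substitution, "'")
  v <- mat$values[substitution, ]
  v[mat$mask[substitution, ] != "scored"] <- NA_real_
  stats::setNames(v, mat$positions)
}

#' Write a residue classification as TSV
#' @param cls a \code{residue_classification}.
#' @param path output file.
#' @export
write_classification <- function(cls, path) {
  df <- data.frame(position = as.integer(names(cls$medians)),
                   median_re = unname(cls$medians),
                   class = ifelse(cls$medians <= cls$threshold,
                                  "inhibitory", "neutral"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# otsu_threshold=%.10g", cls$threshold), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
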