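#' Read / write an assigned 1H-15N peak list
#'
#' TSV with columns \code{residue}, \code{aa}, \code{delta_h} (ppm),
#' \code{delta_n} (ppm), \code{confidence} (\code{high}/\code{low}).
#' Residues must be unique; prolines carry no amide proton and must be
#' absent.
#'
#' @param path TSV file.
#' @param label condition name stored on the list.
#' @return Object of class \code{peak_list}.
#' @export
read_peaklist <- function(path, label = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "aa", "delta_h", "delta_n", "confidence")
  if (!all(need %in% names(df)))
    stop("peak list lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  peak_list(label, df[, need])
}

#' @rdname read_peaklist
#' @param peaks data.frame with the columns above.
#' @export
peak_list <- function(label, peaks) {
  if (anyDuplicated(peaks$residue)) stop("duplicate residues in peak list")
  if (any(peaks$aa == "P")) stop("prolines have no amide cross-peak")
  if (!all(peaks$confidence %in% c("high", "low")))
    stop("confidence must be 'high' or 'low'")
  structure(list(label = label, peaks = peaks), class = "peak_list")
}

#' @rdname read_peaklist
#' @param pl a \code{peak_list}.
#' @export
write_peaklist <- function(pl, path) {
  utils::write.table(pl$peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Chemical shift perturbations between two peak lists
#'
#' For every residue assigned in both spectra, computes the per-dimension
#' shift changes (reference minus comparison) and the combined perturbation
#' CSP = sqrt(ddH^2 + (ddN / 5)^2), the usual amide scaling that down-weights
#' the wider 15N dispersion. Residues missing from either list are excluded;
#' residues flagged low-confidence in either list are excluded from the mean
#' CSP (and flagged in the profile).
#'
#' @param ref reference \code{peak_list} (e.g. wild type).
#' @param cmp comparison \code{peak_list} (e.g. a point mutant).
#' @return Object of class \code{csp_profile}: \code{profile} (data.frame
#'   residue/delta_h/delta_n/csp/high_confidence), \code{mean_csp} (ppm,
#'   high-confidence residues only), \code{labels}.
#' @examples
#' # ddH = 0.03, ddN = 0.10  ->  CSP = sqrt(0.03^2 + 0.02^2) = 0.036056 ppm
#' @export
csp_profile <- function(ref, cmp) {
  common <- intersect(ref$peaks$residue, cmp$peaks$residue)
  if (length(common) == 0L) stop("no residues assigned in both peak lists")
  r <- ref$peaks[match(common, ref$peaks$residue), ]
  m <- cmp$peaks[match(common, cmp$peaks$residue), ]
  dh <- r$delta_h - m$delta_h
  dn <- r$delta_n - m$delta_n
  csp <- sqrt(dh^2 + (dn / 5)^2)
  high <- r$confidence == "high" & m$confidence == "high"
  prof <- data.frame(residue = common, delta_h = dh, delta_n = dn,
                     csp = csp, high_confidence = high)
  prof <- prof[order(prof$residue), ]
  rownames(prof) <- NULL
  structure(list(profile = prof,
                 mean_csp = mean(csp[high]),
                 labels = c(ref = ref$label, cmp = cmp$label)),
            class = "csp_profile")
}

#' @export
print.csp_profile <- function(x, ...) {
  cat(sprintf("csp_profile %s vs %s: %d residues, mean CSP %.5f ppm\n",
              x$labels[["ref"]], x$labels[["cmp"]], nrow(x$profile),
              x$mean_csp))
  invisible(x)
}

#' Call the perturbed region from a CSP profile
#'
#' Residues whose CSP exceeds mean + k_sd standard deviations (over
#' high-confidence residues) are called perturbed and merged into maximal
#' runs, tolerating single-residue gaps for unassigned or proline positions.
#'
#' @param profile a \code{csp_profile}.
#' @param k_sd threshold multiplier (default 1).
#' @param gap maximum unperturbed/unassigned gap bridged when merging runs
#'   (default 1 residue).
#' @return 2-column start/end interval matrix (possibly zero rows).
#' @export
call_perturbed <- function(profile, k_sd = 1, gap = 1L) {
  p <- profile$profile[profile$profile$high_confidence, ]
  if (nrow(p) < 5L) stop("too few high-confidence residues to call a region")
  thr <- mean(p$csp) + k_sd * stats::sd(p$csp)
  hits <- sort(p$residue[p$csp > thr])
  if (length(hits) == 0L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  breaks <- c(0L, which(diff(hits) > gap + 1L), length(hits))
  starts <- hits[breaks[-length(breaks)] + 1L]
  ends <- hits[breaks[-1L]]
  matrix(c(starts, ends), ncol = 2L,
         dimnames = list(NULL, c("start", "end")))
}

#' Write a CSP profile as TSV
#' @param profile a \code{csp_profile}.
#' @param path output file.
#' @export
write_csp_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mean_csp_ppm=%.10g", profile$mean_csp), con)
  utils::write.table(profile$profile, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
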