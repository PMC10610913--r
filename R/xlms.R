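XLINK_COLUMNS <- c("replicate", "pep_a", "pep_b", "res_a", "res_b", "score",
                   "mass_error", "tic_pct", "frags_a", "frags_b",
                   "contig_a", "contig_b")

#' Read / write cross-link identification tables
#'
#' TSV dialect with one row per cross-link identification: \code{replicate},
#' peptide strings \code{pep_a}/\code{pep_b}, linked residue positions
#' \code{res_a}/\code{res_b} (1-based protein coordinates), search-engine
#' \code{score}, \code{mass_error} (ppm), \code{tic_pct} (percent of total
#' ion chromatogram), assigned fragment-ion counts \code{frags_a}/
#' \code{frags_b} and longest contiguous fragment runs \code{contig_a}/
#' \code{contig_b}. The reader validates the header strictly.
#'
#' @param path TSV file.
#' @return data.frame of identifications.
#' @export
read_xlinks_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(XLINK_COLUMNS, names(df))
  if (length(missing_cols))
    stop("cross-link table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  df[, XLINK_COLUMNS]
}

#' @rdname read_xlinks_tsv
#' @param ids data.frame of identifications.
#' @export
write_xlinks_tsv <- function(ids, path) {
  utils::write.table(ids[, XLINK_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Post-search filtering of cross-link identifications
#'
#' Keeps identifications passing all of: score > 30; mass error within
#' [-2.2, +3.8] ppm (edges inclusive); %TIC > 10; both peptides at least six
#' amino acids; and on each peptide at least four assigned fragment ions or
#' at least three contiguous fragments. Records with missing fields are
#' dropped with a message. The filter is idempotent and order-independent.
#'
#' @param ids data.frame as from \code{\link{read_xlinks_tsv}}.
#' @return The passing subset, rows in input order.
#' @export
filter_xlinks <- function(ids) {
  need <- c("score", "mass_error", "tic_pct", "pep_a", "pep_b",
            "frags_a", "frags_b", "contig_a", "contig_b")
  complete <- stats::complete.cases(ids[, need])
  if (any(!complete))
    message(sum(!complete), " identification(s) dropped: missing fields")
  x <- ids[complete, , drop = FALSE]
  keep <- x$score > 30 &
    x$mass_error >= -2.2 & x$mass_error <= 3.8 &
    x$tic_pct > 10 &
    nchar(x$pep_a) >= 6L & nchar(x$pep_b) >= 6L &
    (x$frags_a >= 4L | x$contig_a >= 3L) &
    (x$frags_b >= 4L | x$contig_b >= 3L)
  x[keep, , drop = FALSE]
}

#' Replicate-consensus cross-link map
#'
#' Collapses identifications to unordered residue pairs (peptide context is
#' ignored), then keeps pairs identified in at least \code{required} of the
#' replicates (default: all of them, the n-of-n consensus rule). Each kept
#' pair carries its mean identification count across all replicates.
#'
#' @param ids filtered identifications (single data.frame with a
#'   \code{replicate} column).
#' @param required minimum number of replicates a pair must appear in;
#'   \code{NULL} means every replicate present in the table.
#' @return Object of class \code{consensus_link_map}: \code{pairs}
#'   (data.frame res_a/res_b/freq, res_a <= res_b), \code{n_replicates},
#'   \code{required}.
#' @export
consensus_links <- function(ids, required = NULL) {
  reps <- unique(ids$replicate)
  if (length(reps) == 0L) stop("no replicates in identification table")
  if (is.null(required)) required <- length(reps)
  if (required > length(reps))
    stop("required (", required, ") exceeds replicate count (",
         length(reps), ")")
  a <- pmin(ids$res_a, ids$res_b)
  b <- pmax(ids$res_a, ids$res_b)
  key <- paste(a, b)
  tab <- table(key, factor(ids$replicate, levels = reps))
  n_seen <- rowSums(tab > 0)
  keep <- n_seen >= required
  freq <- rowSums(tab) / length(reps)
  ab <- do.call(rbind, strsplit(rownames(tab)[keep], " "))
  pairs <- if (sum(keep) == 0L)
    data.frame(res_a = integer(0), res_b = integer(0), freq = numeric(0))
  else
    data.frame(res_a = as.integer(ab[, 1L]), res_b = as.integer(ab[, 2L]),
               freq = unname(freq[keep]))
  pairs <- pairs[order(pairs$res_a, pairs$res_b), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, n_replicates = length(reps),
                 required = required),
            class = "consensus_link_map")
}

#' @export
print.consensus_link_map <- function(x, ...) {
  cat(sprintf("consensus_link_map: %d pairs (%d-of-%d rule), total frequency %.1f\n",
              nrow(x$pairs), x$required, x$n_replicates, sum(x$pairs$freq)))
  invisible(x)
}

#' Cross-link content of a residue window
#'
#' Sums consensus frequencies over pairs falling in a region; by default
#' both endpoints must lie inside (the \code{"any"} mode counts pairs with
#' at least one endpoint inside). The distinct-pair count is returned as an
#' attribute.
#'
#' @param map a \code{consensus_link_map}.
#' @param region \code{c(first, last)} residue window (default the
#'   N-terminal 35 residues).
#' @param mode \code{"both"} or \code{"any"} endpoint containment.
#' @return Summed mean frequency, with attribute \code{n_pairs}.
#' @export
region_link_count <- function(map, region = c(1L, 35L),
                              mode = c("both", "any")) {
  mode <- match.arg(mode)
  if (region[2L] < region[1L]) stop("empty region")
  p <- map$pairs
  in_a <- p$res_a >= region[1L] & p$res_a <= region[2L]
  in_b <- p$res_b >= region[1L] & p$res_b <= region[2L]
  sel <- if (mode == "both") in_a & in_b else in_a | in_b
  out <- sum(p$freq[sel])
  attr(out, "n_pairs") <- sum(sel)
  out
}

#' Geometric compatibility of cross-links with a conformer
#'
#' A linked residue pair is compatible with a model when its Calpha-Calpha
#' Euclidean distance is strictly below the cutoff (default 30 angstrom,
#' a generous bound for zero-length chemistry on a disordered chain).
#' Pairs with residues outside the model are dropped with a message.
#'
#' @param map a \code{consensus_link_map}.
#' @param model numeric n x 3 matrix of Calpha coordinates (angstrom), row i
#'   = residue i.
#' @param cutoff distance cutoff in angstrom (strict \code{<}).
#' @return List: \code{n_compatible}, \code{n_total}, \code{distances}
#'   (data.frame res_a/res_b/distance/compatible).
#' @export
xlink_compatibility <- function(map, model, cutoff = 30) {
  p <- map$pairs
  n <- nrow(model)
  ok <- p$res_a >= 1L & p$res_a <= n & p$res_b >= 1L & p$res_b <= n
  if (any(!ok))
    message(sum(!ok), " pair(s) dropped: residue outside the model")
  p <- p[ok, , drop = FALSE]
  d <- sqrt(rowSums((model[p$res_a, , drop = FALSE] -
                     model[p$res_b, , drop = FALSE])^2))
  compatible <- d < cutoff
  list(n_compatible = sum(compatible), n_total = nrow(p),
       distances = data.frame(res_a = p$res_a, res_b = p$res_b,
                              distance = d, compatible = compatible))
}

#' Optimal-superposition RMSD between two coordinate sets
#'
#' Least-squares rigid-body superposition (Kabsch, via SVD with reflection
#' correction) of two matched n x 3 coordinate sets, returning the residual
#' RMSD. Symmetric in its arguments; zero iff the sets are identical up to a
#' rigid motion.
#'
#' @param a,b n x 3 coordinate matrices with matched rows.
#' @return RMSD in the coordinate units.
#' @export
superpose_rmsd <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("coordinate sets must have matching rows")
  a <- sweep(a, 2L, colMeans(a))
  b <- sweep(b, 2L, colMeans(b))
  s <- svd(crossprod(a, b))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((a %*% rot - b)^2)))
}

#' Conformational ensemble container
#'
#' @param models list of n x 3 Calpha coordinate matrices (angstrom) sharing
#'   residue indexing.
#' @return Object of class \code{ensemble}.
#' @export
ensemble <- function(models) {
  n <- unique(vapply(models, nrow, integer(1L)))
  if (length(n) != 1L) stop("models differ in residue count")
  if (!all(vapply(models, function(m) all(is.finite(m)), logical(1L))))
    stop("non-finite coordinates in ensemble")
  structure(list(models = models, n_residues = n), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d models x %d residues\n",
              length(x$models), x$n_residues))
  invisible(x)
}

#' Read a multi-model PDB into a Calpha ensemble
#'
#' Parses a PED-style multi-model PDB file and extracts per-model Calpha
#' coordinates.
#'
#' @param path PDB file.
#' @return An \code{ensemble}.
#' @export
read_ensemble_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  ca <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  xyz <- pdb$xyz[, ca$xyz, drop = FALSE]
  models <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
  ensemble(models)
}

#' Write a Calpha ensemble as a multi-model PDB
#'
#' Emits standard MODEL/ATOM/ENDMDL records with one CA atom per residue
#' (residue type ALA placeholder unless a sequence is given).
#'
#' @param ens an \code{ensemble}.
#' @param path output file.
#' @param aa optional protein string for residue names.
#' @export
write_ensemble_pdb <- function(ens, path, aa = NULL) {
  res3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  resnames <- if (is.null(aa)) rep("ALA", ens$n_residues)
  else res3[strsplit(aa, "")[[1L]]]
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(ens$models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- ens$models[[m]]
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(xyz)), resnames, seq_len(nrow(xyz)),
      xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Cluster a residue window of an ensemble by superposition RMSD
#'
#' Computes all pairwise superposed-RMSD distances over the chosen residue
#' window and partitions the models by k-medoids (PAM on the precomputed
#' distance matrix; deterministic, no random initialization). Reports each
#' cluster's occupancy fraction and medoid model.
#'
#' @param ens an \code{ensemble}.
#' @param region \code{c(first, last)} residue window (default 1..35, the
#'   N terminus).
#' @param k number of clusters (default 4).
#' @return List: \code{labels} (per-model cluster, clusters numbered by
#'   decreasing occupancy), \code{occupancy} (fractions, decreasing),
#'   \code{medoids} (model indices), \code{rmsd} (dist object).
#' @export
cluster_region <- function(ens, region = c(1L, 35L), k = 4L) {
  m <- length(ens$models)
  if (k > m) stop("k (", k, ") exceeds the number of models (", m, ")")
  rows <- seq.int(region[1L], region[2L])
  sub <- lapply(ens$models, function(x) x[rows, , drop = FALSE])
  dm <- matrix(0, m, m)
  for (i in seq_len(m - 1L))
    for (j in seq.int(i + 1L, m)) {
      r <- superpose_rmsd(sub[[i]], sub[[j]])
      dm[i, j] <- r; dm[j, i] <- r
    }
  fit <- cluster::pam(stats::as.dist(dm), k = k, diss = TRUE)
  occ <- as.vector(table(fit$clustering)) / m
  ord <- order(occ, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  list(labels = relabel[fit$clustering],
       occupancy = occ[ord],
       medoids = fit$medoids[ord],
       rmsd = stats::as.dist(dm))
}
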