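#' Exact t-distributed stochastic neighbor embedding
#'
#' Plain O(N^2) exact-gradient t-SNE (no tree approximation), suitable for
#' the ~139-point profile sets this package embeds. Input similarities use
#' Gaussian kernels calibrated per point to the target perplexity by
#' bisection; the low-dimensional kernel is the Student t with one degree of
#' freedom. Gradient descent uses early exaggeration and momentum, with a
#' small Gaussian random initialization, so runs are reproducible for a
#' fixed seed.
#'
#' @param X numeric matrix, one row per object.
#' @param perplexity effective neighbor count (must satisfy
#'   \code{3 * perplexity < nrow(X)}).
#' @param n_iter gradient-descent iterations (default 1000).
#' @param eta learning rate (default 200).
#' @param seed RNG seed for the initialization.
#' @param exaggeration early-exaggeration factor applied for the first
#'   \code{exaggeration_iter} iterations.
#' @param exaggeration_iter see above (default 250; momentum also switches
#'   from 0.5 to 0.8 there).
#' @return n x 2 coordinate matrix.
#' @export
tsne_exact <- function(X, perplexity = 30, n_iter = 1000L, eta = 200,
                       seed = 0L, exaggeration = 12, exaggeration_iter = 250L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n - 1L < 3 * perplexity)
    stop("too few points for perplexity ", perplexity,
         "; lower the perplexity (need > 3*perplexity points)")

  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:64) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0; pj <- w } else {
        pj <- w / sw
        H <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(H - logU) < 1e-7) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- pj
  }
  P <- (P + t(P)) / (2 * n)
  P[P < .Machine$double.xmin] <- .Machine$double.xmin

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2L, sd = 1e-4), n, 2L)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  dY <- matrix(0, n, 2L)
  gains <- matrix(1, n, 2L)
  Pe <- P * exaggeration
  for (it in seq_len(n_iter)) {
    Puse <- if (it <= exaggeration_iter) Pe else P
    mom <- if (it <= exaggeration_iter) 0.5 else 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < .Machine$double.xmin] <- .Machine$double.xmin
    L <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- mom * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}

#' Embed per-residue mutational profiles in 2-D
#'
#' Each scored residue contributes a 20-dimensional feature vector: its RE
#' value for every substitution in the display alphabet, with missing and
#' wild-type cells set to zero. Residues with no scored cell at all are
#' excluded (rather than embedded as all-zero points). The profiles are
#' embedded with exact t-SNE under the Euclidean metric.
#'
#' @param mat an \code{enrichment_matrix}.
#' @param perplexity t-SNE perplexity (default 30).
#' @param seed RNG seed (default 0); reruns with the same seed reproduce the
#'   coordinates exactly.
#' @param ... passed to \code{\link{tsne_exact}}.
#' @return Object of class \code{embedding_result}: \code{features}
#'   (positions x 20), \code{coords} (positions x 2), \code{perplexity},
#'   \code{seed}.
#' @export
embed_profiles <- function(mat, perplexity = 30, seed = 0L, ...) {
  scored_pos <- as.integer(names(residue_medians(mat)))
  j <- match(scored_pos, mat$positions)
  feats <- t(mat$values[, j, drop = FALSE])
  feats[t(mat$mask[, j, drop = FALSE]) != "scored"] <- 0
  feats[is.na(feats)] <- 0
  rownames(feats) <- scored_pos
  coords <- tsne_exact(feats, perplexity = perplexity, seed = seed, ...)
  rownames(coords) <- scored_pos
  colnames(coords) <- c("x", "y")
  structure(list(features = feats, coords = coords,
                 perplexity = perplexity, seed = seed),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("embedding_result: %d residues, perplexity %g, seed %d\n",
              nrow(x$coords), x$perplexity, x$seed))
  invisible(x)
}

#' Write embedding coordinates as TSV
#' @param emb an \code{embedding_result}.
#' @param path output file.
#' @param class_labels optional named vector (by position) appended as a
#'   column.
#' @export
write_embedding <- function(emb, path, class_labels = NULL) {
  df <- data.frame(position = as.integer(rownames(emb$coords)),
                   x = emb$coords[, 1L], y = emb$coords[, 2L])
  if (!is.null(class_labels))
    df$class <- class_labels[as.character(df$position)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
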