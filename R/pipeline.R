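#' Run the screen analysis end to end
#'
#' Chains library enumeration, per-pool counting, enrichment scoring,
#' residue classification and (optionally) profile embedding, writing every
#' stage's table plus a JSON run manifest to \code{out_dir}. Input is either
#' a \code{screen_sim} object (in-memory reads) or a named list with
#' \code{fastq} (paths named \code{input_library}, \code{fret_pos},
#' \code{fret_neg}), \code{wt} (a \code{coding_sequence}) and optional
#' \code{anchors}. Deterministic stages rerun bit-identically for the same
#' inputs and configuration.
#'
#' @param input \code{screen_sim} or list as described.
#' @param out_dir output directory (created).
#' @param min_input_count scoring filter (default 10 input reads).
#' @param otsu_bins histogram bins for the Otsu threshold (default 256).
#' @param run_embedding embed profiles with t-SNE (default TRUE; needs
#'   > 3 x perplexity scored residues).
#' @param perplexity,tsne_seed embedding parameters.
#' @return Invisibly, a list with \code{counts}, \code{records},
#'   \code{matrix}, \code{classification}, \code{embedding}, \code{fdr},
#'   \code{manifest}.
#' @export
run_screen_pipeline <- function(input, out_dir,
                                min_input_count = 10L, otsu_bins = 256L,
                                run_embedding = TRUE, perplexity = 30,
                                tsne_seed = 0L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pools <- c("input_library", "fret_pos", "fret_neg")

  if (inherits(input, "screen_sim")) {
    db <- input$db
    reads <- input$reads
    frac_pos <- input$frac_pos
    seed <- input$config$seed
  } else {
    if (!all(pools %in% names(input$fastq)))
      stop("missing pool(s): ",
           paste(setdiff(pools, names(input$fastq)), collapse = ", "))
    db <- enumerate_nns(input$wt)
    anchors <- if (is.null(input$anchors)) default_anchors() else
      input$anchors
    reads <- lapply(input$fastq, function(p)
      trim_to_gene(read_pool_fastq(p, "pool")$reads, anchors,
                   expected_length = nchar(input$wt$nt)))
    names(reads) <- names(input$fastq)
    frac_pos <- input$frac_pos
    seed <- NA_integer_
  }

  counts <- lapply(pools, function(p) count_reads(reads[[p]], db, p))
  names(counts) <- pools
  for (p in pools)
    write_count_table(counts[[p]], file.path(out_dir,
                                             paste0(p, ".counts.tsv")))

  records <- enrichment_records(counts$fret_pos, counts$input_library, db,
                                min_input_count = min_input_count)
  mat <- build_matrix(records, db)
  write_matrix_tsv(mat, file.path(out_dir, "enrichment_matrix.tsv"))

  med <- residue_medians(mat)
  cls <- classify_residues(med, bins = otsu_bins)
  write_classification(cls, file.path(out_dir, "classification.tsv"))

  fdr <- list(positive_re = tryCatch(
    as.numeric(stop_codon_fdr(records, "positive_re")), error = function(e)
      NA_real_))
  if (!is.null(frac_pos))
    fdr$gate_leakage <- as.numeric(
      stop_codon_fdr(records, "gate_leakage", frac_pos = frac_pos))

  emb <- NULL
  if (run_embedding) {
    emb <- embed_profiles(mat, perplexity = perplexity, seed = tsne_seed)
    lab <- stats::setNames(
      ifelse(as.integer(names(med)) %in% cls$inhibitory, "inhibitory",
             "neutral"), names(med))
    write_embedding(emb, file.path(out_dir, "embedding.tsv"),
                    class_labels = lab)
  }

  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package = "aggscan",
    version = as.character(utils::packageVersion("aggscan")),
    created = format(Sys.time(), tz = "UTC"),
    seed = seed,
    tsne_seed = if (run_embedding) tsne_seed else NULL,
    config = list(min_input_count = min_input_count,
                  otsu_bins = otsu_bins, perplexity = perplexity,
                  mutable_range = db$mutable_range,
                  wt_name = db$wt$name),
    otsu_threshold = cls$threshold,
    inhibitory_intervals = format_intervals(cls$intervals),
    stop_fdr = fdr,
    output_md5 = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(counts = counts, records = records, matrix = mat,
                 classification = cls, embedding = emb, fdr = fdr,
                 manifest = manifest))
}

#' Export the enrichment matrix in heatmap layout
#'
#' Convenience wrapper around \code{\link{write_matrix_tsv}}: 20 rows in the
#' fixed substitution display order, one column per position, cells holding
#' the RE value, \code{NA} for insufficiently-detected variants and
#' \code{WT} for wild-type cells.
#'
#' @param mat an \code{enrichment_matrix}.
#' @param path output TSV.
#' @export
export_heatmap_table <- function(mat, path) {
  write_matrix_tsv(mat, path)
}
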