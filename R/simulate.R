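# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  force(code)
}

#' Configuration for the synthetic sort-seq screen
#'
#' Defines the generative model for a one-variant-per-cell FRET-sorting
#' screen. Each cell carries one library allele; a cell with variant i
#' aggregates (is truly FRET-positive) with probability
#' \code{plogis(alpha + beta * s_i)}, where \code{s_i} is the variant's
#' ground-truth seeding propensity (wild type s = 0, core-residue missense
#' substitutions strongly negative, designated enhancers positive). Stop
#' variants truncate the protein before the fluorophore and can never FRET.
#' The sorter misassigns each cell's gate with probability
#' \code{sorter_error}. Reads are drawn multinomially from each gate's cell
#' population and carry independent per-base substitution errors.
#'
#' @param wt wild-type \code{coding_sequence} (default alpha-synuclein).
#' @param mutable_range mutagenized residue window (default 2..140).
#' @param core_residues residues whose missense substitutions inhibit
#'   seeding; defaults to four amyloid-core windows (36-42, 47-56, 65-78,
#'   88-95).
#' @param s_core propensity of core missense substitutions (default -4).
#' @param proline_range window where proline substitutions inhibit seeding
#'   regardless of core membership (default 30..100).
#' @param enhancer_variants optional data.frame (position, substitution)
#'   of seeding-enhancing variants.
#' @param s_enhancer propensity of enhancer variants (default +1).
#' @param alpha logistic intercept; default \code{qlogis(0.3)} for a 30
#'   percent baseline seeding rate.
#' @param beta logistic slope on the propensity (default 1).
#' @param sorter_error probability a cell is sorted into the wrong gate
#'   (default 0.036).
#' @param n_cells cells sorted (default 5e5).
#' @param reads_per_pool sequencing depth per pool (default 2e5).
#' @param per_base_error substitution error rate per base in merged reads
#'   (default 2.5e-4, consistent with overlap-corrected merged amplicons).
#' @param dirichlet_conc concentration of the Dirichlet prior on library
#'   allele frequencies (default 50: roughly even coverage).
#' @param seed RNG seed.
#' @return A \code{screen_sim_config} list.
#' @export
screen_sim_config <- function(wt = asyn_cds(),
                              mutable_range = NULL,
                              core_residues = c(36:42, 47:56, 65:78, 88:95),
                              s_core = -4,
                              proline_range = c(30L, 100L),
                              enhancer_variants = NULL,
                              s_enhancer = 1,
                              alpha = stats::qlogis(0.3),
                              beta = 1,
                              sorter_error = 0.036,
                              n_cells = 5e5,
                              reads_per_pool = 2e5,
                              per_base_error = 2.5e-4,
                              dirichlet_conc = 50,
                              seed = 0L) {
  stopifnot(sorter_error >= 0, sorter_error <= 1, per_base_error >= 0,
            per_base_error < 1)
  structure(list(wt = wt, mutable_range = mutable_range,
                 core_residues = core_residues, s_core = s_core,
                 proline_range = proline_range,
                 enhancer_variants = enhancer_variants,
                 s_enhancer = s_enhancer, alpha = alpha, beta = beta,
                 sorter_error = sorter_error, n_cells = n_cells,
                 reads_per_pool = reads_per_pool,
                 per_base_error = per_base_error,
                 dirichlet_conc = dirichlet_conc, seed = seed),
            class = "screen_sim_config")
}

# Ground-truth propensity for each protein variant in the database.
truth_propensity <- function(db, cfg) {
  pv <- db$protein_variants
  s <- numeric(nrow(pv))
  is_stop <- pv$substitution == STOP_CHAR
  s[pv$position %in% cfg$core_residues & !is_stop] <- cfg$s_core
  in_pro <- pv$substitution == "P" &
    pv$position >= cfg$proline_range[1L] & pv$position <= cfg$proline_range[2L]
  s[in_pro] <- cfg$s_core
  if (!is.null(cfg$enhancer_variants)) {
    key <- paste(pv$position, pv$substitution)
    ek <- paste(cfg$enhancer_variants$position,
                cfg$enhancer_variants$substitution)
    s[key %in% ek] <- cfg$s_enhancer
  }
  cls <- rep("neutral", nrow(pv))
  cls[s < 0] <- "inhibitory"
  cls[s > 0] <- "enhancer"
  cls[is_stop] <- "stop"
  data.frame(pv[, c("position", "wt_aa", "substitution")],
             s = s, is_stop = is_stop, class = cls,
             stringsAsFactors = FALSE)
}

#' Simulate a FRET-sorting saturation-mutagenesis screen
#'
#' Draws library allele frequencies from a Dirichlet prior, assigns cells to
#' alleles multinomially, sorts each cell by its variant's seeding
#' probability with sorter error, samples reads per pool and injects
#' per-base errors. Deterministic for a fixed seed.
#'
#' @param cfg a \code{screen_sim_config}.
#' @return Object of class \code{screen_sim}: \code{db} (the variant
#'   database), \code{reads} (list of gene-region read vectors:
#'   \code{input_library}, \code{fret_pos}, \code{fret_neg}), \code{truth}
#'   (per-variant data.frame with propensities, classes, true cell and read
#'   counts), \code{frac_pos} (positive-gate cell fraction), \code{config}.
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  db <- enumerate_nns(cfg$wt, cfg$mutable_range)
  cv <- db$codon_variants
  # library alleles at the nucleotide level: every NNS substitution whose
  # gene differs from the template, plus the wild-type template itself
  alleles <- cv[cv$gene_nt != db$wt$nt, , drop = FALSE]
  gene <- c(db$wt$nt, alleles$gene_nt)
  a_pos <- c(NA_integer_, alleles$position)
  a_prod <- c("WT", ifelse(alleles$is_synonymous, "WT", alleles$product))
  n_alleles <- length(gene)
  if (cfg$n_cells < n_alleles)
    warning("fewer cells than alleles; expect variant dropout")

  truth <- truth_propensity(db, cfg)
  tkey <- paste(truth$position, truth$substitution)
  s_allele <- ifelse(a_prod == "WT", 0,
                     truth$s[match(paste(a_pos, a_prod), tkey)])
  p_true <- stats::plogis(cfg$alpha + cfg$beta * s_allele)
  p_true[a_prod == STOP_CHAR] <- 0  # truncation removes the fluorophore
  eps <- cfg$sorter_error
  p_gate <- p_true * (1 - eps) + (1 - p_true) * eps

  with_seed(cfg$seed, {
    lib_freq <- stats::rgamma(n_alleles, shape = cfg$dirichlet_conc)
    lib_freq <- lib_freq / sum(lib_freq)
    cells <- as.vector(stats::rmultinom(1L, cfg$n_cells, lib_freq))
    cells_pos <- stats::rbinom(n_alleles, cells, p_gate)
    cells_neg <- cells - cells_pos
    frac_pos <- sum(cells_pos) / cfg$n_cells

    draw_pool <- function(weights) {
      if (sum(weights) == 0) return(character(0))
      counts <- as.vector(stats::rmultinom(1L, cfg$reads_per_pool,
                                           weights / sum(weights)))
      reads <- rep(gene, counts)
      inject_errors(reads, cfg$per_base_error)
    }
    reads <- list(input_library = draw_pool(cells),
                  fret_pos = draw_pool(cells_pos),
                  fret_neg = draw_pool(cells_neg))
  })

  # aggregate allele-level truth to protein level
  agg <- function(x) {
    out <- tapply(x, paste(a_pos, a_prod), sum)
    v <- out[tkey]
    ifelse(is.na(v), 0L, as.integer(v))
  }
  truth$cells <- agg(cells)
  truth$cells_pos <- agg(cells_pos)
  truth$cells_neg <- agg(cells_neg)
  truth$p_true <- stats::plogis(cfg$alpha + cfg$beta * truth$s)
  truth$p_true[truth$is_stop] <- 0
  wt_truth <- list(cells = sum(cells[a_prod == "WT"]),
                   cells_pos = sum(cells_pos[a_prod == "WT"]),
                   cells_neg = sum(cells_neg[a_prod == "WT"]))

  structure(list(db = db, reads = reads, truth = truth, wt_truth = wt_truth,
                 frac_pos = frac_pos, config = cfg),
            class = "screen_sim")
}

# Substitution sequencing errors: each base flips independently with rate e;
# implemented by first drawing which reads carry at least one error, then
# mutating Binomial(L, e)-conditioned positions within those reads.
inject_errors <- function(reads, e) {
  if (e <= 0 || length(reads) == 0L) return(reads)
  L <- nchar(reads[1L])
  n_err_bases <- stats::rbinom(length(reads), L, e)
  hit <- which(n_err_bases > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    r <- strsplit(reads[i], "")[[1L]]
    pos <- sample.int(L, n_err_bases[i])
    for (p in pos) r[p] <- sample(setdiff(bases, r[p]), 1L)
    reads[i] <- paste(r, collapse = "")
  }
  reads
}

#' @export
print.screen_sim <- function(x, ...) {
  cat(sprintf(paste0("screen_sim: %d alleles, %d cells (%.1f%% sorted ",
                     "positive), %d reads/pool\n"),
              nrow(x$db$codon_variants), x$config$n_cells,
              100 * x$frac_pos, x$config$reads_per_pool))
  invisible(x)
}

#' Write simulated pools as FASTQ with amplicon anchors
#'
#' Wraps each gene-region read in the constant 5'/3' anchors and emits one
#' FASTQ per pool (constant maximal quality; the pipeline ignores quality).
#'
#' @param sim a \code{screen_sim}.
#' @param dir output directory (created if needed).
#' @param anchors anchor pair as in \code{\link{default_anchors}}.
#' @param gz gzip-compress the FASTQ files (default FALSE).
#' @return Named vector of file paths.
#' @export
write_screen_fastq <- function(sim, dir, anchors = default_anchors(),
                               gz = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- c()
  for (pool in names(sim$reads)) {
    reads <- paste0(anchors[["five"]], sim$reads[[pool]], anchors[["three"]])
    path <- file.path(dir, paste0(pool, ".fastq", if (gz) ".gz" else ""))
    qual <- strrep("I", nchar(reads))
    con <- if (gz) gzfile(path, "w") else file(path, "w")
    writeLines(as.vector(rbind(paste0("@", pool, "_", seq_along(reads)),
                               reads, "+", qual)), con)
    close(con)
    out[pool] <- path
  }
  out
}

#' Simulate replicate cross-link identification tables
#'
#' True residue pairs appear in every replicate with filter-passing fields
#' and Poisson-distributed identification counts; decoys appear in random
#' strict subsets of the replicates and/or with a deliberately failing field
#' (boundary score, out-of-band mass error, short peptide, low TIC, or too
#' few fragments), so post-filter n-of-n consensus recovers exactly the
#' planted pairs.
#'
#' @param true_pairs data.frame (res_a, res_b); default 15 pairs emulating a
#'   compact N terminus plus long-range contacts to the core and C terminus.
#' @param n_replicates number of technical replicates (default 5).
#' @param n_decoys decoy identifications (default 50).
#' @param mean_count mean identifications per true pair per replicate
#'   (default 3).
#' @param protein_length chain length for decoy pair sampling (default 140).
#' @param seed RNG seed.
#' @return List: \code{ids} (one data.frame, all replicates), \code{truth}
#'   (the planted pairs with expected mean frequencies).
#' @export
simulate_xlms <- function(true_pairs = NULL, n_replicates = 5L,
                          n_decoys = 50L, mean_count = 3,
                          protein_length = 140L, seed = 0L) {
  if (is.null(true_pairs))
    true_pairs <- data.frame(
      res_a = c(3L, 5L, 6L, 10L, 12L, 13L, 17L, 21L, 21L, 24L, 32L,
                13L, 23L, 28L, 46L),
      res_b = c(13L, 21L, 24L, 20L, 23L, 32L, 28L, 30L, 34L, 33L, 35L,
                45L, 83L, 60L, 97L))
  stopifnot(all(true_pairs$res_a <= protein_length),
            all(true_pairs$res_b <= protein_length))
  aa_pool <- strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1L]]
  rand_pep <- function(n, len_min = 6L, len_max = 12L)
    vapply(sample(seq.int(len_min, len_max), n, replace = TRUE),
           function(l) paste(sample(aa_pool, l, replace = TRUE),
                             collapse = ""), character(1L))

  with_seed(seed, {
    rows <- list()
    truth_counts <- matrix(0L, nrow(true_pairs), n_replicates)
    for (r in seq_len(n_replicates)) {
      counts <- stats::rpois(nrow(true_pairs), mean_count - 1) + 1L
      truth_counts[, r] <- counts
      idx <- rep(seq_len(nrow(true_pairs)), counts)
      n <- length(idx)
      rows[[r]] <- data.frame(
        replicate = paste0("rep", r),
        pep_a = rand_pep(n), pep_b = rand_pep(n),
        res_a = true_pairs$res_a[idx], res_b = true_pairs$res_b[idx],
        score = stats::runif(n, 32, 60),
        mass_error = stats::runif(n, -1.5, 2.5),
        tic_pct = stats::runif(n, 12, 40),
        frags_a = sample(4:9, n, replace = TRUE),
        frags_b = sample(4:9, n, replace = TRUE),
        contig_a = sample(2:5, n, replace = TRUE),
        contig_b = sample(2:5, n, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    true_key <- paste(pmin(true_pairs$res_a, true_pairs$res_b),
                      pmax(true_pairs$res_a, true_pairs$res_b))
    decoys <- NULL
    while (is.null(decoys) || nrow(decoys) < n_decoys) {
      da <- sample.int(protein_length, n_decoys * 2L, replace = TRUE)
      db_ <- sample.int(protein_length, n_decoys * 2L, replace = TRUE)
      ok <- da != db_ &
        !paste(pmin(da, db_), pmax(da, db_)) %in% true_key
      decoys <- data.frame(res_a = da[ok], res_b = db_[ok])[
        seq_len(min(sum(ok), n_decoys)), ]
    }
    n <- nrow(decoys)
    fail_mode <- sample(c("subset", "score", "ppm", "pep", "tic", "frags"),
                        n, replace = TRUE)
    dec <- data.frame(
      replicate = paste0("rep", sample.int(n_replicates, n, replace = TRUE)),
      pep_a = rand_pep(n), pep_b = rand_pep(n),
      res_a = decoys$res_a, res_b = decoys$res_b,
      score = stats::runif(n, 32, 60),
      mass_error = stats::runif(n, -1.5, 2.5),
      tic_pct = stats::runif(n, 12, 40),
      frags_a = sample(4:9, n, replace = TRUE),
      frags_b = sample(4:9, n, replace = TRUE),
      contig_a = sample(3:5, n, replace = TRUE),
      contig_b = sample(3:5, n, replace = TRUE),
      stringsAsFactors = FALSE)
    dec$score[fail_mode == "score"] <- stats::runif(sum(fail_mode == "score"),
                                                    10, 30)
    dec$mass_error[fail_mode == "ppm"] <-
      sample(c(-4, 4.5), sum(fail_mode == "ppm"), replace = TRUE)
    dec$pep_a[fail_mode == "pep"] <- rand_pep(sum(fail_mode == "pep"), 3L, 5L)
    dec$tic_pct[fail_mode == "tic"] <- stats::runif(sum(fail_mode == "tic"),
                                                    1, 10)
    fr <- fail_mode == "frags"
    dec$frags_a[fr] <- 3L; dec$contig_a[fr] <- 2L
    ids <- rbind(do.call(rbind, rows), dec)
  })
  truth <- true_pairs
  truth$mean_freq <- rowSums(truth_counts) / n_replicates
  list(ids = ids, truth = truth)
}

#' Straight extended chain at fixed Calpha spacing
#'
#' @param n residues.
#' @param spacing Calpha-Calpha distance in angstrom (default 3.8).
#' @return n x 3 coordinate matrix along the x axis.
#' @export
extended_chain <- function(n, spacing = 3.8) {
  cbind(x = spacing * (seq_len(n) - 1L), y = 0, z = 0)
}

# Self-avoiding random walk with fixed bond length; clash distance 3.4 A.
random_chain <- function(n, spacing = 3.8, clash = 3.4, max_try = 200L) {
  xyz <- matrix(0, n, 3L)
  for (i in seq.int(2L, n)) {
    for (t in seq_len(max_try)) {
      u <- stats::rnorm(3L)
      u <- u / sqrt(sum(u^2))
      cand <- xyz[i - 1L, ] + spacing * u
      prev <- xyz[seq_len(max(1L, i - 2L)), , drop = FALSE]
      if (min(sqrt(rowSums(sweep(prev, 2L, cand)^2))) > clash) break
      if (t == max_try) cand <- xyz[i - 1L, ] + spacing * c(1, 0, 0)
    }
    xyz[i, ] <- cand
  }
  xyz
}

#' Simulate a multi-model conformational ensemble with planted clusters
#'
#' Builds \code{k} base conformers as self-avoiding random walks at 3.8
#' angstrom Calpha spacing, replicates each according to its occupancy and
#' adds isotropic Gaussian coordinate noise.
#'
#' @param k_conformers number of distinct conformations (default 4).
#' @param occupancies fractions summing to 1 (default 0.4/0.3/0.2/0.1).
#' @param n_models total models (default 100).
#' @param n_residues chain length (default 140).
#' @param noise coordinate noise SD in angstrom (default 0.2).
#' @param seed RNG seed.
#' @return List: \code{ensemble} (an \code{ensemble}), \code{truth}
#'   (per-model conformer index, occupancies, base conformers).
#' @export
simulate_ensemble <- function(k_conformers = 4L,
                              occupancies = c(0.4, 0.3, 0.2, 0.1),
                              n_models = 100L, n_residues = 140L,
                              noise = 0.2, seed = 0L) {
  stopifnot(length(occupancies) == k_conformers,
            abs(sum(occupancies) - 1) < 1e-8)
  with_seed(seed, {
    base <- lapply(seq_len(k_conformers), function(i)
      random_chain(n_residues))
    counts <- diff(round(cumsum(c(0, occupancies)) * n_models))
    assignment <- rep(seq_len(k_conformers), counts)
    models <- lapply(assignment, function(ci)
      base[[ci]] + matrix(stats::rnorm(n_residues * 3L, sd = noise),
                          n_residues, 3L))
  })
  list(ensemble = ensemble(models),
       truth = list(assignment = assignment,
                    occupancy = counts / n_models,
                    base = base))
}

#' Simulate paired HSQC peak lists with a localized perturbation
#'
#' Reference shifts are drawn from realistic amide ranges (1H 7.8-8.6 ppm,
#' 15N 108-130 ppm); the comparison list adds a small global jitter plus
#' localized offsets inside the perturbed region (1H offset = magnitude,
#' 15N offset = 5 x magnitude, random signs). Prolines are omitted.
#'
#' @param aa protein string (default alpha-synuclein).
#' @param perturbed_region \code{c(first, last)} (default 4..23).
#' @param magnitude 1H offset in ppm inside the region (default 0.05).
#' @param jitter global shift jitter SD in ppm (default 0.001).
#' @param n_low_confidence residues flagged low-confidence (drawn outside
#'   the perturbed region; default 12, leaving 123 of 135 aSyn residues
#'   high-confidence).
#' @param seed RNG seed.
#' @return List: \code{ref}, \code{cmp} (two \code{peak_list}s),
#'   \code{truth} (region and per-residue offsets).
#' @export
simulate_peaklists <- function(aa = asyn_cds()$aa,
                               perturbed_region = c(4L, 23L),
                               magnitude = 0.05, jitter = 0.001,
                               n_low_confidence = 12L, seed = 0L) {
  res <- strsplit(aa, "")[[1L]]
  keep <- which(res != "P")
  with_seed(seed, {
    dh <- stats::runif(length(keep), 7.8, 8.6)
    dn <- stats::runif(length(keep), 108, 130)
    in_reg <- keep >= perturbed_region[1L] & keep <= perturbed_region[2L]
    off_h <- ifelse(in_reg, magnitude * sample(c(-1, 1), length(keep),
                                               replace = TRUE), 0)
    off_n <- ifelse(in_reg, 5 * magnitude * sample(c(-1, 1), length(keep),
                                                   replace = TRUE), 0)
    jit_h <- stats::rnorm(length(keep), sd = jitter)
    jit_n <- stats::rnorm(length(keep), sd = jitter)
    conf <- rep("high", length(keep))
    low_pool <- which(!in_reg)
    if (n_low_confidence > 0L)
      conf[sample(low_pool, min(n_low_confidence, length(low_pool)))] <- "low"
  })
  ref <- peak_list("ref", data.frame(
    residue = keep, aa = res[keep], delta_h = dh, delta_n = dn,
    confidence = conf, stringsAsFactors = FALSE))
  cmp <- peak_list("mutant", data.frame(
    residue = keep, aa = res[keep],
    delta_h = dh + off_h + jit_h, delta_n = dn + off_n + jit_n,
    confidence = conf, stringsAsFactors = FALSE))
  list(ref = ref, cmp = cmp,
       truth = list(region = perturbed_region, off_h = off_h, off_n = off_n))
}
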