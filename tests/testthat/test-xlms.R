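base_id <- function(...) {
  row <- list(replicate = "rep1", pep_a = "AAAAAA", pep_b = "CCCCCCC",
              res_a = 5L, res_b = 20L, score = 40, mass_error = 0,
              tic_pct = 15, frags_a = 5L, frags_b = 5L,
              contig_a = 4L, contig_b = 4L)
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, stringsAsFactors = FALSE)
}

test_that("the post-search filter applies every criterion at its exact boundary", {
  keep <- base_id()
  expect_equal(nrow(filter_xlinks(keep)), 1L)
  expect_equal(nrow(filter_xlinks(base_id(score = 30))), 0L)       # strict >
  expect_equal(nrow(filter_xlinks(base_id(score = 30.01))), 1L)
  expect_equal(nrow(filter_xlinks(base_id(mass_error = -2.2))), 1L)  # inclusive
  expect_equal(nrow(filter_xlinks(base_id(mass_error = 3.8))), 1L)
  expect_equal(nrow(filter_xlinks(base_id(mass_error = -2.21))), 0L)
  expect_equal(nrow(filter_xlinks(base_id(mass_error = 3.81))), 0L)
  expect_equal(nrow(filter_xlinks(base_id(tic_pct = 10))), 0L)     # strict >
  expect_equal(nrow(filter_xlinks(base_id(pep_a = "AAAAA"))), 0L)  # len 5 < 6
  expect_equal(nrow(filter_xlinks(base_id(pep_a = "AAAAAA"))), 1L)
  # fragment rule: >= 4 assigned OR >= 3 contiguous, per peptide
  expect_equal(nrow(filter_xlinks(base_id(frags_a = 3L, contig_a = 3L))), 1L)
  expect_equal(nrow(filter_xlinks(base_id(frags_a = 3L, contig_a = 2L))), 0L)
  expect_equal(nrow(filter_xlinks(base_id(frags_b = 3L, contig_b = 2L))), 0L)
  expect_equal(nrow(filter_xlinks(base_id(frags_a = 4L, contig_a = 1L))), 1L)
})

test_that("filtering is idempotent, order-independent, and drops incomplete records", {
  set.seed(9)
  ids <- do.call(rbind, lapply(1:40, function(i)
    base_id(score = runif(1, 10, 60), mass_error = runif(1, -4, 5),
            tic_pct = runif(1, 5, 30))))
  f1 <- filter_xlinks(ids)
  expect_equal(filter_xlinks(f1), f1)
  perm <- sample.int(nrow(ids))
  f2 <- filter_xlinks(ids[perm, ])
  expect_equal(nrow(f2), nrow(f1))
  expect_setequal(f2$score, f1$score)
  incomplete <- base_id(); incomplete$score <- NA
  expect_message(out <- filter_xlinks(rbind(base_id(), incomplete)),
                 "missing fields")
  expect_equal(nrow(out), 1L)
})

test_that("consensus keeps only pairs in the required replicate count, with mean frequency", {
  ids <- rbind(
    do.call(rbind, lapply(1:5, function(r) {
      n <- c(3L, 2L, 4L, 3L, 3L)[r]
      do.call(rbind, replicate(n, base_id(replicate = paste0("rep", r),
                                          res_a = 13L, res_b = 45L),
                               simplify = FALSE))
    })),
    do.call(rbind, lapply(1:4, function(r)
      base_id(replicate = paste0("rep", r), res_a = 46L, res_b = 97L))))
  cons <- consensus_links(ids)
  expect_equal(cons$n_replicates, 5L)
  expect_equal(nrow(cons$pairs), 1L)            # 4-of-5 pair dropped
  expect_equal(cons$pairs$res_a, 13L)
  expect_equal(cons$pairs$freq, 3.0)            # mean of 3,2,4,3,3
  # unordered pair normalization
  flipped <- base_id(replicate = "rep1", res_a = 45L, res_b = 13L)
  cons2 <- consensus_links(rbind(ids, flipped))
  expect_equal(nrow(cons2$pairs), 1L)
  expect_equal(cons2$pairs$freq, 3.2)           # 16/5
  # lowering required only adds pairs (monotone)
  cons3 <- consensus_links(ids, required = 4L)
  expect_true(all(paste(cons$pairs$res_a, cons$pairs$res_b) %in%
                    paste(cons3$pairs$res_a, cons3$pairs$res_b)))
  expect_equal(nrow(cons3$pairs), 2L)
  expect_error(consensus_links(ids, required = 6L), "exceeds")
})

test_that("synthetic replicates recover exactly the planted consensus pairs", {
  xl <- simulate_xlms(seed = 0L)
  cons <- consensus_links(filter_xlinks(xl$ids))
  truth <- data.frame(res_a = pmin(xl$truth$res_a, xl$truth$res_b),
                      res_b = pmax(xl$truth$res_a, xl$truth$res_b),
                      freq = xl$truth$mean_freq)
  truth <- truth[order(truth$res_a, truth$res_b), ]
  rownames(truth) <- NULL
  expect_equal(cons$pairs, truth)
  # single replicate, required 1: consensus equals the filtered pair set
  one <- xl$ids[xl$ids$replicate == "rep1", ]
  c1 <- consensus_links(filter_xlinks(one), required = 1L)
  filt_pairs <- unique(with(filter_xlinks(one),
                            paste(pmin(res_a, res_b), pmax(res_a, res_b))))
  expect_setequal(paste(c1$pairs$res_a, c1$pairs$res_b), filt_pairs)
})

test_that("region link counts sum both-endpoint pairs by default", {
  pairs <- data.frame(res_a = c(5L, 10L, 13L), res_b = c(20L, 30L, 45L),
                      freq = c(2.0, 1.5, 3.0))
  map <- structure(list(pairs = pairs, n_replicates = 5L, required = 5L),
                   class = "consensus_link_map")
  expect_equal(as.numeric(region_link_count(map, c(1L, 35L))), 3.5)
  expect_equal(attr(region_link_count(map, c(1L, 35L)), "n_pairs"), 2L)
  expect_equal(as.numeric(region_link_count(map, c(1L, 35L), mode = "any")),
               6.5)
  expect_equal(as.numeric(region_link_count(map, c(1L, 140L))), 6.5)
  empty <- structure(list(pairs = pairs[0L, ], n_replicates = 5L,
                          required = 5L), class = "consensus_link_map")
  expect_equal(as.numeric(region_link_count(empty)), 0)
  expect_error(region_link_count(map, c(10L, 5L)), "empty region")
})

test_that("compatibility uses a strict Calpha distance cutoff", {
  chain <- extended_chain(140L)
  pairs <- data.frame(res_a = c(1L, 1L, 1L), res_b = c(5L, 10L, 2L),
                      freq = 1)
  map <- structure(list(pairs = pairs, n_replicates = 5L, required = 5L),
                   class = "consensus_link_map")
  comp <- xlink_compatibility(map, chain, cutoff = 30)
  expect_equal(comp$n_total, 3L)
  expect_equal(comp$distances$distance, c(4, 9, 1) * 3.8)
  expect_equal(comp$n_compatible, 2L)      # 15.2 and 3.8 yes; 34.2 no
  # exactly at the cutoff is NOT compatible
  at30 <- structure(list(pairs = data.frame(res_a = 1L, res_b = 2L, freq = 1),
                         n_replicates = 1L, required = 1L),
                    class = "consensus_link_map")
  m <- rbind(c(0, 0, 0), c(30, 0, 0))
  expect_equal(xlink_compatibility(at30, m, cutoff = 30)$n_compatible, 0L)
  # monotone non-decreasing in the cutoff
  n_by_cut <- vapply(c(5, 15.3, 34.3, 50), function(ct)
    xlink_compatibility(map, chain, cutoff = ct)$n_compatible, integer(1L))
  expect_true(all(diff(n_by_cut) >= 0L))
  # residues outside the model are dropped with a message
  out_map <- structure(list(pairs = data.frame(res_a = 1L, res_b = 999L,
                                               freq = 1),
                            n_replicates = 1L, required = 1L),
                       class = "consensus_link_map")
  expect_message(res <- xlink_compatibility(out_map, chain), "outside")
  expect_equal(res$n_total, 0L)
})

test_that("superposition RMSD is a proper rigid-motion residual", {
  set.seed(8)
  a <- matrix(rnorm(35 * 3), 35L, 3L)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
  b <- a %*% rot + matrix(rep(c(5, -3, 2), each = 35L), 35L, 3L)
  expect_lt(superpose_rmsd(a, b), 1e-10)          # rigid copy -> 0
  cset <- a + matrix(rnorm(35 * 3, sd = 0.5), 35L, 3L)
  expect_equal(superpose_rmsd(a, cset), superpose_rmsd(cset, a))  # symmetric
  expect_gt(superpose_rmsd(a, cset), 0)
  # independent oracle: bio3d least-squares fit gives the same residual
  fit <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(a)),
                                         mobile = as.vector(t(cset))))
  expect_equal(superpose_rmsd(a, cset),
               bio3d::rmsd(as.vector(t(a)), fit), tolerance = 1e-3)
})

test_that("k-medoids on planted ensembles recovers clusters and occupancies", {
  # two duplicated conformers, zero noise
  two <- simulate_ensemble(k_conformers = 2L, occupancies = c(0.5, 0.5),
                           n_models = 40L, n_residues = 60L, noise = 0,
                           seed = 2L)
  cl <- cluster_region(two$ensemble, region = c(1L, 35L), k = 2L)
  expect_equal(cl$occupancy, c(0.5, 0.5))
  within_rmsd <- as.matrix(cl$rmsd)
  for (g in 1:2) {
    members <- which(cl$labels == g)
    expect_lt(max(within_rmsd[members, members]), 1e-8)
  }
  expect_error(cluster_region(two$ensemble, k = 100L), "exceeds")
})

test_that("ensembles round-trip through multi-model PDB", {
  sim <- simulate_ensemble(k_conformers = 2L, occupancies = c(0.6, 0.4),
                           n_models = 5L, n_residues = 25L, noise = 0.1,
                           seed = 3L)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(sim$ensemble, path, aa = strrep("A", 25L))
  back <- read_ensemble_pdb(path)
  expect_equal(length(back$models), 5L)
  expect_equal(back$n_residues, 25L)
  for (i in 1:5)
    expect_equal(unname(back$models[[i]]), unname(sim$ensemble$models[[i]]),
                 tolerance = 1e-3)  # PDB fixed-width 3-decimal coordinates
})

test_that("cross-link tables round-trip and the reader validates headers", {
  ids <- rbind(base_id(), base_id(res_a = 7L, res_b = 30L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_xlinks_tsv(ids, path)
  back <- read_xlinks_tsv(path)
  expect_equal(back, ids, ignore_attr = TRUE)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("res_a\tres_b\n1\t2", bad)
  expect_error(read_xlinks_tsv(bad), "lacks column")
})
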