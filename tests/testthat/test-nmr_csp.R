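make_pl <- function(label, residue, dh, dn, conf = "high",
                    aa = rep("A", length(residue))) {
  peak_list(label, data.frame(residue = residue, aa = aa, delta_h = dh,
                              delta_n = dn,
                              confidence = rep(conf, length.out =
                                                 length(residue)),
                              stringsAsFactors = FALSE))
}

test_that("CSP follows the amide-scaled combined-shift formula", {
  ref <- make_pl("ref", 1:3, c(8.0, 8.1, 8.2), c(115, 120, 125))
  mut <- make_pl("mut", 1:3, c(8.0, 8.1 - 0.03, 8.2), c(115, 120 - 0.10, 124.5))
  prof <- csp_profile(ref, mut)
  expect_equal(prof$profile$csp[1L], 0)
  expect_equal(prof$profile$csp[2L], sqrt(0.03^2 + 0.02^2))  # 0.036056 ppm
  expect_equal(prof$profile$csp[3L], 0.1)   # 15N-only shift, scale factor 5
  expect_equal(prof$profile$delta_h[2L], 0.03)  # signed, reference minus mutant
  expect_equal(prof$profile$delta_n[3L], 0.5)
  # identical lists
  same <- csp_profile(ref, ref)
  expect_true(all(same$profile$csp == 0))
  expect_equal(same$mean_csp, 0)
})

test_that("CSP is invariant to swapping the reference, and scales linearly", {
  set.seed(13)
  n <- 20L
  ref <- make_pl("a", 1:n, runif(n, 7.8, 8.6), runif(n, 108, 130))
  mut <- make_pl("b", 1:n, ref$peaks$delta_h + rnorm(n, sd = 0.02),
                 ref$peaks$delta_n + rnorm(n, sd = 0.1))
  fwd <- csp_profile(ref, mut)
  rev <- csp_profile(mut, ref)
  expect_equal(fwd$profile$csp, rev$profile$csp)
  expect_equal(fwd$profile$delta_h, -rev$profile$delta_h)
  expect_equal(fwd$mean_csp, rev$mean_csp)
  # uniform 3x scaling of both shift differences scales CSP 3x
  mut3 <- make_pl("b3", 1:n,
                  ref$peaks$delta_h + 3 * (mut$peaks$delta_h -
                                             ref$peaks$delta_h),
                  ref$peaks$delta_n + 3 * (mut$peaks$delta_n -
                                             ref$peaks$delta_n))
  expect_equal(csp_profile(ref, mut3)$profile$csp, 3 * fwd$profile$csp)
  # mean equals brute force over included residues
  expect_equal(fwd$mean_csp,
               mean(fwd$profile$csp[fwd$profile$high_confidence]))
})

test_that("residues missing from either list or low-confidence are handled", {
  ref <- make_pl("ref", 1:10, rep(8, 10L), rep(120, 10L),
                 conf = c(rep("high", 8L), "low", "high"))
  mut <- make_pl("mut", 3:12, rep(8.05, 10L), rep(120, 10L))
  prof <- csp_profile(ref, mut)
  expect_equal(prof$profile$residue, 3:10)     # intersection only
  expect_false(prof$profile$high_confidence[prof$profile$residue == 9L])
  expect_equal(prof$mean_csp, 0.05)            # low-confidence excluded
  disjoint <- make_pl("x", 50:60, rep(8, 11L), rep(120, 11L))
  expect_error(csp_profile(ref, disjoint), "no residues")
  expect_error(peak_list("p", data.frame(residue = c(1L, 1L), aa = "A",
                                         delta_h = 8, delta_n = 120,
                                         confidence = "high")),
               "duplicate")
  expect_error(peak_list("p", data.frame(residue = 1L, aa = "P",
                                         delta_h = 8, delta_n = 120,
                                         confidence = "high")),
               "proline")
})

test_that("perturbed-region calling thresholds at mean + k SD and merges runs", {
  flat <- make_pl("ref", 1:30, rep(8, 30L), rep(120, 30L))
  bump <- flat$peaks
  bump$delta_h[10:15] <- bump$delta_h[10:15] + 0.5
  prof <- csp_profile(flat, make_pl("mut", 1:30, bump$delta_h, bump$delta_n))
  reg <- call_perturbed(prof)
  expect_equal(unname(reg), matrix(c(10L, 15L), 1L))
  # flat profile: no intervals
  jitter <- make_pl("mut", 1:30, flat$peaks$delta_h + rnorm(30L, sd = 1e-4),
                    flat$peaks$delta_n)
  set.seed(1)
  flat_prof <- csp_profile(flat, jitter)
  expect_true(nrow(call_perturbed(flat_prof, k_sd = 3)) %in% c(0L, 1L))
  # single elevated residue
  one <- flat$peaks; one$delta_h[7L] <- one$delta_h[7L] + 0.5
  prof1 <- csp_profile(flat, make_pl("mut", 1:30, one$delta_h, one$delta_n))
  expect_equal(unname(call_perturbed(prof1)), matrix(c(7L, 7L), 1L))
  # single-residue gaps (e.g. prolines) are bridged
  gap <- flat$peaks[-12L, ]
  gp_ref <- make_pl("ref", gap$residue, gap$delta_h, gap$delta_n)
  gp_mut_shift <- gap$delta_h + ifelse(gap$residue %in% 10:15, 0.5, 0)
  gp_mut <- make_pl("mut", gap$residue, gp_mut_shift, gap$delta_n)
  expect_equal(unname(call_perturbed(csp_profile(gp_ref, gp_mut))),
               matrix(c(10L, 15L), 1L))
  expect_error(call_perturbed(csp_profile(make_pl("a", 1:3, rep(8, 3),
                                                  rep(120, 3)),
                                          make_pl("b", 1:3, rep(8, 3),
                                                  rep(120, 3)))),
               "too few")
})

test_that("synthetic peak lists recover the planted perturbed region", {
  sim <- simulate_peaklists(seed = 4L)
  prof <- csp_profile(sim$ref, sim$cmp)
  expect_equal(nrow(prof$profile), 135L)   # aSyn: 135 non-proline residues
  reg <- call_perturbed(prof)
  expect_equal(unname(reg), matrix(c(4L, 23L), 1L))
  # zero magnitude: mean CSP sits at the jitter floor
  null <- simulate_peaklists(magnitude = 0, jitter = 0.001, seed = 4L)
  null_prof <- csp_profile(null$ref, null$cmp)
  expect_lt(null_prof$mean_csp, 0.005)
  # peak lists round-trip through TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peaklist(sim$ref, path)
  back <- read_peaklist(path, label = "ref")
  expect_equal(back$peaks, sim$ref$peaks, ignore_attr = TRUE)
})
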