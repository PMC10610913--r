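test_that("relative enrichment matches the closed form", {
  expect_equal(relative_enrichment(0.002, 0.001, 0.01, 0.01), log10(2))
  # identical sel/input ratio to WT
  expect_equal(relative_enrichment(0.004, 0.002, 0.02, 0.01), 0)
  expect_equal(relative_enrichment(0.0001, 0.001, 0.01, 0.01), -1)
  # zero variant frequency -> NA, no pseudocount
  expect_true(is.na(relative_enrichment(0, 0.001, 0.01, 0.01)))
  expect_error(relative_enrichment(0.1, 0.1, 0, 0.01), "wild-type")
})

test_that("RE is antisymmetric under swapping variant and reference", {
  # two-allele pools: RE of A vs WT equals minus RE of WT vs A
  f <- list(a_sel = 0.3, a_in = 0.5, wt_sel = 0.7, wt_in = 0.5)
  re_a <- relative_enrichment(f$a_sel, f$a_in, f$wt_sel, f$wt_in)
  re_wt <- relative_enrichment(f$wt_sel, f$wt_in, f$a_sel, f$a_in)
  expect_equal(re_a, -re_wt)
})

test_that("RE is invariant to sequencing depth per pool", {
  db <- toy_db()
  sel <- make_counts(db, wt = 100L, "K@2" = 20L, "W@3" = 40L, pool = "sel")
  inp <- make_counts(db, wt = 200L, "K@2" = 80L, "W@3" = 80L, pool = "in")
  sel10 <- make_counts(db, wt = 1000L, "K@2" = 200L, "W@3" = 400L,
                       pool = "sel")
  r1 <- enrichment_records(sel, inp, db, min_input_count = 1L)
  r2 <- enrichment_records(sel10, inp, db, min_input_count = 1L)
  expect_equal(r1$re[r1$status == "scored"], r2$re[r2$status == "scored"])
  # and invariant to pool-specific junk (unmatched) reads
  sel_junk <- make_counts(db, wt = 100L, unmatched = 500L, "K@2" = 20L,
                          "W@3" = 40L, pool = "sel")
  r3 <- enrichment_records(sel_junk, inp, db, min_input_count = 1L)
  expect_equal(r3$re[r3$status == "scored"], r1$re[r1$status == "scored"])
})

test_that("scoring status distinguishes low-count and absent variants", {
  db <- toy_db()
  sel <- make_counts(db, wt = 100L, "K@2" = 12L, "D@2" = 5L, "W@3" = 2L)
  inp <- make_counts(db, wt = 100L, "K@2" = 12L, "D@2" = 3L, "W@3" = 15L)
  rec <- enrichment_records(sel, inp, db, min_input_count = 10L)
  get <- function(p, s, col)
    rec[[col]][rec$position == p & rec$substitution == s]
  expect_equal(get(2L, "K", "status"), "scored")
  expect_false(is.na(get(2L, "K", "re")))
  expect_equal(get(2L, "D", "status"), "missing_low_count")  # input 3 < 10
  expect_equal(get(3L, "W", "status"), "scored")
  expect_equal(get(2L, "W", "status"), "missing_absent")
  expect_equal(get(3L, "Y", "status"), "missing_absent")     # never seen
  expect_true(all(is.na(rec$re[rec$status != "scored"])))
})

test_that("the enrichment matrix has the fixed row order and flags WT cells", {
  db <- toy_db()
  sel <- make_counts(db, wt = 100L, "K@2" = 12L)
  inp <- make_counts(db, wt = 100L, "K@2" = 12L)
  rec <- enrichment_records(sel, inp, db, min_input_count = 10L)
  mat <- build_matrix(rec, db)
  expect_equal(rownames(mat$values),
               c("R", "H", "K", "D", "E", "S", "T", "N", "Q", "C",
                 "G", "P", "A", "V", "I", "L", "M", "F", "Y", "W"))
  expect_equal(mat$mask["E", "2"], "wt")   # toy protein is M-E-A-Y
  expect_equal(mat$mask["A", "3"], "wt")
  expect_equal(mat$mask["K", "2"], "scored")
  expect_equal(mat$values["K", "2"], 0)    # same ratio as WT
  expect_true(all(is.na(mat$values[mat$mask != "scored"])))
  # stops live outside the 20-row display matrix
  expect_false(STOP_CHAR %in% rownames(mat$values))
  expect_equal(names(mat$stop_re), c("2", "3", "4"))
  dup <- rbind(rec, rec[1L, ])
  expect_error(build_matrix(dup, db), "duplicate")
})

test_that("the matrix round-trips losslessly through TSV", {
  db <- toy_db()
  sel <- make_counts(db, wt = 100L, "K@2" = 30L, "D@2" = 5L, "*@3" = 20L)
  inp <- make_counts(db, wt = 90L, "K@2" = 15L, "D@2" = 3L, "*@3" = 25L)
  rec <- enrichment_records(sel, inp, db, min_input_count = 10L)
  mat <- build_matrix(rec, db)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_heatmap_table(mat, path)
  back <- read_matrix_tsv(path)
  expect_equal(back$values, mat$values)
  expect_equal(back$mask, mat$mask)
  expect_equal(back$positions, mat$positions)
  expect_equal(back$stop_re, mat$stop_re)
  expect_equal(back$wt_aa, mat$wt_aa)
  # header sentinels in heatmap layout
  lines <- readLines(path)
  expect_match(lines[2L], "^R\t")
  expect_match(lines[21L], "^W\t")
  expect_true(grepl("\tWT", paste(lines[1:21], collapse = "\n")))
})

test_that("stop-codon FDR counts positive-RE stops / calibrates gate leakage", {
  db <- toy_db()
  rec <- data.frame(position = c(2L, 2L, 3L, 4L), wt_aa = "X",
                    substitution = STOP_CHAR,
                    count_sel = 1L, count_in = 20L,
                    f_sel = 0.01, f_in = 0.01,
                    re = c(-2, -1, 0.3, -0.5), status = "scored")
  expect_equal(as.numeric(stop_codon_fdr(rec)), 0.25)
  rec0 <- transform(rec, re = c(-2.1, -1.5, -0.8, -0.4))
  expect_equal(as.numeric(stop_codon_fdr(rec0)), 0)
  # gate leakage: stop enrichment ratio x positive-gate fraction
  rec2 <- transform(rec, f_sel = c(0.002, 0.001, 0.001, 0.0),
                    f_in = c(0.01, 0.01, 0.01, 0.01))
  est <- stop_codon_fdr(rec2, "gate_leakage", frac_pos = 0.30)
  expect_equal(as.numeric(est), (0.004 / 0.04) * 0.30)
  expect_error(stop_codon_fdr(rec2, "gate_leakage"), "frac_pos")
  none <- rec[0L, ]
  expect_error(stop_codon_fdr(none), "no scored stop")
})
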