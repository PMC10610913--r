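# Shared fixtures: built once per test run, in code.

.fixture_env <- new.env(parent = emptyenv())

# aSyn variant database (enumeration is deterministic; cache it)
asyn_db <- function() {
  if (is.null(.fixture_env$db))
    .fixture_env$db <- enumerate_nns(asyn_cds())
  .fixture_env$db
}

# a small 4-codon gene (M-E-A-Y) for counting tests
toy_cds <- function() coding_sequence("toy4", "ATGGAAGCTTAC")

toy_db <- function() {
  if (is.null(.fixture_env$toy))
    .fixture_env$toy <- enumerate_nns(toy_cds())
  .fixture_env$toy
}

# build a count_table directly from a named count spec, e.g.
# make_counts(toy_db(), wt = 50, unmatched = 2, "K@2" = 10)
make_counts <- function(db, wt = 0L, unmatched = 0L, ...,
                        pool = "pool") {
  spec <- c(...)
  pv <- db$protein_variants
  counts <- data.frame(position = pv$position,
                       substitution = pv$substitution,
                       count = 0L, stringsAsFactors = FALSE)
  for (k in names(spec)) {
    parts <- strsplit(k, "@")[[1L]]
    i <- which(counts$substitution == parts[1L] &
                 counts$position == as.integer(parts[2L]))
    stopifnot(length(i) == 1L)
    counts$count[i] <- as.integer(spec[[k]])
  }
  structure(list(pool_label = pool, counts = counts, wt_count = as.integer(wt),
                 unmatched = as.integer(unmatched),
                 total = as.integer(wt + unmatched + sum(counts$count))),
            class = "count_table")
}

# gene string for a given codon variant of a db
gene_for <- function(db, position, codon) {
  nt <- db$wt$nt
  paste0(substr(nt, 1L, (position - 1L) * 3L), codon,
         substr(nt, position * 3L + 1L, nchar(nt)))
}

# exhaustive between-class-variance threshold search (oracle for Otsu):
# evaluates every midpoint between consecutive sorted unique values
otsu_bruteforce <- function(values) {
  u <- sort(unique(values))
  cuts <- (u[-1L] + u[-length(u)]) / 2
  score <- vapply(cuts, function(t) {
    lo <- values[values <= t]; hi <- values[values > t]
    w0 <- length(lo) / length(values)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }, numeric(1L))
  cuts[which.max(score)]
}
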