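test_that("pattern TSV parses, validates and collapses duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tregion_id\tpattern\tcount",
               "S1\ttoy\t0101\t12",
               "S1\ttoy\t0101\t3",
               "S1\ttoy\t1111\t5"), path)
  reads <- read_pattern_tsv(path, region_panel(list(toy_region)))
  expect_equal(nrow(reads), 2L)
  expect_equal(reads$count[reads$pattern == "0101"], 15L)

  writeLines(c("sample_id\tregion_id\tpattern\tcount", "S1\ttoy\t012\t1"),
             path)
  expect_error(read_pattern_tsv(path), "only characters 0 and 1")
  writeLines(c("sample_id\tregion_id\tpattern\tcount", "S1\ttoy\t011\t1"),
             path)
  expect_error(read_pattern_tsv(path, region_panel(list(toy_region))),
               "length mismatch")
})

test_that("pattern table round-trips through TSV with identical counts", {
  reads <- simulate_reads(fix_normal, fix_panel$regions[[1]], 500, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pattern_tsv(reads, path)
  back <- read_pattern_tsv(path, fix_panel)
  ord <- function(d) d[order(d$pattern), c("sample_id", "region_id",
                                           "pattern", "count")]
  expect_equal(ord(back), ord(reads), ignore_attr = TRUE)
})

test_that("per-read calls map to patterns only when coverage is complete", {
  panel <- region_panel(list(toy_region))
  calls <- data.frame(
    read_id = rep(c("r1", "r2", "r3"), c(4, 3, 1)),
    state = c("+", "-", "+", "-",   # full coverage -> 1010
              "+", "+", "+",        # 3 of 4 CpGs -> discarded
              "Z"),                 # off-panel position
    chrom = "chr1",
    position = c(100, 110, 120, 130, 100, 110, 120, 999))
  out <- from_bismark_calls(calls, panel, sample_id = "S1")
  expect_equal(out$pattern, "1010")
  expect_equal(attr(out, "tallies"),
               c(assigned = 1L, partial = 1L, unassigned = 1L))
  calls$state[1] <- "?"
  expect_error(from_bismark_calls(calls, panel), "state symbol")
})

test_that("depth bookkeeping matches the simulator's emitted reads", {
  s <- simulate_sample(fix_normal, fix_aberrant, fix_panel, fraction = 0.3,
                       reads_per_region = 120, sample_id = "S1", seed = 4)
  d <- read_depths(s, fix_panel)
  expect_equal(unname(unlist(d[1, names(fix_panel$regions)])),
               rep(120, 4))
})

test_that("QC excludes a sample iff any amplicon is below 50 reads", {
  mk_sample <- function(sid, depths) {
    do.call(rbind, Map(function(r, n)
      if (n > 0) toy_reads(strrep("0", n_cpgs(r)), n, sid, r$region_id),
      fix_panel$regions, depths))
  }
  reads <- rbind(mk_sample("ok", c(60, 80, 50, 51)),
                 mk_sample("low", c(60, 80, 49, 1000)),
                 mk_sample("empty_region", c(60, 80, 0, 51)))
  qc <- qc_filter(reads, fix_panel)
  expect_equal(sort(qc$excluded_samples), c("empty_region", "low"))
  expect_equal(unique(qc$kept$sample_id), "ok")
  # conservation: kept + excluded = input
  expect_equal(sum(qc$kept$count) + sum(qc$excluded$count),
               sum(reads$count))
})

test_that("control split is a 7:3 sample-level partition, deterministic
           under a seed", {
  ids <- paste0("S", 1:10)
  sp <- split_controls(ids, seed = 1)
  expect_length(sp$train, 7L)
  expect_length(sp$validation, 3L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_setequal(c(sp$train, sp$validation), ids)
  expect_identical(split_controls(ids, seed = 1), sp)
  expect_length(split_controls(paste0("S", 1:3), seed = 2)$train, 2L)
})
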