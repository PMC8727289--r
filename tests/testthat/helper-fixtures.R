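# Shared fixtures for the test suite. Everything is generated in code under
# fixed seeds; the expensive trained-model fixture is built once per run.

fix_panel <- default_panel()
fix_normal <- clone_profile(fix_panel, "normal")          # epsilon 0.02
fix_aberrant <- clone_profile(fix_panel, "aberrant")
fix_normal0 <- clone_profile(fix_panel, "normal", epsilon = 0)   # separable
fix_aberrant0 <- clone_profile(fix_panel, "aberrant", epsilon = 0)

toy_region <- amplicon_region("toy", "cgTOY", "chr1",
                              cpg_positions = c(100, 110, 120, 130),
                              target_index = 1, direction = "hyper_in_aml")

toy_reads <- function(patterns, counts, sample_id = "S1",
                      region_id = "toy") {
  data.frame(sample_id = sample_id, region_id = region_id,
             pattern = patterns, count = as.integer(counts),
             stringsAsFactors = FALSE)
}

# BA-seq study cohort: 62 controls and 48 first-diagnosis samples at 300
# reads per amplicon, mirroring the study layout at desk scale. Cached:
# building it trains all four methods once for the whole suite.
.fixture_cache <- new.env(parent = emptyenv())

fitted_fixture <- function() {
  if (is.null(.fixture_cache$fitted)) {
    ctrl <- simulate_cohort(fix_normal, fix_aberrant, fix_panel,
                            n_samples = 62L, fraction = 0,
                            reads_per_region = 300L, prefix = "ctrl",
                            seed = 101L)
    aml <- simulate_cohort(fix_normal, fix_aberrant, fix_panel,
                           n_samples = 48L, fraction = 1,
                           reads_per_region = 300L, prefix = "dx",
                           seed = 202L)
    .fixture_cache$ctrl <- ctrl
    .fixture_cache$aml <- aml
    .fixture_cache$fitted <- train_all_methods(ctrl, aml, fix_panel,
                                               seed = 1L)
  }
  .fixture_cache
}

# linear-interpolation percentile oracle, independent of stats::quantile
percentile_oracle <- function(x, p) {
  x <- sort(x)
  h <- 1 + (p / 100) * (length(x) - 1)
  lo <- floor(h); hi <- ceiling(h)
  unname(x[lo] + (h - lo) * (x[hi] - x[lo]))
}
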