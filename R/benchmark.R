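#' Pooled sensitivity from per-study positive counts
#'
#' Pools positives and totals across studies and returns the percentage of
#' positive calls, e.g. the fraction of AML samples scoring above the
#' AML-score cutoff across several array cohorts.
#'
#' @param positives integer vector of positive counts per study
#' @param totals integer vector of study sizes
#' @return sensitivity in percent
#' @export
pooled_sensitivity <- function(positives, totals) {
  stopifnot(length(positives) == length(totals), all(positives <= totals))
  100 * sum(positives) / sum(totals)
}

#' Train all four detection methods on a shared training split
#'
#' Controls are split 7:3 into training and validation at the sample level;
#' the random forest trains on control-training plus AML-diagnosis reads,
#' both autoencoder variants (with k-means clustering, and without) on
#' control-training reads only. Each anomaly method gets a cutoff at the
#' 99th percentile of the control-training anomaly scores; the AML-score
#' keeps its fixed cutoff.
#'
#' @param control_reads pattern data frame of control samples
#' @param aml_reads pattern data frame of AML first-diagnosis samples
#' @param panel a `region_panel`
#' @param seed integer seed (split and all model training)
#' @param aml_score_cutoff AML-score cutoff (default 0.125)
#' @param k autoencoder cluster count (default 5)
#' @param epochs autoencoder training epochs (default 2000)
#' @param aml_flagged optional character vector of diagnosis sample ids to
#'   restrict forest training to (e.g. NPM1-mutated samples); `NULL` uses
#'   all diagnosis samples
#' @return object of class `mrd_models`: per-method models, cutoffs, and
#'   the control split
#' @export
train_all_methods <- function(control_reads, aml_reads,
                              panel = default_panel(), seed = 1L,
                              aml_score_cutoff = 0.125, k = 5L,
                              epochs = 2000L, aml_flagged = NULL) {
  split <- split_controls(unique(control_reads$sample_id), seed = seed)
  train_reads <- control_reads[control_reads$sample_id %in% split$train, ]
  rf_aml <- if (is.null(aml_flagged)) aml_reads
    else aml_reads[aml_reads$sample_id %in% aml_flagged, ]

  models <- list(
    rf = train_rf_model(train_reads, rf_aml, panel, seed = seed),
    ae = train_ae_model(train_reads, panel, k = 1L, epochs = epochs,
                        seed = seed),
    ae_cluster = train_ae_model(train_reads, panel, k = k,
                                epochs = epochs, seed = seed))

  train_scores <- lapply(models, function(m)
    vapply(split$train, function(s)
      anomaly_result(m, train_reads[train_reads$sample_id == s, ])$score,
      numeric(1)))
  cutoffs <- c(aml_score = aml_score_cutoff,
               vapply(train_scores, calibrate_anomaly_cutoff, numeric(1)))

  structure(list(models = models, cutoffs = cutoffs, split = split,
                 panel = panel, seed = seed,
                 train_scores = train_scores),
            class = "mrd_models")
}

#' Score one sample with all four methods
#'
#' @param fitted an `mrd_models` object from [train_all_methods()]
#' @param reads pattern data frame of one sample
#' @return data frame with one row per method: `sample_id`, `method`,
#'   `score`, `cutoff`, `call`
#' @export
score_sample_all <- function(fitted, reads) {
  sid <- unique(reads$sample_id)[1]
  rows <- list(data.frame(
    sample_id = sid, method = "aml_score",
    score = aml_score_sample(reads, fitted$panel,
                             cutoff = fitted$cutoffs[["aml_score"]])$score,
    stringsAsFactors = FALSE))
  for (m in names(fitted$models))
    rows[[m]] <- data.frame(
      sample_id = sid, method = m,
      score = anomaly_result(fitted$models[[m]], reads)$score,
      stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$cutoff <- unname(fitted$cutoffs[out$method])
  out$call <- ifelse(out$score > out$cutoff, "positive", "negative")
  rownames(out) <- NULL
  out
}

#' Benchmark all methods against ground-truth labels
#'
#' Scores every sample with the four methods (AML-score, random forest,
#' autoencoder without and with clustering) under one shared training
#' split, and tabulates a per-method confusion matrix against the truth
#' labels when provided.
#'
#' @param fitted an `mrd_models` object
#' @param test_reads pattern data frame of the samples to score
#' @param truth optional named character vector sample_id -> `"normal"` /
#'   `"abnormal"`
#' @return list with `scores` (long data frame) and `confusion` (list of
#'   per-method 2x2 tables; `NULL` without truth)
#' @export
run_benchmark <- function(fitted, test_reads, truth = NULL) {
  scores <- do.call(rbind, lapply(
    split(test_reads, test_reads$sample_id),
    function(rr) score_sample_all(fitted, rr)))
  rownames(scores) <- NULL
  confusion <- NULL
  if (!is.null(truth)) {
    confusion <- lapply(split(scores, scores$method), function(sc) {
      pred <- factor(ifelse(sc$call == "positive", "abnormal", "normal"),
                     levels = c("normal", "abnormal"))
      tr <- factor(truth[sc$sample_id], levels = c("normal", "abnormal"))
      table(truth = tr, predicted = pred)
    })
  }
  list(scores = scores, confusion = confusion)
}

#' Limiting-dilution sensitivity evaluation
#'
#' Repeats an in-silico dilution series over several seeds, scores every
#' sample with all four methods, and reports for each method the smallest
#' aberrant fraction at which the call is positive in at least
#' `detect_rate` of the seeds.
#'
#' @param fitted an `mrd_models` object
#' @param normal,aberrant `clone_profile`s used for the dilution samples
#' @param design a [dilution_design()] (its seed is combined with each
#'   replicate index)
#' @param n_seeds number of replicate series (default 10)
#' @param detect_rate required detection rate (default 0.95)
#' @return list with `table` (long data frame: seed, fraction, method,
#'   score, call) and `detection_limit` (named numeric vector per method)
#' @export
run_dilution_eval <- function(fitted, normal, aberrant,
                              design = dilution_design(),
                              n_seeds = 10L, detect_rate = 0.95) {
  rows <- list()
  for (s in seq_len(n_seeds)) {
    d <- design
    d$seed <- mix_seed(design$seed, s)
    series <- simulate_dilution(normal, aberrant, d, fitted$panel)
    for (i in seq_along(series)) {
      sc <- score_sample_all(fitted, series[[i]])
      sc$fraction <- attr(series[[i]], "nominal_fraction")
      sc$seed_rep <- s
      rows[[length(rows) + 1L]] <- sc
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  limit <- vapply(unique(tab$method), function(m) {
    sub <- tab[tab$method == m, ]
    rate <- tapply(sub$call == "positive", sub$fraction, mean)
    f <- as.numeric(names(rate))[rate >= detect_rate & as.numeric(names(rate)) > 0]
    if (length(f) == 0L) NA_real_ else min(f)
  }, numeric(1))
  list(table = tab, detection_limit = limit)
}

# deterministic 31-bit seed mixer, keeps derived seeds valid R integers
mix_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(salt) * 104729) %%
               2147483647)
}
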