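#' Train a per-region random forest for read-level anomaly detection
#'
#' Supervised setup: every read of the control training samples is labeled
#' `normal` and every read of the AML first-diagnosis samples `abnormal`
#' (diagnosis samples contain normal reads too — this deliberate label noise
#' is part of the design). Features are the region's CpG bit columns; trees
#' are depth-limited to 5. Pattern counts enter as case weights, rescaled so
#' both classes carry equal total weight.
#'
#' @param control_reads pattern data frame of control training reads for one
#'   region
#' @param aml_reads pattern data frame of AML diagnosis reads for the same
#'   region
#' @param region the `amplicon_region`
#' @param n_trees number of trees (default 100)
#' @param max_depth maximal tree depth (default 5)
#' @param seed integer seed; training is deterministic under a fixed seed
#' @return object of class `rf_region_model`
#' @export
train_forest <- function(control_reads, aml_reads, region,
                         n_trees = 100L, max_depth = 5L, seed = 1L) {
  if (nrow(control_reads) == 0L || nrow(aml_reads) == 0L)
    stop("both normal and abnormal training reads are required for region '",
         region$region_id, "'")
  n <- n_cpgs(region)
  x <- rbind(pattern_bits(control_reads$pattern, n),
             pattern_bits(aml_reads$pattern, n))
  y <- factor(rep(c("normal", "abnormal"),
                  c(nrow(control_reads), nrow(aml_reads))),
              levels = c("normal", "abnormal"))
  counts <- c(control_reads$count, aml_reads$count)
  # class-balanced case weights: each class sums to 1
  w <- counts / ave(counts, y, FUN = sum)
  df <- data.frame(x)
  names(df) <- paste0("cpg", seq_len(n))
  fit <- ranger::ranger(
    y = y, x = df, num.trees = n_trees, max.depth = max_depth,
    case.weights = w, seed = seed, num.threads = 1L,
    classification = TRUE, verbose = FALSE)
  structure(list(region_id = region$region_id, n_cpgs = n,
                 n_trees = n_trees, max_depth = max_depth, seed = seed,
                 fit = fit),
            class = "rf_region_model")
}

#' Classify one region's reads with a trained forest
#'
#' @param model an `rf_region_model`
#' @param reads pattern data frame for the model's region
#' @return character vector (`"normal"`/`"abnormal"`) per pattern row
#' @export
classify_reads_rf <- function(model, reads) {
  df <- data.frame(pattern_bits(reads$pattern, model$n_cpgs))
  names(df) <- paste0("cpg", seq_len(model$n_cpgs))
  as.character(stats::predict(model$fit, data = df,
                              num.threads = 1L)$predictions)
}

#' Count-weighted anomaly ratio of one sample's region reads
#'
#' @param labels character vector of per-pattern classifications
#' @param counts integer pattern multiplicities
#' @return fraction of reads classified abnormal, in \[0,1\]; `NA` when no
#'   reads are present (region marked missing)
#' @export
anomaly_ratio <- function(labels, counts) {
  if (length(labels) == 0L || sum(counts) == 0L) return(NA_real_)
  sum(counts[labels == "abnormal"]) / sum(counts)
}

#' Sample-level anomaly score
#'
#' The mean of the available per-region anomaly ratios; regions without
#' reads (`NA` ratios, e.g. QC-failed) contribute nothing and raise a
#' warning.
#'
#' @param ratios named numeric vector of per-region anomaly ratios
#' @return the score in \[0,1\]
#' @export
anomaly_score <- function(ratios) {
  ok <- !is.na(ratios)
  if (!any(ok)) stop("no region ratios available; score undefined")
  if (!all(ok))
    warning("score from ", sum(ok), " of ", length(ratios),
            " regions (missing: ",
            paste(names(ratios)[!ok], collapse = ", "), ")")
  mean(ratios[ok])
}

#' Calibrate the anomaly-score cutoff on control training scores
#'
#' The cutoff is the 99th linear-interpolation percentile of the control
#' training samples' anomaly scores; a sample is called positive when its
#' score is strictly above it.
#'
#' @param control_scores numeric vector of control training anomaly scores
#' @param percentile percentile in (0,100), default 99
#' @return the cutoff
#' @export
calibrate_anomaly_cutoff <- function(control_scores, percentile = 99) {
  stopifnot(length(control_scores) >= 1L, percentile > 0, percentile < 100)
  unname(stats::quantile(control_scores, probs = percentile / 100,
                         type = 7, names = FALSE))
}

#' Train the panel-wide random-forest anomaly model
#'
#' One depth-limited forest per panel region, trained on pooled control
#' training reads (label `normal`) and AML diagnosis reads (label
#' `abnormal`).
#'
#' @param control_reads pattern data frame of control training samples
#' @param aml_reads pattern data frame of AML diagnosis samples
#' @param panel a `region_panel`
#' @param n_trees,max_depth,seed forwarded to [train_forest()]
#' @return object of class `rf_model` (list of per-region models)
#' @export
train_rf_model <- function(control_reads, aml_reads,
                           panel = default_panel(),
                           n_trees = 100L, max_depth = 5L, seed = 1L) {
  models <- lapply(panel$regions, function(r)
    train_forest(control_reads[control_reads$region_id == r$region_id, ],
                 aml_reads[aml_reads$region_id == r$region_id, ],
                 r, n_trees = n_trees, max_depth = max_depth, seed = seed))
  structure(list(regions = models, panel = panel, seed = seed,
                 params = list(n_trees = n_trees, max_depth = max_depth)),
            class = "rf_model")
}

#' Anomaly ratios and score of one sample under a trained model
#'
#' Works for both the random-forest model and the autoencoder models: each
#' region's reads are classified normal/abnormal, the count-weighted
#' abnormal fraction is the region's anomaly ratio, and the sample score is
#' the mean of available ratios.
#'
#' @param model an `rf_model` or `ae_model`
#' @param reads pattern data frame of one sample
#' @return list with `sample_id`, `ratios` (named per-region vector) and
#'   `score`
#' @export
anomaly_result <- function(model, reads) {
  ratios <- vapply(names(model$regions), function(rid) {
    rr <- reads[reads$region_id == rid, , drop = FALSE]
    if (nrow(rr) == 0L) return(NA_real_)
    labels <- classify_region_reads(model, rid, rr)
    anomaly_ratio(labels, rr$count)
  }, numeric(1))
  list(sample_id = unique(reads$sample_id)[1], ratios = ratios,
       score = anomaly_score(ratios))
}

#' Classify one region's reads under a trained anomaly model
#'
#' @param model an `rf_model` or `ae_model`
#' @param region_id region identifier
#' @param reads pattern data frame restricted to that region
#' @return character vector of per-pattern labels
#' @export
classify_region_reads <- function(model, region_id, reads) {
  UseMethod("classify_region_reads")
}

#' @export
classify_region_reads.rf_model <- function(model, region_id, reads) {
  classify_reads_rf(model$regions[[region_id]], reads)
}
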