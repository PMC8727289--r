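#' Compute the four-CpG AML-score
#'
#' The AML-score averages direction-adjusted beta values at the four anchor
#' CpGs: hypermethylated-in-AML anchors contribute beta, hypomethylated
#' anchors contribute 1 - beta. With the default panel this is
#' (b_cg15289427 + b_cg22797031 + (1 - b_cg27630153) + (1 - b_cg19586199))/4,
#' a score in \[0,1\]: 0 for the perfect healthy archetype, 1 for the fully
#' aberrant one.
#'
#' @param betas named numeric vector of beta values, names = anchor
#'   cg-identifiers; all panel anchors must be present and in \[0,1\]
#' @param panel a `region_panel`
#' @return the score, a number in \[0,1\]
#' @export
compute_aml_score <- function(betas, panel = default_panel()) {
  anchors <- vapply(panel$regions, `[[`, character(1), "anchor_cpg")
  missing <- setdiff(anchors, names(betas))
  if (length(missing) > 0L)
    stop("missing anchor beta(s): ", paste(missing, collapse = ", "))
  b <- betas[anchors]
  if (any(is.na(b)) || any(b < 0 | b > 1))
    stop("anchor betas must be in [0,1]")
  dir <- vapply(panel$regions, `[[`, character(1), "direction")
  mean(ifelse(dir == "hyper_in_aml", b, 1 - b))
}

#' Calibrate a control-percentile cutoff
#'
#' Returns the given percentile (default 99.5) of control scores using
#' linear interpolation between order statistics. At least 10 control scores
#' are required, below which the tail percentile is unreliable.
#'
#' @param control_scores numeric vector of scores from control samples
#' @param percentile percentile in (0,100), default 99.5
#' @return the cutoff value
#' @export
calibrate_cutoff <- function(control_scores, percentile = 99.5) {
  if (length(control_scores) < 10L)
    stop("need at least 10 control scores to calibrate a cutoff")
  stopifnot(percentile > 0, percentile < 100)
  unname(stats::quantile(control_scores, probs = percentile / 100,
                         type = 7, names = FALSE))
}

#' Classify a sample by its score
#'
#' A sample is called positive when its score is strictly above the cutoff
#' (controls sit at or below the cutoff by construction).
#'
#' @param score score in \[0,1\]
#' @param cutoff cutoff in \[0,1\]; the BA-seq convention carried over from
#'   the array studies is 0.125
#' @return `"positive"` or `"negative"`
#' @export
classify_sample <- function(score, cutoff = 0.125) {
  stopifnot(score >= 0, score <= 1, cutoff >= 0, cutoff <= 1)
  if (score > cutoff) "positive" else "negative"
}

#' Anchor beta values of one sample from BA-seq reads
#'
#' For each panel region, beta at the anchor CpG is the count-weighted
#' fraction of reads methylated at the region's target CpG column. With
#' `use_amplicon_mean = TRUE` the mean methylated fraction over all CpGs of
#' the amplicon is used instead of the target column.
#'
#' @param reads pattern data frame of one sample (columns `sample_id`,
#'   `region_id`, `pattern`, `count`)
#' @param panel a `region_panel`
#' @param use_amplicon_mean use the amplicon-mean beta instead of the
#'   target-CpG beta (default `FALSE`)
#' @return named numeric vector anchor_cpg -> beta
#' @export
baseq_anchor_betas <- function(reads, panel = default_panel(),
                               use_amplicon_mean = FALSE) {
  out <- vapply(panel$regions, function(r) {
    rr <- reads[reads$region_id == r$region_id, , drop = FALSE]
    if (nrow(rr) == 0L)
      stop("no reads for region '", r$region_id,
           "'; AML-score undefined without all four anchors")
    bits <- pattern_bits(rr$pattern, n_cpgs(r))
    w <- rr$count / sum(rr$count)
    if (use_amplicon_mean) sum(rowMeans(bits) * w)
    else sum(bits[, r$target_index] * w)
  }, numeric(1))
  names(out) <- vapply(panel$regions, `[[`, character(1), "anchor_cpg")
  out
}

#' AML-score of one BA-seq sample
#'
#' Convenience wrapper: anchor betas via [baseq_anchor_betas()], score via
#' [compute_aml_score()], call via [classify_sample()].
#'
#' @inheritParams baseq_anchor_betas
#' @param cutoff classification cutoff (default 0.125)
#' @return list with `sample_id`, `betas`, `score`, `cutoff`, `call`
#' @export
aml_score_sample <- function(reads, panel = default_panel(),
                             cutoff = 0.125) {
  betas <- baseq_anchor_betas(reads, panel)
  score <- compute_aml_score(betas, panel)
  list(sample_id = unique(reads$sample_id)[1], betas = betas,
       score = score, cutoff = cutoff,
       call = classify_sample(score, cutoff))
}
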