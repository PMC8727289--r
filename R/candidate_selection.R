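#' Selection criteria for AML-associated CpGs
#'
#' Thresholds of the three-step candidate filter: a CpG is eligible when its
#' control-group mean beta is extreme (`< low_bound` or `> high_bound`) and
#' its control standard deviation is small (`< sd_max`); eligible CpGs are
#' then ranked by the mean methylation difference between AML and control,
#' keeping the `top_k` per direction.
#'
#' @param low_bound lower extreme-methylation bound (default 0.1)
#' @param high_bound upper extreme-methylation bound (default 0.9)
#' @param sd_max maximum control standard deviation (default 0.05)
#' @param top_k number of CpGs kept per direction (default 100)
#' @return object of class `selection_criteria`
#' @export
selection_criteria <- function(low_bound = 0.1, high_bound = 0.9,
                               sd_max = 0.05, top_k = 100L) {
  stopifnot(low_bound >= 0, low_bound < high_bound, high_bound <= 1,
            sd_max > 0, top_k >= 1)
  structure(list(low_bound = low_bound, high_bound = high_bound,
                 sd_max = sd_max, top_k = as.integer(top_k)),
            class = "selection_criteria")
}

#' Filter CpGs with invariant extreme methylation in controls
#'
#' Keeps CpGs whose control mean beta is `< low_bound` or `> high_bound` and
#' whose control sample (n-1) standard deviation is `< sd_max`. Means and
#' standard deviations exclude missing values pairwise; a CpG with fewer than
#' two non-missing control values is excluded and reported, not an error.
#'
#' @param bm a [beta_matrix()] (only its control columns are used)
#' @param criteria a [selection_criteria()]
#' @return character vector of kept CpG ids, with attribute
#'   `"excluded_low_n"` listing CpGs dropped for insufficient control data
#' @export
filter_invariant_cpgs <- function(bm, criteria = selection_criteria()) {
  ctrl <- group_values(bm, "control")
  n_ok <- rowSums(!is.na(ctrl))
  low_n <- rownames(ctrl)[n_ok < 2L]
  m <- rowMeans(ctrl, na.rm = TRUE)
  s <- apply(ctrl, 1L, stats::sd, na.rm = TRUE)
  keep <- !is.na(m) & !is.na(s) & n_ok >= 2L &
    (m < criteria$low_bound | m > criteria$high_bound) &
    s < criteria$sd_max
  structure(rownames(ctrl)[keep], excluded_low_n = low_n)
}

#' Rank eligible CpGs by methylation difference and select the top lists
#'
#' Computes delta = mean(AML) - mean(control) per eligible CpG and returns
#' the `top_k` CpGs with delta > 0 (hypermethylated in AML, ranked by delta
#' descending) and the `top_k` with delta < 0 (hypomethylated, ranked by
#' |delta| descending). Ties are broken lexicographically by CpG id.
#'
#' @param bm a [beta_matrix()] containing both groups
#' @param eligible character vector of eligible CpG ids (subset of rownames)
#' @param criteria a [selection_criteria()] (only `top_k` is used)
#' @return object of class `candidate_set` with fields `hyper`, `hypo`
#'   (ordered id vectors) and `delta` (named numeric vector)
#' @export
rank_and_select <- function(bm, eligible, criteria = selection_criteria()) {
  if (length(eligible) == 0L) {
    warning("empty eligible set; returning empty candidate set")
    return(structure(list(hyper = character(0), hypo = character(0),
                          delta = numeric(0)), class = "candidate_set"))
  }
  stopifnot(all(eligible %in% rownames(bm$values)))
  aml <- group_values(bm, "aml")[eligible, , drop = FALSE]
  ctrl <- group_values(bm, "control")[eligible, , drop = FALSE]
  delta <- rowMeans(aml, na.rm = TRUE) - rowMeans(ctrl, na.rm = TRUE)
  delta <- delta[!is.na(delta)]
  take <- function(d) {   # d already restricted to one sign, magnitude rank
    ids <- names(d)[order(-abs(d), names(d))]
    utils::head(ids, criteria$top_k)
  }
  structure(list(hyper = take(delta[delta > 0]),
                 hypo = take(delta[delta < 0]),
                 delta = delta),
            class = "candidate_set")
}

#' Intersect candidate sets across study pairs
#'
#' Consensus candidates: CpGs present in the hyper (resp. hypo) list of
#' every study pair, ordered by mean |delta| across pairs descending.
#'
#' @param sets list of at least two `candidate_set` objects
#' @return a `candidate_set`; its `delta` holds the across-set mean delta of
#'   the consensus CpGs
#' @export
intersect_candidates <- function(sets) {
  stopifnot(length(sets) >= 2L)
  hyper <- Reduce(intersect, lapply(sets, `[[`, "hyper"))
  hypo <- Reduce(intersect, lapply(sets, `[[`, "hypo"))
  mean_delta <- function(ids) {
    if (length(ids) == 0L) return(numeric(0))
    d <- rowMeans(vapply(sets, function(s) s$delta[ids],
                         numeric(length(ids))))
    stats::setNames(d, ids)
  }
  dh <- mean_delta(hyper); dl <- mean_delta(hypo)
  ord <- function(d) {
    if (length(d) == 0L) return(character(0))
    names(d)[order(-abs(d), names(d))]
  }
  structure(list(hyper = ord(dh), hypo = ord(dl), delta = c(dh, dl)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d hypermethylated, %d hypomethylated CpGs\n",
              length(x$hyper), length(x$hypo)))
  invisible(x)
}
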