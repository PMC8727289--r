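#' Convert pattern strings to a bit matrix
#'
#' @param patterns character vector of strings over \{0,1\}
#' @param n expected pattern length (region CpG count)
#' @return integer matrix, one row per pattern, columns = CpG positions
#' @export
pattern_bits <- function(patterns, n) {
  if (any(nchar(patterns) != n))
    stop("pattern length mismatch: expected ", n, " CpGs")
  if (any(grepl("[^01]", patterns)))
    stop("patterns must contain only characters 0 and 1")
  if (length(patterns) == 0L)
    return(matrix(integer(0), 0L, n))
  m <- matrix(as.integer(unlist(strsplit(patterns, "", fixed = TRUE))),
              nrow = length(patterns), ncol = n, byrow = TRUE)
  m
}

#' Collapse duplicate pattern rows
#'
#' Rows with identical (sample_id, region_id, pattern, allele_bases) are
#' merged with counts added; the collapsed table is the canonical
#' representation consumed by all downstream operations.
#'
#' @param reads pattern data frame
#' @return collapsed data frame
#' @export
collapse_patterns <- function(reads) {
  if (nrow(reads) == 0L) return(reads)
  ab <- if ("allele_bases" %in% names(reads)) reads$allele_bases else ""
  key <- paste(reads$sample_id, reads$region_id, reads$pattern, ab,
               sep = "\r")
  agg <- rowsum(reads$count, key)
  first <- !duplicated(key)
  out <- reads[first, , drop = FALSE]
  out$count <- as.integer(agg[key[first], 1L])
  rownames(out) <- NULL
  out
}

#' Read a per-read methylation pattern table
#'
#' The TSV has columns `sample_id`, `region_id`, `pattern` (a string over
#' \{0,1\}, one character per CpG), `count`, and optionally `allele_bases`
#' (`pos=base` pairs separated by commas). Pattern lengths are validated
#' against the panel; rows with identical keys are collapsed additively.
#'
#' @param path path to the TSV
#' @param panel a `region_panel` for validation (optional, recommended)
#' @return collapsed pattern data frame
#' @export
read_pattern_tsv <- function(path, panel = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(pattern = "character"))
  need <- c("sample_id", "region_id", "pattern", "count")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L)
    stop("pattern TSV is missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(grepl("[^01]", tab$pattern)))
    stop("patterns must contain only characters 0 and 1")
  if (any(tab$count < 1L)) stop("pattern counts must be >= 1")
  if (!is.null(panel)) {
    for (r in panel$regions) {
      idx <- tab$region_id == r$region_id
      bad <- idx & nchar(tab$pattern) != n_cpgs(r)
      if (any(bad))
        stop("pattern length mismatch in sample '",
             tab$sample_id[which(bad)[1]], "', region '", r$region_id,
             "': expected ", n_cpgs(r), " CpGs")
    }
    unknown <- setdiff(unique(tab$region_id), names(panel$regions))
    if (length(unknown) > 0L)
      stop("unknown region id(s): ", paste(unknown, collapse = ", "))
  }
  collapse_patterns(tab)
}

#' Write a pattern table to TSV
#'
#' @param reads pattern data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pattern_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build read patterns from per-read CpG methylation calls
#'
#' Consumes Bismark-style per-read CpG-context calls (columns `read_id`,
#' `state`, `chrom`, `position`; `state` is `+`/`Z` for methylated, `-`/`z`
#' for unmethylated, 1-based position of the C). Each read is assigned to the
#' panel region whose CpG positions it covers completely; its states, ordered
#' by genomic position, become the pattern bits. Reads covering only part of
#' a region's CpGs are discarded and tallied rather than imputed, and calls
#' at positions outside every panel region are skipped with a tally.
#'
#' @param calls data frame of per-read calls
#' @param panel a `region_panel`
#' @param sample_id sample identifier for the emitted patterns
#' @return collapsed pattern data frame with attribute `"tallies"` (named
#'   integer vector: `assigned`, `partial`, `unassigned` read counts)
#' @export
from_bismark_calls <- function(calls, panel, sample_id = "sample") {
  need <- c("read_id", "state", "chrom", "position")
  missing <- setdiff(need, names(calls))
  if (length(missing) > 0L)
    stop("calls are missing column(s): ", paste(missing, collapse = ", "))
  meth <- calls$state %in% c("+", "Z")
  unmeth <- calls$state %in% c("-", "z")
  if (!all(meth | unmeth))
    stop("unrecognized methylation state symbol(s): ",
         paste(unique(calls$state[!(meth | unmeth)]), collapse = ", "))
  calls$bit <- as.integer(meth)

  tallies <- c(assigned = 0L, partial = 0L, unassigned = 0L)
  rows <- list()
  for (rd in split(calls, calls$read_id)) {
    hit <- FALSE
    for (r in panel$regions) {
      on_region <- rd$chrom == r$chrom & rd$position %in% r$cpg_positions
      if (!any(on_region)) next
      sub <- rd[on_region, , drop = FALSE]
      if (!all(r$cpg_positions %in% sub$position)) {
        tallies["partial"] <- tallies["partial"] + 1L
        hit <- TRUE
        break
      }
      sub <- sub[match(r$cpg_positions, sub$position), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, region_id = r$region_id,
        pattern = paste(sub$bit, collapse = ""), count = 1L,
        stringsAsFactors = FALSE)
      tallies["assigned"] <- tallies["assigned"] + 1L
      hit <- TRUE
      break
    }
    if (!hit) tallies["unassigned"] <- tallies["unassigned"] + 1L
  }
  out <- if (length(rows) == 0L)
    data.frame(sample_id = character(0), region_id = character(0),
               pattern = character(0), count = integer(0),
               stringsAsFactors = FALSE)
  else collapse_patterns(do.call(rbind, rows))
  attr(out, "tallies") <- tallies
  out
}

#' Per-sample, per-region read depth
#'
#' @param reads pattern data frame
#' @param panel a `region_panel`
#' @return data frame `sample_id` x region columns of total read counts
#'   (0 for regions without reads)
#' @export
read_depths <- function(reads, panel) {
  samples <- unique(reads$sample_id)
  depths <- sapply(names(panel$regions), function(rid)
    vapply(samples, function(s)
      sum(reads$count[reads$sample_id == s & reads$region_id == rid]),
      numeric(1)))
  depths <- matrix(depths, nrow = length(samples),
                   dimnames = list(samples, names(panel$regions)))
  data.frame(sample_id = samples, depths, check.names = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Depth-based sample quality control
#'
#' A sample is excluded when any panel region has fewer than `min_depth`
#' reads (strictly below 50 by default); samples with exactly `min_depth`
#' reads on every region are kept.
#'
#' @param reads pattern data frame covering one or more samples
#' @param panel a `region_panel`
#' @param min_depth minimum per-region read count (default 50)
#' @return list with `kept` and `excluded` pattern data frames and
#'   `excluded_samples` (character vector)
#' @export
qc_filter <- function(reads, panel = default_panel(), min_depth = 50L) {
  if (nrow(reads) == 0L)
    return(list(kept = reads, excluded = reads,
                excluded_samples = character(0)))
  d <- read_depths(reads, panel)
  dm <- as.matrix(d[, names(panel$regions), drop = FALSE])
  fail <- apply(dm < min_depth, 1L, any)
  bad <- d$sample_id[fail]
  list(kept = reads[!(reads$sample_id %in% bad), , drop = FALSE],
       excluded = reads[reads$sample_id %in% bad, , drop = FALSE],
       excluded_samples = bad)
}

#' Split control samples into training and validation sets
#'
#' Sample-level (never read-level) random partition with a 7:3 default
#' ratio; the training size is `round(train_fraction * n)` and the split is
#' deterministic under a fixed seed.
#'
#' @param sample_ids character vector of control sample ids (>= 2)
#' @param train_fraction fraction assigned to training (default 0.7)
#' @param seed integer seed
#' @return list with `train` and `validation` id vectors
#' @export
split_controls <- function(sample_ids, train_fraction = 0.7, seed = 1L) {
  stopifnot(length(sample_ids) >= 2L,
            train_fraction > 0, train_fraction < 1)
  n_train <- round(train_fraction * length(sample_ids))
  n_train <- max(1L, min(length(sample_ids) - 1L, n_train))
  train <- local_seed(seed, sample(sample_ids, n_train))
  list(train = train, validation = setdiff(sample_ids, train))
}

# run expr under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
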