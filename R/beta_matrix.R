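#' Beta-value matrix with group labels
#'
#' Container for CpG-by-sample DNA methylation levels (beta values in
#' \[0,1\], `NA` allowed) together with a control/AML group assignment, the
#' substrate for CpG candidate selection and the array AML-score.
#'
#' @param values numeric matrix, rows CpGs (unique rownames = cg-identifiers),
#'   columns samples (colnames = sample ids)
#' @param group named character vector mapping every sample id to
#'   `"control"` or `"aml"`
#' @return object of class `beta_matrix`
#' @export
beta_matrix <- function(values, group) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have CpG rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("cpg ids must be unique")
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values outside [0,1]")
  missing <- setdiff(colnames(values), names(group))
  if (length(missing) > 0L)
    stop("samples missing from group map: ", paste(missing, collapse = ", "))
  group <- group[colnames(values)]
  bad <- setdiff(unique(group), c("control", "aml"))
  if (length(bad) > 0L)
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  structure(list(values = values, group = group), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d CpGs x %d samples (%d control, %d aml)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "control"), sum(x$group == "aml")))
  invisible(x)
}

#' Subset a beta matrix to one group
#' @param bm a `beta_matrix`
#' @param group `"control"` or `"aml"`
#' @return numeric matrix of the group's columns
#' @export
group_values <- function(bm, group = c("control", "aml")) {
  group <- match.arg(group)
  bm$values[, bm$group == group, drop = FALSE]
}

#' Load a beta matrix and group map from TSV files
#'
#' The matrix TSV has a first column of cg-identifiers and a header row of
#' sample ids; the group map is a two-column TSV (`sample_id`, `group`) with
#' `group` in `control`/`aml`. Missing cells (`NA` or empty) are preserved as
#' missing; any non-missing value outside \[0,1\] or a sample absent from the
#' group map is a validation error.
#'
#' @param path path to the beta-value TSV
#' @param groups_path path to the group-map TSV
#' @return a [beta_matrix()]
#' @export
load_beta_matrix <- function(path, groups_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L)
    stop("no CpGs in beta matrix file: ", path)
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(tab[[1]])
  gm <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(gm)))
    stop("group map must have columns sample_id and group")
  group <- stats::setNames(gm$group, gm$sample_id)
  beta_matrix(values, group)
}
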