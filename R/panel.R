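#' Amplicon region panel
#'
#' An amplicon region describes one bisulfite amplicon sequencing (BA-seq)
#' target: its ordered CpG positions on the reference (+) strand, the anchor
#' CpG that enters the AML-score, the direction of the aberration in AML, and
#' optional SNP positions usable for allele splitting. A panel is a set of
#' such regions; the default panel carries the four AML-associated regions
#' with 14, 10, 15 and 9 CpGs anchored at cg15289427, cg22797031,
#' cg27630153 and cg19586199.
#'
#' Coordinates are 1-based and refer to the C of each CG dinucleotide on the
#' (+) strand, matching the Illumina manifest convention for cg-identifiers.
#' `target_index` is the 1-based index of the anchor CpG within
#' `cpg_positions`.
#'
#' @param region_id unique region identifier
#' @param anchor_cpg cg-identifier of the anchor CpG
#' @param chrom chromosome name
#' @param cpg_positions strictly increasing integer vector of CpG positions
#'   (position of the C of each CpG)
#' @param target_index 1-based index of the anchor CpG in `cpg_positions`
#' @param direction `"hyper_in_aml"` (unmethylated in health, methylated in
#'   AML) or `"hypo_in_aml"` (the reverse)
#' @param snp_positions optional integer vector of SNP positions; every SNP
#'   must be at least 3 bp from both the C and the G of every CpG
#' @return an object of class `amplicon_region`
#' @export
amplicon_region <- function(region_id, anchor_cpg, chrom, cpg_positions,
                            target_index, direction,
                            snp_positions = integer(0)) {
  cpg_positions <- as.integer(cpg_positions)
  target_index <- as.integer(target_index)
  snp_positions <- as.integer(snp_positions)
  if (length(region_id) != 1L || !nzchar(region_id))
    stop("region_id must be a non-empty string")
  if (length(cpg_positions) < 1L || any(diff(cpg_positions) <= 0L))
    stop("cpg_positions must be strictly increasing in region '",
         region_id, "'")
  if (target_index < 1L || target_index > length(cpg_positions))
    stop("target_index out of range in region '", region_id, "'")
  direction <- match.arg(direction, c("hyper_in_aml", "hypo_in_aml"))
  for (s in snp_positions) {
    # distance to both the C and the G of each CpG dinucleotide
    d <- pmin(abs(s - cpg_positions), abs(s - (cpg_positions + 1L)))
    if (any(d < 3L))
      stop("snp_position ", s, " is closer than 3 bp to a CpG in region '",
           region_id, "'")
  }
  structure(
    list(region_id = region_id, anchor_cpg = anchor_cpg, chrom = chrom,
         cpg_positions = cpg_positions, target_index = target_index,
         direction = direction, snp_positions = snp_positions),
    class = "amplicon_region")
}

#' Number of CpGs in a region
#' @param region an `amplicon_region`
#' @return integer CpG count
#' @export
n_cpgs <- function(region) length(region$cpg_positions)

#' Build a region panel
#'
#' @param regions list of [amplicon_region()] objects
#' @return object of class `region_panel`
#' @export
region_panel <- function(regions) {
  ids <- vapply(regions, `[[`, character(1), "region_id")
  if (anyDuplicated(ids)) stop("region_ids must be unique")
  names(regions) <- ids
  structure(list(regions = regions), class = "region_panel")
}

#' @export
print.region_panel <- function(x, ...) {
  cat("region_panel with", length(x$regions), "regions\n")
  for (r in x$regions)
    cat(sprintf("  %s (%s, %s): %d CpGs, anchor %s, %d SNP(s)\n",
                r$region_id, r$chrom, r$direction, n_cpgs(r), r$anchor_cpg,
                length(r$snp_positions)))
  invisible(x)
}

#' Load a region panel from a YAML configuration file
#'
#' The file holds a top-level `regions:` list; each record carries the fields
#' of [amplicon_region()] (`region_id`, `anchor_cpg`, `chrom`,
#' `cpg_positions`, `target_index`, `direction`, optional `snp_positions`).
#' All type invariants are enforced; a SNP closer than 3 bp to a CpG is a
#' validation error.
#'
#' @param path path to the YAML panel file
#' @return a `region_panel`
#' @export
load_region_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$regions) || length(doc$regions) == 0L)
    stop("panel file has no 'regions' entry: ", path)
  required <- c("region_id", "anchor_cpg", "chrom", "cpg_positions",
                "target_index", "direction")
  regions <- lapply(doc$regions, function(rec) {
    missing <- setdiff(required, names(rec))
    if (length(missing) > 0L)
      stop("panel record is missing field(s): ",
           paste(missing, collapse = ", "))
    amplicon_region(rec$region_id, rec$anchor_cpg, rec$chrom,
                    rec$cpg_positions, rec$target_index, rec$direction,
                    if (is.null(rec$snp_positions)) integer(0)
                    else rec$snp_positions)
  })
  region_panel(regions)
}

#' Write a region panel to a YAML file
#'
#' Inverse of [load_region_panel()]: the written file parses back to an
#' identical panel.
#'
#' @param panel a `region_panel`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_panel <- function(panel, path) {
  recs <- lapply(unname(panel$regions), function(r) {
    rec <- list(region_id = r$region_id, anchor_cpg = r$anchor_cpg,
                chrom = r$chrom, cpg_positions = as.list(r$cpg_positions),
                target_index = r$target_index, direction = r$direction)
    if (length(r$snp_positions) > 0L)
      rec$snp_positions <- as.list(r$snp_positions)
    rec
  })
  yaml::write_yaml(list(regions = recs), path)
  invisible(path)
}

#' The default four-region AML panel
#'
#' Four BA-seq amplicons anchored at cg15289427 (14 CpGs, hypermethylated in
#' AML), cg22797031 (10 CpGs, hypermethylated), cg27630153 (15 CpGs,
#' hypomethylated) and cg19586199 (9 CpGs, hypomethylated). The two
#' hypomethylated regions carry the heterozygous SNPs rs115701567
#' (chr16:88844998) and rs917911737 (chr19:14225172) as optional allele-split
#' annotations. CpG coordinates in the shipped file are synthetic
#' placeholders laid out around the anchors; counts, anchors, directions and
#' SNP positions are the panel's defining content.
#'
#' @return a `region_panel` with four regions
#' @export
default_panel <- function() {
  load_region_panel(system.file("extdata", "default_panel.yaml",
                                package = "epiMRD", mustWork = TRUE))
}
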