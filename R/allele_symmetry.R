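# allele_bases strings are "pos=base" pairs separated by commas,
# e.g. "88844998=A". Helpers parse the base observed at one position.

allele_base_at <- function(allele_bases, pos) {
  vapply(strsplit(allele_bases, ",", fixed = TRUE), function(pairs) {
    pairs <- pairs[nzchar(pairs)]
    kv <- strsplit(pairs, "=", fixed = TRUE)
    hit <- vapply(kv, function(x) x[1] == as.character(pos), logical(1))
    if (any(hit)) kv[[which(hit)[1]]][2] else NA_character_
  }, character(1))
}

#' Detect a heterozygous SNP within an amplicon
#'
#' Scans the region's annotated SNP positions for one where the two most
#' frequent bases each reach at least `min_minor` of the (count-weighted)
#' reads — the operational reading of "around 50% of the top two variants".
#' Positions closer than 3 bp to a CpG are already rejected when the panel
#' is loaded.
#'
#' @param reads pattern data frame of one sample and region with an
#'   `allele_bases` column
#' @param region the `amplicon_region`
#' @param min_minor minimum frequency of each of the top two bases
#'   (default 0.3)
#' @return the first qualifying SNP position, or `NULL` when none qualifies
#' @export
detect_het_snp <- function(reads, region, min_minor = 0.3) {
  if (!"allele_bases" %in% names(reads)) return(NULL)
  for (pos in region$snp_positions) {
    base <- allele_base_at(reads$allele_bases, pos)
    ok <- !is.na(base)
    if (!any(ok)) next
    freq <- rowsum(reads$count[ok], base[ok])[, 1L]
    freq <- sort(freq / sum(freq), decreasing = TRUE)
    if (length(freq) >= 2L && freq[2] >= min_minor) return(pos)
  }
  NULL
}

#' Split reads by the base at a heterozygous SNP
#'
#' Partitions a sample's reads into the two allele groups defined by the top
#' two bases at `snp_position`; reads carrying a third base or no call at
#' the position are discarded and tallied.
#'
#' @param reads pattern data frame with `allele_bases`
#' @param snp_position SNP position
#' @return object of class `allele_split` with `reads_a`, `reads_b` (pattern
#'   data frames, a = major allele), `allele_a_base`, `allele_b_base`,
#'   `minor_fraction` and `discarded` (read count)
#' @export
split_by_allele <- function(reads, snp_position) {
  base <- allele_base_at(reads$allele_bases, snp_position)
  ok <- !is.na(base)
  freq <- sort(rowsum(reads$count[ok], base[ok])[, 1L], decreasing = TRUE)
  if (length(freq) < 2L)
    stop("fewer than two alleles observed at position ", snp_position)
  a <- names(freq)[1]; b <- names(freq)[2]
  reads_a <- reads[ok & base == a, , drop = FALSE]
  reads_b <- reads[ok & base == b, , drop = FALSE]
  n_a <- sum(reads_a$count); n_b <- sum(reads_b$count)
  structure(list(
    snp_position = snp_position,
    allele_a_base = a, allele_b_base = b,
    reads_a = reads_a, reads_b = reads_b,
    minor_fraction = min(n_a, n_b) / (n_a + n_b),
    discarded = sum(reads$count) - n_a - n_b),
    class = "allele_split")
}

#' Quantify methylation symmetry between the two alleles
#'
#' Computes, per CpG, the absolute difference of the count-weighted
#' methylation level between the two allele groups, and a distribution-level
#' statistic: half the L1 distance between the two alleles' normalized
#' pattern-frequency distributions (0 = identical epiallele distributions,
#' 1 = disjoint). Both allele groups must reach the usual depth rule of 50
#' reads.
#'
#' @param split an `allele_split`
#' @param region the `amplicon_region`
#' @param min_reads minimum reads per allele group (default 50)
#' @return object of class `symmetry_stat` with `per_cpg_delta`,
#'   `max_delta`, `l1_pattern_distance`
#' @export
symmetry_stat <- function(split, region, min_reads = 50L) {
  n_a <- sum(split$reads_a$count); n_b <- sum(split$reads_b$count)
  if (n_a < min_reads || n_b < min_reads)
    stop("allele groups have ", n_a, "/", n_b, " reads; at least ",
         min_reads, " per allele are required - sequence deeper")
  n <- n_cpgs(region)
  beta_of <- function(rr) {
    bits <- pattern_bits(rr$pattern, n)
    colSums(bits * (rr$count / sum(rr$count)))
  }
  delta <- abs(beta_of(split$reads_a) - beta_of(split$reads_b))
  freq_of <- function(rr) {
    f <- rowsum(rr$count, rr$pattern)[, 1L]
    f / sum(f)
  }
  fa <- freq_of(split$reads_a); fb <- freq_of(split$reads_b)
  pats <- union(names(fa), names(fb))
  l1 <- 0.5 * sum(abs(ifelse(pats %in% names(fa), fa[pats], 0) -
                      ifelse(pats %in% names(fb), fb[pats], 0)))
  structure(list(per_cpg_delta = delta, max_delta = max(delta),
                 l1_pattern_distance = l1),
            class = "symmetry_stat")
}
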