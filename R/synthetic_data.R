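#' Clone methylation profile over a panel
#'
#' A clone profile gives, per region, the per-CpG probability that a read
#' from this clone is methylated. The `normal` clone follows each region's
#' healthy state (unmethylated for hyper-in-AML regions, methylated for
#' hypo-in-AML regions) up to the error rate `epsilon`, which lumps
#' bisulfite-conversion failure and sequencing error. The `aberrant` clone
#' flips the entire amplicon to the opposite state, emulating the coherent
#' whole-amplicon aberrations seen in leukemic reads.
#'
#' @param panel a `region_panel`
#' @param label `"normal"` or `"aberrant"`
#' @param epsilon error rate in \[0, 0.5) (default 0.02)
#' @return object of class `clone_profile`: list region_id -> probability
#'   vector, with attributes `label` and `epsilon`
#' @export
clone_profile <- function(panel = default_panel(),
                          label = c("normal", "aberrant"),
                          epsilon = 0.02) {
  label <- match.arg(label)
  stopifnot(epsilon >= 0, epsilon < 0.5)
  prof <- lapply(panel$regions, function(r) {
    healthy_methylated <- r$direction == "hypo_in_aml"
    state <- if (label == "normal") healthy_methylated else !healthy_methylated
    rep(if (state) 1 - epsilon else epsilon, n_cpgs(r))
  })
  structure(prof, label = label, epsilon = epsilon,
            class = "clone_profile")
}

#' Simulate reads from a clone profile for one region
#'
#' Each read's bits are drawn CpG-wise independent Bernoulli from the
#' profile's probability vector; identical patterns are collapsed with
#' counts.
#'
#' @param profile a `clone_profile`
#' @param region the `amplicon_region`
#' @param n_reads number of reads
#' @param sample_id emitted sample id
#' @param seed integer seed
#' @return collapsed pattern data frame
#' @export
simulate_reads <- function(profile, region, n_reads,
                           sample_id = "sim", seed = 1L) {
  p <- profile[[region$region_id]]
  stopifnot(!is.null(p), length(p) == n_cpgs(region))
  bits <- local_seed(seed,
    matrix(stats::rbinom(n_reads * length(p), 1L, rep(p, each = n_reads)),
           nrow = n_reads))
  collapse_patterns(data.frame(
    sample_id = sample_id, region_id = region$region_id,
    pattern = apply(bits, 1L, paste, collapse = ""), count = 1L,
    stringsAsFactors = FALSE))
}

#' Simulate one sample over the whole panel
#'
#' A mixture sample: each read comes from the aberrant clone with
#' probability `fraction` and from the normal clone otherwise, independently
#' per read and region — the in-silico analogue of diluting leukemic DNA
#' into healthy DNA.
#'
#' @param normal,aberrant `clone_profile`s covering the panel
#' @param panel a `region_panel`
#' @param fraction aberrant-clone fraction in \[0,1\]
#' @param reads_per_region reads per amplicon
#' @param sample_id emitted sample id
#' @param seed integer seed
#' @return collapsed pattern data frame with attribute
#'   `"aberrant_fraction"` (named per-region realized fractions)
#' @export
simulate_sample <- function(normal, aberrant, panel = default_panel(),
                            fraction = 0, reads_per_region = 1000L,
                            sample_id = "sim", seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  out <- list(); realized <- numeric(0)
  for (i in seq_along(panel$regions)) {
    r <- panel$regions[[i]]
    n_ab <- local_seed(mix_seed(seed, 3L * i),
                       stats::rbinom(1L, reads_per_region, fraction))
    parts <- list()
    if (reads_per_region - n_ab > 0L)
      parts$n <- simulate_reads(normal, r, reads_per_region - n_ab,
                                sample_id, seed = mix_seed(seed, 3L * i + 1L))
    if (n_ab > 0L)
      parts$a <- simulate_reads(aberrant, r, n_ab, sample_id,
                                seed = mix_seed(seed, 3L * i + 2L))
    out[[r$region_id]] <- do.call(rbind, unname(parts))
    realized[r$region_id] <- n_ab / reads_per_region
  }
  res <- collapse_patterns(do.call(rbind, out))
  rownames(res) <- NULL
  attr(res, "aberrant_fraction") <- realized
  res
}

#' Limiting-dilution design
#'
#' @param fractions aberrant-DNA fractions, sorted descending (default
#'   1, 0.5, 0.25, 0.10, 0.05, 0.01, 0)
#' @param reads_per_region reads per amplicon per sample
#' @param seed integer seed
#' @return object of class `dilution_design`
#' @export
dilution_design <- function(fractions = c(1, 0.5, 0.25, 0.10, 0.05,
                                          0.01, 0),
                            reads_per_region = 1000L, seed = 1L) {
  stopifnot(all(diff(fractions) <= 0), all(fractions >= 0),
            all(fractions <= 1))
  structure(list(fractions = fractions,
                 reads_per_region = as.integer(reads_per_region),
                 seed = as.integer(seed)),
            class = "dilution_design")
}

#' Simulate a limiting-dilution series
#'
#' One sample per design fraction, each mixing aberrant and normal reads at
#' that fraction; ground-truth nominal and realized fractions are recorded.
#'
#' @param normal,aberrant `clone_profile`s
#' @param design a [dilution_design()]
#' @param panel a `region_panel`
#' @return list of pattern data frames, one per fraction, named by sample
#'   id `dil_<fraction>`; each carries attributes `"nominal_fraction"` and
#'   `"aberrant_fraction"`
#' @export
simulate_dilution <- function(normal, aberrant, design,
                              panel = default_panel()) {
  out <- lapply(seq_along(design$fractions), function(i) {
    f <- design$fractions[i]
    sid <- paste0("dil_", f)
    s <- simulate_sample(normal, aberrant, panel, fraction = f,
                         reads_per_region = design$reads_per_region,
                         sample_id = sid, seed = mix_seed(design$seed, i))
    attr(s, "nominal_fraction") <- f
    s
  })
  names(out) <- paste0("dil_", design$fractions)
  out
}

#' Simulate a cohort of samples from one clone mixture
#'
#' @param normal,aberrant `clone_profile`s
#' @param panel a `region_panel`
#' @param n_samples number of samples
#' @param fraction aberrant fraction shared by all samples
#' @param reads_per_region reads per amplicon
#' @param prefix sample-id prefix
#' @param seed integer seed
#' @return pattern data frame covering all samples
#' @export
simulate_cohort <- function(normal, aberrant, panel = default_panel(),
                            n_samples = 10L, fraction = 0,
                            reads_per_region = 500L, prefix = "S",
                            seed = 1L) {
  out <- lapply(seq_len(n_samples), function(i) {
    s <- simulate_sample(normal, aberrant, panel, fraction = fraction,
                         reads_per_region = reads_per_region,
                         sample_id = paste0(prefix, i),
                         seed = mix_seed(seed, i))
    attr(s, "aberrant_fraction") <- NULL
    s
  })
  do.call(rbind, out)
}

#' Simulate a beta-value matrix with planted aberrant CpGs
#'
#' Null CpGs share a common mean between groups (uniform baseline plus
#' Gaussian noise); planted hypermethylated-in-AML CpGs have control mean
#' 0.05 shifted up by `effect` in AML, planted hypomethylated CpGs control
#' mean 0.95 shifted down by `effect`. All values are clipped to \[0,1\].
#'
#' @param n_null number of null CpGs
#' @param n_planted_hyper,n_planted_hypo numbers of planted CpGs
#' @param n_controls,n_aml group sizes
#' @param effect planted |delta beta| in (0,1]
#' @param noise_sd Gaussian noise standard deviation (default 0.03)
#' @param seed integer seed
#' @return list with `matrix` (a [beta_matrix()]), `planted_hyper`,
#'   `planted_hypo` (CpG id vectors)
#' @export
simulate_beta_matrix <- function(n_null = 480L, n_planted_hyper = 10L,
                                 n_planted_hypo = 10L, n_controls = 50L,
                                 n_aml = 20L, effect = 0.5,
                                 noise_sd = 0.03, seed = 1L) {
  stopifnot(effect > 0, effect <= 1, noise_sd >= 0)
  local_seed(seed, {
    n_cpg <- n_null + n_planted_hyper + n_planted_hypo
    ids <- sprintf("cg%08d", seq_len(n_cpg))
    planted_hyper <- ids[seq_len(n_planted_hyper)]
    planted_hypo <- ids[n_planted_hyper + seq_len(n_planted_hypo)]
    ctrl_mean <- c(rep(0.05, n_planted_hyper), rep(0.95, n_planted_hypo),
                   stats::runif(n_null))
    aml_mean <- c(rep(0.05 + effect, n_planted_hyper),
                  rep(0.95 - effect, n_planted_hypo),
                  ctrl_mean[n_planted_hyper + n_planted_hypo + seq_len(n_null)])
    draw <- function(means, n_samp)
      matrix(pmin(1, pmax(0, stats::rnorm(length(means) * n_samp,
                                          mean = rep(means, n_samp),
                                          sd = noise_sd))),
             nrow = length(means))
    values <- cbind(draw(ctrl_mean, n_controls), draw(aml_mean, n_aml))
    rownames(values) <- ids
    samples <- c(sprintf("ctrl_%03d", seq_len(n_controls)),
                 sprintf("aml_%03d", seq_len(n_aml)))
    colnames(values) <- samples
    group <- stats::setNames(rep(c("control", "aml"),
                                 c(n_controls, n_aml)), samples)
    list(matrix = beta_matrix(values, group),
         planted_hyper = planted_hyper, planted_hypo = planted_hypo)
  })
}

#' Simulate a heterozygous sample for allele-symmetry analysis
#'
#' Each read of one region is assigned to allele a or b with probability
#' 0.5, its pattern drawn from that allele's clone profile, and the allele
#' base recorded at the SNP position.
#'
#' @param profile_a,profile_b `clone_profile`s for the two alleles
#' @param region the `amplicon_region` containing the SNP
#' @param snp_position SNP position (must be annotated in the region)
#' @param bases two base characters for alleles a and b (default A, G)
#' @param n_reads total reads
#' @param sample_id emitted sample id
#' @param seed integer seed
#' @return collapsed pattern data frame with `allele_bases`; attribute
#'   `"allele_counts"` records the per-allele read counts
#' @export
simulate_het_sample <- function(profile_a, profile_b, region, snp_position,
                                bases = c("A", "G"), n_reads = 4000L,
                                sample_id = "het", seed = 1L) {
  stopifnot(snp_position %in% region$snp_positions, length(bases) == 2L,
            bases[1] != bases[2])
  n_a <- local_seed(seed, stats::rbinom(1L, n_reads, 0.5))
  mk <- function(profile, n, base, sub_seed) {
    if (n == 0L) return(NULL)
    rr <- simulate_reads(profile, region, n, sample_id, seed = sub_seed)
    rr$allele_bases <- paste0(snp_position, "=", base)
    rr
  }
  out <- collapse_patterns(rbind(
    mk(profile_a, n_a, bases[1], mix_seed(seed, 1L)),
    mk(profile_b, n_reads - n_a, bases[2], mix_seed(seed, 2L))))
  rownames(out) <- NULL
  attr(out, "allele_counts") <- stats::setNames(c(n_a, n_reads - n_a),
                                                bases)
  out
}
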