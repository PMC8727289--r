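het_region <- fix_panel$regions[["cg19586199"]]   # SNP at 14225172

ab <- function(base) paste0("14225172=", base)

test_that("heterozygous SNP detection needs two common bases", {
  het <- toy_reads(c(strrep("1", 9), strrep("1", 9)), c(48, 52),
                   region_id = "cg19586199")
  het$allele_bases <- c(ab("A"), ab("G"))
  expect_equal(detect_het_snp(het, het_region), 14225172)
  hom <- het
  hom$count <- c(95, 5)     # 95% A / 5% G: homozygous plus error
  expect_null(detect_het_snp(hom, het_region))
  expect_null(detect_het_snp(het[, 1:4], het_region))  # no base calls
})

test_that("allele split partitions reads and conserves counts", {
  reads <- toy_reads(c("111111111", "000000000", "101010101"),
                     c(48, 49, 3), region_id = "cg19586199")
  reads$allele_bases <- c(ab("A"), ab("G"), ab("T"))
  sp <- split_by_allele(reads, 14225172)
  expect_equal(sum(sp$reads_a$count), 49)   # major allele first
  expect_equal(sum(sp$reads_b$count), 48)
  expect_equal(sp$discarded, 3)
  expect_equal(sum(sp$reads_a$count) + sum(sp$reads_b$count) +
                 sp$discarded, sum(reads$count))
  expect_equal(sp$minor_fraction, 48 / 97)
})

test_that("simulated heterozygote has near-even alleles", {
  s <- simulate_het_sample(fix_normal, fix_normal, het_region, 14225172,
                           n_reads = 4000, seed = 21)
  sp <- split_by_allele(s, 14225172)
  expect_lt(abs(sp$minor_fraction - 0.5), 0.02)
})

test_that("symmetry statistics hit the degenerate limits", {
  mk <- function(pat_a, pat_b, n = 60) {
    r <- toy_reads(c(pat_a, pat_b), c(n, n), region_id = "cg19586199")
    r$allele_bases <- c(ab("A"), ab("G"))
    r
  }
  same <- symmetry_stat(split_by_allele(mk("101010101", "101010101"),
                                        14225172), het_region)
  expect_equal(same$max_delta, 0)
  expect_equal(same$l1_pattern_distance, 0)
  opposite <- symmetry_stat(split_by_allele(mk("111111111", "000000000"),
                                            14225172), het_region)
  expect_equal(opposite$max_delta, 1)
  expect_equal(opposite$l1_pattern_distance, 1)
  expect_error(symmetry_stat(split_by_allele(mk("111111111", "000000000",
                                                n = 20), 14225172),
                             het_region), "at least 50")
})

test_that("symmetry statistic is symmetric under allele swap", {
  s <- simulate_het_sample(fix_normal, fix_aberrant, het_region, 14225172,
                           n_reads = 2000, seed = 23)
  sp <- split_by_allele(s, 14225172)
  swapped <- sp
  swapped$reads_a <- sp$reads_b; swapped$reads_b <- sp$reads_a
  a <- symmetry_stat(sp, het_region)
  b <- symmetry_stat(swapped, het_region)
  expect_equal(a$max_delta, b$max_delta)
  expect_equal(a$l1_pattern_distance, b$l1_pattern_distance)
})

test_that("symmetric alleles converge, asymmetric alleles diverge", {
  sym <- simulate_het_sample(fix_normal, fix_normal, het_region, 14225172,
                             n_reads = 4000, seed = 24)
  st_sym <- symmetry_stat(split_by_allele(sym, 14225172), het_region)
  expect_lt(st_sym$max_delta, 0.05)
  asym <- simulate_het_sample(fix_aberrant, fix_normal, het_region,
                              14225172, n_reads = 4000, seed = 25)
  st_asym <- symmetry_stat(split_by_allele(asym, 14225172), het_region)
  expect_gt(st_asym$max_delta, 0.5)
  # deeper sequencing tightens the symmetric case
  deltas <- vapply(c(200, 2000, 20000), function(n) {
    s <- simulate_het_sample(fix_normal, fix_normal, het_region, 14225172,
                             n_reads = n, seed = 26)
    symmetry_stat(split_by_allele(s, 14225172), het_region,
                  min_reads = 50)$max_delta
  }, numeric(1))
  expect_lt(deltas[3], deltas[1])
})
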