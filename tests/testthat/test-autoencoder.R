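test_that("encoding maps 0/1 to -1/+1 and decodes by sign", {
  enc <- encode_reads("0101", 4)
  expect_equal(as.vector(enc), c(-1, 1, -1, 1))
  expect_equal(as.vector(encode_reads("0000", 4)), rep(-1, 4))
  pats <- c("0101", "1111", "0010")
  enc <- encode_reads(pats, 4)
  decoded <- apply((sign(enc) + 1) / 2, 1, paste, collapse = "")
  expect_equal(decoded, pats)
})

test_that("k-means recovers pure populations and reduces k when needed", {
  reads <- toy_reads(c("0000", "1111"), c(500, 500))
  cm <- fit_clusters(reads, toy_region, k = 2, seed = 1)
  cents <- cm$centroids[order(cm$centroids[, 1]), ]
  expect_equal(cents, rbind(rep(-1, 4), rep(1, 4)))
  # assignment routes each archetype to its own cluster
  a <- assign_cluster(encode_reads(c("0000", "1111"), 4), cm)
  expect_length(unique(a), 2L)
  expect_warning(cm1 <- fit_clusters(toy_reads("0000", 10), toy_region,
                                     k = 5, seed = 1), "reducing k")
  expect_equal(cm1$k, 1L)
  expect_equal(cm1$centroids, matrix(rep(-1, 4), 1))
})

test_that("five planted pattern populations map to five distinct clusters", {
  r <- fix_panel$regions[["cg27630153"]]   # 15 CpGs
  archetypes <- c(strrep("0", 15), strrep("1", 15),
                  paste0(strrep("1", 7), strrep("0", 8)),
                  paste0(strrep("0", 7), strrep("1", 8)),
                  paste0(strrep("10", 7), "1"))
  pops <- do.call(rbind, lapply(seq_along(archetypes), function(i) {
    prof <- structure(list(cg27630153 = abs(as.numeric(
      strsplit(archetypes[i], "")[[1]]) - 0.01)), class = "clone_profile")
    simulate_reads(prof, r, 400, sample_id = "S1", seed = 40 + i)
  }))
  pops <- collapse_patterns(pops)
  cm <- fit_clusters(pops, r, k = 5, seed = 2)
  assigned <- assign_cluster(encode_reads(archetypes, 15), cm)
  expect_equal(sort(assigned), 1:5)   # one cluster per planted population
})

test_that("autoencoder reconstructs a homogeneous cluster and its
           threshold bounds the training flag rate", {
  reads <- toy_reads(strrep("0", 4), 1000)
  ae <- train_autoencoder(reads, toy_region, seed = 1)
  expect_lt(ae$final_loss, 0.01)
  losses <- ae_read_loss(ae, encode_reads(reads$pattern, 4))
  expect_lte(sum(reads$count[losses > ae$loss_threshold]) /
               sum(reads$count), 0.01)
  # complement of everything seen in training reconstructs badly
  expect_gt(ae_read_loss(ae, encode_reads("1111", 4)), ae$loss_threshold)
  ae2 <- train_autoencoder(reads, toy_region, seed = 1)
  expect_identical(ae2$loss_threshold, ae$loss_threshold)
  expect_identical(ae2$params, ae$params)
})

test_that("training flag rate stays at or below one percent on noisy
           control reads", {
  r <- fix_panel$regions[["cg15289427"]]
  reads <- simulate_reads(fix_normal, r, 20000, seed = 9)
  ae <- train_autoencoder(reads, r, seed = 2)
  flagged <- sum(reads$count[ae_read_loss(ae, encode_reads(reads$pattern,
                                                           14)) >
                               ae$loss_threshold])
  expect_lte(flagged / sum(reads$count), 0.01)
})

test_that("k = 1 clustering variant classifies identically to the
           no-clustering variant", {
  ctrl <- simulate_cohort(fix_normal, fix_aberrant, fix_panel,
                          n_samples = 6, fraction = 0,
                          reads_per_region = 200, seed = 55)
  m_plain <- train_ae_model(ctrl, fix_panel, k = 1, epochs = 800, seed = 3)
  m_k1 <- m_plain
  for (rid in names(m_k1$regions)) {
    rr <- ctrl[ctrl$region_id == rid, ]
    m_k1$regions[[rid]]$cluster_model <-
      fit_clusters(rr, fix_panel$regions[[rid]], k = 1, seed = 3)
  }
  test <- simulate_sample(fix_normal, fix_aberrant, fix_panel,
                          fraction = 0.3, reads_per_region = 400,
                          sample_id = "T", seed = 56)
  for (rid in names(fix_panel$regions)) {
    tr <- test[test$region_id == rid, ]
    expect_identical(classify_region_reads(m_k1, rid, tr),
                     classify_region_reads(m_plain, rid, tr))
  }
})

test_that("reads far from all training patterns are abnormal, training
           archetype reads normal", {
  r <- fix_panel$regions[["cg22797031"]]
  ctrl <- simulate_reads(fix_normal, r, 5000, seed = 12)
  m <- train_ae_model(ctrl, region_panel(list(r)), k = 1, seed = 4)
  archetype <- strrep("0", 10)            # healthy state: unmethylated
  complement <- strrep("1", 10)
  labels <- classify_region_reads(m, "cg22797031",
                                  toy_reads(c(archetype, complement),
                                            c(1, 1), region_id =
                                              "cg22797031"))
  expect_equal(labels, c("normal", "abnormal"))
})
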