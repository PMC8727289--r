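make_bm <- function(ctrl_rows, aml_rows = NULL) {
  n_ctrl <- ncol(ctrl_rows)
  if (is.null(aml_rows)) aml_rows <- ctrl_rows
  values <- cbind(ctrl_rows, aml_rows)
  colnames(values) <- c(paste0("c", seq_len(n_ctrl)),
                        paste0("a", seq_len(ncol(aml_rows))))
  beta_matrix(values, stats::setNames(
    rep(c("control", "aml"), c(n_ctrl, ncol(aml_rows))), colnames(values)))
}

test_that("invariant-CpG filter applies mean and s.d. thresholds", {
  ctrl <- rbind(cg_low = c(0.04, 0.06, 0.05, 0.05),    # mean .05, sd .008
                cg_mid = c(0.5, 0.5, 0.5, 0.5),        # mean not extreme
                cg_var = c(0.99, 0.85, 0.99, 0.85))    # mean .92, sd .081
  bm <- make_bm(ctrl)
  expect_equal(mean(ctrl["cg_low", ]), 0.05)
  expect_lt(sd(ctrl["cg_low", ]), 0.01)
  expect_gt(sd(ctrl["cg_var", ]), 0.05)
  kept <- filter_invariant_cpgs(bm)
  expect_equal(as.character(kept), "cg_low")
})

test_that("CpGs with fewer than two control values are excluded, reported", {
  ctrl <- rbind(cg_ok = c(0.05, 0.05, 0.04),
                cg_na = c(0.05, NA, NA))
  bm <- make_bm(ctrl)
  kept <- filter_invariant_cpgs(bm)
  expect_equal(as.character(kept), "cg_ok")
  expect_equal(attr(kept, "excluded_low_n"), "cg_na")
})

test_that("ranking orders by delta within direction and breaks ties by id", {
  ctrl <- rbind(cgA = rep(0.05, 4), cgB = rep(0.05, 4),
                cgC = rep(0.95, 4), cgD = rep(0.05, 4),
                cgE = rep(0.05, 4))
  aml <- rbind(cgA = rep(0.65, 4), cgB = rep(0.25, 4),
               cgC = rep(0.45, 4), cgD = rep(0.45, 4),
               cgE = rep(0.45, 4))
  bm <- make_bm(ctrl, aml)
  cs <- rank_and_select(bm, rownames(ctrl),
                        selection_criteria(top_k = 2))
  expect_equal(cs$hyper, c("cgA", "cgD"))  # +0.6 first; tie +0.4 -> cgD < cgE
  expect_equal(cs$hypo, "cgC")
  expect_warning(empty <- rank_and_select(bm, character(0)), "empty")
  expect_length(empty$hyper, 0)
})

test_that("intersection is a set intersection, order-invariant", {
  mk <- function(hyper, hypo = character(0)) {
    structure(list(hyper = hyper, hypo = hypo,
                   delta = stats::setNames(rep(0.5, length(c(hyper, hypo))),
                                           c(hyper, hypo))),
              class = "candidate_set")
  }
  sets <- list(mk(c("a", "b", "c")), mk(c("b", "c", "d")), mk(c("c", "b")))
  expect_setequal(intersect_candidates(sets)$hyper, c("b", "c"))
  expect_equal(sort(intersect_candidates(rev(sets))$hyper),
               sort(intersect_candidates(sets)$hyper))
  expect_length(intersect_candidates(list(mk("a"), mk("b")))$hyper, 0)
})

test_that("planted CpGs are recovered from synthetic matrices", {
  sim <- simulate_beta_matrix(n_null = 480, n_planted_hyper = 20,
                              n_planted_hypo = 0, n_controls = 50,
                              n_aml = 20, effect = 0.7, noise_sd = 0.03,
                              seed = 7)
  kept <- filter_invariant_cpgs(sim$matrix)
  cs <- rank_and_select(sim$matrix, kept)
  expect_true(all(sim$planted_hyper %in% cs$hyper))
})

test_that("a CpG planted in all study pairs survives intersection; one in
           only some pairs does not", {
  sims <- lapply(1:3, function(s)
    simulate_beta_matrix(n_null = 100, n_planted_hyper = 5,
                         n_planted_hypo = 5, n_controls = 50, n_aml = 20,
                         effect = 0.6, seed = s))
  sets <- lapply(sims, function(sim)
    rank_and_select(sim$matrix, filter_invariant_cpgs(sim$matrix),
                    selection_criteria(top_k = 100)))
  consensus <- intersect_candidates(sets)
  planted <- sims[[1]]$planted_hyper   # same ids planted in every pair
  expect_true(all(planted %in% consensus$hyper))
  # remove a planted CpG from one pair's list: it must drop out
  sets2 <- sets
  sets2[[2]]$hyper <- setdiff(sets2[[2]]$hyper, planted[1])
  expect_false(planted[1] %in% intersect_candidates(sets2)$hyper)
  expect_true(all(planted[-1] %in% intersect_candidates(sets2)$hyper))
})

test_that("filter decisions match a brute-force oracle", {
  sim <- simulate_beta_matrix(n_null = 200, n_planted_hyper = 5,
                              n_planted_hypo = 5, n_controls = 30,
                              n_aml = 10, effect = 0.5, seed = 11)
  bm <- sim$matrix
  crit <- selection_criteria()
  kept <- filter_invariant_cpgs(bm, crit)
  ctrl <- group_values(bm, "control")
  for (cg in rownames(ctrl)) {
    v <- ctrl[cg, ]; v <- v[!is.na(v)]
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / (length(v) - 1))
    expect_identical(cg %in% kept,
                     (m < crit$low_bound || m > crit$high_bound) &&
                       s < crit$sd_max)
  }
})
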