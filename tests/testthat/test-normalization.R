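# Channel (sample loading) normalization and per-protein bridge correction.

test_that("channel normalization equalizes channel totals to the grand mean", {
  # two-channel toy folded into the 10-channel layout: hand arithmetic says
  # totals 100 and 200 scale by 1.5 and 0.75 to the grand mean 150
  m <- matrix(c(40, 60, 80, 120), nrow = 2,
              dimnames = list(c("P1", "P2"), c("126", "127N")))
  grand <- mean(c(100, 200))
  f <- grand / colSums(m)
  expect_equal(unname(f), c(1.5, 0.75))
  scaled <- sweep(m, 2, f, "*")
  expect_equal(unname(colSums(scaled)), c(150, 150))

  fix <- make_bridged(n = 40, seed = 2)
  normed <- channel_normalize(fix$sim$matrices)
  totals <- unlist(lapply(normed, function(x) colSums(x$intensities)))
  expect_equal(unname(totals), rep(mean(totals), 30), tolerance = 1e-12)
})

test_that("channel normalization is a fixed point on equal totals and scale invariant", {
  set.seed(4)
  mats <- lapply(stages(), function(mx) {
    m <- matrix(rexp(200), 20, 10,
                dimnames = list(sprintf("P%02d", 1:20), tmt_channels()))
    m <- sweep(m, 2, colSums(m), "/") * 1000  # all totals 1000
    reporter_matrix(mx, m)
  })
  normed <- channel_normalize(mats)
  for (i in 1:3) {
    expect_equal(normed[[i]]$intensities, mats[[i]]$intensities,
                 tolerance = 1e-12)
  }
  # doubling one multiplex rescales the grand mean only: the normalized
  # matrices change by a single global factor (4/3 here), which downstream
  # log2 differences cancel; channel totals still all equal the grand mean
  doubled <- mats
  doubled[[2]]$intensities <- 2 * doubled[[2]]$intensities
  n2 <- channel_normalize(doubled)
  for (i in 1:3) {
    expect_equal(n2[[i]]$intensities, 4 / 3 * normed[[i]]$intensities,
                 tolerance = 1e-12)
  }
  totals2 <- unlist(lapply(n2, function(x) colSums(x$intensities)))
  expect_equal(unname(totals2), rep(mean(totals2), 30), tolerance = 1e-12)
})

test_that("a zero-total channel is a named normalization error", {
  mats <- lapply(stages(), function(mx) {
    m <- matrix(1, 5, 10, dimnames = list(paste0("P", 1:5), tmt_channels()))
    reporter_matrix(mx, m)
  })
  mats[[2]]$intensities[, "127C"] <- 0
  expect_error(channel_normalize(mats), "EM.127C")
})

test_that("bridge correction applies the per-protein log2 offset", {
  # protein with bridge log2 values (10, 11, 10) across (M, EM, LM):
  # EM channels shift by -1, LM channels unshifted
  mats <- lapply(seq_along(stages()), function(i) {
    m <- matrix(2^10, 2, 10,
                dimnames = list(c("P1", "P2"), tmt_channels()))
    if (stages()[i] == "EM") m[1, "131"] <- 2^11
    reporter_matrix(stages()[i], m)
  })
  br <- bridge_correct(mats, default_design(), reference = "M")
  em_cols <- grep("^EM\\.", colnames(br$log2), value = TRUE)
  lm_cols <- grep("^LM\\.", colnames(br$log2), value = TRUE)
  expect_equal(unname(br$log2["P1", em_cols]), rep(9, 9))
  expect_equal(unname(br$log2["P1", lm_cols]), rep(10, 9))
  # identical bridges: no change at all
  expect_equal(unname(br$log2["P2", ]), rep(10, 27))
})

test_that("bridge correction errors on an unknown reference and drops zero bridges", {
  fix <- make_bridged(n = 10, seed = 3)
  mats <- channel_normalize(fix$sim$matrices)
  expect_error(bridge_correct(mats, fix$sim$design, reference = "day0"),
               "reference")
  mats[[2]]$intensities[3, "131"] <- 0
  br <- bridge_correct(mats, fix$sim$design)
  expect_equal(br$dropped, rownames(mats[[1]]$intensities)[3])
  expect_equal(nrow(br$log2), 9)
})

test_that("bridge log2 spread is zero after correction and batch terms cancel", {
  cfg <- sim_config(n_proteins = 5000, noise_sd_log2 = 0,
                    multiplex_batch_log2 = c(0.3, 1.7, -2.2), seed = 21)
  truth <- generate_ground_truth(cfg)
  sim <- simulate_multiplexes(truth, cfg)
  br <- bridge_correct(sim$matrices, sim$design)
  spread <- apply(br$bridge_log2, 1, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-9)
  # corrected sample abundances equal the truth up to the reference
  # multiplex's own (unidentifiable, global) batch constant
  ref_batch <- 0.3
  for (co in conditions()) {
    for (tp in stages()) {
      keys <- grep(paste0("^", tp, "\\.", co, "\\."), colnames(br$log2),
                   value = TRUE)
      expected <- bridgeTMT:::program_log2(truth, co, tp) + ref_batch
      for (k in keys) {
        expect_equal(unname(br$log2[, k]), expected, tolerance = 1e-9)
      }
    }
  }
})

test_that("normalize then bridge recovers planted offsets exactly under balanced loads", {
  # totals-based channel normalization assumes equal per-channel loads; a
  # load-balanced planted composition (mean linear fold change 1 at every
  # stage: 1/3 of proteins at +1, 2/3 at -1) makes the full two-layer
  # normalization recover archetype offsets exactly at noise 0
  offs <- bridgeTMT:::default_archetype_offsets()
  offs["C1_decrease", ] <- c(0, 1, 1)
  offs["C2_dip_recover", ] <- c(0, -1, -1)
  cfg <- sim_config(n_proteins = 60,
                    fractions = c(C1_decrease = 1 / 3, C2_dip_recover = 2 / 3),
                    archetype_offsets = offs,
                    noise_sd_log2 = 0, base_log2_sd = 0,
                    archetype_base_shift = c(C1_decrease = 0,
                                             C2_dip_recover = 0,
                                             C3_peak_EM = 0,
                                             C4_gradual_up = 0,
                                             C5_early_jump = 0, flat = 0),
                    multiplex_batch_log2 = c(0, 0.9, -0.4), seed = 22)
  truth <- generate_ground_truth(cfg)
  sim <- simulate_multiplexes(truth, cfg)
  br <- normalize_experiment(sim$matrices, sim$design)
  m_mean <- rowMeans(br$log2[, sample_keys(br, "untreated", "M")])
  em_mean <- rowMeans(br$log2[, sample_keys(br, "untreated", "EM")])
  lm_mean <- rowMeans(br$log2[, sample_keys(br, "untreated", "LM")])
  ord <- match(rownames(br$log2), truth$protein_id)
  expect_equal(unname(em_mean - m_mean), truth$offset_EM[ord],
               tolerance = 1e-9)
  expect_equal(unname(lm_mean - m_mean), truth$offset_LM[ord],
               tolerance = 1e-9)

  # with an unbalanced composition the ratios carry a common compositional
  # shift log2(S_M / S_EM) -- a known property of totals-based scaling
  cfg2 <- sim_config(n_proteins = 50,
                     fractions = equal_archetype_fractions(),
                     noise_sd_log2 = 0, base_log2_sd = 0, seed = 23)
  truth2 <- generate_ground_truth(cfg2)
  sim2 <- simulate_multiplexes(truth2, cfg2)
  br2 <- normalize_experiment(sim2$matrices, sim2$design)
  em2 <- rowMeans(br2$log2[, sample_keys(br2, "untreated", "EM")]) -
    rowMeans(br2$log2[, sample_keys(br2, "untreated", "M")])
  ord2 <- match(rownames(br2$log2), truth2$protein_id)
  shift <- log2(sum(2^bridgeTMT:::program_log2(truth2, "untreated", "M")) /
                  sum(2^bridgeTMT:::program_log2(truth2, "untreated", "EM")))
  expect_equal(unname(em2), truth2$offset_EM[ord2] + shift, tolerance = 1e-9)
})
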