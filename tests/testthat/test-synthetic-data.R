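test_that("the reference configuration carries the published truth surfaces", {
  cfg <- reference_study_config()
  lw <- cfg$responses$larval_weight$truth
  expect_equal(lw$estimate[lw$label == "Ph*Ru"], 14.47)
  expect_equal(lw$estimate[lw$label == "Ca"], 21.11)
  pd <- cfg$responses$pupal_dev_time$truth
  expect_equal(pd$estimate[pd$label == "Ph*Ru*[Conc]"], -3.22)
  de <- cfg$responses$deformity$truth
  expect_equal(de$estimate[de$label == "Ca*[Conc]"], -0.50)
  expect_equal(cfg$responses$deformity$transform$lambda, -2.6)
  # null responses are pure blending surfaces (no interactions)
  for (nm in c("pupal_weight", "pupation", "emergence", "survival")) {
    tr <- cfg$responses[[nm]]$truth
    expect_true(all(is.na(tr$c2)) && all(tr$a == 0))
    expect_equal(length(unique(tr$estimate)), 1)
  }
  expect_equal(cfg$n_larvae, 30)
  expect_equal(cfg$amount$low, 75)
  expect_equal(cfg$amount$high, 225)
})

test_that("continuous simulation is exact at zero noise and seeded", {
  d <- build_study_design(space5, af_ref, seed = 7)
  cfg <- reference_study_config()
  truth <- cfg$responses$larval_weight$truth
  y0 <- simulate_continuous(d, truth, 0, 0, seed = 1)
  expect_equal(y0, predict_surface(truth, d), tolerance = 1e-12)
  y1 <- simulate_continuous(d, truth, 2, 0.5, seed = 5)
  expect_identical(y1, simulate_continuous(d, truth, 2, 0.5, seed = 5))
  expect_false(identical(y1, simulate_continuous(d, truth, 2, 0.5, seed = 6)))
})

test_that("dish noise has the configured standard deviation", {
  d <- build_study_design(space5, af_ref, seed = 8)
  big <- d[rep(seq_len(nrow(d)), 100), ] # 10^4 dishes
  big <- mixamount:::new_design(big, space5, af_ref, attr(d, "terms"))
  cfg <- reference_study_config()
  truth <- cfg$responses$larval_weight$truth
  y <- simulate_continuous(big, truth, sigma_dish = 2, sigma_block = 0, seed = 9)
  noise <- y - predict_surface(truth, big)
  expect_lt(abs(sd(noise) - 2) / 2, 0.05)
})

test_that("percentage simulation has binomial moments and bounds", {
  d <- build_study_design(space5, af_ref, seed = 10)
  big <- mixamount:::new_design(d[rep(seq_len(nrow(d)), 100), ], space5, af_ref,
                                attr(d, "terms"))
  half <- coef_table(space5, c(Ca = 50, Ph = 50, Ru = 50, ChA = 50, pCoA = 50))
  sim <- simulate_percentage(big, half, n_larvae = 30, seed = 11)
  expect_true(all(sim$count >= 0 & sim$count <= 30))
  expect_true(all(sim$percentage >= 0 & sim$percentage <= 100))
  expect_lt(abs(mean(sim$percentage) - 50), 1)
  expect_lt(abs(var(sim$percentage) - 100^2 * 0.25 / 30) / (100^2 * 0.25 / 30), 0.1)
  # chi-square goodness of fit of counts against Binomial(30, 0.5)
  obs <- table(factor(sim$count, levels = 0:30))
  p <- dbinom(0:30, 30, 0.5)
  keep <- p * length(sim$count) >= 5
  chi <- sum((obs[keep] - sum(obs[keep]) * p[keep] / sum(p[keep]))^2 /
               (sum(obs[keep]) * p[keep] / sum(p[keep])))
  expect_gt(pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.01)
  # boundary truth is clipped to 99.5%
  full <- coef_table(space5, c(Ca = 100, Ph = 100, Ru = 100, ChA = 100, pCoA = 100))
  simf <- simulate_percentage(big, full, n_larvae = 30, seed = 12)
  expect_gte(mean(simf$count), 30 * 0.994)
  expect_error(simulate_percentage(d, half, n_larvae = 0), "positive")
})

test_that("whole-study simulation is deterministic in (config, seed)", {
  cfg <- reference_study_config()
  s1 <- simulate_study(cfg, seed = 21)
  s2 <- simulate_study(cfg, seed = 21)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  s3 <- simulate_study(cfg, seed = 22)
  expect_false(identical(s1$larval_weight, s3$larval_weight))
  expect_true(all(c("larval_weight", "deformity", "pupation", "pupation_count")
                  %in% names(s1)))
  expect_true(all(s1$deformity >= 0 & s1$deformity <= 100))
  expect_true(all(s1$pupation_count <= 30))
})

test_that("end-to-end recovery is exact at zero noise", {
  cfg <- reference_study_config()
  cfg$responses$larval_weight$sigma_dish <- 0
  cfg$responses$larval_weight$sigma_block <- 0
  rec <- end_to_end_recovery(cfg, "larval_weight", n_replicates = 2, seed = 31)
  expect_true(all(rec$replicates$all_true_retained))
  expect_true(all(rec$replicates$max_abs_error < 1e-6))
  # any term surviving on numerical noise alone has a numerically zero estimate
  truth <- cfg$responses$larval_weight$truth
  d <- rec$design
  y0 <- simulate_continuous(d, truth, 0, 0, seed = 1)
  red <- backward_eliminate(fit_rsm(d, y0, enumerate_terms(space5, 2, 1)))
  false_kept <- !(red$terms$label %in% truth$label)
  expect_true(all(abs(red$coef[false_kept]) < 1e-6))
})
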