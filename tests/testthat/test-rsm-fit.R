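test_that("noiseless surfaces are recovered exactly", {
  d <- small_design(q = 3, n_rep = 4, n_blocks = 2, seed = 1)
  tt <- attr(d, "terms")
  truth <- tt
  truth$estimate <- c(2, -1, 3, 1.5, 0.5, -2, 4, 1, 0, -0.5, 2, 0.25)[seq_len(nrow(tt))]
  y <- predict_surface(truth, d)
  f <- fit_rsm(d, y, tt)
  expect_equal(unname(f$coef), truth$estimate, tolerance = 1e-8)
  expect_equal(unname(f$block_effects), rep(0, f$n_blocks), tolerance = 1e-8)
  expect_equal(r2_stats(f)$r.squared, 1, tolerance = 1e-10)
  an <- anova_rsm(f)
  expect_equal(an$sumsq[an$source == "Lack of fit"], 0, tolerance = 1e-12)
  # residuals orthogonal to model columns
  X <- build_model_matrix(d, tt)
  expect_true(all(abs(crossprod(X, f$residuals)) < 1e-8))
})

test_that("a constant response loads the blending coefficients only", {
  d <- small_design(q = 3, n_rep = 3, n_blocks = 1, seed = 2)
  f <- fit_rsm(d, rep(7, nrow(d)), attr(d, "terms"))
  lin <- is.na(f$terms$c2) & f$terms$a == 0
  expect_equal(unname(f$coef[lin]), rep(7, sum(lin)), tolerance = 1e-8)
  expect_equal(unname(f$coef[!lin]), rep(0, sum(!lin)), tolerance = 1e-8)
})

test_that("fit predictions reproduce fitted values at design points", {
  d <- small_design(q = 3, n_rep = 4, n_blocks = 2, seed = 3)
  y <- withr::with_seed(4, rnorm(nrow(d), 5))
  f <- fit_rsm(d, y)
  expect_equal(predict(f, d, include_blocks = TRUE),
               unname(fitted(f$lm)), tolerance = 1e-10)
})

test_that("rank-deficient crossings are rejected with the columns named", {
  d <- small_design(q = 3, n_rep = 2, n_blocks = 1, seed = 5)
  tt <- attr(d, "terms")
  tt2 <- dplyr::bind_rows(tt, tt[3, ]) # duplicated column
  tt2$label[nrow(tt2)] <- "dup"
  expect_error(fit_rsm(d, rnorm(nrow(d)), tt2), "dup")
})

test_that("partial F of a single term equals its drop-one SS test", {
  d <- small_design(q = 3, n_rep = 5, n_blocks = 2, seed = 6)
  tt <- attr(d, "terms")
  y <- withr::with_seed(7, rnorm(nrow(d), 10, 2))
  f <- fit_rsm(d, y, tt)
  an <- anova_rsm(f)
  k <- which(tt$label == "A*B")
  f_red <- fit_rsm(d, y, tt[-k, ])
  f_drop <- (sum(f_red$residuals^2) - sum(f$residuals^2)) / f$sigma2
  expect_equal(an$statistic[an$source == "A*B"], f_drop, tolerance = 1e-8)
})

test_that("linear mixture F tests equality of blending coefficients", {
  d <- small_design(q = 3, n_rep = 5, n_blocks = 2, seed = 8)
  tt <- attr(d, "terms")
  truth <- tt
  truth$estimate <- ifelse(is.na(tt$c2) & tt$a == 0, 5, 0) # equal blending
  y <- predict_surface(truth, d)
  f <- fit_rsm(d, y, tt)
  lmx <- anova_rsm(f)
  expect_equal(lmx$sumsq[lmx$source == "Linear mixture"], 0, tolerance = 1e-8)
})

test_that("sequential model SS telescopes upward over orders", {
  d <- build_study_design(space5, af_ref, seed = 2)
  y <- withr::with_seed(9, rnorm(100, 20, 2))
  sel <- select_model_order(d, y)
  fits <- attr(sel, "fits")
  sse <- vapply(fits, function(f) sum(f$residuals^2), numeric(1))
  expect_true(all(diff(sse) < 1e-8)) # SSE non-increasing => model SS non-decreasing
})

test_that("order selection finds the true order under strong signal", {
  d <- build_study_design(space5, af_ref, seed = 3)
  cfg <- reference_study_config()
  truth <- cfg$responses$larval_weight$truth
  hits <- vapply(1:60, function(k) {
    y <- simulate_continuous(d, truth, sigma_dish = 0.5, seed = 100 + k)
    sel <- select_model_order(d, y)
    ch <- sel[sel$chosen, ]
    ch$mixture_order == 2 && ch$amount_order == 1
  }, logical(1))
  # the rule itself steps past the true order with probability ~ alpha, so the
  # hit rate is bounded by ~1 - alpha; assert comfortably below that
  expect_gte(mean(hits), 0.88)
  # pure linear blend -> linear model chosen most of the time
  lin_truth <- coef_table(space5, c(Ca = 10, Ph = 14, Ru = 18, ChA = 22, pCoA = 26))
  lin_hits <- vapply(1:20, function(k) {
    y <- simulate_continuous(d, lin_truth, sigma_dish = 1, seed = 200 + k)
    sel <- select_model_order(d, y)
    sel$mixture_order[sel$chosen] == 1
  }, logical(1))
  expect_gte(mean(lin_hits), 0.8)
})

test_that("backward elimination respects alpha_out and protected terms", {
  d <- build_study_design(space5, af_ref, seed = 4)
  cfg <- reference_study_config()
  truth <- cfg$responses$larval_weight$truth
  y <- simulate_continuous(d, truth, sigma_dish = 2, seed = 11)
  f <- fit_rsm(d, y, enumerate_terms(space5, 2, 1))
  # alpha_out = 1 is the identity
  expect_equal(nrow(backward_eliminate(f, alpha_out = 1)$terms), nrow(f$terms))
  red <- backward_eliminate(f, alpha_out = 0.10)
  lin <- is.na(red$terms$c2) & red$terms$a == 0
  expect_equal(sum(lin), 5) # blending terms never removed
  el <- attr(red, "elimination")
  expect_true(all(el$p.value > 0.10))
  # removals are one per round, worst first
  expect_equal(el$step, seq_len(nrow(el)))
})

test_that("null interactions are mostly eliminated under low noise", {
  d <- build_study_design(space5, af_ref, seed = 5)
  lin_truth <- coef_table(space5, c(Ca = 10, Ph = 12, Ru = 14, ChA = 16, pCoA = 18))
  kept_null <- vapply(1:20, function(k) {
    y <- simulate_continuous(d, lin_truth, sigma_dish = 0.5, seed = 300 + k)
    f <- fit_rsm(d, y, enumerate_terms(space5, 2, 1))
    red <- backward_eliminate(f, alpha_out = 0.10)
    nrow(red$terms) - 5L
  }, integer(1))
  # a null term survives elimination with probability ~ alpha_out; with 25
  # null terms the average survivor count is ~2.5
  expect_lte(mean(kept_null) / 25, 0.2)
  expect_gte(mean(kept_null == 0), 0.05)
})

test_that("PRESS matches brute-force leave-one-out refitting", {
  d <- small_design(q = 3, n_rep = 6, n_blocks = 2, seed = 10)
  y <- withr::with_seed(12, rnorm(nrow(d), 10, 2))
  f <- fit_rsm(d, y)
  expect_equal(r2_stats(f)$press, deletion_oracle(f)$press, tolerance = 1e-8)
})

test_that("R-squared family is ordered and exact fits give all ones", {
  d <- small_design(q = 3, n_rep = 4, n_blocks = 2, seed = 13)
  tt <- attr(d, "terms")
  truth <- tt; truth$estimate <- seq_len(nrow(tt))
  f0 <- fit_rsm(d, predict_surface(truth, d), tt)
  r0 <- r2_stats(f0)
  expect_equal(unlist(r0[, 1:3], use.names = FALSE), c(1, 1, 1), tolerance = 1e-8)
  set.seed(14)
  for (k in 1:25) {
    y <- rnorm(nrow(d), 10, 1 + k / 10)
    r <- r2_stats(fit_rsm(d, y, tt))
    expect_lte(r$adj.r.squared, r$r.squared + 1e-10)
    expect_lte(r$pred.r.squared, r$adj.r.squared + 1e-10)
  }
})

test_that("tidy, glance and augment expose broom-shaped summaries", {
  d <- small_design(q = 3, n_rep = 4, n_blocks = 2, seed = 15)
  y <- withr::with_seed(16, rnorm(nrow(d), 8))
  f <- fit_rsm(d, y)
  td <- tidy(f)
  expect_true(all(c("term", "type", "estimate", "std.error", "p.value") %in% names(td)))
  expect_equal(nrow(td), nrow(f$terms) + f$n_blocks - 1)
  g <- glance(f)
  expect_equal(g$nobs, nrow(d))
  expect_true(g$df.residual > 0)
  au <- augment(f)
  expect_equal(au$.resid, f$residuals)
  expect_equal(sum(au$.hat), f$p, tolerance = 1e-8)
})
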