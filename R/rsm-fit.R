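#' Fit a crossed Scheffe mixture-amount model
#'
#' No-intercept least squares on the Scheffe basis (the blending constraint
#' absorbs the intercept) plus fixed block effects in sum-to-zero coding.
#' Blocks are estimated but never tested or removed.
#'
#' @param design A `mix_design` (optionally carrying response columns, e.g.
#'   from [simulate_study()]).
#' @param y Response: a column name in `design` or a numeric vector of length
#'   `nrow(design)`.
#' @param terms `scheffe_terms` term set; defaults to the design's own.
#' @return An object of class `rsm_fit`. Supports [tidy()][generics::tidy],
#'   [glance()][generics::glance], [augment()][generics::augment],
#'   [predict()][predict.rsm_fit] and [anova_rsm()].
#' @export
fit_rsm <- function(design, y, terms = NULL) {
  terms <- terms %||% attr(design, "terms")
  if (is.null(terms)) stop("a term set is required", call. = FALSE)
  y_name <- NULL
  if (is.character(y) && length(y) == 1) {
    y_name <- y
    if (!y %in% names(design)) stop("no response column `", y, "`", call. = FALSE)
    y <- design[[y]]
  }
  y <- as.numeric(y)
  n <- nrow(design)
  if (length(y) != n) stop("response length must equal the run count", call. = FALSE)

  X <- build_model_matrix(design, terms)
  blk <- design$block
  nb <- if (all(is.na(blk))) 1L else dplyr::n_distinct(blk[!is.na(blk)])
  if (nb > 1) {
    f <- factor(blk)
    B <- stats::model.matrix(~f, contrasts.arg = list(f = "contr.sum"))[, -1, drop = FALSE]
    colnames(B) <- paste0("block_", seq_len(nb - 1))
    Z <- cbind(X, B)
  } else {
    Z <- X
  }
  dat <- data.frame(.y = y)
  dat$.Z <- Z
  fm <- stats::lm(.y ~ 0 + .Z, data = dat)
  cf <- stats::coef(fm)
  names(cf) <- colnames(Z)
  if (anyNA(cf)) {
    stop("rank-deficient model matrix; aliased columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  block_effects <- if (nb > 1) {
    g <- cf[seq(nrow(terms) + 1, length(cf))]
    stats::setNames(c(g, -sum(g)), paste0("block", sort(unique(blk))))
  } else {
    numeric(0)
  }
  structure(list(
    lm = fm, terms = terms, design = design, response = y_name, y = y,
    n = n, n_blocks = nb, p = ncol(Z),
    coef = cf[seq_len(nrow(terms))],
    block_effects = block_effects,
    sigma2 = stats::sigma(fm)^2,
    df_residual = stats::df.residual(fm),
    hat = unname(stats::hatvalues(fm)),
    residuals = unname(stats::residuals(fm))
  ), class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("<rsm_fit> %s: %d terms + %d block df, n = %d, sigma = %.4g\n",
              x$response %||% "response", nrow(x$terms), x$n_blocks - 1, x$n,
              sqrt(x$sigma2)))
  invisible(x)
}

# block-corrected total SS and df (SS of y after mean + block effects)
total_ss <- function(fit) {
  blk <- fit$design$block
  if (fit$n_blocks > 1) {
    f0 <- stats::lm(fit$y ~ factor(blk))
  } else {
    f0 <- stats::lm(fit$y ~ 1)
  }
  list(ss = sum(stats::residuals(f0)^2), df = fit$n - fit$n_blocks)
}

# pure-error SS from the block + distinct-point saturated model; df by the
# residual-remainder convention (see df_partition)
pure_error <- function(fit) {
  id <- distinct_point_id(fit$design)
  ndist <- dplyr::n_distinct(id)
  lof_df <- ndist - nrow(fit$terms)
  pe_df <- fit$df_residual - lof_df
  if (fit$n == ndist) {
    return(list(ss = 0, df = 0, lof_df = lof_df, available = FALSE))
  }
  blk <- fit$design$block
  sat <- if (fit$n_blocks > 1) {
    stats::lm(fit$y ~ factor(blk) + factor(id))
  } else {
    stats::lm(fit$y ~ factor(id))
  }
  list(ss = sum(stats::residuals(sat)^2), df = pe_df, lof_df = lof_df,
       available = pe_df > 0)
}

# lack-of-fit F with guards for numerically-exact fits: when both the LOF and
# pure-error SS are rounding noise the test is unavailable; a real LOF signal
# over zero pure error is infinitely significant
lof_test <- function(sse, pe, y) {
  eps <- 1e-12 * (mean(y^2) + 1)
  if (!pe$available || pe$lof_df <= 0) {
    return(list(ss = NA_real_, f = NA_real_, p = NA_real_))
  }
  lof_ss <- max(sse - pe$ss, 0)
  if (pe$ss <= eps) {
    if (lof_ss <= eps) return(list(ss = lof_ss, f = NA_real_, p = NA_real_))
    return(list(ss = lof_ss, f = Inf, p = 0))
  }
  f <- (lof_ss / pe$lof_df) / (pe$ss / pe$df)
  list(ss = lof_ss, f = f,
       p = stats::pf(f, pe$lof_df, pe$df, lower.tail = FALSE))
}

# coefficient matrix without summary.lm's exact-fit warning (exact fits are a
# supported case here)
coef_summary <- function(fit) {
  suppressWarnings(summary(fit$lm)$coefficients)
}

linear_mixture_test <- function(fit) {
  lin <- which(is.na(fit$terms$c2) & fit$terms$a == 0)
  if (length(lin) < 2) return(NULL)
  p_all <- fit$p
  Cm <- matrix(0, length(lin) - 1, p_all)
  for (j in seq_len(length(lin) - 1)) {
    Cm[j, lin[1]] <- 1
    Cm[j, lin[j + 1]] <- -1
  }
  b <- stats::coef(fit$lm)
  V <- suppressWarnings(stats::vcov(fit$lm)) # exact fits are supported
  cb <- drop(Cm %*% b)
  ss <- as.numeric(crossprod(cb, solve(Cm %*% V %*% t(Cm), cb))) * fit$sigma2
  df <- length(lin) - 1
  f <- (ss / df) / fit$sigma2
  list(ss = ss, df = df, f = f,
       p = stats::pf(f, df, fit$df_residual, lower.tail = FALSE))
}

#' Mixture-convention ANOVA for an `rsm_fit`
#'
#' Produces the standard response-surface ANOVA for a blocked mixture model:
#' a Model row (model df = terms - 1), a joint Linear Mixture row testing
#' equality of the blending coefficients (q - 1 contrasts, after block
#' adjustment), a partial (Type-III) F row per non-linear term, Residual, and
#' the Lack of Fit / Pure Error split with F = MS_LOF / MS_PE. Total SS is
#' block-corrected.
#'
#' @param fit An [fit_rsm()] result.
#' @return A tibble with columns `source`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`; attribute `"r2"` holds [r2_stats()] and
#'   `"lof_available"` whether a pure-error estimate exists.
#' @export
anova_rsm <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  tot <- total_ss(fit)
  sse <- sum(fit$residuals^2)
  ms_res <- fit$sigma2
  model_ss <- tot$ss - sse
  model_df <- nrow(fit$terms) - 1
  rows <- list(tibble::tibble(
    source = "Model", df = model_df, sumsq = model_ss,
    meansq = model_ss / model_df,
    statistic = (model_ss / model_df) / ms_res,
    p.value = stats::pf((model_ss / model_df) / ms_res, model_df,
                        fit$df_residual, lower.tail = FALSE)))
  lmx <- linear_mixture_test(fit)
  if (!is.null(lmx)) {
    rows$linmix <- tibble::tibble(source = "Linear mixture", df = lmx$df,
                                  sumsq = lmx$ss, meansq = lmx$ss / lmx$df,
                                  statistic = lmx$f, p.value = lmx$p)
  }
  nonlin <- which(!(is.na(fit$terms$c2) & fit$terms$a == 0))
  if (length(nonlin)) {
    sm <- coef_summary(fit)
    fv <- unname(sm[nonlin, 3]^2)
    rows$terms <- tibble::tibble(
      source = fit$terms$label[nonlin], df = 1, sumsq = fv * ms_res,
      meansq = fv * ms_res, statistic = fv,
      p.value = stats::pf(fv, 1, fit$df_residual, lower.tail = FALSE))
  }
  rows$resid <- tibble::tibble(source = "Residual", df = fit$df_residual,
                               sumsq = sse, meansq = ms_res,
                               statistic = NA_real_, p.value = NA_real_)
  pe <- pure_error(fit)
  if (pe$available) {
    lt <- lof_test(sse, pe, fit$y)
    rows$lof <- tibble::tibble(
      source = "Lack of fit", df = pe$lof_df, sumsq = max(sse - pe$ss, 0),
      meansq = if (pe$lof_df > 0) max(sse - pe$ss, 0) / pe$lof_df else NA_real_,
      statistic = lt$f, p.value = lt$p)
    rows$pe <- tibble::tibble(source = "Pure error", df = pe$df, sumsq = pe$ss,
                              meansq = pe$ss / pe$df, statistic = NA_real_,
                              p.value = NA_real_)
  }
  rows$total <- tibble::tibble(source = "Total (block-corrected)", df = tot$df,
                               sumsq = tot$ss, meansq = NA_real_,
                               statistic = NA_real_, p.value = NA_real_)
  out <- dplyr::bind_rows(rows)
  attr(out, "r2") <- r2_stats(fit)
  attr(out, "lof_available") <- pe$available
  out
}

#' Multiple correlation summaries
#'
#' `R^2 = 1 - SSE/SST` with the block-corrected total SS; adjusted `R^2` uses
#' the residual df; predicted `R^2 = 1 - PRESS/SST` with PRESS from
#' leave-one-out deletion via the hat diagonal.
#'
#' @param fit An [fit_rsm()] result.
#' @return A one-row tibble: `r.squared`, `adj.r.squared`, `pred.r.squared`,
#'   `press`.
#' @export
r2_stats <- function(fit) {
  tot <- total_ss(fit)
  if (tot$ss <= 0) {
    return(tibble::tibble(r.squared = NA_real_, adj.r.squared = NA_real_,
                          pred.r.squared = NA_real_, press = NA_real_))
  }
  sse <- sum(fit$residuals^2)
  r2 <- 1 - sse / tot$ss
  adj <- if (fit$df_residual > 0) {
    1 - (sse / fit$df_residual) / (tot$ss / tot$df)
  } else NA_real_
  h <- fit$hat
  press <- if (any(h > 1 - 1e-10)) NA_real_ else sum((fit$residuals / (1 - h))^2)
  tibble::tibble(r.squared = r2, adj.r.squared = adj,
                 pred.r.squared = 1 - press / tot$ss, press = press)
}

order_ladder <- function(max_mixture_order, max_amount_order) {
  steps <- list(c(1L, min(1L, max_amount_order)))
  if (max_mixture_order >= 2) steps <- c(steps, list(c(2L, min(1L, max_amount_order))))
  if (max_amount_order >= 2) {
    m <- min(2L, max_mixture_order)
    steps <- c(steps, list(c(m, max_amount_order)))
  }
  unique(steps)
}

#' Select the polynomial model order
#'
#' Walks a nested ladder of crossed orders upward from linear mixture x
#' linear amount, computing the sequential F test for each block of added
#' terms and the lack-of-fit test of each model. The chosen order is the
#' highest whose added terms are jointly significant (`p < alpha`) and whose
#' lack-of-fit p-value is at least `alpha`; if no order qualifies the lowest
#' is returned with attribute `fallback = TRUE`.
#'
#' @param design A `mix_design`.
#' @param y Response column name or vector.
#' @param max_mixture_order,max_amount_order Upper bounds of the ladder.
#' @param alpha Significance level for both tests.
#' @param amount_name Amount label used in term labels.
#' @return A tibble trace (one row per candidate order) with columns
#'   `mixture_order`, `amount_order`, `n_terms`, `added_df`, `seq_f`, `seq_p`,
#'   `lof_f`, `lof_p`, `chosen`; attributes `chosen_fit` (the winning
#'   `rsm_fit`) and `fits`.
#' @export
select_model_order <- function(design, y, max_mixture_order = 2,
                               max_amount_order = 2, alpha = 0.05,
                               amount_name = "Conc") {
  sp <- design_space(design)
  ladder <- order_ladder(max_mixture_order, max_amount_order)
  fits <- lapply(ladder, function(o) {
    fit_rsm(design, y, enumerate_terms(sp, o[1], o[2], amount_name = amount_name))
  })
  base_df <- total_ss(fits[[1]])$df
  base_ss <- total_ss(fits[[1]])$ss
  eps <- 1e-12 * (mean(fits[[1]]$y^2) + 1)
  rows <- purrr::map_dfr(seq_along(ladder), function(k) {
    f <- fits[[k]]
    sse <- sum(f$residuals^2)
    prev_sse <- if (k == 1) base_ss else sum(fits[[k - 1]]$residuals^2)
    prev_df <- if (k == 1) base_df else fits[[k - 1]]$df_residual
    added_df <- prev_df - f$df_residual
    gain <- prev_sse - sse
    seq_f <- if (gain <= eps) 0 else if (f$sigma2 <= eps) Inf else
      (gain / added_df) / f$sigma2
    lt <- lof_test(sse, pure_error(f), f$y)
    tibble::tibble(
      mixture_order = ladder[[k]][1], amount_order = ladder[[k]][2],
      n_terms = nrow(f$terms), added_df = added_df, seq_f = seq_f,
      seq_p = stats::pf(seq_f, added_df, f$df_residual, lower.tail = FALSE),
      lof_f = lt$f, lof_p = lt$p)
  })
  ok <- rows$seq_p < alpha & (is.na(rows$lof_p) | rows$lof_p >= alpha)
  chosen <- if (any(ok)) max(which(ok)) else 1L
  rows$chosen <- seq_len(nrow(rows)) == chosen
  attr(rows, "fallback") <- !any(ok)
  attr(rows, "chosen_fit") <- fits[[chosen]]
  attr(rows, "fits") <- fits
  rows
}

#' Reduce a model by backward elimination
#'
#' Iteratively refits after removing the eligible term with the largest
#' partial-F p-value exceeding `alpha_out`. Linear blending terms (and block
#' effects) are never removed when `keep_linear_mixture` is `TRUE`;
#' amount-crossed terms are eliminated independently of their mixture parents.
#'
#' @param fit An [fit_rsm()] result.
#' @param alpha_out Stay threshold; a term is dropped only if its partial
#'   p-value exceeds this. Default 0.10.
#' @param keep_linear_mixture Keep all `q` blending terms regardless of
#'   significance.
#' @return The reduced `rsm_fit`, with attribute `"elimination"`: a tibble of
#'   the removal sequence (`step`, `dropped`, `p.value`).
#' @export
backward_eliminate <- function(fit, alpha_out = 0.10, keep_linear_mixture = TRUE) {
  trace <- tibble::tibble(step = integer(), dropped = character(),
                          p.value = numeric())
  step <- 0L
  repeat {
    terms <- fit$terms
    eligible <- if (keep_linear_mixture) {
      which(!(is.na(terms$c2) & terms$a == 0))
    } else {
      seq_len(nrow(terms))
    }
    if (length(eligible) == 0) break
    sm <- coef_summary(fit)
    pvals <- sm[eligible, 4]
    pvals[is.na(pvals)] <- 1  # 0/0 t-stats from exact fits carry no signal
    worst <- which.max(pvals)
    if (pvals[worst] <= alpha_out) break
    step <- step + 1L
    drop_idx <- eligible[worst]
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step, dropped = terms$label[drop_idx], p.value = pvals[worst]))
    fit <- fit_rsm(fit$design, fit$y, terms[-drop_idx, ])
  }
  attr(fit, "elimination") <- trace
  fit
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy an `rsm_fit`
#'
#' @param x An [fit_rsm()] result.
#' @param ... Unused.
#' @return One row per model coefficient: `term`, `type` (`"blending"`,
#'   `"mixture"`, `"amount"` or `"block"`), `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy rsm_fit
#' @export
tidy.rsm_fit <- function(x, ...) {
  sm <- coef_summary(x)
  nt <- nrow(x$terms)
  type <- ifelse(is.na(x$terms$c2) & x$terms$a == 0, "blending",
                 ifelse(x$terms$a == 0, "mixture", "amount"))
  labels <- c(x$terms$label, if (x$n_blocks > 1) paste0("block_", seq_len(x$n_blocks - 1)))
  tibble::tibble(
    term = labels,
    type = c(type, rep("block", x$n_blocks - 1)),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4])
}

#' Glance at an `rsm_fit`
#'
#' @param x An [fit_rsm()] result.
#' @param ... Unused.
#' @return One-row tibble of model-level summaries including block-corrected
#'   `r.squared`, `adj.r.squared`, `pred.r.squared`, the overall model F and
#'   the lack-of-fit test.
#' @method glance rsm_fit
#' @export
glance.rsm_fit <- function(x, ...) {
  an <- anova_rsm(x)
  r2 <- attr(an, "r2")
  lof <- an[an$source == "Lack of fit", ]
  mod <- an[an$source == "Model", ]
  tibble::tibble(
    r.squared = r2$r.squared, adj.r.squared = r2$adj.r.squared,
    pred.r.squared = r2$pred.r.squared, sigma = sqrt(x$sigma2),
    statistic = mod$statistic, p.value = mod$p.value, df = mod$df,
    df.residual = x$df_residual,
    lof.statistic = if (nrow(lof)) lof$statistic else NA_real_,
    lof.p.value = if (nrow(lof)) lof$p.value else NA_real_,
    nobs = x$n)
}

#' Augment the design with per-run fit quantities
#'
#' @param x An [fit_rsm()] result.
#' @param ... Unused.
#' @return The design tibble plus `.response`, `.fitted`, `.resid`, `.hat`,
#'   `.sigma2`, `.std.resid`, `.outlier.t`, `.cooksd`.
#' @method augment rsm_fit
#' @export
augment.rsm_fit <- function(x, ...) {
  d <- tibble::as_tibble(x$design)
  d$.response <- x$y
  d$.fitted <- unname(stats::fitted(x$lm))
  d$.resid <- x$residuals
  d$.hat <- x$hat
  d$.std.resid <- unname(stats::rstandard(x$lm))
  d$.outlier.t <- unname(stats::rstudent(x$lm))
  d$.cooksd <- unname(stats::cooks.distance(x$lm))
  d
}

#' Predict from an `rsm_fit`
#'
#' Population-average surface predictions: block effects are excluded (they
#' sum to zero) unless `newdata` carries a `block` column and
#' `include_blocks = TRUE`.
#'
#' @param object An [fit_rsm()] result.
#' @param newdata Data frame with component columns and `amount` (actual
#'   units) or `amount_coded`. Defaults to the design points.
#' @param include_blocks Add the estimated block effect for `newdata$block`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rsm_fit <- function(object, newdata = NULL, include_blocks = FALSE, ...) {
  newdata <- newdata %||% object$design
  af <- design_amount(object$design)
  if (!"amount_coded" %in% names(newdata)) {
    if (!"amount" %in% names(newdata) || is.null(af)) {
      stop("newdata needs `amount_coded`, or `amount` with a known amount factor",
           call. = FALSE)
    }
    newdata$amount_coded <- code_amount(newdata$amount, af, warn = FALSE)
  }
  X <- build_model_matrix(newdata, object$terms)
  pred <- drop(X %*% object$coef)
  if (include_blocks && "block" %in% names(newdata) &&
      length(object$block_effects)) {
    be <- object$block_effects[paste0("block", newdata$block)]
    pred <- pred + ifelse(is.na(be), 0, be)
  }
  unname(pred)
}
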