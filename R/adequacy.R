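#' Studentized residuals
#'
#' Internally studentized residuals divide each raw residual by its estimated
#' standard deviation; externally studentized ("outlier-t") residuals use the
#' delete-one variance estimate and follow a t distribution under the model.
#'
#' @param fit An [fit_rsm()] result with residual df >= 2.
#' @return A tibble: `run_id`, `residual`, `leverage`, `internal`, `external`.
#'   Runs with leverage 1 get `NA` studentized values.
#' @export
studentized_residuals <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  if (fit$df_residual < 2) stop("residual df must be at least 2", call. = FALSE)
  h <- fit$hat
  if (fit$sigma2 <= 1e-16 * (mean(fit$y^2) + 1)) {
    # exact interpolation: residuals are numerically zero
    int <- ext <- rep(0, fit$n)
  } else {
    int <- unname(stats::rstandard(fit$lm))
    ext <- unname(stats::rstudent(fit$lm))
  }
  sat <- h > 1 - 1e-10
  int[sat] <- NA_real_
  ext[sat] <- NA_real_
  tibble::tibble(run_id = fit$design$run_id, residual = fit$residuals,
                 leverage = h, internal = int, external = ext)
}

#' Influence thresholds
#'
#' Conventional flag cutoffs: Cook's distance 1, `|DFFITS| > 2*sqrt(p/n)`,
#' `|DFBETAS| > 2/sqrt(n)`, `|outlier-t| > 3.5`.
#'
#' @param p,n Parameter and run counts.
#' @param cooks,outlier_t Overrides for the fixed cutoffs.
#' @return Named list of thresholds.
#' @export
influence_thresholds <- function(p, n, cooks = 1, outlier_t = 3.5) {
  list(cooks = cooks, dffits = 2 * sqrt(p / n), dfbetas = 2 / sqrt(n),
       outlier_t = outlier_t)
}

#' Per-run influence diagnostics
#'
#' Leverage, Cook's distance, DFFITS, per-coefficient DFBETAS and the
#' externally studentized residual for every run, with conventional flags
#' (see [influence_thresholds()]).
#'
#' @param fit An [fit_rsm()] result.
#' @param thresholds A list from [influence_thresholds()]; defaults computed
#'   from the fit.
#' @return A tibble with one row per run: `run_id`, `leverage`, `cooksd`,
#'   `dffits`, `outlier_t`, `dfbetas_` columns per coefficient, logical flag
#'   columns and `flagged` (any flag). Thresholds are kept in attribute
#'   `"thresholds"`.
#' @export
influence_rsm <- function(fit, thresholds = NULL) {
  stopifnot(inherits(fit, "rsm_fit"))
  thresholds <- thresholds %||% influence_thresholds(fit$p, fit$n)
  cook <- unname(stats::cooks.distance(fit$lm))
  dff <- unname(stats::dffits(fit$lm))
  dfb <- stats::dfbetas(fit$lm)
  labels <- c(fit$terms$label,
              if (fit$n_blocks > 1) paste0("block_", seq_len(fit$n_blocks - 1)))
  colnames(dfb) <- paste0("dfbetas_", labels)
  ot <- unname(stats::rstudent(fit$lm))
  out <- tibble::tibble(run_id = fit$design$run_id, leverage = fit$hat,
                        cooksd = cook, dffits = dff, outlier_t = ot)
  out <- dplyr::bind_cols(out, tibble::as_tibble(dfb))
  out$flag_cooksd <- out$cooksd > thresholds$cooks
  out$flag_dffits <- abs(out$dffits) > thresholds$dffits
  out$flag_dfbetas <- apply(abs(dfb) > thresholds$dfbetas, 1, any)
  out$flag_outlier_t <- abs(out$outlier_t) > thresholds$outlier_t
  out$flagged <- out$flag_cooksd | out$flag_dffits | out$flag_dfbetas |
    out$flag_outlier_t
  attr(out, "thresholds") <- thresholds
  out
}

#' Drop runs and refit
#'
#' The exclusion workflow for a suspect run: remove the given runs from the
#' design and response and refit the same term set once. No iterative outlier
#' hunting is performed.
#'
#' @param fit An [fit_rsm()] result.
#' @param runs Run ids to exclude.
#' @return A new `rsm_fit` on the reduced data, with attribute
#'   `"excluded_runs"`.
#' @export
refit_without <- function(fit, runs) {
  keep <- !(fit$design$run_id %in% runs)
  if (all(keep)) return(fit)
  kept_ids <- fit$design$run_id[keep]
  d <- fit$design[keep, ]
  d <- new_design(d, design_space(fit$design), design_amount(fit$design),
                  terms = attr(fit$design, "terms"))
  d$run_id <- kept_ids  # keep original run identities for reporting
  out <- fit_rsm(d, fit$y[keep], fit$terms)
  attr(out, "excluded_runs") <- runs
  out
}

#' Apply (and invert) a shifted power transformation
#'
#' The simple power family `(y + k)^lambda`, with the natural log at
#' `lambda = 0`. The shift `k` (typically 1) removes zeros before a negative
#' power.
#'
#' @param y Numeric vector; `y + k` must be positive.
#' @param lambda Power exponent.
#' @param k Shift constant.
#' @return Transformed vector.
#' @examples
#' apply_transform(7, -2.6, 1) # 8^-2.6
#' @export
apply_transform <- function(y, lambda, k = 0) {
  if (any(y + k <= 0)) {
    stop("y + k must be positive (offending positions: ",
         paste(which(y + k <= 0), collapse = ", "), ")", call. = FALSE)
  }
  if (abs(lambda) < 1e-12) log(y + k) else (y + k)^lambda
}

#' @rdname apply_transform
#' @param z Transformed values.
#' @export
inverse_transform <- function(z, lambda, k = 0) {
  if (abs(lambda) < 1e-12) exp(z) - k else z^(1 / lambda) - k
}

#' Box-Cox transformation profile
#'
#' Profile log-likelihood of the normal linear model in the Box-Cox
#' transformed response `(y + k)^(lambda)` (log at 0), including the Jacobian
#' term, maximized over a lambda grid. The ~95% confidence interval is the set
#' of grid lambdas within `qchisq(0.95, 1) / 2` of the maximum.
#'
#' @param design A `mix_design`.
#' @param y Response column name or vector.
#' @param terms Term set (defaults to the design's).
#' @param k Shift constant; `y + k` must be positive everywhere.
#' @param lambda Grid of exponents.
#' @return A tibble of class `boxcox_profile` (`lambda`, `loglik`) with
#'   attributes `best`, `ci` (length-2), `k` and `label` (a human-readable
#'   transform recommendation).
#' @export
box_cox <- function(design, y, terms = NULL, k = 0,
                    lambda = seq(-3, 3, by = 0.01)) {
  terms <- terms %||% attr(design, "terms")
  if (is.character(y) && length(y) == 1) y <- design[[y]]
  y <- as.numeric(y)
  if (any(y + k <= 0)) {
    stop("y + k must be positive for Box-Cox (offending runs: ",
         paste(which(y + k <= 0), collapse = ", "), ")", call. = FALSE)
  }
  X <- build_model_matrix(design, terms)
  blk <- design$block
  if (!all(is.na(blk)) && dplyr::n_distinct(blk[!is.na(blk)]) > 1) {
    f <- factor(blk)
    B <- stats::model.matrix(~f, contrasts.arg = list(f = "contr.sum"))[, -1, drop = FALSE]
    X <- cbind(X, B)
  }
  qrz <- qr(X)
  n <- length(y)
  ys <- y + k
  logj <- sum(log(ys))
  ll <- vapply(lambda, function(l) {
    z <- if (abs(l) < 1e-12) log(ys) else (ys^l - 1) / l
    rss <- sum(qr.resid(qrz, z)^2)
    -n / 2 * log(rss / n) + (l - 1) * logj
  }, numeric(1))
  best <- lambda[which.max(ll)]
  cut <- max(ll) - stats::qchisq(0.95, 1) / 2
  ci <- range(lambda[ll >= cut])
  label <- if (ci[1] <= 1 && 1 <= ci[2]) {
    "none required"
  } else if (ci[1] <= 0 && 0 <= ci[2]) {
    "log"
  } else {
    sprintf("power (y + %g)^%.2f", k, best)
  }
  out <- tibble::tibble(lambda = lambda, loglik = ll)
  attr(out, "best") <- best
  attr(out, "ci") <- ci
  attr(out, "k") <- k
  attr(out, "label") <- label
  class(out) <- c("boxcox_profile", class(out))
  out
}

#' @export
print.boxcox_profile <- function(x, ...) {
  cat(sprintf("<boxcox_profile> best lambda = %.2f, 95%% CI [%.2f, %.2f], k = %g: %s\n",
              attr(x, "best"), attr(x, "ci")[1], attr(x, "ci")[2],
              attr(x, "k"), attr(x, "label")))
  invisible(x)
}

#' Prediction precision ratio
#'
#' Signal-to-noise style adequacy measure: the range of the model predictions
#' at the design points divided by the average prediction standard deviation
#' `sqrt(p * sigma^2 / n)`. Values below 4 indicate the model discriminates
#' poorly over the design region.
#'
#' @param fit An [fit_rsm()] result.
#' @return A scalar; attribute `"adequate"` is `TRUE` when the ratio is at
#'   least 4. Infinite when `sigma^2 = 0`.
#' @export
precision_ratio <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  yhat <- unname(stats::fitted(fit$lm))
  rng <- max(yhat) - min(yhat)
  scale <- mean(yhat^2) + 1
  if (rng^2 <= 1e-16 * scale) {
    out <- 0
  } else if (fit$sigma2 <= 1e-16 * scale) {
    out <- Inf
  } else {
    out <- rng / sqrt(fit$p * fit$sigma2 / fit$n)
  }
  attr(out, "adequate") <- out >= 4
  out
}
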