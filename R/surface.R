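coef_from <- function(model) {
  if (inherits(model, "rsm_fit")) {
    tt <- model$terms
    tt$estimate <- unname(model$coef)
    return(tt)
  }
  if (inherits(model, "scheffe_terms") && "estimate" %in% names(model)) {
    return(model)
  }
  stop("`model` must be an rsm_fit or a coef_table()", call. = FALSE)
}

#' Evaluate a mixture-amount surface at arbitrary points
#'
#' Computes `sum(coefficient * term value)` at each point; block effects are
#' never included (the surface is population-average). Works from a fitted
#' model or directly from a hand-written coefficient table, e.g. published
#' coefficient estimates.
#'
#' @param model An [fit_rsm()] result or a [coef_table()].
#' @param points Data frame with component columns and `amount` (actual) or
#'   `amount_coded`.
#' @param amount_factor Needed to code `amount` when `model` is a coefficient
#'   table.
#' @return Numeric vector of predictions.
#' @examples
#' sp <- component_space(c("A", "B"))
#' m <- coef_table(sp, c(A = 1, B = 3, "A*B" = -4))
#' predict_surface(m, data.frame(A = 0.5, B = 0.5, amount_coded = 0))
#' @export
predict_surface <- function(model, points, amount_factor = NULL) {
  coefs <- coef_from(model)
  af <- amount_factor %||%
    (if (inherits(model, "rsm_fit")) design_amount(model$design) else NULL)
  if (!"amount_coded" %in% names(points)) {
    if ("amount" %in% names(points) && !is.null(af)) {
      points$amount_coded <- code_amount(points$amount, af, warn = FALSE)
    } else if (any(coefs$a > 0)) {
      stop("points need `amount_coded`, or `amount` plus an amount factor",
           call. = FALSE)
    }
  }
  X <- build_model_matrix(points, coefs)
  drop(X %*% coefs$estimate)
}

#' Binary-blend x amount slice of a response surface
#'
#' Sweeps the blend fraction `t` between two named components (proportions
#' `t` on the first, `1 - t` on the second, all others zero) against the
#' actual amount, evaluating the surface on the grid. This is the slice
#' geometry behind two-component contour displays.
#'
#' @param model An [fit_rsm()] result or [coef_table()].
#' @param pair Character vector of two distinct component names.
#' @param amount_factor Amount factor defining the swept range (defaults to
#'   the fit's).
#' @param n_frac,n_amount Grid resolution per axis (>= 2).
#' @return A tibble of class `surface_grid`: `frac_a` (fraction of
#'   `pair[1]`), `amount`, `.pred`; attributes `pair` and `response`.
#' @export
slice_grid <- function(model, pair, amount_factor = NULL, n_frac = 26,
                       n_amount = 26) {
  coefs <- coef_from(model)
  sp <- attr(coefs, "space")
  af <- amount_factor %||%
    (if (inherits(model, "rsm_fit")) design_amount(model$design) else NULL)
  if (is.null(af)) stop("an amount factor is required", call. = FALSE)
  if (length(pair) != 2 || pair[1] == pair[2] || !all(pair %in% sp$names)) {
    stop("`pair` must name two distinct components", call. = FALSE)
  }
  if (n_frac < 2 || n_amount < 2) stop("resolution must be at least 2", call. = FALSE)
  grid <- tidyr::crossing(frac_a = seq(0, 1, length.out = n_frac),
                          amount = seq(af$low, af$high, length.out = n_amount))
  pts <- tibble::as_tibble(matrix(0, nrow(grid), sp$q, dimnames = list(NULL, sp$names)))
  pts[[pair[1]]] <- grid$frac_a
  pts[[pair[2]]] <- 1 - grid$frac_a
  pts$amount <- grid$amount
  grid$.pred <- predict_surface(coefs, pts, amount_factor = af)
  attr(grid, "pair") <- pair
  attr(grid, "response") <- if (inherits(model, "rsm_fit")) model$response else NULL
  class(grid) <- c("surface_grid", class(grid))
  grid
}

#' Grid-search extremum of a surface
#'
#' Deterministic search over a simplex lattice crossed with an amount grid;
#' ties broken by lexicographic point order (component columns, then amount).
#'
#' @param model An [fit_rsm()] result or [coef_table()].
#' @param amount_factor Amount factor (defaults to the fit's).
#' @param sense `"max"` or `"min"`.
#' @param resolution Lattice degree along each axis (>= 11 recommended):
#'   proportions move in steps of `1/(resolution - 1)` and the amount grid has
#'   `resolution` levels.
#' @return One-row tibble: component proportions, `amount`, `value`.
#' @export
find_extremum <- function(model, amount_factor = NULL, sense = c("max", "min"),
                          resolution = 11) {
  sense <- match.arg(sense)
  coefs <- coef_from(model)
  sp <- attr(coefs, "space")
  af <- amount_factor %||%
    (if (inherits(model, "rsm_fit")) design_amount(model$design) else NULL)
  lat <- simplex_lattice(sp$q, resolution - 1)
  colnames(lat) <- sp$names
  pts <- tibble::as_tibble(lat)
  need_amount <- any(coefs$a > 0)
  amounts <- if (need_amount || !is.null(af)) {
    if (is.null(af)) stop("an amount factor is required", call. = FALSE)
    seq(af$low, af$high, length.out = resolution)
  } else 0
  grid <- tidyr::crossing(pts, amount = amounts)
  grid$amount_coded <- if (!is.null(af)) code_amount(grid$amount, af, warn = FALSE) else 0
  grid <- dplyr::arrange(grid, dplyr::across(dplyr::all_of(c(sp$names, "amount"))))
  v <- predict_surface(coefs, grid, amount_factor = af)
  i <- if (sense == "max") which.max(v) else which.min(v)
  out <- grid[i, c(sp$names, "amount")]
  out$value <- v[i]
  out
}

#' Plot a surface slice grid
#'
#' Filled contour display of a [slice_grid()]: blend fraction on the x axis,
#' actual amount on the y axis.
#'
#' @param object A `surface_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot surface_grid
#' @export
autoplot.surface_grid <- function(object, ...) {
  pair <- attr(object, "pair")
  ggplot2::ggplot(object, ggplot2::aes(.data$frac_a, .data$amount, z = .data$.pred)) +
    ggplot2::geom_contour_filled() +
    ggplot2::labs(
      x = sprintf("fraction %s (1 - fraction %s)", pair[1], pair[2]),
      y = "amount", fill = attr(object, "response") %||% "prediction")
}

#' Plot a Box-Cox profile
#'
#' Profile log-likelihood against lambda with the best value and ~95% CI.
#'
#' @param object A [box_cox()] profile.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot boxcox_profile
#' @export
autoplot.boxcox_profile <- function(object, ...) {
  ci <- attr(object, "ci")
  ggplot2::ggplot(object, ggplot2::aes(.data$lambda, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "best"), linetype = 2) +
    ggplot2::geom_vline(xintercept = ci, linetype = 3) +
    ggplot2::labs(x = "lambda", y = "profile log-likelihood")
}

#' Diagnostic panels for an `rsm_fit`
#'
#' Residuals against fitted values and a normal quantile plot of the
#' externally studentized residuals.
#'
#' @param object An [fit_rsm()] result.
#' @param ... Unused.
#' @return A ggplot (faceted).
#' @method autoplot rsm_fit
#' @export
autoplot.rsm_fit <- function(object, ...) {
  a <- augment(object)
  long <- dplyr::bind_rows(
    tibble::tibble(panel = "residuals vs fitted", x = a$.fitted, y = a$.resid),
    tibble::tibble(panel = "normal Q-Q (outlier-t)",
                   x = stats::qnorm(stats::ppoints(length(a$.outlier.t)))[
                     order(order(a$.outlier.t))],
                   y = a$.outlier.t))
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL)
}
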