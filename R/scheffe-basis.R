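#' Define a mixture component space
#'
#' A mixture experiment varies the proportions `x_1, ..., x_q` of `q`
#' components under the simplex constraint `sum(x) = 1` (the blend always adds
#' up to 100 % of the mixture). The component space records the component
#' labels and, optionally, per-component lower/upper bounds on the
#' proportions.
#'
#' @param names Character vector of component labels (length `q >= 2`), or a
#'   single integer `q` to use labels `x1, ..., xq`.
#' @param lower,upper Numeric vectors of per-component proportion bounds,
#'   recycled to length `q`. Defaults span the full simplex.
#'
#' @return An object of class `component_space`: a list with elements `names`,
#'   `q`, `lower`, `upper`.
#' @examples
#' component_space(c("Ca", "Ph", "Ru", "ChA", "pCoA"))
#' @export
component_space <- function(names, lower = 0, upper = 1) {
  if (is.numeric(names) && length(names) == 1) {
    names <- paste0("x", seq_len(names))
  }
  names <- as.character(names)
  q <- length(names)
  if (q < 2) stop("a mixture needs at least two components", call. = FALSE)
  if (anyDuplicated(names)) stop("component names must be unique", call. = FALSE)
  lower <- rep_len(as.numeric(lower), q)
  upper <- rep_len(as.numeric(upper), q)
  if (any(lower < 0) || any(upper > 1) || any(lower > upper)) {
    stop("bounds must satisfy 0 <= lower_i <= upper_i <= 1", call. = FALSE)
  }
  if (sum(lower) > 1 + 1e-9 || sum(upper) < 1 - 1e-9) {
    stop("bounds leave no feasible blend: need sum(lower) <= 1 <= sum(upper)",
         call. = FALSE)
  }
  structure(list(names = names, q = q, lower = lower, upper = upper),
            class = "component_space")
}

#' @export
print.component_space <- function(x, ...) {
  cat("<component_space> q =", x$q, ":", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

as_space <- function(space) {
  if (inherits(space, "component_space")) return(space)
  if (is.numeric(space) && length(space) == 1) return(component_space(space))
  stop("`space` must be a component_space or a component count", call. = FALSE)
}

#' Define an amount (total concentration) factor
#'
#' The amount factor is the total quantity of the mixture applied, in actual
#' units (e.g. mg per 100 g of diet). Internally it is coded affinely onto
#' `[-1, +1]` so that `coded(low) = -1` and `coded(high) = +1`.
#'
#' @param low,high Range of the factor in actual units; `low < high`.
#' @param name Factor label used in model-term labels.
#' @param units Unit string, for reporting only.
#' @return An object of class `amount_factor`.
#' @examples
#' amount_factor(75, 225, units = "mg/100g")
#' @export
amount_factor <- function(low, high, name = "Conc", units = "") {
  low <- as.numeric(low); high <- as.numeric(high)
  if (!is.finite(low) || !is.finite(high) || low >= high) {
    stop("amount factor needs a non-degenerate range with low < high", call. = FALSE)
  }
  structure(list(name = name, low = low, high = high, units = units),
            class = "amount_factor")
}

#' @export
print.amount_factor <- function(x, ...) {
  cat(sprintf("<amount_factor> %s in [%g, %g] %s\n", x$name, x$low, x$high, x$units))
  invisible(x)
}

#' Code an actual amount onto [-1, +1] (and back)
#'
#' @param actual Numeric vector of amounts in actual units.
#' @param factor An [amount_factor()].
#' @param warn Warn when values fall outside the factor range (extrapolation).
#' @return Numeric vector of coded values in `[-1, 1]` (or beyond when
#'   extrapolating).
#' @examples
#' af <- amount_factor(75, 225)
#' code_amount(c(75, 150, 225), af)
#' @export
code_amount <- function(actual, factor, warn = TRUE) {
  stopifnot(inherits(factor, "amount_factor"))
  out_of_range <- actual < factor$low - 1e-9 | actual > factor$high + 1e-9
  if (warn && any(out_of_range, na.rm = TRUE)) {
    warning("amount values outside the factor range; coded values extrapolate",
            call. = FALSE)
  }
  2 * (actual - factor$low) / (factor$high - factor$low) - 1
}

#' @rdname code_amount
#' @param coded Numeric vector of coded amounts.
#' @export
decode_amount <- function(coded, factor) {
  stopifnot(inherits(factor, "amount_factor"))
  factor$low + (coded + 1) / 2 * (factor$high - factor$low)
}

#' Derive an amount range from mean component contents
#'
#' The low end of the amount range is the rounded (half away from zero) sum of
#' the mean per-component contents measured in the natural substrate; the high
#' end is that low value times a multiplier.
#'
#' @param mean_contents Numeric vector of non-negative mean contents
#'   (e.g. mg/100 g per compound).
#' @param multiplier Scalar `> 1` scaling low to high.
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' amount_range_from_composition(c(2.63, 5.87, 0.78, 28.43, 36.79), 3)
#' @export
amount_range_from_composition <- function(mean_contents, multiplier = 3) {
  if (length(mean_contents) == 0) stop("empty content list", call. = FALSE)
  if (any(mean_contents < 0)) stop("contents must be non-negative", call. = FALSE)
  if (multiplier <= 1) stop("multiplier must exceed 1", call. = FALSE)
  total <- sum(mean_contents)
  # round half away from zero (round() would round 3.5 to 4 but 4.5 to 4)
  low <- sign(total) * floor(abs(total) + 0.5)
  c(low = low, high = low * multiplier)
}

#' Enumerate the crossed Scheffe x amount term set
#'
#' A Scheffe mixture polynomial has no intercept: the linear part is the `q`
#' blending terms `x_i`, the quadratic part adds the `choose(q, 2)` pairwise
#' terms `x_i * x_j`. Crossing with an amount factor of polynomial order `d`
#' multiplies every mixture term by `A^a`, `a = 0, ..., d`, where `A` is the
#' coded amount. Terms are ordered lexicographically by component indices and
#' then by increasing amount exponent, so matrices and reports are
#' reproducible.
#'
#' @param space A [component_space()] or component count.
#' @param mixture_order 1 (linear blending) or 2 (adds pairwise blending).
#' @param amount_order 0, 1 or 2: polynomial order of the crossed amount
#'   factor.
#' @param amount_name Label for the amount factor in term labels.
#' @return A tibble of class `scheffe_terms` with one row per model term:
#'   columns `label`, `c1`, `c2` (`NA` for linear mixture terms), `a` (amount
#'   exponent). The component space is kept as an attribute.
#' @examples
#' enumerate_terms(component_space(3), 2, 1)
#' nrow(enumerate_terms(5, 2, 2)) # 45
#' @export
enumerate_terms <- function(space, mixture_order = 2, amount_order = 1,
                            amount_name = "Conc") {
  space <- as_space(space)
  if (!mixture_order %in% 1:2) {
    stop("mixture_order must be 1 (linear) or 2 (quadratic)", call. = FALSE)
  }
  if (!amount_order %in% 0:2) {
    stop("amount_order must be 0, 1 or 2", call. = FALSE)
  }
  q <- space$q
  mix <- tibble::tibble(c1 = seq_len(q), c2 = NA_integer_)
  if (mixture_order == 2) {
    pairs <- utils::combn(q, 2)
    mix <- dplyr::bind_rows(mix, tibble::tibble(c1 = pairs[1, ], c2 = pairs[2, ]))
  }
  terms <- tidyr::crossing(mix, a = 0:amount_order) |>
    dplyr::arrange(.data$c1, !is.na(.data$c2), .data$c2, .data$a)
  terms$label <- term_label(terms$c1, terms$c2, terms$a, space$names, amount_name)
  terms <- terms[, c("label", "c1", "c2", "a")]
  new_scheffe_terms(terms, space, amount_name)
}

new_scheffe_terms <- function(terms, space, amount_name = "Conc") {
  terms <- tibble::as_tibble(terms)
  attr(terms, "space") <- space
  attr(terms, "amount_name") <- amount_name
  class(terms) <- c("scheffe_terms", class(tibble::tibble()))
  terms
}

term_label <- function(c1, c2, a, comp_names, amount_name = "Conc") {
  base <- comp_names[c1]
  base <- ifelse(is.na(c2), base, paste0(base, "*", comp_names[c2]))
  amt <- c("", paste0("*[", amount_name, "]"), paste0("*[", amount_name, "]^2"))
  paste0(base, amt[a + 1])
}

#' Build a coefficient table from labelled values
#'
#' Convenience for writing a model surface down by hand: parses labels of the
#' form `"Ca"`, `"Ca*ChA"`, `"Ca*[Conc]"`, `"Ph*Ru*[Conc]^2"` against a
#' component space and returns a `scheffe_terms` tibble with an `estimate`
#' column, suitable for [predict_surface()] and as a simulation truth.
#'
#' @param space A [component_space()].
#' @param values Named numeric vector or list; names are term labels.
#' @param amount_name Amount label used inside `[...]`.
#' @return A `scheffe_terms` tibble with an `estimate` column.
#' @examples
#' sp <- component_space(c("A", "B"))
#' coef_table(sp, c(A = 1, B = 2, "A*B" = -4, "A*[Conc]" = 0.5))
#' @export
coef_table <- function(space, values, amount_name = "Conc") {
  space <- as_space(space)
  labels <- names(values)
  if (is.null(labels) || any(labels == "")) {
    stop("`values` must be fully named by term labels", call. = FALSE)
  }
  parse_one <- function(lab) {
    parts <- strsplit(lab, "*", fixed = TRUE)[[1]]
    amt <- grepl("^\\[", parts)
    comp <- parts[!amt]
    a <- 0L
    if (any(amt)) {
      tok <- parts[amt]
      if (length(tok) > 1) stop("bad term label: ", lab, call. = FALSE)
      a <- if (grepl("\\^2$", tok)) 2L else 1L
    }
    idx <- match(comp, space$names)
    if (anyNA(idx) || length(idx) < 1 || length(idx) > 2) {
      stop("term label `", lab, "` does not match the component space", call. = FALSE)
    }
    idx <- sort(idx)
    tibble::tibble(c1 = idx[1], c2 = if (length(idx) == 2) idx[2] else NA_integer_,
                   a = a)
  }
  terms <- purrr::map_dfr(labels, parse_one)
  terms$label <- term_label(terms$c1, terms$c2, terms$a, space$names, amount_name)
  terms$estimate <- as.numeric(unlist(values))
  new_scheffe_terms(terms[, c("label", "c1", "c2", "a", "estimate")],
                    space, amount_name)
}

check_proportions <- function(props, tol = 1e-9) {
  bad <- abs(rowSums(props) - 1) > tol | apply(props, 1, function(p) any(p < -tol | p > 1 + tol))
  if (any(bad)) {
    stop("proportions must lie in [0, 1] and sum to 1 (rows: ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Evaluate the model matrix of a crossed Scheffe basis
#'
#' Each entry is the product of the term's component proportions times the
#' coded amount raised to the term's exponent. There is no intercept column:
#' the blending constraint `sum(x) = 1` absorbs it.
#'
#' @param points A data frame with one column per component (named as in the
#'   term set's component space) and a column `amount_coded` (defaults to 0
#'   when absent and no amount-crossed term is requested).
#' @param terms A `scheffe_terms` tibble from [enumerate_terms()] or
#'   [coef_table()].
#' @return Numeric matrix, one column per term, labelled by term label.
#' @examples
#' sp <- component_space(c("A", "B"))
#' tt <- enumerate_terms(sp, 2, 1)
#' pts <- data.frame(A = c(1, 0.5), B = c(0, 0.5), amount_coded = c(0, -1))
#' build_model_matrix(pts, tt)
#' @export
build_model_matrix <- function(points, terms) {
  space <- attr(terms, "space")
  missing_cols <- setdiff(space$names, names(points))
  if (length(missing_cols)) {
    stop("points lack component columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  props <- as.matrix(points[, space$names, drop = FALSE])
  check_proportions(props)
  if (!"amount_coded" %in% names(points)) {
    if (any(terms$a > 0)) stop("points lack an `amount_coded` column", call. = FALSE)
    amount <- rep(0, nrow(props))
  } else {
    amount <- points$amount_coded
  }
  X <- vapply(seq_len(nrow(terms)), function(k) {
    v <- props[, terms$c1[k]]
    if (!is.na(terms$c2[k])) v <- v * props[, terms$c2[k]]
    if (terms$a[k] > 0) v <- v * amount^terms$a[k]
    v
  }, numeric(nrow(props)))
  X <- matrix(X, nrow = nrow(props))
  colnames(X) <- terms$label
  X
}

#' Convert proportions to and from pseudo-components
#'
#' With nonzero lower bounds `L_i`, pseudo-components rescale the constrained
#' region back onto the full simplex: `x'_i = (x_i - L_i) / (1 - sum(L))`.
#' Off by default throughout the package; provided for constrained spaces.
#'
#' @param points Data frame with component columns.
#' @param space A [component_space()] carrying the lower bounds.
#' @return `points` with component columns rescaled.
#' @export
to_pseudo <- function(points, space) {
  space <- as_space(space)
  denom <- 1 - sum(space$lower)
  if (denom <= 0) stop("degenerate pseudo-component scaling", call. = FALSE)
  for (i in seq_len(space$q)) {
    points[[space$names[i]]] <- (points[[space$names[i]]] - space$lower[i]) / denom
  }
  points
}

#' @rdname to_pseudo
#' @export
from_pseudo <- function(points, space) {
  space <- as_space(space)
  denom <- 1 - sum(space$lower)
  for (i in seq_len(space$q)) {
    points[[space$names[i]]] <- points[[space$names[i]]] * denom + space$lower[i]
  }
  points
}
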