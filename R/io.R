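#' Write a study (design + responses) to plain files
#'
#' Writes `design.csv` (one run per row: `run_id`, `block`, `role`, one
#' column per component proportion, `amount`, `amount_coded`, then any
#' response columns) and `config.json` describing components, amount factor
#' and response columns.
#'
#' @param study A `mix_design` / `mix_study` tibble.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- design_space(study)
  af <- design_amount(study)
  core <- c("run_id", "block", "role", sp$names, "amount", "amount_coded")
  resp <- setdiff(names(study), core)
  design_path <- file.path(dir, "design.csv")
  readr::write_csv(tibble::as_tibble(study)[, c(core, resp)], design_path)
  cfg <- list(components = sp$names,
              lower = sp$lower, upper = sp$upper,
              amount = list(name = af$name, low = af$low, high = af$high,
                            units = af$units),
              responses = resp)
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  invisible(c(design = design_path, config = cfg_path))
}

#' Read a study from plain files
#'
#' Validates every run on ingest: component proportions must lie in `[0, 1]`
#' and sum to 1 within 1e-6 (violations are reported with their row ids), and
#' all configured columns must be present.
#'
#' @param design_csv Path to the design/response CSV.
#' @param config_json Path to the JSON configuration naming components and
#'   the amount factor. Alternatively supply `components` and `amount`.
#' @param components Character vector of component column names (if no
#'   config file).
#' @param amount An [amount_factor()] (if no config file).
#' @return A `mix_design` tibble with response columns attached.
#' @export
read_study <- function(design_csv, config_json = NULL, components = NULL,
                       amount = NULL) {
  if (!file.exists(design_csv)) stop("no such file: ", design_csv, call. = FALSE)
  if (!is.null(config_json)) {
    cfg <- jsonlite::read_json(config_json, simplifyVector = TRUE)
    components <- cfg$components
    amount <- amount_factor(cfg$amount$low, cfg$amount$high,
                            name = cfg$amount$name %||% "Conc",
                            units = cfg$amount$units %||% "")
  }
  if (is.null(components) || is.null(amount)) {
    stop("supply `config_json`, or both `components` and `amount`", call. = FALSE)
  }
  d <- readr::read_csv(design_csv, show_col_types = FALSE)
  missing_cols <- setdiff(c(components, "amount"), names(d))
  if (length(missing_cols)) {
    stop("design file lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  props <- as.matrix(d[, components])
  bad <- which(abs(rowSums(props) - 1) > 1e-6 |
                 apply(props, 1, function(p) any(p < -1e-6 | p > 1 + 1e-6)))
  if (length(bad)) {
    stop("proportions invalid (must sum to 1) in rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  if (!"amount_coded" %in% names(d)) {
    d$amount_coded <- code_amount(d$amount, amount, warn = FALSE)
  }
  if (!"block" %in% names(d)) d$block <- NA_integer_
  if (!"role" %in% names(d)) d$role <- "model"
  sp <- component_space(components)
  core <- c("run_id", "block", "role", components, "amount", "amount_coded")
  resp <- setdiff(names(d), core)
  d$run_id <- NULL
  out <- new_design(d[, setdiff(core, "run_id")], sp, amount)
  for (nm in resp) out[[nm]] <- d[[nm]]
  out
}

pipeline_log <- function(log, response, stage, message) {
  dplyr::bind_rows(log, tibble::tibble(response = response, stage = stage,
                                       message = message))
}

#' Run the full analysis pipeline on a study
#'
#' Per response: sequential model-order selection, adequacy screening
#' (a single run exceeding the outlier-t threshold is excluded and the model
#' refitted once), Box-Cox assessment (a shift of `k = 1` is applied
#' automatically when zeros are present; the transform is applied and the
#' model re-selected when the lambda CI excludes 1), backward elimination,
#' and ANOVA / R-squared / precision reporting, plus binary-blend surface
#' grids for any requested component pairs. Every decision is recorded in a
#' structured log. Deterministic for fixed inputs.
#'
#' @param study A `mix_design` with response columns (e.g. from
#'   [simulate_study()] or [read_study()]).
#' @param responses Response column names to analyse; defaults to all
#'   non-design columns (excluding `*_count` companions).
#' @param alpha Significance level for selection and lack of fit.
#' @param alpha_out Backward-elimination stay threshold.
#' @param surface_pairs Optional list of length-2 character vectors of
#'   component names; a [slice_grid()] is produced per pair per response.
#' @param out_dir Optional directory: per-response ANOVA, coefficient,
#'   diagnostic, Box-Cox profile and surface CSVs are written there.
#' @return A list of class `rsm_pipeline`: per response a list with elements
#'   `selection`, `fit` (final reduced fit), `anova`, `coefficients`,
#'   `diagnostics`, `boxcox`, `r2`, `precision`, `surfaces`, `transform`,
#'   `excluded_runs`; plus `log`, a tibble of every decision taken.
#' @export
run_pipeline <- function(study, responses = NULL, alpha = 0.05,
                         alpha_out = 0.10, surface_pairs = NULL,
                         out_dir = NULL) {
  sp <- design_space(study)
  core <- c("run_id", "block", "role", sp$names, "amount", "amount_coded")
  responses <- responses %||%
    setdiff(names(study)[!grepl("_count$", names(study))], core)
  log <- tibble::tibble(response = character(), stage = character(),
                        message = character())
  out <- list()
  for (nm in responses) {
    res <- tryCatch({
      y <- study[[nm]]
      if (is.null(y)) stop("no response column `", nm, "`", call. = FALSE)

      sel <- select_model_order(study, y, alpha = alpha)
      fit <- attr(sel, "chosen_fit")
      ch <- sel[sel$chosen, ]
      log <- pipeline_log(log, nm, "selection",
                          sprintf("chose mixture order %d x amount order %d",
                                  ch$mixture_order, ch$amount_order))

      infl <- influence_rsm(fit)
      excluded <- integer(0)
      worst <- which.max(abs(infl$outlier_t))
      if (length(worst) && isTRUE(infl$flag_outlier_t[worst])) {
        excluded <- infl$run_id[worst]
        fit <- refit_without(fit, excluded)
        log <- pipeline_log(log, nm, "adequacy",
                            sprintf("excluded run %d (outlier-t %.2f) and refitted",
                                    excluded, infl$outlier_t[worst]))
      }

      k <- if (any(fit$y == 0)) 1 else 0
      if (k > 0) log <- pipeline_log(log, nm, "transform", "shift k = 1 applied (zero responses present)")
      bc <- box_cox(fit$design, fit$y, fit$terms, k = k)
      ci <- attr(bc, "ci")
      transform <- NULL
      if (ci[1] > 1 || ci[2] < 1) {
        transform <- list(lambda = attr(bc, "best"), k = k)
        yt <- apply_transform(fit$y, transform$lambda, transform$k)
        sel <- select_model_order(fit$design, yt, alpha = alpha)
        fit <- attr(sel, "chosen_fit")
        log <- pipeline_log(log, nm, "transform",
                            sprintf("applied %s and re-selected model order",
                                    attr(bc, "label")))
      } else {
        log <- pipeline_log(log, nm, "transform", "no transformation required")
      }

      fit <- backward_eliminate(fit, alpha_out = alpha_out)
      el <- attr(fit, "elimination")
      log <- pipeline_log(log, nm, "reduction",
                          if (nrow(el)) paste("removed", paste(el$dropped, collapse = ", "))
                          else "no terms removed")

      an <- anova_rsm(fit)
      surfaces <- NULL
      if (!is.null(surface_pairs)) {
        surfaces <- lapply(surface_pairs, function(p) slice_grid(fit, p))
        names(surfaces) <- vapply(surface_pairs, paste, "", collapse = ":")
      }
      list(selection = sel, fit = fit, anova = an, coefficients = tidy(fit),
           diagnostics = influence_rsm(fit), boxcox = bc,
           r2 = attr(an, "r2"), precision = precision_ratio(fit),
           surfaces = surfaces, transform = transform,
           excluded_runs = excluded)
    }, error = function(e) {
      log <<- pipeline_log(log, nm, "error", conditionMessage(e))
      NULL
    })
    out[[nm]] <- res
  }
  out$log <- log
  class(out) <- "rsm_pipeline"
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

write_pipeline <- function(pipeline, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in setdiff(names(pipeline), "log")) {
    res <- pipeline[[nm]]
    if (is.null(res)) next
    readr::write_csv(res$anova, file.path(out_dir, paste0(nm, "_anova.csv")))
    readr::write_csv(res$coefficients,
                     file.path(out_dir, paste0(nm, "_coefficients.csv")))
    readr::write_csv(res$diagnostics,
                     file.path(out_dir, paste0(nm, "_diagnostics.csv")))
    readr::write_csv(tibble::as_tibble(res$boxcox),
                     file.path(out_dir, paste0(nm, "_boxcox.csv")))
    if (!is.null(res$surfaces)) {
      for (pn in names(res$surfaces)) {
        readr::write_csv(tibble::as_tibble(res$surfaces[[pn]]),
                         file.path(out_dir, paste0(nm, "_surface_",
                                                   gsub(":", "_", pn), ".csv")))
      }
    }
  }
  readr::write_csv(pipeline$log, file.path(out_dir, "pipeline_log.csv"))
  invisible(out_dir)
}

#' @export
print.rsm_pipeline <- function(x, ...) {
  nms <- setdiff(names(x), "log")
  cat("<rsm_pipeline>", length(nms), "responses\n")
  for (nm in nms) {
    res <- x[[nm]]
    if (is.null(res)) {
      cat(sprintf("  %s: failed (see $log)\n", nm))
      next
    }
    g <- glance(res$fit)
    cat(sprintf("  %s: %d terms, R2_adj = %.2f, model p = %.3g\n", nm,
                nrow(res$fit$terms), g$adj.r.squared, g$p.value))
  }
  invisible(x)
}
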