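new_design <- function(runs, space, amount_factor, terms = NULL) {
  runs <- tibble::as_tibble(runs)
  runs$run_id <- seq_len(nrow(runs))
  runs <- runs[, c("run_id", "block", "role", space$names, "amount", "amount_coded")]
  attr(runs, "space") <- space
  attr(runs, "amount_factor") <- amount_factor
  attr(runs, "terms") <- terms
  class(runs) <- c("mix_design", class(tibble::tibble()))
  runs
}

design_space <- function(design) attr(design, "space")
design_amount <- function(design) attr(design, "amount_factor")

#' @export
print.mix_design <- function(x, ...) {
  sp <- design_space(x)
  cat(sprintf("<mix_design> %d runs, %d distinct points, %d block(s), %d components\n",
              nrow(x), dplyr::n_distinct(distinct_point_id(x)),
              dplyr::n_distinct(x$block[!is.na(x$block)]) , sp$q))
  NextMethod()
}

# integer id shared by runs at the same (proportions, amount) within 1e-9
distinct_point_id <- function(design) {
  sp <- design_space(design)
  key <- apply(round(as.matrix(design[, c(sp$names, "amount_coded")]), 9), 1,
               paste, collapse = "|")
  match(key, unique(key))
}

#' Generate a candidate set over the simplex x amount grid
#'
#' Standard candidate classes for D-optimal mixture design: the `q` vertices
#' (pure components), all binary 50:50 edge midpoints, the overall centroid,
#' axial check blends (midpoints between each vertex and the centroid), and an
#' optional interior simplex lattice. Each simplex candidate is crossed with
#' every requested coded amount level.
#'
#' @param space A [component_space()].
#' @param amount_levels Coded amount levels in `[-1, 1]`.
#' @param include Candidate classes to generate.
#' @param lattice_degree Optional degree `s` of an interior `{0, 1/s, ...}`
#'   simplex lattice added with provenance `"interior"`.
#' @param amount_factor Optional [amount_factor()] recorded for unit
#'   conversion downstream.
#' @return Tibble with component columns, `amount_coded` and `provenance`;
#'   duplicates (within 1e-9) removed.
#' @examples
#' generate_candidates(component_space(3), c(-1, 1))
#' @export
generate_candidates <- function(space, amount_levels = c(-1, 0, 1),
                                include = c("vertex", "edge_midpoint",
                                            "centroid", "axial"),
                                lattice_degree = NULL, amount_factor = NULL) {
  space <- as_space(space)
  if (length(amount_levels) == 0 || any(abs(amount_levels) > 1 + 1e-9)) {
    stop("amount_levels must be non-empty coded values in [-1, 1]", call. = FALSE)
  }
  include <- match.arg(include, c("vertex", "edge_midpoint", "centroid", "axial"),
                       several.ok = TRUE)
  q <- space$q
  rows <- list()
  if ("vertex" %in% include) {
    rows$vertex <- diag(q)
  }
  if ("edge_midpoint" %in% include && q >= 2) {
    pairs <- utils::combn(q, 2)
    m <- matrix(0, ncol(pairs), q)
    for (k in seq_len(ncol(pairs))) m[k, pairs[, k]] <- 0.5
    rows$edge_midpoint <- m
  }
  if ("centroid" %in% include) {
    rows$centroid <- matrix(1 / q, 1, q)
  }
  if ("axial" %in% include) {
    rows$axial <- (diag(q) + matrix(1 / q, q, q)) / 2
  }
  if (!is.null(lattice_degree)) {
    lat <- simplex_lattice(q, lattice_degree)
    rows$interior <- lat
  }
  simplex <- purrr::imap_dfr(rows, function(m, tag) {
    d <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
    names(d) <- space$names
    d$provenance <- tag
    d
  })
  cand <- tidyr::crossing(simplex, amount_coded = sort(amount_levels)) |>
    dplyr::select(dplyr::all_of(space$names), "amount_coded", "provenance")
  key <- apply(round(as.matrix(cand[, c(space$names, "amount_coded")]), 9), 1,
               paste, collapse = "|")
  cand <- cand[!duplicated(key), ]
  attr(cand, "space") <- space
  attr(cand, "amount_factor") <- amount_factor
  cand
}

# all q-part compositions of s, scaled to the simplex
simplex_lattice <- function(q, s) {
  stopifnot(s >= 1)
  if (q == 1) return(matrix(1, 1, 1))
  # stars-and-bars enumeration of all q-part compositions of s
  comps <- utils::combn(s + q - 1, q - 1)
  n <- ncol(comps)
  m <- matrix(0L, n, q)
  for (j in seq_len(n)) {
    cuts <- c(0L, comps[, j], s + q)
    m[j, ] <- diff(cuts) - 1L
  }
  m / s
}

candidate_matrix <- function(candidates, terms) {
  build_model_matrix(candidates, terms)
}

#' Select a D-optimal subset of candidate points
#'
#' Maximizes `det(X'X)` of the model matrix over distinct candidate subsets of
#' size `n_points` by Fedorov point exchange: from a random nonsingular start,
#' repeatedly apply the best single in/out swap until no swap improves the
#' determinant by more than a relative 1e-10, with multiple random starts
#' keeping the best design found.
#'
#' @param candidates Candidate tibble from [generate_candidates()].
#' @param terms `scheffe_terms` model term set the design must support.
#' @param n_points Number of design points (`>= nrow(terms)`).
#' @param seed Integer seed for the random starts.
#' @param n_starts Number of random multi-starts (>= 10 recommended).
#' @return A `mix_design` of `n_points` runs with role `"model"`, carrying the
#'   term set as an attribute. The achieved `log det(X'X)` is in attribute
#'   `logdet`.
#' @export
select_d_optimal <- function(candidates, terms, n_points, seed = 1L,
                             n_starts = 10L) {
  space <- attr(terms, "space")
  Xc <- candidate_matrix(candidates, terms)
  p <- ncol(Xc)
  nc <- nrow(Xc)
  if (n_points < p) stop("n_points must be at least the term count", call. = FALSE)
  if (nc < n_points) stop("need at least n_points distinct candidates", call. = FALSE)

  best <- withr::with_seed(seed, {
    res <- NULL
    for (s in seq_len(n_starts)) {
      cur <- fedorov_exchange(Xc, n_points)
      if (!is.null(cur) && (is.null(res) || cur$logdet > res$logdet + 1e-12)) {
        res <- cur
      }
    }
    res
  })
  if (is.null(best)) {
    stop("model not estimable from candidates: every start gave a singular ",
         "information matrix", call. = FALSE)
  }
  runs <- candidates[best$idx, c(space$names, "amount_coded")]
  af <- attr(candidates, "amount_factor")
  runs$amount <- if (!is.null(af)) decode_amount(runs$amount_coded, af) else NA_real_
  runs$block <- NA_integer_
  runs$role <- "model"
  d <- new_design(runs, space, af, terms = terms)
  attr(d, "logdet") <- best$logdet
  d
}

# QR-based log det(X'X) and unscaled inverse; NULL when rank-deficient
xtx_decomp <- function(Xsub, p) {
  qx <- qr(Xsub)
  if (qx$rank < p) return(NULL)
  r <- diag(qr.R(qx))
  list(logdet = 2 * sum(log(abs(r))), Minv = chol2inv(qr.R(qx)))
}

# one multi-start replicate: random (QR-guided) start + best-swap exchange
fedorov_exchange <- function(Xc, n_points, rel_tol = 1e-10, max_iter = 200L) {
  p <- ncol(Xc); nc <- nrow(Xc)
  perm <- sample.int(nc)
  piv <- qr(t(Xc[perm, , drop = FALSE]), LAPACK = TRUE)$pivot
  base <- perm[piv[seq_len(p)]]
  extra <- setdiff(perm, base)[seq_len(n_points - p)]
  idx <- c(base, if (n_points > p) extra)
  dec <- xtx_decomp(Xc[idx, , drop = FALSE], p)
  if (is.null(dec)) return(NULL)
  Minv <- dec$Minv

  for (iter in seq_len(max_iter)) {
    V <- Xc %*% Minv %*% t(Xc)      # nc x nc dispersion (small candidate sets)
    d <- diag(V)
    in_set <- idx
    # delta(i -> j) = (1 + d_j)(1 - d_i) + v_ij^2 ; accept if > 1 + tol
    best_gain <- 1 + rel_tol
    best_swap <- NULL
    avail <- setdiff(seq_len(nc), in_set)
    if (length(avail) == 0) break
    for (s in seq_along(in_set)) {
      i <- in_set[s]
      gain <- (1 + d[avail]) * (1 - d[i]) + V[i, avail]^2
      j_best <- which.max(gain)
      if (gain[j_best] > best_gain) {
        best_gain <- gain[j_best]
        best_swap <- c(s, avail[j_best])
      }
    }
    if (is.null(best_swap)) break
    idx[best_swap[1]] <- best_swap[2]
    dec <- xtx_decomp(Xc[idx, , drop = FALSE], p)
    if (is.null(dec)) return(NULL)
    Minv <- dec$Minv
  }
  dec <- xtx_decomp(Xc[idx, , drop = FALSE], p)
  if (is.null(dec)) return(NULL)
  list(idx = sort(idx), logdet = dec$logdet)
}

#' Augment a design with lack-of-fit points
#'
#' Adds `n` candidate points chosen greedily to maximize the minimum Euclidean
#' distance, in coded space (proportions plus coded amount), to all points
#' already in the design (maximin augmentation). Added runs get role
#' `"lack_of_fit"`.
#'
#' @param design A `mix_design`.
#' @param candidates Candidate tibble.
#' @param n Number of points to add.
#' @param seed Seed for tie-breaking order.
#' @return The augmented `mix_design`.
#' @export
augment_lack_of_fit <- function(design, candidates, n, seed = 1L) {
  if (n == 0) return(design)
  sp <- design_space(design)
  cols <- c(sp$names, "amount_coded")
  C <- as.matrix(candidates[, cols])
  D <- as.matrix(design[, cols])
  # drop candidates already present
  dup <- apply(C, 1, function(x) any(colSums(abs(t(D) - x)) < 1e-9))
  free <- which(!dup)
  if (length(free) < n) {
    stop("requested ", n, " lack-of-fit points but only ", length(free),
         " distinct candidates remain", call. = FALSE)
  }
  ord <- withr::with_seed(seed, sample(free))
  picked <- integer(0)
  mind <- apply(C, 1, function(x) min(sqrt(colSums((t(D) - x)^2))))
  for (k in seq_len(n)) {
    j <- ord[which.max(mind[ord])]
    picked <- c(picked, j)
    ord <- setdiff(ord, j)
    newd <- sqrt(colSums((t(C) - C[j, ])^2))
    mind <- pmin(mind, newd)
  }
  add <- candidates[picked, cols]
  af <- design_amount(design)
  add$amount <- if (!is.null(af)) decode_amount(add$amount_coded, af) else NA_real_
  add$block <- NA_integer_
  add$role <- "lack_of_fit"
  out <- dplyr::bind_rows(design, add)
  new_design(out, sp, af, terms = attr(design, "terms"))
}

#' Augment a design with replicate runs
#'
#' Duplicates the `n` distinct design points with the highest leverage under
#' the design's model term set (ties broken by a seeded shuffle); if `n`
#' exceeds the number of distinct points the selection cycles. Replicates are
#' exact copies with role `"replicate"`; they never change the distinct-point
#' count.
#'
#' @inheritParams augment_lack_of_fit
#' @param terms Term set defining leverage; defaults to the design's own.
#' @return The augmented `mix_design`.
#' @export
augment_replicates <- function(design, n, seed = 1L, terms = NULL) {
  if (n == 0) return(design)
  sp <- design_space(design)
  terms <- terms %||% attr(design, "terms")
  if (is.null(terms)) stop("no term set available to compute leverage", call. = FALSE)
  id <- distinct_point_id(design)
  first <- match(unique(id), id)
  Xd <- build_model_matrix(design[first, ], terms)
  h <- diag(Xd %*% solve(crossprod(Xd), t(Xd)))
  ord <- withr::with_seed(seed, order(-h, sample.int(length(h))))
  take <- rep(ord, length.out = n)
  add <- design[first[take], c(sp$names, "amount", "amount_coded")]
  add$block <- NA_integer_
  add$role <- "replicate"
  out <- dplyr::bind_rows(design, add)
  new_design(out, sp, design_amount(design), terms = attr(design, "terms"))
}

#' Add center points
#'
#' Appends `n` copies of the overall centroid (equal proportions `1/q`) at the
#' mid amount (coded 0), role `"center"`.
#'
#' @inheritParams augment_lack_of_fit
#' @return The augmented `mix_design`.
#' @export
add_center_points <- function(design, n) {
  if (n == 0) return(design)
  sp <- design_space(design)
  af <- design_amount(design)
  ctr <- tibble::as_tibble(as.data.frame(matrix(1 / sp$q, n, sp$q),
                                         col.names = sp$names),
                           .name_repair = "minimal")
  names(ctr) <- sp$names
  ctr$amount_coded <- 0
  ctr$amount <- if (!is.null(af)) decode_amount(0, af) else NA_real_
  ctr$block <- NA_integer_
  ctr$role <- "center"
  out <- dplyr::bind_rows(design, ctr)
  new_design(out, sp, af, terms = attr(design, "terms"))
}

#' Assign runs to blocks
#'
#' Balanced randomized assignment: block sizes differ by at most one, and
#' copies of the same distinct point (replicates, centers) are spread across
#' blocks where possible.
#'
#' @inheritParams augment_lack_of_fit
#' @param n_blocks Number of blocks (`1 <= n_blocks <=` run count).
#' @return The design with its `block` column filled in.
#' @export
assign_blocks <- function(design, n_blocks, seed = 1L) {
  n <- nrow(design)
  if (n_blocks < 1 || n_blocks > n) {
    stop("n_blocks must be between 1 and the number of runs", call. = FALSE)
  }
  id <- distinct_point_id(design)
  cap <- rep(floor(n / n_blocks), n_blocks) +
    (seq_len(n_blocks) <= n %% n_blocks)
  block <- integer(n)
  withr::with_seed(seed, {
    counts <- integer(n_blocks)
    copies <- matrix(0L, n_blocks, max(id))
    # process groups largest first so replicate sets can still spread
    groups <- split(seq_len(n), id)
    groups <- groups[order(-lengths(groups), vapply(groups, min, 1L))]
    for (g in groups) {
      for (r in g[sample.int(length(g))]) {
        open <- which(counts < cap)
        few <- open[copies[open, id[r]] == min(copies[open, id[r]])]
        few <- few[counts[few] == min(counts[few])]
        b <- if (length(few) > 1) sample(few, 1) else few
        block[r] <- b
        counts[b] <- counts[b] + 1L
        copies[b, id[r]] <- copies[b, id[r]] + 1L
      }
    }
  })
  design$block <- block
  design
}

#' Degrees-of-freedom partition of a blocked mixture design
#'
#' Mixture-convention accounting for a design with `N` runs, `n_b` blocks and
#' a no-intercept crossed Scheffe term set of size `t`: block df `n_b - 1`,
#' model df `t - 1` (one df absorbed by the blending constraint), lack-of-fit
#' df `(#distinct points) - t`, and pure-error df the residual remainder
#' `(N - 1) - block - model - lack_of_fit`. The remainder convention (rather
#' than the within-replicate count) is used because block effects consume
#' replicate df.
#'
#' @param design A `mix_design` with blocks assigned (unassigned = 1 block).
#' @param terms `scheffe_terms`; defaults to the design's own term set.
#' @return A one-row tibble: `block_df`, `model_df`, `lack_of_fit_df`,
#'   `pure_error_df`, `total_df` (`= N - 1`).
#' @export
df_partition <- function(design, terms = NULL) {
  terms <- terms %||% attr(design, "terms")
  if (is.null(terms)) stop("a term set is required", call. = FALSE)
  n <- nrow(design)
  nb <- max(1L, dplyr::n_distinct(design$block[!is.na(design$block)]))
  id <- distinct_point_id(design)
  ndist <- dplyr::n_distinct(id)
  t <- nrow(terms)
  Xd <- build_model_matrix(design[match(unique(id), id), ], terms)
  if (ndist < t || qr(Xd)$rank < t) {
    stop("model not estimable: fewer independent distinct points (", ndist,
         ") than model terms (", t, ")", call. = FALSE)
  }
  block_df <- nb - 1L
  model_df <- t - 1L
  lof_df <- ndist - t
  pe_df <- (n - 1L) - block_df - model_df - lof_df
  if (pe_df < 0) stop("negative pure-error df: design too small", call. = FALSE)
  tibble::tibble(block_df = block_df, model_df = model_df,
                 lack_of_fit_df = lof_df, pure_error_df = pe_df,
                 total_df = n - 1L)
}

#' Build a complete blocked mixture-amount study design
#'
#' One-call constructor chaining candidate generation, D-optimal model-point
#' selection, maximin lack-of-fit augmentation, leverage-guided replication,
#' center points and block assignment. With the defaults and a five-component
#' space this reproduces the canonical 100-run structure: 45 model + 5
#' lack-of-fit + 45 replicate + 5 center runs in 5 blocks, 51 distinct points,
#' and df partition 4 / 44 / 6 / 45.
#'
#' The exact centroid at coded amount 0 is reserved for the center-point role
#' and excluded from the model/lack-of-fit candidate pool, so the center runs
#' always contribute one fresh distinct point.
#'
#' @param space A [component_space()].
#' @param amount [amount_factor()].
#' @param terms Term set to optimize for; default full quadratic x quadratic.
#' @param n_model,n_lof,n_replicates,n_centers,n_blocks Design structure.
#' @param amount_levels Coded candidate levels.
#' @param seed Integer seed driving every stochastic step.
#' @param n_starts Multi-starts for the D-optimal exchange.
#' @return A `mix_design`.
#' @examples
#' \donttest{
#' sp <- component_space(c("Ca", "Ph", "Ru", "ChA", "pCoA"))
#' d <- build_study_design(sp, amount_factor(75, 225), seed = 1)
#' df_partition(d)
#' }
#' @export
build_study_design <- function(space, amount,
                               terms = enumerate_terms(space, 2, 2,
                                                       amount_name = amount$name),
                               n_model = 45, n_lof = 5, n_replicates = 45,
                               n_centers = 5, n_blocks = 5,
                               amount_levels = c(-1, 0, 1),
                               seed = 1L, n_starts = 10L) {
  space <- as_space(space)
  cand <- generate_candidates(space, amount_levels, amount_factor = amount)
  if (n_centers > 0) {
    ctr <- abs(as.matrix(cand[, space$names]) - 1 / space$q)
    is_ctr <- rowSums(ctr) < 1e-9 & abs(cand$amount_coded) < 1e-9
    cand <- cand[!is_ctr, ]
  }
  d <- select_d_optimal(cand, terms, n_model, seed = seed, n_starts = n_starts)
  d <- augment_lack_of_fit(d, cand, n_lof, seed = seed + 1L)
  d <- augment_replicates(d, n_replicates, seed = seed + 2L)
  d <- add_center_points(d, n_centers)
  assign_blocks(d, n_blocks, seed = seed + 3L)
}
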