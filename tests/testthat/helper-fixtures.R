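# Shared fixtures and independent brute-force oracles.

space3 <- component_space(c("A", "B", "C"))
space5 <- component_space(c("Ca", "Ph", "Ru", "ChA", "pCoA"))
af_ref <- amount_factor(75, 225, units = "mg/100g")

# small blocked design with replicates, for fit-level tests
small_design <- function(q = 3, n_rep = 4, n_blocks = 2, seed = 1,
                         mixture_order = 2, amount_order = 1) {
  sp <- component_space(LETTERS[seq_len(q)])
  af <- amount_factor(10, 30)
  tt <- enumerate_terms(sp, mixture_order, amount_order)
  cand <- generate_candidates(sp, c(-1, 0, 1), amount_factor = af)
  d <- select_d_optimal(cand, tt, nrow(tt), seed = seed, n_starts = 4)
  d <- augment_lack_of_fit(d, cand, 2, seed = seed)
  d <- augment_replicates(d, n_rep, seed = seed)
  assign_blocks(d, n_blocks, seed = seed)
}

# exhaustive D-optimality oracle: best log det(X'X) over all full-rank subsets
brute_force_logdet <- function(Xc, n) {
  best <- -Inf
  p <- ncol(Xc)
  idx <- utils::combn(nrow(Xc), n)
  for (j in seq_len(ncol(idx))) {
    Xs <- Xc[idx[, j], , drop = FALSE]
    if (qr(Xs)$rank < p) next
    best <- max(best, 2 * sum(log(abs(diag(qr.R(qr(Xs)))))))
  }
  best
}

# delete-one refit oracles computed from the fit's own model matrix and
# response, independently of stats' influence formulas
deletion_oracle <- function(fit) {
  Z <- stats::model.matrix(fit$lm)
  y <- fit$y
  n <- nrow(Z); p <- ncol(Z)
  XtXi <- solve(crossprod(Z))
  b <- drop(XtXi %*% crossprod(Z, y))
  s2 <- sum((y - Z %*% b)^2) / (n - p)
  out <- lapply(seq_len(n), function(i) {
    Zi <- Z[-i, , drop = FALSE]; yi <- y[-i]
    bi <- drop(solve(crossprod(Zi), crossprod(Zi, yi)))
    s2i <- sum((yi - Zi %*% bi)^2) / (n - 1 - p)
    pred_res <- y[i] - drop(Z[i, ] %*% bi)
    vi <- drop(Z[i, ] %*% XtXi %*% Z[i, ])
    db <- b - bi
    list(
      press_res = pred_res,
      ext_t = pred_res / sqrt(s2i * (1 + drop(Z[i, ] %*% solve(crossprod(Zi)) %*% Z[i, ]))),
      cooks = drop(crossprod(db, crossprod(Z) %*% db)) / (p * s2),
      dffits = drop(Z[i, ] %*% db) / sqrt(s2i * vi),
      dfbetas = db / sqrt(s2i * diag(XtXi)))
  })
  list(press = sum(vapply(out, `[[`, 1, "press_res")^2),
       ext_t = vapply(out, `[[`, 1, "ext_t"),
       cooks = vapply(out, `[[`, 1, "cooks"),
       dffits = vapply(out, `[[`, 1, "dffits"),
       dfbetas = t(vapply(out, `[[`, numeric(ncol(Z)), "dfbetas")))
}

# latent normal-linear data with a known Box-Cox exponent. The latent mean is
# a blending surface mapped so that lambda*z + 1 spans [0.3, 2.2]: the noise
# (2% of the latent range) then never approaches the transform's domain
# boundary, and the response spans a severalfold range so the exponent is
# identifiable.
sim_boxcox_response <- function(design, lambda, seed) {
  sp <- design_space(design)
  vals <- stats::setNames(seq(0, 1, length.out = sp$q), sp$names)
  u <- predict_surface(coef_table(sp, vals), design) # in [0, 1]
  u <- (u - min(u)) / diff(range(u))
  # latent mean linear in the blending surface, spanning the z image of
  # lambda * z + 1 in [0.3, 2.2]
  zlim <- if (abs(lambda) < 1e-12) log(c(0.3, 2.2)) else
    sort((c(0.3, 2.2) - 1) / lambda)
  z <- zlim[1] + u * diff(zlim)
  zr <- diff(range(z))
  z <- z + withr::with_seed(seed, stats::rnorm(length(z), 0, 0.02 * zr))
  if (abs(lambda) < 1e-12) exp(z) else (lambda * z + 1)^(1 / lambda)
}
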