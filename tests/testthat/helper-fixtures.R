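# Small programmatic fixtures shared across the suite.

# A random but valid multi-view dataset; labels are category names with a
# proper zero-shot split between paired and additional blocks.
tiny_dataset <- function(df = 4, dv = 3, ds = 2, n = 6, m = 0, seed = 1) {
  set.seed(seed)
  add_v <- if (m > 0) matrix(rnorm(dv * m), dv) else NULL
  add_s <- if (m > 0) matrix(rnorm(ds * m), ds) else NULL
  multiview_dataset(
    brain = matrix(rnorm(df * n), df),
    visual = matrix(rnorm(dv * n), dv),
    semantic = matrix(rnorm(ds * n), ds),
    paired_labels = paste0("src", rep_len(seq_len(max(n %/% 2, 1)), n)),
    add_visual = add_v, add_semantic = add_s,
    add_labels = if (m > 0) paste0("tgt", rep_len(seq_len(max(m %/% 2, 1)), m))
                 else character(0))
}

# A brain-only variational state whose moments can be set by hand, for
# checking single updates against hand-worked or integrated oracles.
manual_brain_state <- function(x, zbar, beta = 1, alpha = 1, sz_inv = 0,
                               w = 0, w_prec = Inf) {
  x <- matrix(x, nrow = 1)
  n <- ncol(x)
  data <- multiview_dataset(x, matrix(0, 1, n), matrix(0, 1, n),
                            rep("a", n), zero_shot = FALSE)
  cfg <- model_config(latent_dim = 1, included_views = "brain", seed = 1)
  st <- init_state(data, cfg)
  st$Z <- matrix(zbar, nrow = 1)
  st$Sz_inv <- matrix(sz_inv, 1, 1)
  st$Sz <- matrix(if (sz_inv > 0) 1 / sz_inv else Inf, 1, 1)
  st$beta[["brain"]] <- beta
  st$alpha[["brain"]] <- matrix(alpha, 1, 1)
  st$W[["brain"]] <- matrix(w, 1, 1)
  st$W_prec[["brain"]] <- matrix(w_prec, 1, 1)
  list(state = st, data = data)
}

# Exact posterior moments of scalar W in x_n = W z_n + N(0, 1/beta) with
# prior N(0, 1/alpha), by brute-force quadrature on a fine grid.
grid_posterior_w <- function(x, z, beta, alpha, half_width = 8, n_grid = 4e5) {
  prec <- beta * sum(z^2) + alpha
  centre <- beta * sum(x * z) / prec
  grid <- seq(centre - half_width / sqrt(prec),
              centre + half_width / sqrt(prec), length.out = n_grid)
  loglik <- -0.5 * alpha * grid^2 -
    0.5 * beta * vapply(grid, function(w) sum((x - w * z)^2), 0)
  dens <- exp(loglik - max(loglik))
  dens <- dens / sum(dens)
  mu <- sum(grid * dens)
  list(mean = mu, var = sum((grid - mu)^2 * dens))
}

expect_spd <- function(m) {
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_true(all(eigen(m, symmetric = TRUE, only.values = TRUE)$values > 0))
}
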