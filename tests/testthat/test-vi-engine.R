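test_that("initialization is seeded, prior-faithful and dimensionally right", {
  d <- tiny_dataset(df = 6, dv = 4, ds = 3, n = 10, m = 4, seed = 2)
  cfg <- model_config(seed = 99)
  s1 <- init_state(d, cfg)
  s2 <- init_state(d, cfg)
  expect_identical(s1, s2)                       # same seed, bit-identical
  expect_equal(s1$Dz, 3)                         # auto = smallest view dim
  expect_true(all(vapply(s1$alpha, function(a) all(a == 1), TRUE)))
  expect_equal(s1$gamma_shape, 0.5)              # 1/2 + gamma0 with gamma0 = 0
  expect_equal(unname(s1$gamma_beta),
               unname(s1$dims * (s1$N + s1$M) / 2))
  expect_equal(dim(s1$Xmiss), c(6, 4))
  expect_error(init_state(d, model_config(latent_dim = 4)),
               class = "mvg_config_error")

  big <- init_state(tiny_dataset(df = 100, dv = 100, ds = 100, n = 100, seed = 3),
                    model_config(seed = 17))
  expect_lt(abs(mean(big$Z)), 0.03)              # SE bound for 10,000 normals
})

test_that("q(W) update reproduces the hand-worked scalar case", {
  # Df = Dz = 1, N = 2, zbar = (1,1), x = (2,2), beta = 1, alpha = 1,
  # [Sz^-1] = 0.5: precision = 1*(2 + 2*0.5) + 1 = 4, mean = (1/4)*4 = 1
  ms <- manual_brain_state(x = c(2, 2), zbar = c(1, 1), sz_inv = 0.5)
  st <- update_w(ms$state, ms$data, "brain")
  expect_equal(st$W_prec$brain[1, 1], 4)
  expect_equal(st$W$brain[1, 1], 1)
  # zero cross-moment gives a zero mean, and precision never drops below alpha
  ms0 <- manual_brain_state(x = c(1, -1), zbar = c(1, 1), alpha = 2.5)
  st0 <- update_w(ms0$state, ms0$data, "brain")
  expect_equal(st0$W$brain[1, 1], 0)
  expect_true(all(st0$W_prec$brain >= st0$alpha$brain))
})

test_that("q(W) update equals the exact scalar posterior from quadrature", {
  set.seed(31)
  z <- rnorm(5); x <- 1.4 * z + rnorm(5, sd = 0.5)
  beta <- 4; alpha <- 0.7
  ms <- manual_brain_state(x = x, zbar = z, beta = beta, alpha = alpha,
                           sz_inv = 0)   # latents treated as exact
  st <- update_w(ms$state, ms$data, "brain")
  oracle <- grid_posterior_w(x, z, beta, alpha)
  expect_equal(st$W$brain[1, 1], oracle$mean, tolerance = 1e-6)
  expect_equal(1 / st$W_prec$brain[1, 1], oracle$var, tolerance = 1e-6)
})

test_that("q(Z) update matches the scalar case and the ridge limit", {
  # one view, Wbar = 2, beta = 1, V = 0: Sz = 5, zbar = 0.4 x
  ms <- manual_brain_state(x = c(1, -2, 3), zbar = c(0, 0, 0), w = 2)
  st <- update_z(ms$state, ms$data)
  expect_equal(st$Sz[1, 1], 5)
  expect_equal(as.numeric(st$Z), 0.4 * c(1, -2, 3))
  expect_spd(st$Sz)

  # all-zero observations give all-zero latents
  msz <- manual_brain_state(x = c(0, 0), zbar = c(1, 1), w = 2)
  expect_equal(as.numeric(update_z(msz$state, msz$data)$Z), c(0, 0))

  # W = I, vanishing loading variance, huge beta: zbar -> x
  set.seed(8)
  n <- 5
  x <- matrix(rnorm(3 * n), 3)
  d <- multiview_dataset(x, matrix(0, 1, n), matrix(0, 1, n), rep("a", n),
                         zero_shot = FALSE)
  st <- init_state(d, model_config(latent_dim = 3, included_views = "brain"))
  st$W$brain <- diag(3)
  st$W_prec$brain <- matrix(Inf, 3, 3)
  st$beta[["brain"]] <- 1e10
  out <- update_z(st, d)
  expect_equal(out$Z, x, tolerance = 1e-8)
})

test_that("missing-value update is the loading map of the latent means", {
  d <- tiny_dataset(df = 3, dv = 3, ds = 3, n = 4, m = 2, seed = 5)
  st <- init_state(d, model_config(latent_dim = 2, seed = 1))
  st$W$brain <- matrix(c(3, 0, 0, 0, 3, 0), 3, 2)  # scalar-like loading of 3
  st$Z[, 5:6] <- 2
  st <- update_missing(st)
  expect_equal(st$Xmiss[1, ], c(6, 6))
  expect_equal(st$Xmiss, st$W$brain %*% st$Z[, 5:6])
  expect_equal(st$Xmiss_var, 1 / st$beta[["brain"]])
  # M = 0 is a no-op, not an error
  d0 <- tiny_dataset(m = 0)
  st0 <- init_state(d0, model_config(seed = 1))
  expect_identical(update_missing(st0), st0)
})

test_that("ARD update follows Eq-style moments and clips at the cap", {
  ms <- manual_brain_state(x = c(1, 1), zbar = c(1, 1), w = 1, w_prec = 1)
  st <- update_alpha(ms$state)
  expect_equal(st$alpha$brain[1, 1], 0.5)        # 1/(W^2 + sigma^-1) = 1/2
  ms2 <- manual_brain_state(x = c(1, 1), zbar = c(1, 1), w = 0, w_prec = 1e30)
  st2 <- update_alpha(ms2$state)
  expect_equal(st2$alpha$brain[1, 1], st2$config$alpha_cap)
})

test_that("noise precision update matches shape and the scalar residual case", {
  d <- tiny_dataset(df = 10, dv = 3, ds = 2, n = 20, m = 0, seed = 4)
  st <- init_state(d, model_config(latent_dim = 2, seed = 2))
  expect_equal(unname(st$gamma_beta[["brain"]]), 100)  # Dk(N+M)/2

  # residuals (1, 1), no variance terms, Dk = 1, N+M = 2: beta^-1 = 1
  ms <- manual_brain_state(x = c(1, 1), zbar = c(0, 0), w = 1, w_prec = Inf,
                           sz_inv = 0)
  st2 <- update_beta(ms$state, ms$data, "brain")
  expect_equal(unname(st2$beta[["brain"]]), 1)
  # perfect fit with vanishing variances hits the guard floor, stays positive
  msp <- manual_brain_state(x = c(2, 2), zbar = c(1, 1), w = 2, w_prec = Inf,
                            sz_inv = 0)
  stp <- update_beta(msp$state, msp$data, "brain")
  expect_true(is.finite(stp$beta[["brain"]]) && stp$beta[["brain"]] > 0)
  expect_equal(unname(1 / stp$beta[["brain"]]), stp$config$beta_inv_floor)
})

test_that("fit keeps precisions positive, Sz SPD, and logs every sweep", {
  bench <- sample_dataset(sample_ground_truth(seed = 21), seed = 22)
  std <- standardize_bundle(bench$dataset)
  cfg <- model_config(latent_dim = 5, seed = 23)
  expect_equal(cfg$n_iterations, 10)             # protocol default
  st <- mvg_fit(std$dataset, cfg)
  expect_length(st$diagnostics, 10)
  expect_true(all(unlist(st$beta) > 0))
  for (k in st$views) {
    expect_true(all(st$W_prec[[k]] > 0))
    expect_true(all(st$alpha[[k]] > 0))
  }
  expect_spd(st$Sz)
  d <- compute_diagnostics(st, std$dataset)
  expect_named(d$recon_error, st$views)
  expect_true(all(d$recon_error > 0))
})

test_that("diagnostics report zero error for an exact noiseless fit", {
  set.seed(12)
  W <- matrix(rnorm(8), 4, 2); Z <- matrix(rnorm(12), 2, 6)
  x <- W %*% Z
  d <- multiview_dataset(x, matrix(0, 1, 6), matrix(0, 1, 6), rep("a", 6),
                         zero_shot = FALSE)
  st <- init_state(d, model_config(latent_dim = 2, included_views = "brain"))
  st$W$brain <- W; st$W_prec$brain <- matrix(Inf, 4, 2)
  st$Z <- Z; st$Sz_inv <- matrix(0, 2, 2)
  expect_equal(unname(compute_diagnostics(st, d)$recon_error[["brain"]]), 0)
})

test_that("two-view runs reduce exactly to the dedicated BCCA entry points", {
  bench <- sample_dataset(sample_ground_truth(seed = 31), seed = 32)
  std <- standardize_bundle(bench$dataset)
  base <- drop_additional(std$dataset)
  for (fv in c("visual", "semantic")) {
    cfg <- model_config(latent_dim = 4, seed = 77,
                        included_views = c("brain", fv))
    direct <- mvg_fit(base, cfg)
    named <- fit_bcca(std$dataset, model_config(latent_dim = 4, seed = 77),
                      feature_view = fv)
    expect_identical(direct$W, named$W)
    expect_identical(direct$Z, named$Z)
    expect_identical(direct$beta, named$beta)
    expect_identical(direct$alpha, named$alpha)
  }
  # fit_mgm is the M = 0 three-view model
  mgm <- fit_mgm(std$dataset, model_config(latent_dim = 4, seed = 78))
  expect_equal(mgm$M, 0)
  expect_identical(mgm$W, mvg_fit(base, model_config(latent_dim = 4, seed = 78))$W)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(model_config(included_views = c("visual", "semantic")),
               class = "mvg_config_error")
  expect_error(model_config(n_iterations = 0), class = "mvg_config_error")
  expect_error(model_config(alpha_cap = 0.5), class = "mvg_config_error")
  expect_error(model_config(latent_dim = -1), class = "mvg_config_error")
})

test_that("principal angles separate aligned from orthogonal subspaces", {
  set.seed(9)
  a <- matrix(rnorm(40), 10, 4)
  expect_lt(max(principal_angles(a, a)), 1e-4)
  rot <- a %*% qr.Q(qr(matrix(rnorm(16), 4)))
  expect_lt(max(principal_angles(a, rot)), 1e-4)
  expect_equal(principal_angles(diag(4)[, 1:2], diag(4)[, 3:4]),
               c(90, 90))
})
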