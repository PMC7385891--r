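# Gibbs sampler: conditional draws against conjugate oracles, chains,
# diagnostics

test_that("draw_augmented respects threshold intervals and moments", {
  set.seed(101)
  # binary, category 2 with t1 = 0: all draws positive
  x <- draw_augmented(rep(2L, 1000), 0)
  expect_true(all(x > 0))
  # category 1 of balanced binary: mean of N(0,1) truncated to (-Inf, 0]
  y <- draw_augmented(rep(1L, 1e5), 0)
  expect_lt(abs(mean(y) - (-sqrt(2 / pi))), 0.01)
  expect_true(all(y <= 0))
  # three categories: every draw inside its own interval
  cuts <- c(-0.7, 0.9)
  k <- sample(1:3, 5000, replace = TRUE)
  z <- draw_augmented(k, cuts)
  t_full <- c(-Inf, cuts, Inf)
  expect_true(all(z > t_full[k] & z <= t_full[k + 1L]))
  # missing codes draw unconstrained
  expect_length(draw_augmented(c(NA, 1L), 0), 2)
})

test_that("draw_eta matches the conjugate-normal closed form", {
  # single factor, loading vector l, theta_delta d: posterior of eta given p
  # is N(V l' D^-1 p, V), V = (1/v0 + l' D^-1 l)^-1 — standard conjugacy
  m <- model_spec("F1", c("T1", "T2"),
                  Lambda = matrix(c(1, 0.5), 2), Lambda_mask = matrix(c(3L, 2L), 2),
                  theta_eps = 0.8, theta_delta = c(0.5, 0.4))
  p <- c(1.2, -0.3)
  l <- c(1, 0.5); D <- c(0.5, 0.4)
  Vpost <- 1 / (1 / 0.8 + sum(l^2 / D))
  mupost <- Vpost * sum(l * p / D)
  set.seed(102)
  P <- matrix(p, 1e5, 2, byrow = TRUE)
  G <- matrix(0, 1e5, 0); Y <- matrix(0, 1e5, 0)
  draws <- draw_eta(m, P, G, Y)
  expect_lt(abs(mean(draws) - mupost), 0.01)
  expect_lt(abs(var(draws) - Vpost), 0.01)
  # noiseless limit: square invertible Lambda pins eta at Lambda^-1 p
  m2 <- model_spec(c("F1", "F2"), c("T1", "T2"),
                   Lambda = diag(2), Lambda_mask = matrix(2L, 2, 2),
                   theta_eps = c(1, 1), theta_delta = c(1e-10, 1e-10))
  d2 <- draw_eta(m2, matrix(c(0.7, -0.2), 50, 2, byrow = TRUE),
                 matrix(0, 50, 0), matrix(0, 50, 0))
  expect_lt(max(abs(sweep(d2, 2, c(0.7, -0.2)))), 1e-3)
})

test_that("draw_variances matches inverse-gamma moments", {
  set.seed(103)
  # zero residuals, n = 0: prior recovery, E = beta0/(alpha0-1)
  x <- draw_variances(rep(0, 1e5), 0, alpha0 = 3, beta0 = 2)
  expect_lt(abs(mean(x) - 1), 0.02)
  # fixed SSR: E = (beta0 + SSR/2)/(alpha0 + n/2 - 1)
  ssr <- 120; n <- 80
  y <- draw_variances(rep(ssr, 1e5), n, alpha0 = 2, beta0 = 1)
  expect_lt(abs(mean(y) - (1 + ssr / 2) / (2 + n / 2 - 1)) , 0.02)
  expect_true(all(y > 0))
})

test_that("draw_coefficient_rows matches the OLS oracle in the flat-prior limit", {
  set.seed(104)
  n <- 400
  eta <- cbind(rnorm(n), rnorm(n))
  colnames(eta) <- c("F1", "F2")
  b_true <- 0.6
  m <- model_spec(c("F1", "F2"), c("T1", "T2"), theta_eps = c(1, 0.25),
                  theta_delta = c(1, 1))
  m$B_mask[2, 1] <- 1L
  eta[, 2] <- b_true * eta[, 1] + 0.5 * rnorm(n)
  G <- matrix(0, n, 0); Y <- matrix(0, n, 0)
  P <- matrix(0, n, 2)
  ols <- unname(coef(lm(eta[, 2] ~ eta[, 1] - 1)))
  draws <- replicate(2000, {
    st <- draw_coefficient_rows(m, m, eta, P, G, Y, prior_var = 1e8,
                                rows = "structural")
    st$B[2, 1]
  })
  expect_lt(abs(mean(draws) - ols), 0.02)
  # prior dominance: precision -> Inf collapses draws onto the prior mean
  mp <- m; mp$B[2, 1] <- 0.123
  st <- draw_coefficient_rows(mp, mp, eta, P, G, Y, prior_var = 1e-10,
                              rows = "structural")
  expect_lt(abs(st$B[2, 1] - 0.123), 1e-3)
  # row with no sampled cells is unchanged
  m3 <- model_spec("F1", c("T1", "T2"))
  st3 <- draw_coefficient_rows(m3, m3, matrix(rnorm(10), 10, 1), P[1:10, ],
                               matrix(0, 10, 0), matrix(0, 10, 0),
                               rows = "structural")
  expect_identical(st3$B, m3$B)
})

test_that("run_chains is seed-reproducible and respects intervals", {
  tm <- make_true_model(1, 3, snps_per_factor = 2, effect_sizes = 0.4,
                        seed = 105, n_ordinal_traits = 1)
  ds <- simulate_dataset(tm, 200, seed = 106)
  em <- estimation_model_from_truth(tm)
  bh <- bundle_hybrid(ds)
  snps <- colnames(ds$genotypes)
  ft <- fit_ml(em, bh$hb$psd, 200, exo = bh$hb$psd[snps, snps])
  mfit <- freeze_masks(ft$model, c("B", "Lambda", "Pi", "K"))
  gd <- gibbs_data(mfit, ds$phenotypes, ds$genotypes)
  ps1 <- run_chains(mfit, gd, quick_gibbs(), seed = 9)
  ps2 <- run_chains(mfit, gd, quick_gibbs(), seed = 9)
  expect_identical(ps1$draws, ps2$draws)
  ps3 <- run_chains(mfit, gd, quick_gibbs(), seed = 10)
  expect_false(identical(ps1$draws[[1]], ps3$draws[[1]]))
  # theta draws strictly positive
  sm <- posterior_summary(ps1)
  th <- grepl("^theta", sm$parameter)
  pooled <- do.call(rbind, ps1$draws)
  expect_true(all(pooled[, th] > 0))
})

test_that("gelman_rubin flags non-convergence and ignores affine scale", {
  set.seed(107)
  iid <- replicate(4, matrix(rnorm(2000), ncol = 1), simplify = FALSE)
  r1 <- gelman_rubin(iid)
  expect_true(r1 > 0.99 && r1 < 1.02)
  apart <- list(matrix(rnorm(2000, 0), ncol = 1),
                matrix(rnorm(2000, 10), ncol = 1))
  expect_gt(gelman_rubin(apart), 1.05)
  shifted <- lapply(iid, function(d) 100 + 5 * d)
  expect_equal(unname(gelman_rubin(shifted)), unname(r1), tolerance = 1e-10)
  expect_error(gelman_rubin(iid[1]), "at least 2")
})

test_that("effective_sample_size matches iid and AR(1) oracles", {
  set.seed(108)
  x <- matrix(rnorm(1e4), ncol = 1)
  e1 <- effective_sample_size(list(x))
  expect_lt(abs(e1 - 1e4) / 1e4, 0.1)
  # AR(1): ESS ~= n (1 - phi) / (1 + phi)
  phi <- 0.9
  ar <- as.numeric(stats::arima.sim(list(ar = phi), 2e4))
  e2 <- effective_sample_size(list(matrix(ar, ncol = 1)))
  expect_lt(abs(e2 - 2e4 * (1 - phi) / (1 + phi)) / (2e4 * (1 - phi) / (1 + phi)),
            0.3)
  expect_lte(e2, 2e4)
  # constant chain: 0 with flag
  e3 <- effective_sample_size(list(matrix(1, 100, 1)))
  expect_equal(unname(e3), 0)
})

test_that("posterior_summary pools chains and matches raw draws", {
  d1 <- matrix(1:6, 3, 2, dimnames = list(NULL, c("a", "b")))
  d2 <- matrix(7:12, 3, 2, dimnames = list(NULL, c("a", "b")))
  ps <- structure(list(draws = list(d1, d2)), class = "posterior_samples")
  sm <- posterior_summary(ps)
  expect_equal(sm$mean, colMeans(rbind(d1, d2)), ignore_attr = TRUE)
  # single-value chains: sd 0, mean that value
  ps2 <- structure(list(draws = list(matrix(2, 5, 1,
                                            dimnames = list(NULL, "a")))),
                   class = "posterior_samples")
  sm2 <- posterior_summary(ps2)
  expect_equal(sm2$mean, 2)
  expect_equal(sm2$sd, 0)
})

test_that("posterior concentrates as n grows", {
  sds <- sapply(c(200, 2000), function(n) {
    tm <- make_true_model(1, 3, snps_per_factor = 1, effect_sizes = 0.4,
                          seed = 109)
    ds <- simulate_dataset(tm, n, seed = 110)
    em <- estimation_model_from_truth(tm)
    bh <- bundle_hybrid(ds)
    snps <- colnames(ds$genotypes)
    ft <- fit_ml(em, bh$hb$psd, n, exo = bh$hb$psd[snps, snps])
    mfit <- freeze_masks(ft$model, c("B", "Lambda", "Pi", "K"))
    gd <- gibbs_data(mfit, ds$phenotypes, ds$genotypes)
    ps <- run_chains(mfit, gd, quick_gibbs(), seed = 11)
    sm <- posterior_summary(ps)
    mean(sm$sd[grepl("^(Pi|Lambda)", sm$parameter)])
  })
  expect_lt(sds[2], sds[1])
})
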