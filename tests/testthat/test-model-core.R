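# model core: implied covariance, Wishart likelihood, ML fitting, Wald tests

test_that("implied covariance: trivial single-factor cases", {
  m <- tiny_model()
  m$Lambda[2, 1] <- 0
  m$Lambda_mask[2, 1] <- 0L
  # one factor, one effective trait, loading 1, theta_eps = theta_delta = 1:
  # Var(T1) = 1 + 1 = 2
  Sig <- implied_covariance(m)
  expect_equal(Sig["T1", "T1"], 2)
  expect_equal(Sig["T2", "T2"], 1)  # loading 0: pure error variance
  expect_true(isSymmetric(Sig))
})

test_that("implied covariance: no-SNP model is independent of exo", {
  m <- tiny_model()
  expect_identical(implied_covariance(m), implied_covariance(m, exo = NULL))
  # factor-analysis reduction: Lambda Cov(eta) Lambda' + Theta_delta
  Sig <- implied_covariance(m)
  L <- m$Lambda
  expect_equal(unname(Sig[1:2, 1:2]),
               unname(L %*% t(L) * m$theta_eps + diag(m$theta_delta)))
})

test_that("implied covariance matches Monte-Carlo oracle on random small models", {
  # brute-force simulation from the generative equations
  for (seed in c(41, 42)) {
    tm <- make_true_model(2, c(2, 2), snps_per_factor = c(2, 1),
                          snps_per_trait = c(1, 0, 0, 0),
                          b_edges = data.frame(from = "F1", to = "F2",
                                               coef = 0.4),
                          effect_sizes = 0.4, seed = seed)
    ds <- simulate_dataset(tm, 2e5, seed = seed + 100)
    X <- cbind(as.matrix(ds$phenotypes), ds$latent_snps)
    S <- stats::cov(X)
    exo <- diag(1, ncol(ds$latent_snps))
    dimnames(exo) <- list(colnames(ds$latent_snps), colnames(ds$latent_snps))
    Sig <- implied_covariance(tm, exo)
    vn <- rownames(Sig)
    rel <- norm(S[vn, vn] - Sig, "F") / norm(Sig, "F")
    expect_lt(rel, 0.02)
    # admissible parameters give a PSD implied covariance
    expect_gte(min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("implied covariance error cases", {
  m <- tiny_model()
  m$B[1, 1] <- 1  # (I - B) singular
  expect_error(implied_covariance(m), "singular")
  tm <- make_true_model(1, 2, snps_per_factor = 1, seed = 1)
  expect_error(implied_covariance(tm, exo = NULL), "exogenous")
  bad_exo <- matrix(1, 1, 1, dimnames = list("wrong", "wrong"))
  expect_error(implied_covariance(tm, bad_exo), "missing")
})

test_that("wishart_loglik agrees with an independently coded density", {
  # oracle: direct transcription of the Wishart pdf, written separately
  wishart_oracle <- function(S, Sigma, n) {
    d <- nrow(S); nu <- n - 1; W <- nu * S
    lmg <- d * (d - 1) / 4 * log(pi) +
      sum(lgamma(nu / 2 + (1 - seq_len(d)) / 2))
    as.numeric((nu - d - 1) / 2 * determinant(W)$modulus -
                 sum(diag(solve(Sigma, W))) / 2 -
                 nu * d / 2 * log(2) - nu / 2 * determinant(Sigma)$modulus -
                 lmg)
  }
  S <- diag(2)
  expect_equal(wishart_loglik(S, S, 100), wishart_oracle(S, S, 100))
  set.seed(7)
  A <- crossprod(matrix(rnorm(9), 3))
  B <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  expect_equal(wishart_loglik(A, B, 50), wishart_oracle(A, B, 50))
  # d = 1: W = (n-1)s2 with W/sig ~ chi-squared(n-1)
  s2 <- 1.7; sig <- 2.0; n <- 50; nu <- n - 1
  expect_equal(wishart_loglik(matrix(s2, 1, 1), matrix(sig, 1, 1), n),
               dchisq(nu * s2 / sig, nu, log = TRUE) - log(sig))
})

test_that("wishart_loglik is monotone decreasing under Sigma inflation", {
  S <- diag(2)
  lls <- sapply(c(1, 2, 5, 50, 500), function(cc) wishart_loglik(S, cc * S, 100))
  expect_true(all(diff(lls) < 0))
  expect_error(wishart_loglik(S, matrix(c(1, 2, 2, 1), 2), 100), "positive definite")
})

test_that("fit_ml recovers a single free loading exactly at zero noise", {
  m <- tiny_model()
  m$theta_eps_free <- FALSE   # keep the 2-trait model identified
  truth <- m
  truth$Lambda[2, 1] <- 0.7
  S <- implied_covariance(truth)  # exact implied covariance as 'data'
  ft <- fit_ml(m, S, 1000)
  expect_true(ft$converged)
  expect_equal(unname(ft$model$Lambda[2, 1]), 0.7, tolerance = 1e-5)
  # monotone improvement over the deterministic start
  start_model <- ft$model
  idx <- ft$param_index
  start_vals <- semgwas:::default_start(idx, m, S)
  m0 <- semgwas:::set_free_params(m, idx, start_vals)
  ll0 <- wishart_loglik(S, implied_covariance(m0), 1000)
  expect_gte(ft$loglik, ll0)
})

test_that("fit_ml: saturated 2-variable model reproduces S at the optimum", {
  # saturated: anchor loading + free loading + free trait variances,
  # factor variance fixed (3 parameters for 3 distinct covariance entries)
  m <- tiny_model()
  m$theta_eps_free <- FALSE
  m$theta_eps <- 0.5   # below the sample variances so theta_delta stays positive
  set.seed(3)
  X <- matrix(rnorm(400), 200)
  X[, 2] <- 0.5 * X[, 1] + sqrt(0.75) * X[, 2]
  S <- cov(X); dimnames(S) <- list(c("T1", "T2"), c("T1", "T2"))
  ft <- fit_ml(m, S, 200)
  Sig <- implied_covariance(ft$model)
  expect_equal(unname(Sig[1:2, 1:2]), unname(S), tolerance = 1e-3)
})

test_that("fit_ml refuses over-parameterised models", {
  # 2 observed variables: 3 distinct covariance entries; 5 free parameters
  m <- tiny_model()
  m$Lambda_mask[1, 1] <- 1L  # both loadings free + 2 theta_delta + theta_eps
  S <- diag(2); dimnames(S) <- list(c("T1", "T2"), c("T1", "T2"))
  expect_error(fit_ml(m, S, 100), "not identified")
})

test_that("param_significance implements the two-sided Wald z-test", {
  est <- c(a = 1.96, b = 0, c = 0.5)
  info <- diag(c(1, 1, 1 / 0.1^2))  # se = 1, 1, 0.1
  ps <- param_significance(est, info)
  expect_equal(ps$p_value[1], 0.05, tolerance = 1e-3)
  expect_equal(ps$p_value[2], 1)
  expect_equal(ps$p_value[3], 2 * (1 - pnorm(5)))  # independent normal oracle
  # singular information: affected parameters get p = 1 with a warning
  info2 <- matrix(0, 3, 3)
  expect_warning(ps2 <- param_significance(est, info2), "not invertible")
  expect_true(all(ps2$p_value == 1))
})

test_that("is_acyclic classifies graphs correctly", {
  expect_true(is_acyclic(matrix(0, 3, 3)))
  cyc <- matrix(0, 2, 2); cyc[1, 2] <- cyc[2, 1] <- 1
  expect_false(is_acyclic(cyc))
  expect_false(is_acyclic(matrix(1, 1, 1)))  # self loop
  # random DAGs from topological construction are always acyclic
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:7, 1)
    adj <- matrix(0, n, n)
    ord <- sample(n)
    for (j in 2:n) for (i2 in 1:(j - 1))
      if (runif(1) < 0.4) adj[ord[j], ord[i2]] <- 1  # edge early -> late
    expect_true(is_acyclic(adj))
  }
})

test_that("model JSON serialisation round-trips losslessly", {
  tm <- make_true_model(2, c(3, 2), snps_per_factor = 2, snps_per_trait = 1,
                        b_edges = data.frame(from = "F1", to = "F2", coef = 0.3),
                        n_ordinal_traits = 1, seed = 5)
  js <- model_to_json(tm)
  back <- model_from_json(js)
  for (f in c("latent_names", "trait_names", "trait_kinds",
              "snp_factor_names", "snp_trait_names", "theta_eps",
              "theta_delta")) {
    expect_equal(back[[f]], tm[[f]], info = f)
  }
  for (f in c("B", "Lambda", "Pi", "K")) {
    expect_equal(back[[f]], tm[[f]], info = f)
    expect_equal(back[[paste0(f, "_mask")]], tm[[paste0(f, "_mask")]], info = f)
  }
  # file round-trip
  p <- tempfile(fileext = ".json")
  model_to_json(tm, p)
  expect_equal(model_from_json(p)$Lambda, tm$Lambda)
})

test_that("model_spec validation enforces invariants", {
  expect_error(model_spec("F1", c("T1", "T2"), theta_eps = -1),
               "strictly positive")
  B <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(model_spec(c("F1", "F2"), c("T1", "T2"),
                          B = B, B_mask = B), "cyclic")
  Pi <- matrix(1, 2, 1); Pi_mask <- matrix(1L, 2, 1)
  expect_error(model_spec(c("F1", "F2"), c("T1", "T2"),
                          snp_factor_names = "g1",
                          Pi = Pi, Pi_mask = Pi_mask), "one nonzero cell")
})
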