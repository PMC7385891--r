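# trait prediction, metrics, CV plumbing, window congruence, permutation test

test_that("predict_phenotypes maps codes to truncated-normal means", {
  m <- model_spec("F1", c("T1", "T2"),
                  snp_factor_names = "g1",
                  Lambda = matrix(c(1, 0.8), 2), Lambda_mask = matrix(2L, 2, 1),
                  Pi = matrix(0.5, 1, 1), Pi_mask = matrix(2L, 1, 1))
  th <- list(g1 = 0)  # balanced binary SNP
  geno <- matrix(c(1L, 0L, NA), 3, 1, dimnames = list(NULL, "g1"))
  pred <- predict_phenotypes(m, geno, th)
  gtil <- sqrt(2 / pi)  # truncated-normal mean for the upper half
  expect_equal(unname(pred[1, "T1"]), 0.5 * gtil)  # category 2 -> +0.7979
  expect_equal(unname(pred[2, "T1"]), -0.5 * gtil) # category 1 -> -0.7979
  expect_equal(unname(pred[3, ]), c(0, 0))         # missing code -> 0
  expect_equal(unname(pred[1, "T2"]), 0.8 * 0.5 * gtil)
  # all-zero effects give all-zero predictions
  m0 <- m; m0$Pi[] <- 0
  expect_true(all(predict_phenotypes(m0, geno, th) == 0))
  # model SNP absent from test data
  expect_error(predict_phenotypes(m, matrix(1L, 2, 1,
                                            dimnames = list(NULL, "other")),
                                  th), "missing model SNPs")
})

test_that("noiseless model predictions attain the discretisation ceiling", {
  tm <- make_true_model(1, 4, snps_per_factor = 3, effect_sizes = 0.55,
                        seed = 121)
  # shrink noise: SNPs then dominate trait variance
  tm$theta_eps <- 0.01
  tm$theta_delta <- rep(0.01, 4)
  ds <- simulate_dataset(tm, 3000, seed = 122)
  th <- lapply(seq_len(ncol(ds$genotypes)), function(j)
    semgwas:::hw_thresholds(tm$maf[j]))
  names(th) <- colnames(ds$genotypes)
  pred <- predict_phenotypes(tm, ds$genotypes, th)
  # ceiling oracle: predictions see only the category, so the attainable r is
  # sqrt of the average categorisation R^2, Var(E[x|category]) per SNP
  r2cat <- vapply(names(th), function(s) {
    cuts <- th[[s]]; t_full <- c(-Inf, cuts, Inf)
    p <- diff(pnorm(t_full))
    m <- truncnorm_mean(t_full[-length(t_full)], t_full[-1])
    sum(p * m^2)
  }, numeric(1))
  ceiling_r <- sqrt(mean(r2cat))
  for (tr in colnames(pred)) {
    r <- cor(ds$phenotypes[[tr]], pred[, tr])
    expect_gt(r, 0.8)
    expect_lt(abs(r - ceiling_r), 0.05)
  }
})

test_that("prediction_metrics implements the r / r^2 / NRMSE conventions", {
  x <- c(1, 2, 3, 4)
  m <- prediction_metrics(x, x)
  expect_equal(m$r, 1); expect_equal(m$r2, 1); expect_equal(m$nrmse, 0)
  # r = 0.75 pairs with r2 = 0.5625 under the squared-correlation convention
  set.seed(123)
  a <- rnorm(5000); b <- 0.75 * a + sqrt(1 - 0.75^2) * rnorm(5000)
  mm <- prediction_metrics(a, b)
  expect_lt(abs(mm$r - 0.75), 0.03)
  expect_lt(abs(mm$r2 - 0.5625), 0.04)
  # anti-correlated: r = -1 but r2 = 1 (documented convention)
  m2 <- prediction_metrics(x, -x)
  expect_equal(m2$r, -1); expect_equal(m2$r2, 1)
  m3 <- prediction_metrics(rep(1, 5), 1:5)
  expect_equal(m3$flag, "zero_variance")
})

test_that("cross_validate is deterministic and leak-free", {
  tm <- make_true_model(1, 4, snps_per_factor = 3, effect_sizes = 0.5,
                        seed = 124)
  ds <- simulate_dataset(tm, 400, seed = 125)
  geno <- cbind(ds$genotypes, null_snp_codes(400, 4, 126))
  args <- list(phenotypes = ds$phenotypes, genotypes = geno,
               kinds = ds$trait_meta$kind, k = 2, model_type = "zero-base",
               seed = 7, gibbs = quick_gibbs(), n_factors = 1, n_sim = 100,
               stop_cfg = snp_stop_cfg(max_snps = 4))
  cv1 <- do.call(cross_validate, args)
  cv2 <- do.call(cross_validate, args)
  expect_identical(cv1$metrics, cv2$metrics)
  expect_equal(cv1$folds, cv2$folds)
  expect_gt(mean(cv1$metrics$r), 0.2)   # heritable architecture is predictable
  # permuted phenotypes: no real signal to exploit (leakage check)
  set.seed(127)
  phperm <- ds$phenotypes[sample(400), , drop = FALSE]
  rownames(phperm) <- NULL
  argsp <- args; argsp$phenotypes <- phperm
  cvp <- do.call(cross_validate, argsp)
  expect_lt(max(abs(cvp$metrics$r), na.rm = TRUE), 0.2)
})

test_that("window_congruence counts models per window", {
  lens <- c("1" = 2e6)
  # 20 models all with a SNP at 1,000,000: covering windows count 20
  pos <- data.frame(model = 1:20, chrom = "1", pos = 1e6)
  tr <- window_congruence(pos, lens)
  cover <- tr$start <= 1e6 & tr$end > 1e6
  expect_true(all(tr$count[cover] == 20))
  expect_true(all(tr$count[!cover] == 0))
  expect_true(all(tr$count <= 20))
  # hand enumeration: single SNP at 250,000, window 500k, step 100k:
  # starts 0, 100k, 200k qualify (300k+ start after the SNP)
  t2 <- window_congruence(data.frame(model = 1, chrom = "1", pos = 2.5e5),
                          lens)
  expect_equal(t2$start[t2$count == 1], c(0, 1e5, 2e5))
  # empty input: all-zero track
  t3 <- window_congruence(data.frame(model = integer(), chrom = character(),
                                     pos = numeric()), lens)
  expect_true(all(t3$count == 0))
  # order invariance
  t4 <- window_congruence(pos[20:1, ], lens)
  expect_equal(t4$count, tr$count)
  expect_error(window_congruence(data.frame(model = 1, chrom = "1", pos = 3e6),
                                 lens), "beyond chromosome length")
})

test_that("peak_hit_permutation calibrates against circular-shift null", {
  lens <- c("1" = 2e6)
  # irregular spacing so no single circular shift recreates full overlap
  peaks <- data.frame(chrom = "1", start = c(0, 3.3e5, 7.7e5),
                      end = c(1e5, 4.3e5, 8.7e5))
  hits <- data.frame(chrom = "1", pos = c(5e4, 3.8e5, 8.2e5))
  # hits at peak centres: maximal overlap, small p
  res <- peak_hit_permutation(peaks, hits, lens, n_perm = 200, seed = 3)
  expect_equal(res$observed, 3)
  expect_lte(res$p_value, 0.05)
  # no peaks: p = 1
  expect_equal(peak_hit_permutation(peaks[0, ], hits, lens, 200)$p_value, 1)
  # independent hits: p roughly uniform (check it is not systematically tiny)
  set.seed(4)
  ps <- replicate(20, {
    h <- data.frame(chrom = "1", pos = runif(10) * 2e6)
    peak_hit_permutation(peaks, h, lens, n_perm = 100,
                         seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(mean(ps), 0.2)
  expect_warning(peak_hit_permutation(peaks, hits, lens, n_perm = 50),
                 "coarse")
})
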