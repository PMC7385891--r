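# Trait prediction and cross-validated assessment.
#
# Prediction maps each observed SNP code to the conditional mean of its
# latent-normal variable given the category, propagates through the
# structural equations (eta_hat = (I - B)^{-1} Pi g_tilde) and the
# measurement equations (p_hat = Lambda eta_hat + K y_tilde). Missing codes
# map to the latent-scale mean 0.

#' Predict phenotypes from genotypes
#'
#' @param model fitted `model_spec` (e.g. posterior-mean values from
#'   [apply_posterior_means()]).
#' @param genotypes matrix of SNP codes (samples x SNPs) covering all model
#'   SNPs; `NA` allowed.
#' @param thresholds named list of cutpoints per model SNP (from training
#'   data); an entry per SNP in the model is required.
#' @return matrix of predicted trait values (samples x traits), on the
#'   standardised trait scale (ordinal traits: predicted latent score).
#' @export
predict_phenotypes <- function(model, genotypes, thresholds) {
  snps <- c(model$snp_factor_names, model$snp_trait_names)
  missing_snps <- setdiff(snps, colnames(genotypes))
  if (length(missing_snps))
    stop("test genotypes are missing model SNPs: ",
         paste(missing_snps, collapse = ", "), call. = FALSE)
  n <- nrow(genotypes)
  latentize <- function(s) {
    x <- genotypes[, s]
    cut <- thresholds[[s]]
    if (is.null(cut))
      stop("no thresholds supplied for SNP ", s, call. = FALSE)
    lev <- seq_len(length(cut) + 1L)
    # codes may be 0-based (0,1,2) or already 1-based; align to categories
    k <- if (min(x, na.rm = TRUE) == 0) x + 1L else match(x, sort(unique(x[!is.na(x)])))
    t_full <- c(-Inf, cut, Inf)
    m <- truncnorm_mean(t_full[pmin(k, length(lev))],
                        t_full[pmin(k, length(lev)) + 1L])
    m[is.na(x)] <- 0
    m
  }
  nl <- length(model$latent_names)
  G <- vapply(model$snp_factor_names, latentize, numeric(n))
  Y <- vapply(model$snp_trait_names, latentize, numeric(n))
  if (!is.matrix(G)) G <- matrix(G, n)
  if (!is.matrix(Y)) Y <- matrix(Y, n)
  A <- solve(diag(nl) - model$B)
  eta_hat <- if (length(model$snp_factor_names))
    G %*% t(A %*% model$Pi) else matrix(0, n, nl)
  p_hat <- eta_hat %*% t(model$Lambda)
  if (length(model$snp_trait_names)) p_hat <- p_hat + Y %*% t(model$K)
  colnames(p_hat) <- model$trait_names
  p_hat
}

#' Prediction accuracy metrics
#'
#' Pearson correlation, coefficient of determination (reported as the
#' squared correlation, matching the convention where r and r-squared are
#' published as a pair), and RMSE normalised by the observed standard
#' deviation.
#'
#' @param observed,predicted equal-length numeric vectors (>= 3 pairs).
#' @return list with `r`, `r2`, `nrmse`, `n`, `flag` (`"zero_variance"` when
#'   the observed vector is constant; metrics are then `NA`).
#' @export
prediction_metrics <- function(observed, predicted) {
  ok <- !is.na(observed) & !is.na(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  stopifnot(length(observed) >= 3)
  if (stats::sd(observed) == 0)
    return(list(r = NA_real_, r2 = NA_real_, nrmse = NA_real_,
                n = length(observed), flag = "zero_variance"))
  r <- suppressWarnings(stats::cor(observed, predicted))
  if (is.na(r)) r <- 0           # constant predictions: no linear association
  rmse <- sqrt(mean((observed - predicted)^2))
  list(r = r, r2 = r^2, nrmse = rmse / stats::sd(observed),
       n = length(observed), flag = "")
}

#' Full model-construction pipeline on one training set
#'
#' measurement -> (optional) structural -> SNP selection -> Gibbs ->
#' posterior-mean estimates. Exposed so cross-validation and the CLI share
#' one code path.
#'
#' @param phenotypes training trait data.frame.
#' @param genotypes training SNP code matrix.
#' @param kinds per-trait kinds.
#' @param model_type one of `"zero-base"`, `"connected-base"`,
#'   `"zero-extended"`, `"connected-extended"` (zero/connected: without/with
#'   structural edges; base/extended: SNPs on factors only / factors and
#'   traits).
#' @param stop_cfg SNP-selection stopping configuration.
#' @param gibbs Gibbs control ([gibbs_control()]); `NULL` skips sampling and
#'   keeps construction-time ML estimates.
#' @param seed seed for the Gibbs stage.
#' @param n_factors optional override for the factor count.
#' @param n_sim parallel-analysis simulations.
#' @return list with `model` (fitted), `measurement`, `structural`,
#'   `selection_log`, `samples` (posterior), `thresholds` (named cutpoint
#'   list for prediction).
#' @export
build_pipeline <- function(phenotypes, genotypes, kinds,
                           model_type = "connected-base",
                           stop_cfg = snp_stop_cfg(), gibbs = gibbs_control(),
                           seed = 1, n_factors = NULL, n_sim = 200) {
  model_type <- match.arg(model_type,
    c("zero-base", "connected-base", "zero-extended", "connected-extended"))
  connected <- startsWith(model_type, "connected")
  extended <- endsWith(model_type, "extended")
  n <- nrow(phenotypes)
  meas <- build_measurement(phenotypes, kinds, n_sim = n_sim,
                            n_factors = n_factors)
  # hybrid matrix over retained traits + all candidate SNPs
  keep <- meas$model$trait_names
  dat <- cbind(phenotypes[, keep, drop = FALSE], as.data.frame(genotypes))
  kk <- c(meas$model$trait_kinds, rep("ordinal", ncol(genotypes)))
  hb <- hybrid_matrix(dat, kk)
  S <- hb$psd
  struct <- NULL
  if (connected) {
    struct <- build_structural(meas$model, S, n)
    model <- struct$model
    fit <- struct$fit
  } else {
    fit <- fit_ml(meas$model, S, n)
    model <- fit$model
  }
  snps <- colnames(genotypes)
  exo_full <- S[snps, snps, drop = FALSE]
  full <- build_full_model(model, S, n, exo_full, candidates = snps,
                           geno_codes = genotypes, extended = extended,
                           stop_cfg = stop_cfg)
  model <- full$model
  samples <- NULL
  if (!is.null(gibbs)) {
    gd <- gibbs_data(model, phenotypes, genotypes)
    samples <- run_chains(model, gd, gibbs, seed = seed)
    model <- apply_posterior_means(model, samples)
    thresholds <- gd$cutpoints
  } else {
    gd <- gibbs_data(model, phenotypes, genotypes)
    thresholds <- gd$cutpoints
  }
  list(model = model, measurement = meas, structural = struct,
       selection_log = full$selection_log, samples = samples,
       thresholds = thresholds)
}

#' k-fold cross-validated trait prediction
#'
#' Seeded equal-size partition; for each fold the full pipeline (threshold
#' estimation, measurement, structural per `model_type`, SNP selection,
#' Gibbs) runs on the training folds only, and the held-out fold is
#' predicted. Metrics are computed on the pooled held-out predictions.
#'
#' @param phenotypes,genotypes,kinds full dataset.
#' @param k number of folds.
#' @param model_type see [build_pipeline()].
#' @param seed seed controlling the partition and all per-fold randomness.
#' @param ... further arguments passed to [build_pipeline()].
#' @return object of class `cv_result`: list with `metrics` (data.frame per
#'   trait: r, r2, nrmse), `pooled` (observed/predicted per trait),
#'   `fold_info` (per fold: retained traits, SNP counts), `folds`.
#' @export
cross_validate <- function(phenotypes, genotypes, kinds, k = 20,
                           model_type = "connected-base", seed = 1, ...) {
  n <- nrow(phenotypes)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  traits <- colnames(phenotypes)
  pooled_obs <- pooled_pred <- stats::setNames(
    replicate(length(traits), numeric(), simplify = FALSE), traits)
  fold_info <- list()
  for (f in seq_len(k)) {
    test <- fold == f
    pl <- tryCatch(
      build_pipeline(phenotypes[!test, , drop = FALSE],
                     genotypes[!test, , drop = FALSE], kinds,
                     model_type = model_type,
                     seed = as.integer((seed * 131 + f) %% 2147483647), ...),
      error = function(e) e)
    if (inherits(pl, "error")) {
      warning(sprintf("fold %d skipped: %s", f, conditionMessage(pl)))
      fold_info[[f]] <- data.frame(fold = f, ok = FALSE,
                                   n_snp_factor = NA, n_snp_trait = NA)
      next
    }
    pred <- predict_phenotypes(pl$model, genotypes[test, , drop = FALSE],
                               pl$thresholds)
    for (tr in colnames(pred)) {
      pooled_obs[[tr]] <- c(pooled_obs[[tr]], phenotypes[test, tr])
      pooled_pred[[tr]] <- c(pooled_pred[[tr]], pred[, tr])
    }
    fold_info[[f]] <- data.frame(
      fold = f, ok = TRUE,
      n_snp_factor = length(pl$model$snp_factor_names),
      n_snp_trait = length(pl$model$snp_trait_names))
  }
  metrics <- do.call(rbind, lapply(traits, function(tr) {
    if (length(pooled_obs[[tr]]) >= 3) {
      m <- prediction_metrics(pooled_obs[[tr]], pooled_pred[[tr]])
      data.frame(trait = tr, r = m$r, r2 = m$r2, nrmse = m$nrmse, n = m$n)
    } else {
      data.frame(trait = tr, r = NA, r2 = NA, nrmse = NA,
                 n = length(pooled_obs[[tr]]))
    }
  }))
  structure(list(metrics = metrics,
                 pooled = list(observed = pooled_obs, predicted = pooled_pred),
                 fold_info = do.call(rbind, fold_info), folds = fold,
                 model_type = model_type, k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s model)\n", x$k, x$model_type))
  print(transform(x$metrics, r = round(r, 3), r2 = round(r2, 3),
                  nrmse = round(nrmse, 3)))
  invisible(x)
}

#' Sliding-window congruence of SNP positions across models
#'
#' For every window (fixed size, fixed step, 0-based half-open, start grid
#' at multiples of the step per chromosome) counts how many models have at
#' least one SNP inside.
#'
#' @param snp_positions data.frame with columns `model`, `chrom`, `pos` and
#'   optionally `subset` (e.g. the factor a SNP belongs to).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window,step window size and step in bp.
#' @return data.frame `chrom`, `start`, `end`, `subset`, `count`.
#' @export
window_congruence <- function(snp_positions, chrom_lengths,
                              window = 5e5, step = 1e5) {
  if (is.null(snp_positions$subset))
    snp_positions$subset <- rep("all", nrow(snp_positions))
  if (!nrow(snp_positions)) {
    subsets <- "all"
  } else {
    if (any(snp_positions$pos > chrom_lengths[as.character(snp_positions$chrom)]))
      stop("SNP positions beyond chromosome length", call. = FALSE)
    subsets <- unique(snp_positions$subset)
  }
  out <- list()
  for (ch in names(chrom_lengths)) {
    starts <- seq(0, max(0, chrom_lengths[[ch]] - 1), by = step)
    for (sb in subsets) {
      sel <- snp_positions$chrom == ch & snp_positions$subset == sb
      pos <- snp_positions$pos[sel]
      mod <- snp_positions$model[sel]
      counts <- vapply(starts, function(s)
        length(unique(mod[pos >= s & pos < s + window])), integer(1))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = starts, end = starts + window,
        subset = sb, count = counts, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Permutation test for peak / GWAS-hit concordance
#'
#' Observed statistic: number of hits falling inside peak windows. Null:
#' hit positions circularly shifted per chromosome by uniform offsets.
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param peaks data.frame `chrom`, `start`, `end` of peak windows.
#' @param hits data.frame `chrom`, `pos` of external hits.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n_perm number of permutations (warns below 100).
#' @param seed seed.
#' @return list with `p_value`, `observed`, `null` (vector of null counts).
#' @export
peak_hit_permutation <- function(peaks, hits, chrom_lengths, n_perm = 1000,
                                 seed = 1) {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value")
  count_in <- function(pos_by_chrom) {
    tot <- 0L
    for (ch in names(pos_by_chrom)) {
      pk <- peaks[peaks$chrom == ch, , drop = FALSE]
      if (!nrow(pk)) next
      p <- pos_by_chrom[[ch]]
      for (i in seq_along(p))
        if (any(p[i] >= pk$start & p[i] < pk$end)) tot <- tot + 1L
    }
    tot
  }
  if (!nrow(peaks)) return(list(p_value = 1, observed = 0L, null = integer()))
  hp <- split(hits$pos, as.character(hits$chrom))
  observed <- count_in(hp)
  set.seed(seed)
  null <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    shifted <- lapply(names(hp), function(ch) {
      L <- chrom_lengths[[ch]]
      (hp[[ch]] + stats::runif(1) * L) %% L
    })
    names(shifted) <- names(hp)
    null[b] <- count_in(shifted)
  }
  list(p_value = (1 + sum(null >= observed)) / (1 + n_perm),
       observed = observed, null = null)
}
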