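# Automatic model construction.
#
# Measurement part: parallel analysis fixes the number of factors; ML factor
# analysis with varimax rotation provides standardised loadings; a trait is
# attributed to the factor on which its absolute loading exceeds 0.5 (highest
# |loading| on ties), factors with fewer than two attributed traits and
# unattributed traits are dropped.
#
# Structural part: greedy forward search over directed factor pairs; an edge
# is admissible if it keeps B acyclic and leaves every free Lambda and B
# parameter significant at alpha; the admissible edge with the highest fitted
# log-likelihood is added; search stops when the best gain is <= 1e-4.

#' Parallel analysis for the number of factors
#'
#' Horn's criterion with a column-permutation null: the number of eigenvalues
#' of the observed correlation matrix exceeding the `quantile` (default 95th)
#' percentile of the corresponding null eigenvalues over `n_sim`
#' permuted datasets.
#'
#' @param trait_data numeric matrix/data.frame of (standardised) traits.
#' @param n_sim number of permuted null datasets (>= 100).
#' @param quantile null quantile for the comparison.
#' @return integer number of factors.
#' @export
parallel_analysis <- function(trait_data, n_sim = 500, quantile = 0.95) {
  X <- as.matrix(trait_data)
  stopifnot(n_sim >= 100)
  if (nrow(X) < ncol(X))
    warning("fewer samples than traits; eigenvalues are unstable")
  obs <- eigen(stats::cor(X, use = "pairwise.complete.obs"),
               symmetric = TRUE, only.values = TRUE)$values
  p <- ncol(X)
  null_ev <- matrix(0, n_sim, p)
  for (s in seq_len(n_sim)) {
    Xp <- apply(X, 2, sample)
    null_ev[s, ] <- eigen(stats::cor(Xp, use = "pairwise.complete.obs"),
                          symmetric = TRUE, only.values = TRUE)$values
  }
  thr <- apply(null_ev, 2, stats::quantile, probs = quantile, names = FALSE)
  sum(cumprod(obs > thr))   # contiguous leading eigenvalues only
}

#' Build the measurement part from trait data
#'
#' Runs parallel analysis, ML factor analysis (varimax rotation) on the
#' hybrid correlation matrix, applies the 0.5 attribution rule, drops weak
#' factors and unattributed traits, and returns a model specification whose
#' Lambda mask anchors the first attributed trait of each factor at 1.
#'
#' @param trait_data samples x traits matrix/data.frame (ordinal traits as
#'   integer codes).
#' @param kinds per-trait kind (`"continuous"`/`"ordinal"`); default all
#'   continuous.
#' @param n_sim,quantile passed to [parallel_analysis()].
#' @param cutoff attribution threshold on |standardised loading| (strict
#'   inequality).
#' @param n_factors optional override skipping parallel analysis.
#' @return list with `model` (a `model_spec`), `attribution` (data.frame
#'   factor/trait/loading), `loadings` (full rotated loading matrix),
#'   `n_factors`, `dropped_traits`, `dropped_factors`, `hybrid`.
#' @export
build_measurement <- function(trait_data, kinds = NULL, n_sim = 500,
                              quantile = 0.95, cutoff = 0.5,
                              n_factors = NULL) {
  X <- as.data.frame(trait_data)
  if (is.null(kinds)) kinds <- rep("continuous", ncol(X))
  hb <- hybrid_matrix(X, kinds)
  if (is.null(n_factors)) {
    # parallel analysis on numeric codes (null calibration only needs shape)
    n_factors <- parallel_analysis(data.matrix(X), n_sim = n_sim,
                                   quantile = quantile)
  }
  if (n_factors < 1)
    stop("no measurement structure: parallel analysis retained zero factors",
         call. = FALSE)
  fa <- stats::factanal(covmat = hb$psd, factors = n_factors,
                        n.obs = hb$n, rotation = "varimax")
  Lfull <- unclass(fa$loadings)
  # attribution: |loading| > cutoff, ties to the largest |loading|
  best <- apply(abs(Lfull), 1, which.max)
  bestval <- abs(Lfull)[cbind(seq_len(nrow(Lfull)), best)]
  attributed <- bestval > cutoff
  att <- data.frame(trait = rownames(Lfull), factor_idx = best,
                    loading = Lfull[cbind(seq_len(nrow(Lfull)), best)],
                    stringsAsFactors = FALSE)[attributed, , drop = FALSE]
  keep_f <- as.integer(names(which(table(att$factor_idx) >= 2)))
  dropped_factors <- setdiff(seq_len(n_factors), keep_f)
  att <- att[att$factor_idx %in% keep_f, , drop = FALSE]
  if (!nrow(att))
    stop("no measurement structure: no factor retains two attributed traits",
         call. = FALSE)
  dropped_traits <- setdiff(colnames(X), att$trait)
  # relabel retained factors in order
  att$factor <- paste0("F", match(att$factor_idx, keep_f))
  ln <- paste0("F", seq_along(keep_f))
  tn <- att$trait
  nt <- length(tn)
  Lambda <- matrix(0, nt, length(ln), dimnames = list(tn, ln))
  L_mask <- storage_int(Lambda)
  for (i in seq_len(nt)) {
    j <- match(att$factor[i], ln)
    Lambda[i, j] <- att$loading[i]
    L_mask[i, j] <- MASK_FREE
  }
  for (j in seq_along(ln)) {
    first <- which(L_mask[, j] == MASK_FREE)[1]
    L_mask[first, j] <- MASK_ANCHOR
    Lambda[first, j] <- 1
  }
  model <- model_spec(ln, tn, kinds[match(tn, colnames(X))],
                      Lambda = Lambda, Lambda_mask = L_mask)
  list(model = model,
       attribution = att[, c("factor", "trait", "loading")],
       loadings = Lfull, n_factors = n_factors,
       dropped_traits = dropped_traits, dropped_factors = dropped_factors,
       hybrid = hb)
}

#' Greedy construction of the structural part
#'
#' Iteratively adds directed edges between latent factors. Each iteration
#' evaluates every ordered factor pair whose edge (a) is not yet present,
#' (b) keeps B acyclic, and (c) after refitting leaves all free Lambda and B
#' parameters significant at `alpha`; the candidate with the highest fitted
#' log-likelihood is added. Search stops when the best admissible candidate
#' improves the log-likelihood by `tol` or less.
#'
#' @param model measurement-part model from [build_measurement()].
#' @param S sample (hybrid) covariance over the model traits.
#' @param n sample size.
#' @param alpha significance level for Wald tests on Lambda and B entries.
#' @param tol minimal log-likelihood gain to continue.
#' @return list with `model` (B mask and fitted values), `fit` (final
#'   [fit_ml()] result), `edges` (data.frame from/to/estimate/p_value),
#'   `loglik_trace`.
#' @export
build_structural <- function(model, S, n, alpha = 0.05, tol = 1e-4) {
  base_fit <- fit_ml(model, S, n)
  model <- base_fit$model
  trace <- base_fit$loglik
  repeat {
    nl <- length(model$latent_names)
    cand <- which(model$B_mask == MASK_ABSENT & !diag(TRUE, nl), arr.ind = TRUE)
    best <- NULL
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 2]; j <- cand[r, 1]       # edge i -> j sits at B[j, i]
      m2 <- model
      m2$B_mask[j, i] <- MASK_FREE
      if (!is_acyclic(m2$B_mask != MASK_ABSENT)) next
      ft <- tryCatch(fit_ml(m2, S, n), error = function(e) NULL)
      if (is.null(ft) || !ft$converged) next
      sig <- param_significance(ft$estimates, ft$info)
      coef_rows <- grepl("^(B|Lambda)\\[", sig$parameter)
      if (any(sig$p_value[coef_rows] >= alpha)) next
      if (is.null(best) || ft$loglik > best$loglik)
        best <- list(fit = ft, loglik = ft$loglik, i = i, j = j)
    }
    if (is.null(best) || best$loglik - trace[length(trace)] <= tol) break
    model <- best$fit$model
    trace <- c(trace, best$loglik)
    base_fit <- best$fit
  }
  sig <- param_significance(base_fit$estimates, base_fit$info)
  bsel <- grepl("^B\\[", sig$parameter)
  edges <- data.frame(from = character(), to = character(),
                      estimate = numeric(), p_value = numeric())
  if (any(bsel)) {
    lbl <- sub("^B\\[", "", sub("\\]$", "", sig$parameter[bsel]))
    parts <- strsplit(lbl, ",", fixed = TRUE)
    edges <- data.frame(
      from = vapply(parts, `[`, "", 2), to = vapply(parts, `[`, "", 1),
      estimate = sig$estimate[bsel], p_value = sig$p_value[bsel],
      stringsAsFactors = FALSE)
  }
  list(model = model, fit = base_fit, edges = edges, loglik_trace = trace)
}
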