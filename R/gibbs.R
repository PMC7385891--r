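# Gibbs sampler with data augmentation for ordinal variables.
#
# One sweep, in order: (1) augmented latent data for ordinal traits and all
# SNP codes from truncated standard normals given the observed category
# (independently of the parameters); (2) latent factors from their exact
# multivariate-normal full conditional; (3) Theta_eps from inverse-gamma;
# (4) rows of [B, Pi] from conjugate normal regressions; (5) Theta_delta
# from inverse-gamma; (6) rows of [Lambda, K] likewise. Coefficient priors
# are N(construction value, prior_var); variance priors IG(alpha0, beta0).
# Anchor cells (mask 3) are never sampled; absent cells stay zero.

#' Draw augmented latent data for ordinal observations
#'
#' Truncated standard-normal draws inside the threshold interval of each
#' observed category; missing codes get unconstrained N(0,1) draws.
#'
#' @param codes integer codes, 1-based consecutive categories.
#' @param cutpoints finite threshold vector (length n_categories - 1).
#' @return numeric vector of draws, one per observation.
#' @export
draw_augmented <- function(codes, cutpoints) {
  t_full <- c(-Inf, cutpoints, Inf)
  k <- as.integer(codes)
  lo <- rep(-Inf, length(k)); hi <- rep(Inf, length(k))
  ok <- !is.na(k)
  lo[ok] <- t_full[k[ok]]
  hi[ok] <- t_full[k[ok] + 1L]
  rtruncnorm_std(length(k), lo, hi)
}

# per-sweep state is a plain list; helpers below read/write it

#' Draw latent factors from their full conditional
#'
#' Gaussian conditioning: prior for a sample row is
#' `eta ~ N(A Pi g, A Theta_eps A')` with `A = (I - B)^{-1}`; the likelihood
#' comes from `p = Lambda eta + K y + delta`. All samples share the
#' conditional covariance, so rows are drawn in one vectorised step.
#'
#' @param model `model_spec` with current parameter values.
#' @param P traits on the latent/observed scale (n x traits; augmented
#'   values for ordinal traits).
#' @param G,Y augmented SNP matrices (n x ng, n x ny).
#' @return n x n_latent matrix of draws.
#' @export
draw_eta <- function(model, P, G, Y) {
  nl <- length(model$latent_names)
  A <- solve(diag(nl) - model$B)
  V0 <- A %*% diag(model$theta_eps, nl) %*% t(A)
  m0 <- G %*% t(A %*% model$Pi)                 # n x nl prior means
  V0i <- solve(V0)
  Ldi <- model$Lambda / model$theta_delta       # Theta_delta^{-1} Lambda
  prec <- V0i + t(model$Lambda) %*% Ldi
  prec <- (prec + t(prec)) / 2
  resid <- P - Y %*% t(model$K)                 # n x nt
  rhs <- m0 %*% t(V0i) + resid %*% Ldi          # n x nl
  Vpost <- tryCatch(solve(prec), error = function(e) {
    solve(prec + diag(1e-8, nl))                # jitter repair
  })
  Vpost <- (Vpost + t(Vpost)) / 2
  mu <- rhs %*% Vpost
  rmvnorm_chol(mu, Vpost)
}

#' Draw error variances from their inverse-gamma full conditionals
#'
#' Conjugate update: shape `alpha0 + n/2`, rate `beta0 + SSR/2` per diagonal
#' entry, from the current structural/measurement residuals.
#'
#' @param ssr vector of residual sums of squares.
#' @param n number of samples.
#' @param alpha0,beta0 inverse-gamma prior hyperparameters.
#' @return vector of strictly positive draws.
#' @export
draw_variances <- function(ssr, n, alpha0 = 2, beta0 = 1) {
  pmax(rinvgamma(length(ssr), alpha0 + n / 2, beta0 + ssr / 2), 1e-10)
}

# Conjugate normal draw for the sampled cells of one row of [B, Pi] or
# [Lambda, K]. X: design (n x k), y: response residual (length n), sigma2:
# row error variance, prior N(m0, prior_var I).
draw_row_coefs <- function(X, y, sigma2, m0, prior_var) {
  k <- ncol(X)
  prec <- crossprod(X) / sigma2 + diag(1 / prior_var, k)
  rhs <- crossprod(X, y) / sigma2 + m0 / prior_var
  L <- tryCatch(chol(prec), error = function(e) chol(prec + diag(1e-8, k)))
  mu <- backsolve(L, backsolve(L, rhs, transpose = TRUE))
  drop(mu + backsolve(L, stats::rnorm(k)))
}

#' Draw sampled cells of the coefficient block matrices
#'
#' For each endogenous row, the free/fixed (non-anchor) entries of `[B, Pi]`
#' (factor rows) or `[Lambda, K]` (trait rows) are drawn from the conjugate
#' multivariate-normal full conditional of the row's Gaussian regression,
#' with prior mean at the construction-time values.
#'
#' @param model current `model_spec`; its matrix values hold the current
#'   state.
#' @param prior model holding the prior means (construction-time values).
#' @param eta current latent factor draws (n x nl).
#' @param P,G,Y as in [draw_eta()].
#' @param prior_var prior variance of each coefficient.
#' @param rows which block to update: `"structural"` for `[B, Pi]`,
#'   `"measurement"` for `[Lambda, K]`.
#' @return the model with updated coefficient values.
#' @export
draw_coefficient_rows <- function(model, prior, eta, P, G, Y, prior_var = 1,
                                  rows = c("structural", "measurement")) {
  rows <- match.arg(rows)
  sampled <- function(mask, i) {
    r <- mask[i, ]
    which(r == MASK_FREE | r == MASK_FIXED)
  }
  if (rows == "structural") {
    for (i in seq_along(model$latent_names)) {
      jb <- sampled(model$B_mask, i)
      jp <- sampled(model$Pi_mask, i)
      if (!length(jb) && !length(jp)) next
      X <- cbind(eta[, jb, drop = FALSE], G[, jp, drop = FALSE])
      # response minus anchored/absent contributions (anchors impossible in B
      # by construction, but keep the algebra honest)
      fixed_b <- setdiff(which(model$B_mask[i, ] == MASK_ANCHOR), jb)
      offset <- if (length(fixed_b))
        eta[, fixed_b, drop = FALSE] %*% model$B[i, fixed_b] else 0
      y <- eta[, i] - offset
      m0 <- c(prior$B[i, jb], prior$Pi[i, jp])
      beta <- draw_row_coefs(X, y, model$theta_eps[i], m0, prior_var)
      if (length(jb)) model$B[i, jb] <- beta[seq_along(jb)]
      if (length(jp)) model$Pi[i, jp] <- beta[length(jb) + seq_along(jp)]
    }
  } else {
    for (i in seq_along(model$trait_names)) {
      jl <- sampled(model$Lambda_mask, i)
      jk <- sampled(model$K_mask, i)
      if (!length(jl) && !length(jk)) next
      X <- cbind(eta[, jl, drop = FALSE], Y[, jk, drop = FALSE])
      anchors <- which(model$Lambda_mask[i, ] == MASK_ANCHOR)
      offset <- if (length(anchors))
        eta[, anchors, drop = FALSE] %*% model$Lambda[i, anchors] else 0
      y <- P[, i] - offset
      m0 <- c(prior$Lambda[i, jl], prior$K[i, jk])
      beta <- draw_row_coefs(X, y, model$theta_delta[i], m0, prior_var)
      if (length(jl)) model$Lambda[i, jl] <- beta[seq_along(jl)]
      if (length(jk)) model$K[i, jk] <- beta[length(jl) + seq_along(jk)]
    }
  }
  model
}

#' Gibbs sampler control settings
#'
#' @param n_chains number of independent chains.
#' @param length iterations per chain.
#' @param burn_in discarded leading iterations.
#' @param prior_var coefficient prior variance around the construction values.
#' @param alpha0,beta0 inverse-gamma variance prior.
#' @param init_sd sd of the random initialisation around the prior means.
#' @param augmentation `"conditional"` (default) draws augmented ordinal data
#'   from their exact truncated-normal full conditionals given the current
#'   parameters and latent factors — a correct Gibbs sampler for the joint
#'   model. `"marginal"` draws them from truncated standard normals given
#'   only the observed category (independently of the parameters); this is
#'   simpler but attenuates SNP coefficients toward zero by the
#'   within-category variance share (see the methods vignette).
#' @return list of settings for [run_chains()].
#' @export
gibbs_control <- function(n_chains = 5L, length = 2000L, burn_in = 500L,
                          prior_var = 1, alpha0 = 2, beta0 = 1,
                          init_sd = sqrt(0.1),
                          augmentation = c("conditional", "marginal")) {
  stopifnot(burn_in < length)
  list(n_chains = as.integer(n_chains), length = as.integer(length),
       burn_in = as.integer(burn_in), prior_var = prior_var,
       alpha0 = alpha0, beta0 = beta0, init_sd = init_sd,
       augmentation = match.arg(augmentation))
}

# category interval bounds per observation for one augmented column
aug_bounds <- function(codes, cutpoints) {
  t_full <- c(-Inf, cutpoints, Inf)
  k <- as.integer(codes)
  lo <- rep(-Inf, length(k)); hi <- rep(Inf, length(k))
  ok <- !is.na(k)
  lo[ok] <- t_full[k[ok]]
  hi[ok] <- t_full[k[ok] + 1L]
  list(lo = lo, hi = hi)
}

# Exact full-conditional update of one augmented exogenous column: the
# variable enters a single row equation with coefficient b and error
# variance s2; resid excludes its own contribution.
draw_aug_conditional <- function(resid, b, s2, bounds) {
  prec <- 1 + b^2 / s2
  mu <- (b * resid / s2) / prec
  rtruncnorm(length(resid), mu, sqrt(1 / prec), bounds$lo, bounds$hi)
}

# gather sampled-parameter labels and current values
sampled_param_index <- function(model) {
  out <- list()
  for (nm in c("B", "Lambda", "Pi", "K")) {
    mk <- model[[paste0(nm, "_mask")]]
    w <- which(mk == MASK_FREE | mk == MASK_FIXED, arr.ind = TRUE)
    if (nrow(w))
      out[[nm]] <- data.frame(
        matrix_name = nm, row = w[, 1], col = w[, 2],
        label = paste0(nm, "[", rownames(model[[nm]])[w[, 1]], ",",
                       colnames(model[[nm]])[w[, 2]], "]"))
  }
  out$te <- data.frame(matrix_name = "theta_eps",
                       row = seq_along(model$theta_eps), col = 0L,
                       label = paste0("theta_eps[", model$latent_names, "]"))
  out$td <- data.frame(matrix_name = "theta_delta",
                       row = seq_along(model$theta_delta), col = 0L,
                       label = paste0("theta_delta[", model$trait_names, "]"))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

read_sampled <- function(model, idx) {
  vapply(seq_len(nrow(idx)), function(i) {
    m <- idx$matrix_name[i]
    if (m %in% c("theta_eps", "theta_delta")) model[[m]][idx$row[i]]
    else model[[m]][idx$row[i], idx$col[i]]
  }, numeric(1))
}

#' Prepare sampler data from genotype codes and phenotypes
#'
#' Maps observed codes to 1-based consecutive category indices, estimates
#' thresholds from the observed category counts (so a SNP with an absent
#' homozygote class is treated as binary), and assembles the list consumed
#' by [run_chains()]. Missing continuous phenotypes are imputed at the
#' standardised mean (0); missing ordinal codes get unconstrained augmented
#' draws.
#'
#' @param model a constructed `model_spec`.
#' @param phenotypes data.frame over `model$trait_names` (continuous traits
#'   standardised; ordinal traits as integer codes).
#' @param genotypes matrix of SNP codes covering the model's SNP columns.
#' @param thresholds optional pre-estimated named cutpoint list (e.g. from
#'   training data inside cross-validation); estimated from the provided
#'   data when missing.
#' @return list with `P`, `G`, `Y`, `cutpoints`.
#' @export
gibbs_data <- function(model, phenotypes, genotypes, thresholds = NULL) {
  n <- nrow(phenotypes)
  cutpoints <- list()
  to_cat <- function(x) {
    lev <- sort(unique(x[!is.na(x)]))
    list(k = match(x, lev), counts = tabulate(match(x, lev), length(lev)))
  }
  P <- matrix(0, n, length(model$trait_names),
              dimnames = list(NULL, model$trait_names))
  for (j in seq_along(model$trait_names)) {
    tn_j <- model$trait_names[j]
    x <- phenotypes[[tn_j]]
    if (model$trait_kinds[j] == "ordinal") {
      cc <- to_cat(x)
      P[, j] <- cc$k
      cutpoints[[tn_j]] <- thresholds[[tn_j]] %||%
        estimate_thresholds(cc$counts)$cutpoints
    } else {
      P[, j] <- ifelse(is.na(x), 0, x)
    }
  }
  grab <- function(snps) {
    M <- matrix(NA_integer_, n, length(snps), dimnames = list(NULL, snps))
    for (s in snps) {
      cc <- to_cat(genotypes[, s])
      M[, s] <- cc$k
      cutpoints[[s]] <<- thresholds[[s]] %||%
        estimate_thresholds(cc$counts)$cutpoints
    }
    M
  }
  G <- grab(model$snp_factor_names)
  Y <- grab(model$snp_trait_names)
  list(P = P, G = G, Y = Y, cutpoints = cutpoints)
}

#' Run Gibbs sampling chains
#'
#' Bayesian estimation of all sampled parameters with data augmentation.
#' Thresholds for ordinal variables are fixed at their empirical estimates
#' (they are not sampled). Chains are initialised randomly around the prior
#' means with per-chain seeds derived from `seed`.
#'
#' @param model fully constructed `model_spec` (construction values serve as
#'   prior means).
#' @param data list with `P` (n x traits matrix: continuous traits on their
#'   standardised scale, ordinal traits as 1-based consecutive category
#'   indices), `G`, `Y` (SNP category matrices, 1-based), and per-variable
#'   `cutpoints` (named list covering ordinal traits and all model SNPs).
#'   Build it with [gibbs_data()].
#' @param control from [gibbs_control()].
#' @param seed master seed.
#' @param keep_latent store posterior draws of the latent factor matrix
#'   (memory-heavy; default FALSE keeps running means only).
#' @return object of class `posterior_samples`: list with `draws` (list of
#'   chain matrices, iterations x parameters, post-burn-in), `param_index`,
#'   `control`, `seed`, `eta_mean` (posterior mean of latent factors).
#' @export
run_chains <- function(model, data, control = gibbs_control(), seed = 1,
                       keep_latent = FALSE) {
  idx <- sampled_param_index(model)
  nl <- length(model$latent_names); nt <- length(model$trait_names)
  gn <- model$snp_factor_names; yn <- model$snp_trait_names
  n <- nrow(data$P)
  ord_traits <- which(model$trait_kinds == "ordinal")
  prior <- model
  chains <- vector("list", control$n_chains)
  eta_accum <- matrix(0, n, nl)
  eta_count <- 0
  for (ch in seq_len(control$n_chains)) {
    set.seed(as.integer((as.numeric(seed) * 1009 + ch * 7919) %% 2147483647))
    st <- model
    # random initialisation around prior means
    for (nm in c("B", "Lambda", "Pi", "K")) {
      mk <- st[[paste0(nm, "_mask")]]
      cells <- which(mk %in% c(MASK_FREE, MASK_FIXED))
      if (length(cells))
        st[[nm]][cells] <- prior[[nm]][cells] +
          stats::rnorm(length(cells), 0, control$init_sd)
    }
    st$theta_eps <- rinvgamma(nl, control$alpha0, control$beta0)
    st$theta_delta <- rinvgamma(nt, control$alpha0, control$beta0)
    draws <- matrix(NA_real_, control$length - control$burn_in, nrow(idx),
                    dimnames = list(NULL, idx$label))
    kept <- 0L
    failed <- FALSE
    conditional <- control$augmentation == "conditional"
    # initial augmented state (marginal) and factors for the first sweep
    G <- matrix(0, n, length(gn), dimnames = list(NULL, gn))
    for (j in seq_along(gn))
      G[, j] <- draw_augmented(data$G[, gn[j]], data$cutpoints[[gn[j]]])
    Y <- matrix(0, n, length(yn), dimnames = list(NULL, yn))
    for (j in seq_along(yn))
      Y[, j] <- draw_augmented(data$Y[, yn[j]], data$cutpoints[[yn[j]]])
    P <- data$P
    for (j in ord_traits)
      P[, j] <- draw_augmented(data$P[, j],
                               data$cutpoints[[model$trait_names[j]]])
    eta <- draw_eta(st, P, G, Y)
    for (it in seq_len(control$length)) {
      step <- tryCatch({
        # (1) augmented data
        if (!conditional) {
          for (j in seq_along(gn))
            G[, j] <- draw_augmented(data$G[, gn[j]], data$cutpoints[[gn[j]]])
          for (j in seq_along(yn))
            Y[, j] <- draw_augmented(data$Y[, yn[j]], data$cutpoints[[yn[j]]])
          for (j in ord_traits)
            P[, j] <- draw_augmented(data$P[, j],
                                     data$cutpoints[[model$trait_names[j]]])
        } else {
          # exact full conditionals given current parameters and factors
          for (j in seq_along(gn)) {
            f <- which(st$Pi_mask[, j] != MASK_ABSENT)
            bd <- aug_bounds(data$G[, gn[j]], data$cutpoints[[gn[j]]])
            if (!length(f)) {
              G[, j] <- rtruncnorm_std(n, bd$lo, bd$hi)
            } else {
              r <- eta[, f] - eta %*% st$B[f, ] - G %*% st$Pi[f, ] +
                st$Pi[f, j] * G[, j]
              G[, j] <- draw_aug_conditional(r, st$Pi[f, j],
                                             st$theta_eps[f], bd)
            }
          }
          for (j in seq_along(yn)) {
            tr <- which(st$K_mask[, j] != MASK_ABSENT)
            bd <- aug_bounds(data$Y[, yn[j]], data$cutpoints[[yn[j]]])
            if (!length(tr)) {
              Y[, j] <- rtruncnorm_std(n, bd$lo, bd$hi)
            } else {
              r <- P[, tr] - eta %*% st$Lambda[tr, ] - Y %*% st$K[tr, ] +
                st$K[tr, j] * Y[, j]
              Y[, j] <- draw_aug_conditional(r, st$K[tr, j],
                                             st$theta_delta[tr], bd)
            }
          }
          for (j in ord_traits) {
            bd <- aug_bounds(data$P[, j],
                             data$cutpoints[[model$trait_names[j]]])
            mu <- eta %*% st$Lambda[j, ] + Y %*% st$K[j, ]
            P[, j] <- rtruncnorm(n, as.numeric(mu),
                                 sqrt(st$theta_delta[j]), bd$lo, bd$hi)
          }
        }
        # (2) latent factors
        eta <- draw_eta(st, P, G, Y)
        # (3) Theta_eps
        res_eta <- eta - eta %*% t(st$B) - G %*% t(st$Pi)
        st$theta_eps <- draw_variances(colSums(res_eta^2), n,
                                       control$alpha0, control$beta0)
        # (4) [B, Pi] rows
        st <- draw_coefficient_rows(st, prior, eta, P, G, Y,
                                    control$prior_var, "structural")
        # (5) Theta_delta
        res_p <- P - eta %*% t(st$Lambda) - Y %*% t(st$K)
        st$theta_delta <- draw_variances(colSums(res_p^2), n,
                                         control$alpha0, control$beta0)
        # (6) [Lambda, K] rows
        st <- draw_coefficient_rows(st, prior, eta, P, G, Y,
                                    control$prior_var, "measurement")
        list(st = st, eta = eta)
      }, error = function(e) e)
      if (inherits(step, "error")) {
        warning(sprintf("chain %d aborted at iteration %d: %s",
                        ch, it, conditionMessage(step)))
        failed <- TRUE
        break
      }
      st <- step$st
      if (it > control$burn_in) {
        kept <- kept + 1L
        draws[kept, ] <- read_sampled(st, idx)
        eta_accum <- eta_accum + step$eta
        eta_count <- eta_count + 1L
      }
    }
    if (!failed) chains[[ch]] <- draws[seq_len(kept), , drop = FALSE]
  }
  chains <- Filter(Negate(is.null), chains)
  if (!length(chains)) stop("all Gibbs chains failed", call. = FALSE)
  structure(list(draws = chains, param_index = idx, control = control,
                 seed = seed,
                 eta_mean = if (eta_count) eta_accum / eta_count else NULL),
            class = "posterior_samples")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic multi-chain PSRF per parameter:
#' `sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain variance
#' and `B` the between-chain variance of chain means (times n).
#'
#' @param samples `posterior_samples` (>= 2 chains) or list of draw matrices.
#' @return named vector of R-hat values.
#' @export
gelman_rubin <- function(samples) {
  draws <- if (inherits(samples, "posterior_samples")) samples$draws else samples
  m <- length(draws)
  if (m < 2L) stop("Gelman-Rubin diagnostic needs at least 2 chains", call. = FALSE)
  n <- nrow(draws[[1]])
  stopifnot(all(vapply(draws, nrow, 1L) == n))
  means <- vapply(draws, colMeans, numeric(ncol(draws[[1]])))
  vars <- vapply(draws, function(d) apply(d, 2, stats::var),
                 numeric(ncol(draws[[1]])))
  if (is.null(dim(means))) { means <- matrix(means, 1); vars <- matrix(vars, 1) }
  W <- rowMeans(vars)
  B <- n * apply(means, 1, stats::var)
  rhat <- sqrt(((n - 1) / n * W + B / n) / W)
  rhat[W == 0] <- 1
  stats::setNames(rhat, colnames(draws[[1]]))
}

#' Effective sample size
#'
#' Spectral-density ESS per parameter, pooled over chains: per chain
#' `n * var(x) / spec0` where `spec0` is the spectral density at frequency
#' zero from an AIC-selected AR fit (the estimator used by the standard MCMC
#' diagnostic packages), then summed across chains. For iid draws
#' ESS ~ chain length; for an AR(1) chain with coefficient `phi` it
#' approaches `n (1 - phi) / (1 + phi)`. Constant chains report 0 (flagged).
#'
#' @param samples `posterior_samples` or list of draw matrices.
#' @return named vector of ESS values.
#' @export
effective_sample_size <- function(samples) {
  draws <- if (inherits(samples, "posterior_samples")) samples$draws else samples
  if (is.matrix(draws)) draws <- list(draws)
  p <- ncol(draws[[1]])
  ess1 <- function(x) {
    n <- length(x)
    v <- stats::var(x)
    if (v == 0) return(0)
    fit <- tryCatch(stats::ar(x, aic = TRUE,
                              order.max = min(n - 1L, floor(10 * log10(n)))),
                    error = function(e) NULL)
    if (is.null(fit)) return(n)
    spec0 <- fit$var.pred / (1 - sum(fit$ar))^2
    min(n, n * v / spec0)
  }
  out <- numeric(p)
  for (j in seq_len(p))
    out[j] <- sum(vapply(draws, function(d) ess1(d[, j]), numeric(1)))
  flagged <- out == 0
  if (any(flagged))
    attr(out, "constant") <- colnames(draws[[1]])[flagged]
  stats::setNames(out, colnames(draws[[1]]))
}

#' Posterior summary statistics
#'
#' Pooled over chains: mean, sd, and 5%/95% quantiles per parameter.
#'
#' @param samples a `posterior_samples`.
#' @return data.frame with `parameter`, `mean`, `sd`, `q05`, `q95`.
#' @export
posterior_summary <- function(samples) {
  pooled <- do.call(rbind, samples$draws)
  data.frame(parameter = colnames(pooled),
             mean = colMeans(pooled),
             sd = apply(pooled, 2, stats::sd),
             q05 = apply(pooled, 2, stats::quantile, 0.05, names = FALSE),
             q95 = apply(pooled, 2, stats::quantile, 0.95, names = FALSE),
             row.names = NULL)
}

#' Write posterior estimates back into a model
#'
#' Replaces the sampled cells' values with their posterior means, giving the
#' point-estimate model used for prediction.
#'
#' @param model the `model_spec` that was sampled.
#' @param samples `posterior_samples` from [run_chains()].
#' @return updated `model_spec`.
#' @export
apply_posterior_means <- function(model, samples) {
  sm <- posterior_summary(samples)
  idx <- samples$param_index
  for (i in seq_len(nrow(idx))) {
    m <- idx$matrix_name[i]
    v <- sm$mean[match(idx$label[i], sm$parameter)]
    if (m %in% c("theta_eps", "theta_delta")) model[[m]][idx$row[i]] <- v
    else model[[m]][idx$row[i], idx$col[i]] <- v
  }
  model
}
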