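# Model-implied covariance and maximum-likelihood estimation.
#
# The implied covariance over (traits, factor-SNPs, trait-SNPs) follows the
# standard LISREL-with-exogenous-covariates algebra. With A = (I - B)^{-1},
# Sigma_gg/Sigma_gy/Sigma_yy the exogenous (latent-scale) SNP covariances:
#   Cov(eta)    = A (Pi Sigma_gg Pi' + Theta_eps) A'
#   Cov(eta, y) = A Pi Sigma_gy
#   Cov(p)      = L Cov(eta) L' + L Cov(eta,y) K' + K Cov(eta,y)' L'
#                 + K Sigma_yy K' + Theta_delta
#   Cov(p, g)   = L A Pi Sigma_gg + K Sigma_yg
#   Cov(p, y)   = L A Pi Sigma_gy + K Sigma_yy

#' Model-implied covariance matrix
#'
#' Computes the covariance matrix over (traits, factor-SNPs, trait-SNPs)
#' implied by the current parameter values of `model`, given the covariance
#' of the exogenous SNP variables on the latent-normal scale.
#'
#' @param model a [model_spec()] with values filled in.
#' @param exo covariance matrix of the exogenous variables, with dimnames
#'   covering `c(snp_factor_names, snp_trait_names)`; may be `NULL` when the
#'   model has no SNPs.
#' @return symmetric covariance matrix with dimnames
#'   `c(trait_names, snp_factor_names, snp_trait_names)`.
#' @export
implied_covariance <- function(model, exo = NULL) {
  ln <- model$latent_names; tn <- model$trait_names
  gn <- model$snp_factor_names; yn <- model$snp_trait_names
  nl <- length(ln); nt <- length(tn); ng <- length(gn); ny <- length(yn)
  en <- c(gn, yn)
  if (length(en)) {
    if (is.null(exo)) stop("exogenous covariance required when the model contains SNPs", call. = FALSE)
    if (!all(en %in% rownames(exo)))
      stop("exogenous covariance is missing model SNPs: ",
           paste(setdiff(en, rownames(exo)), collapse = ", "), call. = FALSE)
    exo <- exo[en, en, drop = FALSE]
  } else {
    exo <- matrix(0, 0, 0)
  }
  Sgg <- exo[seq_len(ng), seq_len(ng), drop = FALSE]
  Sgy <- exo[seq_len(ng), ng + seq_len(ny), drop = FALSE]
  Syy <- exo[ng + seq_len(ny), ng + seq_len(ny), drop = FALSE]
  ImB <- diag(nl) - model$B
  A <- tryCatch(solve(ImB), error = function(e)
    stop("structural singularity: (I - B) is not invertible", call. = FALSE))
  L <- model$Lambda; P <- model$Pi; K <- model$K
  APi <- A %*% P
  cov_eta <- A %*% (P %*% Sgg %*% t(P) + diag(model$theta_eps, nl)) %*% t(A)
  cov_eta_y <- APi %*% Sgy                         # nl x ny
  LcL <- L %*% cov_eta %*% t(L)
  cross <- L %*% cov_eta_y %*% t(K)
  cov_p <- LcL + cross + t(cross) + K %*% Syy %*% t(K) + diag(model$theta_delta, nt)
  cov_pg <- L %*% APi %*% Sgg + K %*% t(Sgy)       # nt x ng
  cov_py <- L %*% cov_eta_y + K %*% Syy            # nt x ny
  d <- nt + ng + ny
  out <- matrix(0, d, d, dimnames = list(c(tn, en), c(tn, en)))
  out[seq_len(nt), seq_len(nt)] <- cov_p
  if (ng) {
    out[seq_len(nt), nt + seq_len(ng)] <- cov_pg
    out[nt + seq_len(ng), seq_len(nt)] <- t(cov_pg)
  }
  if (ny) {
    out[seq_len(nt), nt + ng + seq_len(ny)] <- cov_py
    out[nt + ng + seq_len(ny), seq_len(nt)] <- t(cov_py)
  }
  if (ng + ny) out[nt + seq_len(ng + ny), nt + seq_len(ng + ny)] <- exo
  (out + t(out)) / 2
}

# ---- free-parameter packing -------------------------------------------------

free_param_index <- function(model) {
  idx <- list()
  for (nm in c("B", "Lambda", "Pi", "K")) {
    w <- which(model[[paste0(nm, "_mask")]] == MASK_FREE, arr.ind = TRUE)
    if (nrow(w)) {
      rn <- rownames(model[[nm]])[w[, 1]]
      cn <- colnames(model[[nm]])[w[, 2]]
      idx[[nm]] <- data.frame(matrix_name = nm, row = w[, 1], col = w[, 2],
                              label = paste0(nm, "[", rn, ",", cn, "]"))
    }
  }
  if (model$theta_eps_free && length(model$theta_eps))
    idx$theta_eps <- data.frame(matrix_name = "theta_eps",
                                row = seq_along(model$theta_eps), col = 0L,
                                label = paste0("theta_eps[", model$latent_names, "]"))
  if (model$theta_delta_free && length(model$theta_delta))
    idx$theta_delta <- data.frame(matrix_name = "theta_delta",
                                  row = seq_along(model$theta_delta), col = 0L,
                                  label = paste0("theta_delta[", model$trait_names, "]"))
  do.call(rbind, c(idx, list(make.row.names = FALSE)))
}

get_free_params <- function(model, idx) {
  vapply(seq_len(nrow(idx)), function(i) {
    m <- idx$matrix_name[i]
    if (m %in% c("theta_eps", "theta_delta")) model[[m]][idx$row[i]]
    else model[[m]][idx$row[i], idx$col[i]]
  }, numeric(1))
}

set_free_params <- function(model, idx, values) {
  for (m in unique(idx$matrix_name)) {
    sel <- idx$matrix_name == m
    if (m %in% c("theta_eps", "theta_delta")) {
      model[[m]][idx$row[sel]] <- values[sel]
    } else {
      model[[m]][cbind(idx$row[sel], idx$col[sel])] <- values[sel]
    }
  }
  model
}

# Deterministic starting values: B/Pi/K cells 0.05, variances 0.5. Free
# loadings start from the sample covariance with their factor's anchor trait
# (scaled by a nominal factor variance of 0.5): an all-ones start cannot
# cross the sign barrier when the anchor trait loads negatively, and BFGS
# then escapes along the lambda -> Inf, theta -> 0 ridge.
default_start <- function(idx, model = NULL, S = NULL) {
  st <- ifelse(idx$matrix_name == "Lambda", 1,
               ifelse(idx$matrix_name %in% c("theta_eps", "theta_delta"), 0.5, 0.05))
  if (!is.null(model) && !is.null(S)) {
    lam <- which(idx$matrix_name == "Lambda")
    for (i in lam) {
      j <- idx$col[i]
      anchor <- which(model$Lambda_mask[, j] == MASK_ANCHOR)
      if (length(anchor) == 1L) {
        tr <- model$trait_names[idx$row[i]]
        an <- model$trait_names[anchor]
        if (all(c(tr, an) %in% rownames(S))) {
          v <- 2 * S[tr, an]
          st[i] <- sign(v + (v == 0)) * min(max(abs(v), 0.1), 2)
        }
      }
    }
  }
  st
}

#' Fit free model parameters by maximum likelihood
#'
#' Maximises the Wishart log-likelihood of the sample covariance matrix over
#' the free cells of B, Lambda, Pi, K and the free error variances. Variances
#' are optimised on the log scale to keep them positive. Quasi-Newton (BFGS)
#' with numerical gradients, deterministic start unless `start` is given.
#'
#' @param model a `model_spec`.
#' @param S sample covariance matrix over
#'   `c(trait_names, snp_factor_names, snp_trait_names)` (dimnames required).
#' @param n sample size behind `S`.
#' @param exo exogenous covariance (see [implied_covariance()]).
#' @param start optional numeric vector of starting values (natural scale) in
#'   free-parameter order; defaults to the documented deterministic start.
#' @param warm_start logical: start from the model's current values instead
#'   of the deterministic defaults.
#' @param maxit maximum BFGS iterations.
#' @param hessian compute the observed information matrix (skip for cheap
#'   repeated fits where no standard errors are needed).
#' @return list with `model` (values updated), `estimates` (named vector),
#'   `loglik`, `info` (observed information for the coefficient block),
#'   `converged`, `param_index`.
#' @export
fit_ml <- function(model, S, n, exo = NULL, start = NULL, warm_start = FALSE,
                   maxit = 500L, hessian = TRUE) {
  vn <- c(model$trait_names, model$snp_factor_names, model$snp_trait_names)
  stopifnot(all(vn %in% rownames(S)))
  S <- S[vn, vn, drop = FALSE]
  idx <- free_param_index(model)
  if (is.null(idx) || !nrow(idx))
    return(list(model = model, estimates = numeric(),
                loglik = wishart_loglik(S, implied_covariance(model, exo), n),
                info = matrix(0, 0, 0), converged = TRUE, param_index = idx))
  d <- length(vn)
  if (nrow(idx) > d * (d + 1) / 2)
    stop("model is not identified: ", nrow(idx), " free parameters for ",
         d * (d + 1) / 2, " distinct covariance entries", call. = FALSE)
  is_var <- idx$matrix_name %in% c("theta_eps", "theta_delta")
  if (is.null(start)) {
    start <- if (warm_start) get_free_params(model, idx)
             else default_start(idx, model, S)
  }
  to_opt <- function(v) { v[is_var] <- log(pmax(v[is_var], 1e-8)); v }
  from_opt <- function(v) { v[is_var] <- exp(v[is_var]); v }
  objective <- function(par) {
    m <- set_free_params(model, idx, from_opt(par))
    Sigma <- tryCatch(implied_covariance(m, exo), error = function(e) NULL)
    if (is.null(Sigma)) return(1e10)
    ll <- tryCatch(wishart_loglik(S, Sigma, n), error = function(e) NULL)
    if (is.null(ll) || !is.finite(ll)) return(1e10)
    -ll
  }
  opt <- stats::optim(to_opt(start), objective, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  est <- from_opt(opt$par)
  model <- set_free_params(model, idx, est)
  names(est) <- idx$label
  # observed information on the natural scale (coefficients and variances);
  # optimum is interior so a plain finite-difference Hessian is fine
  if (hessian) {
    obj_nat <- function(par) {
      m <- set_free_params(model, idx, par)
      Sigma <- tryCatch(implied_covariance(m, exo), error = function(e) NULL)
      if (is.null(Sigma)) return(1e10)
      ll <- tryCatch(wishart_loglik(S, Sigma, n), error = function(e) NULL)
      if (is.null(ll) || !is.finite(ll)) return(1e10)
      -ll
    }
    info <- tryCatch(stats::optimHess(est, obj_nat), error = function(e)
      matrix(NA_real_, length(est), length(est)))
    dimnames(info) <- list(idx$label, idx$label)
  } else {
    info <- matrix(NA_real_, length(est), length(est),
                   dimnames = list(idx$label, idx$label))
  }
  list(model = model, estimates = est, loglik = -opt$value, info = info,
       converged = opt$convergence == 0L, param_index = idx)
}

#' Wald significance tests for fitted parameters
#'
#' Two-sided z-tests from the observed information matrix:
#' `p = 2 * (1 - pnorm(|est / se|))`. If the information matrix is not
#' invertible, affected parameters get `p = 1` and a warning flag.
#'
#' @param estimates named vector of estimates (from [fit_ml()]).
#' @param info observed information matrix (negative Hessian of the
#'   log-likelihood at the optimum).
#' @return data.frame with `parameter`, `estimate`, `se`, `p_value`, `flag`.
#' @export
param_significance <- function(estimates, info) {
  k <- length(estimates)
  se <- rep(NA_real_, k)
  flag <- rep("", k)
  Vi <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(Vi) || any(!is.finite(diag(Vi))) || any(diag(Vi) < 0)) {
    # fall back per-parameter where possible
    dg <- diag(info)
    ok <- is.finite(dg) & dg > 0
    se[ok] <- 1 / sqrt(dg[ok])          # conservative (no covariance adjustment)
    flag[!ok] <- "singular_information"
    if (is.null(Vi)) warning("information matrix not invertible; flagged parameters get p = 1")
  } else {
    se <- sqrt(diag(Vi))
  }
  p <- ifelse(is.na(se) | se == 0 | flag != "", 1,
              2 * (1 - stats::pnorm(abs(estimates / se))))
  data.frame(parameter = names(estimates), estimate = unname(estimates),
             se = se, p_value = p, flag = flag, row.names = NULL)
}
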