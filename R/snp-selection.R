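# Greedy Wishart-density SNP selection.
#
# With the structural/measurement coefficients (B, Lambda) frozen at their
# construction-time ML values, candidate SNPs are attached one at a time —
# first to latent factors (Pi columns) in breadth-first DAG order, then to
# traits (K columns). A candidate is scored by (1) ML-fitting its single new
# coefficient (error variances stay free; B and Lambda do not) over the full
# observed covariance including the candidate, then (2) evaluating Wishart
# log-densities at the fit. Ranking and stopping use the full-covariance
# density gain relative to the same variable set with the candidate's
# coefficient at zero — densities are comparable across candidates because
# every SNP has unit variance on the latent-normal scale, and the gain is the
# likelihood-ratio improvement attributable to the SNP. The phenotype-block
# density is reported alongside (see the methods vignette for why it is not
# the ranking statistic). The best SNP is added with its coefficient frozen;
# selection stops on a gain threshold or a per-variable SNP cap.

#' Breadth-first traversal order of model variables
#'
#' Latent factors in BFS order over the structural DAG starting from
#' in-degree-zero factors (name order breaks ties), followed by the traits in
#' their declared order.
#'
#' @param model a `model_spec`.
#' @return character vector of variable names.
#' @export
traversal_order <- function(model) {
  adj <- model$B_mask != MASK_ABSENT   # adj[j, i]: edge i -> j
  if (!is_acyclic(adj)) stop("structural part is cyclic", call. = FALSE)
  ln <- model$latent_names
  n <- length(ln)
  visited <- logical(n)
  queue <- sort(ln[rowSums(adj) == 0])
  out <- character()
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    vi <- match(v, ln)
    if (visited[vi]) next
    visited[vi] <- TRUE
    out <- c(out, v)
    kids <- ln[adj[, vi] & !visited]
    queue <- c(queue, sort(kids))
  }
  c(out, ln[!visited], model$trait_names)
}

#' Stopping configuration for SNP selection
#'
#' @param gain_min minimal phenotype-block log-density gain to keep adding
#'   SNPs (~ AIC-style penalty for one parameter).
#' @param max_snps cap on SNPs added per variable.
#' @param redundancy_r drop remaining candidates whose genotype-code Pearson
#'   correlation with an added SNP exceeds this in absolute value.
#' @param rescore if `FALSE`, candidates are ranked once per variable and not
#'   rescored after each addition (cheaper, less faithful to the greedy
#'   reading).
#' @return a list used by [select_snps_for_variable()].
#' @export
snp_stop_cfg <- function(gain_min = 2.0, max_snps = 15L, redundancy_r = 0.9,
                         rescore = TRUE) {
  list(gain_min = gain_min, max_snps = as.integer(max_snps),
       redundancy_r = redundancy_r, rescore = isTRUE(rescore))
}

# add a SNP column to Pi (latent target) or K (trait target)
add_snp_column <- function(model, snp, target, value, mask_code) {
  if (target %in% model$latent_names) {
    model$snp_factor_names <- c(model$snp_factor_names, snp)
    model$Pi <- cbind(model$Pi, stats::setNames(numeric(length(model$latent_names)), NULL))
    colnames(model$Pi)[ncol(model$Pi)] <- snp
    model$Pi_mask <- cbind(model$Pi_mask, 0L)
    colnames(model$Pi_mask)[ncol(model$Pi_mask)] <- snp
    i <- match(target, model$latent_names)
    model$Pi[i, snp] <- value
    model$Pi_mask[i, snp] <- mask_code
  } else {
    model$snp_trait_names <- c(model$snp_trait_names, snp)
    model$K <- cbind(model$K, numeric(length(model$trait_names)))
    colnames(model$K)[ncol(model$K)] <- snp
    model$K_mask <- cbind(model$K_mask, 0L)
    colnames(model$K_mask)[ncol(model$K_mask)] <- snp
    i <- match(target, model$trait_names)
    model$K[i, snp] <- value
    model$K_mask[i, snp] <- mask_code
  }
  model
}

# phenotype-block Wishart log-density of the current model
pheno_block_density <- function(model, S, n, exo) {
  Sigma <- implied_covariance(model, exo)
  tn <- model$trait_names
  wishart_loglik(S[tn, tn, drop = FALSE], Sigma[tn, tn, drop = FALSE], n)
}

#' Score one candidate SNP for one target variable
#'
#' @param model model with frozen B and Lambda.
#' @param snp candidate SNP name (must index into `S`/`exo_full`, not already
#'   in the model).
#' @param target latent factor or trait name.
#' @param S hybrid sample covariance over traits + model SNPs + candidate.
#' @param n sample size.
#' @param exo_full latent-scale covariance over all SNPs (model + candidates).
#' @return list with `coef`, `gain` (full-covariance log-density gain over
#'   the zero-coefficient baseline; the ranking/stopping statistic),
#'   `logdens` (full-covariance log-density at the fit), `logdens_pheno`
#'   (phenotype-block log-density), `ok`, `fit`. On fit failure `gain` and
#'   `logdens` are `-Inf` with `ok = FALSE`.
#' @param quick rank-only mode: fit just the SNP coefficient by 1-D
#'   optimisation with the error variances held at their current values
#'   (used to pre-rank large candidate pools; the winner gets a full fit).
#' @export
score_snp <- function(model, snp, target, S, n, exo_full, quick = FALSE) {
  stopifnot(!(snp %in% c(model$snp_factor_names, model$snp_trait_names)))
  m2 <- add_snp_column(model, snp, target, 0.0, MASK_FREE)
  vn <- c(m2$trait_names, m2$snp_factor_names, m2$snp_trait_names)
  Ssub <- S[vn, vn]
  res <- tryCatch({
    base <- wishart_loglik(Ssub, implied_covariance(m2, exo_full), n)
    if (quick) {
      mq <- m2
      mq$theta_eps_free <- mq$theta_delta_free <- FALSE
      idx <- free_param_index(mq)
      obj <- function(v) {
        mm <- set_free_params(mq, idx, v)
        ll <- tryCatch(
          wishart_loglik(Ssub, implied_covariance(mm, exo_full), n),
          error = function(e) -Inf)
        if (!is.finite(ll)) 1e10 else -ll
      }
      op <- stats::optimize(obj, c(-2, 2), tol = 1e-5)
      return(list(coef = op$minimum, gain = -op$objective - base,
                  logdens = -op$objective, logdens_pheno = NA_real_,
                  ok = TRUE, fit = NULL))
    }
    ft <- fit_ml(m2, S, n, exo = exo_full, warm_start = TRUE, hessian = FALSE)
    full <- wishart_loglik(Ssub, implied_covariance(ft$model, exo_full), n)
    lbl <- if (target %in% model$latent_names) "Pi" else "K"
    co <- ft$estimates[grep(paste0("^", lbl, "\\[.*,", snp, "\\]"),
                            names(ft$estimates), fixed = FALSE)]
    list(coef = unname(co), gain = full - base, logdens = full,
         logdens_pheno = pheno_block_density(ft$model, S, n, exo_full),
         ok = ft$converged, fit = ft)
  }, error = function(e) list(coef = NA_real_, gain = -Inf, logdens = -Inf,
                              logdens_pheno = NA_real_, ok = FALSE, fit = NULL))
  res
}

#' Greedy SNP selection for a single variable
#'
#' Repeats score-all / add-best / freeze until the stopping rule fires.
#'
#' @param model model with frozen B and Lambda.
#' @param candidates candidate SNP names.
#' @param target variable (factor or trait) name.
#' @param S hybrid sample covariance over traits and all SNPs.
#' @param n sample size.
#' @param exo_full latent-scale SNP covariance (all SNPs).
#' @param geno_codes genotype-code matrix (samples x SNPs) for the redundancy
#'   filter; optional (`NULL` disables the filter).
#' @param stop_cfg from [snp_stop_cfg()].
#' @param log_env optional environment collecting a selection log
#'   (data.frames appended to `log_env$log`).
#' @return updated `model_spec`.
#' @export
select_snps_for_variable <- function(model, candidates, target, S, n, exo_full,
                                     geno_codes = NULL,
                                     stop_cfg = snp_stop_cfg(),
                                     log_env = NULL) {
  if (!length(candidates) || stop_cfg$max_snps <= 0L) return(model)
  pool <- setdiff(candidates, c(model$snp_factor_names, model$snp_trait_names))
  added <- 0L
  ranked_once <- NULL
  while (length(pool) && added < stop_cfg$max_snps) {
    if (stop_cfg$rescore || is.null(ranked_once)) {
      # cheap 1-D pre-ranking of the whole pool, full fit for the winner only
      qgain <- vapply(pool, function(s)
        score_snp(model, s, target, S, n, exo_full, quick = TRUE)$gain,
        numeric(1))
      if (!stop_cfg$rescore) ranked_once <- pool[order(qgain, decreasing = TRUE)]
      best <- pool[which.max(qgain)]
    } else {
      best <- intersect(ranked_once, pool)[1]
    }
    sc <- score_snp(model, best, target, S, n, exo_full)
    if (!is.finite(sc$gain) || sc$gain < stop_cfg$gain_min) break
    # adopt the scored fit (coefficient frozen, refreshed error variances)
    model <- sc$fit$model
    model <- freeze_masks(model, c("Pi", "K"))
    added <- added + 1L
    if (!is.null(log_env)) {
      log_env$log <- rbind(log_env$log, data.frame(
        iteration = added, target = target, snp = best,
        coefficient = sc$coef, log_density = sc$logdens,
        log_density_pheno = sc$logdens_pheno, gain = sc$gain,
        stringsAsFactors = FALSE))
    }
    pool <- setdiff(pool, best)
    if (!is.null(geno_codes) && length(pool)) {
      r <- suppressWarnings(stats::cor(geno_codes[, best], geno_codes[, pool, drop = FALSE],
                                       use = "pairwise.complete.obs"))
      drop <- pool[!is.na(r) & abs(as.numeric(r)) > stop_cfg$redundancy_r]
      pool <- setdiff(pool, drop)
    }
  }
  model
}

#' Build the full SNP-augmented model
#'
#' Freezes the measurement/structural coefficients at their ML estimates,
#' then runs greedy SNP selection for every latent factor in breadth-first
#' DAG order (filling Pi) and — for extended models — for every trait
#' (filling K). SNPs already fixed in Pi are excluded from trait candidacy.
#'
#' @param model constructed (measurement + optional structural) model with
#'   fitted values; free cells are frozen here.
#' @param S hybrid sample covariance over traits and all candidate SNPs.
#' @param n sample size.
#' @param exo_full latent-scale covariance over all candidate SNPs.
#' @param candidates candidate SNP names (default: all SNPs in `exo_full`).
#' @param geno_codes genotype codes for the redundancy filter (optional).
#' @param extended add trait-level SNPs (K) after factor-level SNPs (Pi).
#' @param stop_cfg from [snp_stop_cfg()].
#' @return list with `model` and `selection_log`.
#' @export
build_full_model <- function(model, S, n, exo_full,
                             candidates = colnames(exo_full),
                             geno_codes = NULL, extended = FALSE,
                             stop_cfg = snp_stop_cfg()) {
  model <- freeze_masks(model, c("B", "Lambda"))
  env <- new.env()
  env$log <- data.frame()
  ord <- traversal_order(model)
  latents <- ord[ord %in% model$latent_names]
  for (v in latents) {
    model <- select_snps_for_variable(model, candidates, v, S, n, exo_full,
                                      geno_codes, stop_cfg, env)
  }
  if (extended) {
    traits <- ord[ord %in% model$trait_names]
    for (v in traits) {
      pool <- setdiff(candidates,
                      c(model$snp_factor_names, model$snp_trait_names))
      model <- select_snps_for_variable(model, pool, v, S, n, exo_full,
                                        geno_codes, stop_cfg, env)
    }
  }
  list(model = model, selection_log = env$log)
}
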