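# Synthetic-data generation from the model's own generative equations, with
# known truth. Latent factors and traits are scaled so that marginal
# variances are ~1 (traits in real panels are z-scored before modelling), so
# true loadings are comparable to the standardised loadings the construction
# stage estimates. SNP codes arise from Hardy-Weinberg proportions via the
# latent-normal threshold representation, which keeps the generative pass and
# the polychoric machinery on the same scale.

#' Create a fully-valued true model
#'
#' Builds a ground-truth model: factor loadings drawn with magnitude in
#' `loading_range` (random sign with probability `neg_loading_prob`), the
#' requested structural edges, and SNP effects on factors/traits. Error
#' variances are chosen so factor and trait variances are close to 1.
#'
#' @param n_factors number of latent factors.
#' @param traits_per_factor trait-block sizes (recycled to `n_factors`).
#' @param snps_per_factor SNPs attached to each factor (recycled).
#' @param snps_per_trait SNPs attached to each trait (recycled).
#' @param b_edges `NULL` (empty structural part) or data.frame with columns
#'   `from`, `to` (factor indices or names) and `coef`.
#' @param effect_sizes SNP effect sizes; a single number, or a list with
#'   elements `pi` and `k` (recycled over SNPs).
#' @param seed integer seed; the result is deterministic given it.
#' @param loading_range magnitude range for loadings.
#' @param neg_loading_prob probability a loading is negative.
#' @param n_ordinal_traits how many traits (from the last) are ordinal.
#' @param ordinal_categories number of categories for ordinal traits.
#' @param maf_range range for allele frequencies (must stay within the MAF
#'   filter's admissible band).
#' @param n_chrom chromosomes over which SNPs are spread.
#' @param chrom_length chromosome length in bp.
#' @param ld_rho adjacent-locus latent correlation within a chromosome
#'   (0 = independent loci, the default).
#' @return a `true_model`: a [model_spec()] (all cells fixed) with extra
#'   fields `maf`, `snp_info` (chrom/pos), `trait_thresholds`, `ld_rho`.
#' @export
make_true_model <- function(n_factors, traits_per_factor,
                            snps_per_factor = 0, snps_per_trait = 0,
                            b_edges = NULL, effect_sizes = 0.5, seed = 1,
                            loading_range = c(0.6, 0.9),
                            neg_loading_prob = 0.25,
                            n_ordinal_traits = 0, ordinal_categories = 3,
                            maf_range = c(0.15, 0.85),
                            n_chrom = 4, chrom_length = 5e7, ld_rho = 0) {
  set.seed(seed)
  blocks <- rep_len(traits_per_factor, n_factors)
  nt <- sum(blocks)
  ln <- paste0("F", seq_len(n_factors))
  tn <- paste0("T", seq_len(nt))
  factor_of_trait <- rep(seq_len(n_factors), blocks)
  # loadings
  Lambda <- matrix(0, nt, n_factors, dimnames = list(tn, ln))
  mag <- stats::runif(nt, loading_range[1], loading_range[2])
  sgn <- ifelse(stats::runif(nt) < neg_loading_prob, -1, 1)
  Lambda[cbind(seq_len(nt), factor_of_trait)] <- mag * sgn
  L_mask <- storage_int((Lambda != 0) * MASK_FIXED)
  # structural edges
  B <- matrix(0, n_factors, n_factors, dimnames = list(ln, ln))
  if (!is.null(b_edges) && nrow(b_edges)) {
    from <- if (is.numeric(b_edges$from)) b_edges$from else match(b_edges$from, ln)
    to <- if (is.numeric(b_edges$to)) b_edges$to else match(b_edges$to, ln)
    B[cbind(to, from)] <- b_edges$coef
    if (!is_acyclic(B)) stop("b_edges define a cyclic structural part", call. = FALSE)
  }
  B_mask <- storage_int((B != 0) * MASK_FIXED)
  # SNP attachment
  spf <- rep_len(snps_per_factor, n_factors)
  spt <- rep_len(snps_per_trait, nt)
  ng <- sum(spf); ny <- sum(spt)
  gn <- if (ng) paste0("gsnp", seq_len(ng)) else character()
  yn <- if (ny) paste0("ysnp", seq_len(ny)) else character()
  es <- if (is.list(effect_sizes)) effect_sizes else list(pi = effect_sizes, k = effect_sizes)
  Pi <- matrix(0, n_factors, ng, dimnames = list(ln, gn))
  if (ng) Pi[cbind(rep(seq_len(n_factors), spf), seq_len(ng))] <- rep_len(es$pi, ng)
  K <- matrix(0, nt, ny, dimnames = list(tn, yn))
  if (ny) K[cbind(rep(seq_len(nt), spt), seq_len(ny))] <- rep_len(es$k, ny)
  # error variances targeting unit marginal variances (Sigma_gg = I at the
  # latent scale, g and y independent loci)
  A_of <- function(Bm) solve(diag(n_factors) - Bm)
  A <- A_of(B)
  base <- A %*% Pi %*% t(Pi) %*% t(A)       # SNP-driven part of Cov(eta)
  G <- A^2                                  # diag contribution of theta_eps
  theta_eps <- tryCatch(solve(G, pmax(1 - diag(base), 0.05)),
                        error = function(e) rep(0.5, n_factors))
  theta_eps <- pmax(as.numeric(theta_eps), 0.05)
  cov_eta <- A %*% (Pi %*% t(Pi) + diag(theta_eps, n_factors)) %*% t(A)
  explained <- diag(Lambda %*% cov_eta %*% t(Lambda) + K %*% t(K))
  theta_delta <- pmax(1 - explained, 0.1)
  kinds <- rep("continuous", nt)
  if (n_ordinal_traits > 0)
    kinds[seq.int(nt - n_ordinal_traits + 1L, nt)] <- "ordinal"
  tm <- model_spec(ln, tn, kinds, gn, yn,
                   B = B, B_mask = B_mask,
                   Lambda = Lambda, Lambda_mask = L_mask,
                   Pi = Pi, Pi_mask = storage_int((Pi != 0) * MASK_FIXED),
                   K = K, K_mask = storage_int((K != 0) * MASK_FIXED),
                   theta_eps = theta_eps, theta_delta = theta_delta,
                   theta_eps_free = FALSE, theta_delta_free = FALSE)
  nsnp <- ng + ny
  tm$maf <- stats::setNames(stats::runif(nsnp, maf_range[1], maf_range[2]),
                            c(gn, yn))
  if (nsnp) {
    chrom <- sort(rep_len(seq_len(n_chrom), nsnp))
    pos <- unlist(lapply(split(seq_len(nsnp), chrom), function(ii)
      sort(sample.int(chrom_length, length(ii)))), use.names = FALSE)
    tm$snp_info <- data.frame(snp = c(gn, yn), chrom = chrom, pos = pos,
                              ref = "A", alt = "G", stringsAsFactors = FALSE)
  } else {
    tm$snp_info <- data.frame(snp = character(), chrom = integer(),
                              pos = integer(), ref = character(),
                              alt = character(), stringsAsFactors = FALSE)
  }
  # balanced thresholds for ordinal traits
  tm$trait_thresholds <- stats::setNames(lapply(seq_len(nt), function(i) {
    if (kinds[i] == "ordinal")
      stats::qnorm(seq_len(ordinal_categories - 1L) / ordinal_categories)
    else NULL
  }), tn)
  tm$ld_rho <- ld_rho
  class(tm) <- c("true_model", class(tm))
  tm
}

# Hardy-Weinberg thresholds on the latent-normal scale for allele freq p
hw_thresholds <- function(p) {
  f <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  stats::qnorm(cumsum(f)[1:2])
}

#' Discretize continuous values through thresholds
#'
#' Code `k` iff the value lies in `(t_{k-1}, t_k]` with `t_0 = -Inf`,
#' `t_n = +Inf` (right-closed intervals: a value exactly at a threshold gets
#' the lower code). Codes are 1-based.
#'
#' @param x numeric vector.
#' @param thresholds strictly increasing finite cutpoints.
#' @return integer codes in `1 .. length(thresholds) + 1`.
#' @export
discretize <- function(x, thresholds) {
  stopifnot(!is.unsorted(thresholds, strictly = TRUE))
  findInterval(x, thresholds, left.open = TRUE) + 1L
}

#' Simulate a dataset from a true model
#'
#' Draws latent SNP variables (standard normal, optionally AR(1)-correlated
#' within chromosomes to mimic LD), discretises them through Hardy-Weinberg
#' thresholds into codes {0,1,2}, solves the structural equations for the
#' factors, produces traits from the measurement equations, and discretises
#' ordinal traits.
#'
#' @param true_model from [make_true_model()].
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @param missing_rate elementwise missingness rate applied to genotypes and
#'   phenotypes (default 0; the upstream call-rate filter caps realistic
#'   values at 0.1).
#' @return a `dataset_bundle`: list with `samples`, `genotypes` (n x SNP
#'   integer matrix, `NA` for missing), `snp_info`, `phenotypes` (data.frame;
#'   ordinal traits as integer codes), `trait_meta`, and truth extras
#'   `latent_factors`, `latent_snps`.
#' @export
simulate_dataset <- function(true_model, n_samples, seed = 1,
                             missing_rate = 0) {
  stopifnot(n_samples >= 2)
  set.seed(seed)
  tm <- true_model
  ln <- tm$latent_names; tn <- tm$trait_names
  gn <- tm$snp_factor_names; yn <- tm$snp_trait_names
  allsnp <- c(gn, yn)
  nsnp <- length(allsnp)
  # latent SNP scale, optional within-chromosome AR(1)
  Z <- matrix(stats::rnorm(n_samples * nsnp), n_samples, nsnp,
              dimnames = list(NULL, allsnp))
  if (nsnp && tm$ld_rho > 0) {
    ord <- order(tm$snp_info$chrom, tm$snp_info$pos)
    r <- tm$ld_rho
    for (i in seq_along(ord)[-1]) {
      if (tm$snp_info$chrom[ord[i]] == tm$snp_info$chrom[ord[i - 1]])
        Z[, ord[i]] <- r * Z[, ord[i - 1]] + sqrt(1 - r^2) * Z[, ord[i]]
    }
  }
  codes <- matrix(NA_integer_, n_samples, nsnp,
                  dimnames = list(NULL, allsnp))
  for (j in seq_len(nsnp))
    codes[, j] <- discretize(Z[, j], hw_thresholds(tm$maf[allsnp[j]])) - 1L
  nl <- length(ln); nt <- length(tn)
  A <- solve(diag(nl) - tm$B)
  eps <- matrix(stats::rnorm(n_samples * nl), n_samples) %*%
    diag(sqrt(tm$theta_eps), nl)
  G <- Z[, gn, drop = FALSE]
  eta <- (G %*% t(tm$Pi) + eps) %*% t(A)
  colnames(eta) <- ln
  delta <- matrix(stats::rnorm(n_samples * nt), n_samples) %*%
    diag(sqrt(tm$theta_delta), nt)
  Y <- Z[, yn, drop = FALSE]
  P <- eta %*% t(tm$Lambda) + Y %*% t(tm$K) + delta
  colnames(P) <- tn
  pheno <- as.data.frame(P)
  for (i in seq_len(nt)) {
    if (tm$trait_kinds[i] == "ordinal")
      pheno[[i]] <- discretize(P[, i], tm$trait_thresholds[[i]])
  }
  if (missing_rate > 0) {
    if (nsnp) codes[stats::runif(length(codes)) < missing_rate] <- NA_integer_
    for (i in seq_len(nt))
      pheno[[i]][stats::runif(n_samples) < missing_rate] <- NA
  }
  structure(list(
    samples = sprintf("S%04d", seq_len(n_samples)),
    genotypes = codes, snp_info = tm$snp_info, phenotypes = pheno,
    trait_meta = data.frame(trait = tn, kind = tm$trait_kinds,
                            stringsAsFactors = FALSE),
    latent_factors = eta, latent_snps = Z
  ), class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("dataset bundle: %d samples, %d SNPs, %d traits (%d ordinal)\n",
              length(x$samples), ncol(x$genotypes), ncol(x$phenotypes),
              sum(x$trait_meta$kind == "ordinal")))
  invisible(x)
}
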