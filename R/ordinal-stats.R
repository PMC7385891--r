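# Ordinal-variable machinery. Every ordinal variable (SNP codes included) is
# modelled as a discretisation of a hidden standard normal through ordered
# thresholds; correlations involving ordinal variables are estimated on that
# latent scale (polychoric / polyserial) so that the Wishart-likelihood
# machinery can treat the hybrid matrix as a covariance of normals.

#' Estimate thresholds of an ordinal variable
#'
#' Thresholds `t_k` are the standard-normal quantiles of the cumulative
#' category proportions: `n` categories yield `n - 1` finite cutpoints
#' dividing N(0,1) into parts matching the observed proportions.
#'
#' @param category_counts named or unnamed vector of per-category counts, in
#'   category order.
#' @return object of class `threshold_set`: list with `cutpoints` (finite,
#'   length `n - 1`), `proportions`, `levels`.
#' @export
estimate_thresholds <- function(category_counts) {
  counts <- as.numeric(category_counts)
  if (length(counts) < 2L)
    stop("ordinal variable needs at least 2 categories", call. = FALSE)
  if (any(counts < 1))
    stop("empty ordinal category: merge categories before analysis", call. = FALSE)
  f <- counts / sum(counts)
  t <- stats::qnorm(cumsum(f)[-length(f)])
  structure(list(cutpoints = t, proportions = f,
                 levels = names(category_counts) %||% as.character(seq_along(f))),
            class = "threshold_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# interval bounds (lo, hi] for category k under a threshold set
threshold_bounds <- function(th, k) {
  t_full <- c(-Inf, th$cutpoints, Inf)
  list(lo = t_full[k], hi = t_full[k + 1L])
}

# cell probabilities of a 2-way ordinal table under a bivariate normal with
# given thresholds and correlation
polychoric_cell_probs <- function(rho, tr, tc) {
  ar <- c(-Inf, tr, Inf); ac <- c(-Inf, tc, Inf)
  nr <- length(ar) - 1L; nc <- length(ac) - 1L
  # CDF at all grid corners, vectorised in one call
  grid <- expand.grid(r = ar, c = ac)
  Fg <- matrix(pbvnorm(grid$r, grid$c, rho), length(ar), length(ac))
  P <- Fg[-1, -1, drop = FALSE] - Fg[-nrow(Fg), -1, drop = FALSE] -
    Fg[-1, -ncol(Fg), drop = FALSE] + Fg[-nrow(Fg), -ncol(Fg), drop = FALSE]
  pmax(P, 1e-12)
}

#' Polychoric correlation from a contingency table
#'
#' Two-step estimator: thresholds fixed at the standard-normal quantiles of
#' the marginal proportions, then the latent correlation maximises the
#' bivariate-normal cell-probability likelihood over `[-0.999, 0.999]`.
#' Zero cells receive a 0.5 continuity correction before likelihood
#' evaluation.
#'
#' @param tab contingency table (matrix of counts, rows/cols in category
#'   order).
#' @return list with `rho`, `converged`, `boundary` (TRUE when the estimate
#'   sits at the search boundary).
#' @export
polychoric <- function(tab) {
  tab <- as.matrix(tab)
  if (sum(tab > 0) <= 1L)
    stop("degenerate contingency table: all mass in one cell, correlation undefined",
         call. = FALSE)
  rm <- rowSums(tab); cm <- colSums(tab)
  if (any(rm == 0) || any(cm == 0))
    stop("empty ordinal category: merge categories before analysis", call. = FALSE)
  tr <- estimate_thresholds(rm)$cutpoints
  tc <- estimate_thresholds(cm)$cutpoints
  tl <- tab
  tl[tl == 0] <- 0.5
  negll <- function(rho) -sum(tl * log(polychoric_cell_probs(rho, tr, tc)))
  opt <- stats::optimize(negll, c(-0.999, 0.999), tol = 1e-6)
  rho <- opt$minimum
  boundary <- abs(rho) > 0.9985
  if (boundary) rho <- sign(rho) * 0.999
  list(rho = rho, converged = TRUE, boundary = boundary)
}

#' Polyserial correlation between a continuous and an ordinal variable
#'
#' Maximum-likelihood estimate under the bivariate-normal model in which the
#' ordinal variable is observed through fixed thresholds (two-step: margins
#' first). The continuous variable is standardised internally.
#'
#' @param x continuous values.
#' @param d ordinal codes (integer-valued; any ordered coding).
#' @return list with `rho`, `converged`, `boundary`.
#' @export
polyserial <- function(x, d) {
  ok <- is.finite(x) & !is.na(d)
  x <- x[ok]; d <- d[ok]
  if (stats::sd(x) == 0)
    stop("zero-variance continuous variable: polyserial correlation undefined",
         call. = FALSE)
  z <- (x - mean(x)) / stats::sd(x)
  lev <- sort(unique(d))
  if (length(lev) < 2L)
    stop("ordinal variable has a single category", call. = FALSE)
  k <- match(d, lev)
  th <- estimate_thresholds(tabulate(k, length(lev)))
  t_full <- c(-Inf, th$cutpoints, Inf)
  lo <- t_full[k]; hi <- t_full[k + 1L]
  negll <- function(rho) {
    s <- sqrt(1 - rho^2)
    p <- stats::pnorm((hi - rho * z) / s) - stats::pnorm((lo - rho * z) / s)
    -sum(log(pmax(p, 1e-12)))
  }
  opt <- stats::optimize(negll, c(-0.999, 0.999), tol = 1e-6)
  rho <- opt$minimum
  boundary <- abs(rho) > 0.9985
  if (boundary) rho <- sign(rho) * 0.999
  list(rho = rho, converged = TRUE, boundary = boundary)
}

#' Hybrid correlation matrix for mixed continuous/ordinal data
#'
#' Pairwise-complete estimation: Pearson correlation for continuous pairs,
#' polyserial for mixed pairs, polychoric for ordinal pairs; unit diagonal
#' (all variables live on a standardised/latent-normal scale). A PSD-repaired
#' copy is returned alongside the raw matrix because polychoric matrices are
#' not guaranteed positive semi-definite.
#'
#' @param data data.frame or matrix (samples x variables), `NA` allowed.
#' @param kinds character vector, `"continuous"` or `"ordinal"`, one per
#'   column.
#' @return list with `raw`, `psd` (repaired copy), `delta` (Frobenius norm of
#'   the repair), `flags` (per-pair issues, if any), `n` (sample count).
#' @export
hybrid_matrix <- function(data, kinds) {
  data <- as.data.frame(data)
  p <- ncol(data)
  stopifnot(length(kinds) == p, all(kinds %in% c("continuous", "ordinal")))
  vn <- colnames(data) %||% paste0("V", seq_len(p))
  R <- diag(1, p)
  dimnames(R) <- list(vn, vn)
  flags <- character()
  for (i in seq_len(p - 1L)) for (j in seq((i + 1L), p)) {
    xi <- data[[i]]; xj <- data[[j]]
    ok <- !is.na(xi) & !is.na(xj)
    r <- tryCatch({
      if (kinds[i] == "continuous" && kinds[j] == "continuous") {
        stats::cor(xi[ok], xj[ok])
      } else if (kinds[i] == "ordinal" && kinds[j] == "ordinal") {
        polychoric(table(factor(xi[ok]), factor(xj[ok])))$rho
      } else if (kinds[i] == "continuous") {
        polyserial(xi[ok], xj[ok])$rho
      } else {
        polyserial(xj[ok], xi[ok])$rho
      }
    }, error = function(e) {
      flags <<- c(flags, sprintf("%s~%s: %s", vn[i], vn[j], conditionMessage(e)))
      NA_real_
    })
    R[i, j] <- R[j, i] <- r
  }
  if (anyNA(R))
    stop("unestimable correlation entries:\n  ", paste(flags, collapse = "\n  "),
         call. = FALSE)
  rep_ <- psd_repair(R)
  list(raw = R, psd = rep_$mat, delta = rep_$delta, flags = flags,
       n = nrow(data))
}
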