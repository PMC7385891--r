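# ModelSpec: the parameter skeleton of the multi-trait multi-locus SEM
#
#   eta = B eta + Pi g + eps,   eps ~ N(0, Theta_eps)   (structural part)
#   p   = Lambda eta + K y + delta, delta ~ N(0, Theta_delta) (measurement part)
#
# Each coefficient matrix carries an integer mask with cell codes:
#   0 = structurally absent (always zero)
#   1 = free (estimated by ML / optimised)
#   2 = fixed at its value (frozen ML estimate; prior mean for the Gibbs stage)
#   3 = anchor (identification constraint, never estimated or sampled)

MASK_ABSENT <- 0L
MASK_FREE   <- 1L
MASK_FIXED  <- 2L
MASK_ANCHOR <- 3L

#' Construct a model specification
#'
#' Assembles and validates the parameter matrices of the SEM linking SNPs,
#' latent factors and traits. Matrices default to empty/zero structures of
#' the right dimension, so a bare measurement model needs only `Lambda`.
#'
#' @param latent_names character vector of factor names.
#' @param trait_names character vector of trait names.
#' @param trait_kinds character vector, `"continuous"` or `"ordinal"`, one per
#'   trait.
#' @param snp_factor_names names of SNPs attached to factors (columns of `Pi`).
#' @param snp_trait_names names of SNPs attached to traits (columns of `K`).
#' @param B,B_mask square latent-by-latent coefficient matrix and mask.
#' @param Lambda,Lambda_mask trait-by-latent loading matrix and mask.
#' @param Pi,Pi_mask latent-by-SNP matrix and mask (one nonzero cell per column).
#' @param K,K_mask trait-by-SNP matrix and mask (one nonzero cell per column).
#' @param theta_eps,theta_delta positive error-variance vectors for factors
#'   and traits.
#' @param theta_eps_free,theta_delta_free logical: are the variances free in
#'   ML fits.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(latent_names, trait_names,
                       trait_kinds = rep("continuous", length(trait_names)),
                       snp_factor_names = character(),
                       snp_trait_names = character(),
                       B = NULL, B_mask = NULL,
                       Lambda = NULL, Lambda_mask = NULL,
                       Pi = NULL, Pi_mask = NULL,
                       K = NULL, K_mask = NULL,
                       theta_eps = rep(1, length(latent_names)),
                       theta_delta = rep(1, length(trait_names)),
                       theta_eps_free = TRUE, theta_delta_free = TRUE) {
  nl <- length(latent_names); nt <- length(trait_names)
  ng <- length(snp_factor_names); ny <- length(snp_trait_names)
  zm <- function(r, c, rn, cn) {
    m <- matrix(0, r, c, dimnames = list(rn, cn)); m
  }
  if (is.null(B)) B <- zm(nl, nl, latent_names, latent_names)
  if (is.null(B_mask)) B_mask <- zm(nl, nl, latent_names, latent_names)
  if (is.null(Lambda)) Lambda <- zm(nt, nl, trait_names, latent_names)
  if (is.null(Lambda_mask)) Lambda_mask <- zm(nt, nl, trait_names, latent_names)
  if (is.null(Pi)) Pi <- zm(nl, ng, latent_names, snp_factor_names)
  if (is.null(Pi_mask)) Pi_mask <- zm(nl, ng, latent_names, snp_factor_names)
  if (is.null(K)) K <- zm(nt, ny, trait_names, snp_trait_names)
  if (is.null(K_mask)) K_mask <- zm(nt, ny, trait_names, snp_trait_names)
  obj <- structure(list(
    latent_names = latent_names, trait_names = trait_names,
    trait_kinds = trait_kinds,
    snp_factor_names = snp_factor_names, snp_trait_names = snp_trait_names,
    B = B, B_mask = storage_int(B_mask),
    Lambda = Lambda, Lambda_mask = storage_int(Lambda_mask),
    Pi = Pi, Pi_mask = storage_int(Pi_mask),
    K = K, K_mask = storage_int(K_mask),
    theta_eps = as.numeric(theta_eps), theta_delta = as.numeric(theta_delta),
    theta_eps_free = isTRUE(theta_eps_free),
    theta_delta_free = isTRUE(theta_delta_free)
  ), class = "model_spec")
  validate_model_spec(obj)
  obj
}

storage_int <- function(m) {
  storage.mode(m) <- "integer"
  m
}

#' Validate a model specification
#'
#' Checks the structural invariants: acyclic B, at most one nonzero cell per
#' Pi/K column, strictly positive diagonal error variances, matching
#' dimensions, and (when Lambda has free cells) exactly one anchor loading
#' per factor.
#'
#' @param model a `model_spec`.
#' @return the model, invisibly; errors on violation.
#' @export
validate_model_spec <- function(model) {
  nl <- length(model$latent_names); nt <- length(model$trait_names)
  ng <- length(model$snp_factor_names); ny <- length(model$snp_trait_names)
  stopifnot(
    all(dim(model$B) == c(nl, nl)), all(dim(model$B_mask) == c(nl, nl)),
    all(dim(model$Lambda) == c(nt, nl)), all(dim(model$Pi) == c(nl, ng)),
    all(dim(model$K) == c(nt, ny)),
    length(model$trait_kinds) == nt,
    all(model$trait_kinds %in% c("continuous", "ordinal")),
    length(model$theta_eps) == nl, length(model$theta_delta) == nt
  )
  if (any(model$theta_eps <= 0) || any(model$theta_delta <= 0))
    stop("error variances must be strictly positive", call. = FALSE)
  if (!is_acyclic(model$B_mask != MASK_ABSENT))
    stop("structural matrix B defines a cyclic graph", call. = FALSE)
  for (nm in c("Pi", "K")) {
    mk <- model[[paste0(nm, "_mask")]]
    if (ncol(mk) && any(colSums(mk != MASK_ABSENT) > 1L))
      stop(sprintf("each column of %s may have at most one nonzero cell (a SNP influences only one variable)", nm),
           call. = FALSE)
  }
  lm <- model$Lambda_mask
  if (any(lm == MASK_FREE)) {
    anchors <- colSums(lm == MASK_ANCHOR)
    used <- colSums(lm != MASK_ABSENT) > 0
    if (any(used & anchors != 1L))
      stop("each factor with free loadings needs exactly one anchor loading", call. = FALSE)
  }
  invisible(model)
}

#' Test whether a directed graph is acyclic
#'
#' Kahn's algorithm on the adjacency matrix; `adj[j, i]` nonzero/`TRUE` means
#' an edge i -> j (the row variable is the child, as in the B matrix).
#'
#' @param adj square logical/numeric adjacency matrix.
#' @return `TRUE` iff there is no directed cycle.
#' @export
is_acyclic <- function(adj) {
  adj <- adj != 0
  n <- nrow(adj)
  stopifnot(ncol(adj) == n)
  if (n == 0L) return(TRUE)
  alive <- rep(TRUE, n)
  repeat {
    indeg <- rowSums(adj[, alive, drop = FALSE])
    src <- which(alive & indeg == 0)
    if (!length(src)) break
    alive[src] <- FALSE
  }
  !any(alive)
}

# count of free (mask == 1) cells plus free variances
n_free_params <- function(model) {
  sum(model$B_mask == MASK_FREE) + sum(model$Lambda_mask == MASK_FREE) +
    sum(model$Pi_mask == MASK_FREE) + sum(model$K_mask == MASK_FREE) +
    (if (model$theta_eps_free) length(model$theta_eps) else 0L) +
    (if (model$theta_delta_free) length(model$theta_delta) else 0L)
}

#' Freeze free cells at their current values
#'
#' Demotes free (mask 1) cells of the given matrices to fixed (mask 2), so
#' later fits treat them as constants and the Gibbs stage uses them as prior
#' means. Used after construction-time ML and after each SNP addition.
#'
#' @param model a `model_spec`.
#' @param which which matrices to freeze.
#' @return the updated model.
#' @export
freeze_masks <- function(model, which = c("B", "Lambda", "Pi", "K")) {
  for (nm in which) {
    mk <- model[[paste0(nm, "_mask")]]
    mk[mk == MASK_FREE] <- MASK_FIXED
    model[[paste0(nm, "_mask")]] <- mk
  }
  model
}

#' @export
print.model_spec <- function(x, ...) {
  cat("SEM model specification\n")
  cat(sprintf("  factors: %d (%s)\n", length(x$latent_names),
              paste(x$latent_names, collapse = ", ")))
  cat(sprintf("  traits:  %d (%d ordinal)\n", length(x$trait_names),
              sum(x$trait_kinds == "ordinal")))
  cat(sprintf("  SNPs on factors: %d; SNPs on traits: %d\n",
              length(x$snp_factor_names), length(x$snp_trait_names)))
  cat(sprintf("  B edges: %d; free parameters: %d\n",
              sum(x$B_mask != MASK_ABSENT), n_free_params(x)))
  invisible(x)
}

# ---- JSON serialization (sparse triplets per matrix) ------------------------

mat_to_triplets <- function(val, mask) {
  idx <- which(mask != MASK_ABSENT, arr.ind = TRUE)
  data.frame(row = idx[, 1], col = idx[, 2],
             value = val[idx], mask = mask[idx])
}

triplets_to_mat <- function(tr, nr, nc, rn, cn) {
  val <- matrix(0, nr, nc, dimnames = list(rn, cn))
  mask <- storage_int(val)
  if (length(tr$row)) {
    val[cbind(tr$row, tr$col)] <- tr$value
    mask[cbind(tr$row, tr$col)] <- as.integer(tr$mask)
  }
  list(val = val, mask = mask)
}

#' Serialize a model specification to JSON
#'
#' Sparse-triplet JSON document; `model_from_json(model_to_json(m))` is
#' lossless.
#'
#' @param model a `model_spec`.
#' @param path optional file path; if given the JSON is written there.
#' @return JSON string (invisibly if `path` given).
#' @export
model_to_json <- function(model, path = NULL) {
  doc <- list(
    latent_names = model$latent_names, trait_names = model$trait_names,
    trait_kinds = model$trait_kinds,
    snp_factor_names = model$snp_factor_names,
    snp_trait_names = model$snp_trait_names,
    B = mat_to_triplets(model$B, model$B_mask),
    Lambda = mat_to_triplets(model$Lambda, model$Lambda_mask),
    Pi = mat_to_triplets(model$Pi, model$Pi_mask),
    K = mat_to_triplets(model$K, model$K_mask),
    theta_eps = model$theta_eps, theta_delta = model$theta_delta,
    theta_eps_free = model$theta_eps_free,
    theta_delta_free = model$theta_delta_free
  )
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Load a model specification from JSON
#'
#' @param x JSON string or path to a JSON file written by [model_to_json()].
#' @return a `model_spec`.
#' @export
model_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x)
  chr <- function(v) if (is.null(v) || !length(v)) character() else as.character(v)
  ln <- chr(doc$latent_names); tn <- chr(doc$trait_names)
  gn <- chr(doc$snp_factor_names); yn <- chr(doc$snp_trait_names)
  B <- triplets_to_mat(doc$B, length(ln), length(ln), ln, ln)
  L <- triplets_to_mat(doc$Lambda, length(tn), length(ln), tn, ln)
  P <- triplets_to_mat(doc$Pi, length(ln), length(gn), ln, gn)
  K <- triplets_to_mat(doc$K, length(tn), length(yn), tn, yn)
  model_spec(ln, tn, chr(doc$trait_kinds), gn, yn,
             B = B$val, B_mask = B$mask,
             Lambda = L$val, Lambda_mask = L$mask,
             Pi = P$val, Pi_mask = P$mask,
             K = K$val, K_mask = K$mask,
             theta_eps = doc$theta_eps, theta_delta = doc$theta_delta,
             theta_eps_free = isTRUE(doc$theta_eps_free),
             theta_delta_free = isTRUE(doc$theta_delta_free))
}
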