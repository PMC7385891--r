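# Shared fixtures. Everything is generated in code; no stored data.

# small measurement-only model: 1 factor, 2 traits, loading fixed
tiny_model <- function() {
  model_spec(
    latent_names = "F1", trait_names = c("T1", "T2"),
    Lambda = matrix(c(1, 0.8), 2, 1, dimnames = list(c("T1", "T2"), "F1")),
    Lambda_mask = matrix(c(3L, 1L), 2, 1),
    theta_eps = 1, theta_delta = c(1, 1))
}

# estimation model matching a true model's structure: masks set free with
# anchored first loading per factor
estimation_model_from_truth <- function(tm) {
  m <- tm
  m$B_mask[m$B_mask == 2L] <- 1L
  m$Lambda_mask[m$Lambda_mask == 2L] <- 1L
  for (j in seq_along(m$latent_names)) {
    first <- which(m$Lambda_mask[, j] == 1L)[1]
    m$Lambda_mask[first, j] <- 3L
    m$Lambda[first, j] <- 1
  }
  m$Pi_mask[m$Pi_mask == 2L] <- 1L
  m$K_mask[m$K_mask == 2L] <- 1L
  m$theta_eps_free <- m$theta_delta_free <- TRUE
  class(m) <- "model_spec"
  m
}

# truth values on the anchored scale for comparing fits to a true model
anchored_truth <- function(tm, est_model, labels) {
  anchors <- vapply(seq_along(tm$latent_names), function(j)
    tm$Lambda[which(est_model$Lambda_mask[, j] == 3L)[1], j], numeric(1))
  out <- rep(NA_real_, length(labels))
  for (i in seq_along(labels)) {
    p <- labels[i]
    inner <- sub("^[A-Za-z_]+\\[", "", sub("\\]$", "", p))
    ij <- strsplit(inner, ",")[[1]]
    if (startsWith(p, "Lambda[")) {
      out[i] <- tm$Lambda[ij[1], ij[2]] / anchors[match(ij[2], tm$latent_names)]
    } else if (startsWith(p, "Pi[")) {
      out[i] <- tm$Pi[ij[1], ij[2]] * anchors[match(ij[1], tm$latent_names)]
    } else if (startsWith(p, "B[")) {
      af <- anchors[match(ij[2], tm$latent_names)]
      at <- anchors[match(ij[1], tm$latent_names)]
      out[i] <- tm$B[ij[1], ij[2]] * at / af
    } else if (startsWith(p, "K[")) {
      out[i] <- tm$K[ij[1], ij[2]]
    } else if (startsWith(p, "theta_eps[")) {
      j <- match(inner, tm$latent_names)
      out[i] <- tm$theta_eps[j] * anchors[j]^2
    } else if (startsWith(p, "theta_delta[")) {
      out[i] <- tm$theta_delta[match(inner, tm$trait_names)]
    }
  }
  out
}

# independent simulated SNPs for null candidates
null_snp_codes <- function(n, n_snps, seed, prefix = "null") {
  set.seed(seed)
  M <- vapply(stats::runif(n_snps, 0.2, 0.8), function(p)
    semgwas::discretize(stats::rnorm(n), semgwas:::hw_thresholds(p)) - 1L,
    integer(n))
  colnames(M) <- paste0(prefix, seq_len(n_snps))
  M
}

# hybrid matrix for a bundle plus extra SNP codes
bundle_hybrid <- function(ds, extra_codes = NULL) {
  geno <- ds$genotypes
  if (!is.null(extra_codes)) geno <- cbind(geno, extra_codes)
  dat <- cbind(ds$phenotypes, as.data.frame(geno))
  kinds <- c(ds$trait_meta$kind, rep("ordinal", ncol(geno)))
  list(hb = hybrid_matrix(dat, kinds), geno = geno)
}

quick_gibbs <- function(n_chains = 2L, length = 300L, burn_in = 100L, ...)
  gibbs_control(n_chains = n_chains, length = length, burn_in = burn_in, ...)

# map a constructed model's factor labels back to truth via trait blocks
truth_label_of <- function(attribution, tm) {
  function(f) {
    trs <- attribution$trait[attribution$factor == f]
    tf <- unique(colnames(tm$Lambda)[apply(
      tm$Lambda[trs, , drop = FALSE] != 0, 1, which)])
    if (length(tf) == 1) tf else NA_character_
  }
}

# undirected skeleton of a recovered edge table, in truth labels
recovered_skeleton <- function(edges, attribution, tm) {
  if (!nrow(edges)) return(character())
  lab <- truth_label_of(attribution, tm)
  sort(vapply(seq_len(nrow(edges)), function(i) {
    pair <- sort(c(lab(edges$from[i]), lab(edges$to[i])))
    paste(pair, collapse = "-")
  }, ""))
}
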