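# Genotype/phenotype input, data-preparation filters and transforms.

#' Read a genotype matrix
#'
#' VCF input (minimal v4.2 subset: CHROM, POS, ID, REF, ALT, GT) is parsed
#' with VariantAnnotation; diploid genotypes are coded 0/1/2 by
#' alternate-allele count, missing calls become `NA`, multi-allelic records
#' are skipped (count reported). Alternatively a plain sample x SNP table
#' (TSV; header = SNP ids, first column = sample id, cells in {0,1,2,NA})
#' is accepted.
#'
#' @param path file path.
#' @param format `"vcf"` or `"table"`.
#' @return list with `genotypes` (samples x SNPs integer matrix), `snp_info`
#'   (snp, chrom, pos, ref, alt), `samples`, `n_multiallelic_skipped`.
#' @export
read_genotypes <- function(path, format = c("vcf", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "table") {
    tab <- utils::read.delim(path, check.names = FALSE)
    samples <- as.character(tab[[1]])
    M <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(M) <- "integer"
    rownames(M) <- samples
    bad <- !(M %in% c(0L, 1L, 2L, NA))
    if (any(bad)) stop("genotype table contains codes outside {0,1,2,NA}",
                       call. = FALSE)
    return(list(genotypes = M,
                snp_info = data.frame(snp = colnames(M), chrom = NA,
                                      pos = NA, ref = NA, alt = NA),
                samples = samples, n_multiallelic_skipped = 0L))
  }
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package", call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  multi <- S4Vectors::elementNROWS(alt) > 1L
  n_multi <- sum(multi)
  if (any(multi)) vcf <- vcf[!multi]
  gt <- VariantAnnotation::geno(vcf)$GT
  code1 <- function(g) {
    g <- sub("\\|", "/", g)
    ifelse(g %in% c("./.", ".", ".|."), NA_integer_,
           vapply(strsplit(g, "/", fixed = TRUE), function(a)
             sum(a != "0" & a != "."), integer(1)))
  }
  M <- t(apply(gt, 1, code1))
  if (nrow(gt) == 1L) M <- matrix(M, nrow = 1L)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ids <- names(vcf) %||% paste0("snp", seq_len(nrow(gt)))
  M <- t(M)  # samples x SNPs
  dimnames(M) <- list(colnames(gt), ids)
  storage.mode(M) <- "integer"
  list(genotypes = M,
       snp_info = data.frame(
         snp = ids,
         chrom = as.character(GenomicRanges::seqnames(rr)),
         pos = GenomicRanges::start(rr),
         ref = as.character(VariantAnnotation::ref(vcf)),
         alt = vapply(as(VariantAnnotation::alt(vcf), "CharacterList"),
                      `[`, "", 1),
         stringsAsFactors = FALSE),
       samples = colnames(gt), n_multiallelic_skipped = n_multi)
}

#' Write genotype codes as a minimal VCF
#'
#' Emits an uncompressed VCF v4.2 with CHROM, POS, ID, REF, ALT and GT
#' fields; code 0 -> 0/0, 1 -> 0/1, 2 -> 1/1, `NA` -> ./. (used to export
#' synthetic datasets so the whole pipeline can run from standard formats).
#'
#' @param genotypes samples x SNPs code matrix.
#' @param snp_info data.frame with snp, chrom, pos, ref, alt.
#' @param samples sample ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, snp_info, samples, path) {
  gtmap <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(snp_info)), function(i) {
    g <- genotypes[, snp_info$snp[i]]
    gt <- ifelse(is.na(g), "./.", gtmap[g + 1L])
    paste(c(snp_info$chrom[i], snp_info$pos[i], snp_info$snp[i],
            snp_info$ref[i] %||% "A", snp_info$alt[i] %||% "G",
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Filter variants on minor allele frequency and call rate
#'
#' MAF is `min(p, 1-p)` with `p = mean(code)/2` over non-missing calls; a
#' SNP is retained iff `MAF > maf_min` and call rate `> call_rate_min`
#' (strict inequalities). Idempotent.
#'
#' @param geno list as returned by [read_genotypes()] (or any list with
#'   `genotypes` and `snp_info`).
#' @param maf_min minimum minor allele frequency (exclusive).
#' @param call_rate_min minimum fraction of non-missing calls (exclusive).
#' @return list with filtered `genotypes`/`snp_info` plus `report`
#'   (data.frame: n_input, n_dropped_maf, n_dropped_callrate, n_retained).
#' @export
filter_variants <- function(geno, maf_min = 0.03, call_rate_min = 0.90) {
  M <- geno$genotypes
  call_rate <- colMeans(!is.na(M))
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep_maf <- maf > maf_min
  keep_cr <- call_rate > call_rate_min
  keep <- keep_maf & keep_cr
  list(genotypes = M[, keep, drop = FALSE],
       snp_info = geno$snp_info[keep, , drop = FALSE],
       samples = geno$samples,
       report = data.frame(n_input = ncol(M),
                           n_dropped_maf = sum(!keep_maf),
                           n_dropped_callrate = sum(!keep_cr),
                           n_retained = sum(keep)))
}

#' Prepare phenotypes: merges, transforms, standardisation
#'
#' Applies per-trait category merges (ordinal traits), log transforms
#' (natural log; requires strictly positive values), and z-scoring of all
#' quantitative traits. Ordinal traits stay integer codes (thresholds are
#' estimated downstream, on training data only within cross-validation).
#'
#' @param raw data.frame of raw trait values.
#' @param meta data.frame with columns `trait`, `kind`
#'   (`continuous`/`ordinal`), `transform` (`none`, `log`, `zscore`,
#'   `log+zscore`), and optionally `merge` (string like `"1:1,2:1,3:2"`
#'   mapping old codes to new).
#' @return list with `phenotypes` (prepared data.frame), `meta`.
#' @export
prepare_phenotypes <- function(raw, meta) {
  stopifnot(all(meta$trait %in% colnames(raw)))
  out <- raw[, meta$trait, drop = FALSE]
  for (i in seq_len(nrow(meta))) {
    tr <- meta$trait[i]
    x <- out[[tr]]
    if (!is.null(meta$merge) && !is.na(meta$merge[i]) && nzchar(meta$merge[i])) {
      pairs <- strsplit(strsplit(meta$merge[i], ",", fixed = TRUE)[[1]],
                        ":", fixed = TRUE)
      map <- stats::setNames(vapply(pairs, `[`, "", 2),
                             vapply(pairs, `[`, "", 1))
      x <- as.integer(map[as.character(x)])
    }
    tf <- meta$transform[i] %||% "none"
    if (grepl("log", tf)) {
      bad <- which(!is.na(x) & x <= 0)
      if (length(bad))
        stop(sprintf("log transform of trait %s: non-positive value at sample %d",
                     tr, bad[1]), call. = FALSE)
      x <- log(x)
    }
    # every quantitative trait ends up z-scored (the model assumes
    # standardised traits with no intercept); population-sd convention
    if (meta$kind[i] == "continuous") {
      mu <- mean(x, na.rm = TRUE)
      sdp <- sqrt(mean((x - mu)^2, na.rm = TRUE))
      x <- (x - mu) / sdp
    }
    out[[tr]] <- x
  }
  list(phenotypes = out, meta = meta)
}
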