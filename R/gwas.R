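#' Single-marker association scan
#'
#' Regresses an adjusted phenotype on each variant's alt-allele dosage,
#' optionally conditioning on the dosages of previously selected tag
#' variants (fitted as covariates).  Conditioning is handled by projecting
#' the phenotype and every test dosage onto the orthogonal complement of
#' the covariate space (Frisch-Waugh), so the per-variant fit is a cheap
#' univariate regression.  Missing dosages are mean-imputed per column.
#'
#' @param genotypes individuals x variants dosage matrix.
#' @param phenotype named numeric vector (names = individual ids) of
#'   adjusted phenotypes, aligned to `rownames(genotypes)` by name.
#' @param catalog variant catalog (`variant_id`, `chrom`, `pos`) used to
#'   annotate results.
#' @param condition character vector of variant ids fitted as covariates;
#'   these (and anything in `exclude`) are not tested.
#' @param exclude further variant ids to skip.
#' @return `data.frame` with `variant_id`, `chrom`, `pos`, `beta`, `se`,
#'   `p_value`, `monomorphic`, `n`.  Monomorphic variants (or variants with
#'   no residual dosage variance after conditioning) get `beta = 0`,
#'   `p_value = 1` and the flag set.  P-values are clamped to the smallest
#'   positive double so they remain in `(0, 1]` even when the signal is
#'   noiseless.
#' @export
single_marker_scan <- function(genotypes, phenotype, catalog,
                               condition = character(),
                               exclude = condition) {
  ids <- rownames(genotypes)
  if (is.null(names(phenotype))) {
    stopifnot(length(phenotype) == nrow(genotypes))
    names(phenotype) <- ids
  }
  common <- intersect(ids, names(phenotype))
  if (!length(common)) stop("no shared individuals", call. = FALSE)
  G <- genotypes[common, , drop = FALSE]
  y <- phenotype[common]
  bad <- setdiff(condition, colnames(G))
  if (length(bad))
    stop("conditioning variants absent from genotypes: ",
         paste(bad, collapse = ", "), call. = FALSE)
  # column mean imputation of missing calls
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2L]]
  }
  n <- length(y)
  C <- cbind(Intercept = rep(1, n), G[, condition, drop = FALSE])
  Qc <- qr.Q(qr(C))
  ystar <- y - Qc %*% crossprod(Qc, y)
  test_ids <- setdiff(colnames(G), unique(c(condition, exclude)))
  Z <- G[, test_ids, drop = FALSE]
  Z <- Z - Qc %*% crossprod(Qc, Z)
  szz <- colSums(Z^2)
  syy <- sum(ystar^2)
  df <- n - ncol(C) - 1L
  if (df < 1L) stop("not enough residual degrees of freedom", call. = FALSE)
  mono <- szz < 1e-10
  beta <- rep(0, length(test_ids))
  pval <- rep(1, length(test_ids))
  se <- rep(NA_real_, length(test_ids))
  ok <- !mono
  beta[ok] <- as.vector(crossprod(Z[, ok, drop = FALSE], ystar)) / szz[ok]
  rss <- pmax(syy - beta^2 * szz, 0)
  se[ok] <- sqrt((rss[ok] / df) / szz[ok])
  tt <- beta[ok] / se[ok]
  pval[ok] <- pmax(2 * stats::pt(-abs(tt), df), .Machine$double.xmin)
  ord <- match(test_ids, catalog$variant_id)
  out <- data.frame(variant_id = test_ids,
                    chrom = catalog$chrom[ord],
                    pos = catalog$pos[ord],
                    beta = beta, se = se, p_value = pval,
                    monomorphic = mono, n = n,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Iterative conditional GWAS tag discovery
#'
#' Repeats a genome scan in which the single most significant variant per
#' chromosome with `p < threshold` is added to the tag set and fitted as an
#' additional fixed covariate in the next iteration, until no chromosome
#' yields a new significant variant.  Tags are never removed once selected.
#' Ties are broken deterministically (smaller p, then lower position, then
#' lexicographic id), making the tag set invariant to variant input order.
#'
#' @inheritParams single_marker_scan
#' @param threshold genome-wide significance threshold; default
#'   `1.9e-10`.
#' @param max_iterations safety bound on the conditioning loop.
#' @return list with `tags` (character vector of tag variant ids, in
#'   selection order) and `history` (per-iteration scan rows for the
#'   selected tags, with `iteration` and `conditioning` columns).
#' @export
iterative_conditional_gwas <- function(genotypes, phenotype, catalog,
                                       threshold = 1.9e-10,
                                       max_iterations = 20) {
  stopifnot(threshold > 0, threshold < 1)
  tags <- character()
  history <- list()
  for (it in seq_len(max_iterations)) {
    res <- single_marker_scan(genotypes, phenotype, catalog,
                              condition = tags)
    sig <- res[res$p_value < threshold & !res$monomorphic, , drop = FALSE]
    if (!nrow(sig)) break
    # deterministic per-chromosome top hit
    sig <- sig[order(sig$chrom, sig$p_value, sig$pos, sig$variant_id), ]
    top <- sig[!duplicated(sig$chrom), , drop = FALSE]
    top$iteration <- it
    top$conditioning <- paste(tags, collapse = ";")
    history[[it]] <- top
    tags <- c(tags, top$variant_id)
    if (it == max_iterations && nrow(top))
      warning("iterative GWAS stopped at max_iterations with new hits ",
              "still appearing", call. = FALSE)
  }
  list(tags = tags,
       history = if (length(history)) do.call(rbind, history)
                 else data.frame())
}
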