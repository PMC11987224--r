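#' Molecular phenotype container
#'
#' A light container pairing per-individual phenotype values for genomic
#' features (genes, exons, splice junctions, peaks) with the feature
#' coordinates needed for cis-window scans.
#'
#' @param values `data.frame` with `feature_id`, `individual_id`, `value`.
#' @param features `data.frame` with `feature_id`, `chrom`, `pos` (one
#'   representative coordinate per feature; the cis window is centred on
#'   it and closed at both ends).
#' @return object of class `molecular_phenotype`.
#' @export
molecular_phenotype <- function(values, features) {
  stopifnot(all(c("feature_id", "individual_id", "value") %in% names(values)),
            all(c("feature_id", "chrom", "pos") %in% names(features)))
  if (any(!is.finite(values$value)))
    stop("molecular phenotype values must be finite", call. = FALSE)
  structure(list(values = values,
                 features = features[!duplicated(features$feature_id), ]),
            class = "molecular_phenotype")
}

#' Splicing-efficiency phenotype
#'
#' Per junction and individual, the proportion of reads spliced out of all
#' reads crossing the junction, logit-transformed:
#' `logit((spliced + c) / (spliced + unspliced + 2c))` with pseudocount `c`.
#' With `c = 0`, zero-total rows are dropped (with a message).  Features
#' retained must have at least `min_individuals` rows.
#'
#' @param counts `data.frame` with `individual_id`, `feature_id`,
#'   `spliced_count`, `unspliced_count` (e.g. from
#'   [simulate_splice_counts()]).
#' @param pseudocount non-negative pseudocount `c`; default 0.5
#'   (Haldane-Anscombe).
#' @param features feature coordinate table; defaults to the `features`
#'   attribute of `counts`.
#' @param min_individuals minimum rows per retained feature.
#' @return a [molecular_phenotype()].
#' @export
splicing_efficiency_phenotype <- function(counts, pseudocount = 0.5,
                                          features = attr(counts, "features"),
                                          min_individuals = 20) {
  stopifnot(pseudocount >= 0)
  s <- counts$spliced_count
  u <- counts$unspliced_count
  if (any(s < 0 | u < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- s + u + 2 * pseudocount
  drop <- tot == 0
  if (any(drop)) {
    message(sum(drop), " zero-total rows dropped (pseudocount = 0)")
    counts <- counts[!drop, ]; s <- s[!drop]; u <- u[!drop]; tot <- tot[!drop]
  }
  vals <- data.frame(feature_id = counts$feature_id,
                     individual_id = counts$individual_id,
                     value = qlogis((s + pseudocount) / tot),
                     stringsAsFactors = FALSE)
  keep <- names(which(table(vals$feature_id) >= min_individuals))
  vals <- vals[vals$feature_id %in% keep, ]
  molecular_phenotype(vals, features[features$feature_id %in% keep, ])
}

#' Intron (pre-mRNA) expression phenotype
#'
#' Counts of unspliced reads per junction, transformed as standardized
#' `log(count + 1)` within feature.  The log1p + z-score combination is a
#' simple monotone variance-stabilising choice; zero-variance features map
#' to all-zero values.
#'
#' @inheritParams splicing_efficiency_phenotype
#' @return a [molecular_phenotype()].
#' @export
intron_expression_phenotype <- function(counts,
                                        features = attr(counts, "features"),
                                        min_individuals = 20) {
  u <- counts$unspliced_count
  if (any(u < 0)) stop("counts must be non-negative", call. = FALSE)
  lv <- log1p(u)
  vals <- data.frame(feature_id = counts$feature_id,
                     individual_id = counts$individual_id,
                     value = 0,
                     stringsAsFactors = FALSE)
  for (f in unique(vals$feature_id)) {
    i <- vals$feature_id == f
    x <- lv[i]
    s <- stats::sd(x)
    vals$value[i] <- if (is.na(s) || s == 0) 0 else (x - mean(x)) / s
  }
  keep <- names(which(table(vals$feature_id) >= min_individuals))
  vals <- vals[vals$feature_id %in% keep, ]
  molecular_phenotype(vals, features[features$feature_id %in% keep, ])
}

#' QTL tag set container
#' @param class_label functional class the tags belong to.
#' @param tags `data.frame` with `variant_id`, `feature_id`, `p_value`.
#' @param params list of thresholds used.
#' @return object of class `qtl_tag_set`.
#' @export
qtl_tag_set <- function(class_label, tags, params = list()) {
  structure(list(class = class_label, tags = tags, params = params),
            class = "qtl_tag_set")
}

#' @method print qtl_tag_set
#' @export
print.qtl_tag_set <- function(x, ...) {
  cat("QTL tag set [", x$class, "]: ", nrow(x$tags), " tags\n", sep = "")
  invisible(x)
}

# Univariate regression p-values of y on each column of Z (with intercept).
.scan_columns <- function(Z, y) {
  n <- length(y)
  Zc <- sweep(Z, 2, colMeans(Z))
  yc <- y - mean(y)
  szz <- colSums(Zc^2)
  ok <- szz > 1e-10
  beta <- rep(0, ncol(Z)); pv <- rep(1, ncol(Z))
  beta[ok] <- as.vector(crossprod(Zc[, ok, drop = FALSE], yc)) / szz[ok]
  rss <- pmax(sum(yc^2) - beta^2 * szz, 0)
  df <- n - 2L
  se2 <- (rss[ok] / df) / szz[ok]
  tt <- beta[ok] / sqrt(se2)
  pv[ok] <- pmax(2 * stats::pt(-abs(tt), df), .Machine$double.xmin)
  list(beta = beta, p = pv)
}

#' Cis-window QTL scan with per-feature tagging
#'
#' For each feature, regresses its molecular phenotype on the dosage of
#' every variant within `window_bp` of the feature position (closed window)
#' passing the MAF floor; if the smallest p-value beats `p_threshold`, that
#' most significant variant is emitted as the feature's tag.  Tags are
#' deduplicated across features (a variant tagging several features is kept
#' once, at its smallest p).
#'
#' @param genotypes dosage matrix.
#' @param catalog variant catalog.
#' @param phen a [molecular_phenotype()].
#' @param window_bp cis window half-width in bp (default 1 Mb).
#' @param p_threshold per-feature significance threshold (1e-6 is the usual
#'   default; exon-expression scans use 1e-8).
#' @param maf_min MAF floor, exclusive (variants with `maf > maf_min` are
#'   tested); default 0.1.
#' @param class_label label stored on the resulting tag set.
#' @param min_individuals minimum phenotyped individuals per feature.
#' @return a [qtl_tag_set()]; features with no variant in the window are
#'   skipped with a message.
#' @export
cis_scan <- function(genotypes, catalog, phen, window_bp = 1e6,
                     p_threshold = 1e-6, maf_min = 0.1,
                     class_label = "eQTL", min_individuals = 20) {
  stopifnot(inherits(phen, "molecular_phenotype"), window_bp > 0)
  feats <- phen$features
  hits <- list()
  skipped <- 0L
  for (k in seq_len(nrow(feats))) {
    fid <- feats$feature_id[k]
    rows <- phen$values[phen$values$feature_id == fid, ]
    if (nrow(rows) < min_individuals) next
    cand <- which(catalog$chrom == feats$chrom[k] &
                    abs(catalog$pos - feats$pos[k]) <= window_bp &
                    catalog$maf > maf_min)
    if (!length(cand)) { skipped <- skipped + 1L; next }
    ids <- intersect(rows$individual_id, rownames(genotypes))
    rows <- rows[match(ids, rows$individual_id), ]
    Z <- genotypes[ids, catalog$variant_id[cand], drop = FALSE]
    if (anyNA(Z)) {
      mu <- colMeans(Z, na.rm = TRUE)
      idx <- which(is.na(Z), arr.ind = TRUE)
      Z[idx] <- mu[idx[, 2L]]
    }
    sc <- .scan_columns(Z, rows$value)
    j <- which.min(sc$p)
    if (sc$p[j] < p_threshold)
      hits[[fid]] <- data.frame(variant_id = colnames(Z)[j],
                                feature_id = fid, p_value = sc$p[j],
                                stringsAsFactors = FALSE)
  }
  if (skipped) message(skipped, " features had no variant in the cis window")
  tags <- if (length(hits)) do.call(rbind, hits) else
    data.frame(variant_id = character(), feature_id = character(),
               p_value = numeric(), stringsAsFactors = FALSE)
  tags <- tags[order(tags$p_value), ]
  tags <- tags[!duplicated(tags$variant_id), ]
  rownames(tags) <- NULL
  qtl_tag_set(class_label, tags,
              list(window_bp = window_bp, p_threshold = p_threshold,
                   maf_min = maf_min))
}

#' Two-stage allele-specific expression/binding QTL test
#'
#' Stage 1: for each candidate variant in the feature's cis window, allelic
#' reads of heterozygous carriers are pooled and tested for imbalance with
#' the binomial-normal statistic
#' `Z = (sum maternal - sum paternal) / sqrt(total)`; two-sided normal
#' p-values below `stage1_gate` pass.  Stage 2: for survivors, the
#' per-individual log allelic ratio `log((maternal + c)/(paternal + c))` is
#' regressed on carrier heterozygosity at the candidate (a cis allele
#' unbalances only heterozygotes, so genotype enters as the heterozygote
#' indicator).  The feature's tag is its most significant stage-2 variant
#' with `p < final_threshold`; tags are deduplicated across features.
#'
#' @param counts allelic count table (`individual_id`, `feature_id`,
#'   `maternal_count`, `paternal_count`), e.g. from
#'   [simulate_allelic_counts()].
#' @param genotypes dosage matrix.
#' @param catalog variant catalog.
#' @param stage1_gate stage-1 p-value gate (default 1e-3).
#' @param final_threshold stage-2 tagging threshold (1e-8 for expression
#'   aseQTL, 1e-6 for binding asbQTL).
#' @param maf_min MAF floor, exclusive.
#' @param window_bp cis window half-width.
#' @param pseudocount log-ratio pseudocount `c` (default 0.5).
#' @param class_label label stored on the tag set.
#' @param min_informative minimum informative individuals per feature;
#'   features below it are skipped with a message.
#' @param features feature coordinates; defaults to the `features`
#'   attribute of `counts`.
#' @return a [qtl_tag_set()].
#' @export
ase_two_stage_test <- function(counts, genotypes, catalog,
                               stage1_gate = 1e-3, final_threshold = 1e-8,
                               maf_min = 0.1, window_bp = 1e6,
                               pseudocount = 0.5, class_label = "aseQTL",
                               min_informative = 10,
                               features = attr(counts, "features")) {
  stopifnot(!is.null(features))
  hits <- list()
  skipped <- 0L
  for (k in seq_len(nrow(features))) {
    fid <- features$feature_id[k]
    rows <- counts[counts$feature_id == fid, ]
    rows <- rows[rows$individual_id %in% rownames(genotypes), ]
    if (nrow(rows) < min_informative) { skipped <- skipped + 1L; next }
    cand <- which(catalog$chrom == features$chrom[k] &
                    abs(catalog$pos - features$pos[k]) <= window_bp &
                    catalog$maf > maf_min)
    if (!length(cand)) next
    D <- genotypes[rows$individual_id, catalog$variant_id[cand],
                   drop = FALSE]
    logratio <- log((rows$maternal_count + pseudocount) /
                      (rows$paternal_count + pseudocount))
    best_p <- Inf; best_id <- NA_character_
    for (j in seq_len(ncol(D))) {
      d <- D[, j]
      het <- !is.na(d) & d == 1
      if (sum(het) < 3L) next
      tot <- sum(rows$maternal_count[het] + rows$paternal_count[het])
      if (tot == 0) next
      z <- (sum(rows$maternal_count[het]) - sum(rows$paternal_count[het])) /
        sqrt(tot)
      p1 <- 2 * stats::pnorm(-abs(z))
      if (p1 >= stage1_gate) next
      # stage 2: slope of log-ratio on heterozygosity
      x <- as.numeric(het)
      ok <- !is.na(d)
      sxx <- sum((x[ok] - mean(x[ok]))^2)
      if (sxx < 1e-10) next
      fit <- stats::lm.fit(cbind(1, x[ok]), logratio[ok])
      df <- sum(ok) - 2L
      if (df < 1L) next
      s2 <- sum(fit$residuals^2) / df
      se <- sqrt(s2 / sxx)
      p2 <- if (se == 0) .Machine$double.xmin else
        pmax(2 * stats::pt(-abs(fit$coefficients[2] / se), df),
             .Machine$double.xmin)
      if (p2 < best_p) { best_p <- p2; best_id <- colnames(D)[j] }
    }
    if (is.finite(best_p) && best_p < final_threshold)
      hits[[fid]] <- data.frame(variant_id = best_id, feature_id = fid,
                                p_value = best_p, stringsAsFactors = FALSE)
  }
  if (skipped)
    message(skipped, " features skipped (< ", min_informative,
            " informative individuals)")
  tags <- if (length(hits)) do.call(rbind, hits) else
    data.frame(variant_id = character(), feature_id = character(),
               p_value = numeric(), stringsAsFactors = FALSE)
  tags <- tags[order(tags$p_value), ]
  tags <- tags[!duplicated(tags$variant_id), ]
  rownames(tags) <- NULL
  qtl_tag_set(class_label, tags,
              list(stage1_gate = stage1_gate,
                   final_threshold = final_threshold, maf_min = maf_min,
                   window_bp = window_bp, pseudocount = pseudocount))
}
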