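#' Marker panel container
#'
#' A named, ordered set of variant ids with provenance: per-class counts,
#' a MAF-bin histogram, and a construction log.
#'
#' @param name panel name.
#' @param variant_ids character vector of unique variant ids.
#' @param catalog variant catalog used to compute provenance.
#' @param log character vector describing construction steps.
#' @return object of class `panel`.
#' @export
new_panel <- function(name, variant_ids, catalog, log = character()) {
  if (anyDuplicated(variant_ids)) stop("panel ids must be unique", call. = FALSE)
  idx <- match(variant_ids, catalog$variant_id)
  if (anyNA(idx)) stop("panel ids missing from catalog", call. = FALSE)
  cls <- split_classes(catalog$classes[idx])
  class_counts <- table(unlist(cls))
  hist <- if (length(variant_ids))
    maf_bin_histogram(variant_ids, catalog) else
    stats::setNames(integer(10), names(maf_bin_histogram(character(), catalog)))
  structure(list(name = name,
                 variant_ids = variant_ids,
                 provenance = list(class_counts = class_counts,
                                   maf_histogram = hist,
                                   log = log)),
            class = "panel")
}

#' @method print panel
#' @export
print.panel <- function(x, ...) {
  cat("Panel '", x$name, "': ", length(x$variant_ids), " variants\n", sep = "")
  if (length(x$provenance$log))
    cat(paste0("  - ", x$provenance$log, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
length.panel <- function(x) length(x$variant_ids)

#' Exact Hardy-Weinberg equilibrium test (mid-p)
#'
#' Exact conditional test of HWE for a biallelic locus given the genotype
#' counts, using the distribution of heterozygote counts conditional on the
#' minor-allele count.  The two-sided p-value sums probabilities of
#' heterozygote counts no more likely than the observed one; the mid-p
#' variant counts half of the observed outcome's probability, which makes
#' the null distribution close to uniform.
#'
#' @param n_ref,n_het,n_alt genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @param midp use the mid-p convention (default TRUE).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_ref, n_het, n_alt, midp = TRUE) {
  n <- n_ref + n_het + n_alt
  if (n == 0) return(1)
  n_a <- 2 * n_alt + n_het          # alt allele count
  rare <- min(n_a, 2 * n - n_a)     # minor allele count
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # log probabilities of each heterozygote count given `rare`
  lp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, 1)
  p <- exp(lp - max(lp)); p <- p / sum(p)
  i <- match(n_het, hets)
  if (is.na(i)) stop("inconsistent genotype counts", call. = FALSE)
  pv <- sum(p[p <= p[i] + 1e-12])
  if (midp) pv <- pv - p[i] / 2
  min(max(pv, .Machine$double.xmin), 1)
}

#' Benchmark SNP-chip panel quality-control filter
#'
#' Applies, in order, the QC cascade used for commercial genomic-selection
#' chip panels: (1) remove variants with MAF < `maf_min`; (2) remove call
#' rates below `call_rate_min`; (3) greedy LD pruning that keeps the
#' earlier-position member of any pair with r^2 > `ld_r2_max` within
#' `window_bp`; (4) remove variants whose exact HWE test gives
#' `p < hwe_p_min`.
#'
#' @param genotypes dosage matrix (`NA` = missing call).
#' @param catalog variant catalog.
#' @param maf_min MAF floor (kept if `maf >= maf_min`); default 0.02.
#' @param call_rate_min minimum call rate; default 0.9.
#' @param ld_r2_max r^2 above which the later variant of a pair is pruned;
#'   default 0.9.
#' @param hwe_p_min HWE removal threshold (removed if `p < hwe_p_min`);
#'   default 0.15.
#' @param window_bp LD pruning scan window; default 1 Mb.
#' @param name panel name.
#' @return a [new_panel()] of surviving variants with a step-by-step log.
#' @export
benchmark_qc_filter <- function(genotypes, catalog, maf_min = 0.02,
                                call_rate_min = 0.9, ld_r2_max = 0.9,
                                hwe_p_min = 0.15, window_bp = 1e6,
                                name = "current") {
  stopifnot(identical(colnames(genotypes), catalog$variant_id))
  log <- sprintf("input: %d variants", nrow(catalog))
  maf <- column_maf(genotypes)
  keep <- !is.na(maf) & maf >= maf_min
  log <- c(log, sprintf("MAF >= %.3g: %d kept", maf_min, sum(keep)))
  cr <- 1 - colMeans(is.na(genotypes))
  keep <- keep & cr >= call_rate_min
  log <- c(log, sprintf("call rate >= %.3g: %d kept", call_rate_min, sum(keep)))
  # greedy LD pruning in position order, earlier variant wins
  ord <- order(catalog$chrom, catalog$pos)
  kept_idx <- integer()
  for (j in ord) {
    if (!keep[j]) next
    near <- kept_idx[catalog$chrom[kept_idx] == catalog$chrom[j] &
                       abs(catalog$pos[kept_idx] - catalog$pos[j]) <= window_bp]
    pruned <- FALSE
    for (i in near) {
      r2 <- dosage_r2(genotypes[, i], genotypes[, j])
      if (!is.na(r2) && r2 > ld_r2_max) { pruned <- TRUE; break }
    }
    if (!pruned) kept_idx <- c(kept_idx, j)
  }
  keep <- seq_len(nrow(catalog)) %in% kept_idx
  log <- c(log, sprintf("LD pruning r^2 <= %.3g: %d kept", ld_r2_max, sum(keep)))
  hwe_p <- vapply(which(keep), function(j) {
    d <- genotypes[, j]; d <- d[!is.na(d)]
    hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2))
  }, 1)
  keep[which(keep)[hwe_p < hwe_p_min]] <- FALSE
  log <- c(log, sprintf("HWE p >= %.3g: %d kept", hwe_p_min, sum(keep)))
  if (!any(keep)) stop("no variants survive benchmark QC", call. = FALSE)
  new_panel(name, catalog$variant_id[keep], catalog, log)
}

#' Assign variants to LD blocks
#'
#' Single-linkage clustering within each chromosome over variant pairs with
#' `r^2 >= r2_threshold` and positions within `window_bp` of each other
#' (`window_bp = NULL` disables the window, giving the brute-force
#' transitive closure over the full pairwise r^2 matrix).  r^2 is the
#' squared correlation of dosage columns over complete pairs.
#'
#' @param genotypes dosage matrix.
#' @param catalog variant catalog.
#' @param candidates variant ids to block (default: all catalog variants).
#' @param r2_threshold LD threshold; default 0.98.
#' @param window_bp maximum pair distance, or `NULL` for no limit.
#' @return list of class `ld_blocks`: `assignment` (named block id per
#'   variant) and `blocks` (list of member id vectors per block).
#' @export
assign_ld_blocks <- function(genotypes, catalog, candidates = catalog$variant_id,
                             r2_threshold = 0.98, window_bp = 1e6) {
  idx <- match(candidates, catalog$variant_id)
  if (anyNA(idx)) stop("candidates missing from catalog", call. = FALSE)
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  for (ch in unique(catalog$chrom[idx])) {
    members <- which(catalog$chrom[idx] == ch)
    if (length(members) < 2L) next
    members <- members[order(catalog$pos[idx[members]])]
    G <- genotypes[, catalog$variant_id[idx[members]], drop = FALSE]
    pos <- catalog$pos[idx[members]]
    for (a in seq_len(length(members) - 1L)) {
      for (b in (a + 1L):length(members)) {
        if (!is.null(window_bp) && pos[b] - pos[a] > window_bp) break
        r2 <- dosage_r2(G[, a], G[, b])
        if (!is.na(r2) && r2 >= r2_threshold) union2(members[a], members[b])
      }
    }
  }
  roots <- vapply(seq_along(idx), find, 1L)
  block_id <- sprintf("b%04d", match(roots, sort(unique(roots))))
  assignment <- stats::setNames(block_id, candidates)
  structure(list(assignment = assignment,
                 blocks = split(candidates, block_id)),
            class = "ld_blocks")
}

#' Choose one representative variant per LD block
#'
#' Representatives are prioritised by annotation tier: gene-expression QTL
#' classes (eeQTL, aseQTL, ieQTL, seQTL) first, then coding variants, then
#' GWAS tags, then everything else.  Within a tier, ties break by more
#' class labels, then lower position, then lexicographic id.
#'
#' @param blocks an `ld_blocks` object from [assign_ld_blocks()].
#' @param catalog variant catalog.
#' @return character vector of representative variant ids (one per block).
#' @export
select_block_representatives <- function(blocks, catalog) {
  tier_of <- function(cls) {
    if (any(cls %in% EXPRESSION_CLASSES)) return(1L)
    if ("coding" %in% cls) return(2L)
    if ("GWAS" %in% cls) return(3L)
    4L
  }
  vapply(blocks$blocks, function(ids) {
    idx <- match(ids, catalog$variant_id)
    cls <- split_classes(catalog$classes[idx])
    tier <- vapply(cls, tier_of, 1L)
    nlab <- lengths(cls)
    ord <- order(tier, -nlab, catalog$pos[idx], ids)
    ids[ord[1L]]
  }, "")
}

#' MAF-bin histogram
#'
#' Counts panel variants in half-open minor-allele-frequency bins
#' `[k*w, (k+1)*w)` of width `w` spanning `[0, 0.5]`; the top bin is closed
#' so MAF exactly 0.5 lands in it.
#'
#' @param panel a `panel` object or character vector of variant ids.
#' @param catalog variant catalog with `maf`.
#' @param bin_width bin width; default 0.05.
#' @return named integer vector of bin counts (sums to panel size).
#' @export
maf_bin_histogram <- function(panel, catalog, bin_width = 0.05) {
  ids <- if (inherits(panel, "panel")) panel$variant_ids else panel
  nb <- ceiling(0.5 / bin_width)
  lo <- (seq_len(nb) - 1) * bin_width
  labels <- sprintf("[%.2f,%.2f)", lo, lo + bin_width)
  labels[nb] <- sub("\\)$", "]", labels[nb])
  counts <- stats::setNames(integer(nb), labels)
  if (!length(ids)) return(counts)
  maf <- catalog$maf[match(ids, catalog$variant_id)]
  if (anyNA(maf) || any(maf < 0 | maf > 0.5))
    stop("MAF must be known and in [0, 0.5] for all panel variants",
         call. = FALSE)
  bin <- pmin(floor(maf / bin_width), nb - 1L) + 1L
  tab <- table(factor(bin, levels = seq_len(nb)))
  counts[] <- as.integer(tab)
  counts
}

#' Subsample candidates to match a reference MAF spectrum
#'
#' Within each MAF bin, samples candidates without replacement down to the
#' reference bin count, weighting each candidate by the number of distinct
#' functional classes it carries (variants supported by more discovery
#' streams are preferred).  Bins with fewer candidates than the reference
#' count keep everything and the shortfall is logged with a warning.
#'
#' @param candidates character vector of candidate variant ids.
#' @param reference_histogram bin counts from [maf_bin_histogram()] on the
#'   reference panel (same bin width).
#' @param catalog variant catalog.
#' @param seed integer seed.
#' @param bin_width bin width matching the reference histogram.
#' @param name panel name.
#' @return a [new_panel()] whose MAF histogram equals the reference wherever
#'   no shortfall occurred.
#' @export
match_maf_spectrum <- function(candidates, reference_histogram, catalog,
                               seed = 1, bin_width = 0.05,
                               name = "functional") {
  set.seed(derive_seed(seed, "maf_match"))
  nb <- length(reference_histogram)
  maf <- catalog$maf[match(candidates, catalog$variant_id)]
  if (anyNA(maf)) stop("candidate MAF missing from catalog", call. = FALSE)
  bin <- pmin(floor(maf / bin_width), nb - 1L) + 1L
  nlab <- lengths(split_classes(
    catalog$classes[match(candidates, catalog$variant_id)]))
  w <- pmax(nlab, 1L)
  out <- character()
  deficit <- integer(nb)
  log <- character()
  for (b in seq_len(nb)) {
    want <- reference_histogram[b]
    pool <- candidates[bin == b]
    if (want == 0) next
    if (length(pool) <= want) {
      out <- c(out, pool)
      deficit[b] <- want - length(pool)
    } else {
      out <- c(out, sample(pool, want, prob = w[bin == b]))
    }
  }
  if (sum(deficit) > 0) {
    warning("MAF-bin shortfall: ", sum(deficit), " variants short (bins: ",
            paste(which(deficit > 0), collapse = ", "), ")", call. = FALSE)
    log <- c(log, sprintf("shortfall of %d variants across %d bins",
                          sum(deficit), sum(deficit > 0)))
  }
  idx <- match(out, catalog$variant_id)
  out <- out[order(catalog$chrom[idx], catalog$pos[idx])]
  new_panel(name, out, catalog,
            c(sprintf("MAF-spectrum matched from %d candidates to %d",
                      length(candidates), length(out)), log))
}

#' Final biallelic + common-variant filter
#'
#' Keeps biallelic variants with MAF >= 0.1 (variants with minor allele
#' frequency below 0.1 are excluded, as are multi-allelic loci).
#'
#' @param panel a `panel` or character vector of variant ids.
#' @param catalog variant catalog with `n_alleles` and `maf`.
#' @param maf_min inclusive MAF floor; default 0.1.
#' @return a [new_panel()] of survivors.
#' @export
final_filter <- function(panel, catalog, maf_min = 0.1) {
  ids <- if (inherits(panel, "panel")) panel$variant_ids else panel
  nm <- if (inherits(panel, "panel")) panel$name else "panel"
  idx <- match(ids, catalog$variant_id)
  if (anyNA(idx)) stop("panel ids missing from catalog", call. = FALSE)
  keep <- catalog$n_alleles[idx] == 2L & catalog$maf[idx] >= maf_min
  new_panel(nm, ids[keep], catalog,
            sprintf("final filter (biallelic, MAF >= %.3g): %d of %d kept",
                    maf_min, sum(keep), length(ids)))
}

#' Random size-matched baseline panel
#'
#' Uniform sample without replacement from the current panel, used as the
#' comparison baseline for a functional panel of the same size.  Output
#' order is canonicalized to the current panel's order.
#'
#' @param current_panel a `panel`.
#' @param n sample size (`n <= length(current_panel)`).
#' @param seed integer seed.
#' @param name panel name.
#' @return a [new_panel()].
#' @export
sample_matched_random_panel <- function(current_panel, n, seed = 1,
                                        name = "random_baseline") {
  ids <- current_panel$variant_ids
  if (n > length(ids))
    stop("requested more variants than the current panel holds", call. = FALSE)
  set.seed(derive_seed(seed, "baseline"))
  take <- sort(sample.int(length(ids), n))
  # catalog-free construction: reuse provenance-less panel
  structure(list(name = name,
                 variant_ids = ids[take],
                 provenance = list(class_counts = table(character()),
                                   maf_histogram = NULL,
                                   log = sprintf(
                                     "uniform sample of %d from '%s' (seed %d)",
                                     n, current_panel$name, seed))),
            class = "panel")
}
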