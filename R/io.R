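#' Write genotypes to VCF
#'
#' Plain-text VCF 4.2 with one sample column per individual and GT-only
#' FORMAT; dosages 0/1/2 map to `0/0`, `0/1`, `1/1` and missing calls to
#' `./.`.
#'
#' @param genotypes dosage matrix (individuals in rows).
#' @param catalog variant catalog aligned to the columns.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, catalog, path) {
  stopifnot(identical(colnames(genotypes), catalog$variant_id))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=funcpanel",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"),
             con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(genotypes))) {
    d <- genotypes[, j]
    gt <- ifelse(is.na(d), "./.", gt_codes[d + 1L])
    writeLines(paste(c(catalog$chrom[j], catalog$pos[j],
                       catalog$variant_id[j], catalog$ref[j], catalog$alt[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Parses GT fields into an alt-allele dosage matrix (count of non-reference
#' alleles; `NA` for missing calls) and a variant-catalog skeleton.
#' Multi-allelic records are preserved with `n_alleles > 2` so the final
#' biallelic filter can reject them downstream.
#'
#' @param path VCF file (plain text or gzipped).
#' @return list with `genotypes` and `catalog` (columns `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `n_alleles`, `maf`, `classes`).
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[
    is.na(ids) | ids == "."]
  # count non-reference alleles in each call
  count_alt <- function(x) {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x) & !grepl("\\.", x)
    alleles <- strsplit(gsub("\\|", "/", x[ok]), "/", fixed = FALSE)
    out[ok] <- vapply(alleles, function(a) sum(a != "0"), 1)
    out
  }
  G <- t(apply(gt, 1, count_alt))
  if (ncol(gt) == 1L) G <- matrix(G, ncol = 1L)
  dimnames(G) <- list(ids, colnames(gt))
  G <- t(G)
  catalog <- data.frame(
    variant_id = ids,
    chrom = suppressWarnings(as.integer(fix[, "CHROM"])),
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    n_alleles = 1L + lengths(strsplit(fix[, "ALT"], ",", fixed = TRUE)),
    stringsAsFactors = FALSE)
  catalog$maf <- unname(column_maf(G))
  catalog$classes <- ""
  rownames(catalog) <- NULL
  list(genotypes = G, catalog = catalog)
}

#' Schema-checked TSV input
#'
#' Reads a tab-separated table with header, verifies required columns are
#' present and numeric columns parse cleanly (naming the offending row and
#' column otherwise), and warns about unexpected extra columns (which are
#' preserved).
#'
#' @param path input file.
#' @param required character vector of required column names.
#' @param numeric_cols columns that must be numeric.
#' @return `data.frame`.
#' @export
read_table_checked <- function(path, required = character(),
                               numeric_cols = character()) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(tab), union(required, numeric_cols))
  if (length(required) && length(extra))
    warning("unexpected column(s) preserved: ", paste(extra, collapse = ", "),
            call. = FALSE)
  for (cl in intersect(numeric_cols, names(tab))) {
    x <- tab[[cl]]
    if (!is.numeric(x)) {
      parsed <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(parsed) & !is.na(x) & x != "NA")
      if (length(bad))
        stop(sprintf("column '%s' is not numeric at row %d (value '%s')",
                     cl, bad[1], x[bad[1]]), call. = FALSE)
      tab[[cl]] <- parsed
    }
  }
  tab
}

#' Write a table as TSV
#'
#' Numeric columns are rendered with 12 significant digits so a write/read
#' round trip is lossless at that precision.
#'
#' @param tab `data.frame`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_table_tsv <- function(tab, path) {
  out <- tab
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]) && !is.integer(out[[cl]]))
      out[[cl]] <- sprintf("%.12g", out[[cl]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write/read a panel as one variant id per line with a JSON provenance
#' sidecar
#'
#' @param panel a `panel`.
#' @param path output text file; provenance goes to `<path>.json`.
#' @param catalog variant catalog (for reading).
#' @param name panel name (for reading).
#' @return `write_panel` the path; `read_panel` a `panel`.
#' @export
write_panel <- function(panel, path) {
  writeLines(panel$variant_ids, path)
  prov <- panel$provenance
  jsonlite::write_json(
    list(name = panel$name,
         n_variants = length(panel$variant_ids),
         class_counts = as.list(prov$class_counts),
         maf_histogram = as.list(prov$maf_histogram),
         log = prov$log),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path, catalog, name = basename(path)) {
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  new_panel(name, ids, catalog, log = sprintf("read from %s", path))
}

#' Write a run manifest
#'
#' Records the configuration snapshot, the seeds used, the package version
#' and md5 digests of the listed artifact files, so a pipeline run can be
#' reproduced and its outputs verified.
#'
#' @param path output JSON file.
#' @param config any list-like configuration snapshot.
#' @param seeds named list/vector of seeds used.
#' @param files character vector of artifact paths to digest.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config = list(), seeds = list(),
                           files = character()) {
  digests <- if (length(files)) as.list(tools::md5sum(files)) else list()
  manifest <- list(
    package = "funcpanel",
    version = as.character(utils::packageVersion("funcpanel")),
    config = config,
    seeds = as.list(seeds),
    file_digests = digests)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

#' Load a simulation configuration from YAML or JSON
#'
#' The document's keys mirror the [sim_config()] argument names; anything
#' omitted keeps its default.  Files ending in `.json` are parsed as JSON,
#' anything else as YAML.
#'
#' @param path configuration file.
#' @return a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (f in c("class_proportions", "causal_enrichment",
              "trait_heritabilities", "trait_means")) {
    if (!is.null(doc[[f]])) doc[[f]] <- unlist(doc[[f]])
  }
  do.call(sim_config, doc)
}

#' Write a BayesC-pi posterior summary to disk
#'
#' Per-marker posterior means and inclusion probabilities go to a TSV;
#' the scalar posterior means (intercept, pi, variances, saved-sample
#' count) go to a JSON sidecar `<path>.json`.
#'
#' @param fit a `bayescpi_fit`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_bayescpi_fit <- function(fit, path) {
  stopifnot(inherits(fit, "bayescpi_fit"))
  write_table_tsv(data.frame(variant_id = fit$variant_ids,
                             mean_effect = unname(fit$mean_alpha),
                             inclusion_prob = unname(fit$inclusion_prob),
                             train_allele_mean = unname(
                               fit$col_means[fit$variant_ids]),
                             stringsAsFactors = FALSE), path)
  jsonlite::write_json(list(mean_mu = fit$mean_mu, mean_pi = fit$mean_pi,
                            mean_sigma2_alpha = fit$mean_sigma2_alpha,
                            mean_sigma2_e = fit$mean_sigma2_e,
                            n_saved = fit$n_saved),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
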