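#' k-fold cross-validation plan
#'
#' Random permutation split of individual ids into k mutually exclusive,
#' exhaustive folds whose sizes differ by at most one.
#'
#' @param individual_ids character vector of unique ids.
#' @param k fold count (>= 2).
#' @param seed integer seed.
#' @return object of class `fold_plan`: `k`, `assignment` (named integer
#'   fold index per id), `seed`.
#' @export
make_folds <- function(individual_ids, k = 5, seed = 1) {
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids", call. = FALSE)
  n <- length(individual_ids)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("need at least k individuals", call. = FALSE)
  set.seed(derive_seed(seed, "folds"))
  perm <- sample(individual_ids)
  sizes <- rep(n %/% k, k) + as.integer(seq_len(k) <= n %% k)
  fold <- rep(seq_len(k), times = sizes)
  assignment <- stats::setNames(fold[match(individual_ids, perm)],
                                individual_ids)
  structure(list(k = as.integer(k), assignment = assignment,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Cross-validated genomic prediction accuracy for one panel
#'
#' Per fold, fits the BayesC-pi model on the out-of-fold individuals
#' (~80% for k = 5), predicts GEBVs for the held-out fold, and scores
#' accuracy as the Pearson correlation between GEBV and adjusted phenotype
#' within the fold.  Per-fold chain seeds are derived deterministically
#' from the config seed.
#'
#' @param panel a `panel` (or character vector of variant ids).
#' @param genotypes dosage matrix covering all phenotyped individuals.
#' @param phenotype named numeric vector of adjusted phenotypes.
#' @param config a [bayescpi_config()].
#' @param folds a [make_folds()] plan covering the phenotyped individuals.
#' @return list with `fold_accuracy` (length k), `mean_accuracy`, `panel`
#'   name.
#' @export
cross_validate <- function(panel, genotypes, phenotype, config, folds) {
  stopifnot(inherits(folds, "fold_plan"))
  ids <- names(phenotype)
  if (is.null(ids)) stop("phenotype must be a named vector", call. = FALSE)
  uncovered <- setdiff(ids, names(folds$assignment))
  if (length(uncovered))
    stop("fold plan does not cover all phenotyped individuals", call. = FALSE)
  panel_ids <- if (inherits(panel, "panel")) panel$variant_ids else panel
  acc <- numeric(folds$k)
  for (f in seq_len(folds$k)) {
    test_ids <- ids[folds$assignment[ids] == f]
    train_ids <- setdiff(ids, test_ids)
    if (length(test_ids) < 10)
      stop("fold ", f, " has fewer than 10 individuals", call. = FALSE)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("fold", f))
    fit <- run_bayescpi(genotypes[train_ids, panel_ids, drop = FALSE],
                        phenotype[train_ids], cfg)
    gebv <- predict_gebv(fit, genotypes[test_ids, , drop = FALSE])
    acc[f] <- stats::cor(gebv, phenotype[test_ids])
  }
  list(fold_accuracy = acc, mean_accuracy = mean(acc),
       panel = if (inherits(panel, "panel")) panel$name else "panel")
}

#' Relative improvement in prediction accuracy
#'
#' `100 * (functional - current) / current`, the percent change of a
#' functional panel's accuracy over its size-matched current-panel
#' baseline.  Negative values indicate a decrease.
#'
#' @param functional_accuracy,current_accuracy accuracies (correlations);
#'   the baseline must be nonzero.
#' @return percent improvement (vectorised).
#' @export
improvement <- function(functional_accuracy, current_accuracy) {
  if (any(current_accuracy == 0))
    stop("improvement undefined for zero baseline accuracy", call. = FALSE)
  100 * (functional_accuracy - current_accuracy) / current_accuracy
}

#' Functional-vs-matched-random panel benchmarking experiment
#'
#' For every functional panel and trait, runs [cross_validate()] on the
#' functional panel and on a size-matched random sample from the current
#' panel, using one shared fold plan and the same sampler config, so all
#' comparisons are paired.  Baseline draws use documented per-panel derived
#' seeds.
#'
#' @param functional_panels named list of `panel` objects.
#' @param current_panel the benchmark `panel`.
#' @param genotypes dosage matrix.
#' @param phenotypes `data.frame` with `individual_id` and one column per
#'   adjusted trait.
#' @param traits character vector of trait columns to evaluate.
#' @param config a [bayescpi_config()].
#' @param k fold count.
#' @param seed root seed for folds and baseline draws.
#' @param n_baseline_draws number of independent baseline samples to
#'   average (default 1, matching a single-draw design).
#' @return object of class `evaluation_report`: `results` (a `data.frame`
#'   with per-panel, per-trait mean accuracies, baseline accuracies and
#'   improvement percents), `fold_accuracy` (nested list), `folds`, `seed`.
#' @export
benchmark_experiment <- function(functional_panels, current_panel,
                                 genotypes, phenotypes, traits,
                                 config = bayescpi_config(), k = 5,
                                 seed = 1, n_baseline_draws = 1) {
  stopifnot(is.list(functional_panels), length(names(functional_panels)) ==
              length(functional_panels))
  ids <- phenotypes$individual_id
  folds <- make_folds(ids, k = k, seed = derive_seed(seed, "experiment_folds"))
  rows <- list()
  fold_acc <- list()
  for (pname in names(functional_panels)) {
    fp <- functional_panels[[pname]]
    n_f <- length(fp$variant_ids)
    if (n_f > length(current_panel$variant_ids)) {
      warning("functional panel '", pname, "' larger than current panel; ",
              "baseline is the whole current panel", call. = FALSE)
      n_f <- length(current_panel$variant_ids)
    }
    baselines <- lapply(seq_len(n_baseline_draws), function(d)
      sample_matched_random_panel(
        current_panel, n_f,
        seed = derive_seed(seed, paste0("baseline_", pname, "_", d)),
        name = paste0(pname, "_baseline", d)))
    for (tr in traits) {
      y <- stats::setNames(phenotypes[[tr]], ids)
      # chain seeds derive from panel content + trait, so two panels with
      # identical variant sets are scored identically (paired design)
      cfg_f <- config
      cfg_f$seed <- derive_seed(seed, paste(c("fit", tr, fp$variant_ids),
                                            collapse = ":"))
      cv_f <- cross_validate(fp, genotypes, y, cfg_f, folds)
      base_means <- vapply(seq_along(baselines), function(d) {
        cfg_b <- config
        cfg_b$seed <- derive_seed(seed, paste(c("fit", tr,
                                                baselines[[d]]$variant_ids),
                                              collapse = ":"))
        cv_b <- cross_validate(baselines[[d]], genotypes, y, cfg_b, folds)
        fold_acc[[paste(pname, tr, "baseline", d, sep = ".")]] <<-
          cv_b$fold_accuracy
        cv_b$mean_accuracy
      }, 1)
      fold_acc[[paste(pname, tr, "functional", sep = ".")]] <- cv_f$fold_accuracy
      rows[[paste(pname, tr, sep = ".")]] <- data.frame(
        panel = pname, trait = tr, n_variants = length(fp$variant_ids),
        accuracy = cv_f$mean_accuracy,
        baseline_accuracy = mean(base_means),
        improvement_pct = improvement(cv_f$mean_accuracy, mean(base_means)),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, fold_accuracy = fold_acc,
                 folds = folds, seed = seed,
                 config = config),
            class = "evaluation_report")
}

#' @method print evaluation_report
#' @export
print.evaluation_report <- function(x, ...) {
  cat("Panel benchmarking report (k =", x$folds$k, "folds)\n")
  print(x$results, digits = 3)
  invisible(x)
}

#' Serialise / restore an evaluation report
#'
#' JSON round trip of the report's results table, fold accuracies, fold
#' assignment and seeds.
#'
#' @param report an `evaluation_report`.
#' @param path output / input file path.
#' @return `read_report` returns an `evaluation_report` (without the
#'   sampler config, which is not needed to interpret the numbers).
#' @export
write_report <- function(report, path) {
  payload <- list(results = report$results,
                  fold_accuracy = report$fold_accuracy,
                  folds = list(k = report$folds$k,
                               assignment = as.list(report$folds$assignment),
                               seed = report$folds$seed),
                  seed = report$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  assignment <- unlist(payload$folds$assignment)
  folds <- structure(list(k = payload$folds$k,
                          assignment = assignment,
                          seed = payload$folds$seed),
                     class = "fold_plan")
  structure(list(results = payload$results,
                 fold_accuracy = payload$fold_accuracy,
                 folds = folds, seed = payload$seed),
            class = "evaluation_report")
}
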