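#' BayesC-pi sampler configuration
#'
#' The model treats each marker effect as zero with probability `pi` and
#' Normal with common variance `sigma2_alpha` otherwise; `pi` gets a uniform
#' prior (Beta-updated each iteration) unless fixed.  Variances carry scaled
#' inverse chi-square priors whose scales are chosen at run time so the
#' prior mode matches an assumed heritability split over the markers.
#'
#' The default schedule (10,000 iterations, 2,000 burn-in, thin 10) is a
#' desk-scale choice that mixes well at the problem sizes the package
#' simulates; `preset = "paper"` switches to the production-scale schedule
#' of 300,000 iterations with 50,000 burn-in and thinning interval 200.
#'
#' @param chain_length total Gibbs iterations.
#' @param burn_in discarded initial iterations (`burn_in < chain_length`).
#' @param thin save interval (>= 1); saved-sample count is
#'   `floor((chain_length - burn_in)/thin)`.
#' @param pi_prior `"uniform"` or a fixed numeric value in `[0, 1]`
#'   (`pi` = prior probability a marker has no effect; 0 means every marker
#'   is always in the model).
#' @param nu_alpha,nu_e degrees of freedom of the variance priors.
#' @param assumed_h2 heritability used to set prior scales.
#' @param fix_effect_var,fix_resid_var optional fixed values for
#'   `sigma2_alpha` / `sigma2_e` (no sampling); mainly for validation
#'   against the closed-form ridge limit.
#' @param seed integer seed for the chain.
#' @param preset `NULL` or `"paper"`.
#' @param save_traces keep per-saved-sample scalar traces.
#' @param debug_residual_check recompute the residual from scratch every
#'   1000 iterations and track the maximum deviation from the maintained
#'   vector.
#' @return object of class `bayescpi_config`.
#' @export
bayescpi_config <- function(chain_length = 10000, burn_in = 2000, thin = 10,
                            pi_prior = "uniform", nu_alpha = 4.2, nu_e = 4.2,
                            assumed_h2 = 0.3, fix_effect_var = NULL,
                            fix_resid_var = NULL, seed = 1, preset = NULL,
                            save_traces = FALSE,
                            debug_residual_check = FALSE) {
  if (!is.null(preset)) {
    if (preset == "paper") {
      chain_length <- 300000; burn_in <- 50000; thin <- 200
    } else stop("unknown preset: ", preset, call. = FALSE)
  }
  if (burn_in >= chain_length) stop("burn_in must be < chain_length", call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  if (is.numeric(pi_prior) && (pi_prior < 0 || pi_prior > 1))
    stop("fixed pi must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(pi_prior) && !identical(pi_prior, "uniform"))
    stop("pi_prior must be \"uniform\" or a numeric value", call. = FALSE)
  structure(list(chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 pi_prior = pi_prior, nu_alpha = nu_alpha, nu_e = nu_e,
                 assumed_h2 = assumed_h2,
                 fix_effect_var = fix_effect_var,
                 fix_resid_var = fix_resid_var,
                 seed = as.integer(seed), save_traces = save_traces,
                 debug_residual_check = debug_residual_check),
            class = "bayescpi_config")
}

#' Fit the BayesC-pi model by Gibbs sampling
#'
#' Each iteration samples, in order: the intercept from its Normal full
#' conditional; every marker's inclusion indicator from its Bernoulli full
#' conditional with the effect integrated out, then (if included) the
#' effect from its Normal full conditional; the common effect variance and
#' the residual variance from scaled inverse chi-square full conditionals;
#' and `pi` from `Beta(m - k + 1, k + 1)` where `k` is the number of
#' markers currently in the model.  Markers are visited in their given
#' (position) order and the residual vector is updated incrementally.
#'
#' Dosage columns are centred internally (the centring constant is absorbed
#' by the intercept); missing dosages are mean-imputed first.
#'
#' @param genotypes dosage matrix restricted to the panel's variants
#'   (training individuals in rows).
#' @param y named or plain numeric response (adjusted phenotypes), aligned
#'   with `rownames(genotypes)`.
#' @param config a [bayescpi_config()].
#' @return object of class `bayescpi_fit`: posterior means of the intercept,
#'   per-marker effects (`E[alpha * delta]`), inclusion probabilities, `pi`
#'   and the two variances, plus the saved-sample count, training allele
#'   means (for later imputation) and the config echo.
#' @export
run_bayescpi <- function(genotypes, y, config = bayescpi_config()) {
  stopifnot(inherits(config, "bayescpi_config"))
  if (!is.null(names(y)) && !is.null(rownames(genotypes))) {
    common <- intersect(rownames(genotypes), names(y))
    genotypes <- genotypes[common, , drop = FALSE]
    y <- y[common]
  }
  n <- nrow(genotypes); m <- ncol(genotypes)
  if (n < 50) stop("need at least 50 training individuals", call. = FALSE)
  if (stats::var(y) == 0) stop("phenotype has zero variance", call. = FALSE)
  col_means <- colMeans(genotypes, na.rm = TRUE)
  if (anyNA(genotypes)) {
    idx <- which(is.na(genotypes), arr.ind = TRUE)
    genotypes[idx] <- col_means[idx[, 2L]]
  }
  if (m == 0L) {
    warning("empty panel: GEBV reduces to the intercept", call. = FALSE)
    fit <- list(mean_mu = mean(y), mean_alpha = numeric(0),
                inclusion_prob = numeric(0), mean_pi = NA_real_,
                mean_sigma2_alpha = NA_real_, mean_sigma2_e = stats::var(y),
                n_saved = 0L, variant_ids = character(0),
                col_means = col_means, config = config)
    class(fit) <- "bayescpi_fit"
    return(fit)
  }
  Z <- sweep(genotypes, 2, col_means)
  vy <- stats::var(y)
  h2 <- config$assumed_h2
  pi_fixed <- is.numeric(config$pi_prior)
  pi_init <- if (pi_fixed) config$pi_prior else 0.5
  # prior scales: mode of scaled-inv-chisq(nu, S) is nu*S/(nu+2)
  scale_e <- vy * (1 - h2) * (config$nu_e + 2) / config$nu_e
  sum_var_z <- sum(apply(Z, 2, stats::var))
  expected_included <- max(1, (1 - pi_init) * m)
  s2a_target <- vy * h2 / max(sum_var_z * expected_included / m, 1e-8)
  scale_a <- s2a_target * (config$nu_alpha + 2) / config$nu_alpha
  s2a_init <- config$fix_effect_var %||% s2a_target
  s2e_init <- config$fix_resid_var %||% vy
  set.seed(config$seed)
  res <- .bayescpi_gibbs(Z, as.numeric(y),
                         config$chain_length, config$burn_in, config$thin,
                         pi_init, pi_fixed,
                         s2a_init, !is.null(config$fix_effect_var),
                         s2e_init, !is.null(config$fix_resid_var),
                         config$nu_alpha, scale_a, config$nu_e, scale_e,
                         config$save_traces, config$debug_residual_check)
  fit <- list(mean_mu = res$mean_mu,
              mean_alpha = stats::setNames(res$mean_alpha, colnames(genotypes)),
              inclusion_prob = stats::setNames(res$inclusion_prob,
                                               colnames(genotypes)),
              mean_pi = res$mean_pi,
              mean_sigma2_alpha = res$mean_sigma2_alpha,
              mean_sigma2_e = res$mean_sigma2_e,
              n_saved = res$n_saved,
              max_residual_deviation = res$max_residual_deviation,
              variant_ids = colnames(genotypes),
              col_means = col_means,
              config = config)
  if (config$save_traces) {
    colnames(res$traces) <- c("mu", "pi", "sigma2_alpha", "sigma2_e",
                              "n_included")
    fit$traces <- res$traces
  }
  class(fit) <- "bayescpi_fit"
  fit
}

#' @method print bayescpi_fit
#' @export
print.bayescpi_fit <- function(x, ...) {
  cat("BayesC-pi fit:", length(x$variant_ids), "markers,",
      x$n_saved, "saved samples\n")
  cat(sprintf("  posterior means: pi = %.3f, sigma2_alpha = %.4g, sigma2_e = %.4g\n",
              x$mean_pi, x$mean_sigma2_alpha, x$mean_sigma2_e))
  invisible(x)
}

#' Predict genomic estimated breeding values
#'
#' `GEBV_i = sum_j z_ij * E[alpha_j delta_j]` over the fitted panel;
#' missing dosages are imputed with the training allele means.  The
#' intercept is reported in the fit but excluded here, so GEBVs are on the
#' marker-effect scale (a constant shift, irrelevant for correlations and
#' ranking).
#'
#' @param fit a `bayescpi_fit`.
#' @param genotypes dosage matrix for the target individuals; must contain
#'   every panel variant as a column.
#' @return named numeric vector of GEBVs.
#' @export
predict_gebv <- function(fit, genotypes) {
  stopifnot(inherits(fit, "bayescpi_fit"))
  missing_ids <- setdiff(fit$variant_ids, colnames(genotypes))
  if (length(missing_ids))
    stop("target genotypes lack panel variants: ",
         paste(head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) " ...", call. = FALSE)
  if (!length(fit$variant_ids))
    return(stats::setNames(rep(0, nrow(genotypes)), rownames(genotypes)))
  Z <- genotypes[, fit$variant_ids, drop = FALSE]
  if (anyNA(Z)) {
    idx <- which(is.na(Z), arr.ind = TRUE)
    Z[idx] <- fit$col_means[fit$variant_ids][idx[, 2L]]
  }
  gebv <- as.vector(Z %*% fit$mean_alpha)
  stats::setNames(gebv, rownames(genotypes))
}
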