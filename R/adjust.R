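#' Legendre polynomial covariate basis
#'
#' Standard Legendre basis evaluated on values rescaled to `[-1, 1]`,
#' commonly used to model days-in-milk trajectories as fixed covariates.
#'
#' @param x numeric vector (e.g. days in milk).
#' @param degree highest polynomial degree (>= 0).
#' @param range length-2 vector mapped to `[-1, 1]`; defaults to
#'   `range(x)`.
#' @return matrix with `degree + 1` columns `L0 ... L<degree>`.
#' @export
legendre_basis <- function(x, degree = 3, range = base::range(x)) {
  stopifnot(degree >= 0, range[2] > range[1])
  t <- 2 * (x - range[1]) / (range[2] - range[1]) - 1
  out <- matrix(0, length(x), degree + 1)
  out[, 1] <- 1
  if (degree >= 1) out[, 2] <- t
  if (degree >= 2) {
    for (k in 2:degree) {
      # (k) P_k = (2k-1) t P_{k-1} - (k-1) P_{k-2}
      out[, k + 1] <- ((2 * k - 1) * t * out[, k] - (k - 1) * out[, k - 1]) / k
    }
  }
  colnames(out) <- paste0("L", 0:degree)
  out
}

#' Build a fixed-effects design matrix
#'
#' Expands categorical factors to treatment-coded indicator columns (first
#' level dropped), passes covariates through, and supports interaction
#' terms such as breed x age.  Column order is deterministic (the order of
#' terms in `spec`).  Factors left with a single level are dropped with a
#' warning.
#'
#' @param raw phenotype `data.frame` containing the named columns.
#' @param spec list with character elements `factors` and `covariates`, and
#'   optionally `interactions` (a list of character vectors of column names
#'   to cross).
#' @return numeric design matrix with an intercept column; attribute
#'   `dropped_factors` lists single-level factors that were removed.
#' @export
build_design <- function(raw, spec) {
  factors <- spec$factors %||% character()
  covariates <- spec$covariates %||% character()
  interactions <- spec$interactions %||% list()
  all_cols <- unique(c(factors, covariates, unlist(interactions)))
  missing_cols <- setdiff(all_cols, names(raw))
  if (length(missing_cols))
    stop("columns absent from phenotype table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dropped <- character()
  for (f in factors) {
    raw[[f]] <- droplevels(factor(raw[[f]]))
    if (nlevels(raw[[f]]) < 2L) {
      warning("factor '", f, "' has a single level and was dropped",
              call. = FALSE)
      dropped <- c(dropped, f)
    }
  }
  factors <- setdiff(factors, dropped)
  for (ia in interactions) {
    for (f in intersect(ia, spec$factors %||% character()))
      raw[[f]] <- droplevels(factor(raw[[f]]))
  }
  terms <- c(factors, covariates,
             vapply(interactions, paste, "", collapse = ":"))
  fml <- if (length(terms)) paste("~", paste(terms, collapse = " + "))
         else "~ 1"
  X <- stats::model.matrix(stats::as.formula(fml), data = raw)
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  attr(X, "dropped_factors") <- dropped
  X
}

#' Fit fixed effects and adjust phenotypes to yield deviations
#'
#' Fits `y = X beta + e` by least squares, one trait at a time, and returns
#' the residuals (`y - X beta_hat`) as adjusted phenotypes ("yield
#' deviations") for downstream genomic evaluation.  Under rank deficiency
#' the minimum-norm solution (Moore-Penrose pseudo-inverse) is used and the
#' aliased columns are reported in the fit.
#'
#' @param raw phenotype `data.frame` with an `individual_id` column and one
#'   column per trait.
#' @param design design matrix from [build_design()] with rows aligned to
#'   `raw`.
#' @param traits character vector of trait column names to adjust.
#' @return list with `fits` (per trait: `coefficients`, `sigma2`, `rank`,
#'   `aliased`, `n_used`) and `adjusted` (a `data.frame` of
#'   `individual_id` plus yield deviations per trait).
#' @export
fit_and_adjust <- function(raw, design, traits) {
  X <- as.matrix(design)
  n <- nrow(X); p <- ncol(X)
  if (nrow(raw) != n) stop("design and phenotype rows differ", call. = FALSE)
  if (n <= p) stop("need more rows than design columns (n > p)", call. = FALSE)
  missing_tr <- setdiff(traits, names(raw))
  if (length(missing_tr))
    stop("traits absent from table: ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  qrX <- qr(X)
  rank <- qrX$rank
  aliased <- if (rank < p) colnames(X)[qrX$pivot[(rank + 1L):p]] else character()
  if (length(aliased))
    message("rank-deficient design; aliased columns: ",
            paste(aliased, collapse = ", "))
  Xp <- MASS::ginv(X)   # minimum-norm least squares
  adjusted <- data.frame(individual_id = raw$individual_id,
                         stringsAsFactors = FALSE)
  fits <- list()
  for (tr in traits) {
    y <- raw[[tr]]
    beta <- as.vector(Xp %*% y)
    e <- y - as.vector(X %*% beta)
    fits[[tr]] <- list(coefficients = stats::setNames(beta, colnames(X)),
                       sigma2 = sum(e^2) / (n - rank),
                       rank = rank, aliased = aliased, n_used = n)
    adjusted[[tr]] <- e
  }
  list(fits = fits, adjusted = adjusted)
}
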