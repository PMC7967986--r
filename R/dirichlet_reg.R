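#' Dirichlet log-likelihood
#'
#' Sum over observations of the Dirichlet log-density
#' `log G(sum_k a_ik) - sum_k log G(a_ik) + sum_k (a_ik - 1) log y_ik`.
#'
#' @param composition O x K matrix of compositions strictly inside the
#'   simplex (rows sum to 1, all entries in (0,1)).
#' @param alpha_params O x K matrix of positive concentration
#'   parameters.
#' @return Scalar log-likelihood.
#' @export
dirichlet_loglik <- function(composition, alpha_params) {
  y <- as.matrix(composition); a <- as.matrix(alpha_params)
  stopifnot(identical(dim(y), dim(a)))
  if (any(y <= 0) || any(y >= 1))
    stop("composition on the simplex boundary; apply squeeze_composition()",
         call. = FALSE)
  if (any(a <= 0)) stop("alpha parameters must be positive", call. = FALSE)
  sum(lgamma(rowSums(a)) - rowSums(lgamma(a)) + rowSums((a - 1) * log(y)))
}

#' Squeeze a composition off the simplex boundary
#'
#' The standard transform `y' = (y*(n-1) + 1/K) / n` with `n` the number
#' of observations: rows still sum to 1, every entry strictly inside
#' (0,1), and interior rows move by at most 1/n.
#'
#' @param composition O x K matrix with rows summing to 1 and entries in
#'   `[0, 1]`.
#' @return The squeezed O x K matrix.
#' @export
squeeze_composition <- function(composition) {
  y <- as.matrix(composition)
  n <- nrow(y); K <- ncol(y)
  (y * (n - 1) + 1 / K) / n
}

#' Bonferroni threshold and p-value adjustment
#'
#' @param alpha family-wise error rate in (0, 1].
#' @param m_tests number of tests (>= 1).
#' @return `bonferroni_threshold`: the per-test threshold `alpha/m`.
#' @export
bonferroni_threshold <- function(alpha, m_tests) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  if (m_tests < 1) stop("m_tests must be >= 1", call. = FALSE)
  alpha / m_tests
}

#' @rdname bonferroni_threshold
#' @param p raw p-value(s) in `[0, 1]`.
#' @return `adjust_p_bonferroni`: `min(1, p * m)`.
#' @export
adjust_p_bonferroni <- function(p, m_tests) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]", call. = FALSE)
  if (m_tests < 1) stop("m_tests must be >= 1", call. = FALSE)
  pmin(1, p * m_tests)
}

# Negative log-likelihood and gradient for the common parametrization:
# log a_ik = x_i' gamma_k, one coefficient vector per component.
dirichlet_nll <- function(par, X, logy) {
  K <- ncol(logy); p <- ncol(X)
  G <- matrix(par, p, K)
  A <- exp(X %*% G)
  a0 <- rowSums(A)
  -(sum(lgamma(a0)) - sum(lgamma(A)) + sum((A - 1) * logy))
}

dirichlet_nll_grad <- function(par, X, logy) {
  K <- ncol(logy); p <- ncol(X)
  G <- matrix(par, p, K)
  A <- exp(X %*% G)
  a0 <- rowSums(A)
  W <- A * (digamma(a0) - digamma(A) + logy)
  -as.vector(crossprod(X, W))
}

#' Dirichlet regression of subgroup probabilities on covariates
#'
#' Maximum-likelihood Dirichlet regression in the common
#' parametrization: each of the K composition components gets its own
#' coefficient vector through a log link on its concentration parameter,
#' `log a_ik = x_i' gamma_k`, with no reference component. Optimized by
#' BFGS with analytic gradient from a moment-based start; Wald tests use
#' standard errors from the inverse observed information.
#'
#' Rows with missing values in any used variable are dropped and
#' counted. Continuous predictors are divided by their standard
#' deviation when `standardize = TRUE`, so coefficients are per-SD.
#' Compositions with entries at or below 1e-12 are squeezed off the
#' boundary with [squeeze_composition()] (with a message).
#'
#' @param outcome O x K composition matrix (e.g. LDA theta), rows
#'   named by sample id and summing to 1.
#' @param covariates a [covariate_table()].
#' @param exposure name of the exposure variable.
#' @param adjustments character vector of adjustment variable names.
#' @param standardize divide continuous predictors by their SD.
#' @param m_tests Bonferroni multiplier applied to the reported
#'   exposure p-values (default 1 = no adjustment).
#' @return Object of class `dirichlet_fit`: `coefficients` (long
#'   data.frame: subgroup, term, estimate, se, z, p, p_adj,
#'   is_exposure), `log_likelihood`, `converged`, `n`, `n_dropped`,
#'   `fitted` (expected compositions `a / sum(a)`).
#' @export
fit_dirichlet_regression <- function(outcome, covariates, exposure,
                                     adjustments = character(),
                                     standardize = TRUE, m_tests = 1L) {
  stopifnot(inherits(covariates, "covariate_table"))
  y <- as.matrix(outcome)
  if (is.null(rownames(y)))
    stop("outcome rows must be named by sample id", call. = FALSE)
  vars <- c(exposure, adjustments)
  missing_vars <- setdiff(vars, names(covariates$data))
  if (length(missing_vars))
    stop("variables absent from covariate table: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  if (max(abs(rowSums(y) - 1)) > 1e-6)
    stop("outcome rows must sum to 1", call. = FALSE)

  cd <- covariates$data
  common <- intersect(rownames(y), cd$sample_id)
  cd <- cd[match(common, cd$sample_id), c("sample_id", vars), drop = FALSE]
  y <- y[common, , drop = FALSE]
  ok <- stats::complete.cases(cd)
  n_dropped <- sum(!ok)
  cd <- cd[ok, , drop = FALSE]
  y <- y[ok, , drop = FALSE]
  n <- nrow(y)
  if (n < ncol(y) + length(vars) + 1L)
    stop("too few complete observations to fit", call. = FALSE)

  for (v in vars) {
    if (is.numeric(cd[[v]])) {
      s <- stats::sd(cd[[v]])
      if (!is.finite(s) || s == 0)
        stop("zero-variance predictor: ", v, call. = FALSE)
      if (standardize) cd[[v]] <- cd[[v]] / s
    } else if (nlevels(droplevels(cd[[v]])) < 2L) {
      stop("zero-variance predictor: ", v, call. = FALSE)
    }
  }

  if (any(y <= 1e-12)) {
    message("composition at the simplex boundary; applying squeeze transform")
    y <- squeeze_composition(y)
  }

  fml <- stats::reformulate(vars)
  X <- stats::model.matrix(fml, data = cd)
  K <- ncol(y); p <- ncol(X)
  subgroups <- colnames(y) %||% paste0("component_", seq_len(K))

  # moment-based start: intercepts from the mean composition and a
  # method-of-moments precision, slopes at zero
  m_bar <- colMeans(y)
  v_bar <- apply(y, 2, stats::var)
  s0 <- stats::median(m_bar * (1 - m_bar) / pmax(v_bar, 1e-12) - 1)
  s0 <- max(s0, 1)
  start <- matrix(0, p, K)
  start[1L, ] <- log(m_bar * s0)
  logy <- log(y)

  opt <- stats::optim(as.vector(start), fn = dirichlet_nll,
                      gr = dirichlet_nll_grad, X = X, logy = logy,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 1000L, reltol = 1e-12))
  converged <- opt$convergence == 0L
  if (!converged)
    warning("Dirichlet regression did not converge (code ",
            opt$convergence, "); coefficients reported anyway")

  G <- matrix(opt$par, p, K,
              dimnames = list(colnames(X), subgroups))
  se <- tryCatch({
    covm <- solve(opt$hessian)
    d <- diag(covm)
    if (any(d <= 0)) stop("non-positive variance")
    matrix(sqrt(d), p, K, dimnames = dimnames(G))
  }, error = function(e) {
    warning("observed information not invertible; standard errors are NA")
    matrix(NA_real_, p, K, dimnames = dimnames(G))
  })

  assign_idx <- attr(X, "assign")
  term_labels <- attr(stats::terms(fml), "term.labels")
  exposure_cols <- assign_idx %in% which(term_labels == exposure)

  z <- G / se
  pval <- 2 * stats::pnorm(-abs(z))
  coefs <- data.frame(
    subgroup = rep(subgroups, each = p),
    term = rep(colnames(X), times = K),
    estimate = as.vector(G), se = as.vector(se),
    z = as.vector(z), p = as.vector(pval),
    is_exposure = rep(exposure_cols, times = K),
    stringsAsFactors = FALSE)
  coefs$p_adj <- ifelse(is.na(coefs$p), NA_real_,
                        adjust_p_bonferroni(coefs$p, m_tests))

  A <- exp(X %*% G)
  fitted <- A / rowSums(A)
  rownames(fitted) <- cd$sample_id

  structure(list(coefficients = coefs,
                 log_likelihood = -opt$value,
                 start_log_likelihood = -dirichlet_nll(as.vector(start),
                                                       X, logy),
                 converged = converged, n = n, n_dropped = n_dropped,
                 exposure = exposure, fitted = fitted),
            class = "dirichlet_fit")
}

#' @export
print.dirichlet_fit <- function(x, ...) {
  cat(sprintf(
    "<dirichlet_fit> exposure=%s, n=%d (%d dropped), logLik=%.2f%s\n",
    x$exposure, x$n, x$n_dropped, x$log_likelihood,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Run the full exposure battery of Dirichlet regressions
#'
#' One Dirichlet regression per exposure, organized into families (e.g.
#' diet and disease) each with its own adjustment set and optional
#' exclusion rule. The Bonferroni multiplier is the total number of
#' exposures across all families unless overridden.
#'
#' @param outcome O x K composition matrix (LDA theta).
#' @param covariates a [covariate_table()].
#' @param families named list; each element is a list with `exposures`
#'   (character vector), `adjustments` (character vector), and
#'   optionally `exclude_if`, the name of a logical covariate column
#'   marking samples to drop for that family (e.g. non-fasted samples
#'   for serum-lipid models).
#' @param standardize per-SD scaling of continuous predictors.
#' @param m_tests override the Bonferroni multiplier.
#' @return data.frame in long format (family, exposure, subgroup, term,
#'   estimate, se, z, p, p_adj, n), exposure terms only; attribute
#'   `"m_tests"` records the multiplier and `"fits"` the underlying
#'   `dirichlet_fit` objects.
#' @export
run_association_battery <- function(outcome, covariates, families,
                                    standardize = TRUE, m_tests = NULL) {
  stopifnot(inherits(covariates, "covariate_table"))
  all_exposures <- unlist(lapply(families, `[[`, "exposures"),
                          use.names = FALSE)
  missing_vars <- setdiff(all_exposures, names(covariates$data))
  if (length(missing_vars))
    stop("exposures absent from covariate table: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  if (is.null(m_tests)) m_tests <- length(all_exposures)

  rows <- list(); fits <- list()
  for (fam in names(families)) {
    spec <- families[[fam]]
    cov_f <- covariates
    if (!is.null(spec$exclude_if)) {
      drop <- isTRUE_vec(cov_f$data[[spec$exclude_if]])
      # subset in place (no re-validation: declared reference levels
      # may be absent from the subset)
      cov_f$data <- cov_f$data[!drop, , drop = FALSE]
    }
    for (ex in spec$exposures) {
      fit <- fit_dirichlet_regression(outcome, cov_f, ex,
                                      spec$adjustments %||% character(),
                                      standardize = standardize,
                                      m_tests = m_tests)
      cf <- fit$coefficients[fit$coefficients$is_exposure, , drop = FALSE]
      cf$family <- fam; cf$exposure <- ex; cf$n <- fit$n
      rows[[paste(fam, ex)]] <- cf
      fits[[paste(fam, ex)]] <- fit
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[, c("family", "exposure", "subgroup", "term", "estimate",
                 "se", "z", "p", "p_adj", "n")]
  attr(out, "m_tests") <- m_tests
  attr(out, "fits") <- fits
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
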