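#' Jensen-Shannon divergence distance matrix
#'
#' Pairwise root-JSD between probability profiles (rows), the classic
#' enterotyping distance: `JSD(p,q) = KL(p||m)/2 + KL(q||m)/2` with
#' `m = (p+q)/2`, returned as `sqrt(JSD)` so it is a metric. A
#' pseudocount guards the log terms against zeros.
#'
#' @param profiles samples x features matrix of non-negative rows;
#'   rows are renormalized to sum to 1 after the pseudocount.
#' @param pseudocount added to every entry; default 1e-9.
#' @return A `dist` object of root-JSD distances.
#' @export
js_divergence_dist <- function(profiles, pseudocount = 1e-9) {
  p <- as.matrix(profiles) + pseudocount
  p <- p / rowSums(p)
  n <- nrow(p)
  # entropy-based form: JSD(p,q) = H(m) - (H(p)+H(q))/2
  H <- function(x) -rowSums(x * log(x))
  h <- H(p)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    m <- (p[rep(i, n - i), , drop = FALSE] +
            p[(i + 1L):n, , drop = FALSE]) / 2
    jsd <- H(m) - (h[i] + h[(i + 1L):n]) / 2
    d[i, (i + 1L):n] <- d[(i + 1L):n, i] <- sqrt(pmax(jsd, 0))
  }
  rownames(d) <- colnames(d) <- rownames(p)
  stats::as.dist(d)
}

#' Enterotype-style clustering of samples
#'
#' Collapses a normalized OTU table to genus level, computes pairwise
#' root Jensen-Shannon divergences, and partitions the samples around
#' k medoids. Clusters are labelled C1..Ck in order of decreasing size
#' and annotated with their dominant genus (highest mean abundance
#' within the cluster).
#'
#' @param table normalized `otu_counts` object.
#' @param tax taxonomy map from [read_taxonomy()].
#' @param k number of clusters (>= 2; classically 3).
#' @param pseudocount passed to [js_divergence_dist()].
#' @return Object of class `enterotype_assignment`: `cluster` (named
#'   factor per sample), `dominant_genus` (named character per
#'   cluster), `sizes`, `silhouette` (mean width, NA when k = n),
#'   `medoids`.
#' @export
assign_enterotypes <- function(table, tax, k = 3L, pseudocount = 1e-9) {
  stopifnot(inherits(table, "otu_counts"))
  if (!table$normalized)
    stop("assign_enterotypes expects a normalized table", call. = FALSE)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  n <- nrow(table$values)
  if (n < k) stop("fewer samples than clusters", call. = FALSE)
  g <- collapse_to_genus(table, tax)

  if (k == n) {  # degenerate: every sample its own cluster
    idx <- seq_len(n)
    sil <- NA_real_
    medoids <- rownames(g)
  } else {
    d <- js_divergence_dist(g, pseudocount)
    pm <- cluster::pam(d, k = k, diss = TRUE)
    idx <- pm$clustering
    sil <- if (!is.null(pm$silinfo)) pm$silinfo$avg.width else NA_real_
    medoids <- pm$medoids
  }

  ord <- order(-tabulate(idx, nbins = k), seq_len(k))
  relabel <- match(seq_len(k), ord)
  lab <- factor(paste0("C", relabel[idx]),
                levels = paste0("C", seq_len(k)))
  names(lab) <- rownames(g)
  dominant <- vapply(levels(lab), function(cl) {
    colnames(g)[which.max(colMeans(g[lab == cl, , drop = FALSE]))]
  }, character(1))
  structure(list(cluster = lab, dominant_genus = dominant,
                 sizes = table(lab), silhouette = sil,
                 medoids = medoids),
            class = "enterotype_assignment")
}

#' @export
print.enterotype_assignment <- function(x, ...) {
  cat("<enterotype_assignment>\n")
  for (cl in levels(x$cluster))
    cat(sprintf("  %s: n=%d, dominant genus %s\n", cl, x$sizes[[cl]],
                x$dominant_genus[[cl]]))
  if (is.finite(x$silhouette))
    cat(sprintf("  mean silhouette width: %.3f\n", x$silhouette))
  invisible(x)
}

#' Multinomial logistic regression of cluster membership
#'
#' Maximum-likelihood multinomial logit of enterotype membership on an
#' exposure with adjustment covariates; continuous predictors are
#' divided by their SD when `standardize = TRUE` so odds ratios are
#' per-SD. Reports `exp(coef)` with Wald 95% confidence intervals and
#' p-values for every non-reference cluster. With two clusters this is
#' exactly binary logistic regression.
#'
#' @param labels an `enterotype_assignment` or a named factor of
#'   cluster labels (names = sample ids).
#' @param covariates a [covariate_table()].
#' @param exposure exposure variable name.
#' @param adjustments adjustment variable names.
#' @param reference_cluster cluster used as the outcome baseline.
#' @param standardize per-SD scaling of continuous predictors.
#' @param m_tests Bonferroni multiplier for the reported p-values.
#' @return Object of class `multinom_fit`: `coefficients` (long
#'   data.frame: cluster, term, estimate, se, z, p, p_adj, OR, OR_lo,
#'   OR_hi, is_exposure), `n`, `n_dropped`, `converged`, `separation`.
#' @export
fit_multinomial_logit <- function(labels, covariates, exposure,
                                  adjustments = character(),
                                  reference_cluster = NULL,
                                  standardize = TRUE, m_tests = 1L) {
  if (inherits(labels, "enterotype_assignment")) labels <- labels$cluster
  stopifnot(is.factor(labels), !is.null(names(labels)))
  stopifnot(inherits(covariates, "covariate_table"))
  if (is.null(reference_cluster)) reference_cluster <- levels(labels)[1L]
  if (!reference_cluster %in% levels(labels))
    stop("reference cluster not among observed labels", call. = FALSE)
  labels <- stats::relevel(labels, ref = reference_cluster)

  vars <- c(exposure, adjustments)
  missing_vars <- setdiff(vars, names(covariates$data))
  if (length(missing_vars))
    stop("variables absent from covariate table: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  cd <- covariates$data
  common <- intersect(names(labels), cd$sample_id)
  cd <- cd[match(common, cd$sample_id), c("sample_id", vars),
           drop = FALSE]
  y <- labels[common]
  ok <- stats::complete.cases(cd)
  n_dropped <- sum(!ok)
  cd <- cd[ok, , drop = FALSE]; y <- y[ok]

  for (v in vars) {
    if (is.numeric(cd[[v]])) {
      s <- stats::sd(cd[[v]])
      if (!is.finite(s) || s == 0)
        stop("zero-variance predictor: ", v, call. = FALSE)
      if (standardize) cd[[v]] <- cd[[v]] / s
    }
  }
  cd$.outcome <- y
  fml <- stats::reformulate(vars, response = ".outcome")
  fit <- nnet::multinom(fml, data = cd, trace = FALSE, maxit = 1000L,
                        reltol = 1e-14, Hess = TRUE)
  sm <- summary(fit)
  co <- sm$coefficients; se <- sm$standard.errors
  if (is.null(dim(co))) {  # two outcome levels: vectors
    nm <- names(co)
    co <- matrix(co, 1L, dimnames = list(levels(y)[2L], nm))
    se <- matrix(se, 1L, dimnames = list(levels(y)[2L], nm))
  }
  separation <- any(abs(co) > 15)
  if (separation)
    warning("possible separation: very large multinomial coefficients")

  X <- stats::model.matrix(fml, data = cd)
  assign_idx <- attr(X, "assign")
  term_labels <- attr(stats::terms(fml), "term.labels")
  exposure_cols <- colnames(X)[assign_idx %in%
                                 which(term_labels == exposure)]

  z <- co / se
  pv <- 2 * stats::pnorm(-abs(z))
  long <- data.frame(
    cluster = rep(rownames(co), times = ncol(co)),
    term = rep(colnames(co), each = nrow(co)),
    estimate = as.vector(co), se = as.vector(se),
    z = as.vector(z), p = as.vector(pv), stringsAsFactors = FALSE)
  long$p_adj <- adjust_p_bonferroni(long$p, m_tests)
  long$OR <- exp(long$estimate)
  long$OR_lo <- exp(long$estimate - stats::qnorm(0.975) * long$se)
  long$OR_hi <- exp(long$estimate + stats::qnorm(0.975) * long$se)
  long$is_exposure <- long$term %in% exposure_cols

  structure(list(coefficients = long, n = nrow(cd),
                 n_dropped = n_dropped,
                 converged = fit$convergence == 0L,
                 separation = separation,
                 reference_cluster = reference_cluster,
                 fitted = stats::fitted(fit)),
            class = "multinom_fit")
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat(sprintf("<multinom_fit> reference=%s, n=%d (%d dropped)%s\n",
              x$reference_cluster, x$n, x$n_dropped,
              if (x$separation) " [SEPARATION]" else ""))
  invisible(x)
}
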