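#' Hyperparameters for collapsed-Gibbs LDA
#'
#' Symmetric Dirichlet priors: `alpha` on the per-sample subgroup
#' proportions, `beta` on the per-subgroup OTU distributions. Defaults
#' follow the common Gibbs-LDA practice of `alpha = 50/K` and
#' `beta = 0.1`, with 2000 sweeps, 1000 burn-in, and every 10th
#' post-burn-in sweep retained for the posterior mean.
#'
#' @param K number of subgroups (integer >= 1).
#' @param alpha,beta positive Dirichlet concentrations.
#' @param n_sweeps,n_burnin total and discarded Gibbs sweeps
#'   (`n_burnin < n_sweeps`).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer RNG seed; the sampler is bit-reproducible given
#'   the seed.
#' @return A list of class `lda_hyperparams`.
#' @export
lda_hyperparams <- function(K, alpha = 50 / K, beta = 0.1,
                            n_sweeps = 2000L, n_burnin = 1000L,
                            thin = 10L, seed = 1L) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be an integer >= 1", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  n_sweeps <- as.integer(n_sweeps); n_burnin <- as.integer(n_burnin)
  if (n_burnin >= n_sweeps)
    stop("n_burnin must be smaller than n_sweeps", call. = FALSE)
  structure(list(K = K, alpha = alpha, beta = beta, n_sweeps = n_sweeps,
                 n_burnin = n_burnin, thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "lda_hyperparams")
}

check_integer_counts <- function(counts) {
  stopifnot(inherits(counts, "otu_counts"))
  v <- counts$values
  if (any(abs(v - round(v)) > 1e-9))
    stop("LDA requires integer counts; use rescale_to_counts()",
         call. = FALSE)
  tot <- rowSums(v)
  bad <- which(tot < 1)
  if (length(bad))
    stop("zero-read sample(s): ",
         paste(rownames(v)[bad], collapse = ", "), call. = FALSE)
  storage.mode(v) <- "integer"
  v
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Token-level resampling from the collapsed conditional proportional to
#' `(n_dk + alpha) * (m_kv + beta) / (m_k + V*beta)`. After burn-in,
#' `theta` and `phi` are posterior means of the smoothed count ratios
#' over the retained sweeps, so all probabilities are strictly positive
#' and rows sum to one.
#'
#' @param counts an integer `otu_counts` object (every sample with at
#'   least one read).
#' @param hp an [lda_hyperparams()] object.
#' @return An object of class `lda_model`: `theta` (samples x K), `phi`
#'   (K x V), `hyperparams`, `assignments` (final per-read subgroup
#'   labels), `log_likelihood` (training).
#' @export
fit_lda_gibbs <- function(counts, hp) {
  stopifnot(inherits(hp, "lda_hyperparams"))
  v <- check_integer_counts(counts)
  if (hp$K > ncol(v))
    warning("K exceeds the number of distinct OTUs (", ncol(v), ")")
  res <- .gibbs_lda_cpp(v, hp$K, hp$alpha, hp$beta, hp$n_sweeps,
                        hp$n_burnin, hp$thin, hp$seed)
  theta <- res$theta
  dimnames(theta) <- list(rownames(v), paste0("subgroup_", seq_len(hp$K)))
  phi <- res$phi
  dimnames(phi) <- list(paste0("subgroup_", seq_len(hp$K)), colnames(v))
  model <- structure(list(theta = theta, phi = phi, hyperparams = hp,
                          assignments = res$assignments,
                          n_kept = res$n_kept),
                     class = "lda_model")
  model$log_likelihood <- log_likelihood(model, counts)
  model
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> K=%d, %d samples, %d OTUs, logLik=%.2f\n",
              x$hyperparams$K, nrow(x$theta), ncol(x$phi),
              x$log_likelihood))
  invisible(x)
}

#' Fold in held-out samples
#'
#' Re-estimates per-sample subgroup proportions for new samples by Gibbs
#' sampling their token assignments with the subgroup-OTU distributions
#' `phi` held fixed.
#'
#' @param model a fitted `lda_model`.
#' @param counts integer `otu_counts` sharing the model's OTU axis.
#' @param n_sweeps,n_burnin,thin fold-in sweep schedule (shorter than a
#'   full fit since only theta is sampled).
#' @param seed RNG seed.
#' @return Theta matrix (new samples x K).
#' @export
fold_in_theta <- function(model, counts, n_sweeps = 200L, n_burnin = 100L,
                          thin = 2L, seed = model$hyperparams$seed) {
  v <- check_integer_counts(counts)
  if (!identical(colnames(v), colnames(model$phi)))
    stop("OTU axes of model and counts do not match", call. = FALSE)
  th <- .gibbs_fold_in_cpp(v, model$phi, model$hyperparams$alpha,
                           as.integer(n_sweeps), as.integer(n_burnin),
                           as.integer(thin), as.integer(seed))
  dimnames(th) <- list(rownames(v), rownames(model$phi))
  th
}

#' Corpus log-likelihood under a fitted model
#'
#' Computes `sum_i sum_v counts[i,v] * log(sum_k theta[i,k]*phi[k,v])`.
#' For samples not present in the model's theta (held-out data), theta
#' is first re-estimated by fold-in.
#'
#' @param model a fitted `lda_model`.
#' @param counts integer `otu_counts` on the model's OTU axis.
#' @param theta optional samples x K matrix overriding the model/fold-in
#'   theta (rows aligned with `counts`).
#' @param ... passed to [fold_in_theta()] when folding in.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(model, counts, theta = NULL, ...) {
  v <- check_integer_counts(counts)
  if (!identical(colnames(v), colnames(model$phi)))
    stop("OTU axes of model and counts do not match", call. = FALSE)
  if (is.null(theta)) {
    if (all(rownames(v) %in% rownames(model$theta)))
      theta <- model$theta[rownames(v), , drop = FALSE]
    else
      theta <- fold_in_theta(model, counts, ...)
  }
  mix <- theta %*% model$phi
  sum(v * log(mix))
}

#' Perplexity
#'
#' `exp(-log_likelihood / total_reads)`; lower is better. Equals the
#' vocabulary size exactly when every OTU is equally likely.
#'
#' @inheritParams log_likelihood
#' @return Positive scalar.
#' @export
perplexity <- function(model, counts, theta = NULL, ...) {
  v <- check_integer_counts(counts)
  n_reads <- sum(v)
  if (n_reads == 0) stop("zero total reads", call. = FALSE)
  exp(-log_likelihood(model, counts, theta = theta, ...) / n_reads)
}

#' Cross-validated selection curve for the subgroup number K
#'
#' Partitions samples into `folds` seeded folds; for each candidate K,
#' fits on the training folds and scores the held-out fold by fold-in
#' perplexity. Returns the per-K mean curve rather than auto-selecting a
#' K: the curve typically improves monotonically without a clear
#' optimum, and the choice is made by inspecting jumps. An optional
#' largest-relative-improvement heuristic is provided.
#'
#' @param counts integer `otu_counts`.
#' @param k_grid integer vector of candidate K values.
#' @param folds number of folds (>= 2, <= number of samples).
#' @param hp_template [lda_hyperparams()] whose alpha rule, beta and
#'   sweep schedule are reused at each K (alpha is re-derived as 50/K
#'   when the template used the default rule).
#' @param seed seed controlling the fold partition and per-fit seeds.
#' @param suggest if `TRUE`, attach the K after the largest relative
#'   perplexity improvement as attribute `"suggested_k"`.
#' @return data.frame with columns `K`, `mean_perplexity`,
#'   `mean_log_likelihood`, plus attribute `"per_fold"` (long
#'   data.frame).
#' @export
select_k_cv <- function(counts, k_grid, folds = 5L,
                        hp_template = lda_hyperparams(K = max(k_grid)),
                        seed = hp_template$seed, suggest = FALSE) {
  v <- check_integer_counts(counts)
  n <- nrow(v)
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (folds > n) stop("more folds than samples", call. = FALSE)
  if (any(k_grid < 1L)) stop("every K must be >= 1", call. = FALSE)
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), n))
  default_alpha <- isTRUE(all.equal(hp_template$alpha,
                                    50 / hp_template$K))
  rows <- list()
  for (K in sort(as.integer(k_grid))) {
    for (f in seq_len(folds)) {
      train <- otu_count_table(v[fold_of != f, , drop = FALSE],
                               normalized = FALSE)
      test <- otu_count_table(v[fold_of == f, , drop = FALSE],
                              normalized = FALSE)
      hp <- lda_hyperparams(
        K = K,
        alpha = if (default_alpha) 50 / K else hp_template$alpha,
        beta = hp_template$beta, n_sweeps = hp_template$n_sweeps,
        n_burnin = hp_template$n_burnin, thin = hp_template$thin,
        seed = (seed + 131L * K + f) %% .Machine$integer.max)
      fit <- fit_lda_gibbs(train, hp)
      th <- fold_in_theta(fit, test, seed = hp$seed + 1L)
      ll <- log_likelihood(fit, test, theta = th)
      rows[[length(rows) + 1L]] <- data.frame(
        K = K, fold = f, log_likelihood = ll,
        perplexity = exp(-ll / sum(test$values)))
    }
  }
  per_fold <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(perplexity, log_likelihood) ~ K,
                          data = per_fold, FUN = mean)
  out <- data.frame(K = agg$K, mean_perplexity = agg$perplexity,
                    mean_log_likelihood = agg$log_likelihood)
  attr(out, "per_fold") <- per_fold
  if (suggest && nrow(out) > 1L) {
    rel <- -diff(out$mean_perplexity) / out$mean_perplexity[-nrow(out)]
    attr(out, "suggested_k") <- out$K[which.max(rel) + 1L]
  }
  out
}

#' Best-of-m refit
#'
#' Fits `m` models with distinct derived seeds and returns the one with
#' the highest training log-likelihood; all m scores are attached as
#' attribute `"scores"`.
#'
#' @param counts integer `otu_counts`.
#' @param hp [lda_hyperparams()]; run `i` uses seed
#'   `hp$seed + 7919 * (i - 1)`.
#' @param m number of restarts (>= 1).
#' @return The winning `lda_model`.
#' @export
refit_best_of_m <- function(counts, hp, m = 5L) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  fits <- vector("list", m)
  scores <- numeric(m)
  for (i in seq_len(m)) {
    hpi <- hp
    hpi$seed <- as.integer((hp$seed + 7919L * (i - 1L)) %%
                             .Machine$integer.max)
    fits[[i]] <- fit_lda_gibbs(counts, hpi)
    scores[i] <- fits[[i]]$log_likelihood
  }
  best <- fits[[which.max(scores)]]
  attr(best, "scores") <- scores
  best
}

#' Serialize / load a fitted model as TSV matrices plus a JSON sidecar
#'
#' @param model an `lda_model`.
#' @param dir output directory (created if needed); writes `theta.tsv`,
#'   `phi.tsv`, `model.json`.
#' @export
write_lda_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(model$theta, file.path(dir, "theta.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(model$phi, file.path(dir, "phi.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  jsonlite::write_json(unclass(model$hyperparams),
                       file.path(dir, "model.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_lda_model
#' @param dir directory written by [write_lda_model()].
#' @export
read_lda_model <- function(dir) {
  theta <- as.matrix(utils::read.delim(file.path(dir, "theta.tsv"),
                                       row.names = 1, check.names = FALSE))
  phi <- as.matrix(utils::read.delim(file.path(dir, "phi.tsv"),
                                     row.names = 1, check.names = FALSE))
  hp <- jsonlite::read_json(file.path(dir, "model.json"),
                            simplifyVector = TRUE)
  hp <- lda_hyperparams(hp$K, hp$alpha, hp$beta, hp$n_sweeps, hp$n_burnin,
                        hp$thin, hp$seed)
  structure(list(theta = theta, phi = phi, hyperparams = hp,
                 assignments = NULL, n_kept = NA_integer_,
                 log_likelihood = NA_real_),
            class = "lda_model")
}
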