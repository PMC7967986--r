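#' Generate an OTU table from the LDA generative model
#'
#' Draws per-sample subgroup proportions `theta_i ~ Dir(alpha)` (or
#' takes them as given), then for each read samples a subgroup from
#' `theta_i` and an OTU from that subgroup's distribution — exactly the
#' generative process the sampler inverts. The planted subgroup-OTU
#' distributions are block-structured: each subgroup owns a vocabulary
#' block, and `separation` interpolates between fully disjoint
#' vocabularies (1) and a shared background (0).
#'
#' @param n_samples,n_otus,K corpus dimensions (all >= 1).
#' @param alpha symmetric Dirichlet concentration for theta; default 1.
#' @param reads_per_sample reads drawn per sample (library size).
#' @param seed RNG seed; the fixture regenerates bit-identically.
#' @param separation in `[0, 1]`: 1 = disjoint subgroup vocabularies.
#' @param theta optional n_samples x K matrix of proportions to use
#'   instead of Dirichlet draws (e.g. covariate-linked thetas).
#' @param phi optional K x n_otus matrix of planted subgroup-OTU
#'   distributions, overriding the block construction.
#' @return List with `counts` (integer `otu_counts`) and `truth` (list:
#'   `phi`, `theta`, and all generator parameters).
#' @export
generate_lda_corpus <- function(n_samples = 300L, n_otus = 120L, K = 5L,
                                alpha = 1, reads_per_sample = 1000L,
                                seed = 1L, separation = 1,
                                theta = NULL, phi = NULL) {
  stopifnot(n_samples >= 1L, n_otus >= 1L, K >= 1L,
            reads_per_sample >= 1L)
  if (separation < 0 || separation > 1)
    stop("separation must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  otu_names <- sprintf("OTU_%04d", seq_len(n_otus))
  sample_names <- sprintf("S%04d", seq_len(n_samples))

  if (is.null(phi)) {
    block <- sort(rep_len(seq_len(K), n_otus))
    phi <- matrix(0, K, n_otus)
    background <- rgamma(n_otus, 1)
    background <- background / sum(background)
    for (k in seq_len(K)) {
      own <- which(block == k)
      base <- rgamma(length(own), 1)
      base <- base / sum(base)
      row <- (1 - separation) * background
      row[own] <- row[own] + separation * base
      phi[k, ] <- row / sum(row)
    }
  } else {
    phi <- as.matrix(phi)
    stopifnot(nrow(phi) == K, ncol(phi) == n_otus)
  }
  dimnames(phi) <- list(paste0("subgroup_", seq_len(K)), otu_names)

  if (is.null(theta)) {
    theta <- matrix(rgamma(n_samples * K, alpha), n_samples, K)
    theta <- theta / rowSums(theta)
  } else {
    theta <- as.matrix(theta)
    stopifnot(nrow(theta) == n_samples, ncol(theta) == K)
  }
  dimnames(theta) <- list(sample_names, rownames(phi))

  counts <- matrix(0L, n_samples, n_otus,
                   dimnames = list(sample_names, otu_names))
  for (i in seq_len(n_samples)) {
    nz <- as.vector(stats::rmultinom(1, reads_per_sample, theta[i, ]))
    for (k in which(nz > 0))
      counts[i, ] <- counts[i, ] +
        as.vector(stats::rmultinom(1, nz[k], phi[k, ]))
  }
  list(counts = otu_count_table(counts + 0, normalized = FALSE),
       truth = list(phi = phi, theta = theta, alpha = alpha, K = K,
                    n_samples = n_samples, n_otus = n_otus,
                    reads_per_sample = reads_per_sample,
                    separation = separation, seed = seed))
}

#' Generate covariates and covariate-linked subgroup proportions
#'
#' Draws a covariate design (continuous variables optionally
#' correlated; categorical variables with stated frequencies), then
#' plants the Dirichlet-regression model: concentration
#' `a_ik = precision * base_k * exp(x_i' gamma_k)` and
#' `theta_i ~ Dir(a_i)`. Emitting the thetas directly tests the
#' regression in isolation; feeding them to [generate_lda_corpus()]
#' gives the end-to-end pipeline fixture.
#'
#' @param n_samples number of samples.
#' @param K number of subgroups.
#' @param covariate_specs named list; each element is either
#'   `list(kind = "continuous", mean =, sd =)` or
#'   `list(kind = "categorical", levels =, probs =, reference =)`.
#' @param gamma coefficient matrix (model-matrix columns of the
#'   continuous variables and non-reference categorical levels) x K;
#'   row names must name covariates (continuous) or
#'   `"<var><level>"` (categorical dummies). Missing rows are zero.
#'   Continuous-covariate coefficients are per-SD effects: the linear
#'   predictor uses `(x - mean)/sd` with the declared moments.
#' @param precision overall Dirichlet precision (positive); default 30.
#' @param base_alpha baseline composition (length K, sums to 1);
#'   default uniform.
#' @param correlation optional correlation matrix for the continuous
#'   covariates (in spec order).
#' @param seed RNG seed.
#' @return List with `covariates` (a [covariate_table()]), `theta`
#'   (n_samples x K), and `truth` (gamma, precision, base_alpha,
#'   specs, seed).
#' @export
generate_covariate_linked_thetas <- function(n_samples = 300L, K = 5L,
                                             covariate_specs,
                                             gamma = NULL,
                                             precision = 30,
                                             base_alpha = rep(1 / K, K),
                                             correlation = NULL,
                                             seed = 1L) {
  if (!is.finite(precision) || precision <= 0)
    stop("precision must be positive", call. = FALSE)
  stopifnot(length(base_alpha) == K, abs(sum(base_alpha) - 1) < 1e-8)
  set.seed(seed)
  sample_names <- sprintf("S%04d", seq_len(n_samples))

  cont <- names(covariate_specs)[vapply(covariate_specs, function(s)
    s$kind == "continuous", logical(1))]
  df <- data.frame(sample_id = sample_names, stringsAsFactors = FALSE)
  if (length(cont)) {
    Zc <- matrix(stats::rnorm(n_samples * length(cont)), n_samples)
    if (!is.null(correlation)) {
      stopifnot(nrow(correlation) == length(cont))
      Zc <- Zc %*% chol(correlation)
    }
    for (j in seq_along(cont)) {
      s <- covariate_specs[[cont[j]]]
      df[[cont[j]]] <- (s$mean %||% 0) + (s$sd %||% 1) * Zc[, j]
    }
  }
  types <- list()
  for (v in names(covariate_specs)) {
    s <- covariate_specs[[v]]
    if (s$kind == "categorical") {
      df[[v]] <- sample(s$levels, n_samples, replace = TRUE,
                        prob = s$probs)
      types[[v]] <- list(kind = "categorical",
                         reference = s$reference %||% s$levels[1L])
    } else {
      types[[v]] <- list(kind = "continuous", units = s$units %||% "")
    }
  }
  cov_tab <- covariate_table(df, types)

  # linear predictor uses centered per-SD continuous covariates so the
  # planted gamma is a per-SD effect (matching the regression's
  # per-SD standardization); centering only shifts the baseline
  lin_data <- cov_tab$data
  for (v in cont) {
    s <- covariate_specs[[v]]
    lin_data[[v]] <- (lin_data[[v]] - (s$mean %||% 0)) / (s$sd %||% 1)
  }
  X <- stats::model.matrix(stats::reformulate(names(covariate_specs)),
                           data = lin_data)
  G <- matrix(0, ncol(X), K, dimnames = list(colnames(X), NULL))
  if (!is.null(gamma)) {
    gamma <- as.matrix(gamma)
    unknown <- setdiff(rownames(gamma), colnames(X))
    if (length(unknown))
      stop("gamma rows not in the design: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    G[rownames(gamma), ] <- gamma
  }
  A <- precision * matrix(base_alpha, n_samples, K, byrow = TRUE) *
    exp(X %*% G)
  theta <- matrix(stats::rgamma(n_samples * K, shape = A), n_samples, K)
  theta <- theta / rowSums(theta)
  dimnames(theta) <- list(sample_names, paste0("subgroup_", seq_len(K)))

  list(covariates = cov_tab, theta = theta,
       truth = list(gamma = G, precision = precision,
                    base_alpha = base_alpha,
                    covariate_specs = covariate_specs, seed = seed))
}

#' Generate ancillary fixtures: taxonomy, OTU sets, disease labels
#'
#' Assigns genera from a pool with a controllable unknown-genus
#' fraction (sentinel `"NA"`), samples disjoint OTU sets of stated
#' sizes (e.g. arrhythmic-OTU lists), and draws 5-level diabetes-like
#' and hypertension-like categorical labels with stated prevalences
#' (defaults emulate a population-based cohort of ~60-year-olds).
#'
#' @param otu_ids character vector of OTU ids to annotate.
#' @param n_samples number of samples to label.
#' @param genus_pool number of distinct named genera.
#' @param unknown_genus_fraction fraction of OTUs mapped to `"NA"`.
#' @param set_sizes integer vector of disjoint OTU-set sizes, named or
#'   not.
#' @param diabetes_prevalence,hypertension_prevalence named probability
#'   vectors over the 5 levels (first level is the reference).
#' @param seed RNG seed.
#' @return List with `taxonomy` (named character), `otu_sets` (named
#'   list), and `labels` (data.frame: sample_id, diabetes,
#'   hypertension).
#' @export
generate_ancillary <- function(otu_ids, n_samples,
                               genus_pool = 30L,
                               unknown_genus_fraction = 0.15,
                               set_sizes = integer(0),
                               diabetes_prevalence = c(
                                 normal_glucose_tolerance = 0.478,
                                 prediabetes = 0.342, udm = 0.042,
                                 t2dm = 0.100, unknown = 0.038),
                               hypertension_prevalence = c(
                                 normal_blood_pressure = 0.603,
                                 htn_controlled = 0.263,
                                 htn_uncontrolled = 0.068,
                                 htn_untreated = 0.040,
                                 htn_undiagnosed = 0.026),
                               seed = 1L) {
  if (unknown_genus_fraction < 0 || unknown_genus_fraction > 1)
    stop("unknown_genus_fraction must lie in [0, 1]", call. = FALSE)
  if (sum(set_sizes) > length(otu_ids))
    stop("requested OTU-set sizes exceed the number of OTUs",
         call. = FALSE)
  set.seed(seed)
  V <- length(otu_ids)
  genera <- sprintf("Genus_%02d", seq_len(genus_pool))
  tax <- sample(genera, V, replace = TRUE)
  n_na <- round(unknown_genus_fraction * V)
  if (n_na > 0) tax[sample.int(V, n_na)] <- "NA"
  names(tax) <- otu_ids

  otu_sets <- list()
  if (length(set_sizes)) {
    pool <- sample(otu_ids)
    offs <- cumsum(c(0L, utils::head(set_sizes, -1L)))
    otu_sets <- lapply(seq_along(set_sizes), function(s)
      pool[(offs[s] + 1L):(offs[s] + set_sizes[s])])
    names(otu_sets) <- names(set_sizes) %||%
      paste0("set_", seq_along(set_sizes))
  }

  labels <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_samples)),
    diabetes = sample(names(diabetes_prevalence), n_samples,
                      replace = TRUE, prob = diabetes_prevalence),
    hypertension = sample(names(hypertension_prevalence), n_samples,
                          replace = TRUE,
                          prob = hypertension_prevalence),
    stringsAsFactors = FALSE)
  list(taxonomy = tax, otu_sets = otu_sets, labels = labels)
}
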