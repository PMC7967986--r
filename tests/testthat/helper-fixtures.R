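# Shared helpers: tiny table builders and topic-matching utilities.

make_table <- function(values, samples = NULL, otus = NULL,
                       normalized = NULL) {
  values <- as.matrix(values)
  rownames(values) <- samples %||% sprintf("s%d", seq_len(nrow(values)))
  colnames(values) <- otus %||% sprintf("otu%d", seq_len(ncol(values)))
  otu_count_table(values, normalized = normalized)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# best bipartite matching of fitted to planted topic rows by exhaustive
# permutation (fine for the small K used in tests); returns the mean TV
# distance under the best matching
matched_tv <- function(phi_fit, phi_true) {
  K <- nrow(phi_true)
  perms <- gtools_permutations(K)
  best <- Inf
  for (i in seq_len(nrow(perms))) {
    d <- mean(vapply(seq_len(K), function(k)
      tv_dist(phi_fit[perms[i, k], ], phi_true[k, ]), numeric(1)))
    if (d < best) best <- d
  }
  best
}

gtools_permutations <- function(K) {
  if (K == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(K - 1L)
  do.call(rbind, lapply(seq_len(K), function(i)
    cbind(i, matrix(setdiff(seq_len(K), i)[sub], nrow(sub)))))
}

# exhaustive collapsed-posterior enumeration for a micro-corpus:
# returns the exact posterior mean of the smoothed theta estimator
enumerate_theta <- function(counts, K, alpha, beta) {
  docs <- rep(seq_len(nrow(counts)), times = rowSums(counts))
  words <- unlist(lapply(seq_len(nrow(counts)), function(d)
    rep(seq_len(ncol(counts)), times = counts[d, ])))
  N <- length(docs); V <- ncol(counts); D <- nrow(counts)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  lp <- apply(grid, 1, function(z) {
    ll <- 0
    for (d in seq_len(D)) for (k in seq_len(K))
      ll <- ll + lgamma(sum(docs == d & z == k) + alpha)
    for (k in seq_len(K)) {
      for (v in seq_len(V))
        ll <- ll + lgamma(sum(words == v & z == k) + beta)
      ll <- ll - lgamma(sum(z == k) + V * beta)
    }
    ll
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  theta <- matrix(0, D, K)
  for (g in seq_len(nrow(grid))) {
    z <- grid[g, ]
    for (d in seq_len(D)) for (k in seq_len(K))
      theta[d, k] <- theta[d, k] +
        w[g] * (sum(docs == d & z == k) + alpha) /
        (sum(docs == d) + K * alpha)
  }
  theta
}

# same enumeration for the fold-in conditional: phi fixed, theta only
enumerate_fold_in_theta <- function(counts, phi, alpha) {
  K <- nrow(phi)
  docs <- rep(seq_len(nrow(counts)), times = rowSums(counts))
  words <- unlist(lapply(seq_len(nrow(counts)), function(d)
    rep(seq_len(ncol(counts)), times = counts[d, ])))
  N <- length(docs); D <- nrow(counts)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  lp <- apply(grid, 1, function(z) {
    ll <- 0
    for (d in seq_len(D)) for (k in seq_len(K))
      ll <- ll + lgamma(sum(docs == d & z == k) + alpha)
    ll + sum(log(phi[cbind(z, words)]))
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  theta <- matrix(0, D, K)
  for (g in seq_len(nrow(grid))) {
    z <- grid[g, ]
    for (d in seq_len(D)) for (k in seq_len(K))
      theta[d, k] <- theta[d, k] +
        w[g] * (sum(docs == d & z == k) + alpha) /
        (sum(docs == d) + K * alpha)
  }
  theta
}
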