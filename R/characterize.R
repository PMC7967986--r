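#' Top genera per subgroup
#'
#' Collapses the subgroup-OTU probability matrix to genus level and
#' ranks genera per subgroup by probability (descending; exact ties
#' broken lexicographically by label). The unknown-genus `"NA"`
#' category takes part in the collapse and its percentage is reported,
#' but it is excluded from the ranked named-genus list.
#'
#' @param phi K x V subgroup-OTU probability matrix with OTU column
#'   names.
#' @param tax taxonomy map from [read_taxonomy()].
#' @param n_top number of named genera to report per subgroup.
#' @return List with `ranked` (long data.frame: subgroup, rank, genus,
#'   probability) and `unknown_percent` (named numeric, percentage of
#'   probability mass in the `"NA"` category per subgroup).
#' @export
top_genera <- function(phi, tax, n_top = 5L) {
  if (n_top < 1L) stop("n_top must be >= 1", call. = FALSE)
  g <- collapse_to_genus(phi, tax)
  subgroups <- rownames(g) %||% paste0("subgroup_", seq_len(nrow(g)))
  has_na <- "NA" %in% colnames(g)
  unknown <- if (has_na) 100 * g[, "NA"] else rep(0, nrow(g))
  names(unknown) <- subgroups
  named <- g[, setdiff(colnames(g), "NA"), drop = FALSE]
  rows <- lapply(seq_len(nrow(named)), function(k) {
    o <- order(-named[k, ], colnames(named))
    take <- utils::head(o, n_top)
    data.frame(subgroup = subgroups[k], rank = seq_along(take),
               genus = colnames(named)[take],
               probability = unname(named[k, take]),
               stringsAsFactors = FALSE)
  })
  list(ranked = do.call(rbind, rows), unknown_percent = unknown)
}

#' Summarize the per-sample subgroup distribution
#'
#' Per-subgroup medians and interquartile ranges of theta across
#' samples, the per-sample maximum subgroup probability, and per-sample
#' counts of subgroups whose probability strictly exceeds each
#' threshold (the "over 1% / 10% / 25%" summaries).
#'
#' @param theta O x K subgroup-probability matrix, rows summing to 1.
#' @param thresholds probabilities; strict inequality is used.
#' @return Object of class `subgroup_summary`: `per_subgroup`
#'   (data.frame: subgroup, median, q1, q3), `max_theta` (per-sample
#'   numeric), `counts` (samples x thresholds integer matrix), and
#'   `count_summary` (data.frame: threshold, mean, sd).
#' @export
summarize_subgroups <- function(theta, thresholds = c(0.01, 0.10, 0.25)) {
  th <- as.matrix(theta)
  if (nrow(th) == 0L || ncol(th) == 0L)
    stop("empty theta matrix", call. = FALSE)
  if (max(abs(rowSums(th) - 1)) > 1e-6)
    stop("theta rows must sum to 1", call. = FALSE)
  thresholds <- sort(thresholds)
  qs <- apply(th, 2, stats::quantile, probs = c(0.25, 0.5, 0.75))
  per_subgroup <- data.frame(
    subgroup = colnames(th) %||% paste0("subgroup_", seq_len(ncol(th))),
    median = qs[2L, ], q1 = qs[1L, ], q3 = qs[3L, ],
    row.names = NULL, stringsAsFactors = FALSE)
  counts <- vapply(thresholds, function(t) rowSums(th > t),
                   numeric(nrow(th)))
  counts <- matrix(as.integer(counts), nrow(th), length(thresholds),
                   dimnames = list(rownames(th),
                                   paste0("gt_", thresholds)))
  structure(list(
    per_subgroup = per_subgroup,
    max_theta = apply(th, 1, max),
    counts = counts,
    count_summary = data.frame(threshold = thresholds,
                               mean = colMeans(counts),
                               sd = apply(counts, 2, stats::sd),
                               row.names = NULL)),
    class = "subgroup_summary")
}

#' @export
print.subgroup_summary <- function(x, ...) {
  cat(sprintf("<subgroup_summary> %d samples x %d subgroups\n",
              length(x$max_theta), nrow(x$per_subgroup)))
  cat(sprintf("  mean max-probability: %.3f\n", mean(x$max_theta)))
  for (i in seq_len(nrow(x$count_summary)))
    cat(sprintf("  subgroups > %g per sample: %.1f +/- %.1f\n",
                x$count_summary$threshold[i], x$count_summary$mean[i],
                x$count_summary$sd[i]))
  invisible(x)
}

#' Hierarchical clustering of subgroups
#'
#' Ward agglomerative clustering (agnes) on Euclidean distances between
#' the log-transformed rows of the full subgroup-OTU probability
#' matrix. A small pseudocount guards against zeros introduced by
#' serialization round-off.
#'
#' @param phi K x V subgroup-OTU probability matrix.
#' @param n_clusters number of flat clusters to cut (<= K).
#' @param pseudocount added before the natural log; default 1e-6.
#' @return List with `hclust` (the merge tree), `labels` (named integer
#'   cluster assignment of the K subgroups), and `phylo` (the tree as
#'   an `ape` phylo object, for newick export).
#' @export
cluster_subgroups <- function(phi, n_clusters, pseudocount = 1e-6) {
  m <- as.matrix(phi)
  K <- nrow(m)
  if (n_clusters > K) stop("n_clusters exceeds K", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("subgroup_", seq_len(K))
  lm <- log(m + pseudocount)
  ag <- cluster::agnes(stats::dist(lm), diss = TRUE, method = "ward")
  hc <- stats::as.hclust(ag)
  hc$labels <- rownames(m)
  labels <- stats::cutree(hc, k = n_clusters)
  list(hclust = hc, labels = labels, phylo = ape::as.phylo(hc))
}

#' Export a subgroup dendrogram as newick
#'
#' @param clustering result of [cluster_subgroups()].
#' @param path output file.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  ape::write.tree(clustering$phylo, file = path)
  invisible(path)
}

#' Summed subgroup probability over OTU sets
#'
#' For each subgroup and each named OTU set (e.g. the arrhythmic-OTU
#' lists), sums the subgroup's probability mass over the set's OTUs and
#' reports it as a percentage.
#'
#' @param phi K x V subgroup-OTU probability matrix with OTU column
#'   names.
#' @param otu_sets named list of character vectors of OTU ids.
#' @param on_missing `"error"` (default) or `"warn"`: what to do with
#'   ids absent from phi's OTU axis (warn skips them).
#' @return K x n_sets numeric matrix of percentages.
#' @export
arrhythmic_fraction <- function(phi, otu_sets,
                                on_missing = c("error", "warn")) {
  on_missing <- match.arg(on_missing)
  m <- as.matrix(phi)
  if (is.null(colnames(m))) stop("phi needs OTU column names", call. = FALSE)
  out <- matrix(0, nrow(m), length(otu_sets),
                dimnames = list(rownames(m), names(otu_sets)))
  for (s in seq_along(otu_sets)) {
    ids <- otu_sets[[s]]
    unknown <- setdiff(ids, colnames(m))
    if (length(unknown)) {
      msg <- paste0("OTU ids not on phi axis (set '", names(otu_sets)[s],
                    "'): ", paste(unknown, collapse = ", "))
      if (on_missing == "error") stop(msg, call. = FALSE)
      warning(msg)
      ids <- setdiff(ids, unknown)
    }
    out[, s] <- 100 * rowSums(m[, ids, drop = FALSE])
  }
  out
}

#' Read OTU-set files (one id per line, set named by filename)
#'
#' @param paths character vector of file paths.
#' @return Named list of character vectors.
#' @export
read_otu_sets <- function(paths) {
  sets <- lapply(paths, function(p) {
    ids <- trimws(readLines(p))
    ids[nzchar(ids)]
  })
  names(sets) <- sub("\\.[^.]*$", "", basename(paths))
  sets
}
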