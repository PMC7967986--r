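#' OTU count table
#'
#' Container for a samples x OTUs abundance matrix. Values may be raw
#' counts or per-sample relative abundances; the `normalized` flag
#' records which. Samples are always kept in rows internally; reading
#' functions handle the samples-in-columns orientation common in
#' amplicon pipelines at the boundary.
#'
#' @param values numeric matrix, samples in rows, OTUs in columns, with
#'   unique row and column names.
#' @param normalized logical; if `NULL`, detected by checking whether
#'   every row sums to 1 within 1e-8.
#' @return An object of class `otu_counts`: a list with elements
#'   `values` (the matrix) and `normalized`.
#' @export
otu_count_table <- function(values, normalized = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L)
    stop("empty OTU table", call. = FALSE)
  # zero OTU columns are allowed: an aggressive filter may remove all
  if (is.null(rownames(values)) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("sample and OTU identifiers are required as dimnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample identifiers", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate OTU identifiers", call. = FALSE)
  if (any(!is.finite(values)))
    stop("non-finite entries in OTU table", call. = FALSE)
  if (any(values < 0))
    stop("negative entries in OTU table", call. = FALSE)
  if (is.null(normalized))
    normalized <- all(abs(rowSums(values) - 1) <= 1e-8)
  structure(list(values = values, normalized = isTRUE(normalized)),
            class = "otu_counts")
}

#' @export
print.otu_counts <- function(x, ...) {
  cat(sprintf("<otu_counts> %d samples x %d OTUs (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "relative abundances" else "counts"))
  invisible(x)
}

#' @export
dim.otu_counts <- function(x) dim(x$values)

sample_ids <- function(x) rownames(x$values)
otu_ids <- function(x) colnames(x$values)

#' Read an OTU table from TSV
#'
#' Expects a tab-delimited file with a header row and identifiers in the
#' first column. `orientation` says whether the rows of the file are
#' samples or OTUs; the returned table is always samples x OTUs.
#'
#' @param path file path.
#' @param orientation `"samples_in_rows"` (default) or
#'   `"samples_in_columns"`.
#' @return An [otu_count_table()] object.
#' @export
read_otu_table <- function(path,
                           orientation = c("samples_in_rows",
                                           "samples_in_columns")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L || nrow(df) < 1L)
    stop("empty or malformed OTU table: ", path, call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row identifiers in ", path, call. = FALSE)
  if (anyDuplicated(colnames(df)[-1L]))
    stop("duplicate column identifiers in ", path, call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric body in ", path, call. = FALSE)
  rownames(m) <- ids
  if (orientation == "samples_in_columns") m <- t(m)
  otu_count_table(m)
}

#' Write an OTU table to TSV
#'
#' Samples in rows, OTU IDs in the header, sample IDs in the first
#' column; round-trips through [read_otu_table()].
#'
#' @param x an `otu_counts` object.
#' @param path output path.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_counts"))
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Total-count (total-sum) normalization
#'
#' Divides each sample's row by its total so rows sum to 1, accounting
#' for library-size differences.
#'
#' @param x an `otu_counts` object with at least one positive entry per
#'   sample.
#' @return A normalized `otu_counts` object.
#' @export
normalize_total_count <- function(x) {
  stopifnot(inherits(x, "otu_counts"))
  tot <- rowSums(x$values)
  bad <- which(tot <= 0)
  if (length(bad))
    stop("degenerate sample(s) with zero total count: ",
         paste(rownames(x$values)[bad], collapse = ", "), call. = FALSE)
  otu_count_table(x$values / tot, normalized = TRUE)
}

#' Abundance/prevalence OTU filter
#'
#' Keeps exactly those OTUs whose within-sample relative abundance
#' strictly exceeds `abundance_threshold` in at least
#' `ceiling(prevalence_threshold * n_samples)` samples. Column order is
#' preserved and rows are deliberately NOT renormalized; renormalize
#' explicitly with [normalize_total_count()] if needed.
#'
#' @param x a normalized `otu_counts` object.
#' @param abundance_threshold within-sample relative-abundance cutoff in
#'   `[0, 1)`; default 0.001 (0.1%).
#' @param prevalence_threshold minimum fraction of samples in `[0, 1)`
#'   that must exceed the abundance cutoff; default 0.01 (1%).
#' @return An `otu_counts` object with the surviving OTU columns.
#' @export
filter_otus <- function(x, abundance_threshold = 0.001,
                        prevalence_threshold = 0.01) {
  stopifnot(inherits(x, "otu_counts"))
  if (!x$normalized)
    stop("filter_otus expects a normalized table; call normalize_total_count first",
         call. = FALSE)
  for (thr in c(abundance_threshold, prevalence_threshold))
    if (!is.finite(thr) || thr < 0 || thr >= 1)
      stop("thresholds must lie in [0, 1)", call. = FALSE)
  need <- max(1L, ceiling(prevalence_threshold * nrow(x$values)))
  qualifying <- colSums(x$values > abundance_threshold)
  keep <- qualifying >= need
  otu_count_table(x$values[, keep, drop = FALSE], normalized = FALSE)
}

#' Rescale relative abundances to integer pseudo-counts
#'
#' Multiplies every entry by `factor` and rounds half away from zero,
#' producing the integer matrix a Gibbs LDA sampler consumes.
#'
#' @param x a normalized (or filtered-from-normalized) `otu_counts`
#'   object.
#' @param factor positive integer multiplier; default 1000.
#' @return An `otu_counts` object of non-negative integers
#'   (`normalized = FALSE`).
#' @export
rescale_to_counts <- function(x, factor = 1000L) {
  stopifnot(inherits(x, "otu_counts"))
  if (!is.finite(factor) || factor < 1)
    stop("`factor` must be a positive integer", call. = FALSE)
  v <- x$values * factor
  if (any(!is.finite(v))) stop("non-finite entry after rescaling", call. = FALSE)
  # round-half-away-from-zero (entries are non-negative here)
  v <- floor(v + 0.5)
  otu_count_table(v, normalized = FALSE)
}

#' Read a taxonomy map
#'
#' Two-column TSV (otu_id, genus); the literal string `"NA"` is the
#' unknown-genus sentinel and is preserved as a label, never parsed as a
#' missing value.
#'
#' @param path file path.
#' @return Named character vector: OTU id -> genus label.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          na.strings = character(0), check.names = FALSE)
  if (ncol(df) < 2L) stop("taxonomy file needs two columns", call. = FALSE)
  if (anyDuplicated(df[[1L]]))
    stop("duplicate OTU ids in taxonomy map", call. = FALSE)
  stats::setNames(df[[2L]], df[[1L]])
}

#' Collapse OTU columns to genus level
#'
#' Sums columns sharing a genus label; OTUs mapped to the `"NA"`
#' sentinel sum into that category. Row totals are conserved exactly.
#' Works on an `otu_counts` object or on any matrix whose columns are
#' OTUs (e.g. a K x V subgroup-OTU probability matrix).
#'
#' @param x `otu_counts` object or numeric matrix with OTU column names.
#' @param tax named character vector from [read_taxonomy()].
#' @return Numeric matrix over genus labels (columns sorted, with the
#'   `"NA"` category last if present).
#' @export
collapse_to_genus <- function(x, tax) {
  m <- if (inherits(x, "otu_counts")) x$values else x
  if (!is.matrix(m) || is.null(colnames(m)))
    stop("input must carry OTU column names", call. = FALSE)
  missing_ids <- setdiff(colnames(m), names(tax))
  if (length(missing_ids))
    stop("OTUs absent from taxonomy map: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  genus <- tax[colnames(m)]
  lev <- sort(unique(genus))
  if ("NA" %in% lev) lev <- c(setdiff(lev, "NA"), "NA")
  g <- factor(genus, levels = lev)
  out <- t(rowsum(t(m), g))
  rownames(out) <- rownames(m)
  out
}
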