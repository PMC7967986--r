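#' Covariate table with declared variable kinds
#'
#' Wraps a per-sample predictor table (diet, disease and adjustment
#' variables) together with type metadata: each variable is declared
#' continuous (optionally with units) or categorical with a reference
#' level. Categorical variables become factors with the reference level
#' first, so downstream model matrices treat it as the baseline.
#'
#' @param data data.frame with a `sample_id` column (or sample ids as
#'   row names) and one column per variable.
#' @param types named list; each element is a list with `kind`
#'   (`"continuous"` or `"categorical"`), optional `units`, and for
#'   categorical variables a `reference` level that must be observed.
#'   Variables absent from `types` are typed by their storage mode.
#' @return An object of class `covariate_table`: list with `data`
#'   (data.frame, sample ids in `sample_id`) and `types`.
#' @export
covariate_table <- function(data, types = list()) {
  stopifnot(is.data.frame(data))
  if (!"sample_id" %in% names(data)) {
    if (is.null(rownames(data)))
      stop("`data` needs a sample_id column or row names", call. = FALSE)
    data <- cbind(sample_id = rownames(data), data,
                  stringsAsFactors = FALSE)
  }
  data$sample_id <- as.character(data$sample_id)
  if (anyDuplicated(data$sample_id))
    stop("duplicate sample ids in covariate table", call. = FALSE)
  vars <- setdiff(names(data), "sample_id")
  for (v in vars) {
    spec <- types[[v]]
    if (is.null(spec))
      spec <- list(kind = if (is.numeric(data[[v]])) "continuous"
                   else "categorical")
    if (spec$kind == "continuous") {
      if (!is.numeric(data[[v]]))
        stop("variable declared continuous is not numeric: ", v,
             call. = FALSE)
      bad <- !is.na(data[[v]]) & !is.finite(data[[v]])
      if (any(bad))
        stop("non-finite values in continuous variable ", v, call. = FALSE)
    } else if (spec$kind == "categorical") {
      obs <- unique(stats::na.omit(as.character(data[[v]])))
      ref <- spec$reference %||% obs[1L]
      if (!ref %in% obs)
        stop("declared reference level '", ref,
             "' not observed for variable ", v, call. = FALSE)
      data[[v]] <- factor(as.character(data[[v]]),
                          levels = c(ref, setdiff(sort(obs), ref)))
      spec$reference <- ref
    } else stop("unknown kind for variable ", v, call. = FALSE)
    types[[v]] <- spec
  }
  structure(list(data = data, types = types), class = "covariate_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.covariate_table <- function(x, ...) {
  kinds <- vapply(setdiff(names(x$data), "sample_id"),
                  function(v) x$types[[v]]$kind, character(1))
  cat(sprintf("<covariate_table> %d samples, %d continuous, %d categorical\n",
              nrow(x$data), sum(kinds == "continuous"),
              sum(kinds == "categorical")))
  invisible(x)
}

#' Read a covariate table with a JSON types sidecar
#'
#' The TSV carries one sample per row with a `sample_id` column; the
#' sidecar is a JSON object keyed by variable name with `kind`,
#' optional `units`, and `reference` for categorical variables.
#'
#' @param path TSV path.
#' @param types_path optional JSON sidecar path.
#' @return A [covariate_table()].
#' @export
read_covariates <- function(path, types_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  types <- if (!is.null(types_path))
    jsonlite::read_json(types_path, simplifyVector = FALSE) else list()
  covariate_table(df, types)
}

#' Write a covariate table and its types sidecar
#'
#' @param x a `covariate_table`.
#' @param path TSV path.
#' @param types_path optional JSON sidecar path.
#' @export
write_covariates <- function(x, path, types_path = NULL) {
  stopifnot(inherits(x, "covariate_table"))
  utils::write.table(x$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(types_path))
    jsonlite::write_json(x$types, types_path, auto_unbox = TRUE,
                         pretty = TRUE)
  invisible(path)
}
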