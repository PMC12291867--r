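#' Dissimilarity matrix objects
#'
#' Square symmetric pairwise matrices carrying a metric label and, where a
#' partition applies, named component matrices of the same shape (e.g.
#' turnover and nestedness).
#'
#' @param values Square numeric matrix with identical row/column names.
#' @param metric Label, e.g. `"beta_sor"`, `"bray_curtis"`, `"geodesic_m"`.
#' @param components Optional named list of matrices, same dimnames.
#' @param meta Optional named list of metadata (e.g. `standardized = TRUE`).
#' @return An object of class `dissim_matrix`.
#' @export
dissim_matrix <- function(values, metric, components = NULL, meta = list()) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values))) abort("dissimilarity matrix needs site ids")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-10,
                        check.attributes = FALSE)))
    abort("dissimilarity matrix must be symmetric")
  for (cmp in components) stopifnot(identical(dim(cmp), dim(values)))
  structure(values, class = c("dissim_matrix", "matrix", "array"),
            metric = metric, components = components, meta = meta)
}

#' @export
print.dissim_matrix <- function(x, ...) {
  cat("<dissim_matrix> metric:", attr(x, "metric"),
      " sites:", nrow(x), "\n")
  if (!is.null(attr(x, "components")))
    cat("components:", paste(names(attr(x, "components")), collapse = ", "),
        "\n")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Long (one row per unordered site pair) view of a dissimilarity matrix
#'
#' @param x A `dissim_matrix`.
#' @param ... Unused.
#' @return Tibble with `site_i`, `site_j`, `value`, plus one column per
#'   component matrix.
#' @export
tidy.dissim_matrix <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  out <- tibble::tibble(site_i = ids[idx[, 1]], site_j = ids[idx[, 2]],
                        value = unclass(x)[idx])
  for (nm in names(attr(x, "components"))) {
    out[[nm]] <- attr(x, "components")[[nm]][idx]
  }
  attr(out, "metric") <- attr(x, "metric")
  out
}

dissim_component <- function(x, name) attr(x, "components")[[name]]

pair_index <- function(n) which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
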