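#' Build a community matrix from a tidy site-by-taxon table
#'
#' The community matrix is the object every beta-diversity and null-model
#' computation consumes: non-negative integer abundances (individuals, or
#' densities in ind/m^2 rounded to counts), one row per site, one column per
#' taxon.
#'
#' @param data A data frame whose first column (or the column named by
#'   `site_col`) holds unique site identifiers and whose remaining columns
#'   hold non-negative integer counts, one per taxon.
#' @param site_col Name of the site-identifier column. Default `"site_id"`;
#'   if absent, the first column is used.
#' @param allow_empty_sites Keep sites whose row sum is zero? Default `FALSE`
#'   (they are rejected with an error naming the offenders, because pairwise
#'   abundance dissimilarities between two empty sites are undefined).
#'   When `TRUE`, empty sites are retained and downstream pairwise values
#'   involving them propagate `NA`.
#' @return A numeric matrix of class `community_matrix` with site ids as row
#'   names and taxon ids as column names.
#' @examples
#' cm <- community_matrix(data.frame(site_id = c("a", "b"),
#'                                   t1 = c(3L, 0L), t2 = c(1L, 2L)))
#' @export
community_matrix <- function(data, site_col = "site_id",
                             allow_empty_sites = FALSE) {
  data <- as.data.frame(data)
  if (!site_col %in% names(data)) site_col <- names(data)[1]
  ids <- as.character(data[[site_col]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate site ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(data[setdiff(names(data), site_col)])
  storage.mode(m) <- "double"
  if (anyDuplicated(colnames(m))) abort("duplicate taxon ids")
  if (nrow(m) < 2L) abort("a community matrix needs at least 2 sites")
  if (ncol(m) < 1L) abort("a community matrix needs at least 1 taxon")
  if (anyNA(m)) abort("counts must not be missing")
  if (any(m < 0)) abort("counts must be non-negative")
  if (any(abs(m - round(m)) > 1e-8)) {
    bad <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)
    abort(paste0("non-integer counts, e.g. site ", ids[bad[1, 1]],
                 ", taxon ", colnames(m)[bad[1, 2]]))
  }
  m <- round(m)
  rownames(m) <- ids
  empty <- rowSums(m) == 0
  if (any(empty) && !allow_empty_sites) {
    abort(paste0("sites with zero total abundance: ",
                 paste(ids[empty], collapse = ", "),
                 ". Set allow_empty_sites = TRUE to keep them (pairwise ",
                 "values involving them become NA)."))
  }
  structure(m, class = c("community_matrix", "matrix", "array"),
            allow_empty_sites = allow_empty_sites)
}

#' Coerce to a community matrix
#' @param x A `community_matrix`, matrix with dimnames, or data frame.
#' @param ... Passed on to [community_matrix()] for data frames.
#' @return A `community_matrix`.
#' @export
as_community_matrix <- function(x, ...) {
  if (inherits(x, "community_matrix")) return(x)
  if (is.matrix(x)) {
    df <- data.frame(site_id = rownames(x) %||% paste0("s", seq_len(nrow(x))),
                     x, check.names = FALSE)
    return(community_matrix(df, ...))
  }
  community_matrix(x, ...)
}

#' @export
tidy.community_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame(unclass(x)), rownames = "site_id") |>
    tidyr::pivot_longer(-"site_id", names_to = "taxon_id",
                        values_to = "count")
}

site_ids <- function(cm) rownames(cm)

#' Validate a site table
#'
#' @param sites Data frame with columns `site_id`, `longitude`, `latitude`,
#'   `altitude`, and optionally `region` and `month`.
#' @return The site table as a tibble, invisibly validated.
#' @export
validate_sites <- function(sites) {
  sites <- tibble::as_tibble(sites)
  need <- c("site_id", "longitude", "latitude", "altitude")
  miss <- setdiff(need, names(sites))
  if (length(miss)) abort(paste("site table lacks columns:",
                                paste(miss, collapse = ", ")))
  if (anyDuplicated(sites$site_id)) abort("duplicate site ids in site table")
  if (any(sites$longitude < -180 | sites$longitude > 180, na.rm = TRUE))
    abort("longitude outside [-180, 180]")
  if (any(sites$latitude < -90 | sites$latitude > 90, na.rm = TRUE))
    abort("latitude outside [-90, 90]")
  if (!all(is.finite(sites$altitude))) abort("altitudes must be finite")
  sites
}

#' Validate an environmental (physicochemical) table
#'
#' One row per site; all non-id columns numeric. Missing values are refused
#' by default; `impute = "median"` replaces them per variable (logged via a
#' message), matching routine practice for sparse field gaps.
#'
#' @param env Data frame: `site_id` plus numeric variables.
#' @param impute `"none"` (default, error on NA) or `"median"`.
#' @return Tibble with no missing values.
#' @export
validate_env <- function(env, impute = c("none", "median")) {
  impute <- match.arg(impute)
  env <- tibble::as_tibble(env)
  if (!"site_id" %in% names(env)) names(env)[1] <- "site_id"
  vars <- setdiff(names(env), c("site_id", "month", "region"))
  for (v in vars) {
    if (!is.numeric(env[[v]])) abort(paste0("variable '", v, "' is not numeric"))
    if (anyNA(env[[v]])) {
      if (impute == "none")
        abort(paste0("missing values in '", v,
                     "'; use impute = \"median\" to fill them"))
      n_na <- sum(is.na(env[[v]]))
      env[[v]][is.na(env[[v]])] <- median(env[[v]], na.rm = TRUE)
      message("imputed ", n_na, " value(s) in '", v, "' with the median")
    }
  }
  env
}

check_same_sites <- function(a_ids, b_ids, what = "inputs") {
  extra <- setdiff(a_ids, b_ids)
  missing <- setdiff(b_ids, a_ids)
  if (length(extra) || length(missing)) {
    abort(paste0("site ids differ between ", what, ": ",
                 if (length(extra)) paste0("unmatched [",
                   paste(extra, collapse = ", "), "]") else "",
                 if (length(missing)) paste0(" absent [",
                   paste(missing, collapse = ", "), "]") else ""))
  }
  invisible(TRUE)
}
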