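# Geographical-detector q-statistic with optimal parameter selection:
# each continuous driver is discretized by several methods x class counts,
# the stratification maximizing q is kept, and the buffer radius whose
# 11-driver q-profile has the highest 90th percentile wins.

#' Geographical-detector q-statistic
#'
#' Fraction of the response variance explained by a categorical
#' stratification: `q = 1 - SSW/SST`, with `SSW = sum_h N_h * var_h`
#' (population variances) and `SST = N * var` overall. `q = 0` when strata
#' explain nothing, `q = 1` when every stratum is internally constant.
#'
#' @param y Numeric response values.
#' @param strata Class assignment (factor-like), same length as `y`.
#' @return q in `[0, 1]`.
#' @export
q_statistic <- function(y, strata) {
  keep <- !is.na(y) & !is.na(strata)
  y <- y[keep]; strata <- as.character(strata)[keep]
  if (length(unique(strata)) < 2)
    abort("need at least 2 non-empty strata")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) abort("zero total variance in the response")
  ssw <- sum(vapply(split(y, strata),
                    function(v) sum((v - mean(v))^2), numeric(1)))
  1 - ssw / sst
}

# ---- discretization methods ------------------------------------------------

breaks_equal <- function(x, k) seq(min(x), max(x), length.out = k + 1)

breaks_quantile <- function(x, k) {
  unique(quantile(x, probs = seq(0, 1, length.out = k + 1), type = 7))
}

breaks_geometric <- function(x, k) {
  lo <- min(x); hi <- max(x)
  if (lo <= 0) {       # shift to a positive support, then shift back
    off <- 1 - lo
    return(breaks_geometric(x + off, k) - off)
  }
  exp(seq(log(lo), log(hi), length.out = k + 1))
}

breaks_sd <- function(x, k) {
  mu <- mean(x); s <- sd(x)
  half <- ceiling((k - 1) / 2)
  inner <- mu + s * seq(-half, half, length.out = k - 1)
  c(min(x), sort(inner[inner > min(x) & inner < max(x)]), max(x))
}

# exact Fisher-Jenks natural breaks by dynamic programming over sorted x
breaks_natural <- function(x, k) {
  xs <- sort(x); n <- length(xs)
  if (k >= n) return(unique(c(xs, max(xs))))
  # prefix sums for O(1) within-class SSE
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  sse <- function(i, j) { # class xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n); B <- matrix(0L, k, n)
  for (j in seq_len(n)) D[1, j] <- sse(1, j)
  for (g in 2:k) for (j in g:n) {
    for (i in g:j) {
      v <- D[g - 1, i - 1] + sse(i, j)
      if (v < D[g, j]) { D[g, j] <- v; B[g, j] <- i }
    }
  }
  cuts <- integer(0); j <- n
  for (g in k:2) { i <- B[g, j]; cuts <- c(xs[i - 1], cuts); j <- i - 1 }
  c(min(xs), cuts, max(xs))
}

#' Discretize a continuous driver
#'
#' @param x Numeric vector.
#' @param method One of `"equal"`, `"quantile"`, `"natural"`, `"geometric"`,
#'   `"sd"`.
#' @param k Number of classes requested.
#' @return List: `breaks`, `assignment` (integer classes, empties merged
#'   with their nearest neighbour class), `method`, `k_requested`,
#'   `k_effective`.
#' @export
discretize <- function(x, method = c("equal", "quantile", "natural",
                                     "geometric", "sd"), k) {
  method <- match.arg(method)
  br <- switch(method,
               equal = breaks_equal(x, k),
               quantile = breaks_quantile(x, k),
               natural = breaks_natural(x, k),
               geometric = breaks_geometric(x, k),
               sd = breaks_sd(x, k))
  br <- sort(unique(br))
  if (length(br) < 3) abort("driver has too few distinct values to split")
  cl <- cut(x, br, labels = FALSE, include.lowest = TRUE)
  # merge empty classes into the nearest occupied neighbour (relabel run)
  cl <- match(cl, sort(unique(cl)))
  list(breaks = br, assignment = cl, method = method,
       k_requested = k, k_effective = length(unique(cl)))
}

#' Optimal discretization of one driver (the OPGD parameter search)
#'
#' Evaluates every combination of discretization method and class count,
#' computes q for each resulting stratification, and returns the maximum.
#' Ties break toward fewer classes, then method order as listed.
#'
#' @param y Response values.
#' @param x Continuous driver, same length.
#' @param methods Methods to search (see [discretize()]).
#' @param k_range Class counts to search (default 3:7).
#' @return List of class `opgd_q`: `q`, `discretization`, and `search`
#'   (tibble of all evaluated combinations).
#' @export
optimize_discretization <- function(y, x,
                                    methods = c("equal", "quantile",
                                                "natural", "geometric", "sd"),
                                    k_range = 3:7) {
  if (length(unique(x)) <= max(k_range))
    k_range <- k_range[k_range < length(unique(x))]
  grid <- expand.grid(k = k_range, method = methods,
                      stringsAsFactors = FALSE)
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    d <- tryCatch(discretize(x, grid$method[i], grid$k[i]),
                  error = function(e) NULL)
    if (is.null(d) || d$k_effective < 2) return(NULL)
    tibble::tibble(method = grid$method[i], k = grid$k[i],
                   k_effective = d$k_effective,
                   q = q_statistic(y, d$assignment))
  })
  if (!nrow(rows)) abort("no feasible discretization for this driver")
  # tie-break: highest q, then fewer classes, then method order
  rows$method_order <- match(rows$method, methods)
  best <- rows[order(-rows$q, rows$k, rows$method_order), ][1, ]
  structure(list(q = best$q,
                 discretization = discretize(x, best$method, best$k),
                 search = rows[setdiff(names(rows), "method_order")]),
            class = "opgd_q")
}

#' Buffer-scale selection by the 90th percentile of driver q-values
#'
#' For every candidate radius, each of the landscape drivers is optimally
#' discretized against the response (mean WQI) and its q recorded; the
#' radius whose 90th percentile of q-values (linear interpolation between
#' order statistics) peaks is the operating scale. Ties break toward the
#' smallest radius.
#'
#' @param drivers Tibble of driver tables stacked over radii (columns
#'   `site_id`, `radius`, one column per driver), e.g. several
#'   [driver_table()] results row-bound.
#' @param response Data frame `site_id`, `wqi_mean` (or any response column
#'   named by `response_col`).
#' @param response_col Name of the response column. Default `"wqi_mean"`.
#' @param methods,k_range Passed to [optimize_discretization()].
#' @return Object of class `opgd_scale`: list with `optimal_radius`,
#'   `profile` (tibble `radius`, `q90`), and `q_table` (tibble `radius`,
#'   `driver`, `q`, `method`, `k`).
#' @export
buffer_scale_selection <- function(drivers, response,
                                   response_col = "wqi_mean",
                                   methods = c("equal", "quantile", "natural",
                                               "geometric", "sd"),
                                   k_range = 3:7) {
  drivers <- tibble::as_tibble(drivers)
  response <- tibble::as_tibble(response)
  radii <- sort(unique(drivers$radius))
  if (length(radii) < 2) abort("need at least 2 candidate radii")
  dcols <- setdiff(names(drivers), c("site_id", "radius"))
  q_table <- purrr::map_dfr(radii, function(r) {
    sub <- drivers[drivers$radius == r, ]
    y <- response[[response_col]][match(sub$site_id, response$site_id)]
    if (anyNA(y)) abort("response missing for some sites")
    purrr::map_dfr(dcols, function(v) {
      x <- sub[[v]]
      if (length(unique(x)) < 3 || sd(x) == 0) return(NULL)
      fit <- tryCatch(optimize_discretization(y, x, methods, k_range),
                      error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      tibble::tibble(radius = r, driver = v, q = fit$q,
                     method = fit$discretization$method,
                     k = fit$discretization$k_effective)
    })
  })
  profile <- q_table |>
    dplyr::group_by(.data$radius) |>
    dplyr::summarise(n_drivers = dplyr::n(),
                     q90 = quantile(.data$q, 0.9, type = 7),
                     .groups = "drop")
  dropped <- profile$radius[profile$n_drivers < 2]
  if (length(dropped)) {
    warn(paste("radius excluded (fewer than 2 usable drivers):",
               paste(dropped, collapse = ", ")))
    profile <- profile[profile$n_drivers >= 2, ]
  }
  best <- profile$radius[which.max(profile$q90)]  # which.max: first = smallest
  structure(list(optimal_radius = best, profile = profile, q_table = q_table),
            class = "opgd_scale")
}

#' @export
print.opgd_scale <- function(x, ...) {
  cat("<opgd_scale> optimal radius:", x$optimal_radius, "m\n")
  print(x$profile)
  invisible(x)
}

#' @export
autoplot.opgd_scale <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$radius, y = .data$q90)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$optimal_radius,
                        linetype = "dashed") +
    ggplot2::labs(x = "buffer radius (m)",
                  y = "90th percentile of driver q-values") +
    ggplot2::theme_minimal()
}
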