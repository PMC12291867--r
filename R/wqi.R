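# Weighted water-quality index: each physicochemical parameter is mapped
# through a piecewise-linear normalization curve to a score C_i in [0, 100]
# (100 = ideal water), then aggregated with importance weights P_i in 1..4:
# WQI = sum(C_i * P_i) / sum(P_i).

#' WQI parameter specification
#'
#' @param name Parameter name (must match an environmental-table column).
#' @param weight Importance weight, integer 1-4.
#' @param curve Data frame `value`, `score` defining a piecewise-linear
#'   normalization from measured value to a 0-100 score; `value` strictly
#'   increasing, `score` within `[0, 100]`.
#' @return Object of class `wqi_param`.
#' @export
wqi_param <- function(name, weight, curve) {
  if (!(weight %in% 1:4)) abort("weight must be an integer in 1..4")
  curve <- as.data.frame(curve)
  if (is.unsorted(curve$value, strictly = TRUE))
    abort("curve values must be strictly increasing")
  if (any(curve$score < 0 | curve$score > 100))
    abort("curve scores must lie in [0, 100]")
  structure(list(name = name, weight = weight, curve = curve),
            class = "wqi_param")
}

#' Normalize one measured value through a WQI curve
#'
#' Linear interpolation between curve anchors; values outside the curve
#' domain are clamped to the end scores with a warning (or an error when
#' `outside = "error"`).
#'
#' @param value Measured value(s), finite.
#' @param spec A [wqi_param()].
#' @param outside `"clamp"` (default) or `"error"`.
#' @return Score(s) `C_i` in `[0, 100]`.
#' @export
normalize_parameter <- function(value, spec, outside = c("clamp", "error")) {
  outside <- match.arg(outside)
  if (any(!is.finite(value))) abort("values must be finite")
  rng <- range(spec$curve$value)
  out_of_dom <- value < rng[1] | value > rng[2]
  if (any(out_of_dom)) {
    if (outside == "error")
      abort(paste0("value outside the '", spec$name, "' curve domain"))
    warn(paste0(sum(out_of_dom), " value(s) outside the '", spec$name,
                "' curve domain clamped"))
  }
  approx(spec$curve$value, spec$curve$score, xout = pmin(pmax(value, rng[1]),
                                                         rng[2]))$y
}

#' Weighted water-quality index per site
#'
#' @param env Environmental table: `site_id` (optionally `month`, `region`)
#'   plus one column per configured parameter.
#' @param specs List of [wqi_param()] objects; every spec's parameter must
#'   be present in `env`.
#' @param thresholds Classification scheme, see [classify_wqi()].
#' @return Tibble: input id columns, per-parameter scores (`score_<name>`),
#'   `WQI`, `class`.
#' @export
wqi <- function(env, specs, thresholds = wqi_classes()) {
  env <- tibble::as_tibble(env)
  if (!"site_id" %in% names(env)) names(env)[1] <- "site_id"
  nm <- vapply(specs, function(s) s$name, character(1))
  miss <- setdiff(nm, names(env))
  if (length(miss)) abort(paste("environmental table lacks parameter(s):",
                                paste(miss, collapse = ", ")))
  wts <- vapply(specs, function(s) s$weight, numeric(1))
  out <- env[intersect(c("site_id", "region", "month"), names(env))]
  scores <- matrix(NA_real_, nrow(env), length(specs))
  for (k in seq_along(specs)) {
    scores[, k] <- normalize_parameter(env[[nm[k]]], specs[[k]])
    out[[paste0("score_", nm[k])]] <- scores[, k]
  }
  out$WQI <- as.vector(scores %*% wts) / sum(wts)
  out$class <- classify_wqi(out$WQI, thresholds)
  out
}

#' Mean WQI across months per site
#'
#' The OPGD response variable: the mean of the per-month WQI values for
#' each site.
#'
#' @param wqi_table Output of [wqi()] computed on a multi-month table.
#' @return Tibble `site_id`, `wqi_mean`.
#' @export
wqi_mean <- function(wqi_table) {
  dplyr::summarise(dplyr::group_by(wqi_table, .data$site_id),
                   wqi_mean = mean(.data$WQI), .groups = "drop")
}

#' Default WQI classification bands
#'
#' Five 20/25-point bands; a boundary value belongs to the upper class.
#' @return Data frame `lower`, `upper`, `label` covering `[0, 100]`.
#' @export
wqi_classes <- function() {
  data.frame(lower = c(0, 25, 50, 70, 90),
             upper = c(25, 50, 70, 90, 100),
             label = c("Very poor", "Poor", "Medium", "Good", "Excellent"))
}

#' Classify WQI values into quality bands
#'
#' Intervals are `(lower, upper]`: a value lying exactly on a boundary is
#' assigned to the upper class. The bottom band includes its lower bound.
#'
#' @param x WQI values in `[0, 100]`.
#' @param thresholds Data frame `lower`, `upper`, `label`; bands must be
#'   contiguous, strictly ordered, and cover `[0, 100]`.
#' @return Character vector of class labels.
#' @export
classify_wqi <- function(x, thresholds = wqi_classes()) {
  th <- thresholds[order(thresholds$lower), ]
  if (any(th$lower >= th$upper) ||
      any(abs(th$lower[-1] - th$upper[-nrow(th)]) > 1e-9))
    abort("classification bands must be contiguous and strictly ordered")
  breaks <- c(th$lower[1], th$upper)
  as.character(th$label[cut(x, breaks, labels = FALSE,
                            include.lowest = TRUE, right = FALSE)]) -> lab
  # right = FALSE puts a boundary in the class above it, as documented;
  # but the top bound must still fall in the top class
  lab[x >= breaks[length(breaks)]] <- as.character(th$label[nrow(th)])
  lab
}

#' Example WQI parameter set (13 indicators)
#'
#' Placeholder normalization curves and weights for the thirteen routine
#' indicators (pH, WT, EC, TUR, DO, TDS, TN, NH3N, NO2N, NO3N, TP, CODMn,
#' Chla), intended for tests and synthetic data only — NOT an authoritative
#' transcription of any published WQI parameterization. Curves are monotone
#' except pH and WT, which peak at an optimum.
#'
#' @return Named list of [wqi_param()] objects.
#' @export
example_wqi_params <- function() {
  lin <- function(worst, best) {
    # monotone 0..100 between worst and best anchor values
    if (worst < best) data.frame(value = c(worst, best), score = c(0, 100))
    else data.frame(value = c(best, worst), score = c(100, 0))
  }
  specs <- list(
    wqi_param("pH", 1, data.frame(value = c(4, 7.25, 10.5),
                                  score = c(0, 100, 0))),
    wqi_param("WT", 1, data.frame(value = c(0, 16, 32), score = c(0, 100, 0))),
    wqi_param("EC", 2, lin(2000, 100)),
    wqi_param("TUR", 2, lin(120, 0)),
    wqi_param("DO", 4, lin(2, 12)),
    wqi_param("TDS", 2, lin(1500, 50)),
    wqi_param("TN", 3, lin(8, 0.1)),
    wqi_param("NH3N", 3, lin(3, 0.01)),
    wqi_param("NO2N", 2, lin(0.6, 0.001)),
    wqi_param("NO3N", 2, lin(12, 0.05)),
    wqi_param("TP", 3, lin(1.2, 0.005)),
    wqi_param("CODMn", 3, lin(18, 0.5)),
    wqi_param("Chla", 2, lin(60, 0.5)))
  stats::setNames(specs, vapply(specs, function(s) s$name, character(1)))
}
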