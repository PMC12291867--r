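# Generalized Dissimilarity Modelling: compositional dissimilarity y_ij in
# [0,1] regressed on monotone I-spline transforms of pairwise predictor
# distances through the negative-exponential link mu = 1 - exp(-eta),
# eta = alpha + sum_pk w_pk I_pk(D_p), all coefficients >= 0. Fitted by
# IRLS with a non-negative least-squares inner solve and binomial-type
# deviance.

#' Assemble a site-pair table
#'
#' One row per unordered site pair: the response dissimilarity plus each
#' predictor's pairwise distance value.
#'
#' @param response A `dissim_matrix` of compositional dissimilarities in
#'   `[0, 1]` (e.g. from [pairwise_sorensen()]).
#' @param predictors Named list of `dissim_matrix` objects sharing the
#'   response's site ids (geographic distance, altitude distance,
#'   environmental dissimilarities, ...).
#' @return Tibble of class `sitepair_table`: `site_i`, `site_j`, `y`, one
#'   column per predictor; `n(n-1)/2` rows.
#' @export
build_sitepair_table <- function(response, predictors) {
  ids <- rownames(response)
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    abort("predictors must be a named list")
  for (nm in names(predictors))
    check_same_sites(rownames(predictors[[nm]]), ids,
                     paste0("response and predictor '", nm, "'"))
  idx <- pair_index(length(ids))
  out <- tibble::tibble(site_i = ids[idx[, 1]], site_j = ids[idx[, 2]],
                        y = unclass(response)[idx])
  if (any(out$y < 0 | out$y > 1, na.rm = TRUE))
    abort("response dissimilarities must lie in [0, 1]")
  for (nm in names(predictors)) {
    p <- predictors[[nm]]
    out[[nm]] <- unclass(p)[ids, ids][idx]
  }
  class(out) <- c("sitepair_table", class(out))
  out
}

gdm_deviance <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)
  2 * sum(t1 + t2)
}

# IRLS with NNLS inner solve; X excludes the intercept column
gdm_irls <- function(y, X, max_iter = 100, tol = 1e-6) {
  n <- length(y)
  Xf <- cbind(`(Intercept)` = 1, X)
  beta <- numeric(ncol(Xf))
  mu <- pmin(pmax((y + mean(y)) / 2, 0.01), 0.99)
  eta <- -log(1 - mu)
  dev <- gdm_deviance(y, mu)
  dev_trace <- dev
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu_c <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
    dmu <- 1 - mu_c                       # d mu / d eta
    z <- eta + (y - mu_c) / dmu
    w <- dmu^2 / (mu_c * (1 - mu_c))      # binomial variance, unit weights
    sw <- sqrt(w)
    beta_new <- pracma::lsqnonneg(Xf * sw, z * sw)$x
    # step-halve toward the previous iterate if deviance would rise
    step <- 1
    repeat {
      beta_try <- (1 - step) * beta + step * beta_new
      eta_try <- drop(Xf %*% beta_try)
      mu_try <- 1 - exp(-eta_try)
      dev_try <- gdm_deviance(y, mu_try)
      if (dev_try <= dev + 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    rel <- abs(dev - dev_try) / (abs(dev) + 0.1)
    beta <- beta_try; eta <- eta_try; mu <- mu_try; dev <- dev_try
    dev_trace <- c(dev_trace, dev)
    if (rel < tol) { converged <- TRUE; break }
  }
  list(beta = beta, mu = mu, deviance = dev, deviance_trace = dev_trace,
       converged = converged, iterations = length(dev_trace) - 1)
}

#' Fit a generalized dissimilarity model
#'
#' @param table A [build_sitepair_table()] result (or a data frame with
#'   columns `y` plus predictor distances).
#' @param predictors Character vector of predictor columns; default every
#'   column except `site_i`, `site_j`, `y`.
#' @param n_splines I-splines per predictor (default 3).
#' @param knot_quantiles Knot-placement probabilities (default evenly
#'   spaced, i.e. min/median/max).
#' @param max_iter,tol IRLS control: stop when the relative deviance change
#'   drops below `tol` (default 1e-6) or after `max_iter` iterations (a
#'   non-converged fit is returned flagged, with the last iterate).
#' @return Object of class `gdm_fit`: intercept, non-negative spline
#'   coefficients per predictor, null/residual deviance, percent deviance
#'   explained, per-predictor coefficient sums, bases, convergence log.
#' @export
fit_gdm <- function(table, predictors = NULL, n_splines = 3,
                    knot_quantiles = NULL, max_iter = 100, tol = 1e-6) {
  tab <- tibble::as_tibble(table)
  if (is.null(predictors))
    predictors <- setdiff(names(tab), c("site_i", "site_j", "y"))
  y <- tab$y
  keep <- !is.na(y)
  if (!all(keep)) tab <- tab[keep, , drop = FALSE]
  y <- tab$y
  if (length(unique(y)) < 2) {
    # constant response: the null model is the fit
    nullfit <- gdm_irls(y, matrix(numeric(0), length(y), 0), max_iter, tol)
    bases <- lapply(tab[predictors], ispline_basis, n_splines = n_splines,
                    knot_quantiles = knot_quantiles)
    coefs <- lapply(bases, function(b) numeric(b$n_splines))
    return(new_gdm_fit(nullfit$beta[1], coefs, bases, nullfit$deviance,
                       nullfit$deviance, nullfit, predictors))
  }
  bases <- lapply(tab[predictors], ispline_basis, n_splines = n_splines,
                  knot_quantiles = knot_quantiles)
  blocks <- lapply(predictors, function(p)
    ispline_evaluate(bases[[p]], tab[[p]]))
  X <- do.call(cbind, blocks)
  sizes <- vapply(bases, function(b) b$n_splines, integer(1))
  if (nrow(X) < ncol(X) + 1)
    abort("fewer site pairs than coefficients")
  colnames(X) <- unlist(purrr::map2(predictors, sizes[predictors],
                                    function(p, s) paste0(p, "_I", seq_len(s))))
  fit <- gdm_irls(y, X, max_iter, tol)
  null_fit <- gdm_irls(y, matrix(numeric(0), length(y), 0), max_iter, tol)
  coefs <- split(fit$beta[-1], rep(predictors, sizes[predictors]))
  coefs <- coefs[predictors]
  for (p in predictors) names(coefs[[p]]) <- paste0("I", seq_along(coefs[[p]]))
  new_gdm_fit(fit$beta[1], coefs, bases, fit$deviance, null_fit$deviance,
              fit, predictors)
}

new_gdm_fit <- function(intercept, coefs, bases, deviance, null_deviance,
                        irls, predictors) {
  expl <- if (null_deviance > 0) 100 * (1 - deviance / null_deviance) else 0
  structure(list(intercept = unname(intercept), coefficients = coefs,
                 bases = bases, deviance = deviance,
                 null_deviance = null_deviance,
                 explained = expl, predictors = predictors,
                 converged = irls$converged, iterations = irls$iterations,
                 deviance_trace = irls$deviance_trace),
            class = "gdm_fit")
}

#' @export
print.gdm_fit <- function(x, ...) {
  cat("<gdm_fit>", length(x$predictors), "predictor(s);",
      format(x$explained, digits = 4), "% deviance explained",
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(predictor_contributions(x))
  invisible(x)
}

#' Per-predictor relative contributions
#'
#' The height of a predictor's partial response is the sum of its I-spline
#' coefficients (each basis tops out at 1); relative contribution is that
#' height as a share of the summed heights. Predictors whose coefficients
#' were shrunk to zero stay in the table with 0% contribution.
#'
#' @param fit A `gdm_fit`.
#' @return Tibble: `predictor`, `height` (partial-response maximum),
#'   `contribution` (%). If every height is zero the contributions are `NA`
#'   and a warning is raised.
#' @export
predictor_contributions <- function(fit) {
  h <- vapply(fit$coefficients, sum, numeric(1))
  tot <- sum(h)
  if (tot == 0) {
    warn("all coefficient sums are zero; contributions undefined")
    contrib <- rep(NA_real_, length(h))
  } else contrib <- 100 * h / tot
  tibble::tibble(predictor = fit$predictors, height = unname(h[fit$predictors]),
                 contribution = unname(contrib[fit$predictors]))
}

#' Partial response curve of one predictor
#'
#' The fitted monotone transform `f_p(d) = sum_k w_pk I_pk(d)`, evaluated
#' on a grid: 0 at the grid minimum, the coefficient sum at the maximum,
#' non-decreasing throughout.
#'
#' @param fit A `gdm_fit`.
#' @param predictor Predictor name.
#' @param grid Evaluation points; default 200 points over the knot range.
#' @return Tibble `predictor`, `x`, `f`.
#' @export
partial_response <- function(fit, predictor, grid = NULL) {
  if (!predictor %in% fit$predictors)
    abort(paste0("unknown predictor '", predictor, "'"))
  b <- fit$bases[[predictor]]
  if (is.null(grid))
    grid <- seq(min(b$knots), max(b$knots), length.out = 200)
  f <- drop(ispline_evaluate(b, grid) %*% fit$coefficients[[predictor]])
  tibble::tibble(predictor = predictor, x = grid, f = f)
}

#' @export
tidy.gdm_fit <- function(x, ...) {
  purrr::map_dfr(x$predictors, function(p)
    tibble::tibble(predictor = p,
                   basis = names(x$coefficients[[p]]),
                   estimate = unname(x$coefficients[[p]])))
}

#' @export
glance.gdm_fit <- function(x, ...) {
  tibble::tibble(intercept = x$intercept, deviance = x$deviance,
                 null_deviance = x$null_deviance,
                 explained = x$explained, converged = x$converged,
                 iterations = x$iterations)
}

#' @export
autoplot.gdm_fit <- function(object, ...) {
  curves <- purrr::map_dfr(object$predictors, function(p)
    partial_response(object, p))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$f)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~predictor, scales = "free_x") +
    ggplot2::labs(x = "predictor distance",
                  y = "partial response f(d)") +
    ggplot2::theme_minimal()
}
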