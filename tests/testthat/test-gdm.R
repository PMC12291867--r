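random_dissim <- function(n, seed, scale = 1) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- runif(n * (n - 1) / 2) * scale
  dissim_matrix(m + t(m), "x")
}

test_that("I-spline bases hit their boundary values and are monotone", {
  set.seed(71)
  v <- c(runif(97), 0, 0.5, 1)
  b <- ispline_basis(v)
  expect_equal(b$n_splines, 3L)
  grid <- seq(min(b$knots), max(b$knots), length.out = 500)
  M <- ispline_evaluate(b, grid)
  expect_equal(unname(M[1, ]), c(0, 0, 0))
  expect_equal(unname(M[500, ]), c(1, 1, 1))
  expect_true(all(apply(M, 2, function(cl) all(diff(cl) >= -1e-10))))
  # clamping outside the knot range
  expect_equal(unname(ispline_evaluate(b, min(v) - 1)[1, ]), c(0, 0, 0))
  expect_equal(unname(ispline_evaluate(b, max(v) + 1)[1, ]), c(1, 1, 1))
  expect_error(ispline_basis(rep(2, 10)), "degenerate")
})

test_that("I-splines agree with numerically integrated M-splines", {
  set.seed(72)
  for (ns in c(3, 4)) {
    b <- ispline_basis(runif(150), n_splines = ns)
    g <- seq(min(b$knots), max(b$knots), length.out = 4001)
    M <- ispline_evaluate(b, g)
    for (i in seq_len(ns)) {
      f <- betadrivers:::mspline_eval(g, b$t_full, i, 2)
      num <- cumsum(c(0, (f[-1] + f[-length(f)]) / 2 * diff(g)))
      expect_lt(max(abs(M[, i] - num)), 1e-5)
    }
  }
})

test_that("site-pair tables have one row per unordered pair", {
  resp <- random_dissim(50, seed = 73, scale = 0.9)
  pred <- random_dissim(50, seed = 74)
  tab <- build_sitepair_table(resp, list(p1 = pred))
  expect_equal(nrow(tab), 1225)
  tab2 <- build_sitepair_table(random_dissim(2, 75, 0.5),
                               list(p1 = random_dissim(2, 76)))
  expect_equal(nrow(tab2), 1)
  # permuting site order preserves the row set
  perm <- sample(50)
  resp_p <- dissim_matrix(unclass(resp)[perm, perm], "x")
  tab_p <- build_sitepair_table(resp_p, list(p1 = pred))
  key <- function(t) {
    k <- purrr::map2_chr(t$site_i, t$site_j,
                         function(a, b) paste(sort(c(a, b)), collapse = "|"))
    t[order(k), c("y", "p1")]
  }
  expect_equal(key(tab_p), key(tab), ignore_attr = TRUE)
  bad <- random_dissim(49, seed = 77)
  expect_error(build_sitepair_table(resp, list(p1 = bad)), "site ids")
})

test_that("a noiseless single-predictor link is recovered almost exactly", {
  g <- random_dissim(40, seed = 78)
  y <- 1 - exp(-(0.1 + 2 * unclass(g))); diag(y) <- 0
  tab <- build_sitepair_table(dissim_matrix(y, "y"), list(g = g))
  fit <- fit_gdm(tab)
  expect_gt(glance(fit)$explained, 99)
  expect_true(fit$converged)
  expect_true(all(diff(fit$deviance_trace) <= 1e-9))
  pc <- predictor_contributions(fit)
  expect_equal(pc$contribution, 100)
})

test_that("constant and shuffled responses yield no explained deviance", {
  g <- random_dissim(30, seed = 79)
  y_const <- matrix(0.4, 30, 30, dimnames = dimnames(g)); diag(y_const) <- 0
  tab <- build_sitepair_table(dissim_matrix(y_const, "y"), list(g = g))
  fit <- fit_gdm(tab)
  expect_equal(glance(fit)$explained, 0)
  expect_true(all(unlist(fit$coefficients) == 0))
  # predictor shuffled against response at ~200 pairs (21 sites = 210)
  set.seed(80)
  g2 <- random_dissim(21, seed = 81)
  y2 <- 1 - exp(-(0.2 + unclass(g2))); diag(y2) <- 0
  tab2 <- build_sitepair_table(dissim_matrix(y2, "y"), list(g = g2))
  tab2$g <- sample(tab2$g)
  expect_lt(glance(fit_gdm(tab2))$explained, 5)
})

test_that("fits are invariant to affine predictor rescaling", {
  g <- random_dissim(25, seed = 82)
  set.seed(83)
  y <- 1 - exp(-(0.1 + 1.5 * unclass(g) + 0.2 * matrix(runif(625), 25)))
  y <- (y + t(y)) / 2; diag(y) <- 0
  dimnames(y) <- dimnames(g)
  tab <- build_sitepair_table(dissim_matrix(pmin(y, 1), "y"), list(g = g))
  fit1 <- fit_gdm(tab)
  tab2 <- tab; tab2$g <- 1000 * tab2$g + 5
  fit2 <- fit_gdm(tab2)
  expect_equal(fit1$deviance, fit2$deviance, tolerance = 1e-6)
  expect_equal(glance(fit1)$explained, glance(fit2)$explained,
               tolerance = 1e-4)
})

test_that("partial responses start at zero, end at the coefficient sum,
           and never decrease", {
  g1 <- random_dissim(30, seed = 84)
  g2 <- random_dissim(30, seed = 85)
  y <- 1 - exp(-(0.1 + 1.2 * unclass(g1) + 0.6 * unclass(g2)))
  diag(y) <- 0
  tab <- build_sitepair_table(dissim_matrix(y, "y"),
                              list(a = g1, b = g2))
  fit <- fit_gdm(tab)
  for (p in c("a", "b")) {
    pr <- partial_response(fit, p)
    expect_equal(pr$f[1], 0, tolerance = 1e-10)
    expect_equal(pr$f[nrow(pr)], sum(fit$coefficients[[p]]),
                 tolerance = 1e-10)
    expect_true(all(diff(pr$f) >= -1e-10))
  }
  expect_error(partial_response(fit, "nope"), "unknown")
  # fitted values stay inside (0, 1): eta >= 0 under the constraints
  expect_true(all(unlist(fit$coefficients) >= 0))
  expect_gte(fit$intercept, 0)
  # equal coefficient sums split the contribution 50/50
  h <- predictor_contributions(fit)
  expect_equal(sum(h$contribution), 100)
})

test_that("tidiers expose coefficients and fit statistics", {
  g <- random_dissim(20, seed = 86)
  y <- 1 - exp(-(0.1 + unclass(g))); diag(y) <- 0
  fit <- fit_gdm(build_sitepair_table(dissim_matrix(y, "y"), list(g = g)))
  td <- tidy(fit)
  expect_equal(names(td), c("predictor", "basis", "estimate"))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_true(all(c("deviance", "null_deviance", "explained",
                    "converged") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})
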