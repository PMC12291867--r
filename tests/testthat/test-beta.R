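test_that("pairwise Sorensen partition matches hand-computed cases", {
  # {A,B,C} vs {B,C,D}: a=2, b=1, c=1
  cm <- community_matrix(data.frame(site_id = c("u", "v"),
                                    A = c(1, 0), B = c(1, 1),
                                    C = c(1, 1), D = c(0, 1)))
  p <- tidy(pairwise_sorensen(cm))
  expect_equal(p$beta_sor, 1 / 3)
  expect_equal(p$beta_sim, 1 / 3)
  expect_equal(p$beta_nes, 0)
  # nested {A,B,C,D} vs {A,B}: a=2, b=2, c=0
  cm2 <- community_matrix(data.frame(site_id = c("u", "v"),
                                     A = c(1, 1), B = c(1, 1),
                                     C = c(1, 0), D = c(1, 0)))
  p2 <- tidy(pairwise_sorensen(cm2))
  expect_equal(p2$beta_sor, 1 / 3)
  expect_equal(p2$beta_sim, 0)
  expect_equal(p2$beta_nes, 1 / 3)
  # identical sites
  cm3 <- community_matrix(data.frame(site_id = c("u", "v"),
                                     A = c(2, 2), B = c(1, 1)))
  expect_equal(unlist(tidy(pairwise_sorensen(cm3))[, 3:6]),
               c(value = 0, beta_sor = 0, beta_sim = 0, beta_nes = 0))
})

test_that("pairwise Bray-Curtis partition matches hand-computed cases", {
  # (10,0,5) vs (5,5,5): A=10, B=5, C=5
  cm <- community_matrix(data.frame(site_id = c("i", "j"),
                                    t1 = c(10, 5), t2 = c(0, 5),
                                    t3 = c(5, 5)))
  p <- tidy(pairwise_braycurtis(cm))
  expect_equal(p$d_BC, 1 / 3)
  expect_equal(p$d_BC_bal, 1 / 3)
  expect_equal(p$d_BC_gra, 0)
  # pure gradient: x_j = x_i / 2 with x_i = (2,4,6): A=6, B=6, C=0
  cm2 <- community_matrix(data.frame(site_id = c("i", "j"),
                                     t1 = c(2, 1), t2 = c(4, 2),
                                     t3 = c(6, 3)))
  p2 <- tidy(pairwise_braycurtis(cm2))
  expect_equal(p2$d_BC, 1 / 3)
  expect_equal(p2$d_BC_bal, 0)
  expect_equal(p2$d_BC_gra, 1 / 3)
})

test_that("multi-site indices match hand-computed sums and reduce to the
           pairwise values at N = 2", {
  # {A,B},{B,C},{C,D}: K = 2, Smin = Smax = 4
  cm <- community_matrix(data.frame(site_id = c("s1", "s2", "s3"),
                                    A = c(1, 0, 0), B = c(1, 1, 0),
                                    C = c(0, 1, 1), D = c(0, 0, 1)))
  ms <- multisite_sorensen(cm)
  expect_equal(ms$beta_SOR, 2 / 3)
  expect_equal(ms$beta_SIM, 2 / 3)
  expect_equal(ms$beta_SNE, 0)
  # all-identical sites -> all zero
  cm_id <- community_matrix(data.frame(site_id = c("a", "b", "c"),
                                       t1 = c(3, 3, 3), t2 = c(1, 1, 1)))
  expect_equal(unlist(multisite_sorensen(cm_id)),
               c(beta_SOR = 0, beta_SIM = 0, beta_SNE = 0))
  expect_equal(unlist(multisite_braycurtis(cm_id)),
               c(beta_BC = 0, beta_BC_BAL = 0, beta_BC_GRA = 0))
  # N = 2 reduction, both families
  for (seed in 1:5) {
    cm2 <- random_community(2, 12, seed = seed)
    pw_s <- tidy(pairwise_sorensen(cm2))
    ms_s <- multisite_sorensen(cm2)
    expect_equal(ms_s$beta_SOR, pw_s$beta_sor)
    expect_equal(ms_s$beta_SIM, pw_s$beta_sim)
    pw_b <- tidy(pairwise_braycurtis(cm2))
    ms_b <- multisite_braycurtis(cm2)
    expect_equal(ms_b$beta_BC, pw_b$d_BC)
    expect_equal(ms_b$beta_BC_BAL, pw_b$d_BC_bal)
  }
  expect_error(multisite_sorensen(community_matrix(
    data.frame(site_id = c("a", "b"), t1 = c(1L, 0L)),
    allow_empty_sites = TRUE)), "2 non-empty")
})

test_that("multi-site 3-site toy agrees with a brute-force evaluation of
           the defining sums", {
  m <- matrix(c(2, 0, 1,
                0, 2, 1), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("t1", "t2")))
  cm <- as_community_matrix(m)
  # independent brute force over explicit pairs
  pairs <- combn(3, 2)
  A <- B <- C <- numeric(3)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    A[k] <- sum(pmin(m[i, ], m[j, ]))
    B[k] <- sum(m[i, ]) - A[k]
    C[k] <- sum(m[j, ]) - A[k]
  }
  smin <- sum(pmin(B, C)); smax <- sum(pmax(B, C))
  expect_equal(multisite_braycurtis(cm)$beta_BC,
               (smin + smax) / (2 * sum(A) + smin + smax))
  expect_equal(multisite_braycurtis(cm)$beta_BC_BAL,
               smin / (sum(A) + smin))
})

test_that("pairwise results agree with vegan as an independent oracle", {
  skip_if_not_installed("vegan")
  cm <- random_community(8, 15, seed = 21)
  m <- unclass(cm)
  expect_equal(as.vector(stats::as.dist(unclass(pairwise_braycurtis(cm)))),
               as.vector(vegan::vegdist(m, "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
  ms <- multisite_sorensen(cm)
  vg <- vegan::nestedbetasor(m > 0)
  expect_equal(unname(ms$beta_SOR), unname(vg["sorensen"]),
               tolerance = 1e-12)
  expect_equal(unname(ms$beta_SIM), unname(vg["turnover"]),
               tolerance = 1e-12)
  expect_equal(unname(ms$beta_SNE), unname(vg["nestedness"]),
               tolerance = 1e-12)
})

test_that("adding taxa shared by both sites lowers (never raises)
           pairwise turnover", {
  for (seed in 1:10) {
    cm <- random_community(2, 10, seed = 100 + seed)
    m <- unclass(cm)
    base <- tidy(pairwise_sorensen(cm))$beta_sim
    m2 <- cbind(m, shared1 = c(2, 2), shared2 = c(1, 3))
    aug <- tidy(pairwise_sorensen(as_community_matrix(m2)))$beta_sim
    expect_lte(aug, base + 1e-12)
  }
})

test_that("component summaries report pair counts and additive means", {
  cm <- random_community(16, 20, seed = 31)
  dm <- pairwise_sorensen(cm)
  s <- component_summary(dm)
  expect_equal(s$n_pairs, 16 * 15 / 2)
  expect_equal(s$mean_dissimilarity, s$mean_turnover + s$mean_nestedness)
  expect_equal(s$mean_similarity, 1 - s$mean_dissimilarity)
  # grouped: 6 + 10 sites
  groups <- tibble::tibble(site_id = rownames(cm),
                           group = rep(c("g1", "g2"), c(6, 10)))
  sg <- component_summary(dm, groups)
  expect_equal(sort(sg$n_pairs), c(15, 45))
  # a singleton group is skipped with a warning
  g2 <- tibble::tibble(site_id = rownames(cm),
                       group = c("solo", rep("rest", 15)))
  expect_warning(s2 <- component_summary(dm, g2), "fewer than 2")
  expect_equal(nrow(s2), 1)
})
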