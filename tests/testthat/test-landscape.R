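test_that("buffer masks follow the centre-in-circle rule", {
  g <- uniform_grid(21, cellsize = 10)
  centre <- list(x = 105, y = 105)  # centre of the middle cell
  # radius 1.5 cells: exactly the 9 centres within 15 m (the 3x3 block's
  # corners are at sqrt(2)*10 = 14.14)
  mask <- extract_buffer(g, centre, 15)
  expect_equal(sum(mask), 9)
  # radius covering the whole grid (necessarily partial -> warning)
  expect_equal(sum(suppressWarnings(extract_buffer(g, centre, 1000))),
               21 * 21)
  expect_warning(extract_buffer(g, centre, 300), "partial")
  expect_error(extract_buffer(g, centre, 5), "radius")
  expect_identical(extract_buffer(g, centre, 15), mask)
})

test_that("land-use proportions count masked cells and are translation
           invariant", {
  m <- matrix(1L, 10, 10); m[, 6:10] <- 2L
  g <- tiny_grid(m)
  all_mask <- matrix(TRUE, 10, 10)
  p <- landuse_proportions(g, all_mask)
  expect_equal(unname(p[c("cultivated", "forest")]), c(0.5, 0.5))
  expect_equal(sum(p), 1)
  g_shift <- landuse_grid(m, cellsize = 10, xll = 500, yll = 700)
  expect_equal(landuse_proportions(g_shift, all_mask), p)
  p1 <- landuse_proportions(g, extract_buffer(g, list(x = 25, y = 50), 20))
  expect_equal(unname(p1["cultivated"]), 1)
})

test_that("patch labelling uses 8-neighbour connectivity", {
  all_mask <- matrix(TRUE, 4, 4)
  # single class: one patch
  lab <- patch_label(uniform_grid(4), all_mask)
  expect_equal(length(unique(as.vector(lab))), 1)
  # two diagonal same-class cells merge into one patch
  m <- matrix(2L, 3, 3); m[1, 1] <- 1L; m[2, 2] <- 1L
  lab2 <- patch_label(tiny_grid(m), matrix(TRUE, 3, 3))
  expect_equal(lab2[1, 1], lab2[2, 2])
  # 4x4 checkerboard: each colour's diagonals connect -> 2 patches total
  cb <- matrix(ifelse((outer(1:4, 1:4, "+")) %% 2 == 0, 1L, 2L), 4, 4)
  lab3 <- patch_label(tiny_grid(cb), all_mask)
  expect_equal(length(unique(as.vector(lab3))), 2)
})

test_that("LPI and SHDI match direct counts", {
  m <- matrix(1L, 10, 10); m[1:3, 1:10] <- 2L  # patches of 30 and 70
  lab <- patch_label(tiny_grid(m), matrix(TRUE, 10, 10))
  expect_equal(metric_lpi(lab), 70)
  expect_equal(metric_lpi(patch_label(uniform_grid(5),
                                      matrix(TRUE, 5, 5))), 100)
  expect_equal(metric_shdi(c(a = 1)), 0)
  expect_equal(metric_shdi(c(a = 0.5, b = 0.5)), log(2))
  expect_equal(metric_shdi(rep(1 / 7, 7)), log(7))
  expect_lte(metric_shdi(c(0.6, 0.3, 0.1)), log(3))
})

test_that("CONTAG matches a brute-force adjacency oracle and responds to
           aggregation", {
  cb <- matrix(ifelse((outer(1:8, 1:8, "+")) %% 2 == 0, 1L, 2L), 8, 8)
  g <- tiny_grid(cb)
  mask <- matrix(TRUE, 8, 8)
  # independent oracle: enumerate 4-neighbour adjacencies cell by cell
  oracle_contag <- function(m) {
    classes <- sort(unique(as.vector(m)))
    k <- length(classes)
    gik <- matrix(0, k, k)
    nr <- nrow(m); nc <- ncol(m)
    for (r in 1:nr) for (c in 1:nc) {
      for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
        r2 <- r + d[1]; c2 <- c + d[2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          i <- match(m[r, c], classes); j <- match(m[r2, c2], classes)
          gik[i, j] <- gik[i, j] + 1
        }
      }
    }
    p <- as.vector(table(factor(m, classes))) / length(m)
    pstar <- p * gik / rowSums(gik)
    terms <- pstar[pstar > 0]
    (1 + sum(terms * log(terms)) / (2 * log(k))) * 100
  }
  expect_equal(metric_contag(g, mask), oracle_contag(cb), tolerance = 1e-12)
  # same composition: a random salt-and-pepper mix (near-even adjacency
  # distribution) scores strictly below solid blocks. (A perfect
  # checkerboard is NOT the minimum: its all-unlike adjacencies are fully
  # predictable, which the information-theoretic formula rewards.)
  set.seed(40)
  mixed <- matrix(sample(rep(c(1L, 2L), 32)), 8, 8)
  blocks <- matrix(rep(c(1L, 2L), each = 32), 8, 8)
  expect_gt(metric_contag(tiny_grid(blocks), mask),
            metric_contag(tiny_grid(mixed), mask))
  expect_equal(metric_contag(tiny_grid(mixed), mask),
               oracle_contag(mixed), tolerance = 1e-12)
  # single class is defined as maximum contagion
  expect_equal(metric_contag(uniform_grid(5), matrix(TRUE, 5, 5)), 100)
})

test_that("HAILS is the CI-weighted class share in percent", {
  p <- c(construction = 0.5, grass = 0.5, cultivated = 0, forest = 0,
         water = 0, wetland = 0, bare = 0)
  expect_equal(hails(p, c(construction = 1, grass = 0.067)), 53.35)
  expect_equal(hails(c(construction = 1), c(construction = 1)), 100)
  expect_equal(hails(c(water = 1), c(water = 0)), 0)
  expect_error(hails(c(bare = 0.5, water = 0.5), c(bare = 0)), "water")
})

test_that("metrics are invariant to a consistent class relabelling", {
  set.seed(41)
  m <- matrix(sample(1:3, 144, replace = TRUE), 12, 12)
  mask <- matrix(TRUE, 12, 12)
  g1 <- tiny_grid(m)
  perm <- c(3L, 1L, 2L)                      # 1->3, 2->1, 3->2
  g2 <- tiny_grid(matrix(perm[m], 12, 12))
  expect_equal(metric_contag(g1, mask), metric_contag(g2, mask))
  expect_equal(metric_lpi(patch_label(g1, mask)),
               metric_lpi(patch_label(g2, mask)))
  p1 <- landuse_proportions(g1, mask); p2 <- landuse_proportions(g2, mask)
  expect_equal(metric_shdi(p1), metric_shdi(p2))
  ci <- c(cultivated = 0.3, forest = 0.6, grass = 0.9)
  ci2 <- stats::setNames(ci, names(landuse_classes())[perm[1:3]])
  expect_equal(hails(p1, ci), hails(p2, ci2))
})

test_that("driver tables carry exactly 11 driver columns per site", {
  set.seed(42)
  spec <- synth_spec(n_sites = 6, grid_dim = 60, cellsize = 100,
                     radii = c(200, 500), r_star = 500)
  grid <- gen_landscape(spec)
  sites <- gen_sites(spec, grid)
  dt <- driver_table(grid, sites, 500)
  expect_equal(nrow(dt), 6)
  expect_equal(setdiff(names(dt), c("site_id", "radius")),
               c(paste0("prop_", names(landuse_classes())),
                 "LPI", "CONTAG", "SHDI", "HAILS"))
  expect_identical(dt, driver_table(grid, sites, 500))
  # homogeneous landscape: zero variance in every driver
  g1 <- uniform_grid(60, class = 2L, cellsize = 100)
  dt1 <- driver_table(g1, sites, 500)
  expect_true(all(vapply(dt1[setdiff(names(dt1), c("site_id", "radius"))],
                         function(v) sd(v) == 0, logical(1))))
})
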