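test_that("Gower dissimilarity matches a brute-force loop and hand values", {
  df <- data.frame(mass = c(0, 1, 2), diet = factor(c("f", "f", "o")),
                   act = factor(c("n", "d", "d")),
                   row.names = c("s1", "s2", "s3"))
  G <- gower_matrix(df)
  expect_identical(G, oracle_gower(df))
  # hand check: masses 0 and 1 with range 2, same diet, different activity
  df2 <- data.frame(mass = c(0, 1, 2), diet = factor(c("f", "f", "f")),
                    act = factor(c("n", "d", "d")),
                    row.names = c("s1", "s2", "s3"))
  expect_equal(gower_matrix(df2)["s1", "s2"], (0.5 + 0 + 1) / 3)
  # identical rows: 0; all-different rows at full range: 1
  expect_equal(G["s1", "s1"], 0)
  df3 <- data.frame(mass = c(0, 2), diet = factor(c("f", "o")),
                    act = factor(c("n", "d")), row.names = c("s1", "s2"))
  expect_equal(gower_matrix(df3)["s1", "s2"], 1)
  # random mixed data against the loop oracle
  set.seed(42)
  dfr <- data.frame(a = rnorm(15), b = factor(sample(letters[1:3], 15, TRUE)),
                    c = runif(15), d = factor(sample(c("x", "y"), 15, TRUE)),
                    row.names = sprintf("sp%02d", 1:15))
  expect_equal(gower_matrix(dfr), oracle_gower(dfr), tolerance = 1e-15)
  expect_true(all(gower_matrix(dfr) >= 0 & gower_matrix(dfr) <= 1))
  dfz <- data.frame(a = c(1, 1, 1), b = factor(c("x", "y", "x")),
                    row.names = c("s1", "s2", "s3"))
  expect_warning(gower_matrix(dfz), "zero range")
})

test_that("the matrix regression residuals match hand OLS and sum to zero", {
  # exact linear relation: residuals are all zero
  Dp <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  Dt <- 0.2 + 0.1 * Dp; diag(Dt) <- 0
  r <- phylo_residual(Dt, Dp)
  expect_equal(max(abs(r$residuals)), 0, tolerance = 1e-12)
  expect_equal(r$slope, 0.1, tolerance = 1e-12)
  # 3-species hand example: pairs x = (1,2,3), y = (1,2,4)
  Dp2 <- matrix(0, 3, 3); Dp2[lower.tri(Dp2)] <- c(1, 2, 3)
  Dp2 <- Dp2 + t(Dp2)
  Dt2 <- matrix(0, 3, 3); Dt2[lower.tri(Dt2)] <- c(1, 2, 4)
  Dt2 <- Dt2 + t(Dt2)
  r2 <- phylo_residual(Dt2, Dp2)
  # hand OLS on 3 points: slope 1.5, intercept -2/3
  expect_equal(r2$slope, 1.5, tolerance = 1e-12)
  expect_equal(r2$intercept, -2 / 3, tolerance = 1e-12)
  expect_equal(r2$residuals[lower.tri(r2$residuals)],
               c(1, 2, 4) - (-2 / 3 + 1.5 * c(1, 2, 3)), tolerance = 1e-12)
  # mean residual is zero (OLS with intercept)
  expect_equal(mean(r2$residuals[lower.tri(r2$residuals)]), 0,
               tolerance = 1e-12)
  expect_error(phylo_residual(Dt2, matrix(1, 3, 3) - diag(3)), "constant")
})

test_that("NMDS recovers trivial geometry and is monotone in dimension", {
  pts <- cbind(seq_len(10), 0)
  D <- as.matrix(dist(pts))
  e1 <- nmds_embed(D, k = 1, n_starts = 10, seed = 1)
  expect_lt(e1$stress, 1e-4)
  e2 <- nmds_embed(D, k = 2, n_starts = 10, seed = 1)
  expect_lte(e2$stress, e1$stress + 1e-10)
  # deterministic under a fixed seed
  set.seed(99)
  M <- as.matrix(dist(matrix(rnorm(40), ncol = 2)))
  a <- nmds_embed(M, seed = 7); b <- nmds_embed(M, seed = 7)
  expect_identical(a$points, b$points)
  # coordinates are centered
  expect_equal(colMeans(a$points), c(MDS1 = 0, MDS2 = 0), tolerance = 1e-10)
})

test_that("convex hull areas match the shoelace formula and nest monotonically", {
  sq <- rbind(s1 = c(0, 0), s2 = c(1, 0), s3 = c(1, 1), s4 = c(0, 1))
  h <- hull_areas(sq, list(all = rownames(sq)))
  expect_equal(h$areas$area, 1)
  tri <- rbind(a = c(0, 0), b = c(2, 0), c = c(0, 2))
  expect_equal(hull_areas(tri, list(all = rownames(tri)))$areas$area, 2)
  col <- rbind(a = c(0, 0), b = c(1, 1), c = c(2, 2))
  hc <- hull_areas(col, list(all = rownames(col)))
  expect_equal(hc$areas$area, 0)
  expect_true(hc$areas$degenerate)
  # subset hulls never exceed superset hulls (random embeddings)
  set.seed(3)
  for (i in 1:5) {
    P <- matrix(rnorm(40), ncol = 2,
                dimnames = list(sprintf("x%02d", 1:20), NULL))
    sub <- sample(rownames(P), 8)
    ha <- hull_areas(P, list(all = rownames(P), extant = sub))
    expect_lte(ha$areas$area[2L], ha$areas$area[1L] + 1e-12)
    expect_lte(ha$contraction, 1)
  }
})

test_that("the full ecospace pipeline is seed-deterministic and contracts after extinction", {
  sc <- make_scenario(seed = 21, n_posterior = 2L)
  dat <- data.frame(ln_mass_g = unname(sc$mass[names(sc$mass)]),
                    diet = sub(".*-", "", sc$niche[names(sc$mass)]),
                    activity = sub("-.*", "", sc$niche[names(sc$mass)]),
                    row.names = names(sc$mass))
  eco1 <- build_ecospace(sc$tree, dat, sc$extinct, n_starts = 10, seed = 5)
  eco2 <- build_ecospace(sc$tree, dat, sc$extinct, n_starts = 10, seed = 5)
  expect_identical(eco1$embedding$points, eco2$embedding$points)
  expect_identical(eco1$hulls$areas$area, eco2$hulls$areas$area)
  # the extinct species are the largest-bodied: hull must contract
  expect_lt(eco1$hulls$contraction, 1)
  expect_gte(eco1$hulls$contraction, 0)
  expect_true(eco1$embedding$stress >= 0 && eco1$embedding$stress < 1)
})
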