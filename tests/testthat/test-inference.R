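test_that("one-way ANOVA branch matches a hand-computed sums-of-squares oracle", {
  # textbook 3 x 5 layout
  y <- c(6, 8, 4, 5, 7,
         8, 12, 9, 11, 10,
         13, 9, 11, 8, 12)
  grp <- rep(c("g1", "g2", "g3"), each = 5)
  res <- compare_groups(y, grp)
  expect_identical(res$method, "anova+tukey")

  # explicit SSB / SSW arithmetic
  gm <- mean(y)
  means <- tapply(y, grp, mean)
  ssb <- 5 * sum((means - gm)^2)
  ssw <- sum((y - means[grp])^2)
  f_oracle <- (ssb / 2) / (ssw / 12)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-8)
  expect_equal(res$p_value, pf(f_oracle, 2, 12, lower.tail = FALSE),
               tolerance = 1e-8)

  # Tukey p from the studentized range of the hand-computed MSW
  msw <- ssw / 12
  q12 <- abs(means["g2"] - means["g1"]) / sqrt(msw / 5)
  p12 <- ptukey(q12, 3, 12, lower.tail = FALSE)
  got <- res$pairwise
  row12 <- got[(got$group1 == "g2" & got$group2 == "g1") |
                 (got$group1 == "g1" & got$group2 == "g2"), ]
  expect_equal(row12$p_adj, unname(p12), tolerance = 1e-8)
})

test_that("a single shifted group is the only one flagged", {
  set.seed(12)
  y <- c(rnorm(8), rnorm(8), rnorm(8, mean = 3))
  grp <- rep(c("a", "b", "c"), each = 8)
  res <- compare_groups(y, grp)
  pw <- res$pairwise
  involves_c <- pw$group1 == "c" | pw$group2 == "c"
  expect_true(all(pw$p_adj[involves_c] < 0.05))
  expect_true(all(pw$p_adj[!involves_c] >= 0.05))
  expect_identical(res$letters[["a"]], res$letters[["b"]])
  expect_false(res$letters[["c"]] == res$letters[["a"]])
})

test_that("non-normal residuals route to Kruskal-Wallis with Dunn tests", {
  set.seed(3)
  y <- c(rlnorm(10, sdlog = 2.5), rlnorm(10, sdlog = 2.5),
         rlnorm(10, meanlog = 4, sdlog = 2.5))
  grp <- rep(c("a", "b", "c"), each = 10)
  res <- compare_groups(y, grp)
  expect_identical(res$method, "kruskal+dunn")
  expect_lt(res$shapiro_p, 0.05)
  kw <- kruskal.test(y, factor(grp))
  expect_equal(res$statistic, unname(kw$statistic))
  expect_equal(res$p_value, kw$p.value)
  expect_equal(nrow(res$pairwise), 3L)
  expect_error(compare_groups(1:5, c("a", "a", "a", "a", "b")),
               "at least 2 observations")
})

test_that("group comparison holds its nominal type-I error", {
  set.seed(99)
  rej <- vapply(1:2000, function(i) {
    y <- rnorm(15)
    compare_groups(y, rep(c("a", "b", "c"), each = 5))$p_value < 0.05
  }, logical(1))
  expect_equal(mean(rej), 0.05, tolerance = 0.2)
  expect_lt(abs(mean(rej) - 0.05), 0.01)
})

test_that("PERMANOVA reproduces the four-point hand computation", {
  # 4 sites, two groups of 2, all pairwise distances 1:
  # SS_total = 6 * 1 / 4 = 1.5; SS_within = 2 * (1/2) = 1.0; F = 1
  d <- matrix(1, 4, 4); diag(d) <- 0
  res <- permanova(d, c("a", "a", "b", "b"), n_perm = 99, seed = 1)
  expect_equal(res$observed, 1, tolerance = 1e-12)
  expect_equal(res$r_squared, (1.5 - 1) / 1.5, tolerance = 1e-12)
  # every permutation gives F = 1, so p = 1
  expect_equal(res$p_value, 1)
})

test_that("PERMANOVA agrees with vegan::adonis2 on random fixtures", {
  set.seed(2024)
  for (i in 1:50) {
    n <- sample(8:14, 1)
    g <- sample(rep(c("a", "b", if (i %% 2) "c"), length.out = n))
    while (min(table(g)) < 2) g <- sample(rep(c("a", "b"), length.out = n))
    x <- matrix(rnorm(n * 3), n, 3)
    d <- dist(x)
    mine <- permanova(d, g, n_perm = 9, seed = i)
    ref <- vegan::adonis2(d ~ g, data = data.frame(g = g), permutations = 9)
    expect_equal(mine$observed, ref$F[1], tolerance = 1e-8)
    expect_equal(mine$r_squared, ref$R2[1], tolerance = 1e-8)
  }
})

test_that("PERMANOVA permutation stream is seeded and never reports p = 0", {
  set.seed(8)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 30), 20, 2))
  d <- dist(x)
  g <- rep(c("a", "b"), each = 20)
  r1 <- permanova(d, g, n_perm = 999, seed = 7)
  r2 <- permanova(d, g, n_perm = 999, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  # two tight clusters far apart: minimum attainable p under the +1 rule
  expect_equal(r1$p_value, 1 / 1000)
  expect_error(permanova(matrix(c(0, 1, 2, 0), 2), c("a", "b")), "symmetric")
})

test_that("Moran's I matches ape and finds a planted gradient", {
  set.seed(21)
  xy <- matrix(runif(50, 0, 100), 25, 2)
  v <- rnorm(25)
  mine <- morans_i(v, xy, n_perm = 99, seed = 1)
  w <- 1 / as.matrix(dist(xy)); diag(w) <- 0

  # loop-based arithmetic oracle for the raw inverse-distance statistic
  z <- v - mean(v)
  num <- 0
  for (i in 1:25) for (j in 1:25) num <- num + w[i, j] * z[i] * z[j]
  expect_equal(mine$observed, (25 / sum(w)) * num / sum(z^2),
               tolerance = 1e-10)
  expect_equal(mine$expected, -1 / 24)

  # ape row-standardizes internally; feed the row-standardized matrix to both
  w_std <- w / rowSums(w)
  ref <- ape::Moran.I(v, w)
  mine_std <- morans_i(v, xy, n_perm = 9, seed = 1, weights = w_std)
  expect_equal(mine_std$observed, ref$observed, tolerance = 1e-10)

  grad <- morans_i(xy[, 1] + rnorm(25, sd = 5), xy, n_perm = 999, seed = 2)
  expect_gt(grad$observed, 0)
  expect_lte(grad$p_value, 0.01)

  expect_error(morans_i(rep(1, 25), xy), "constant")
  xy2 <- xy; xy2[2, ] <- xy2[1, ]
  expect_error(morans_i(v, xy2), "duplicate")
})

test_that("Mantel r is the lower-triangle correlation with add-one p", {
  set.seed(4)
  xy <- matrix(runif(40), 20, 2)
  d <- as.matrix(dist(xy))
  same <- mantel_test(d, d, n_perm = 99, seed = 1)
  expect_equal(same$observed, 1)
  expect_equal(same$p_value, 1 / 100)

  # unrelated matrices: r near 0 on average, p roughly uniform
  rs <- vapply(1:30, function(i) {
    b <- as.matrix(dist(matrix(runif(40), 20, 2)))
    mantel_test(d, b, n_perm = 49, seed = i)$observed
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)

  b <- as.matrix(dist(matrix(runif(40), 20, 2)))
  ref <- vegan::mantel(d, b, permutations = 9)
  mine <- mantel_test(d, b, n_perm = 9, seed = 3)
  expect_equal(mine$observed, unname(ref$statistic), tolerance = 1e-10)
})

test_that("permutation p-values are calibrated under the exchangeable null", {
  set.seed(55)
  ps <- vapply(1:400, function(i) {
    x <- matrix(rnorm(24), 12, 2)
    permanova(dist(x), rep(c("a", "b", "c"), each = 4), n_perm = 199,
              seed = i)$p_value
  }, numeric(1))
  expect_true(all(ps > 0))
  expect_equal(mean(ps <= 0.05), 0.05, tolerance = 0.6)
  expect_lt(abs(mean(ps <= 0.05) - 0.05), 0.03)
})
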