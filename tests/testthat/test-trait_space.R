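test_that("allometric standardization matches the log-ratio definition", {
  tab <- make_trait_table()
  std <- standardize_traits(tab)

  # pre-z value of a non-Weber trait is log(trait / webers_length): recover
  # it by inverting the stored constants
  i <- 7L
  raw <- as.numeric(tab[i, "head_width"]) / as.numeric(tab[i, "webers_length"])
  z <- std$individuals[i, "head_width"]
  expect_equal(z * std$scale[["head_width"]] + std$center[["head_width"]],
               log(raw), tolerance = 1e-12)
  # Weber's length is log + z only
  zw <- std$individuals[i, "webers_length"]
  expect_equal(zw * std$scale[["webers_length"]] +
                 std$center[["webers_length"]],
               log(as.numeric(tab[i, "webers_length"])), tolerance = 1e-12)

  # hand value: head_width 0.5 at webers_length 1.0 gives log(0.5)
  one <- tab[1, ]
  one[trait_names()] <- 1
  one$head_width <- 0.5
  tab2 <- rbind(tab, one)
  tab2$individual_id <- sprintf("i%04d", seq_len(nrow(tab2)))
  std2 <- standardize_traits(tab2)
  z2 <- std2$individuals[nrow(tab2), "head_width"]
  expect_equal(z2 * std2$scale[["head_width"]] + std2$center[["head_width"]],
               log(0.5 / 1.0), tolerance = 1e-12)

  # z-scoring reference set is the species means: mean 0, SD 1 there
  expect_equal(unname(colMeans(std$species_means)), rep(0, 8),
               tolerance = 1e-9)
  expect_equal(unname(apply(std$species_means, 2, sd)), rep(1, 8),
               tolerance = 1e-9)

  # reapplication is bit-identical
  expect_identical(std$individuals, standardize_traits(tab)$individuals)
})

test_that("trait tables with missing or non-positive values are rejected", {
  tab <- make_trait_table()
  bad <- tab
  bad$eye_length[3] <- NA
  expect_error(validate_trait_table(bad), "missing")
  bad2 <- tab
  bad2$leg_length[2] <- -0.1
  expect_error(validate_trait_table(bad2), "non-positive.*i0002")
  expect_error(validate_trait_table(tab[, -4]), "missing columns|missing")
})

test_that("PCA on species means is orthonormal, complete and sign-stable", {
  tab <- make_trait_table(n_species = 12, n_per = 8)
  std <- standardize_traits(tab)
  pca <- fit_trait_pca(std)

  L <- pca$loadings
  expect_equal(max(abs(t(L) %*% L - diag(ncol(L)))), 0, tolerance = 1e-9)
  expect_equal(sum(pca$explained_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(pca$explained_fraction) <= 1e-12))
  # sign convention: refitting gives identical loadings
  expect_identical(L, fit_trait_pca(std)$loadings)

  # full back-projection reproduces the standardized species means
  recon <- pca$scores %*% t(L)
  expect_equal(max(abs(recon - sweep(std$species_means, 2, pca$center))), 0,
               tolerance = 1e-8)
})

test_that("collinear two-trait toy puts all variance on axis 1", {
  # 3 species, traits 1 and 2 perfectly collinear, all others constant
  m <- matrix(5, nrow = 3, ncol = 8,
              dimnames = list(NULL, trait_names()))
  m[, 1] <- c(0, 1, 2)
  m[, 2] <- 3 * m[, 1]
  pca <- fit_trait_pca(m)
  expect_equal(pca$explained_fraction[1], 1, tolerance = 1e-9)
  expect_error(fit_trait_pca(m[1, , drop = FALSE]), "at least 2 species")
  expect_error(fit_trait_pca(matrix(1, 3, 8)), "zero-variance")
})

test_that("individual projection is consistent with species scores", {
  tab <- make_trait_table(n_species = 10, n_per = 8)
  std <- standardize_traits(tab)
  pca <- fit_trait_pca(std, retained_axes = 4)
  coords <- project_individuals(pca, std)

  # projecting a species' standardized mean reproduces its PCA score
  proj_means <- project_individuals(pca, std$species_means)
  expect_equal(unname(proj_means),
               unname(pca$scores[, 1:4]), tolerance = 1e-9)

  # the global center maps to the origin
  origin <- project_individuals(pca, matrix(pca$center, 1))
  expect_equal(as.numeric(origin), rep(0, 4), tolerance = 1e-12)

  # brute-force dot-product oracle on random input
  set.seed(42)
  x <- matrix(rnorm(80), 10, 8)
  got <- project_individuals(pca, x)
  expected <- matrix(0, 10, 4)
  for (i in 1:10) {
    for (j in 1:4) {
      expected[i, j] <- sum((x[i, ] - pca$center) * pca$loadings[, j])
    }
  }
  expect_equal(unname(got), expected, tolerance = 1e-9)

  # fingerprint guard
  tab2 <- make_trait_table(seed = 202)
  std2 <- standardize_traits(tab2)
  expect_error(project_individuals(pca, std2), "fingerprint")
})

test_that("six-individual rule: own SDs above, imputed donor-mean SDs below", {
  set.seed(7)
  n <- c(sp_big = 10L, sp_mid = 6L, sp_rare = 2L)
  coords <- data.frame(
    species_id = rep(names(n), n),
    axis1 = rnorm(sum(n)), axis2 = rnorm(sum(n), sd = 2))
  summ <- summarize_species(coords)

  expect_identical(summ$sd_imputed, c(FALSE, FALSE, TRUE))
  big <- coords[coords$species_id == "sp_big", ]
  expect_equal(summ$sd_axis1[summ$species_id == "sp_big"], sd(big$axis1))
  expect_equal(summ$sd_axis2[summ$species_id == "sp_big"], sd(big$axis2))

  # imputed SD is the arithmetic donor-pool mean, per axis
  donors <- summ[!summ$sd_imputed, ]
  expect_equal(summ$sd_axis1[summ$sd_imputed], mean(donors$sd_axis1))
  expect_equal(summ$sd_axis2[summ$sd_imputed], mean(donors$sd_axis2))

  # flag flips exactly at the threshold
  at5 <- summarize_species(coords[-11, ])  # sp_mid down to 5 obs
  expect_true(at5$sd_imputed[at5$species_id == "sp_mid"])
  expect_false(summ$sd_imputed[summ$species_id == "sp_mid"])

  # degenerate: nobody reaches the threshold
  tiny <- coords[c(1:3, 11:13, 17:18), ]
  expect_error(summarize_species(tiny), "donor pool")
})

test_that("imputed SDs never depend on the imputed species' own records", {
  set.seed(8)
  coords <- data.frame(
    species_id = rep(c("a", "b", "c", "rare"), c(8, 8, 8, 3)),
    axis1 = rnorm(27), axis2 = rnorm(27))
  ref <- summarize_species(coords)
  # wildly perturb the rare species' records; its imputed SD must not move
  coords2 <- coords
  coords2$axis1[coords2$species_id == "rare"] <- c(-100, 0, 100)
  got <- summarize_species(coords2)
  expect_equal(got$sd_axis1[got$species_id == "rare"],
               ref$sd_axis1[ref$species_id == "rare"])
})
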