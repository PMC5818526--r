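test_that("Sorensen/Simpson partition matches hand-computed cases", {
  expect_equal(baselga_pair(2, 1, 1),
               c(total = 1 / 3, turnover = 1 / 3, nested = 0),
               tolerance = 1e-12)
  expect_equal(baselga_pair(2, 2, 0),
               c(total = 1 / 3, turnover = 0, nested = 1 / 3),
               tolerance = 1e-12)
  expect_equal(baselga_pair(5, 0, 0),
               c(total = 0, turnover = 0, nested = 0))
  # complete turnover, and the 0/0 turnover convention
  expect_equal(baselga_pair(0, 3, 2)[["turnover"]], 1)
  expect_equal(baselga_pair(0, 3, 0)[["turnover"]], 0)
  expect_error(baselga_pair(0, 0, 0), "positive")
  expect_error(baselga_pair(-1, 1, 1), "non-negative")
})

test_that("partition is additive and symmetric on random triples", {
  set.seed(31)
  res <- t(vapply(1:1000, function(i) {
    abc <- rpois(3, 5)
    if (sum(abc) == 0) abc[1] <- 1
    comp <- baselga_pair(abc[1], abc[2], abc[3])
    swapped <- baselga_pair(abc[1], abc[3], abc[2])
    c(comp, swap_total = swapped[["total"]],
      swap_turn = swapped[["turnover"]])
  }, numeric(5)))
  expect_equal(max(abs(res[, "total"] - res[, "turnover"] - res[, "nested"])),
               0, tolerance = 1e-12)
  expect_true(all(res[, 1:3] >= 0 & res[, 1:3] <= 1))
  expect_identical(res[, "swap_total"], res[, "total"])
  expect_identical(res[, "swap_turn"], res[, "turnover"])
})

test_that("taxonomic beta matrices match a set-arithmetic oracle", {
  set.seed(17)
  comm <- matrix(rbinom(5 * 12, 6, 0.3), 5, 12,
                 dimnames = list(paste0("s", 1:5), paste0("sp", 1:12)))
  comm[rowSums(comm) == 0, 1] <- 1
  bm <- taxonomic_beta(comm)

  expect_equal(unname(diag(bm$total)), rep(0, 5))
  expect_equal(bm$total, t(bm$total))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      si <- which(comm[i, ] > 0); sj <- which(comm[j, ] > 0)
      comp <- baselga_pair(length(intersect(si, sj)),
                           length(setdiff(si, sj)), length(setdiff(sj, si)))
      expect_identical(bm$total[i, j], comp[["total"]])
      expect_identical(bm$turnover[i, j], comp[["turnover"]])
      expect_identical(bm$nested[i, j], comp[["nested"]])
    }
  }
  # additivity over the whole matrix
  expect_equal(bm$total, bm$turnover + bm$nested, tolerance = 1e-12)

  # 25 sites give 300 unique pairs
  big <- matrix(1, 25, 3)
  expect_equal(sum(upper.tri(taxonomic_beta(big)$total)), 300)

  empty <- comm
  empty[2, ] <- 0
  expect_error(taxonomic_beta(empty), "s2")
})

test_that("functional beta separates turnover from nestedness in both modes", {
  g <- grid_1d()
  wide <- species_tpd(grid = g, mean = 0, sd = 2)
  inner <- species_tpd(grid = g, mean = 0, sd = 0.5)
  lo <- species_tpd(grid = g, mean = -3, sd = 0.5)
  hi <- species_tpd(grid = g, mean = 3, sd = 0.5)
  as_comm <- function(tpd, id) {
    tpd$species_id <- id
    community_tpd(list(tpd), 1, site_id = id)
  }
  for (mode in c("volume", "overlap")) {
    same <- functional_beta(list(as_comm(wide, "A"), as_comm(wide, "B")),
                            mode = mode)
    expect_equal(same$total[1, 2], 0, tolerance = 1e-12)
    expect_equal(same$nested[1, 2], 0, tolerance = 1e-12)
    expect_equal(same$total, same$turnover + same$nested, tolerance = 1e-12)
  }

  # support of B strictly inside support of A: pure nestedness (volume mode)
  nest <- functional_beta(list(as_comm(wide, "A"), as_comm(inner, "B")),
                          mode = "volume")
  expect_equal(nest$turnover[1, 2], 0)
  expect_gt(nest$nested[1, 2], 0)
  expect_equal(nest$total[1, 2], nest$nested[1, 2])

  # equal-volume disjoint supports: pure turnover, total 1 (volume mode)
  turn <- functional_beta(list(as_comm(lo, "A"), as_comm(hi, "B")),
                          mode = "volume")
  expect_equal(turn$total[1, 2], 1)
  expect_equal(turn$turnover[1, 2], 1)
  expect_equal(turn$nested[1, 2], 0)

  # overlap mode: disjoint equal-mass supports are pure turnover too
  turn2 <- functional_beta(list(as_comm(lo, "A"), as_comm(hi, "B")),
                           mode = "overlap")
  expect_equal(turn2$total[1, 2], 1, tolerance = 1e-9)
  expect_equal(turn2$nested[1, 2], 0, tolerance = 1e-9)
})

test_that("Bray-Curtis follows its min-sum formula", {
  m <- rbind(a = c(1, 1, 0), b = c(0, 1, 1))
  expect_equal(bray_curtis(m)["a", "b"], 0.5)
  same <- rbind(a = c(2, 3, 1), b = c(2, 3, 1))
  expect_equal(same_val <- bray_curtis(same)["a", "b"], 0)
  disjoint <- rbind(a = c(2, 0), b = c(0, 5))
  expect_equal(bray_curtis(disjoint)["a", "b"], 1)
  zz <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 0))
  expect_error(bray_curtis(zz), "all-zero")
})
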