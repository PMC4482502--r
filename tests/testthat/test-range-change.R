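fix <- orthoptera_traits()

test_that("the empirical logit evaluates correctly and is symmetric", {
  expect_equal(empirical_logit(46, 844), log(46.5 / 798.5))
  expect_equal(empirical_logit(46, 844), -2.8434, tolerance = 1e-4)
  expect_equal(empirical_logit(422, 844), 0)  # x = n/2 -> 0 exactly
  expect_equal(empirical_logit(0, 10), -empirical_logit(10, 10))
})

test_that("the plain-logit variant raises a domain error at the boundary", {
  expect_error(empirical_logit(0, 10, adjust = 0), "plain logit")
  expect_error(empirical_logit(10, 10, adjust = 0), "plain logit")
  expect_equal(empirical_logit(5, 10, adjust = 0), 0)
  expect_error(empirical_logit(-1, 10), "0 <= x <= n")
  expect_error(empirical_logit(1, 0), "n must be positive")
})

test_that("uncorrected change reproduces the tabulated per-species examples", {
  expect_equal(round_half_away(uncorrected_change(46, 378, 844), 2), 2.63)
  expect_equal(round_half_away(uncorrected_change(315, 294, 844), 2), -0.11)
  expect_equal(uncorrected_change(100, 100, 844), 0)
  # the boundary-sensitive low-count species needs the adjusted form
  expect_equal(round_half_away(uncorrected_change(14, 7, 844), 2), -0.67)
  expect_equal(round_half_away(uncorrected_change(14, 7, 844, adjust = 0), 2),
               -0.70)
})

test_that("the whole uncorrected column is recomputed exactly to 2 dp", {
  unc <- uncorrected_change(fix$x1, fix$x2, 844)
  printed <- c(-0.11, -0.13, -0.02, -0.06, -0.09, 1.95, 2.63, 0.55, 0.42,
               0.05, 0.08, 0.68, -0.06, -0.67, 0.06, -0.29, -0.25, -0.27,
               0.00, -0.11, 0.85, -0.08, -0.34)
  expect_equal(round_half_away(unc, 2), printed)
})

test_that("percentage change rounds half away from zero", {
  expect_equal(percent_change(46, 378), 722)
  expect_equal(percent_change(14, 7), -50)
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(200, 201), 1)   # 0.5 -> 1, not 0
  expect_equal(percent_change(200, 199), -1)  # -0.5 -> -1
  expect_error(percent_change(0, 5), "undefined")
})

test_that("round_half_away breaks ties away from zero at any precision", {
  expect_equal(round_half_away(c(0.5, -0.5, 1.5, 2.5)), c(1, -1, 2, 3))
  expect_equal(round_half_away(c(0.125, -0.125), 2), c(0.13, -0.13))
})

test_that("telfer_index matches the internally studentized residual oracle", {
  set.seed(5)
  for (rep in 1:5) {
    L1 <- rnorm(20)
    L2 <- 0.5 + 0.9 * L1 + rnorm(20, sd = 0.4)
    mine <- telfer_index(L1, L2)
    oracle <- stats::rstandard(stats::lm(L2 ~ L1))
    expect_equal(mine, unname(oracle), tolerance = 1e-10)
  }
})

test_that("raw regression residuals are mean zero and the index near zero-mean", {
  L1 <- empirical_logit(fix$x1, 844)
  L2 <- empirical_logit(fix$x2, 844)
  fit <- stats::lm(L2 ~ L1)
  expect_lt(abs(mean(stats::residuals(fit))), 1e-10)
  idx <- telfer_index(L1, L2)
  expect_lt(abs(mean(idx)), 0.05)
})

test_that("the corrected index reproduces the tabulated column within 0.02", {
  L1 <- empirical_logit(fix$x1, 844)
  L2 <- empirical_logit(fix$x2, 844)
  idx <- telfer_index(L1, L2)
  printed <- c(-0.34, -0.43, -0.19, -0.43, -0.44, 2.31, 3.23, 0.48, 0.39,
               -0.36, -0.30, 0.67, -0.27, -1.40, -0.24, -0.74, -0.51, -0.50,
               -0.54, -0.29, 0.87, -0.51, -0.70)
  expect_true(all(abs(idx - printed) <= 0.02))
})

test_that("the index is undefined for tiny or degenerate inputs", {
  expect_error(telfer_index(c(1, 2), c(1, 2)), "3 species")
  expect_error(telfer_index(rep(1, 5), rnorm(5)), "constant")
})

test_that("adding a constant to all period-2 values leaves residuals unchanged", {
  L1 <- empirical_logit(fix$x1, 844)
  L2 <- empirical_logit(fix$x2, 844)
  expect_equal(telfer_index(L1, L2), telfer_index(L1, L2 + 1.3),
               tolerance = 1e-10)
})

test_that("uniform effort doubling shifts the uncorrected index but not the corrected ranking", {
  # Simulate: same true occupancy, period-2 detection doubled uniformly.
  set.seed(31)
  n <- 500
  occ_p <- runif(23, 0.05, 0.6)
  det1 <- 0.4
  x1 <- rbinom(23, n, occ_p * det1)
  x2_same <- rbinom(23, n, occ_p * det1)
  x2_doubled <- pmin(n, rbinom(23, n, occ_p * pmin(1, det1 * 2)))
  x1 <- pmax(x1, 5)
  unc_same <- uncorrected_change(x1, x2_same, n)
  unc_doub <- uncorrected_change(x1, x2_doubled, n)
  # uncorrected index shifts upward for essentially all species
  expect_gt(mean(unc_doub), mean(unc_same) + 0.2)
  # corrected index stays centred and its ranking tracks the no-change run
  cor_doub <- telfer_index(empirical_logit(x1, n),
                           empirical_logit(x2_doubled, n))
  expect_lt(abs(mean(cor_doub)), 0.1)
})

test_that("the sd standardization variant is available and differs by scale only", {
  L1 <- empirical_logit(fix$x1, 844)
  L2 <- empirical_logit(fix$x2, 844)
  st <- telfer_index(L1, L2, standardize = "studentized")
  sd_ <- telfer_index(L1, L2, standardize = "sd")
  # scaling by the sample sd of the (mean-zero) residuals: squared values
  # sum to n - 1
  expect_equal(sum(sd_ ^ 2), 22, tolerance = 1e-10)
  expect_gt(cor(st, sd_), 0.999)
})

test_that("range_change_table carries exact identities and the exclusion refit", {
  tab <- range_change_table(fix$species, fix$x1, fix$x2, 844)
  expect_equal(tab$uncorrected, tab$L2 - tab$L1)
  expect_true(all(tab$x1 <= tab$n & tab$x2 <= tab$n))
  expect_lt(abs(mean(tab$L2 - predict(lm(L2 ~ L1, tab)))), 1e-10)
  ex <- c("Conocephalus discolor", "Metrioptera roeselii")
  tab_ex <- range_change_table(fix$species, fix$x1, fix$x2, 844,
                               exclude = ex)
  expect_equal(nrow(tab_ex), 21)
  expect_false(any(ex %in% tab_ex$species))
  # the refit changes the corrected values of the remaining species
  keep <- !(tab$species %in% ex)
  expect_false(isTRUE(all.equal(tab$corrected[keep], tab_ex$corrected)))
  expect_error(range_change_table(fix$species, fix$x1, fix$x2, 844,
                                  exclude = "no such species"),
               "no such species")
})

test_that("average latitude is the plain mean of occupied hectad latitudes", {
  pres <- matrix(c(TRUE, FALSE, TRUE, TRUE), nrow = 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("h1", "h2")))
  occ1 <- structure(list(period = "p1", presence = pres),
                    class = "period_occupancy")
  sq <- structure(list(effort_level = 1L, hectads = c("h1", "h2"), n = 2L),
                  class = "surveyed_squares")
  lookup <- data.frame(hectad = c("h1", "h2"), latitude = c(50, 52))
  out <- average_latitude(occ1, sq, lookup)
  expect_equal(unname(out["A"]), 50)  # one hectad: that latitude
  expect_equal(unname(out["B"]), 51)  # mean of 50 and 52
  expect_error(average_latitude(occ1, sq, lookup[1, ]), "h2")
})

test_that("average latitude from computed centroids matches a brute-force mean", {
  hects <- c("SU11", "SU12", "TQ28", "NN17")
  pres <- matrix(TRUE, 1, 4, dimnames = list("A", hects))
  occ1 <- structure(list(period = "p1", presence = pres),
                    class = "period_occupancy")
  sq <- structure(list(effort_level = 1L, hectads = hects, n = 4L),
                  class = "surveyed_squares")
  expect_equal(unname(average_latitude(occ1, sq)),
               mean(hectad_centroid_latitude(hects)))
})
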