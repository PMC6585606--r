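test_that("handedness direction is the strict majority of neutral selections", {
  expect_identical(classify_handedness(c("right", "right", "left")),
                   "right")
  expect_identical(classify_handedness(rep("left", 3)), "left")
  expect_identical(classify_handedness(c("left", "right", "both")),
                   "undetermined")
  expect_identical(classify_handedness(c("both", "both", "left")),
                   "left")  # bimanual grasps count toward neither
  expect_error(classify_handedness(character(0)), "no selections")
  expect_error(classify_handedness(c("left", "either")))
})

test_that("preferred-frame transform maps hands through per-child handedness", {
  rec <- data.frame(participant = c(1, 1, 2, 2),
                    hand = c("right", "left", "right", "both"))
  hd <- c("1" = "right", "2" = "left")
  out <- to_preferred_frame(rec, hd)
  expect_equal(out$hand, c("P", "NP", "NP", "both"))
  expect_error(to_preferred_frame(rec, c("1" = "right")), "2")
  expect_error(
    to_preferred_frame(rec, c("1" = "right", "2" = "unknown")), "2")
})

test_that("preferred-frame transform inverts under the handedness map", {
  set.seed(14)
  rec <- data.frame(
    participant = rep(1:12, each = 6),
    hand = sample(c("left", "right", "both"), 72, replace = TRUE,
                  prob = c(0.4, 0.5, 0.1)))
  hd <- stats::setNames(sample(c("left", "right"), 12, replace = TRUE),
                        as.character(1:12))
  fwd <- to_preferred_frame(rec, hd)
  other <- function(h) ifelse(h == "left", "right", "left")
  back <- ifelse(fwd$hand == "both", "both",
                 ifelse(fwd$hand == "P",
                        hd[as.character(fwd$participant)],
                        other(hd[as.character(fwd$participant)])))
  expect_equal(unname(back), rec$hand)
})

test_that("pooling in the preferred frame is invariant to the left/right mix", {
  rec <- data.frame(participant = 1:20,
                    hand = c(rep("right", 10), rep("left", 10)))
  hd <- stats::setNames(c(rep("right", 10), rep("left", 10)),
                        as.character(1:20))
  out <- to_preferred_frame(rec, hd)
  expect_true(all(out$hand == "P"))
})

test_that("chi-squared agrees with the textbook formula on fixed and random tables", {
  r <- chi_squared(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-9)  # 6.6667
  expect_equal(r$df, 1)

  tab3 <- rbind(c(30, 12), c(37, 1), c(52, 0))
  got <- suppressWarnings(chi_squared(tab3))
  want <- oracle_pearson(tab3)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
  expect_equal(got$df, 2)
  expect_equal(got$p, want$p, tolerance = 1e-9)

  # uniform goodness of fit: perfect fit gives statistic 0, p = 1
  g <- chi_squared(c(25, 25))
  expect_equal(g$statistic, 0)
  expect_equal(g$p, 1)
  g2 <- chi_squared(c(30, 12))
  expect_equal(g2$statistic, oracle_gof_uniform(c(30, 12))$statistic,
               tolerance = 1e-9)

  set.seed(6)
  for (i in 1:20) {
    nr <- sample(2:3, 1); nc <- sample(2:3, 1)
    tab <- matrix(sample(1:30, nr * nc, replace = TRUE), nr)
    corr <- nr == 2 && nc == 2 && i %% 2 == 0
    got <- suppressWarnings(chi_squared(tab, corrected = corr))
    want <- oracle_pearson(tab, corrected = corr)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
    expect_equal(got$df, want$df)
  }
  expect_error(chi_squared(rbind(c(0, 0), c(3, 4))), "marginal")
})

test_that("exact McNemar equals the doubled binomial tail", {
  # b = 5, c = 0: p = 2 * 0.5^5
  a <- rep(TRUE, 5); b <- rep(FALSE, 5)
  expect_equal(mcnemar_test(a, b)$p, 0.0625)
  # symmetric discordance: p = 1
  expect_equal(mcnemar_test(c(TRUE, FALSE), c(FALSE, TRUE))$p, 1)
  # no discordant pairs: p = 1 by convention
  expect_equal(mcnemar_test(c(TRUE, FALSE), c(TRUE, FALSE))$p, 1)

  for (b_ in 0:7) for (c_ in 0:7) {
    x <- c(rep(TRUE, b_), rep(FALSE, c_), TRUE, FALSE)
    y <- c(rep(FALSE, b_), rep(TRUE, c_), TRUE, FALSE)  # 2 concordant
    got <- mcnemar_test(x, y)
    expect_equal(got$b, b_); expect_equal(got$c, c_)
    expect_equal(got$p, oracle_mcnemar_exact(b_, c_), tolerance = 1e-12)
  }
  # chi-squared approximation stays close for larger counts
  x <- c(rep(TRUE, 30), rep(FALSE, 12))
  y <- c(rep(FALSE, 30), rep(TRUE, 12))
  approx <- mcnemar_test(x, y, exact = FALSE)
  exact <- mcnemar_test(x, y)
  expect_lt(abs(approx$p - exact$p), 0.02)
})

test_that("proportion tables count preferred-hand use and set aside bimanual grasps", {
  rec <- data.frame(condition = "c", label = "N1",
                    hand = c(rep("P", 10), rep("NP", 5), rep("both", 5)))
  out <- proportion_table(rec)
  expect_equal(out$n, 15)
  expect_equal(out$n_both, 5)
  expect_equal(out$prop_preferred, 10 / 15)

  rec2 <- generate_fixture_cohort(
    4000, list(control = c(N1 = 0.5)), seed = 10)
  p <- proportion_table(rec2)$prop_preferred
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 4000))

  rec3 <- generate_fixture_cohort(50, list(test = c(T3 = 1)), seed = 2)
  expect_equal(proportion_table(rec3)$prop_preferred, 1)
})

test_that("fixture cohorts are reproducible Bernoulli records with validated probabilities", {
  a <- generate_fixture_cohort(30, list(control = c(N1 = 0.4)), seed = 3)
  b <- generate_fixture_cohort(30, list(control = c(N1 = 0.4)), seed = 3)
  expect_identical(a, b)
  expect_true(all(a$hand %in% c("P", "NP")))
  expect_error(
    generate_fixture_cohort(10, list(control = c(N1 = 1.4)), seed = 1),
    "probabilities")
})

test_that("McNemar detects the training effect at subgroup sample sizes", {
  # paired design mirroring the subgroup analysis: preferred-hand use
  # certain in control N1, ~0.57 in test N1, n = 20 children
  n <- 20; p_test <- 0.57
  # analytic power oracle: significant iff the discordant count c
  # (control P, test NP) gives 2 * 0.5^c < 0.05
  c_crit <- which(2 * 0.5^(0:n) < 0.05)[1] - 1
  power_oracle <- sum(stats::dbinom(c_crit:n, n, 1 - p_test))
  set.seed(77)
  hits <- replicate(150, {
    rec <- generate_fixture_cohort(
      n, list(control = c(N1 = 1), test = c(N1 = p_test)),
      seed = sample.int(1e6, 1))
    ctrl <- rec$hand[rec$condition == "control"] == "P"
    tst <- rec$hand[rec$condition == "test"] == "P"
    mcnemar_test(ctrl, tst)$p < 0.05
  })
  expect_gt(mean(hits), 0.5)
  expect_lt(abs(mean(hits) - power_oracle), 0.15)
})
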