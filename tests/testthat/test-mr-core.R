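# Wald ratio, standard IVW, correlated-instrument IVW (GLS), F statistic,
# therapeutic orientation and odds-ratio conversion.

test_that("Wald ratio follows the delta-method formula", {
  inp <- mr_input(0.5, 0.01, 0.25, 0.02)
  est <- wald_ratio(inp)
  expect_equal(est$theta, 0.5)
  expect_equal(est$se, 0.04)
  expect_equal(est$ci_low, 0.5 - 1.96 * 0.04)
  expect_equal(est$n_instruments, 1L)
  # null numerator, ratio symmetry and the beta_x = 0 error
  expect_equal(wald_ratio(mr_input(0.5, 0.01, 0, 0.02))$theta, 0)
  neg <- wald_ratio(mr_input(-0.5, 0.01, -0.25, 0.02))
  expect_equal(neg$theta, est$theta)
  expect_equal(neg$se, est$se)
  expect_error(wald_ratio(mr_input(0, 0.01, 0.2, 0.02)), "beta_x = 0")
})

test_that("standard IVW equals the direct weighted-mean oracle", {
  set.seed(42)
  for (r in 1:5) {
    k <- sample(2:8, 1)
    bx <- runif(k, 0.05, 0.3) * sample(c(-1, 1), k, replace = TRUE)
    sx <- runif(k, 0.005, 0.02)
    by <- rnorm(k, 0.1)
    sy <- runif(k, 0.01, 0.05)
    est <- ivw_standard(mr_input(bx, sx, by, sy))
    oc <- oracle_ivw(bx, by, sy)
    expect_equal(est$theta, oc$theta, tolerance = 1e-12)
    expect_equal(est$se, oc$se, tolerance = 1e-12)
    # permutation invariance
    perm <- sample(k)
    est_p <- ivw_standard(mr_input(bx[perm], sx[perm], by[perm], sy[perm]))
    expect_equal(est_p$theta, est$theta, tolerance = 1e-12)
  }
  # two identical instruments: common ratio, se shrinks by sqrt(2)
  two <- ivw_standard(mr_input(c(0.2, 0.2), c(0.01, 0.01),
                               c(0.1, 0.1), c(0.02, 0.02)))
  one <- wald_ratio(mr_input(0.2, 0.01, 0.1, 0.02))
  expect_equal(two$theta, one$theta, tolerance = 1e-12)
  expect_equal(two$se, one$se / sqrt(2), tolerance = 1e-12)
  expect_error(ivw_standard(mr_input(c(0, 0.2), c(0.01, 0.01),
                                     c(0.1, 0.1), c(0.02, 0.02))),
               "beta_x = 0")
})

test_that("correlated IVW reproduces the frozen explicit-inversion fixture", {
  rho <- 0.3^abs(outer(1:3, 1:3, "-"))
  est <- ivw_correlated(mr_input(c(0.10, 0.20, 0.15), c(0.01, 0.01, 0.01),
                                 c(0.05, 0.11, 0.06), c(0.02, 0.02, 0.03),
                                 rho = rho))
  expect_equal(est$theta, 0.529797979797980, tolerance = 1e-12)
  expect_equal(est$se, 0.095874497088220, tolerance = 1e-12)
  expect_equal(est$method, "ivw_correlated")
})

test_that("correlated IVW collapses to its degenerate cases", {
  # one instrument: identical to the Wald ratio
  w <- wald_ratio(mr_input(0.12, 0.01, -0.03, 0.015))
  c1 <- ivw_correlated(mr_input(0.12, 0.01, -0.03, 0.015))
  expect_equal(c1$theta, w$theta, tolerance = 1e-12)
  expect_equal(c1$se, w$se, tolerance = 1e-12)
  # identity correlation: identical to standard IVW
  bx <- c(0.1, 0.2, 0.15); sx <- rep(0.01, 3)
  by <- c(0.04, 0.1, 0.08); sy <- c(0.02, 0.025, 0.03)
  s <- ivw_standard(mr_input(bx, sx, by, sy))
  c3 <- ivw_correlated(mr_input(bx, sx, by, sy, rho = diag(3)))
  expect_equal(c3$theta, s$theta, tolerance = 1e-12)
  expect_equal(c3$se, s$se, tolerance = 1e-12)
})

test_that("near-collinear instruments raise an error naming the offending pair", {
  rho <- matrix(c(1, 1 - 1e-13, 1 - 1e-13, 1), 2)
  expect_error(
    ivw_correlated(mr_input(c(0.1, 0.1), c(0.01, 0.01), c(0.05, 0.05),
                            c(0.02, 0.02), rho = rho,
                            snps = c("rsA", "rsB"))),
    "most collinear pair: rs[AB] / rs[AB]")
})

test_that("estimator is scale-equivariant and se is monotone in outcome noise", {
  set.seed(7)
  k <- 5
  bx <- runif(k, 0.05, 0.3); sx <- runif(k, 0.005, 0.02)
  by <- rnorm(k, 0.05); sy <- runif(k, 0.01, 0.05)
  rho <- random_corr(k)
  base <- ivw_correlated(mr_input(bx, sx, by, sy, rho = rho))
  for (cc in c(0.5, 3)) {
    sc <- ivw_correlated(mr_input(bx, sx, cc * by, cc * sy, rho = rho))
    expect_equal(sc$theta, cc * base$theta, tolerance = 1e-12)
    expect_equal(sc$se, cc * base$se, tolerance = 1e-12)
  }
  for (infl in c(1.1, 2, 10)) {
    up <- ivw_correlated(mr_input(bx, sx, by, infl * sy, rho = rho))
    expect_gte(up$se, base$se)
  }
})

test_that("F statistic is the mean squared instrument z-score", {
  expect_equal(f_statistic(0.1, 0.01), 100)
  expect_equal(f_statistic(c(0, 0, 0), c(0.1, 0.2, 0.3)), 0)
  bx <- c(0.12, -0.08, 0.2); sx <- c(0.01, 0.02, 0.04)
  expect_equal(f_statistic(bx, sx), mean((bx / sx)^2))
})

test_that("orientation flips to the therapeutic frame and is an involution", {
  est <- ivw_correlated(mr_input(c(0.1, 0.2), c(0.01, 0.01),
                                 c(0.04, 0.08), c(0.02, 0.02)))
  ldl <- drug_target("L", "1", 100, 200, "LDL", therapeutic_direction = -1)
  hdl <- drug_target("H", "1", 100, 200, "HDL", therapeutic_direction = +1)
  o <- orient(est, ldl)
  expect_equal(o$theta, -est$theta)
  expect_equal(o$ci_low, -est$ci_high)
  expect_equal(o$ci_high, -est$ci_low)
  expect_equal(o$se, est$se)
  expect_equal(o$p_value, est$p_value)
  expect_equal(o$orientation_applied, -1)
  # +1 direction is the identity; applying -1 twice restores the original
  expect_equal(orient(est, hdl)$theta, est$theta)
  oo <- orient(o, -1)
  expect_equal(oo$theta, est$theta)
  expect_equal(oo$ci_low, est$ci_low)
  expect_equal(oo$orientation_applied, 1)
})

test_that("odds-ratio conversion exponentiates the estimate and its CI", {
  mk <- function(theta, se) {
    e <- ivw_correlated(mr_input(1, 0.01, theta, se))
    e
  }
  expect_equal(to_odds_ratio(mk(0, 0.1))$or, 1)
  two <- to_odds_ratio(mk(log(2), 1e-12))
  expect_equal(two$or, 2, tolerance = 1e-9)
  expect_equal(two$ci_low, 2, tolerance = 1e-6)
  neg <- to_odds_ratio(mk(-0.3, 0.05))
  expect_equal(neg$or, exp(-0.3))
  expect_equal(neg$ci_low, exp(-0.3 - 1.96 * 0.05))
  expect_equal(neg$ci_high, exp(-0.3 + 1.96 * 0.05))
})

test_that("random-effects option never shrinks the SE and leaves the estimate unchanged", {
  set.seed(31)
  k <- 6
  bx <- runif(k, 0.05, 0.3); sx <- runif(k, 0.005, 0.02)
  by <- bx * 0.5 + rnorm(k, sd = 0.2)  # heterogeneous ratios
  sy <- runif(k, 0.01, 0.05)
  inp <- mr_input(bx, sx, by, sy, rho = random_corr(k))
  fe <- ivw_correlated(inp)
  re <- ivw_correlated(inp, random_effects = TRUE)
  expect_equal(re$theta, fe$theta, tolerance = 1e-12)
  expect_gte(re$se, fe$se)
  # homogeneous ratios: the multiplier floors at 1
  inp0 <- mr_input(bx, sx, bx * 0.5, rep(1, k), rho = diag(k))
  expect_equal(ivw_correlated(inp0, random_effects = TRUE)$se,
               ivw_correlated(inp0)$se, tolerance = 1e-12)
})

test_that("malformed MR inputs are rejected", {
  expect_error(mr_input(c(0.1, 0.2), 0.01, 0.1, 0.02), "equal length")
  expect_error(mr_input(0.1, -0.01, 0.1, 0.02), "positive")
  expect_error(mr_input(c(0.1, 0.2), c(0.01, 0.01), c(0.1, 0.1),
                        c(0.02, 0.02), rho = matrix(c(1, 0.5, 0.4, 1), 2)),
               "symmetric")
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(mr_input(c(0.1, 0.2), c(0.01, 0.01), c(0.1, 0.1),
                        c(0.02, 0.02), rho = bad), "semi-definite")
})
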