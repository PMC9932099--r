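test_that("dilute-regime rule classifies host concentrations", {
  # 0.1 mM host with K = 30.1 mM^-1 violates the rule
  chk <- check_dilute_regime(1e-4, 3.01e4)
  expect_equal(chk$product, 3.01)
  expect_false(chk$pass)
  expect_match(chk$message, "larger uncertainty")

  chk2 <- check_dilute_regime(1e-5, 3.01e4)
  expect_equal(chk2$product, 0.301)
  expect_true(chk2$pass)

  expect_true(check_dilute_regime(1e-5, 1e-9)$pass)
})

test_that("titrant range reproduces the design expressions", {
  rng <- titrant_range(1e-4, 3.01e4)
  expect_equal(unname(rng["G_min"]), 8.3063e-6, tolerance = 1e-4)
  expect_equal(unname(rng["G_max"]), 1.32893e-4, tolerance = 1e-4)

  # zero-host limiting form
  expect_equal(unname(titrant_range(0, 2e4)), c(0.25, 4) / 2e4)

  # homogeneity: K times 10 scales both bounds by one tenth
  expect_equal(titrant_range(1e-4, 3.01e5), titrant_range(1e-4, 3.01e4) / 10)

  # G_min < G_max always
  set.seed(5)
  for (i in 1:25) {
    rng <- titrant_range(10 ^ stats::runif(1, -6, -2),
                         10 ^ stats::runif(1, 0, 7))
    expect_lt(rng[["G_min"]], rng[["G_max"]])
  }
})

test_that("schedules start at zero and span the design window", {
  s3 <- make_schedule(1e-4, 3e4, n_points = 3)
  rng <- titrant_range(1e-4, 3e4)
  expect_equal(s3, c(0, unname(rng)))

  s4 <- make_schedule(1e-4, 3e4, n_points = 4)
  expect_equal(s4[3], sqrt(rng[["G_min"]] * rng[["G_max"]]))  # log midpoint

  s12 <- make_schedule(1e-4, 3e4, n_points = 12)
  expect_identical(s12[1], 0)
  expect_length(s12, 12L)
  expect_true(all(diff(s12) > 0))

  lin <- make_schedule(1e-4, 3e4, n_points = 5, spacing = "linear")
  expect_equal(diff(lin[-1]), rep(diff(lin[2:3]), 3))
})

test_that("free-energy conversion follows -RT ln K", {
  expect_equal(K_to_deltaG(1, 303), 0)
  expect_equal(K_to_deltaG(66500, 303), -6.6865, tolerance = 1e-4)
  expect_equal(rt_energy(303), 0.602, tolerance = 1e-3)
  # strictly decreasing in K, linear in T
  expect_gt(K_to_deltaG(1e3, 300), K_to_deltaG(1e4, 300))
  expect_equal(K_to_deltaG(100, 600), 2 * K_to_deltaG(100, 300))
  expect_error(K_to_deltaG(0), "positive")
  expect_error(K_to_deltaG(-3), "positive")
})

test_that("affinity-energy fit is exact on collinear equal-weight points", {
  rec <- data.frame(host = c("a", "b", "c"),
                    K_mM = exp(c(1, 2, 3)) / 1000,  # ln K = 1, 2, 3 in M^-1
                    K_err_mM = exp(c(1, 2, 3)) / 1000 * 0.1,
                    energy = c(-30, -32, -34),
                    energy_err = c(0, 0, 0),
                    charged = TRUE)
  # zero-residual fixture makes summary.lm grumble about a perfect fit
  f <- suppressWarnings(correlate_affinity_energy(rec))
  expect_equal(f$slope, -0.5, tolerance = 1e-10)
  expect_equal(f$intercept, 1 - 0.5 * 30, tolerance = 1e-8)
  expect_lt(max(abs(f$residuals)), 1e-10)
})

test_that("measured affinities trend with simulation energies as expected", {
  rec <- data.frame(
    host = c("SBX-1", "SBX", "SBX+1", "SBN"),
    K_mM = c(21.7, 30.1, 67, 1.6),
    K_err_mM = c(7.0, 6.2, 23, 0.1),
    energy = c(-30.8, -31.7, -38.6, -35.5),
    energy_err = c(1.4, 0.6, 2.8, 1.2),
    charged = c(TRUE, TRUE, TRUE, FALSE))
  f <- correlate_affinity_energy(rec, temperature = 303)
  # stronger (more negative) energy pairs with larger K: negative slope
  expect_lt(f$slope, 0)
  expect_identical(f$excluded, "SBN")
  expect_equal(f$reference_slope, -1 / 0.6021216, tolerance = 1e-6)
  ord <- order(rec$energy[rec$charged])
  expect_true(all(diff(rec$K_mM[rec$charged][ord]) < 0))
})

test_that("duplicated points act as a single point of doubled weight", {
  rec <- data.frame(host = letters[1:4],
                    K_mM = c(5, 12, 30, 30),
                    K_err_mM = c(0.5, 1, 2, 2),
                    energy = c(-30, -33, -36, -36),
                    energy_err = c(1, 1, 1, 1),
                    charged = TRUE)
  f_dup <- correlate_affinity_energy(rec)
  # same fit from lm with the duplicate row given twice the weight
  y <- log(rec$K_mM[1:3] * 1000)
  sy <- rec$K_err_mM[1:3] / rec$K_mM[1:3]
  v <- sy^2 + f_dup$slope^2 * rec$energy_err[1:3]^2
  w <- 1 / v
  w[3] <- 2 * w[3]
  ref <- stats::lm(y ~ rec$energy[1:3], weights = w)
  expect_equal(f_dup$slope, unname(stats::coef(ref)[2]), tolerance = 1e-6)

  expect_error(correlate_affinity_energy(rec[1:2, ]), "at least 3")
})
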