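test_that("referencing subtracts the internal standard and the first point", {
  raw <- cbind(H3 = c(3.880, 3.900))
  expect_equal(unname(reference_shifts(raw)[, 1]), c(0, 0.020))

  raw_const <- cbind(H3 = c(3.88, 3.88, 3.88))
  expect_true(all(reference_shifts(raw_const) == 0))

  # a +0.002 ppm reference drift with constant raw shifts reads as -0.002
  out <- reference_shifts(cbind(H3 = c(3.88, 3.88)),
                          reference_offset = c(0, 0.002))
  expect_equal(unname(out[, 1]), c(0, -0.002))
  # same via observed acetonitrile positions
  out2 <- reference_shifts(cbind(H3 = c(3.88, 3.88)),
                           acetonitrile_ppm = c(2.014, 2.016))
  expect_equal(out2, out)
})

test_that("predicted shifts follow the fast-exchange population average", {
  m <- one_to_one_model(1e4)
  # bound fraction 3.8197e-5 / 1e-4 at equimolar 1e-4 with K = 1e4
  dd <- predict_shifts(m, c(H3 = 0.100), 1e-4, c(0, 1e-4))
  expect_equal(unname(dd[1, "H3"]), 0)
  expect_equal(unname(dd[2, "H3"]), 0.100 * 3.8196601e-5 / 1e-4,
               tolerance = 1e-6)

  # saturation limit returns the limiting sensitivity
  dd <- predict_shifts(m, c(H3 = 0.100), 1e-4, c(0, 1))
  expect_equal(unname(dd[2, "H3"]), 0.100, tolerance = 1e-4)

  # opposite-sign equal-K orientations cancel exactly
  m2 <- two_orientation_model(2e4, 2e4)
  sens <- rbind(H3 = c(`HG-up` = 0.1, `HG-down` = -0.1))
  dd <- predict_shifts(m2, sens, 1e-4, c(0, 1e-5, 1e-4, 1e-3))
  expect_true(all(abs(dd) < 1e-15))

  expect_error(predict_shifts(m, c(H3 = 0.1), 0, c(0, 1e-4)), "positive")
})

test_that("noiseless global fit recovers the shared constant exactly", {
  d <- make_clean_one_to_one(K = 30.1e3)
  f <- fit_global(d, one_to_one_model(1e3))
  expect_true(f$converged)
  expect_equal(f$constants$beta[1], 30.1e3, tolerance = 1e-6)
  truth <- attr(d, "truth")
  expect_equal(unname(f$sensitivities[, "HG"]),
               unname(truth$sens[rownames(f$sensitivities), "HG"]),
               tolerance = 1e-6)
  # residuals of a converged noiseless fit vanish
  expect_lt(max(abs(f$residuals)), 1e-10)
})

test_that("noisy global fit recovers the constant within its uncertainty", {
  sc <- builtin_scenarios("SBX")
  sc$replicates <- 1L
  d <- generate_titration(sc, seed = 42)[[1]]
  f <- fit_global(d, one_to_one_model(1e3))
  expect_true(f$converged)
  expect_lt(abs(f$constants$beta[1] - 30.1e3), 3 * f$constants$se_beta[1])
  # correlation matrix is a correlation matrix
  cr <- f$correlation
  expect_equal(unname(diag(cr)), rep(1, ncol(cr)))
  expect_equal(cr, t(cr))
  expect_true(all(abs(cr[is.finite(cr)]) <= 1 + 1e-12))
})

test_that("fit is invariant to proton relabeling and unit rescaling", {
  d <- make_clean_one_to_one(K = 5e3)
  f1 <- fit_global(d, one_to_one_model(1e3))

  perm <- rev(seq_len(ncol(d$shifts)))
  d2 <- titration_data(d$total_host, d$total_guest,
                       d$shifts[, perm, drop = FALSE])
  f2 <- fit_global(d2, one_to_one_model(1e3))
  expect_equal(f2$constants$beta, f1$constants$beta, tolerance = 1e-8)

  # concentrations in mM with K in mM^-1 give the same fit after rescaling
  d3 <- titration_data(d$total_host * 1e3, d$total_guest * 1e3, d$shifts)
  f3 <- fit_global(d3, one_to_one_model(1))
  expect_equal(f3$constants$beta * 1e3, f1$constants$beta, tolerance = 1e-6)
})

test_that("fitting a two-orientation model to its own data is flagged degenerate", {
  sc <- scenario("deg", two_orientation_model(2e4, 1e4), host_total = 3e-5,
                 noise_sd = 0, replicates = 1L)
  d <- generate_titration(sc)[[1]]
  f <- fitg_quiet(d, two_orientation_model(1.5e4, 1.5e4))
  expect_true(f$rank_deficient)
  expect_lt(f$rank, ncol(f$correlation))
})

test_that("the profiled objective is stationary at the fitted constant", {
  sc <- builtin_scenarios("SBN")
  sc$replicates <- 1L
  d <- generate_titration(sc, seed = 9)[[1]]
  f <- fit_global(d, one_to_one_model(1e3))
  K <- f$constants$beta[1]
  # profiled RSS computed independently of the fitter internals
  rss_at <- function(k) {
    base <- predict_shifts(one_to_one_model(k), c(b = 1),
                           d$total_host, d$total_guest)[, 1]
    sum(vapply(seq_len(ncol(d$shifts)), function(p) {
      y <- d$shifts[, p]
      s <- sum(base * y) / sum(base * base)
      sum((y - s * base)^2)
    }, numeric(1)))
  }
  expect_equal(rss_at(K), f$rss, tolerance = 1e-8)
  g_opt <- (rss_at(K * 1.001) - rss_at(K * 0.999)) / 0.002
  g_off <- (rss_at(K * 1.201) - rss_at(K * 1.199)) / 0.002
  expect_lt(abs(g_opt), 0.01 * abs(g_off))
})

test_that("two-state fit recovers sandwich constants and reports diagnostics", {
  sc <- builtin_scenarios("SBX+1_two_state")
  sc$noise_sd <- 0
  sc$replicates <- 1L
  d <- generate_titration(sc)[[1]]
  f <- fit2_quiet(d)
  expect_equal(f$K1, 67e3, tolerance = 1e-6)
  expect_equal(f$K2, 2.5e3, tolerance = 1e-6)
  expect_true(is.matrix(f$correlation))
  expect_true(f$max_correlation > 0.9)  # strongly correlated parameters
  expect_match(f$note, "external")
})

test_that("two-state fit on simple 1:1 data collapses the secondary constant", {
  sc <- builtin_scenarios("SBX")
  sc$noise_sd <- 0
  sc$replicates <- 1L
  d <- generate_titration(sc)[[1]]
  expect_warning(f <- fit_two_state(d), "secondary state")
  expect_true(f$low_population)
  expect_lt(f$K2, 100)  # driven to the bound

  # with noise the secondary constant is statistically consistent with zero
  sc$noise_sd <- 0.002
  d2 <- generate_titration(sc, seed = 3)[[1]]
  f2 <- fit2_quiet(d2)
  expect_true(f2$low_population || f2$K2 < 3 * f2$K2_se)
})

test_that("replicate aggregation reproduces mean and n-1 standard deviation", {
  d <- make_clean_one_to_one(K = 28.0e3)
  f <- fit_global(d, one_to_one_model(1e3))
  mk <- function(K) {
    ff <- f
    ff$constants$beta[1] <- K
    ff
  }
  agg <- aggregate_replicates(list(mk(28.0e3), mk(30.0e3), mk(32.3e3)))
  expect_equal(agg$constants$mean, 30.1e3)
  expect_equal(agg$constants$sd / 1e3, 2.1517, tolerance = 1e-4)

  same <- aggregate_replicates(list(mk(3e4), mk(3e4), mk(3e4)))
  expect_equal(same$constants$sd, 0)

  expect_error(aggregate_replicates(list(f)), "at least 2")
  g <- fit_global(d, two_orientation_model(1e4, 1e4))
  expect_error(aggregate_replicates(list(f, g)), "same model")
})

test_that("model adequacy separates monotone, non-monotone and null data", {
  # clean monotone 1:1 data: simple model adequate
  sc <- builtin_scenarios("SBX")
  sc$replicates <- 1L
  d <- generate_titration(sc, seed = 3)[[1]]
  fs <- fit_global(d, one_to_one_model(1e3))
  expect_identical(model_adequacy(d, fs)$verdict, "adequate")

  # engineered sign-reversing proton from a 2:1 state: flagged inadequate
  m <- host_sandwich_model(3e4, 2e4)
  sens <- rbind(H1 = c(HG = 0.002, H2G = 0.12),
                H3 = c(HG = 0.12, H2G = -0.05),
                H5 = c(HG = 0.15, H2G = 0.08),
                H6 = c(HG = 0.03, H2G = 0.02))
  sched <- c(0, exp(seq(log(2e-6), log(1e-3), length.out = 13)))
  sc2 <- scenario("eng", m, sens = sens, host_total = 8e-5,
                  schedule = sched, noise_sd = 0.001, replicates = 1L)
  d2 <- generate_titration(sc2, seed = 11)[[1]]
  fs2 <- fitg_quiet(d2, one_to_one_model(1e4))
  ft2 <- fit2_quiet(d2)
  ad <- model_adequacy(d2, fs2, ft2)
  expect_identical(ad$verdict, "inadequate")
  expect_true(any(ad$per_proton$non_monotonic))

  # pure noise: no binding supported
  scn <- scenario("null", one_to_one_model(1), host_total = 3e-5,
                  schedule = c(0, exp(seq(log(1e-5), log(1e-3),
                                          length.out = 11))),
                  noise_sd = 0.002, replicates = 1L)
  dn <- generate_titration(scn, seed = 5)[[1]]
  fn <- fitg_quiet(dn, one_to_one_model(1e3))
  expect_identical(model_adequacy(dn, fn)$verdict, "no_binding")
})
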