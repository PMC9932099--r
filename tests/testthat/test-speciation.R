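test_that("closed-form 1:1 solution matches hand-evaluated and numeric roots", {
  # no guest -> no complex
  st <- solve_one_to_one(1e-4, 0, 1e4)
  expect_identical(st$complexes[["HG"]], 0)
  expect_identical(st$free_host, 1e-4)

  # saturation: huge K, guest in excess -> host fully bound
  st <- solve_one_to_one(1e-4, 1e-2, 1e9)
  expect_equal(st$complexes[["HG"]], 1e-4, tolerance = 1e-6)

  # quadratic formula by hand: (3 - sqrt(5)) / 2e4
  st <- solve_one_to_one(1e-4, 1e-4, 1e4)
  expect_equal(st$complexes[["HG"]], 3.8196601e-5, tolerance = 1e-7)
  expect_equal(st$complexes[["HG"]], oracle_one_to_one(1e-4, 1e-4, 1e4),
               tolerance = 1e-9)
})

test_that("closed-form solver rejects invalid inputs", {
  expect_error(solve_one_to_one(-1e-4, 1e-4, 1e4), "non-negative")
  expect_error(solve_one_to_one(1e-4, 1e-4, 0), "positive")
})

test_that("species and model constructors enforce their invariants", {
  expect_error(complex_species(0, 1, 1e4), "positive integer")
  expect_error(complex_species(1, -1, 1e4), "non-negative")
  expect_error(complex_species(1, 1, -5), "positive")
  expect_error(complex_species(2, 0, 5), "conformer")
  expect_error(binding_model(complex_species(1, 2, 1e7, "HG2")), "1:1")
  expect_error(binding_model(complex_species(1, 1, 1e4, "A"),
                             complex_species(1, 1, 2e4, "A")), "unique")
})

test_that("general solver agrees with the closed form and conserves mass", {
  set.seed(71)
  for (i in 1:60) {
    K <- 10 ^ stats::runif(1, 0, 6)
    H <- 10 ^ stats::runif(1, -6, -2)
    G <- 10 ^ stats::runif(1, -6, -1)
    m <- one_to_one_model(K)
    st <- solve_speciation(m, H, G)
    ref <- solve_one_to_one(H, G, K)
    expect_equal(st$complexes[["HG"]], ref$complexes[["HG"]],
                 tolerance = 1e-9)
    expect_lt(mass_balance_error(st, m), 1e-10)
  }
})

test_that("multi-state 1:1 models reduce to the effective single constant", {
  set.seed(72)
  for (i in 1:20) {
    K1 <- 10 ^ stats::runif(1, 2, 5)
    K2 <- 10 ^ stats::runif(1, 1, 4)
    H <- 10 ^ stats::runif(1, -5, -3)
    G <- 10 ^ stats::runif(1, -5, -3)
    m2 <- two_orientation_model(K1, K2)
    st2 <- solve_speciation(m2, H, G)
    st1 <- solve_one_to_one(H, G, K1 + K2)
    expect_equal(sum(st2$complexes), st1$complexes[["HG"]],
                 tolerance = 1e-9)
  }
})

test_that("conformer models reduce to the aggregated effective constant", {
  m <- conformer_model(1e4, 0.6)
  expect_equal(effective_one_to_one_constant(m), 1e4 / 1.6)
  st <- solve_speciation(m, 1e-4, 5e-5)
  ref <- solve_one_to_one(1e-4, 5e-5, 1e4 / 1.6)
  expect_equal(st$complexes[["HG"]], ref$complexes[["HG"]], tolerance = 1e-9)
  # conformer population follows the free host
  expect_equal(st$complexes[["H-closed"]], 0.6 * st$free_host,
               tolerance = 1e-12)
})

test_that("effective constant follows the published two-state sum", {
  # 44 + 2.1 mM^-1 aggregates to 46.1 mM^-1
  m <- two_orientation_model(44e3, 2.1e3)
  expect_equal(effective_one_to_one_constant(m) / 1000, 46.1)
  expect_true(is.na(effective_one_to_one_constant(
    guest_sandwich_model(1e4, 1e3))))
  expect_equal(effective_one_to_one_constant(one_to_one_model(5e3)), 5e3)
})

test_that("guest-free and degenerate compositions are handled exactly", {
  m <- host_sandwich_model(1e4, 1e3)
  st <- solve_speciation(m, 1e-4, 0)
  expect_true(all(st$complexes == 0))
  expect_equal(st$free_host, 1e-4)
  st0 <- solve_speciation(m, 0, 0)
  expect_true(all(unlist(st0[c("free_host", "free_guest", "complexes")]) == 0))
  # host-free: nothing can form
  stg <- solve_speciation(m, 0, 1e-3)
  expect_equal(stg$free_guest, 1e-3)
  expect_true(all(stg$complexes == 0))
})

test_that("bound complex is monotone in total guest for 1:1 models", {
  m <- one_to_one_model(3e4)
  G <- seq(0, 5e-4, length.out = 40)
  hg <- vapply(G, function(g) solve_speciation(m, 5e-5, g)$complexes[["HG"]],
               numeric(1))
  expect_true(all(diff(hg) >= -1e-15))
})

test_that("non-1:1 models satisfy mass balance across stiff conditions", {
  models <- list(host_sandwich_model(6.7e4, 2.5e3),
                 guest_sandwich_model(3e4, 5e3),
                 binding_model(complex_species(1, 1, 1e4, "HG"),
                               complex_species(2, 2, 1e12, "H2G2"),
                               name = "with 2:2"))
  for (m in models) {
    for (H in c(1e-6, 1e-4, 1e-2)) {
      for (G in c(1e-6, 1e-4, 1e-2)) {
        st <- solve_speciation(m, H, G)
        expect_lt(mass_balance_error(st, m), 1e-10)
      }
    }
  }
})

test_that("binding models serialize and re-read losslessly", {
  m <- host_sandwich_model(6.7e4, 2.5e3, name = "round trip")
  path <- tempfile(fileext = ".yml")
  write_binding_model(m, path)
  m2 <- read_binding_model(path)
  expect_equal(m2$species, m$species)
  expect_identical(m2$name, "round trip")
})
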