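# Shared fixtures, built in code at test time.

# quiet wrappers: several tests exercise fits whose warnings are expected
fit2_quiet <- function(...) suppressWarnings(fit_two_state(...))
fitg_quiet <- function(...) suppressWarnings(fit_global(...))

# small noiseless 1:1 dataset for fast fitter tests
make_clean_one_to_one <- function(K = 30.1e3, host_total = 3e-5,
                                  n_points = 12) {
  sc <- scenario("fixture", one_to_one_model(K), host_total = host_total,
                 n_points = n_points, noise_sd = 0, replicates = 1L)
  generate_titration(sc)[[1]]
}

# independent oracle for the 1:1 complex concentration: numeric root of the
# mass-balance polynomial, no quadratic formula involved
oracle_one_to_one <- function(H, G, K) {
  if (H == 0 || G == 0) return(0)
  f <- function(x) K * x^2 - (K * (H + G) + 1) * x + K * H * G
  stats::uniroot(f, lower = 0, upper = min(H, G), tol = 1e-18)$root
}
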