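test_that("frequency and phase draws follow their distributions", {
  set.seed(1)
  om <- draw_frequencies(1e4)
  f <- om / (2 * pi)
  expect_lt(abs(mean(f) - 60), 0.05)
  expect_lt(abs(sd(f) - 1), 0.05)

  expect_equal(draw_frequencies(5, sd_hz = 0), rep(2 * pi * 60, 5))

  set.seed(2)
  th <- draw_initial_phases(1e4)
  expect_true(all(th >= 0 & th < 2 * pi))
  expect_lt(Mod(mean(exp(1i * th))), 0.05)  # circular uniformity

  set.seed(3); a <- draw_frequencies(10)
  set.seed(3); b <- draw_frequencies(10)
  expect_identical(a, b)
})

test_that("the order parameter is the mean unit phasor", {
  expect_equal(order_parameter(rep(1.3, 5))$r, 1)
  expect_equal(order_parameter(c(0, pi))$r, 0)
  expect_equal(order_parameter(c(0, pi / 2))$r, sqrt(2) / 2)
  expect_equal(order_parameter(c(0, pi / 2))$phi, pi / 4)
})

test_that("uncoupled oscillators follow the closed-form phase evolution", {
  n <- 5
  C <- matrix(1, n, n); diag(C) <- 0
  set.seed(4)
  om <- draw_frequencies(n)
  th0 <- draw_initial_phases(n)
  tr <- simulate_km(C, om, th0, K = 0, T = 1, dt = 1e-4, burn_in = 0)
  expect_lt(max(abs(tr$theta_final - (th0 + om))), 1e-6)
})

test_that("a symmetric dyad locks exactly above |dOmega|/2", {
  # dphi/dt = dOmega - 2 K sin(phi): lock iff K >= dOmega/2
  C <- matrix(c(0, 1, 1, 0), 2, 2)
  om <- 2 * pi * c(60, 60.5)        # dOmega = pi rad/s, threshold pi/2
  th0 <- c(0, 0.5)
  K_lock <- pi / 2
  below <- summarize_trace(simulate_km(C, om, th0, 0.8 * K_lock, T = 6,
                                       dt = 1e-4, burn_in = 3))
  above <- summarize_trace(simulate_km(C, om, th0, 1.2 * K_lock, T = 6,
                                       dt = 1e-4, burn_in = 3))
  expect_gt(below$metastability, 0.05)   # drifting: r oscillates
  expect_lt(above$metastability, 1e-3)   # locked: r constant
  expect_gt(above$synchrony, below$synchrony)
})

test_that("identical frequencies synchronize fully under coupling", {
  n <- 8
  C <- matrix(1, n, n); diag(C) <- 0
  C <- C / (sum(C) / (n * (n - 1)))
  om <- rep(2 * pi * 60, n)
  set.seed(5)
  th0 <- draw_initial_phases(n)
  tr <- simulate_km(C, om, th0, K = 1, T = 5, dt = 1e-4, burn_in = 0)
  expect_gt(tr$r[length(tr$r)], 0.99)
  expect_true(all(tr$r >= 0 & tr$r <= 1))
})

test_that("trace summaries use the post-burn-in mean and population SD", {
  tr <- structure(list(t = seq(0, 1, by = 0.1), r = rep(0.8, 11),
                       phi = numeric(11), dt = 0.1, burn_in = 0,
                       theta_final = numeric(2)), class = "km_trace")
  s <- summarize_trace(tr)
  expect_equal(s$synchrony, 0.8)
  expect_equal(s$metastability, 0)

  tr$r <- rep(c(0.4, 0.6), length.out = 11)
  tr$burn_in <- 0.05
  s <- summarize_trace(tr, burn_in = 0.05)
  expect_equal(s$synchrony, 0.5)
  expect_equal(s$metastability, 0.1)

  expect_error(summarize_trace(tr, burn_in = 2), "empty post-burn-in")
})

test_that("too-large integration steps trigger the stability guard", {
  C <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(simulate_km(C, 2 * pi * c(60, 61), c(0, 1), K = 1, T = 1,
                           dt = 1e-2, record_every = 1e-2, burn_in = 0),
               "stability error")
})

test_that("halving dt leaves synchrony unchanged at default settings", {
  n <- 20
  set.seed(6)
  W <- random_sc(n, density = 0.5)
  C <- W / (sum(W) / (n * (n - 1)))
  om <- with(list(), {set.seed(7); draw_frequencies(n)})
  th0 <- with(list(), {set.seed(8); draw_initial_phases(n)})
  s1 <- summarize_trace(simulate_km(C, om, th0, K = 0.8, T = 2, dt = 1e-4,
                                    burn_in = 1))
  s2 <- summarize_trace(simulate_km(C, om, th0, K = 0.8, T = 2, dt = 5e-5,
                                    burn_in = 1))
  expect_lt(abs(s1$synchrony - s2$synchrony), 1e-3)
})

test_that("a global phase shift leaves the order-parameter series unchanged", {
  n <- 10
  set.seed(9)
  W <- random_sc(n, density = 0.6)
  C <- W / (sum(W) / (n * (n - 1)))
  om <- draw_frequencies(n)
  th0 <- draw_initial_phases(n)
  t1 <- simulate_km(C, om, th0, K = 0.5, T = 1, dt = 1e-4, burn_in = 0)
  t2 <- simulate_km(C, om, th0 + 1.234, K = 0.5, T = 1, dt = 1e-4,
                    burn_in = 0)
  expect_lt(max(abs(t1$r - t2$r)), 1e-9)
})

test_that("critical couplings implement the 90%-of-max and argmax rules", {
  K <- seq(0, 2, by = 0.25)
  # flat synchrony curve: tie resolved to the first grid point
  crit <- critical_couplings(K, rep(0.7, length(K)), rep(0.1, length(K)))
  expect_equal(crit$Kcrit_syn, 0)
  expect_equal(crit$Kcrit_mts, 0)

  # curve rising to a plateau: first K within 10% of the plateau
  syn <- pmin(K, 1)
  mts <- exp(-(K - 0.75)^2)
  crit <- critical_couplings(K, syn, mts)
  expect_equal(crit$Kcrit_syn, K[which(syn >= 0.9)[1]])
  expect_equal(crit$Kcrit_mts, 0.75)
  expect_equal(crit$auc_synchrony, curve_auc(K, syn))

  # strong coupling on an identical-frequency dyad: metastability -> 0
  C <- matrix(c(0, 1, 1, 0), 2, 2)
  om <- rep(2 * pi * 60, 2)
  s <- summarize_trace(simulate_km(C, om, c(0, 2), K = 5 * pi / 2, T = 4,
                                   dt = 1e-4, burn_in = 2))
  expect_lt(s$metastability, 0.05)
})

test_that("coupling sweeps are reproducible and internally consistent", {
  fine <- small_fine_parcellation(2)
  spec <- population_spec(n_per_group = 2, sexes = "male", fine = fine,
                          seed = 3)
  cm <- generate_population(spec)$subjects[[1]]
  Kg <- seq(0, 2, by = 0.5)
  sw1 <- coupling_sweep(cm, K_grid = Kg, T = 2, dt = 1e-4, burn_in = 1,
                        seed = 11, n_reps = 1)
  sw2 <- coupling_sweep(cm, K_grid = Kg, T = 2, dt = 1e-4, burn_in = 1,
                        seed = 11, n_reps = 1)
  expect_identical(sw1$synchrony, sw2$synchrony)
  expect_true(all(sw1$synchrony >= 0 & sw1$synchrony <= 1))
  expect_true(sw1$Kcrit_syn %in% Kg)
  expect_true(sw1$Kcrit_mts %in% Kg)
  expect_gte(sw1$synchrony[length(Kg)], sw1$synchrony[1])
})
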