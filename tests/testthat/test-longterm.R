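test_that("Psi on the complete graph is the (f'/f)^(N-2) power law", {
  phi <- phi_complete(8)
  expect_equal(psi_ratio(phi, 2, 1), 64, tolerance = 1e-9)
  expect_equal(psi_ratio(phi, 1, 1), 1)
  # cross-check with the exact solver route
  phix <- phi_exact(make_named_graph("complete", 8), "dB-o")
  expect_equal(psi_ratio(phix, 2, 1), 64, tolerance = 1e-7)
})

test_that("nu fitting recovers exact exponents and flags irreversibility", {
  flat <- fit_nu(psi = c(1, 1, 1), ratio = c(0.8, 1.1, 1.3))
  expect_equal(flat$nu, 0)
  expect_equal(flat$max_residual, 0)

  fit <- estimate_nu(phi_complete(8), ratios = c(0.8, 0.9, 1.1, 1.25))
  expect_equal(fit$nu, 6, tolerance = 1e-9)
  expect_lt(fit$max_residual, 1e-9)

  # the finite star is not exactly reversible: residual is non-zero
  fit_star <- estimate_nu(phi_star_reduced(50, "dB-p"))
  expect_gt(fit_star$max_residual, 0)

  expect_error(fit_nu(1, 1.2), class = "evograph_invalid_parameter")
  expect_error(fit_nu(c(1, 1), c(1, 1)), class = "evograph_invalid_parameter")
})

test_that("House-of-Cards stationary moments match numeric integration", {
  expect_equal(hoc_stationary(0, 1, 10)$mean, 5.5, tolerance = 1e-12)
  st <- hoc_stationary(6, 1, 10)
  # independent oracle: direct numerical integration of f^nu on [1, 10]
  Z <- stats::integrate(function(f) f^6, 1, 10)$value
  m1 <- stats::integrate(function(f) f^7, 1, 10)$value / Z
  m2 <- stats::integrate(function(f) f^8, 1, 10)$value / Z
  expect_equal(st$mean, m1, tolerance = 1e-9)
  expect_equal(st$sd, sqrt(m2 - m1^2), tolerance = 1e-9)
  expect_equal(st$mean, 8.7500007875, tolerance = 1e-9)
  # nu = 1 case evaluates to (2/3)(999/99)
  expect_equal(hoc_stationary(1, 1, 10)$mean, (2/3) * 999/99, tolerance = 1e-12)
  # density integrates to one
  expect_equal(stats::integrate(st$density, 1, 10)$value, 1, tolerance = 1e-8)
  expect_error(hoc_stationary(-1, 1, 10), class = "evograph_invalid_parameter")
})

test_that("discrete chain stationary state solves global balance", {
  grid <- c(0.5, 0.75, 1, 1.25, 1.5, 1.75, 2)
  st <- discrete_chain_stationary(phi_complete(8), grid)
  expect_equal(sum(st$pmf), 1, tolerance = 1e-12)
  expect_lt(st$balance_residual, 1e-10)
  # complete graph: exact detailed balance, P(2)/P(0.5) = (2/0.5)^6 = 4096
  expect_equal(st$pmf[7] / st$pmf[1], 4096, tolerance = 1e-8)
  expect_lt(st$detailed_balance_residual, 1e-10)

  single <- discrete_chain_stationary(phi_complete(8), 1.5)
  expect_equal(single$pmf, 1)
  expect_equal(single$mean, 1.5)
})

test_that("the dB-p star attains lower steady-state fitness than well-mixed", {
  grid <- c(0.5, 0.75, 1, 1.25, 1.5, 1.75, 2)
  st_star <- discrete_chain_stationary(
    phi_exact(make_named_graph("star", 8), "dB-p"), grid)
  st_comp <- discrete_chain_stationary(phi_complete(8), grid)
  expect_lt(st_star$mean, st_comp$mean)
})

test_that("origin-fixation MC recovers its exact oracles", {
  # always-accept chain: stationary = proposal distribution, mean 5.5
  st0 <- origin_fixation_mc(function(fp, f) 1, hoc_uniform(1, 10),
                            n_steps = 20000, seed = 31)
  expect_lt(abs(st0$mean - 5.5), 4 * st0$se)

  # complete graph N=8 against the closed-form HoC mean 8.75 (scaled run)
  st <- origin_fixation_mc(phi_complete(8), hoc_uniform(1, 10),
                           n_steps = 30000, seed = 13)
  expect_lt(abs(st$mean - hoc_stationary(6, 1, 10)$mean), 4 * st$se)

  # discrete model agrees with the null-vector solve
  grid <- c(0.5, 0.75, 1, 1.25, 1.5, 1.75, 2)
  std <- origin_fixation_mc(phi_complete(8), neighbour_grid(grid),
                            n_steps = 30000, seed = 17)
  expect_lt(abs(std$mean - discrete_chain_stationary(phi_complete(8), grid)$mean),
            4 * std$se)

  # reproducibility
  again <- origin_fixation_mc(phi_complete(8), hoc_uniform(1, 10),
                              n_steps = 5000, seed = 13)
  expect_identical(origin_fixation_mc(phi_complete(8), hoc_uniform(1, 10),
                                      n_steps = 5000, seed = 13)$mean,
                   again$mean)
})

test_that("psi_ratio signals an infinite ratio on a vanishing denominator", {
  phi_limit <- function(fp, f) limit_complete(fp, f)
  expect_warning(val <- psi_ratio(phi_limit, 2, 1), "infinite")
  expect_identical(val, Inf)
  # both directions vanish at neutrality in the N -> infinity limit
  expect_error(suppressWarnings(psi_ratio(phi_limit, 1, 1)),
               class = "evograph_invalid_parameter")
})
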