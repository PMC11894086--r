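# Frozen expected values below were computed from the closed forms by hand:
#   complete N=8, dB, r=2:  (7/8)(1/2)/(1 - 2^-7) = 896/2032
#   star N=4, dB, centre, r=2:  3/(4 (1 + 2/7)) = 21/36
#   star N=4, dB, leaf,   r=2:  2/((2+4)(9/7))  = 14/54
#   star N=4, dB, temperature:  (3*21/36 + 14/54)/4

test_that("exact solver reproduces the complete-graph closed form", {
  g <- make_named_graph("complete", 8)
  phi <- fixation_per_node_exact(g, "dB-o", fprime = 2, f = 1)
  expect_equal(phi, rep(896/2032, 8), tolerance = 1e-10)
  expect_equal(fixation_complete_closed(8, 2), 896/2032, tolerance = 1e-12)

  for (N in c(3, 5, 10)) {
    gg <- make_named_graph("complete", N)
    for (fp in c(0.6, 1, 1.8)) {
      expect_equal(mean(fixation_per_node_exact(gg, "dB-o", fp)),
                   fixation_complete_closed(N, fp), tolerance = 1e-9)
      # Bd order against the classical birth-death formula
      expect_equal(mean(fixation_per_node_exact(gg, "Bd-o", fp)),
                   fixation_complete_closed(N, fp, order = "Bd"),
                   tolerance = 1e-9)
    }
  }
})

test_that("exact solver reproduces the star closed forms", {
  g4 <- make_named_graph("star", 4)
  phi <- fixation_per_node_exact(g4, "dB-p", fprime = 2)
  expect_equal(phi[1], 21/36, tolerance = 1e-10)
  expect_equal(phi[2], 14/54, tolerance = 1e-10)
  expect_equal(average_fixation(g4, "dB-p", 2), (3 * 21/36 + 14/54) / 4,
               tolerance = 1e-10)
  expect_equal(fixation_star_closed(4, 2, start = "centre"), 21/36)
  expect_equal(fixation_star_closed(4, 2, start = "leaf"), 14/54)
  # neutral centre start simplifies to (N-1)/(2N-2) = 1/2
  expect_equal(fixation_star_closed(6, 1, start = "centre"), 0.5)
})

test_that("kernel-built dense solver agrees with the vectorised solver", {
  for (g in fixture_graphs()[c("star4", "path5", "lollipop5")]) {
    for (rule in c("Bd-o", "dB-o")) {
      for (fp in c(0.7, 1.6)) {
        expect_equal(fixation_per_node_exact(g, rule, fp),
                     oracle_fixation_from_kernel(g, rule, fp),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("neutral conservation: uniform average 1/N, per-node sum 1", {
  for (g in fixture_graphs()) {
    for (ord in c("Bd", "dB")) {
      phi <- fixation_per_node_exact(g, paste0(ord, "-o"), fprime = 1, f = 1)
      expect_equal(sum(phi), 1, tolerance = 1e-9)
      expect_equal(mean(phi), 1 / g$N, tolerance = 1e-10)
    }
  }
})

test_that("reduced star chain matches the full solver and scales up", {
  for (N in c(4, 6, 8)) {
    g <- make_named_graph("star", N)
    for (rule in c("dB-o", "Bd-o")) {
      for (fp in c(0.8, 1, 1.5)) {
        full <- fixation_per_node_exact(g, rule, fp)
        expect_equal(fixation_star_reduced(N, rule, fp, start = "centre"),
                     full[1], tolerance = 1e-9)
        expect_equal(fixation_star_reduced(N, rule, fp, start = "leaf"),
                     full[2], tolerance = 1e-9)
      }
    }
  }
  # large-N temperature-initialised dB star approaches f'/(f+f')
  expect_equal(fixation_star_reduced(2000, "dB-p", 0.8, start = "temperature"),
               limit_star_db_temp(0.8), tolerance = 1e-2)
  # deep deleterious regime stays positive and finite (no LU noise)
  tiny <- fixation_star_reduced(1000, "Bd-p", 0.9, start = "uniform")
  expect_gt(tiny, 0)
  expect_lt(tiny, 1e-80)
})

test_that("closed forms are monotone in mutant fitness", {
  grid <- seq(0.5, 2.5, by = 0.1)
  for (vals in list(fixation_complete_closed(8, grid),
                    fixation_star_closed(8, grid, start = "centre"),
                    fixation_star_closed(8, grid, start = "leaf"),
                    fixation_star_closed(8, grid, start = "temperature"))) {
    expect_true(all(diff(vals) > 0))
  }
})

test_that("large-N limits behave as stated", {
  expect_equal(limit_star_db_temp(1, 1), 0.5)
  expect_equal(limit_star_db_temp(0.5, 1), 1/3)
  expect_equal(limit_complete(0.9, 1), 0)
  expect_equal(limit_complete(2, 1), 0.5)
  # the limiting star profile dominates the limiting complete profile
  fp <- seq(0.2, 3, by = 0.2)
  expect_true(all(limit_star_db_temp(fp) > limit_complete(fp)))
  # finite-N closed form approaches the N -> infinity limit
  expect_equal(fixation_complete_closed(5000, 2), 0.5, tolerance = 1e-3)
})

test_that("mixed-mover average fixation is the lambda-convex combination", {
  g <- make_named_graph("star", 5)
  for (ord in c("Bd", "dB")) {
    off <- average_fixation(g, paste0(ord, "-o"), 1.5)
    par <- average_fixation(g, paste0(ord, "-p"), 1.5)
    mix <- average_fixation(g, sprintf("%s-mix:0.3", ord), 1.5)
    expect_equal(mix, 0.3 * par + 0.7 * off, tolerance = 1e-12)
  }
})

test_that("regular graphs give rule-independent averages", {
  g <- make_named_graph("cycle", 8)
  a <- average_fixation(g, "Bd-o", 1.7)
  b <- average_fixation(g, "Bd-p", 1.7)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("solver guards: disconnected input and capacity", {
  two_comp <- matrix(0, 4, 4)
  two_comp[1, 2] <- two_comp[2, 1] <- 1
  two_comp[3, 4] <- two_comp[4, 3] <- 1
  expect_error(fixation_per_node_exact(evo_graph(two_comp), "dB-o", 2),
               class = "evograph_invalid_parameter")
  big <- make_named_graph("cycle", 17)
  expect_error(fixation_per_node_exact(big, "dB-o", 2),
               class = "evograph_capacity_error")
})
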