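# Origin-fixation (weak mutation) long-term dynamics.
#
# In the low mutation rate regime the population is monomorphic between
# fixation events and its fitness performs a Markov chain with rates
# mu * rho(f'|f) * Phi(f', f). The mutation probability mu multiplies every
# rate and cancels from all stationary quantities; it is therefore not a
# parameter of the solvers below.

#' Fixation probability providers
#'
#' Long-term routines take a provider `phi(fprime, f)` returning the average
#' fixation probability of the underlying short-term process. These
#' constructors wrap the package solvers and memoise repeated evaluations.
#'
#' @param g a connected [evo_graph()].
#' @param rule an [update_rule()] or spec string.
#' @param N population size for the closed-form / reduced providers.
#' @param order `"dB"` or `"Bd"` for the complete-graph closed form.
#' @return a function `(fprime, f) -> probability`.
#' @export
phi_exact <- function(g, rule) {
  rule <- parse_rule(rule)
  cache <- new.env(parent = emptyenv())
  function(fprime, f) {
    key <- paste(fprime, f, sep = "|")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- average_fixation(g, rule, fprime, f)
      cache[[key]] <- val
    }
    val
  }
}

#' @rdname phi_exact
#' @export
phi_complete <- function(N, order = c("dB", "Bd")) {
  order <- match.arg(order)
  function(fprime, f) fixation_complete_closed(N, fprime, f, order = order)
}

#' @rdname phi_exact
#' @export
phi_star_reduced <- function(N, rule) {
  rule <- parse_rule(rule)
  cache <- new.env(parent = emptyenv())
  function(fprime, f) {
    key <- paste(fprime, f, sep = "|")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- fixation_star_reduced(N, rule, fprime, f, start = "rule")
      cache[[key]] <- val
    }
    val
  }
}

#' Ratio of forward and backward fixation probabilities
#'
#' \eqn{\Psi(f', f) = \Phi(f', f) / \Phi(f, f')} compares fixing the mutant
#' against fixing the reverse substitution. When \eqn{\Psi} is a power law
#' \eqn{(f'/f)^\nu}, the origin-fixation chain is reversible and \eqn{\nu}
#' acts as the graph's effective population size.
#'
#' @param phi a provider from [phi_exact()] and friends.
#' @param fprime,f the fitness pair.
#' @return the ratio; `Inf` (with a warning) if the backward probability is
#'   exactly zero while the forward one is positive.
#' @export
psi_ratio <- function(phi, fprime, f) {
  fwd <- phi(fprime, f)
  bwd <- phi(f, fprime)
  if (bwd == 0) {
    if (fwd == 0) stop_invalid("Psi undefined: both fixation probabilities are zero")
    warning("backward fixation probability is zero; Psi is infinite")
    return(Inf)
  }
  fwd / bwd
}

#' Fit the effective population size exponent
#'
#' Least-squares fit of \eqn{\log \Psi = \nu \log(f'/f)} (a line through the
#' origin; the power law has no intercept). The maximum absolute residual is
#' a reversibility diagnostic: zero iff \eqn{\Psi} is exactly a power law on
#' the sampled ratios.
#'
#' @param psi positive ratios \eqn{\Psi(f', f)}.
#' @param ratio the matching fitness ratios f'/f (at least two, not all 1).
#' @return list with `nu`, `residuals`, `max_residual`.
#' @export
fit_nu <- function(psi, ratio) {
  if (length(psi) != length(ratio) || length(psi) < 2)
    stop_invalid("need >= 2 (psi, ratio) pairs")
  if (any(!is.finite(psi)) || any(psi <= 0))
    stop_invalid("all Psi values must be finite and positive")
  lr <- log(ratio)
  if (sum(lr^2) == 0) stop_invalid("fitness ratios are all 1; slope undefined")
  nu <- sum(log(psi) * lr) / sum(lr^2)
  res <- log(psi) - nu * lr
  list(nu = nu, residuals = res, max_residual = max(abs(res)))
}

#' @param ratios fitness ratios at which to evaluate \eqn{\Psi}; the default
#'   window brackets neutrality, where the power-law form is most accurate.
#' @param f resident fitness.
#' @rdname fit_nu
#' @export
estimate_nu <- function(phi, ratios = c(0.9, 0.95, 1.05, 1.1), f = 1) {
  psi <- vapply(ratios, function(r) psi_ratio(phi, r * f, f), numeric(1))
  fit_nu(psi, ratios)
}

#' Mutation models for origin-fixation dynamics
#'
#' `hoc_uniform()` is Kingman's House-of-Cards model with a uniform mutant
#' fitness density on \[f_min, f_max\] independent of the parent's fitness.
#' `neighbour_grid()` is a discrete fitness space with nearest-neighbour
#' proposals: each neighbour is proposed with probability 1/2, and at the
#' boundaries the lost outward proposal becomes a self-loop, preserving the
#' proposal symmetry between neighbouring states.
#'
#' @param f_min,f_max support of the uniform mutant fitness distribution.
#' @param grid strictly increasing fitness values.
#' @return an object of class `mutation_model`.
#' @export
hoc_uniform <- function(f_min, f_max) {
  if (!(f_min < f_max)) stop_invalid("need f_min < f_max")
  if (f_min <= 0) stop_invalid("fitness support must be positive")
  structure(list(type = "hoc_uniform", f_min = f_min, f_max = f_max),
            class = "mutation_model")
}

#' @rdname hoc_uniform
#' @export
neighbour_grid <- function(grid) {
  if (length(grid) < 1 || is.unsorted(grid, strictly = TRUE))
    stop_invalid("grid must be strictly increasing")
  if (any(grid <= 0)) stop_invalid("fitness grid must be positive")
  structure(list(type = "neighbour_grid", grid = grid),
            class = "mutation_model")
}

new_stationary_fitness <- function(type, support, density, mean, sd, nu = NA,
                                   extra = list()) {
  structure(c(list(type = type, support = support, density = density,
                   mean = mean, sd = sd, nu = nu), extra),
            class = "stationary_fitness")
}

#' @export
print.stationary_fitness <- function(x, ...) {
  cat(sprintf("<stationary_fitness (%s): mean = %.6g, sd = %.6g%s>\n",
              x$type, x$mean, x$sd,
              if (is.na(x$nu)) "" else sprintf(", nu = %.6g", x$nu)))
  invisible(x)
}

#' House-of-Cards steady state under a power-law fixation ratio
#'
#' With a uniform mutant fitness distribution on \[f_min, f_max\] and a
#' reversible origin-fixation chain of exponent \eqn{\nu}, the stationary
#' density is \eqn{P^*(f) \propto f^\nu}: selection tilts the House-of-Cards
#' distribution by \eqn{f^\nu}. Mean and standard deviation follow from the
#' \eqn{\nu + 1} and \eqn{\nu + 2} moments in closed form.
#'
#' @param nu effective population size exponent (>= 0).
#' @param f_min,f_max fitness support.
#' @return a `stationary_fitness` object; `$density` is a vectorised density
#'   function on the support.
#' @examples
#' hoc_stationary(0, 1, 10)$mean # flat: 5.5
#' @export
hoc_stationary <- function(nu, f_min, f_max) {
  if (nu < 0) stop_invalid("nu must be >= 0")
  model <- hoc_uniform(f_min, f_max)
  mom <- function(k) (f_max^(nu + k + 1) - f_min^(nu + k + 1)) / (nu + k + 1)
  m0 <- mom(0)
  mean <- mom(1) / m0
  ef2 <- mom(2) / m0
  dens <- function(f) ifelse(f >= f_min & f <= f_max, f^nu / m0, 0)
  new_stationary_fitness(
    "continuous", c(f_min, f_max), dens, mean, sqrt(pmax(ef2 - mean^2, 0)), nu,
    extra = list(moment = m0 / (f_max - f_min), model = model))
}

#' Stationary distribution of the discrete origin-fixation chain
#'
#' Builds the jump chain on a fitness grid with nearest-neighbour proposals
#' (probability 1/2 each; boundary losses become self-loops) and acceptance
#' \eqn{\Phi(f_j, f_i)}, then solves the global-balance equations by a direct
#' left-null-vector solve. Detailed balance is *not* assumed: for most graphs
#' reversibility holds only approximately, and the residual of the
#' detailed-balance construction is reported as a diagnostic.
#'
#' @param phi a fixation probability provider.
#' @param grid strictly increasing fitness values.
#' @return a `stationary_fitness` object with `$pmf`, `$grid`,
#'   `$balance_residual` (global balance, ~1e-15) and
#'   `$detailed_balance_residual` (max deviation of the product construction,
#'   0 iff the chain is reversible).
#' @export
discrete_chain_stationary <- function(phi, grid) {
  model <- neighbour_grid(grid)
  K <- length(grid)
  if (K == 1) {
    return(new_stationary_fitness("discrete", grid, NULL, grid, 0, NA,
                                  extra = list(grid = grid, pmf = 1,
                                               balance_residual = 0,
                                               detailed_balance_residual = 0)))
  }
  P <- matrix(0, K, K)
  for (i in 1:K) for (j in c(i - 1, i + 1)) {
    if (j >= 1 && j <= K) P[i, j] <- 0.5 * phi(grid[j], grid[i])
  }
  if (any(P[cbind(1:(K - 1), 2:K)] == 0) || any(P[cbind(2:K, 1:(K - 1))] == 0))
    stop_invalid("chain is reducible: some neighbour acceptance is zero")
  diag(P) <- 1 - rowSums(P)
  Msys <- rbind(t(diag(K) - P), rep(1, K))
  pi <- qr.solve(Msys, c(rep(0, K), 1))
  resid <- max(abs(as.numeric(pi %*% P) - pi))
  # reversible cross-check: pi_j / pi_i along edges from the rate ratios
  logp <- cumsum(c(0, log(P[cbind(1:(K - 1), 2:K)] /
                            P[cbind(2:K, 1:(K - 1))])))
  pdb <- exp(logp - max(logp)); pdb <- pdb / sum(pdb)
  mean <- sum(pi * grid)
  sd <- sqrt(max(sum(pi * grid^2) - mean^2, 0))
  new_stationary_fitness(
    "discrete", range(grid), NULL, mean, sd, NA,
    extra = list(grid = grid, pmf = pi, balance_residual = resid,
                 detailed_balance_residual = max(abs(pi - pdb)),
                 model = model))
}

#' Monte Carlo origin-fixation dynamics
#'
#' Simulates the fitness jump chain: propose a mutant fitness from the
#' mutation model, accept (the population jumps) with probability
#' \eqn{\Phi(f', f)}, otherwise stay. Every proposal advances the clock by
#' one step -- mutations arrive at a fitness-independent rate, so rejected
#' proposals (self-loops) are counted in the time average.
#'
#' @param phi a fixation probability provider.
#' @param model a [hoc_uniform()] or [neighbour_grid()] mutation model.
#' @param n_steps number of proposal steps.
#' @param seed integer seed.
#' @param burn_in steps discarded before averaging (default `n_steps / 10`).
#' @param f0 initial fitness (default: drawn from the mutant distribution /
#'   the middle grid state).
#' @return a `stationary_fitness` estimate with `$trajectory`, `$se`
#'   (batch-means standard error of the mean, 50 batches), `$n_steps`,
#'   `$burn_in`, `$seed`.
#' @export
origin_fixation_mc <- function(phi, model, n_steps, seed = NULL,
                               burn_in = floor(n_steps / 10), f0 = NULL) {
  if (!inherits(model, "mutation_model")) stop_invalid("model must be a mutation_model")
  if (n_steps <= burn_in) stop_invalid("n_steps must exceed burn_in")
  with_seed(seed, {
    traj <- numeric(n_steps)
    if (model$type == "hoc_uniform") {
      f <- f0 %||% stats::runif(1, model$f_min, model$f_max)
      props <- stats::runif(n_steps, model$f_min, model$f_max)
      us <- stats::runif(n_steps)
      for (t in seq_len(n_steps)) {
        if (us[t] < phi(props[t], f)) f <- props[t]
        traj[t] <- f
      }
    } else {
      grid <- model$grid
      K <- length(grid)
      i <- if (is.null(f0)) (K + 1L) %/% 2L else {
        m <- match(f0, grid)
        if (is.na(m)) stop_invalid("f0 must be a grid value") else m
      }
      dirs <- sample(c(-1L, 1L), n_steps, replace = TRUE)
      us <- stats::runif(n_steps)
      for (t in seq_len(n_steps)) {
        j <- i + dirs[t]
        if (j >= 1L && j <= K && us[t] < phi(grid[j], grid[i])) i <- j
        traj[t] <- grid[i]
      }
    }
    keep <- traj[(burn_in + 1):n_steps]
    nb <- min(50L, length(keep))
    bm <- vapply(split(keep, cut(seq_along(keep), nb, labels = FALSE)),
                 mean, numeric(1))
    new_stationary_fitness(
      "mc", range(keep), NULL, mean(keep), stats::sd(keep), NA,
      extra = list(trajectory = traj, se = stats::sd(bm) / sqrt(nb),
                   n_steps = n_steps, burn_in = burn_in, seed = seed,
                   model = model))
  })
}
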