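# Exact fixation probabilities on the full 2^N configuration space.
#
# The two-type Moran process without mutation is an absorbing Markov chain on
# subsets of nodes; all-wild-type and all-mutant are the absorbing states.
# Fixation probabilities solve (I - P_TT) x = P_T,fix, a sparse M-matrix
# system assembled from per-node flip probabilities.

MAX_FULL_SOLVER_N <- 16L

# Per-node flip probabilities for every configuration row of M (S x N, 0/1
# mutant membership). Returns an S x N matrix: entry (s, i) is the probability
# that one event changes the type of node i when the population is in state s.
flip_probs <- function(A, M, fprime, f, order) {
  N <- ncol(M)
  FF <- f + (fprime - f) * M
  if (order == "Bd") {
    W <- A / rowSums(A)          # W[j, i]: birth at j kills i w.p. 1/deg(j)
    tot <- rowSums(FF)
    mass_mut <- (FF * M) %*% W   # fitness mass of mutant parents hitting i
    mass_wt <- (FF * (1 - M)) %*% W
    P <- ifelse(M == 1, mass_wt, mass_mut) / tot
  } else {
    den <- FF %*% A              # total fitness in the neighbourhood of i
    num <- (FF * M) %*% A        # mutant fitness in the neighbourhood of i
    P <- ifelse(M == 1, (den - num) / den, num / den) / N
  }
  P
}

state_membership <- function(N) {
  S <- 2^N
  s <- 0:(S - 1)
  M <- matrix(0, S, N)
  for (i in 1:N) M[, i] <- as.numeric(bitwAnd(s, 2^(i - 1)) > 0)
  M
}

#' Exact per-node fixation probabilities
#'
#' Solves the absorbing Markov chain over all \eqn{2^N} mutant configurations
#' and returns the fixation probability of a single mutant started on each
#' node. Works for any connected graph with \eqn{N \le 16}; this is the
#' oracle against which the closed forms and reduced solvers are checked.
#'
#' @param g a connected [evo_graph()].
#' @param rule an [update_rule()] or spec string; only the Bd/dB order enters
#'   (the mover choice does not affect mutation-free dynamics).
#' @param fprime mutant fitness.
#' @param f wild-type (resident) fitness.
#' @return numeric vector `phi` of length `N`; `phi[i]` is the probability
#'   that a mutant starting on node i takes over the population.
#' @examples
#' g <- make_named_graph("complete", 4)
#' fixation_per_node_exact(g, "dB-o", fprime = 2)
#' @export
fixation_per_node_exact <- function(g, rule, fprime, f = 1) {
  rule <- parse_rule(rule)
  check_fitness(fprime, f)
  check_connected(g)
  N <- g$N
  if (N > MAX_FULL_SOLVER_N)
    stop_capacity("full-configuration solver supports N <= ", MAX_FULL_SOLVER_N,
                  "; use fixation_star_reduced() for large stars")
  S <- 2^N
  s <- 0:(S - 1)
  M <- state_membership(N)
  P <- flip_probs(g$adjacency, M, fprime, f, rule$order)
  from <- integer(0); to <- integer(0); pr <- numeric(0)
  b <- numeric(S - 2)  # transient states are configurations 1 .. S-2
  for (i in 1:N) {
    tostate <- bitwXor(s, 2^(i - 1))
    p <- P[, i]
    keep <- s >= 1 & s <= S - 2 & p > 0
    fs <- s[keep]; ts <- tostate[keep]; ps <- p[keep]
    hit_full <- ts == S - 1
    b[fs[hit_full]] <- b[fs[hit_full]] + ps[hit_full]
    inner <- !hit_full & ts >= 1
    from <- c(from, fs[inner]); to <- c(to, ts[inner]); pr <- c(pr, ps[inner])
  }
  d <- (1 - rowSums(P))[2:(S - 1)]  # self-loop mass per transient state
  Q <- Matrix::sparseMatrix(i = from, j = to, x = pr, dims = c(S - 2, S - 2))
  Asys <- Matrix::Diagonal(S - 2, 1 - d) - Q
  x <- as.numeric(Matrix::solve(Asys, b))
  x[2^(0:(N - 1))]
}

#' Initialisation-averaged fixation probability
#'
#' The average fixation probability \eqn{\Phi_G = \sum_i p_i \phi_{G,i}}
#' where p is the mutant initialisation distribution induced by the update
#' rule. This is the quantity graphs are classified by.
#'
#' @inheritParams fixation_per_node_exact
#' @return a single probability.
#' @export
average_fixation <- function(g, rule, fprime, f = 1) {
  rule <- parse_rule(rule)
  phi <- fixation_per_node_exact(g, rule, fprime, f)
  sum(initialisation_distribution(g, rule) * phi)
}

# (1 - rho) / (1 - rho^k) evaluated stably, including rho ~ 1 and huge k.
geom_ratio <- function(rho, k) {
  if (rho == 1) return(1 / k)
  lr <- log(rho)
  if (k * lr > 745) {  # rho^k overflows: (1-rho)/(1-rho^k) ~ (rho-1) rho^-k
    return((rho - 1) * exp(-k * lr))
  }
  (1 - rho) / (-expm1(k * lr))
}

#' Closed-form fixation probability on the complete graph
#'
#' Under dB updating a single mutant of fitness f' among N-1 residents of
#' fitness f fixes with probability
#' \deqn{\Phi_C = \frac{N-1}{N}\,\frac{1 - f/f'}{1 - (f/f')^{N-1}},}
#' the classical Moran result scaled by the (N-1)/N chance that the first
#' death event does not remove the mutant itself. Under Bd updating the
#' classical birth-death formula \eqn{(1 - f/f')/(1 - (f/f')^N)} applies.
#' At neutrality both reduce to 1/N.
#'
#' @param N population size (>= 2).
#' @param fprime mutant fitness (vectorised).
#' @param f resident fitness.
#' @param order `"dB"` (default) or `"Bd"`.
#' @return probability (vectorised over `fprime`).
#' @export
fixation_complete_closed <- function(N, fprime, f = 1, order = c("dB", "Bd")) {
  order <- match.arg(order)
  check_fitness(fprime, f)
  if (N < 2) stop_invalid("N must be >= 2")
  vapply(fprime, function(fp) {
    rho <- f / fp
    if (order == "dB") (N - 1) / N * geom_ratio(rho, N - 1)
    else geom_ratio(rho, N)
  }, numeric(1))
}

#' Closed-form fixation probabilities on the star graph (dB updating)
#'
#' Exact finite-N formulas for a mutant starting at the centre or at a leaf
#' of a star on N nodes, and their temperature-weighted average
#' \eqn{((N-1)\phi^\bullet + \phi^\circ)/N}, which is the dB-p average
#' fixation probability.
#'
#' @param N star size (>= 3); the star has one centre and N-1 leaves.
#' @param fprime mutant fitness (vectorised).
#' @param f resident fitness.
#' @param start `"temperature"` (default), `"centre"`, or `"leaf"`.
#' @return probability (vectorised over `fprime`).
#' @examples
#' fixation_star_closed(4, 2, start = "centre") # 21/36
#' @export
fixation_star_closed <- function(N, fprime, f = 1,
                                 start = c("temperature", "centre", "leaf")) {
  start <- match.arg(start)
  check_fitness(fprime, f)
  if (N < 3) stop_invalid("star needs N >= 3")
  r <- fprime / f
  D <- 1 + (N - 2) / (1 + (N - 1) * r)
  centre <- (N - 1) / (N * D)
  leaf <- r / ((N - 2 + 2 * r) * D)
  switch(start,
         centre = centre,
         leaf = leaf,
         temperature = ((N - 1) * centre + leaf) / N)
}

#' Large-N limits of fixation probabilities
#'
#' `limit_star_db_temp()` is the infinite-N limit of the temperature
#' initialised dB star, \eqn{f'/(f + f')}: strictly positive even for
#' deleterious mutants, the hallmark of an amplifier of fixation.
#' `limit_complete()` is the infinite-N complete-graph limit
#' \eqn{\max(0, 1 - f/f')}: deleterious mutants never fix.
#'
#' @param fprime mutant fitness (vectorised).
#' @param f resident fitness.
#' @return probability.
#' @export
limit_star_db_temp <- function(fprime, f = 1) {
  check_fitness(fprime, f)
  fprime / (f + fprime)
}

#' @rdname limit_star_db_temp
#' @export
limit_complete <- function(fprime, f = 1) {
  check_fitness(fprime, f)
  pmax(0, 1 - f / fprime)
}
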