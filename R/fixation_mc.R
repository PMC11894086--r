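#' Monte Carlo fixation probability
#'
#' Forward-simulates the Moran process and reports the fraction of replicates
#' in which the mutant lineage fixed. The simulation runs on the embedded
#' jump chain (self-loop events, which cannot change the configuration, are
#' skipped analytically); absorption probabilities are identical to the full
#' event-by-event process and the step cap counts configuration changes.
#'
#' @param g a connected [evo_graph()] with `N <= 16` (the simulator tabulates
#'   the configuration space once and then replays cheap categorical draws).
#' @param rule an [update_rule()] or spec string.
#' @param fprime mutant fitness.
#' @param f resident fitness.
#' @param n_reps number of independent replicates.
#' @param seed integer seed; same seed gives bitwise identical results.
#' @param start `"init"` to draw the start node from the rule's
#'   initialisation distribution each replicate, or a fixed node index.
#' @param max_steps cap on configuration-changing events per replicate.
#' @return an object of class `mc_estimate`: list with `estimate`,
#'   `se` (binomial standard error), `n_reps`, `fixations`, `seed`.
#' @examples
#' g <- make_named_graph("complete", 4)
#' simulate_fixation(g, "dB-o", fprime = 2, n_reps = 500, seed = 1)
#' @export
simulate_fixation <- function(g, rule, fprime, f = 1, n_reps, seed = NULL,
                              start = "init", max_steps = 1e6) {
  rule <- parse_rule(rule)
  check_fitness(fprime, f)
  check_connected(g)
  if (n_reps < 1) stop_invalid("n_reps must be >= 1")
  N <- g$N
  if (N > MAX_FULL_SOLVER_N)
    stop_capacity("simulate_fixation tabulates 2^N states; N <= ",
                  MAX_FULL_SOLVER_N, " required")
  S <- 2^N
  M <- state_membership(N)
  P <- flip_probs(g$adjacency, M, fprime, f, rule$order)
  s_all <- 0:(S - 1)
  # Conditional successor tables for the embedded (no-self-loop) chain.
  succ_to <- vector("list", S)
  succ_cum <- vector("list", S)
  for (st in 2:(S - 1)) {
    p <- P[st, ]
    nz <- which(p > 0)
    to <- bitwXor(st - 1, 2^(nz - 1)) + 1
    pc <- p[nz] / sum(p[nz])
    succ_to[[st]] <- to
    succ_cum[[st]] <- cumsum(pc)
  }
  if (identical(start, "init")) {
    init <- initialisation_distribution(g, rule)
  } else {
    start <- as.integer(start)
    if (is.na(start) || start < 1 || start > N)
      stop_invalid("start must be 'init' or a node index in 1..N")
  }
  with_seed(seed, {
    fixations <- 0L
    for (rep in seq_len(n_reps)) {
      node <- if (identical(start, "init")) {
        sample.int(N, 1, prob = init)
      } else start
      st <- 1L + 2L^(node - 1L)
      steps <- 0L
      repeat {
        if (st == 1L) break
        if (st == S) { fixations <- fixations + 1L; break }
        steps <- steps + 1L
        if (steps > max_steps)
          stop_sampling("replicate exceeded max_steps without absorbing")
        u <- stats::runif(1)
        cum <- succ_cum[[st]]
        j <- findInterval(u, cum) + 1L
        if (j > length(cum)) j <- length(cum)
        st <- succ_to[[st]][j]
      }
    }
    est <- fixations / n_reps
    structure(list(estimate = est,
                   se = sqrt(est * (1 - est) / n_reps),
                   n_reps = as.integer(n_reps),
                   fixations = fixations,
                   seed = seed),
              class = "mc_estimate")
  })
}

#' @export
print.mc_estimate <- function(x, ...) {
  cat(sprintf("<mc_estimate: %.5f +/- %.5f (%d reps)>\n",
              x$estimate, x$se, x$n_reps))
  invisible(x)
}
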