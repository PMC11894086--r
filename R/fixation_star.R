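# Lumped absorbing chain for the star graph.
#
# Leaves are exchangeable, so the configuration space collapses to
# (centre occupied by a mutant?, number of mutant leaves): 2N states instead
# of 2^N, tractable up to N ~ 1e4. States are laid out along a ladder,
# index(c, m) = 2m + c + 1, making the transition matrix pentadiagonal.
#
# The system (I - P_TT) x = b is solved by banded Gaussian elimination
# WITHOUT pivoting in the natural ladder order. For an M-matrix this
# elimination is cancellation-free in the off-diagonal and right-hand-side
# updates, so the solution is componentwise accurate even when fixation
# probabilities underflow toward 1e-90 (deleterious mutants on large Bd
# stars) -- a regime where generic sparse LU returns noise.

# Solve A x = b for a banded M-matrix stored as B[i, c] = A[i, i + c - 3]
# (five diagonals, offsets -2..2).
band_solve_mmatrix <- function(B, b) {
  n <- length(b)
  for (i in 1:(n - 1)) {
    jmax <- min(i + 2, n)
    for (j in (i + 1):jmax) {
      lij <- B[j, 3 - (j - i)]
      if (lij != 0) {
        fac <- lij / B[i, 3]
        for (k in 0:2) {
          col <- i + k
          if (col <= n) B[j, 3 + col - j] <- B[j, 3 + col - j] - fac * B[i, 3 + k]
        }
        b[j] <- b[j] - fac * b[i]
      }
    }
  }
  x <- numeric(n)
  for (i in n:1) {
    acc <- b[i]
    if (i + 1 <= n) acc <- acc - B[i, 4] * x[i + 1]
    if (i + 2 <= n) acc <- acc - B[i, 5] * x[i + 2]
    x[i] <- acc / B[i, 3]
  }
  x
}

# Centre and leaf fixation probabilities on the star via the lumped chain.
star_reduced_phi <- function(N, order, fprime, f = 1) {
  L <- N - 1
  idx <- function(cc, m) 2 * m + cc + 1     # 1 .. 2N; (0,0) and (1,L) absorb
  nstate <- 2L * N
  n <- nstate - 2L                          # transient rows are idx 2..2N-1
  B <- matrix(0, n, 5)
  b <- numeric(n)
  diagsum <- numeric(n)
  add <- function(fr, t, p) {
    for (q in seq_along(fr)) {
      if (p[q] <= 0) next                   # also skips flows out of absorbers
      ti <- fr[q] - 1L
      diagsum[ti] <<- diagsum[ti] + p[q]
      if (t[q] == nstate) b[ti] <<- b[ti] + p[q]
      else if (t[q] != 1L) B[ti, 3L + t[q] - fr[q]] <<- B[ti, 3L + t[q] - fr[q]] - p[q]
    }
  }
  m <- 0:L
  if (order == "dB") {
    pm <- m * fprime / (m * fprime + (L - m) * f)  # mutant wins centre contest
    add(idx(0, m), idx(1, m), pm / N)
    up <- m > 0
    add(idx(0, m[up]), idx(0, m[up] - 1), m[up] / N)
    add(idx(1, m), idx(0, m), (1 - pm) / N)
    add(idx(1, m), idx(1, m + 1), (L - m) / N)
  } else {
    W0 <- f + m * fprime + (L - m) * f      # total fitness, wild-type centre
    W1 <- fprime + m * fprime + (L - m) * f # total fitness, mutant centre
    up <- m > 0
    add(idx(0, m[up]), idx(0, m[up] - 1), (f / W0[up]) * (m[up] / L))
    add(idx(0, m), idx(1, m), m * fprime / W0)
    add(idx(1, m), idx(1, m + 1), (fprime / W1) * ((L - m) / L))
    add(idx(1, m), idx(0, m), (L - m) * f / W1)
  }
  B[, 3] <- diagsum                         # diag of (I - P_TT): outflow mass
  x <- band_solve_mmatrix(B, b)
  c(centre = x[idx(1, 0) - 1L], leaf = x[idx(0, 1) - 1L])
}

#' Reduced-chain fixation probabilities on the star graph
#'
#' Exploits leaf exchangeability to solve the star's absorbing chain with 2N
#' states instead of \eqn{2^N}, for either update order and stars up to
#' N ~ 1e4. Agrees with [fixation_per_node_exact()] to solver precision and
#' stays accurate deep into the deleterious regime where fixation
#' probabilities are astronomically small.
#'
#' @param N star size (>= 3).
#' @param rule an [update_rule()] or spec string. Determines the Bd/dB order
#'   and, for `start = "rule"`, the initialisation weighting (including mixed
#'   lambda).
#' @param fprime mutant fitness (vectorised).
#' @param f resident fitness.
#' @param start `"rule"` (average under the rule's own initialisation),
#'   `"temperature"`, `"uniform"`, `"centre"`, or `"leaf"`.
#' @return probability (vectorised over `fprime`).
#' @examples
#' fixation_star_reduced(4, "dB-p", 2, start = "centre") # matches closed form
#' @export
fixation_star_reduced <- function(N, rule, fprime, f = 1,
                                  start = c("rule", "temperature", "uniform",
                                            "centre", "leaf")) {
  rule <- parse_rule(rule)
  start <- match.arg(start)
  check_fitness(fprime, f)
  if (N < 3) stop_invalid("star needs N >= 3")
  vapply(fprime, function(fp) {
    ph <- star_reduced_phi(N, rule$order, fp, f)
    temp_avg <- ((N - 1) * ph[["centre"]] + ph[["leaf"]]) / N
    unif_avg <- (ph[["centre"]] + (N - 1) * ph[["leaf"]]) / N
    switch(start,
           centre = ph[["centre"]],
           leaf = ph[["leaf"]],
           temperature = temp_avg,
           uniform = unif_avg,
           rule = {
             w_temp <- if (rule$order == "Bd") 1 - rule$lambda else rule$lambda
             w_temp * temp_avg + (1 - w_temp) * unif_avg
           })
  }, numeric(1))
}
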