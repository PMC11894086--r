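# Independent oracles kept deliberately naive.

# Breadth-first-search connectivity, independent of igraph.
oracle_connected <- function(A) {
  N <- nrow(A)
  seen <- rep(FALSE, N)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(A[v, ] == 1 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Dense absorbing-chain fixation solver built from step_kernel() alone.
# Enumerates all 2^N states through the public kernel, so it shares no code
# with the vectorised machinery inside fixation_per_node_exact().
oracle_fixation_from_kernel <- function(g, rule, fprime, f = 1) {
  N <- g$N
  S <- 2^N
  state_of <- function(s) which(bitwAnd(s, 2^(0:(N - 1))) > 0)
  id_of <- function(state) sum(2^(state - 1)) + 1
  P <- matrix(0, S, S)
  P[1, 1] <- 1
  P[S, S] <- 1
  for (s in 1:(S - 2)) {
    k <- step_kernel(g, rule, state_of(s), fprime, f)
    for (q in seq_along(k$prob)) {
      P[s + 1, id_of(k$states[[q]])] <- P[s + 1, id_of(k$states[[q]])] + k$prob[q]
    }
  }
  trans <- 2:(S - 1)
  x <- solve(diag(S - 2) - P[trans, trans], P[trans, S])
  x[2^(0:(N - 1))]  # singleton starts
}

# Small connected test graphs beyond the named ones.
fixture_graphs <- function() {
  path5 <- matrix(0, 5, 5)
  for (i in 1:4) { path5[i, i + 1] <- 1; path5[i + 1, i] <- 1 }
  lollipop <- matrix(0, 5, 5)
  lollipop[1:3, 1:3] <- 1; diag(lollipop) <- 0
  lollipop[3, 4] <- lollipop[4, 3] <- 1
  lollipop[4, 5] <- lollipop[5, 4] <- 1
  list(star4 = make_named_graph("star", 4),
       cycle5 = make_named_graph("cycle", 5),
       complete4 = make_named_graph("complete", 4),
       path5 = evo_graph(path5, "path5"),
       lollipop5 = evo_graph(lollipop, "lollipop5"))
}

all_rules <- function() list("Bd-o", "Bd-p", "dB-o", "dB-p")
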