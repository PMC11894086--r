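#' Moran update rules
#'
#' An update rule combines the event order with the choice of which daughter
#' cell occupies the vacated node after reproduction:
#' \describe{
#'   \item{order}{`"Bd"`: fitness-proportional birth over all nodes, then
#'     uniform death among the parent's neighbours. `"dB"`: uniform death over
#'     all nodes, then fitness-proportional birth among the dead node's
#'     neighbours.}
#'   \item{mover}{`"offspring"`: the (possibly mutant) offspring moves to the
#'     vacated node; `"parent"`: the parent-type daughter moves and the
#'     offspring stays at the birth site.}
#' }
#' Without mutation the two daughters are identical, so the mover choice never
#' changes the dynamics; it only determines where a *new* mutant appears.
#' Crossing order and mover yields the four rules and their initialisation
#' schemes: Bd-o and dB-p are temperature initialised, Bd-p and dB-o uniform.
#' `lambda` mixes the two movers: at every reproduction the parent moves with
#' probability `lambda`, the offspring with `1 - lambda`.
#'
#' @param order `"Bd"` or `"dB"`.
#' @param mover `"offspring"`, `"parent"`, or `"mixed"` (requires `lambda`).
#' @param lambda parent-moving probability in \[0, 1\]; `0` is pure offspring
#'   moving, `1` pure parent moving.
#' @return an object of class `update_rule`.
#' @examples
#' update_rule("dB", "parent")
#' parse_rule("Bd-mix:0.25")
#' @export
update_rule <- function(order = c("Bd", "dB"),
                        mover = c("offspring", "parent", "mixed"),
                        lambda = NULL) {
  order <- match.arg(order)
  mover <- match.arg(mover)
  if (mover == "mixed") {
    if (is.null(lambda)) stop_invalid("mixed mover needs lambda")
  } else {
    implied <- if (mover == "parent") 1 else 0
    if (!is.null(lambda) && lambda != implied)
      stop_invalid("lambda conflicts with mover; use mover = 'mixed'")
    lambda <- implied
  }
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop_invalid("lambda must be a probability in [0, 1]")
  if (lambda == 0) mover <- "offspring" else if (lambda == 1) mover <- "parent"
  structure(list(order = order, mover = mover, lambda = lambda),
            class = "update_rule")
}

#' @export
print.update_rule <- function(x, ...) {
  cat("<update_rule ", rule_label(x), ">\n", sep = "")
  invisible(x)
}

#' @param spec character rule spec: `"Bd-o"`, `"Bd-p"`, `"dB-o"`, `"dB-p"`,
#'   or `"Bd-mix:<lambda>"`, `"dB-mix:<lambda>"`.
#' @rdname update_rule
#' @export
parse_rule <- function(spec) {
  if (inherits(spec, "update_rule")) return(spec)
  if (!is.character(spec) || length(spec) != 1)
    stop_invalid("rule spec must be a single string")
  m <- regmatches(spec, regexec("^(Bd|dB)-(o|p|mix:([0-9.eE+-]+))$", spec))[[1]]
  if (length(m) == 0) stop_invalid("cannot parse rule spec '", spec, "'")
  order <- m[2]
  if (m[3] == "o") return(update_rule(order, "offspring"))
  if (m[3] == "p") return(update_rule(order, "parent"))
  update_rule(order, "mixed", lambda = as.numeric(m[4]))
}

#' @rdname update_rule
#' @param rule an `update_rule`.
#' @export
rule_label <- function(rule) {
  if (rule$mover == "mixed")
    sprintf("%s-mix:%g", rule$order, rule$lambda)
  else paste0(rule$order, "-", substr(rule$mover, 1, 1))
}

#' Mutant initialisation distribution of an update rule
#'
#' Probability for each node to host the first mutant, given that mutations
#' arise during reproduction in a monomorphic population. Bd with the
#' offspring moving and dB with the parent moving place the mutant with
#' probability proportional to the node's temperature; the other two
#' combinations are uniform. For a mixed rule the distribution is the
#' `lambda`-convex combination of the two pure schemes.
#'
#' @param g an [evo_graph()] without isolated nodes.
#' @param rule an [update_rule()] or rule spec string.
#' @return numeric probability vector of length `N` (sums to 1).
#' @examples
#' initialisation_distribution(make_named_graph("star", 4), "Bd-o")
#' @export
initialisation_distribution <- function(g, rule) {
  rule <- parse_rule(rule)
  N <- g$N
  temp_is_offspring <- rule$order == "Bd"  # Bd-o temperature; dB-o uniform
  need_temp <- (temp_is_offspring && rule$lambda < 1) ||
    (!temp_is_offspring && rule$lambda > 0)
  p_temp <- if (need_temp) temperature(g, "in") / N else NULL
  p_unif <- rep(1 / N, N)
  w_par <- rule$lambda
  if (temp_is_offspring)
    p <- (1 - w_par) * (p_temp %||% p_unif) + w_par * p_unif
  else
    p <- (1 - w_par) * p_unif + w_par * (p_temp %||% p_unif)
  p
}

#' One-step transition kernel of the mutation-free Moran process
#'
#' Enumerates the successor distribution of a mutant configuration under one
#' reproduction event. The mover choice does not appear: without mutation
#' both daughters carry the parent's type, so `Bd-o` and `Bd-p` (and the
#' mixed rules) share one kernel. States that do not change the configuration
#' are aggregated into a single self-loop entry.
#'
#' This direct enumeration (looping over birth/death node pairs) is kept
#' deliberately independent of the vectorised machinery inside the exact
#' solver, so the two can cross-check each other.
#'
#' @param g a connected [evo_graph()].
#' @param rule an [update_rule()] or spec string (only the order matters).
#' @param state integer vector of nodes currently occupied by mutants.
#' @param fprime mutant fitness (> 0).
#' @param f wild-type fitness (> 0).
#' @return a list with `states` (list of successor mutant sets, the first
#'   being the unchanged state when it has positive self-loop mass) and
#'   `prob` (matching probabilities, summing to 1).
#' @export
step_kernel <- function(g, rule, state, fprime, f = 1) {
  rule <- parse_rule(rule)
  check_fitness(fprime, f)
  N <- g$N
  A <- g$adjacency
  state <- sort(unique(as.integer(state)))
  if (length(state) > 0 && (min(state) < 1 || max(state) > N))
    stop_invalid("state contains node indices outside 1..N")
  if (length(state) == 0 || length(state) == N)
    stop_invalid("state is absorbing; the kernel is defined on transient states")
  is_mut <- rep(FALSE, N)
  is_mut[state] <- TRUE
  w <- ifelse(is_mut, fprime, f)
  flip <- numeric(N)  # prob that node i switches type this event
  if (rule$order == "Bd") {
    pb <- w / sum(w)
    for (b in 1:N) {
      nb <- which(A[b, ] == 1)
      for (d in nb) {
        if (is_mut[d] != is_mut[b]) flip[d] <- flip[d] + pb[b] / length(nb)
      }
    }
  } else {
    for (d in 1:N) {
      nb <- which(A[d, ] == 1)
      wn <- w[nb]
      pmut <- sum(wn[is_mut[nb]]) / sum(wn)
      flip[d] <- flip[d] + (if (is_mut[d]) 1 - pmut else pmut) / N
    }
  }
  keep <- which(flip > 0)
  succ <- lapply(keep, function(i) {
    if (is_mut[i]) setdiff(state, i) else sort(c(state, i))
  })
  probs <- flip[keep]
  selfloop <- 1 - sum(probs)
  if (selfloop > 1e-15) {
    succ <- c(list(state), succ)
    probs <- c(selfloop, probs)
  }
  list(states = succ, prob = probs)
}
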