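# Classification of graphs against the complete-graph reference.

#' The standard fitness grid
#'
#' Nine mutant fitness values spanning the deleterious and beneficial regimes
#' with the resident at f = 1: 0.5, 0.75, ..., 2.5.
#'
#' @return numeric vector.
#' @export
default_fitness_grid <- function() seq(0.5, 2.5, by = 0.25)

#' Fixation probability profile over a fitness grid
#'
#' Average (initialisation-weighted) fixation probability of the graph at
#' each mutant fitness of the grid, computed with the exact solver.
#'
#' @param g a connected [evo_graph()].
#' @param rule an [update_rule()] or spec string.
#' @param grid mutant fitness values.
#' @param f resident fitness (1 in the classification convention).
#' @return object of class `fixation_profile`: data frame columns `fprime`,
#'   `phi`, plus attributes `rule`, `N`, `per_node` (grid x N matrix).
#' @export
fixation_profile <- function(g, rule, grid = default_fitness_grid(), f = 1) {
  rule <- parse_rule(rule)
  check_connected(g)
  p_init <- initialisation_distribution(g, rule)
  per_node <- t(vapply(grid, function(fp)
    fixation_per_node_exact(g, rule, fp, f), numeric(g$N)))
  phi <- as.numeric(per_node %*% p_init)
  structure(data.frame(fprime = grid, phi = phi),
            class = c("fixation_profile", "data.frame"),
            rule = rule_label(rule), N = g$N, f = f, per_node = per_node)
}

ref_cache <- new.env(parent = emptyenv())

#' Complete-graph reference profile
#'
#' The benchmark every graph is compared to. Under dB updating the closed
#' form is used; under Bd updating the classical complete-graph value is
#' computed by the exact solver at the same N (the complete graph is regular,
#' so the initialisation scheme is irrelevant). Results are cached per
#' (N, order, grid).
#'
#' @param N population size.
#' @param order `"dB"` or `"Bd"`.
#' @param grid mutant fitness values.
#' @param f resident fitness.
#' @return numeric vector of \eqn{\Phi_C} along the grid.
#' @export
reference_profile <- function(N, order = c("dB", "Bd"),
                              grid = default_fitness_grid(), f = 1) {
  order <- match.arg(order)
  key <- paste(N, order, f, paste(grid, collapse = ","), sep = "|")
  if (!is.null(ref_cache[[key]])) return(ref_cache[[key]])
  val <- if (order == "dB") {
    fixation_complete_closed(N, grid, f, order = "dB")
  } else {
    gC <- make_named_graph("complete", N)
    vapply(grid, function(fp) mean(fixation_per_node_exact(gC, "Bd-p", fp, f)),
           numeric(1))
  }
  ref_cache[[key]] <- val
  val
}

#' Classify a graph as amplifier or suppressor of selection or fixation
#'
#' Compares the graph's average fixation probability with the complete-graph
#' reference at every grid fitness and assigns one of:
#' \describe{
#'   \item{AoS / SoS}{amplifier / suppressor of selection: below (above) the
#'     reference for deleterious mutants and above (below) for beneficial
#'     ones; the neutral grid point is not used.}
#'   \item{AoF / SoF}{amplifier / suppressor of fixation: above (below) the
#'     reference at *every* grid point.}
#'   \item{piecewise-AoF}{above up to a crossing fitness `fstar >= 1` and
#'     below beyond it; `fstar` is reported at grid resolution.}
#'   \item{isothermal}{structurally regular graph. Flagged before any
#'     comparison; note the fixation-probability identity with the complete
#'     graph holds only for Bd updating.}
#'   \item{other}{anything else, including profiles with ties (differences
#'     within `tol`) at points a category needs.}
#' }
#'
#' @param g a connected [evo_graph()].
#' @param rule an [update_rule()] or spec string.
#' @param grid mutant fitness values (resident f = 1).
#' @param tol tie tolerance on \eqn{\Phi_G - \Phi_C}; differences smaller in
#'   magnitude count as ties (exact-solver noise floor).
#' @param f resident fitness.
#' @return object of class `classification_result`: list with `category`,
#'   `fstar` (or NA), `comparisons` (data frame with `fprime`, `phi`,
#'   `phi_complete`, `sign`), `rule`, `N`.
#' @export
classify <- function(g, rule, grid = default_fitness_grid(), tol = 1e-9,
                     f = 1) {
  rule <- parse_rule(rule)
  check_connected(g)
  if (is_regular_graph(g)) {
    comparisons <- data.frame(fprime = grid, phi = NA_real_,
                              phi_complete = NA_real_, sign = 0L)
    return(structure(list(category = "isothermal", fstar = NA_real_,
                          comparisons = comparisons,
                          rule = rule_label(rule), N = g$N,
                          note = paste("regular graph; equality with the",
                                       "complete graph holds only for Bd",
                                       "updating")),
                     class = "classification_result"))
  }
  prof <- fixation_profile(g, rule, grid, f)
  ref <- reference_profile(g$N, rule$order, grid, f)
  diff <- prof$phi - ref
  sgn <- ifelse(abs(diff) <= tol, 0L, ifelse(diff > 0, 1L, -1L))
  dele <- grid < f
  bene <- grid > f
  category <- "other"
  fstar <- NA_real_
  if (all(sgn == 1L)) {
    category <- "AoF"
  } else if (all(sgn == -1L)) {
    category <- "SoF"
  } else if (any(sgn == 1L) && !any(sgn == 0L)) {
    k <- max(which(sgn == 1L))
    if (all(sgn[seq_len(k)] == 1L) && all(sgn[-seq_len(k)] == -1L) &&
        grid[k] >= f) {
      category <- "piecewise-AoF"
      fstar <- grid[k]
    }
  }
  if (category == "other" && any(dele) && any(bene)) {
    if (all(sgn[dele] == -1L) && all(sgn[bene] == 1L)) category <- "AoS"
    else if (all(sgn[dele] == 1L) && all(sgn[bene] == -1L)) category <- "SoS"
  }
  structure(list(category = category, fstar = fstar,
                 comparisons = data.frame(fprime = grid, phi = prof$phi,
                                          phi_complete = ref, sign = sgn),
                 rule = rule_label(rule), N = g$N),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification: %s (rule %s, N = %d)%s>\n", x$category,
              x$rule, x$N,
              if (is.na(x$fstar)) "" else sprintf(", f* = %g", x$fstar)))
  invisible(x)
}

CATEGORY_LEVELS <- c("AoS", "SoS", "AoF", "piecewise-AoF", "SoF",
                     "isothermal", "other")

#' Census of connected Erdős–Rényi graphs
#'
#' Samples connected G(N, p) graphs, classifies each, and tallies the
#' categories. Isomorphic duplicates are kept: the tallies describe the
#' sampled distribution, not distinct topologies.
#'
#' @param N graph size.
#' @param p edge probability.
#' @param n_samples number of connected samples to classify.
#' @param rule an [update_rule()] or spec string.
#' @param seed integer seed making the whole census reproducible.
#' @param grid,tol forwarded to [classify()].
#' @return object of class `census_result`: list with `counts` (named integer
#'   vector over all categories), `records` (one row per sample: `sample`,
#'   `edges`, `category`, `fstar`), and the call parameters.
#' @export
census <- function(N, p, n_samples, rule, seed = 1,
                   grid = default_fitness_grid(), tol = 1e-9) {
  rule <- parse_rule(rule)
  if (n_samples < 1) stop_invalid("n_samples must be >= 1")
  records <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_samples), function(i) {
      g <- sample_er_connected(N, p, seed = NULL)
      cl <- classify(g, rule, grid = grid, tol = tol)
      data.frame(sample = i, edges = sum(g$adjacency) / 2,
                 category = cl$category, fstar = cl$fstar)
    }))
  })
  counts <- table(factor(records$category, levels = CATEGORY_LEVELS))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, records = records, N = N, p = p,
                 n_samples = n_samples, rule = rule_label(rule), seed = seed),
            class = "census_result")
}

#' @export
print.census_result <- function(x, ...) {
  cat(sprintf("<census: %d connected ER(%d, %g) samples, rule %s>\n",
              x$n_samples, x$N, x$p, x$rule))
  print(x$counts[x$counts > 0])
  invisible(x)
}
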