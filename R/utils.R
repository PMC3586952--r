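## Internal numerics shared across modules.

#' @importFrom stats qgamma rexp rpois runif rnorm pnorm qnorm dnorm
#'   rbinom quantile cor kruskal.test
NULL

# The 20 standard amino acids, in the conventional one-letter order.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

GAP <- "-"

# Run `expr` under a local RNG stream: seeds R's RNG, restores the caller's
# state afterwards so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Discrete-gamma rate multipliers
#'
#' Rates for \code{k} equal-probability categories of a gamma distribution
#' with the given shape (mean fixed at 1 before discretization). Category
#' rates are the category medians, rescaled so the discrete distribution has
#' mean exactly 1; category 1 is slowest.
#'
#' @param shape gamma shape parameter (> 0).
#' @param k number of categories (>= 1).
#' @return numeric vector of \code{k} increasing positive rates, mean 1.
#' @export
discreteGammaRates <- function(shape, k) {
  stopifnot(shape > 0, k >= 1)
  med <- qgamma((seq_len(k) - 0.5) / k, shape = shape, rate = shape)
  med / mean(med)
}

# Equal-exchangeability amino-acid CTMC (F81-type over 20 states).
# With stationary frequencies pi, Q_ij = pi_j (i != j), scaled to one
# expected substitution per unit branch length:
#   P_ij(t) = pi_j (1 - e^{-beta t}) + [i == j] e^{-beta t},
#   beta = 1 / (1 - sum(pi^2)).
f81_decay <- function(t, freqs) {
  beta <- 1 / (1 - sum(freqs^2))
  exp(-beta * t)
}

# Sample one state index per column from stationary frequencies.
sample_stationary <- function(n, freqs) {
  sample.int(length(freqs), n, replace = TRUE, prob = freqs)
}

# Evolve a vector of state indices along a branch of length t (already
# multiplied by any per-site rate): with prob e^{-beta t} keep the state,
# otherwise redraw from the stationary distribution.
evolve_states <- function(states, t, freqs) {
  if (length(t) == 1L) t <- rep(t, length(states))
  keep <- runif(length(states)) < exp(-t / (1 - sum(freqs^2)))
  out <- states
  n_new <- sum(!keep)
  if (n_new) out[!keep] <- sample.int(length(freqs), n_new, replace = TRUE, prob = freqs)
  out
}

# Children lists and postorder traversal of a phylo object.
phylo_children <- function(tree) {
  n_node <- max(tree$edge)
  kids <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  kids
}

phylo_postorder <- function(tree) {
  # node numbers in an order where children precede parents
  tree <- ape::reorder.phylo(tree, "postorder")
  unique(as.vector(t(tree$edge[, c(2, 1)])))
}

# Per-node tip sets (species names after mapping) for a rooted phylo.
node_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(ord))) {
    p <- ord[i, 1]; ch <- ord[i, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# Deterministic Newick for a rooted tree: sort children by the
# lexicographically smallest descendant label; used for canonical
# representations and tie-breaks.
canonical_newick <- function(tree) {
  kids <- phylo_children(tree)
  n_tip <- length(tree$tip.label)
  rec <- function(node) {
    if (node <= n_tip) return(list(str = tree$tip.label[node], min = tree$tip.label[node]))
    parts <- lapply(kids[[node]], rec)
    mins <- vapply(parts, `[[`, "", "min")
    parts <- parts[order(mins)]
    list(str = paste0("(", paste(vapply(parts, `[[`, "", "str"), collapse = ","), ")"),
         min = min(mins))
  }
  root <- n_tip + 1L
  paste0(rec(root)$str, ";")
}

# log(sum(exp(x))) stable
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
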