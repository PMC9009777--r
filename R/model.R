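# Four-leaf quartet model of site evolution after gene duplication.
#
# The quartet has a duplication at the root, two paralog copies (a, b), and two
# species lineages (X, Y) inside each copy.  Branches b1, b2 connect the
# duplication to the two pre-speciation ancestors (length t1); branches b3..b6
# connect those ancestors to the leaves Xa, Ya, Xb, Yb (length t2).  Each branch
# carries 0 or 1 substitutions; a substitution replaces the residue by one of
# the other A-1 amino acids uniformly at random.

CATEGORY_NAMES <- c("conserved", "type1", "type2", "recent",
                    "inversion", "species_specific", "non_conserved")

QUARTET_LEAVES <- c("Xa", "Ya", "Xb", "Yb")

# The six leaf pairs.  Inner pairs compare orthologs (same copy, different
# species); outer pairs are all others.
QUARTET_PAIRS <- list(
  "Xa:Ya" = c("Xa", "Ya"),
  "Xb:Yb" = c("Xb", "Yb"),
  "Xa:Xb" = c("Xa", "Xb"),
  "Xa:Yb" = c("Xa", "Yb"),
  "Ya:Xb" = c("Ya", "Xb"),
  "Ya:Yb" = c("Ya", "Yb")
)

#' Probability of at least one substitution on a branch
#'
#' Under the model a branch of length `t` (expected substitutions per site)
#' carries a substitution with probability \eqn{1 - e^{-t}}.
#'
#' @param t non-negative, finite branch length(s).
#' @return numeric vector of probabilities in `[0, 1)`.
#' @examples
#' substitution_probability(log(2))  # 0.5
#' @export
substitution_probability <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("branch length 't' must be finite and >= 0", call. = FALSE)
  }
  1 - exp(-t)
}

#' Probability that two leaves carry the same residue
#'
#' Computes the exact match probability between two leaves given the number of
#' substitutions `k_u`, `k_v` on each leaf's private path below their most
#' recent common ancestor, under the uniform jump chain in which a substitution
#' moves to each of the other `alphabet_size - 1` residues with equal
#' probability.  The result is independent of the ancestral residue.
#'
#' @param k_u,k_v integer substitution counts in `0:2`.
#' @param alphabet_size number of residues (default 20).
#' @return a probability.
#' @examples
#' match_probability(1, 1)        # 1/19
#' match_probability(2, 1)        # 18/361
#' @export
match_probability <- function(k_u, k_v, alphabet_size = 20L) {
  stopifnot(length(k_u) == 1L, length(k_v) == 1L)
  if (!k_u %in% 0:2 || !k_v %in% 0:2) {
    stop("substitution counts must be 0, 1 or 2 (at most one per branch)",
         call. = FALSE)
  }
  A <- as.integer(alphabet_size)
  if (A < 2L) stop("alphabet_size must be >= 2", call. = FALSE)
  J <- matrix(1 / (A - 1), A, A)
  diag(J) <- 0
  pow <- function(k) {
    M <- diag(A)
    for (i in seq_len(k)) M <- M %*% J
    M
  }
  # row c of J^k is the residue distribution after k jumps from ancestor c;
  # the match probability is the inner product of the two rows (any c).
  sum(pow(k_u)[1, ] * pow(k_v)[1, ])
}

# 3x3 lookup of match probabilities indexed by (k_u + 1, k_v + 1).
match_table <- function(alphabet_size = 20L) {
  outer(0:2, 0:2, Vectorize(function(u, v) match_probability(u, v, alphabet_size)))
}

#' Enumerate the 64 branch substitution configurations
#'
#' Every assignment of substitution (1) / no-substitution (0) states to the six
#' branches is enumerated with its probability, the implied leaf states
#' (number of substitutions on the two branches leading to each leaf), the
#' private-path substitution counts for the six leaf pairs, and the resulting
#' pair match probabilities.
#'
#' @param t1 pre-speciation branch length (branches b1, b2).
#' @param t2 post-speciation branch length (branches b3..b6).
#' @param alphabet_size number of residues (default 20).
#' @return a list with elements `states` (64 x 6 0/1 matrix, columns b1..b6),
#'   `probability` (length 64, sums to 1), `leaf_states` (64 x 4, columns
#'   Xa, Ya, Xb, Yb), `pair_counts` (list of two 64 x 6 matrices `k_u`, `k_v`)
#'   and `match` (64 x 6 matrix of pair match probabilities).
#' @export
branch_configurations <- function(t1, t2, alphabet_size = 20L) {
  p1 <- substitution_probability(t1)
  p2 <- substitution_probability(t2)
  states <- as.matrix(expand.grid(b1 = 0:1, b2 = 0:1, b3 = 0:1,
                                  b4 = 0:1, b5 = 0:1, b6 = 0:1))
  p_branch <- c(p1, p1, p2, p2, p2, p2)
  prob <- apply(states, 1L, function(s) prod(ifelse(s == 1, p_branch, 1 - p_branch)))

  leaf_states <- cbind(
    Xa = states[, "b1"] + states[, "b3"],
    Ya = states[, "b1"] + states[, "b4"],
    Xb = states[, "b2"] + states[, "b5"],
    Yb = states[, "b2"] + states[, "b6"]
  )

  # Private-path substitution counts below each pair's MRCA.  Inner pairs share
  # the pre-speciation branch, so only the terminal branches count; outer pairs
  # coalesce at the duplication, so each leaf's full path counts (its state).
  k_u <- cbind("Xa:Ya" = states[, "b3"], "Xb:Yb" = states[, "b5"],
               "Xa:Xb" = leaf_states[, "Xa"], "Xa:Yb" = leaf_states[, "Xa"],
               "Ya:Xb" = leaf_states[, "Ya"], "Ya:Yb" = leaf_states[, "Ya"])
  k_v <- cbind("Xa:Ya" = states[, "b4"], "Xb:Yb" = states[, "b6"],
               "Xa:Xb" = leaf_states[, "Xb"], "Xa:Yb" = leaf_states[, "Yb"],
               "Ya:Xb" = leaf_states[, "Xb"], "Ya:Yb" = leaf_states[, "Yb"])

  mt <- match_table(alphabet_size)
  m <- matrix(mt[cbind(as.vector(k_u) + 1L, as.vector(k_v) + 1L)],
              nrow = nrow(states), dimnames = dimnames(k_u))

  list(states = states, probability = prob, leaf_states = leaf_states,
       pair_counts = list(k_u = k_u, k_v = k_v), match = m,
       t1 = t1, t2 = t2, alphabet_size = as.integer(alphabet_size))
}

# Per-configuration conditional probabilities of the six explicit categories,
# given a 64 x 6 matrix of pair match values.  Returned as a 64 x 6 matrix.
category_given_configuration <- function(m) {
  mi1 <- m[, "Xa:Ya"]; mi2 <- m[, "Xb:Yb"]
  axb <- m[, "Xa:Xb"]; ayb <- m[, "Xa:Yb"]
  bxa <- m[, "Ya:Xb"]; byb <- m[, "Ya:Yb"]

  cons <- mi1 * mi2 * pmax(axb, ayb, bxa, byb)
  type1 <- mi1 * (1 - mi2) * (1 - pmin(axb, bxa)) * (1 - pmin(ayb, byb)) +
    (1 - mi1) * mi2 * (1 - pmin(axb, ayb)) * (1 - pmin(bxa, byb))
  type2 <- mi1 * mi2 * (1 - cons)
  recent <- mi1 * axb * (1 - mi2) + mi1 * ayb * (1 - mi2) +
    mi2 * axb * (1 - mi1) + mi2 * bxa * (1 - mi1)
  inv <- ayb * bxa * (1 - pmin(mi1, mi2))
  ssa <- axb * byb * (1 - pmin(mi1, mi2))

  cbind(conserved = cons, type1 = type1, type2 = type2, recent = recent,
        inversion = inv, species_specific = ssa)
}

#' Category probabilities of the quartet model
#'
#' Marginal probabilities of the seven evolutionary-outcome categories
#' (conserved, type 1 divergence, type 2 divergence, recent divergence,
#' inter-paralog inversion, species-specific adaptation, non-conserved) at
#' branch lengths `t1`, `t2`, obtained by summing each category's conditional
#' probability over the 64 branch configurations weighted by configuration
#' probability.  `non_conserved` is the residual (one minus the other six),
#' clamped at zero.
#'
#' @inheritParams branch_configurations
#' @return named numeric vector over the seven categories.
#' @examples
#' category_probabilities(0, 0)        # conserved = 1
#' category_probabilities(0.3, 0.1)["inversion"]
#' @export
category_probabilities <- function(t1, t2, alphabet_size = 20L) {
  conf <- branch_configurations(t1, t2, alphabet_size)
  pc <- category_given_configuration(conf$match)
  out <- as.numeric(conf$probability %*% pc)
  names(out) <- colnames(pc)
  resid <- 1 - sum(out)
  if (resid < -1e-9) {
    warning(sprintf(
      "explicit categories sum to %.12f > 1; residual clamped to 0", sum(out)))
  }
  res <- c(out, non_conserved = min(max(resid, 0), 1))
  res[CATEGORY_NAMES]
}

#' Category probabilities over a grid of branch lengths
#'
#' Evaluates [category_probabilities()] on the Cartesian grid
#' `t1_grid` x `t2_grid`.
#'
#' @param t1_grid,t2_grid non-empty vectors of branch lengths (>= 0).
#' @param alphabet_size number of residues (default 20).
#' @return named list of matrices, one per category;
#'   `matrix[i, j]` corresponds to `(t1_grid[i], t2_grid[j])`.
#' @seealso [heatmap_long()] for a long-format table.
#' @export
category_heatmap <- function(t1_grid, t2_grid, alphabet_size = 20L) {
  if (length(t1_grid) == 0L || length(t2_grid) == 0L) {
    stop("grids must be non-empty", call. = FALSE)
  }
  if (any(t1_grid < 0) || any(t2_grid < 0)) {
    stop("grid branch lengths must be >= 0", call. = FALSE)
  }
  out <- lapply(CATEGORY_NAMES, function(cat) {
    matrix(NA_real_, length(t1_grid), length(t2_grid),
           dimnames = list(format(t1_grid), format(t2_grid)))
  })
  names(out) <- CATEGORY_NAMES
  for (i in seq_along(t1_grid)) {
    for (j in seq_along(t2_grid)) {
      p <- category_probabilities(t1_grid[i], t2_grid[j], alphabet_size)
      for (cat in CATEGORY_NAMES) out[[cat]][i, j] <- p[[cat]]
    }
  }
  attr(out, "t1_grid") <- t1_grid
  attr(out, "t2_grid") <- t2_grid
  out
}

#' Long-format view of a category heatmap
#'
#' @param hm result of [category_heatmap()].
#' @return data.frame with columns `t1`, `t2`, `category`, `probability`.
#' @export
heatmap_long <- function(hm) {
  t1 <- attr(hm, "t1_grid"); t2 <- attr(hm, "t2_grid")
  do.call(rbind, lapply(names(hm), function(cat) {
    data.frame(
      t1 = rep(t1, times = length(t2)),
      t2 = rep(t2, each = length(t1)),
      category = cat,
      probability = as.vector(hm[[cat]])
    )
  }))
}

#' Expected inversion probability for a duplication tree
#'
#' Estimates the quartet-model branch lengths from a duplication phylogeny and
#' returns the model probability of the inter-paralog inversion category.
#' Convention: `t1` is the mean path length from the duplication node (the most
#' recent common ancestor of both paralog clades) to the MRCA of each paralog
#' clade's leaves, and `t2` is the mean path length from those clade MRCAs to
#' their leaves.  The convention is recorded in the attributes of the result.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param groups a group assignment (see [group_assignment()]) resolvable on
#'   the tree: every tree leaf must be annotated with a paralog label.
#' @param alphabet_size number of residues (default 20).
#' @return the inversion category probability, with attributes `t1` and `t2`.
#' @export
expected_inversion_probability <- function(tree, groups, alphabet_size = 20L) {
  est <- estimate_quartet_lengths(tree, groups)
  p <- category_probabilities(est$t1, est$t2, alphabet_size)[["inversion"]]
  attr(p, "t1") <- est$t1
  attr(p, "t2") <- est$t2
  p
}

# Estimate (t1, t2) from a duplication tree and a paralog labelling.
estimate_quartet_lengths <- function(tree, groups) {
  groups <- as_group_assignment(groups)
  ids <- tree$tip.label
  par <- groups$paralog[match(ids, groups$id)]
  if (anyNA(par)) {
    stop("grouping does not cover tree leaves: ",
         paste(utils::head(ids[is.na(par)], 5L), collapse = ", "), call. = FALSE)
  }
  lab <- sort(unique(par))
  if (length(lab) != 2L) stop("exactly two paralog labels required", call. = FALSE)
  tips_a <- which(par == lab[1L]); tips_b <- which(par == lab[2L])
  if (length(tips_a) == 0L || length(tips_b) == 0L) {
    stop("both paralog clades must be non-empty", call. = FALSE)
  }
  nd <- node_depths(tree)
  mrca_all <- mrca_of(tree, c(tips_a, tips_b))
  t1s <- t2s <- numeric(0)
  for (tips in list(tips_a, tips_b)) {
    m <- mrca_of(tree, tips)
    t1s <- c(t1s, nd[m] - nd[mrca_all])
    t2s <- c(t2s, mean(nd[tips] - nd[m]))
  }
  list(t1 = mean(t1s), t2 = mean(t2s))
}
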