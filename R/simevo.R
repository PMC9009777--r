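# Site-wise sequence evolution along a Newick tree under an empirical
# amino-acid model (JTT or LG) with optional discrete-gamma rate
# heterogeneity, used to build null alignments and empirical score thresholds.

# Access an empirical amino-acid model (lower-triangle exchangeabilities and
# stationary frequencies) from phangorn's bundled model store.
aa_model_store <- function(name) {
  obj <- get(paste0(".", name), envir = environment(phangorn::pml))
  list(Q = obj$Q, bf = as.numeric(obj$bf))
}

#' Empirical amino-acid substitution model
#'
#' Assembles the time-reversible rate matrix `Q[i, j] = S[i, j] * pi[j]`
#' (exchangeabilities `S`, stationary frequencies `pi`), scaled to one expected
#' substitution per site per unit branch length, plus discrete-gamma rate
#' multipliers with mean 1.
#'
#' @param name `"JTT"` or `"LG"`.
#' @param gamma_shape positive shape of the gamma rate distribution, or `NULL`
#'   for rate homogeneity.
#' @param n_categories number of discrete gamma categories (default 4).
#' @return a `substitution_model`: list with `name`, `Q` (scaled 20 x 20 rate
#'   matrix, zero row sums), `frequencies`, `gamma_shape`, `rates` (category
#'   multipliers, mean 1).
#' @export
substitution_model <- function(name = c("JTT", "LG"), gamma_shape = NULL,
                               n_categories = 4L) {
  name <- match.arg(name)
  store <- aa_model_store(name)
  S <- matrix(0, 20L, 20L)
  S[lower.tri(S)] <- store$Q
  S <- S + t(S)
  bf <- store$bf / sum(store$bf)
  Q <- S * rep(bf, each = 20L)            # Q[i, j] = S[i, j] * bf[j]
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(bf * -diag(Q))             # mean rate 1
  dimnames(Q) <- list(AA_LETTERS, AA_LETTERS)
  rates <- 1
  if (!is.null(gamma_shape)) {
    if (gamma_shape <= 0) stop("gamma_shape must be positive", call. = FALSE)
    rates <- phangorn::discrete.gamma(gamma_shape, n_categories)
  }
  structure(list(name = name, Q = Q,
                 frequencies = stats::setNames(bf, AA_LETTERS),
                 gamma_shape = gamma_shape, n_categories = as.integer(n_categories),
                 rates = rates),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("substitution_model:", x$name,
      if (is.null(x$gamma_shape)) "(rate-homogeneous)" else
        sprintf("+ G(shape=%g, %d categories)", x$gamma_shape, x$n_categories),
      "\n")
  invisible(x)
}

# Transition kernel exp(Q * r * t), clipped to a proper stochastic matrix.
transition_kernel <- function(model, t, rate = 1) {
  P <- ape::matexpo(model$Q * (rate * t))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate a protein alignment along a tree
#'
#' Root residues are drawn from the model's stationary frequencies (or
#' uniformly), each site draws one discrete-gamma rate category, and every
#' branch of length `t` evolves states by the kernel `exp(Q * r * t)`.
#'
#' @param tree `ape::phylo` with branch lengths (an error otherwise; the
#'   simulator never substitutes defaults).
#' @param model a [substitution_model()].
#' @param n_sites number of columns (default 5000).
#' @param seed optional integer seed; a given seed reproduces the alignment
#'   exactly.
#' @param root_distribution `"stationary"` or `"uniform"`.
#' @return an `aa_msa` (tips x sites) with attributes `site_rates` (the rate
#'   multiplier of each column) and `seed`.
#' @export
simulate_alignment <- function(tree, model, n_sites = 5000L, seed = NULL,
                               root_distribution = c("stationary", "uniform")) {
  root_distribution <- match.arg(root_distribution)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree must have branch lengths for simulation", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_sites <- as.integer(n_sites)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode

  cat_idx <- sample.int(length(model$rates), n_sites, replace = TRUE)
  site_rates <- model$rates[cat_idx]
  root_p <- if (root_distribution == "stationary") model$frequencies else rep(1 / 20, 20L)

  states <- matrix(NA_integer_, n_node, n_sites)
  root <- n_tip + 1L
  states[root, ] <- sample.int(20L, n_sites, replace = TRUE, prob = root_p)

  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    len <- tr$edge.length[e]
    for (k in seq_along(model$rates)) {
      sites <- which(cat_idx == k)
      if (length(sites) == 0L) next
      if (len == 0) {
        states[child, sites] <- states[parent, sites]
        next
      }
      P <- transition_kernel(model, len, model$rates[k])
      ps <- states[parent, sites]
      for (s in unique(ps)) {
        sel <- sites[ps == s]
        states[child, sel] <- sample.int(20L, length(sel), replace = TRUE,
                                         prob = P[s, ])
      }
    }
  }

  m <- matrix(AA_LETTERS[states[seq_len(n_tip), , drop = FALSE]], n_tip, n_sites,
              dimnames = list(tree$tip.label, NULL))
  class(m) <- c("aa_msa", class(m))
  attr(m, "site_rates") <- site_rates
  attr(m, "seed") <- seed
  m
}

#' Empirical null score distribution from simulated evolution
#'
#' Simulates a neutral alignment on the tree, scores it with
#' [scan_alignment()] under the given grouping, and returns the score
#' distribution with its percentile threshold and a per-residue breakdown
#' along a reference row.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param groups a `group_assignment` resolvable on the tree tips.
#' @param model a [substitution_model()] (default JTT with gamma shape 1).
#' @param n_sites simulated columns (default 5000).
#' @param seed optional seed.
#' @param pc a [pseudocount_config()] or `NULL`.
#' @param gap_threshold,percentile as in [scan_alignment()] /
#'   [percentile_threshold()].
#' @param reference_id tip whose simulated residues index the per-residue
#'   breakdown (default: first tip).
#' @return an `invphy_null`: list with `scores` (the scan table), `threshold`,
#'   `percentile`, `per_residue` (split of inversion scores by the reference
#'   residue) and `alignment`.
#' @export
empirical_null <- function(tree, groups, model = substitution_model("JTT", 1),
                           n_sites = 5000L, seed = NULL,
                           pc = pseudocount_config(), gap_threshold = 0.60,
                           percentile = 99, reference_id = NULL) {
  aln <- simulate_alignment(tree, model, n_sites, seed)
  grouped <- grouped_alignment(aln, groups)
  scores <- scan_alignment(grouped, pc = pc, gap_threshold = gap_threshold)
  thr <- percentile_threshold(scores$inversion_score, percentile)
  reference_id <- reference_id %||% rownames(aln)[1L]
  ref_res <- aln[reference_id, scores$column]
  per_residue <- split(scores$inversion_score, factor(ref_res, levels = AA_LETTERS))
  structure(list(scores = scores, threshold = thr, percentile = percentile,
                 per_residue = per_residue, alignment = aln,
                 reference_id = reference_id, model = model),
            class = "invphy_null")
}

#' @export
print.invphy_null <- function(x, ...) {
  cat("invphy_null:", nrow(x$scores), "simulated columns;",
      sprintf("%g", x$percentile), "th percentile threshold =",
      format(x$threshold, digits = 4), "\n")
  invisible(x)
}
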