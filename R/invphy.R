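# Main user interface: fit the inversion scan to an alignment + tree +
# grouping and return a classed object with the usual accessor methods.

#' Detect inter-paralog amino-acid inversions in a duplication phylogeny
#'
#' Scores every alignment column for the inter-paralog inversion and
#' species-specific adaptation patterns under one or several four-way
#' groupings, computes the model-expected inversion probability from branch
#' lengths estimated on the tree, and (by default) calibrates an empirical
#' score threshold by simulated evolution along the same tree.
#'
#' @param msa an `aa_msa` (see [read_msa()]) or path to an aligned FASTA file.
#' @param tree an `ape::phylo` or path to a Newick file.  Required for the
#'   expected probability and the simulated null; may be `NULL` when
#'   `null = FALSE`.
#' @param groups a `group_assignment`, path to a group table, the string
#'   `"auto"` (candidate groupings are derived from the tree; requires
#'   `species`), or a list of candidate assignments.
#' @param species named id -> species vector, only used with
#'   `groups = "auto"`.
#' @param beta pseudo-count weight (default 5); `0` disables smoothing.
#' @param gap_threshold columns with at least this gap fraction are not scored
#'   (default 0.60).
#' @param percentile percentile of the simulated null used as the selection
#'   threshold (default 99); sites strictly above are selected.
#' @param reference_species optional species used to annotate reported sites
#'   with ungapped coordinates in its two paralog sequences.
#' @param null `TRUE` to calibrate the threshold by simulated evolution,
#'   `FALSE` to skip it, or a precomputed [empirical_null()] object.
#' @param model substitution model for the null simulation (default JTT with
#'   gamma shape 1).
#' @param null_sites simulated columns for the null (default 5000).
#' @param seed seed for the null simulation.
#' @param distance_param,min_group passed to [auto_groupings()] when
#'   `groups = "auto"`.
#' @return an object of class `"invphy"`; see [summary.invphy()],
#'   [coef.invphy()], [plot.invphy()], [simulate.invphy()].
#' @examples
#' sd <- synth_dataset(synth_config(n_sites = 200, seed = 7))
#' fit <- invphy(sd$msa, sd$tree, sd$groups, null = FALSE)
#' head(fit$sites)
#' @export
invphy <- function(msa, tree = NULL, groups, species = NULL, beta = 5,
                   gap_threshold = 0.60, percentile = 99,
                   reference_species = NULL, null = TRUE,
                   model = substitution_model("JTT", 1), null_sites = 5000L,
                   seed = NULL, distance_param = 0, min_group = 2L) {
  if (is.character(msa) && is.null(dim(msa))) msa <- read_msa(msa)
  if (is.character(tree)) tree <- read_tree(tree)

  if (identical(groups, "auto")) {
    if (is.null(tree)) stop("automatic grouping requires a tree", call. = FALSE)
    if (is.null(species)) stop("automatic grouping requires 'species'", call. = FALSE)
    groupings <- auto_groupings(tree, species, distance_param, min_group)
    if (length(groupings) == 0L) stop("no candidate groupings found", call. = FALSE)
  } else if (is.character(groups)) {
    groupings <- list(read_group_table(groups))
  } else if (inherits(groups, "group_assignment") || is.data.frame(groups)) {
    groupings <- list(as_group_assignment(groups))
  } else if (is.list(groups)) {
    groupings <- lapply(groups, as_group_assignment)
  } else {
    stop("cannot interpret 'groups'", call. = FALSE)
  }

  pc <- if (beta > 0) pseudocount_config(beta) else NULL
  sites <- scan_alignment(msa, pc = pc, gap_threshold = gap_threshold,
                          groupings = groupings,
                          reference_species = reference_species)

  expected <- t1 <- t2 <- NULL
  if (!is.null(tree)) {
    check_tree_msa(tree, msa)
    est <- estimate_quartet_lengths(tree, groupings[[1L]])
    t1 <- est$t1; t2 <- est$t2
    expected <- category_probabilities(t1, t2)
  }

  null_obj <- NULL
  if (inherits(null, "invphy_null")) {
    null_obj <- null
  } else if (isTRUE(null)) {
    if (is.null(tree)) stop("the simulated null requires a tree", call. = FALSE)
    null_obj <- empirical_null(tree, groupings[[1L]], model = model,
                               n_sites = null_sites, seed = seed, pc = pc,
                               gap_threshold = gap_threshold,
                               percentile = percentile)
  }
  threshold <- if (!is.null(null_obj)) null_obj$threshold else NA_real_
  sites$selected <- if (is.na(threshold)) NA else sites$inversion_score > threshold

  structure(list(sites = sites, threshold = threshold, percentile = percentile,
                 expected = expected, t1 = t1, t2 = t2, null = null_obj,
                 groupings = groupings, beta = beta,
                 gap_threshold = gap_threshold, tree = tree,
                 n_sequences = nrow(msa), n_columns = ncol(msa),
                 reference_species = reference_species, model = model,
                 call = match.call()),
            class = "invphy")
}

#' @export
print.invphy <- function(x, ...) {
  cat("invphy scan:", x$n_sequences, "sequences,", x$n_columns, "columns,",
      nrow(x$sites), "scored\n")
  if (!is.null(x$expected)) {
    cat(sprintf("  estimated branch lengths: t1 = %.4f, t2 = %.4f\n", x$t1, x$t2))
    cat(sprintf("  model-expected inversion probability: %.3g\n",
                x$expected[["inversion"]]))
  }
  if (!is.na(x$threshold)) {
    cat(sprintf("  %gth-percentile null threshold: %.4f (%d site(s) selected)\n",
                x$percentile, x$threshold, sum(x$sites$selected)))
  }
  invisible(x)
}

#' Summary of an inversion scan
#'
#' @param object an `invphy` fit.
#' @param n number of top sites to display (default 10).
#' @param ... unused.
#' @return the object, invisibly; prints scored-column counts, the threshold,
#'   and the top sites by inversion score.
#' @export
summary.invphy <- function(object, n = 10L, ...) {
  print(object)
  ord <- order(object$sites$inversion_score, decreasing = TRUE)
  top <- utils::head(object$sites[ord, ], n)
  cat("\ntop sites by inversion score:\n")
  print(top, row.names = FALSE, digits = 4)
  invisible(object)
}

#' Estimated quantities of an inversion scan
#'
#' @param object an `invphy` fit with a tree.
#' @param ... unused.
#' @return named vector: estimated `t1`, `t2` and the model-expected
#'   probabilities of the inversion and species-specific-adaptation
#'   categories.
#' @export
coef.invphy <- function(object, ...) {
  if (is.null(object$expected)) {
    stop("no tree was supplied; nothing was estimated", call. = FALSE)
  }
  c(t1 = object$t1, t2 = object$t2,
    expected_inversion = unname(object$expected[["inversion"]]),
    expected_ssa = unname(object$expected[["species_specific"]]))
}

#' Score distribution plot of an inversion scan
#'
#' Histogram of per-column inversion scores with the null threshold (dashed)
#' and selected sites marked in the rug.
#'
#' @param x an `invphy` fit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.invphy <- function(x, ...) {
  s <- x$sites$inversion_score
  graphics::hist(s, breaks = 50, main = "inter-paralog inversion scores",
                 xlab = "inversion score", col = "grey85", border = "grey40", ...)
  if (!is.na(x$threshold)) {
    graphics::abline(v = x$threshold, lty = 2, col = "firebrick")
    sel <- s[x$sites$selected]
    if (length(sel)) graphics::rug(sel, col = "firebrick")
  }
  invisible(x)
}

#' Simulate null alignments from a fitted scan
#'
#' Draws alignments by simulated evolution along the fitted tree under the
#' fitted substitution model — the parametric null of the scan.
#'
#' @param object an `invphy` fit with a tree.
#' @param nsim number of alignments (default 1).
#' @param seed optional seed.
#' @param n_sites columns per alignment (default: the fitted alignment size).
#' @param ... unused.
#' @return list of `aa_msa` alignments.
#' @export
simulate.invphy <- function(object, nsim = 1, seed = NULL, n_sites = NULL, ...) {
  if (is.null(object$tree)) stop("no tree to simulate along", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_sites <- n_sites %||% object$n_columns
  lapply(seq_len(nsim), function(i)
    simulate_alignment(object$tree, object$model, n_sites, seed = NULL))
}

#' Selected sites of a scan
#'
#' @param object an `invphy` fit.
#' @return the rows of `object$sites` strictly above the null threshold.
#' @export
selected_sites <- function(object) {
  stopifnot(inherits(object, "invphy"))
  if (is.na(object$threshold)) stop("no null threshold was computed", call. = FALSE)
  object$sites[object$sites$selected, , drop = FALSE]
}
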