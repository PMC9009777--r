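# Neighbor-joining from BLOSUM80 alignment distances, a bipartition-matching
# (Nye-style) tree similarity, and the bootstrap experiment contrasting the
# phylogenetic information of inverted-site columns with random columns.

blosum80_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM80", package = "Biostrings", envir = e)
  e$BLOSUM80[AA_LETTERS, AA_LETTERS]
}

# Per-pair, per-column BLOSUM80 score components for an encoded alignment.
# For sequence pair p and column j:
#   raw[p, j]   observed score B[x, y]      (0 where either residue is a gap)
#   up[p, j]    upper bound min(B[x, x], B[y, y])
#   valid[p, j] both residues present
# The min-max normalised similarity over a column set C is
#   (sum raw - n B_min) / (sum up - n B_min),  n = #valid columns in C,
# and the distance is one minus that; a pair with no valid column gets
# distance 1.  All components are additive over columns, so bootstrap column
# subsets reuse them.
pair_column_scores <- function(msa) {
  B <- blosum80_matrix()
  M <- matrix(aa_encode(as.vector(msa)), nrow = nrow(msa),
              dimnames = dimnames(msa))
  n <- nrow(M)
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  L <- ncol(M)
  raw <- up <- matrix(0, np, L)
  valid <- matrix(FALSE, np, L)
  diagB <- diag(B)
  for (p in seq_len(np)) {
    x <- M[pairs[1L, p], ]; y <- M[pairs[2L, p], ]
    ok <- !is.na(x) & !is.na(y)
    raw[p, ok] <- B[cbind(x[ok], y[ok])]
    up[p, ok] <- pmin(diagB[x[ok]], diagB[y[ok]])
    valid[p, ok] <- TRUE
  }
  list(raw = raw, up = up, valid = valid, pairs = pairs,
       labels = rownames(msa), min_score = min(B))
}

pair_distances_from_scores <- function(pcs, columns = NULL) {
  cols <- columns %||% seq_len(ncol(pcs$raw))
  raw <- rowSums(pcs$raw[, cols, drop = FALSE])
  up <- rowSums(pcs$up[, cols, drop = FALSE])
  nv <- rowSums(pcs$valid[, cols, drop = FALSE])
  lo <- nv * pcs$min_score
  d <- ifelse(nv > 0, 1 - (raw - lo) / pmax(up - lo, .Machine$double.eps), 1)
  n <- length(pcs$labels)
  D <- matrix(0, n, n, dimnames = list(pcs$labels, pcs$labels))
  D[t(pcs$pairs)] <- d
  D[t(pcs$pairs[2:1, , drop = FALSE])] <- d
  D
}

#' BLOSUM80 pairwise distances of an alignment
#'
#' For each sequence pair, the summed BLOSUM80 score over mutually ungapped
#' columns is min-max normalised between the smallest possible score (the
#' matrix minimum per column) and the pair's self-score bound (the smaller of
#' the two self scores per column); the distance is one minus that similarity.
#' Pairs with no mutually ungapped column get the maximal distance 1 with a
#' warning.
#'
#' @param msa an `aa_msa`.
#' @return a symmetric `dist_matrix`: list with `labels` and `values`.
#' @export
pairwise_distance <- function(msa) {
  pcs <- pair_column_scores(msa)
  if (any(rowSums(pcs$valid) == 0L)) {
    warning("sequence pair(s) with no mutually ungapped column; distance set to 1")
  }
  D <- pair_distances_from_scores(pcs)
  structure(list(labels = rownames(msa), values = D), class = "dist_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper over [ape::nj()]; exact on additive distances.
#'
#' @param dist a `dist_matrix` from [pairwise_distance()], a matrix, or a
#'   `stats::dist`.
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dist) {
  D <- if (inherits(dist, "dist_matrix")) dist$values else as.matrix(dist)
  if (nrow(D) < 3L) stop("at least 3 taxa are required", call. = FALSE)
  ape::nj(stats::as.dist(D))
}

# Non-trivial bipartitions of a tree as a logical matrix (tips x edges), in a
# fixed tip order.
bipartitions <- function(tree, tip_order) {
  n_tip <- length(tree$tip.label)
  desc <- clade_tips(tree)
  internal <- setdiff(seq_along(desc), seq_len(n_tip))
  sets <- lapply(internal, function(nn) desc[[nn]])
  # drop the root split itself and trivial (single-tip / all-but-one) sides
  keep <- vapply(sets, function(s) length(s) >= 2L && length(s) <= n_tip - 2L, TRUE)
  sets <- sets[keep]
  m <- vapply(sets, function(s) {
    v <- rep(FALSE, n_tip)
    v[match(tree$tip.label[s], tip_order)] <- TRUE
    v
  }, logical(n_tip))
  if (is.null(dim(m))) m <- matrix(m, nrow = n_tip, ncol = length(sets))
  m
}

#' Bipartition-matching similarity between two trees
#'
#' For every internal edge of `tree1`, its bipartition is scored against the
#' best-matching edge of `tree2`, where an edge pair scores the maximum over
#' the two consistent side pairings of the minimum intersection-over-union of
#' the paired sides.  The default score is the one-sided sum over `tree1`'s
#' internal edges (so `max_score` is `tree1`'s internal edge count); with
#' `symmetric = TRUE` the two one-sided sums are averaged.
#'
#' @param tree1,tree2 `ape::phylo` trees over the same leaf set.
#' @param symmetric average the two directed scores (default `FALSE`).
#' @return a `tree_similarity`: list with `score` and `max_score`.
#' @export
nye_similarity <- function(tree1, tree2, symmetric = FALSE) {
  if (!setequal(tree1$tip.label, tree2$tip.label)) {
    stop("trees must share the same leaf set", call. = FALSE)
  }
  tip_order <- sort(tree1$tip.label)
  b1 <- bipartitions(tree1, tip_order)
  b2 <- bipartitions(tree2, tip_order)
  one_sided <- function(bA, bB) {
    if (ncol(bA) == 0L || ncol(bB) == 0L) return(0)
    n <- nrow(bA)
    sA <- colSums(bA); sB <- colSums(bB)
    I <- crossprod(bA, bB)                               # |A inter B|
    U <- outer(sA, sB, "+") - I
    Icc <- n - outer(sA, sB, "+") + I                    # |Ac inter Bc|
    Ucc <- n - I
    j_same <- pmin(I / U, Icc / Ucc)
    Ix <- sA - I                                         # |A inter Bc|
    Ux <- outer(sA, n - sB, "+") - Ix                    # |A union Bc|
    Icx <- sweep(-I, 2L, sB, "+")                        # |Ac inter B|
    Ucx <- n - Ix                                        # |Ac union B|
    j_cross <- pmin(Ix / Ux, Icx / Ucx)
    sum(apply(pmax(j_same, j_cross), 1L, max))
  }
  score <- one_sided(b1, b2)
  max_score <- ncol(b1)
  if (symmetric) {
    score <- (score + one_sided(b2, b1)) / 2
    max_score <- (ncol(b1) + ncol(b2)) / 2
  }
  structure(list(score = score, max_score = max_score, symmetric = symmetric),
            class = "tree_similarity")
}

#' @export
print.tree_similarity <- function(x, ...) {
  cat(sprintf("tree similarity: %.2f out of %g\n", x$score, x$max_score))
  invisible(x)
}

#' Bootstrap comparison of inverted-site and random-column trees
#'
#' Builds a neighbor-joining tree from the full alignment and one from the
#' inverted-site columns, then draws bootstrap column samples (with
#' replacement) of each requested length from the columns with less than 90%
#' gaps, resampling whenever a sequence would be left without any residue, and
#' records each bootstrap tree's similarity to the two reference trees.  The
#' inverted-sites tree's similarity to the full tree is finally compared
#' against the length-matched (shortest-length) bootstrap similarities by a
#' one-sample t-test.
#'
#' @param msa an `aa_msa`.
#' @param inverted_sites non-empty vector of column indices.
#' @param lengths sample lengths; the string `"full"` means the number of
#'   eligible columns (default `c("full", 250, 100, 20)`).
#' @param replicates bootstrap replicates per length (default 500).
#' @param seed optional seed.
#' @param gap_exclude columns with at least this gap fraction are never
#'   sampled (default 0.90).
#' @return an `invphy_bootstrap`: list with `table` (length, replicate,
#'   similarity to the full and to the inverted tree), `inverted_similarity`
#'   (inverted tree vs full tree), `t_test` (similarities at the smallest
#'   length vs the inverted similarity, one-sided), `full_tree`,
#'   `inverted_tree` and `eligible_columns`.
#' @export
bootstrap_experiment <- function(msa, inverted_sites,
                                 lengths = c("full", 250, 100, 20),
                                 replicates = 500L, seed = NULL,
                                 gap_exclude = 0.90) {
  if (length(inverted_sites) == 0L) {
    stop("inverted_sites must be non-empty", call. = FALSE)
  }
  if (!all(inverted_sites %in% seq_len(ncol(msa)))) {
    stop("inverted_sites out of range", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  enc_gap <- is.na(matrix(aa_encode(as.vector(msa)), nrow = nrow(msa)))
  eligible <- which(colMeans(enc_gap) < gap_exclude)

  pcs <- pair_column_scores(msa)
  full_tree <- nj_tree(pair_distances_from_scores(pcs))
  inv_tree <- nj_tree(pair_distances_from_scores(pcs, inverted_sites))
  inv_sim <- nye_similarity(full_tree, inv_tree)$score

  res <- list()
  for (len_spec in lengths) {
    L <- if (identical(len_spec, "full")) length(eligible) else as.integer(len_spec)
    sims_full <- sims_inv <- numeric(replicates)
    for (r in seq_len(replicates)) {
      repeat {
        cols <- sample(eligible, L, replace = TRUE)
        # every sequence needs at least one residue in the sample
        if (all(rowSums(!enc_gap[, cols, drop = FALSE]) > 0L)) break
      }
      bt <- nj_tree(pair_distances_from_scores(pcs, cols))
      sims_full[r] <- nye_similarity(full_tree, bt)$score
      sims_inv[r] <- nye_similarity(inv_tree, bt)$score
    }
    res[[length(res) + 1L]] <- data.frame(
      length = if (identical(len_spec, "full")) "full" else as.character(L),
      n_columns = L, replicate = seq_len(replicates),
      similarity_full = sims_full, similarity_inverted = sims_inv)
  }
  tab <- do.call(rbind, res)

  smallest_n <- min(tab$n_columns)
  ref <- tab$similarity_full[tab$n_columns == smallest_n]
  tt <- stats::t.test(ref, mu = inv_sim, alternative = "greater")

  structure(list(table = tab, inverted_similarity = inv_sim, t_test = tt,
                 full_tree = full_tree, inverted_tree = inv_tree,
                 eligible_columns = eligible),
            class = "invphy_bootstrap")
}

#' @export
print.invphy_bootstrap <- function(x, ...) {
  cat("invphy_bootstrap:", nrow(x$table), "replicates;",
      "inverted-sites tree similarity to full tree =",
      format(x$inverted_similarity, digits = 4), "\n")
  cat("one-sided t-test (bootstraps > inverted): p =",
      format(x$t_test$p.value, digits = 3), "\n")
  invisible(x)
}
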