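# Per-column amino-acid frequency profiles and the inversion /
# species-specific-adaptation scores.
#
# For a column with cell frequency arrays Xa, Ya, Xb, Yb the match probability
# between two cells is the dot product of their arrays.  The inversion score is
# the joint probability that paralogs match across species groups while
# orthologs do not:
#
#   sum_i Xa[i] * Yb[i] * ( M(Ya, Xb) - Ya[i] * Xb[i] )
#
# which equals the conditional-times-marginal two-step form
# P(no four-way match | cross matches) * M(Xa, Yb) * M(Ya, Xb) wherever the
# cross matches are non-zero, and is zero when either of them is zero.  The
# species-specific-adaptation score exchanges the roles of Xb and Yb.

#' Pseudo-count configuration
#'
#' Dirichlet-style smoothing of observed frequencies toward a background
#' distribution: with a cell of `n` residues and raw frequencies `f`,
#' `f' = (n * f + beta * g) / (n + beta)`.  The default background `g` is the
#' stationary amino-acid distribution of the LG substitution model.
#'
#' @param beta non-negative pseudo-count weight (default 5).
#' @param background length-20 frequency vector summing to 1.
#' @return a `pseudocount_config`.
#' @export
pseudocount_config <- function(beta = 5, background = lg_frequencies()) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0) {
    stop("beta must be a single non-negative number", call. = FALSE)
  }
  background <- as.numeric(background)
  if (length(background) != 20L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be a length-20 frequency vector summing to 1",
         call. = FALSE)
  }
  structure(list(beta = beta, background = background),
            class = "pseudocount_config")
}

#' Stationary amino-acid frequencies of the LG model
#'
#' @return named length-20 numeric vector (ARNDCQEGHILKMFPSTWYV order).
#' @export
lg_frequencies <- function() {
  bf <- aa_model_store("LG")$bf
  stats::setNames(as.numeric(bf), AA_LETTERS)
}

# Encoded alignment + cell row indices, shared by all column-wise operations.
encode_grouped <- function(grouped) {
  M <- matrix(aa_encode(as.vector(grouped$msa)), nrow = nrow(grouped$msa),
              dimnames = dimnames(grouped$msa))
  idx <- lapply(grouped$cells, function(ids) match(ids, rownames(grouped$msa)))
  list(M = M, idx = idx)
}

# 20 x L count and frequency matrices for one cell of sequences.
cell_frequencies <- function(M, rows, pc = NULL) {
  sub <- M[rows, , drop = FALSE]
  counts <- residue_counts(sub)            # 20 x L
  n <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(n, 1L), "/")
  if (!is.null(pc) && pc$beta > 0) {
    freq <- sweep(sweep(freq, 2L, n, "*") + pc$beta * pc$background,
                  2L, n + pc$beta, "/")
  }
  freq[, n == 0L] <- 0
  list(freq = freq, n = n)
}

#' Frequency profile of one alignment column
#'
#' @param grouped a `grouped_msa`.
#' @param column 1-based column index.
#' @param pc a [pseudocount_config()] or `NULL` for raw frequencies.
#' @return a `column_profile`: list with `column`, `freq` (named list of four
#'   length-20 arrays for cells Xa, Ya, Xb, Yb), `counts` (non-gap residues per
#'   cell), `gap_fraction` (over all grouped sequences) and `empty` (any cell
#'   without residues).
#' @export
column_profile <- function(grouped, column, pc = pseudocount_config()) {
  stopifnot(inherits(grouped, "grouped_msa"))
  if (column < 1L || column > ncol(grouped$msa)) {
    stop("column out of range", call. = FALSE)
  }
  enc <- encode_grouped(grouped)
  col <- enc$M[, column]
  freq <- list(); counts <- integer(0)
  for (cell in names(enc$idx)) {
    x <- col[enc$idx[[cell]]]
    n <- sum(!is.na(x))
    f <- tabulate(x, nbins = 20L) / max(n, 1L)
    if (!is.null(pc) && pc$beta > 0) f <- (n * f + pc$beta * pc$background) / (n + pc$beta)
    if (n == 0L) f <- rep(0, 20L)
    freq[[cell]] <- stats::setNames(f, AA_LETTERS)
    counts[cell] <- n
  }
  grouped_rows <- unlist(enc$idx, use.names = FALSE)
  structure(list(column = as.integer(column), freq = freq, counts = counts,
                 gap_fraction = mean(is.na(col[grouped_rows])),
                 empty = any(counts == 0L)),
            class = "column_profile")
}

#' Match probability between two frequency arrays
#'
#' The dot product of the two length-20 arrays: the probability that one
#' residue drawn from each distribution matches.
#'
#' @param p,q length-20 frequency arrays, each summing to 1.
#' @return a probability in `[0, 1]`.
#' @export
profile_match <- function(p, q) {
  for (v in list(p, q)) {
    if (length(v) != 20L || any(v < 0) || abs(sum(v) - 1) > 1e-6) {
      stop("inputs must be length-20 frequency arrays summing to 1",
           call. = FALSE)
    }
  }
  sum(p * q)
}

score_from_arrays <- function(xa, ya, xb, yb) {
  val <- sum(xa * yb) * sum(ya * xb) - sum(xa * yb * ya * xb)
  min(max(val, 0), 1)
}

#' Inter-paralog inversion score of a column profile
#'
#' @param profile a [column_profile()].
#' @return probability in `[0, 1]`, or `NA` if any cell is empty.
#' @export
inversion_score <- function(profile) {
  if (profile$empty) return(NA_real_)
  with(profile$freq, score_from_arrays(Xa, Ya, Xb, Yb))
}

#' Species-specific adaptation score of a column profile
#'
#' Same joint probability as [inversion_score()] with the roles of the two
#' paralog arrays within each species group exchanged (Xb and Yb swapped).
#'
#' @param profile a [column_profile()].
#' @return probability in `[0, 1]`, or `NA` if any cell is empty.
#' @export
ssa_score <- function(profile) {
  if (profile$empty) return(NA_real_)
  with(profile$freq, score_from_arrays(Xa, Ya, Yb, Xb))
}

#' Scan a grouped alignment for inversion and adaptation signals
#'
#' Scores every column whose gap fraction (over all grouped sequences) is
#' below `gap_threshold`.  With several candidate groupings, each column
#' reports the maximum inversion score over groupings and the grouping that
#' achieves it (its adaptation score is reported alongside).
#'
#' @param grouped a `grouped_msa`, or an `aa_msa` when `groupings` is given.
#' @param pc a [pseudocount_config()] or `NULL` for raw frequencies.
#' @param gap_threshold columns with a gap fraction at or above this value are
#'   excluded (default 0.60).
#' @param groupings optional list of `group_assignment` candidates; when
#'   supplied, `grouped` may be a plain alignment.
#' @param reference_species optional species whose two paralog sequences are
#'   used to annotate reported columns with ungapped reference coordinates.
#' @return data.frame with one row per scored column: `column`,
#'   `inversion_score`, `ssa_score`, `grouping_id`, `gap_fraction`,
#'   `conservation_a`, `conservation_b` and, when a reference is set,
#'   `ref_pos_a`, `ref_residue_a`, `ref_pos_b`, `ref_residue_b`.  Columns
#'   skipped because a cell was empty are listed in the `"skipped"` attribute.
#' @export
scan_alignment <- function(grouped, pc = pseudocount_config(),
                           gap_threshold = 0.60, groupings = NULL,
                           reference_species = NULL) {
  if (is.null(groupings)) {
    stopifnot(inherits(grouped, "grouped_msa"))
    groupings <- list(grouped$groups)
    msa <- grouped$msa
    reference_species <- reference_species %||% attr(grouped, "reference_species")
  } else {
    msa <- if (inherits(grouped, "grouped_msa")) grouped$msa else grouped
    groupings <- lapply(groupings, as_group_assignment)
  }
  L <- ncol(msa)
  best <- data.frame(column = seq_len(L), inversion_score = -Inf,
                     ssa_score = NA_real_, grouping_id = NA_character_)
  keep <- rep(FALSE, L)
  skipped <- integer(0)
  gapfrac <- rep(NA_real_, L)
  cons_a <- cons_b <- rep(NA_real_, L)

  for (k in seq_along(groupings)) {
    g <- grouped_alignment(msa, groupings[[k]])
    gid <- attr(g$groups, "grouping_id") %||% paste0("grouping", k)
    enc <- encode_grouped(g)
    cf <- lapply(enc$idx, function(rows) cell_frequencies(enc$M, rows, pc))
    xa <- cf$Xa$freq; ya <- cf$Ya$freq; xb <- cf$Xb$freq; yb <- cf$Yb$freq
    inv <- colSums(xa * yb) * colSums(ya * xb) - colSums(xa * yb * ya * xb)
    ssa <- colSums(xa * xb) * colSums(ya * yb) - colSums(xa * xb * ya * yb)
    inv <- pmin(pmax(inv, 0), 1); ssa <- pmin(pmax(ssa, 0), 1)

    grouped_rows <- unlist(enc$idx, use.names = FALSE)
    gf <- colMeans(is.na(enc$M[grouped_rows, , drop = FALSE]))
    nonempty <- cf$Xa$n > 0 & cf$Ya$n > 0 & cf$Xb$n > 0 & cf$Yb$n > 0
    ok <- gf < gap_threshold & nonempty
    skipped <- union(skipped, which(gf < gap_threshold & !nonempty))
    upd <- ok & inv > best$inversion_score
    best$inversion_score[upd] <- inv[upd]
    best$ssa_score[upd] <- ssa[upd]
    best$grouping_id[upd] <- gid
    keep <- keep | ok
    if (k == 1L) {
      gapfrac <- gf
      # site conservation (modal-residue identity) per paralog copy, over both
      # species groups jointly
      lab <- sort(unique(g$groups$paralog))
      rows_a <- match(g$groups$id[g$groups$paralog == lab[1L]], rownames(msa))
      rows_b <- match(g$groups$id[g$groups$paralog == lab[2L]], rownames(msa))
      cons_a <- modal_identity(enc$M, rows_a)
      cons_b <- modal_identity(enc$M, rows_b)
    }
  }

  out <- best[keep, , drop = FALSE]
  out$gap_fraction <- gapfrac[keep]
  out$conservation_a <- cons_a[keep]
  out$conservation_b <- cons_b[keep]

  if (!is.null(reference_species)) {
    g1 <- grouped_alignment(msa, groupings[[1L]])
    lab <- sort(unique(g1$groups$paralog))
    ref_ids <- vapply(lab, function(p) {
      id <- g1$groups$id[g1$groups$species == reference_species &
                           g1$groups$paralog == p]
      if (length(id) == 0L) NA_character_ else id[1L]
    }, "")
    for (side in c(1L, 2L)) {
      suffix <- c("a", "b")[side]
      if (is.na(ref_ids[side])) next
      mapped <- lapply(out$column, function(j)
        map_column_to_reference(msa, ref_ids[side], j))
      out[[paste0("ref_pos_", suffix)]] <- vapply(mapped, `[[`, 1, "position")
      out[[paste0("ref_residue_", suffix)]] <- vapply(mapped, `[[`, "", "residue")
    }
  }
  if (nrow(out) == 0L) warning("no scoreable columns")
  if (length(skipped)) {
    message(length(skipped), " column(s) skipped: empty scoring cell")
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- sort(skipped)
  out
}

# 20 x L residue count matrix of an encoded sub-alignment.
residue_counts <- function(sub) {
  raw <- vapply(seq_len(20L), function(a) colSums(sub == a, na.rm = TRUE),
                numeric(ncol(sub)))
  t(matrix(raw, nrow = ncol(sub), ncol = 20L))
}

# Fraction of non-gap residues equal to the modal residue, per column.
modal_identity <- function(M, rows) {
  counts <- residue_counts(M[rows, , drop = FALSE])
  n <- colSums(counts)
  ifelse(n > 0, apply(counts, 2L, max) / pmax(n, 1L), NA_real_)
}

#' Percentile threshold of a score distribution
#'
#' Linear-interpolation percentile (R quantile type 7).  Sites strictly above
#' the threshold are considered selected.
#'
#' @param scores non-empty numeric vector (NAs dropped).
#' @param q percentile in `[0, 100]` (default 99).
#' @return the threshold.
#' @export
percentile_threshold <- function(scores, q = 99) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) stop("no scores to take a percentile of", call. = FALSE)
  if (q < 0 || q > 100) stop("percentile must be in [0, 100]", call. = FALSE)
  unname(stats::quantile(scores, q / 100, type = 7))
}

#' Mean ortholog and paralog matching per column
#'
#' For every scoreable column, the ortholog coordinate is the mean of the two
#' within-copy cross-species matches (M(Xa,Ya), M(Xb,Yb)) and the paralog
#' coordinate the mean of the two cross-copy matches (M(Xa,Yb), M(Ya,Xb)).
#'
#' @param grouped a `grouped_msa`.
#' @param pc a [pseudocount_config()] or `NULL`.
#' @param gap_threshold columns with a gap fraction at or above this are
#'   excluded (default 0.60).
#' @return data.frame with columns `column`, `ortholog_match`,
#'   `paralog_match`.
#' @export
ortholog_paralog_matching <- function(grouped, pc = pseudocount_config(),
                                      gap_threshold = 0.60) {
  stopifnot(inherits(grouped, "grouped_msa"))
  enc <- encode_grouped(grouped)
  cf <- lapply(enc$idx, function(rows) cell_frequencies(enc$M, rows, pc))
  xa <- cf$Xa$freq; ya <- cf$Ya$freq; xb <- cf$Xb$freq; yb <- cf$Yb$freq
  orth <- (colSums(xa * ya) + colSums(xb * yb)) / 2
  para <- (colSums(xa * yb) + colSums(ya * xb)) / 2
  grouped_rows <- unlist(enc$idx, use.names = FALSE)
  gf <- colMeans(is.na(enc$M[grouped_rows, , drop = FALSE]))
  ok <- gf < gap_threshold & cf$Xa$n > 0 & cf$Ya$n > 0 & cf$Xb$n > 0 & cf$Yb$n > 0
  data.frame(column = which(ok), ortholog_match = orth[ok],
             paralog_match = para[ok])
}

#' Map an alignment column to ungapped reference coordinates
#'
#' @param msa an `aa_msa`.
#' @param reference_id id of the reference sequence.
#' @param column 1-based alignment column.
#' @return list with `position` (1-based ungapped position; for a reference
#'   gap, the nearest preceding non-gap position, 0 if none), `residue` (the
#'   reference residue, `"-"` at a gap) and `at_gap` (logical flag).
#' @export
map_column_to_reference <- function(msa, reference_id, column) {
  if (!reference_id %in% rownames(msa)) {
    stop("unknown reference id: ", reference_id, call. = FALSE)
  }
  ref <- msa[reference_id, ]
  is_res <- !(ref %in% c(GAP_CHARS, "X"))
  if (column < 1L || column > length(ref)) stop("column out of range", call. = FALSE)
  pos <- cumsum(is_res)
  list(position = pos[column], residue = ref[column], at_gap = !is_res[column])
}

#' Long-format frequency table for sequence-logo rendering
#'
#' @param grouped a `grouped_msa`.
#' @param columns columns to export.
#' @param pc a [pseudocount_config()] or `NULL`.
#' @return data.frame with columns `column`, `cell`, `residue`, `frequency`.
#' @export
logo_frequencies <- function(grouped, columns, pc = NULL) {
  do.call(rbind, lapply(columns, function(j) {
    pr <- column_profile(grouped, j, pc)
    do.call(rbind, lapply(names(pr$freq), function(cell) {
      data.frame(column = j, cell = cell, residue = AA_LETTERS,
                 frequency = as.numeric(pr$freq[[cell]]))
    }))
  }))
}
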