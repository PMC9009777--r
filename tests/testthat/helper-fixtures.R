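# Shared fixtures and independent oracles, all built in code.

# A tiny grouped alignment: two sequences per cell.
toy_grouped <- function(seqs = c(X1_a = "AAC", X2_a = "ACC",
                                 Y1_a = "ACC", Y2_a = "CCC",
                                 X1_b = "CCC", X2_b = "CCC",
                                 Y1_b = "AAC", Y2_b = "ACC")) {
  msa <- invphy:::as_msa(seqs)
  ids <- names(seqs)
  species <- sub("_[ab]$", "", ids)
  paralog <- sub("^.*_", "", ids)
  sg <- ifelse(startsWith(species, "X"), "group1", "group2")
  grouped_alignment(msa, group_assignment(ids, species, paralog, sg))
}

# One-column grouped alignment with one sequence per cell.
one_col_grouped <- function(xa, ya, xb, yb) {
  toy_grouped(c(X_a = xa, Y_a = ya, X_b = xb, Y_b = yb))
}

# Random frequency profile (four cells), occasionally sparse.
random_profile <- function() {
  f <- replicate(4, {
    v <- stats::rgamma(20, 0.4)
    v / sum(v)
  }, simplify = FALSE)
  names(f) <- c("Xa", "Ya", "Xb", "Yb")
  f
}

# Brute-force oracle for the leaf-pair match probability: enumerate every
# jump path of k_u and k_v uniform substitutions from a common ancestor.
brute_match <- function(k_u, k_v, A) {
  # residue distribution after k jumps from state 1, by explicit path
  # enumeration (not matrix powers)
  dist_after <- function(k) {
    states <- 1L
    probs <- 1
    for (i in seq_len(k)) {
      new_states <- integer(0)
      new_probs <- numeric(0)
      for (s in seq_along(states)) {
        others <- setdiff(seq_len(A), states[s])
        new_states <- c(new_states, others)
        new_probs <- c(new_probs, rep(probs[s] / (A - 1), length(others)))
      }
      agg <- tapply(new_probs, new_states, sum)
      states <- as.integer(names(agg))
      probs <- as.numeric(agg)
    }
    d <- numeric(A)
    d[states] <- probs
    d
  }
  sum(dist_after(k_u) * dist_after(k_v))
}

# Monte-Carlo oracle for the quartet category frequencies: sample residues
# through the six branches and apply the matching rules to the outcomes.
mc_categories <- function(t1, t2, n = 1e6, A = 20L, seed = 1L) {
  set.seed(seed)
  p <- c(t1, t1, t2, t2, t2, t2)
  b <- vapply(p, function(t) stats::runif(n) < (1 - exp(-t)), logical(n))
  jump <- function(cur, do) {
    new <- cur
    k <- sum(do)
    if (k) new[do] <- (cur[do] + sample.int(A - 1L, k, replace = TRUE) - 1L) %% A + 1L
    new
  }
  root <- rep(1L, n)
  anc_a <- jump(root, b[, 1]); anc_b <- jump(root, b[, 2])
  Xa <- jump(anc_a, b[, 3]); Ya <- jump(anc_a, b[, 4])
  Xb <- jump(anc_b, b[, 5]); Yb <- jump(anc_b, b[, 6])
  mi1 <- Xa == Ya; mi2 <- Xb == Yb
  axb <- Xa == Xb; ayb <- Xa == Yb; bxa <- Ya == Xb; byb <- Ya == Yb
  cons <- mi1 & mi2 & (axb | ayb | bxa | byb)
  type1 <- (mi1 & !mi2 & !(axb & bxa) & !(ayb & byb)) |
    (!mi1 & mi2 & !(axb & ayb) & !(bxa & byb))
  type2 <- mi1 & mi2 & !cons
  recent <- (mi1 & axb & !mi2) | (mi1 & ayb & !mi2) |
    (mi2 & axb & !mi1) | (mi2 & bxa & !mi1)
  inv <- ayb & bxa & !(mi1 & mi2)
  ssa <- axb & byb & !(mi1 & mi2)
  c(conserved = mean(cons), type1 = mean(type1), type2 = mean(type2),
    recent = mean(recent), inversion = mean(inv), species_specific = mean(ssa))
}

# Direct evaluation of the two-step (conditional, then joint) score formulas.
two_step_inversion <- function(f) {
  M1 <- sum(f$Xa * f$Yb); M2 <- sum(f$Ya * f$Xb)
  if (M1 == 0 || M2 == 0) return(NA_real_)
  cond <- sum(f$Xa * f$Yb / M1 * (1 - f$Ya * f$Xb / M2))
  cond * M1 * M2
}

# Independent Nye-style similarity: explicit loops over edge pairs and set
# operations on tip-label sets.
brute_nye <- function(tree1, tree2) {
  clades <- function(tr) {
    n <- length(tr$tip.label)
    desc <- invphy:::clade_tips(tr)
    internal <- setdiff(seq_along(desc), seq_len(n))
    sets <- lapply(internal, function(nn) sort(tr$tip.label[desc[[nn]]]))
    Filter(function(s) length(s) >= 2 && length(s) <= n - 2, sets)
  }
  all_tips <- sort(tree1$tip.label)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  s1 <- clades(tree1); s2 <- clades(tree2)
  total <- 0
  for (A in s1) {
    best <- 0
    Ac <- setdiff(all_tips, A)
    for (B in s2) {
      Bc <- setdiff(all_tips, B)
      sc <- max(min(jac(A, B), jac(Ac, Bc)), min(jac(A, Bc), jac(Ac, B)))
      best <- max(best, sc)
    }
    total <- total + best
  }
  list(score = total, max_score = length(s1))
}

write_temp_fasta <- function(seqs) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", seqs), tf)
  tf
}
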