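# Fully synthetic duplication phylogenies and alignments with planted
# inversion / species-specific-adaptation columns, so every other module can
# be exercised without external data.

#' Configuration of the synthetic duplication dataset
#'
#' The defaults describe the study conditions used throughout the package's
#' validation: two species groups of eight, pre-speciation branch length 0.3
#' and post-speciation 0.1 substitutions/site, 2000 columns simulated under
#' JTT with gamma rate heterogeneity (shape 1, 4 categories), ten planted
#' inversion columns with a per-leaf noise rate of 5%.
#'
#' @param n_species_group1,n_species_group2 species per group (>= 2).
#' @param t1,t2 pre- and post-speciation branch lengths (substitutions/site).
#' @param n_sites alignment columns.
#' @param n_planted_inversions,n_planted_ssa planted columns per pattern.
#' @param inversion_residue_pair two distinct residues used for the planted
#'   patterns.
#' @param noise per-leaf probability that a planted residue is replaced by a
#'   random other amino acid.
#' @param seed integer seed controlling tree shape, simulation and planting.
#' @param model a [substitution_model()] for the neutral columns.
#' @return a `synth_config`.
#' @export
synth_config <- function(n_species_group1 = 8L, n_species_group2 = 8L,
                         t1 = 0.3, t2 = 0.1, n_sites = 2000L,
                         n_planted_inversions = 10L, n_planted_ssa = 0L,
                         inversion_residue_pair = c("F", "H"),
                         noise = 0.05, seed = 1L,
                         model = substitution_model("JTT", 1)) {
  stopifnot(n_species_group1 >= 1L, n_species_group2 >= 1L,
            t1 >= 0, t2 >= 0, n_sites >= 1L,
            n_planted_inversions + n_planted_ssa <= n_sites,
            length(inversion_residue_pair) == 2L,
            inversion_residue_pair[1L] != inversion_residue_pair[2L],
            all(inversion_residue_pair %in% AA_LETTERS),
            noise >= 0, noise < 1)
  structure(list(n_species_group1 = as.integer(n_species_group1),
                 n_species_group2 = as.integer(n_species_group2),
                 t1 = t1, t2 = t2, n_sites = as.integer(n_sites),
                 n_planted_inversions = as.integer(n_planted_inversions),
                 n_planted_ssa = as.integer(n_planted_ssa),
                 inversion_residue_pair = inversion_residue_pair,
                 noise = noise, seed = as.integer(seed), model = model),
            class = "synth_config")
}

# Ultrametric coalescent-shaped subtree over `labels`, rescaled to `depth`.
coalescent_subtree <- function(labels, depth) {
  n <- length(labels)
  tr <- ape::rcoal(n, tip.label = labels)
  tr$edge.length <- tr$edge.length * (depth / max(node_depths(tr)))
  tr
}

# Newick fragment of a group subtree with a stem, tips suffixed by copy.
subtree_string <- function(species, copy, t2, template = NULL) {
  labels <- paste0(species, "_", copy)
  if (length(species) == 1L) return(paste0(labels, ":", format(t2, digits = 12)))
  tr <- template
  tr$tip.label <- labels
  crown <- max(node_depths(tr))
  s <- ape::write.tree(tr)
  s <- sub(";$", "", s)
  paste0(s, ":", format(t2 - crown, digits = 12))
}

#' Build a mirrored duplication phylogeny
#'
#' The root is the duplication node; each of the two paralog clades contains
#' an identical species tree: the species-group split sits at path length `t1`
#' below the duplication, every leaf at path length `t2` below the split
#' (group crowns are coalescent-shaped with depth `t2 / 2`).  Leaves are
#' labelled `<species>_<copy>`.
#'
#' @param cfg a [synth_config()] (its `seed` fixes the coalescent topologies).
#' @return list with `tree` (`ape::phylo`) and `groups`
#'   (`group_assignment`).
#' @export
make_duplication_tree <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  sp1 <- sprintf("S%02d", seq_len(cfg$n_species_group1))
  sp2 <- sprintf("S%02d", cfg$n_species_group1 + seq_len(cfg$n_species_group2))
  tpl1 <- if (length(sp1) > 1L) coalescent_subtree(sp1, cfg$t2 / 2) else NULL
  tpl2 <- if (length(sp2) > 1L) coalescent_subtree(sp2, cfg$t2 / 2) else NULL

  clade <- function(copy) {
    paste0("(", subtree_string(sp1, copy, cfg$t2, tpl1), ",",
           subtree_string(sp2, copy, cfg$t2, tpl2), "):",
           format(cfg$t1, digits = 12))
  }
  tree <- ape::read.tree(text = paste0("(", clade("a"), ",", clade("b"), ");"))

  ids <- tree$tip.label
  species <- sub("_[ab]$", "", ids)
  paralog <- sub("^.*_", "", ids)
  groups <- group_assignment(ids, species, paralog,
                             ifelse(species %in% sp1, "group1", "group2"),
                             mode = "manual", grouping_id = "synthetic")
  list(tree = tree, groups = groups)
}

#' Overwrite columns with planted inversion / adaptation patterns
#'
#' The inversion pattern writes the first residue of
#' `cfg$inversion_residue_pair` into the group1-copy-a and group2-copy-b cells
#' and the second residue into the other two cells; the adaptation pattern
#' writes the first residue into both copies of group1 and the second into
#' both copies of group2.  Each planted residue is then independently replaced
#' by a random different amino acid with probability `cfg$noise`.
#'
#' @param msa an `aa_msa` whose rows match `groups$id`.
#' @param groups a `group_assignment`.
#' @param cfg a [synth_config()].
#' @param columns optional explicit columns to overwrite (first the
#'   inversions, then the adaptations); drawn at random by default.
#' @return list with `msa` (modified alignment) and `truth` (data.frame
#'   `column`, `type`).
#' @export
plant_columns <- function(msa, groups, cfg, columns = NULL) {
  n_planted <- cfg$n_planted_inversions + cfg$n_planted_ssa
  if (n_planted > ncol(msa)) stop("more planted columns than sites", call. = FALSE)
  if (is.null(columns)) {
    columns <- sample(ncol(msa), n_planted)
  } else if (length(columns) != n_planted) {
    stop("'columns' must have length n_planted_inversions + n_planted_ssa",
         call. = FALSE)
  }
  g <- grouped_alignment(msa, groups)
  rows <- lapply(g$cells, function(ids) match(ids, rownames(msa)))
  r <- cfg$inversion_residue_pair
  type <- rep(c("inversion", "ssa"),
              c(cfg$n_planted_inversions, cfg$n_planted_ssa))
  for (i in seq_along(columns)) {
    j <- columns[i]
    if (type[i] == "inversion") {
      msa[c(rows$Xa, rows$Yb), j] <- r[1L]
      msa[c(rows$Ya, rows$Xb), j] <- r[2L]
    } else {
      msa[c(rows$Xa, rows$Xb), j] <- r[1L]
      msa[c(rows$Ya, rows$Yb), j] <- r[2L]
    }
    if (cfg$noise > 0) {
      all_rows <- unlist(rows, use.names = FALSE)
      flip <- all_rows[stats::runif(length(all_rows)) < cfg$noise]
      if (length(flip)) {
        cur <- match(msa[flip, j], AA_LETTERS)
        shift <- sample.int(19L, length(flip), replace = TRUE)
        msa[flip, j] <- AA_LETTERS[(cur + shift - 1L) %% 20L + 1L]
      }
    }
  }
  list(msa = msa,
       truth = data.frame(column = columns, type = type))
}

#' Generate a complete synthetic duplication dataset
#'
#' Builds the mirrored duplication tree, simulates neutral columns along it
#' under `cfg$model`, and plants the configured inversion / adaptation
#' columns.  Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return list with `msa`, `tree`, `groups`, `truth` and `config`.
#' @export
synth_dataset <- function(cfg = synth_config()) {
  td <- make_duplication_tree(cfg)           # seeds the RNG with cfg$seed
  aln <- simulate_alignment(td$tree, cfg$model, cfg$n_sites, seed = NULL)
  planted <- plant_columns(aln, td$groups, cfg)
  list(msa = planted$msa, tree = td$tree, groups = td$groups,
       truth = planted$truth, config = cfg)
}
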