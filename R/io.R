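# Alignment and tree input/output, and the four-way grouping of sequences
# (two species groups x two paralog copies).
#
# An alignment is represented as a character matrix of single residues with one
# row per sequence (rownames are the sequence ids), class "aa_msa".

#' Read an aligned protein FASTA file
#'
#' @param path path to an aligned FASTA file.
#' @return an `aa_msa`: character matrix (sequences x columns), upper-case,
#'   with unique rownames.  Residues are restricted to the 20 amino acids,
#'   gaps (`-`, `.`) and `X`.
#' @export
read_msa <- function(path) {
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicated sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  w <- Biostrings::width(set)
  if (length(unique(w)) != 1L) {
    stop("sequences are not aligned (ragged lengths ",
         paste(unique(w), collapse = ", "), ")", call. = FALSE)
  }
  as_msa(toupper(as.character(set)), ids)
}

# Build an aa_msa from a character vector of (equal-length) sequence strings.
as_msa <- function(seqs, ids = names(seqs)) {
  chars <- strsplit(seqs, "", fixed = TRUE)
  m <- do.call(rbind, chars)
  rownames(m) <- ids
  bad <- setdiff(unique(as.vector(m)), ALLOWED_CHARS)
  if (length(bad) > 0L) {
    stop("alignment contains characters outside the amino-acid alphabet: ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  class(m) <- c("aa_msa", class(m))
  m
}

#' @export
print.aa_msa <- function(x, ...) {
  cat("aa_msa:", nrow(x), "sequences x", ncol(x), "columns\n")
  show <- utils::head(rownames(x), 6L)
  for (id in show) {
    s <- paste(x[id, seq_len(min(50L, ncol(x)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", id, s, if (ncol(x) > 50L) "..." else ""))
  }
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more\n")
  invisible(x)
}

#' Write an alignment to FASTA
#'
#' @param msa an `aa_msa`.
#' @param path output path.
#' @export
write_msa <- function(msa, path) {
  seqs <- apply(unclass(msa), 1L, paste, collapse = "")
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- rownames(msa)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a Newick tree
#'
#' Wraps [ape::read.tree()] with explicit error handling; a tree without
#' branch lengths is accepted with a warning and unit lengths.
#'
#' @param path path to a Newick file.
#' @return an `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) stop("cannot parse Newick file: ", path, call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; using unit lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  tree
}

#' Check that tree leaves and alignment ids agree
#'
#' @param tree an `ape::phylo` tree.
#' @param msa an `aa_msa`.
#' @return invisibly `TRUE`; errors naming the offending labels otherwise.
#' @export
check_tree_msa <- function(tree, msa) {
  only_tree <- setdiff(tree$tip.label, rownames(msa))
  only_msa <- setdiff(rownames(msa), tree$tip.label)
  if (length(only_tree) || length(only_msa)) {
    stop("tree/alignment label mismatch",
         if (length(only_tree)) paste0("; only in tree: ",
                                       paste(only_tree, collapse = ", ")),
         if (length(only_msa)) paste0("; only in alignment: ",
                                      paste(only_msa, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a four-way group assignment
#'
#' Each sequence is annotated with its species, its paralog copy (exactly two
#' labels in use) and its species group (`"group1"` or `"group2"`).  The four
#' scoring cells are species group x paralog copy.
#'
#' @param id character vector of sequence ids.
#' @param species species of each sequence.
#' @param paralog paralog copy label of each sequence (two distinct values).
#' @param species_group `"group1"` or `"group2"` for each sequence.
#' @param mode `"manual"` or `"automatic"`.
#' @param grouping_id optional identifier for this grouping.
#' @return a `group_assignment` data.frame.
#' @export
group_assignment <- function(id, species, paralog, species_group,
                             mode = "manual", grouping_id = NULL) {
  g <- data.frame(id = as.character(id), species = as.character(species),
                  paralog = as.character(paralog),
                  species_group = as.character(species_group),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(g$id)) stop("duplicated ids in group assignment", call. = FALSE)
  if (length(unique(g$paralog)) != 2L) {
    stop("exactly two paralog labels are required (binary classification)",
         call. = FALSE)
  }
  if (!all(g$species_group %in% c("group1", "group2"))) {
    stop("species_group must be 'group1' or 'group2'", call. = FALSE)
  }
  attr(g, "mode") <- match.arg(mode, c("manual", "automatic"))
  attr(g, "grouping_id") <- grouping_id %||% "manual"
  class(g) <- c("group_assignment", class(g))
  g
}

as_group_assignment <- function(x) {
  if (inherits(x, "group_assignment")) return(x)
  need <- c("id", "species", "paralog", "species_group")
  if (is.data.frame(x) && all(need %in% names(x))) {
    return(group_assignment(x$id, x$species, x$paralog, x$species_group))
  }
  stop("cannot interpret object as a group assignment", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a group mapping table
#'
#' Tab-separated file with columns `id`, `species`, `paralog`, `species_group`.
#' Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return a `group_assignment`.
#' @export
read_group_table <- function(path) {
  g <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "species", "paralog", "species_group")
  if (!all(need %in% names(g))) {
    stop("group table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  group_assignment(g$id, g$species, g$paralog, g$species_group)
}

#' @rdname read_group_table
#' @param groups a `group_assignment`.
#' @export
write_group_table <- function(groups, path) {
  utils::write.table(as.data.frame(unclass(groups))[, c("id", "species",
                                                        "paralog", "species_group")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Automatic candidate groupings from a duplication tree
#'
#' The two clades flanking the root-most split define the paralog labels.
#' Candidate species groupings are the monophyletic species clades that are
#' mirrored in both paralog clades, whose stem branch exceeds `distance_param`
#' in both clades, and that contain at least `min_group` species; each
#' candidate sets `group1` to the clade's species and `group2` to the
#' complement.
#'
#' @param tree rooted `ape::phylo` tree whose root separates the two paralog
#'   clades.
#' @param species named character vector mapping every tip label to a species.
#' @param distance_param stem-length threshold for a species clade to be
#'   considered (default 0).
#' @param min_group minimum number of species in `group1` (default 2).
#' @return list of `group_assignment` candidates (mode `"automatic"`).
#' @export
auto_groupings <- function(tree, species, distance_param = 0, min_group = 2L) {
  if (anyNA(species[tree$tip.label])) {
    stop("species must be named for every tree tip", call. = FALSE)
  }
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- node_children(tree, root)
  if (length(kids) != 2L) {
    stop("tree root does not split into two paralog clades", call. = FALSE)
  }
  desc <- clade_tips(tree)
  clade_a <- desc[[kids[1L]]]
  clade_b <- desc[[kids[2L]]]
  if (length(clade_a) < 2L || length(clade_b) < 2L) {
    stop("paralog clades must each contain at least two sequences", call. = FALSE)
  }
  paralog <- character(n_tip)
  paralog[clade_a] <- "a"
  paralog[clade_b] <- "b"
  sp <- species[tree$tip.label]
  all_species <- unique(sp)

  # species sets of sufficiently long-stemmed clades inside one paralog clade
  clade_species_sets <- function(clade_root) {
    nodes <- setdiff(which(vapply(desc, function(d)
      all(d %in% desc[[clade_root]]), TRUE)), seq_len(n_tip))
    nodes <- setdiff(nodes, clade_root)
    sets <- lapply(nodes, function(nn) sort(unique(sp[desc[[nn]]])))
    keep <- vapply(nodes, function(nn) stem_length(tree, nn) > distance_param, TRUE)
    sets[keep]
  }
  sets_a <- clade_species_sets(kids[1L])
  sets_b <- clade_species_sets(kids[2L])
  keys_b <- vapply(sets_b, paste, "", collapse = "|")

  cand <- list()
  seen <- character(0)
  for (s in sets_a) {
    key <- paste(s, collapse = "|")
    if (key %in% seen) next
    if (!key %in% keys_b) next            # must be mirrored in the other copy
    if (length(s) < min_group) next
    if (length(s) >= length(all_species)) next
    seen <- c(seen, key)
    sg <- ifelse(sp %in% s, "group1", "group2")
    cand[[length(cand) + 1L]] <- group_assignment(
      tree$tip.label, sp, paralog, sg, mode = "automatic",
      grouping_id = paste0("auto:", key))
  }
  cand
}

#' Bundle an alignment with its grouping
#'
#' @param msa an `aa_msa`.
#' @param groups a `group_assignment`; all its ids must appear in the
#'   alignment.  Alignment rows without an assignment are carried along (e.g.
#'   reference sequences) but not scored.
#' @param reference_id optional id used for coordinate mapping.
#' @return a `grouped_msa` list with elements `msa`, `groups`, `reference_id`
#'   and `cells` (ids per scoring cell `Xa`, `Ya`, `Xb`, `Yb`; `X` = group1,
#'   `Y` = group2, `a`/`b` = the two paralog labels in sorted order).
#' @export
grouped_alignment <- function(msa, groups, reference_id = NULL) {
  groups <- as_group_assignment(groups)
  missing <- setdiff(groups$id, rownames(msa))
  if (length(missing)) {
    stop("grouped ids absent from alignment: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(reference_id) && !reference_id %in% rownames(msa)) {
    stop("reference id not in alignment: ", reference_id, call. = FALSE)
  }
  lab <- sort(unique(groups$paralog))
  cell_of <- function(g, p) groups$id[groups$species_group == g & groups$paralog == p]
  cells <- list(Xa = cell_of("group1", lab[1L]), Ya = cell_of("group2", lab[1L]),
                Xb = cell_of("group1", lab[2L]), Yb = cell_of("group2", lab[2L]))
  if (any(vapply(cells, length, 1L) == 0L)) {
    stop("all four cells (species group x paralog) must be non-empty",
         call. = FALSE)
  }
  structure(list(msa = msa, groups = groups, reference_id = reference_id,
                 cells = cells),
            class = "grouped_msa")
}
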