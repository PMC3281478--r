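#' Parse a Newick string into a phylogenetic tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. Malformed parentheses or
#' an unterminated quoted label are reported with the character offset at which
#' the problem was detected; duplicate leaf labels are rejected. Square-bracket
#' comments are dropped. Branch lengths, when present, are parsed and stored on
#' the returned tree but are ignored by the default (unweighted) ancestral
#' reconstruction; [squared_change_reconstruct()] emits a classed message when
#' it discards them.
#'
#' @param text A Newick string (single tree, terminated by `;`). Quoted labels
#'   are accepted; surrounding quotes are stripped.
#' @return An object of class `phylo` (see [ape::read.tree()]): rooted tree,
#'   tips numbered `1..n` in `tip.label` order, internal nodes `n+1..n+Nnode`
#'   with the root at `n+1`.
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  scan_newick_syntax(text)
  cleaned <- strip_newick_comments(text)
  tr <- tryCatch(
    withCallingHandlers(
      ape::read.tree(text = cleaned),
      warning = function(w) {
        abort(paste0("Newick parse error: ", conditionMessage(w)),
              class = "brushfoot_parse_error")
      }
    ),
    error = function(e) {
      abort(paste0("Newick parse error: ", conditionMessage(e)),
            class = "brushfoot_parse_error")
    }
  )
  if (is.null(tr)) {
    abort("Newick parse error: input did not yield a tree",
          class = "brushfoot_parse_error")
  }
  tr$tip.label <- strip_label_quotes(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- strip_label_quotes(tr$node.label)
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) {
    abort(paste0("duplicate leaf label(s): ", paste(dup, collapse = ", ")),
          class = "brushfoot_validation_error")
  }
  if (any(!nzchar(tr$tip.label))) {
    abort("leaf with empty label", class = "brushfoot_validation_error")
  }
  tr
}

# character-by-character pre-scan so syntax errors carry an offset
scan_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  quote_start <- NA_integer_
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_quote) {
      if (ch == "'") in_quote <- FALSE
      next
    }
    if (ch == "'") {
      in_quote <- TRUE
      quote_start <- i
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("Newick parse error at character offset %d: unmatched ')'", i),
              class = "brushfoot_parse_error")
      }
    }
  }
  if (in_quote) {
    abort(sprintf("Newick parse error at character offset %d: unterminated quote",
                  quote_start),
          class = "brushfoot_parse_error")
  }
  if (depth != 0L) {
    abort(sprintf("Newick parse error at character offset %d: %d unclosed '('",
                  length(chars), depth),
          class = "brushfoot_parse_error")
  }
  invisible(TRUE)
}

# drop [...] comments outside quoted labels
strip_newick_comments <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  out <- character(0)
  in_quote <- FALSE
  in_comment <- FALSE
  for (ch in chars) {
    if (in_comment) {
      if (ch == "]") in_comment <- FALSE
      next
    }
    if (!in_quote && ch == "[") {
      in_comment <- TRUE
      next
    }
    if (ch == "'") in_quote <- !in_quote
    out <- c(out, ch)
  }
  paste(out, collapse = "")
}

strip_label_quotes <- function(x) {
  quoted <- grepl("^'.*'$", x)
  x[quoted] <- gsub("''", "'", substr(x[quoted], 2, nchar(x[quoted]) - 1))
  x
}

#' Serialize a phylogenetic tree to Newick
#'
#' Inverse of [parse_newick()]: `parse_newick(write_newick(tr))` has the same
#' leaf set and the same parent/child relations as `tr`.
#'
#' @param tree A `phylo` object.
#' @return A single Newick string ending in `;`.
#' @export
write_newick <- function(tree) {
  check_phylo(tree)
  ape::write.tree(tree)
}

#' Species-to-family assignment of the 13 study taxa
#'
#' @return A tibble with columns `species` and `family` covering the six
#'   butterfly families represented in the packaged study topology
#'   (Hesperiidae outgroup, Papilionidae, Pieridae, Nymphalidae, Lycaenidae,
#'   Riodinidae).
#' @export
study_families <- function() {
  tibble(
    species = c(
      "Epargyreus_clarus",
      "Parnassius_phoebus",
      "Zerene_eurydice", "Neophasia_terlooii", "Pieris_rapae",
      "Libytheana_carinenta", "Bicyclus_anynana", "Asterocampa_clyton",
      "Junonia_coenia",
      "Lycaena_phlaeas", "Satyrium_titus",
      "Apodemia_mormo", "Calephelis_borealis"
    ),
    family = c(
      "Hesperiidae",
      "Papilionidae",
      rep("Pieridae", 3),
      rep("Nymphalidae", 4),
      rep("Lycaenidae", 2),
      rep("Riodinidae", 2)
    )
  )
}

#' The packaged 13-taxon study topology
#'
#' Rooted cladogram of the 13 study species: *Epargyreus clarus* (Hesperiidae)
#' as outgroup, Papilionidae sister to the remainder, a Pieridae clade, and
#' the clade (Nymphalidae, (Lycaenidae, Riodinidae)) — Riodinidae sister to
#' Lycaenidae, both sister to Nymphalidae. Branch lengths are absent by
#' construction (reconstruction is unweighted). Each leaf carries a family
#' annotation in `attr(tree, "family")`, a character vector named by tip
#' label; see [study_families()].
#'
#' The resolution inside Nymphalidae and Pieridae is an editorial choice of
#' this package (see the methods vignette); family-stem event detection does
#' not depend on it when a whole family is reduced.
#'
#' @return A `phylo` object with 13 tips.
#' @examples
#' tr <- study_tree()
#' ape::Ntip(tr)
#' @export
study_tree <- function() {
  path <- system.file("extdata", "study_13taxa.nwk",
                      package = "brushfoot", mustWork = TRUE)
  tr <- parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
  fam <- study_families()
  attr(tr, "family") <- setNames(fam$family, fam$species)[tr$tip.label]
  tr
}

#' Validate a phylogenetic tree
#'
#' Checks the invariants required by the reconstruction machinery and returns
#' human-readable diagnostics instead of raising errors: duplicate or empty
#' leaf labels, unary internal nodes (exactly one child), nodes unreachable
#' from the root, and trees with fewer than two leaves. Polytomies are
#' permitted.
#'
#' @param tree A `phylo` object.
#' @return A character vector of diagnostics; `character(0)` iff the tree is
#'   valid.
#' @export
validate_tree <- function(tree) {
  out <- character(0)
  if (!inherits(tree, "phylo")) {
    return("not a 'phylo' object")
  }
  n <- ape::Ntip(tree)
  if (n < 2) out <- c(out, sprintf("tree has %d leaf/leaves; need at least 2", n))
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    out <- c(out, sprintf("duplicate leaf label(s): %s", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(tree$tip.label))) out <- c(out, "leaf with empty label")
  m <- n + tree$Nnode
  n_children <- tabulate(tree$edge[, 1], nbins = m)
  unary <- which(n_children == 1L)
  for (u in unary) out <- c(out, sprintf("unary internal node (id %d) has a single child", u))
  root <- tree_root(tree)
  reach <- rep(FALSE, m)
  reach[root] <- TRUE
  # edges in arbitrary order: propagate until fixpoint (trees are tiny)
  repeat {
    new <- reach[tree$edge[, 1]] & !reach[tree$edge[, 2]]
    if (!any(new)) break
    reach[tree$edge[new, 2]] <- TRUE
  }
  if (!all(reach)) {
    out <- c(out, sprintf("node(s) unreachable from root: %s",
                          paste(which(!reach), collapse = ", ")))
  }
  if (anyDuplicated(tree$edge[, 2])) {
    out <- c(out, "node with more than one parent")
  }
  out
}

check_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) {
    abort("`tree` must be a 'phylo' object (see parse_newick())",
          class = "brushfoot_validation_error")
  }
  invisible(tree)
}

tree_root <- function(tree) {
  setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
}

n_nodes <- function(tree) ape::Ntip(tree) + tree$Nnode

# edge matrix reordered so parents precede children (preorder over edges)
preorder_edges <- function(tree) {
  stats::reorder(tree, "cladewise")$edge
}

# node ids in preorder from the root
preorder_nodes <- function(tree) {
  e <- preorder_edges(tree)
  c(e[1, 1], e[, 2])
}

# parent id for every node (NA at the root), indexed by node id
parent_map <- function(tree) {
  p <- rep(NA_integer_, n_nodes(tree))
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

# all node ids in the clade rooted at `node` (inclusive)
clade_node_ids <- function(tree, node) {
  m <- n_nodes(tree)
  if (length(node) != 1 || is.na(node) || node < 1 || node > m) {
    abort(sprintf("unknown node id: %s", paste(node, collapse = ",")),
          class = "brushfoot_validation_error")
  }
  keep <- rep(FALSE, m)
  keep[node] <- TRUE
  e <- preorder_edges(tree)
  for (k in seq_len(nrow(e))) {
    if (keep[e[k, 1]]) keep[e[k, 2]] <- TRUE
  }
  which(keep)
}

# stem node of a set of tip labels: the MRCA (the tip itself for one label)
stem_node <- function(tree, labels) {
  idx <- match(labels, tree$tip.label)
  if (anyNA(idx)) {
    abort(sprintf("unknown leaf label(s): %s",
                  paste(labels[is.na(idx)], collapse = ", ")),
          class = "brushfoot_validation_error")
  }
  if (length(idx) == 1) return(idx)
  ape::getMRCA(tree, idx)
}

# leaf labels subtended by a node, in tip order
clade_tip_labels <- function(tree, node) {
  ids <- clade_node_ids(tree, node)
  tree$tip.label[ids[ids <= ape::Ntip(tree)]]
}
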