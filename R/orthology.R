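# Orthology calling: midpoint rooting plus species-overlap duplication
# detection on per-family gene trees.

#' Midpoint-root a gene tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, so
#' the two distances from the root to its farthest leaves agree to within
#' numerical tolerance.
#'
#' @param tree an `ape::phylo` object or Newick string with branch lengths.
#' @return a rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (ape::Ntip(tree) < 2) stop("midpoint rooting needs at least 2 leaves")
  if (is.null(tree$edge.length) || all(tree$edge.length == 0)) {
    # degenerate zero-length tree: deterministic arbitrary root
    return(ape::root(tree, outgroup = sort(tree$tip.label)[1],
                     resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

#' Detect duplication events by species overlap
#'
#' An internal node of a rooted gene tree is called a duplication when
#' the species sets of (any pair of) its child subtrees intersect. Each
#' event is dated by the deepest taxonomic rank shared by all species
#' under the node, looked up in `lineages`.
#'
#' @param tree rooted `ape::phylo` (or Newick string).
#' @param gene_species named character vector mapping tip label -> species.
#' @param lineages optional named list mapping species -> character(7)
#'   lineage vector (domain ... species) used to date events.
#' @return data.frame with one row per duplication: `node`,
#'   `overlap_species` (comma-collapsed), `n_species_under`, `dated_rank`.
#' @export
detect_duplications <- function(tree, gene_species, lineages = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  ntip <- ape::Ntip(tree)
  missing <- setdiff(tree$tip.label, names(gene_species))
  if (length(missing) > 0)
    stop("no species mapping for tip ", missing[1])
  nnode <- tree$Nnode
  # species set below each node, computed tips-up
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- unname(gene_species[tree$tip.label[i]])
  children <- split(tree$edge[, 2], tree$edge[, 1])
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(post))) {
    parent <- post[e, 1]; child <- post[e, 2]
    sets[[parent]] <- unique(c(sets[[parent]], sets[[child]]))
  }
  events <- list()
  for (nd in sort(unique(tree$edge[, 1]))) {
    kids <- children[[as.character(nd)]]
    overlap <- character(0)
    if (length(kids) >= 2) {
      for (i in seq_len(length(kids) - 1)) for (j in seq(i + 1, length(kids))) {
        overlap <- union(overlap, intersect(sets[[kids[i]]], sets[[kids[j]]]))
      }
    }
    if (length(overlap) > 0) {
      under <- sets[[nd]]
      events[[length(events) + 1]] <- data.frame(
        node = nd,
        overlap_species = paste(sort(overlap), collapse = ","),
        n_species_under = length(under),
        dated_rank = date_species_set(under, lineages),
        stringsAsFactors = FALSE)
    }
  }
  if (length(events) == 0)
    return(data.frame(node = integer(0), overlap_species = character(0),
                      n_species_under = integer(0),
                      dated_rank = character(0)))
  do.call(rbind, events)
}

# Deepest rank at which all species in the set share their lineage.
date_species_set <- function(species, lineages) {
  if (is.null(lineages)) return(NA_character_)
  mat <- do.call(rbind, lineages[species])
  if (is.null(mat)) return(NA_character_)
  shared <- 0L
  for (d in seq_len(ncol(mat))) {
    if (length(unique(mat[, d])) == 1) shared <- d else break
  }
  if (shared == 0L) "root" else GTDB_RANKS[shared]
}

#' Is a family a basal orthologous group?
#'
#' A family qualifies as a single orthologous group at the basal
#' (bacterial/archaeal) level when none of its duplication events dates
#' to a basal taxonomic rank.
#'
#' @param events data.frame from [detect_duplications()].
#' @param basal_ranks ranks treated as basal (default `"domain"`; the
#'   stricter `c("domain", "phylum")` is supported).
#' @return logical scalar.
#' @export
is_basal_orthologous_group <- function(events, basal_ranks = "domain") {
  if (nrow(events) == 0) return(TRUE)
  ranks <- events$dated_rank
  !any(ranks %in% c(basal_ranks, "root"))
}
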