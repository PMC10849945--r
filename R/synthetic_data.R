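# Deterministic, seeded generator of synthetic pangenome collections and
# case/control abundance matrices with planted ground truth for every
# pipeline stage: operon-embedded families for the context predictor,
# calibration ("known") families built the same way, context-shuffled
# null families, clade-restricted synapomorphic families, resistance
# islands, mobile contigs, codon families evolved under chosen dN/dS, and
# blocked abundance matrices with planted fold changes.

#' Simulation configuration
#'
#' Defaults give a balanced taxonomy of 2 domains x 2 phyla each x 3
#' orders per phylum (each order holding two GTDB families so that the
#' deepest rank shared by an order's species is the order itself), one
#' contig per genome, and planted families of every kind. All output is
#' fully determined by `seed`.
#'
#' @param seed integer seed driving every random choice.
#' @param genomes_per_order genomes simulated under each order.
#' @param genes_per_contig background genes per contig.
#' @param gene_len_range CDS length range in nt (rounded to codons).
#' @param gap_range background intergenic gap range in nt.
#' @param background_annotation_rate probability a background gene
#'   carries a (random) pathway annotation.
#' @param n_pathways size of the background KEGG pathway vocabulary.
#' @param n_operon_pathways number of (leading) pathways that form
#'   planted operons; calibration and planted families draw from this
#'   subset so every operon pathway accumulates enough known families.
#' @param n_kos size of the KO vocabulary.
#' @param members_per_family member genes per planted family.
#' @param n_known_families calibration families of known pathway.
#' @param n_operon_families novel operon-embedded families to recover.
#' @param n_null_families context-shuffled null families.
#' @param operon_member_fraction fraction of members embedded in the
#'   planted cassette (rounded to nearest member count).
#' @param cassette_size P-annotated genes per cassette (split across the
#'   two sides of the focal gene).
#' @param operon_max_gap largest intergenic gap inside a cassette (nt).
#' @param n_synapomorphy_families clade-restricted families, planted at
#'   order-level clades.
#' @param synapomorphy_coverage fraction of clade genomes carrying them.
#' @param n_resistance_families families with a resistance-flagged +1
#'   neighbour in every member.
#' @param n_small_peptide_families families whose longest protein is
#'   shorter than 50 residues.
#' @param incomplete_rate fraction of background genes flagged
#'   incomplete.
#' @param plasmid_contig_fraction,viral_contig_fraction mobile contig
#'   fractions.
#' @param abundance abundance-simulation settings: list with
#'   `n_families`, `n_samples`, `n_blocks`, `n_effect`, `fold_change`,
#'   `prevalence`, `sdlog`, `block_sd`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       genomes_per_order = 8,
                       genes_per_contig = 60,
                       gene_len_range = c(300, 900),
                       gap_range = c(20, 200),
                       background_annotation_rate = 0.3,
                       n_pathways = 200,
                       n_operon_pathways = 5,
                       n_kos = 40,
                       members_per_family = 8,
                       n_known_families = 30,
                       n_operon_families = 10,
                       n_null_families = 10,
                       operon_member_fraction = 0.9,
                       cassette_size = 4,
                       operon_max_gap = 60,
                       n_synapomorphy_families = 2,
                       synapomorphy_coverage = 1.0,
                       n_resistance_families = 2,
                       n_small_peptide_families = 2,
                       incomplete_rate = 0.05,
                       plasmid_contig_fraction = 0.1,
                       viral_contig_fraction = 0.05,
                       abundance = list(n_families = 500, n_samples = 200,
                                        n_blocks = 5, n_effect = 20,
                                        fold_change = 2, prevalence = 0.7,
                                        sdlog = 0.25, block_sd = 0.5)) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a balanced GTDB-style taxonomy
#'
#' @param config a [sim_config()].
#' @return taxonomy table (see [read_taxonomy_tsv()]).
#' @export
generate_taxonomy <- function(config) {
  rows <- list()
  g <- 0L
  for (d in 1:2) for (p in 1:2) for (o in 1:3) {
    phylum_idx <- (d - 1) * 2 + p
    order_idx <- (phylum_idx - 1) * 3 + o
    for (k in seq_len(config$genomes_per_order)) {
      g <- g + 1L
      fam_idx <- (order_idx - 1) * 2 + ((k - 1) %% 2) + 1  # 2 families/order
      lineage <- paste0(c(
        sprintf("d__D%d", d), sprintf("p__P%d", phylum_idx),
        sprintf("c__C%d", phylum_idx),  # one class per phylum
        sprintf("o__O%d", order_idx), sprintf("f__F%d", fam_idx),
        sprintf("g__G%d", fam_idx),    # one genus per family
        sprintf("s__S%04d", g)), collapse = ";")
      rows[[g]] <- data.frame(genome_id = sprintf("G%04d", g),
                              lineage = lineage, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  parts <- do.call(rbind, strsplit(tab$lineage, ";", fixed = TRUE))
  out <- data.frame(genome_id = tab$genome_id, parts,
                    stringsAsFactors = FALSE)
  names(out) <- c("genome_id", GTDB_RANKS)
  out$lineage <- tab$lineage
  out$uncultivated <- TRUE
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

random_protein <- function(n_res) {
  paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")), n_res,
               replace = TRUE), collapse = "")
}

#' Generate a synthetic pangenome collection with planted ground truth
#'
#' Simulates genomes under the configured taxonomy, annotates background
#' genes at random, and plants: calibration families of known pathway
#' (operon-embedded), novel operon families to recover, context-shuffled
#' null families, order-level synapomorphic families, resistance-island
#' families, and small-peptide families. Contigs are flagged mobile at
#' the configured rates. Identical configurations (including the seed)
#' yield identical collections.
#'
#' @param config a [sim_config()].
#' @return list with `genes` ([gene_table()]), `clusters` (named list),
#'   `taxonomy`, `contig_flags`, `truth` (list of data.frames:
#'   `known`, `operons`, `nulls`, `synapomorphies`, `resistance`,
#'   `small_peptides`), and `config`.
#' @export
generate_collection <- function(config = sim_config()) {
  set.seed(config$seed)
  taxonomy <- generate_taxonomy(config)
  n_genomes <- nrow(taxonomy)
  pathways <- sprintf("map%05d", seq_len(config$n_pathways))
  operon_pool <- pathways[seq_len(min(config$n_operon_pathways,
                                      config$n_pathways))]
  kos <- sprintf("K%05d", seq_len(config$n_kos))

  # per-contig gene specs: laid out into coordinates only at the end,
  # so planting can edit gaps/strands/annotations freely beforehand
  ngc <- config$genes_per_contig
  contigs <- vector("list", n_genomes)
  for (gi in seq_len(n_genomes)) {
    len <- 3 * sample(seq(config$gene_len_range[1] %/% 3,
                          config$gene_len_range[2] %/% 3), ngc,
                      replace = TRUE)
    spec <- data.frame(
      len = len,
      gap_before = sample(seq(config$gap_range[1], config$gap_range[2]),
                          ngc, replace = TRUE),
      strand = sample(c("+", "-"), ngc, replace = TRUE),
      ko = ifelse(stats::runif(ngc) < config$background_annotation_rate,
                  sample(kos, ngc, replace = TRUE), NA_character_),
      is_resistance = FALSE,
      is_complete = stats::runif(ngc) >= config$incomplete_rate,
      member_of = NA_character_,
      stringsAsFactors = FALSE)
    spec$pathways <- lapply(seq_len(ngc), function(i)
      if (is.na(spec$ko[i])) character(0) else sample(pathways, 1))
    contigs[[gi]] <- spec
  }
  # window slots available for cassette planting on each contig
  free_slots <- lapply(seq_len(n_genomes), function(gi) seq(4, ngc - 3))

  plant_cassette <- function(gi, focal, pathway, resistance_at = NULL) {
    spec <- contigs[[gi]]
    half <- config$cassette_size %/% 2
    offs <- setdiff(seq(-half, config$cassette_size - half), 0)
    for (o in offs) {
      j <- focal + o
      spec$pathways[[j]] <- unique(c(spec$pathways[[j]], pathway))
      if (is.na(spec$ko[j])) spec$ko[j] <- sample(kos, 1)
      spec$strand[j] <- spec$strand[focal]
    }
    for (j in (focal - half):(focal + (config$cassette_size - half)))
      if (j > 1) spec$gap_before[j] <- sample(10:config$operon_max_gap, 1)
    if (!is.null(resistance_at))
      spec$is_resistance[focal + resistance_at] <- TRUE
    contigs[[gi]] <<- spec
  }

  take_slot <- function(gi) {
    slots <- free_slots[[gi]]
    if (length(slots) == 0) return(NA_integer_)
    focal <- slots[sample.int(length(slots), 1)]
    free_slots[[gi]] <<- slots[abs(slots - focal) >= 7]
    focal
  }

  # genomes that can still host a planted member, preferring emptier ones
  pick_genomes <- function(n) {
    avail <- which(lengths(free_slots) > 0)
    sample(avail, min(n, length(avail)))
  }

  claim_member <- function(gi, focal, fam) {
    contigs[[gi]]$member_of[focal] <<- fam
    contigs[[gi]]$is_complete[focal] <<- TRUE
  }

  truth <- list()
  clusters <- list()
  fam_counter <- 0L
  new_family_id <- function() {
    fam_counter <<- fam_counter + 1L
    sprintf("NOVF%04d", fam_counter)
  }

  # families whose members sit inside a pathway cassette; `embed_frac`
  # of members embedded, the rest placed without context
  plant_context_family <- function(n_fams, embed_frac, annotate_members,
                                   resistance_at = NULL,
                                   pathway_cycle = FALSE,
                                   pathway_pool = operon_pool) {
    out <- data.frame(family_id = character(0), pathway = character(0))
    cycle <- rep_len(pathway_pool, max(n_fams, 1))
    for (k in seq_len(n_fams)) {
      fam <- new_family_id()
      p <- if (pathway_cycle) cycle[k] else sample(pathway_pool, 1)
      genomes <- pick_genomes(config$members_per_family)
      n_embed <- round(embed_frac * config$members_per_family)
      plen <- sample(80:300, 1)
      member_ids <- character(0)
      for (m in seq_along(genomes)) {
        gi <- genomes[m]
        focal <- take_slot(gi)
        if (is.na(focal)) next
        claim_member(gi, focal, fam)
        if (m <= n_embed)
          plant_cassette(gi, focal, p, resistance_at = resistance_at)
        if (annotate_members) {
          contigs[[gi]]$pathways[[focal]] <- p
          contigs[[gi]]$ko[focal] <- sample(kos, 1)
        }
        contigs[[gi]]$len[focal] <- 3 * (plen + sample(-5:5, 1) + 1)
        member_ids <- c(member_ids, sprintf("G%04d_g%03d", gi, focal))
      }
      clusters[[fam]] <<- member_ids
      out <- rbind(out, data.frame(family_id = fam, pathway = p,
                                   stringsAsFactors = FALSE))
    }
    out
  }

  # synapomorphic families first (they need slots in specific genomes):
  # exclusive to one order-level clade, covering a set fraction of its
  # genomes, >10 members via multiple copies per genome when needed
  orders <- unique(taxonomy$order)
  syn_rows <- list()
  for (k in seq_len(config$n_synapomorphy_families)) {
    fam <- new_family_id()
    ord <- orders[(k - 1) %% length(orders) + 1]
    clade_gi <- which(taxonomy$order == ord)
    n_cov <- ceiling(config$synapomorphy_coverage * length(clade_gi))
    chosen <- clade_gi[seq_len(n_cov)]
    member_ids <- character(0)
    gi_pool <- rep(chosen, length.out = max(11, length(chosen)))
    for (gi in gi_pool) {
      focal <- take_slot(gi)
      if (is.na(focal)) next
      claim_member(gi, focal, fam)
      member_ids <- c(member_ids, sprintf("G%04d_g%03d", gi, focal))
    }
    clusters[[fam]] <- member_ids
    syn_rows[[k]] <- data.frame(family_id = fam, rank = "order",
                                clade = ord, stringsAsFactors = FALSE)
  }
  truth$synapomorphies <- if (length(syn_rows) > 0) do.call(rbind, syn_rows)
    else data.frame(family_id = character(0), rank = character(0),
                    clade = character(0))

  # calibration families are built exactly like the novel operon
  # families (same embedded-member fraction), but their members carry
  # the true pathway annotation; pathways are cycled so every pathway
  # gets an equal share of calibration families
  truth$known <- plant_context_family(config$n_known_families,
                                      config$operon_member_fraction,
                                      annotate_members = TRUE,
                                      pathway_cycle = TRUE)
  truth$operons <- plant_context_family(config$n_operon_families,
                                        config$operon_member_fraction,
                                        annotate_members = FALSE)
  truth$resistance <- plant_context_family(config$n_resistance_families,
                                           1.0, annotate_members = FALSE,
                                           resistance_at = 1)
  if (config$n_resistance_families > 0)
    truth$resistance$position <- 1L

  # null families: members drawn at random, background context untouched
  nulls <- character(0)
  for (k in seq_len(config$n_null_families)) {
    fam <- new_family_id()
    member_ids <- character(0)
    for (gi in pick_genomes(config$members_per_family)) {
      focal <- take_slot(gi)
      if (is.na(focal)) next
      claim_member(gi, focal, fam)
      member_ids <- c(member_ids, sprintf("G%04d_g%03d", gi, focal))
    }
    clusters[[fam]] <- member_ids
    nulls <- c(nulls, fam)
  }
  truth$nulls <- data.frame(family_id = nulls, stringsAsFactors = FALSE)

  # small-peptide families (longest member < 50 residues)
  sp_rows <- list()
  for (k in seq_len(config$n_small_peptide_families)) {
    fam <- new_family_id()
    plen <- sample(20:45, 1)
    member_ids <- character(0)
    for (gi in pick_genomes(config$members_per_family)) {
      focal <- take_slot(gi)
      if (is.na(focal)) next
      claim_member(gi, focal, fam)
      contigs[[gi]]$len[focal] <- 3 * (plen + 1)
      member_ids <- c(member_ids, sprintf("G%04d_g%03d", gi, focal))
    }
    clusters[[fam]] <- member_ids
    sp_rows[[k]] <- data.frame(family_id = fam, max_len = plen,
                               stringsAsFactors = FALSE)
  }
  truth$small_peptides <- if (length(sp_rows) > 0) do.call(rbind, sp_rows)
    else data.frame(family_id = character(0), max_len = integer(0))

  # lay out coordinates and build the gene table
  gene_rows <- vector("list", n_genomes)
  for (gi in seq_len(n_genomes)) {
    spec <- contigs[[gi]]
    start <- cumsum(spec$gap_before + c(0, spec$len[-ngc])) - spec$gap_before[1]
    gid <- sprintf("G%04d_g%03d", gi, seq_len(ngc))
    is_member <- !is.na(spec$member_of)
    prot <- rep(NA_character_, ngc)
    prot[is_member] <- vapply(spec$len[is_member] %/% 3 - 1,
                              random_protein, character(1))
    df <- data.frame(gene_id = gid,
                     genome_id = taxonomy$genome_id[gi],
                     contig_id = sprintf("G%04d_c1", gi),
                     start = as.integer(start),
                     end = as.integer(start + spec$len),
                     strand = spec$strand,
                     is_complete = spec$is_complete,
                     protein_seq = prot,
                     ko = spec$ko,
                     is_resistance = spec$is_resistance,
                     stringsAsFactors = FALSE)
    df$pathways <- spec$pathways
    gene_rows[[gi]] <- df
  }
  genes <- gene_table(do.call(rbind, gene_rows))

  # drop families that could not be placed (window slots exhausted)
  empty <- names(clusters)[lengths(clusters) == 0]
  if (length(empty) > 0) {
    warning(length(empty), " planted families dropped: no free window",
            " slots left (increase genes_per_contig or genomes)")
    clusters <- clusters[lengths(clusters) > 0]
    for (nm in names(truth))
      if ("family_id" %in% names(truth[[nm]]))
        truth[[nm]] <- truth[[nm]][!truth[[nm]]$family_id %in% empty, ,
                                   drop = FALSE]
  }

  contig_ids <- sprintf("G%04d_c1", seq_len(n_genomes))
  contig_flags <- data.frame(
    contig_id = contig_ids,
    plasmid = stats::runif(n_genomes) < config$plasmid_contig_fraction,
    viral = stats::runif(n_genomes) < config$viral_contig_fraction,
    stringsAsFactors = FALSE)

  list(genes = genes, clusters = clusters, taxonomy = taxonomy,
       contig_flags = contig_flags, truth = truth, config = config)
}

#' Write a synthetic collection to disk in pipeline input formats
#'
#' Emits `genes.gff`, `annotations.tsv`, `clusters.tsv`, `taxonomy.tsv`,
#' `contig_flags.tsv`, `proteins.faa` and the truth tables under
#' `truth_*.tsv`. Output is byte-identical for identical collections.
#'
#' @param collection from [generate_collection()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- collection$genes
  write_gff(genes, file.path(dir, "genes.gff"))
  ann <- data.frame(gene_id = genes$gene_id,
                    ko = ifelse(is.na(genes$ko), "", genes$ko),
                    pathways = vapply(genes$pathways, paste, "",
                                      collapse = ","),
                    is_resistance = as.integer(genes$is_resistance))
  utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cl <- data.frame(
    family_id = rep(names(collection$clusters),
                    lengths(collection$clusters)),
    gene_id = unlist(collection$clusters, use.names = FALSE))
  utils::write.table(cl, file.path(dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_taxonomy_tsv(collection$taxonomy, file.path(dir, "taxonomy.tsv"))
  cf <- collection$contig_flags
  cf$plasmid <- as.integer(cf$plasmid); cf$viral <- as.integer(cf$viral)
  utils::write.table(cf, file.path(dir, "contig_flags.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prot <- genes$protein_seq[!is.na(genes$protein_seq)]
  names(prot) <- genes$gene_id[!is.na(genes$protein_seq)]
  if (length(prot) > 0) write_fasta(prot, file.path(dir, "proteins.faa"))
  for (nm in names(collection$truth))
    utils::write.table(collection$truth[[nm]],
                       file.path(dir, sprintf("truth_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# ---- codon-family evolution -------------------------------------------

random_cds <- function(n_codons, code = genetic_code()) {
  sense <- names(code)[code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# HKY-weighted choice of a replacement nucleotide (transitions favoured
# by kappa)
hky_target <- function(current, kappa) {
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  others <- setdiff(NUCS, current)
  w <- ifelse(others == transitions[current], kappa, 1)
  sample(others, 1, prob = w)
}

#' Evolve a codon family along a tree under a chosen dN/dS
#'
#' Markov codon substitution: mutation events arrive along each branch at
#' rate `mu` per nucleotide site; proposed changes use HKY transition
#' bias `kappa`; changes creating stop codons are rejected, and
#' non-synonymous changes are accepted with probability `omega`. The
#' resulting tip sequences are gap-free and aligned by construction.
#'
#' @param tree `ape::phylo` or Newick string with branch lengths.
#' @param omega non-synonymous acceptance probability (dN/dS dial).
#' @param n_codons ancestral sequence length (ignored when
#'   `ancestral_cds` is given).
#' @param ancestral_cds optional ancestral coding sequence.
#' @param kappa transition/transversion bias.
#' @param mu mutation-attempt rate per nt per unit branch length.
#' @param seed optional seed.
#' @return named character vector of tip sequences.
#' @export
evolve_codon_family <- function(tree, omega, n_codons = 100,
                                ancestral_cds = NULL, kappa = 2, mu = 1,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  code <- genetic_code()
  if (is.null(ancestral_cds)) ancestral_cds <- random_cds(n_codons, code)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- strsplit(ancestral_cds, "")[[1]]
  # parents precede children in a preorder edge walk
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    s <- seqs[[parent]]
    t_len <- ord$edge.length[e]
    n_events <- stats::rpois(1, mu * t_len * length(s))
    for (ev in seq_len(n_events)) {
      pos <- sample.int(length(s), 1)
      new_nuc <- hky_target(s[pos], kappa)
      cod_idx <- (pos - 1) %/% 3
      cod_pos <- (cod_idx * 3 + 1):(cod_idx * 3 + 3)
      old_codon <- paste(s[cod_pos], collapse = "")
      new_s <- s; new_s[pos] <- new_nuc
      new_codon <- paste(new_s[cod_pos], collapse = "")
      if (code[[new_codon]] == "*") next
      if (code[[new_codon]] != code[[old_codon]] &&
          stats::runif(1) >= omega) next
      s <- new_s
    }
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  names(out) <- tree$tip.label
  out
}

# ---- gene trees --------------------------------------------------------

# Nested newick following the taxonomy hierarchy; tip labels are gene
# ids, one per species (unless a clade subtree is duplicated). Trees are
# built clock-like: each taxonomic level sits at a fixed height (tips at
# 0) with mild per-edge rate jitter, so midpoint rooting recovers the
# basal split (the assumption the rooting step itself relies on).
clade_heights <- c(8, 7, 6, 5, 4, 3, 2, 1)  # above depth 1..7, tips 0

jittered <- function(len) len * (1 + stats::runif(length(len), -0.1, 0.1))

# returns "subtree" newick; the caller appends the edge above it
build_clade_newick <- function(lineages, labels, depth = 1) {
  if (length(labels) == 1) return(list(nwk = labels, height = 0))
  if (depth > ncol(lineages)) {
    parts <- sprintf("%s:%.4f", labels, jittered(rep(1, length(labels))))
    return(list(nwk = sprintf("(%s)", paste(parts, collapse = ",")),
                height = 1))
  }
  groups <- split(seq_along(labels), lineages[, depth])
  if (length(groups) == 1)
    return(build_clade_newick(lineages, labels, depth + 1))
  height <- clade_heights[depth]
  parts <- vapply(groups, function(i) {
    sub <- build_clade_newick(lineages[i, , drop = FALSE], labels[i],
                              depth + 1)
    sprintf("%s:%.4f", sub$nwk, jittered(height - sub$height))
  }, character(1))
  list(nwk = sprintf("(%s)", paste(parts, collapse = ",")),
       height = height)
}

#' Generate a per-family gene tree from the species taxonomy
#'
#' Builds a gene tree whose topology follows the taxonomy (one gene per
#' species), with random branch lengths. Optionally plants exactly one
#' duplication: the subtree of the given order-level clade is duplicated
#' into two sister gene copies, producing one species-overlap event dated
#' at that clade.
#'
#' @param taxonomy taxonomy table; the tree spans `species_genomes`
#'   (default: all genomes).
#' @param species_genomes genome ids to include.
#' @param planted_dup_order optional order name (e.g. `"o__O1"`) whose
#'   clade subtree is duplicated.
#' @return list with `newick`, `gene_species` (named vector tip ->
#'   species), and `lineages` (named list species -> character(7)).
#' @export
generate_gene_tree <- function(taxonomy, species_genomes = NULL,
                               planted_dup_order = NULL) {
  if (is.null(species_genomes)) species_genomes <- taxonomy$genome_id
  tax <- taxonomy[taxonomy$genome_id %in% species_genomes, , drop = FALSE]
  lin <- as.matrix(tax[, GTDB_RANKS])
  gene_species <- character(0)
  make_labels <- function(rows, suffix) {
    lb <- paste0("gene_", sub("^s__", "", lin[rows, "species"]), suffix)
    gene_species[lb] <<- lin[rows, "species"]
    lb
  }
  finish <- function(sub) sprintf("%s;", sub$nwk)
  if (is.null(planted_dup_order)) {
    labels <- make_labels(seq_len(nrow(tax)), "")
    nwk <- finish(build_clade_newick(lin, labels))
  } else {
    in_clade <- which(tax$order == planted_dup_order)
    if (length(in_clade) == 0) stop("no genomes under ", planted_dup_order)
    out_clade <- setdiff(seq_len(nrow(tax)), in_clade)
    sub_a <- build_clade_newick(lin[in_clade, , drop = FALSE],
                                make_labels(in_clade, "_a"))
    sub_b <- build_clade_newick(lin[in_clade, , drop = FALSE],
                                make_labels(in_clade, "_b"))
    # the duplication node sits just above the clade's own height, each
    # gene copy hanging from a short edge
    dup_h <- max(sub_a$height, sub_b$height) + 0.5
    dup_node <- list(
      nwk = sprintf("(%s:%.4f,%s:%.4f)", sub_a$nwk,
                    jittered(dup_h - sub_a$height), sub_b$nwk,
                    jittered(dup_h - sub_b$height)),
      height = dup_h)
    if (length(out_clade) == 0) {
      nwk <- finish(dup_node)
    } else {
      rest <- build_clade_newick(lin[out_clade, , drop = FALSE],
                                 make_labels(out_clade, ""))
      root_h <- max(clade_heights[1], rest$height + 1)
      nwk <- sprintf("(%s:%.4f,%s:%.4f);", dup_node$nwk,
                     jittered(root_h - dup_node$height), rest$nwk,
                     jittered(root_h - rest$height))
    }
  }
  lineages <- split(lin, row(lin))
  names(lineages) <- lin[, "species"]
  lineages <- lapply(split(seq_len(nrow(lin)), lin[, "species"]),
                     function(i) lin[i[1], ])
  list(newick = nwk, gene_species = gene_species, lineages = lineages)
}

#' Generate a blocked case/control abundance matrix with planted effects
#'
#' Log-normal baseline abundances per family, Gaussian per-block offsets
#' on the log scale, zero-inflation to the configured prevalence, and a
#' multiplicative fold change on case samples for the first `n_effect`
#' families. A fold change of 1 gives a null matrix (empty truth table).
#'
#' @param config a [sim_config()]; only its `seed` and `abundance`
#'   settings are used.
#' @return list with `abundance` (matrix families x samples), `meta`
#'   (data.frame `sample_id`, `condition`, `block`) and `truth`
#'   (data.frame of effect families with their fold change).
#' @export
generate_abundance <- function(config = sim_config()) {
  set.seed(config$seed + 1L)
  a <- config$abundance
  fams <- sprintf("AF%04d", seq_len(a$n_families))
  samples <- sprintf("S%04d", seq_len(a$n_samples))
  block <- sprintf("study%d", rep_len(seq_len(a$n_blocks), a$n_samples))
  # alternate conditions within each block so every block holds both
  idx_in_block <- stats::ave(seq_len(a$n_samples), block,
                             FUN = seq_along)
  condition <- ifelse(idx_in_block %% 2 == 1, "case", "control")
  meanlog <- stats::runif(a$n_families, -3, -1)
  block_off <- stats::rnorm(a$n_blocks, 0, a$block_sd)
  names(block_off) <- sprintf("study%d", seq_len(a$n_blocks))
  mat <- matrix(stats::rlnorm(a$n_families * a$n_samples,
                              meanlog = rep(meanlog, a$n_samples),
                              sdlog = a$sdlog),
                nrow = a$n_families, ncol = a$n_samples,
                dimnames = list(fams, samples))
  mat <- sweep(mat, 2, exp(block_off[block]), `*`)
  n_eff <- min(a$n_effect, a$n_families)
  if (n_eff > 0 && a$fold_change != 1) {
    case_cols <- condition == "case"
    mat[seq_len(n_eff), case_cols] <- mat[seq_len(n_eff), case_cols] *
      a$fold_change
  }
  detected <- matrix(stats::runif(length(mat)) < a$prevalence,
                     nrow = nrow(mat))
  mat[!detected] <- 0
  truth <- if (n_eff > 0 && a$fold_change != 1)
    data.frame(family_id = fams[seq_len(n_eff)],
               fold_change = a$fold_change, stringsAsFactors = FALSE)
  else data.frame(family_id = character(0), fold_change = numeric(0))
  list(abundance = mat,
       meta = data.frame(sample_id = samples, condition = condition,
                         block = block, stringsAsFactors = FALSE),
       truth = truth)
}
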