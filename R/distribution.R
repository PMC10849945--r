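# Taxonomic breadth (LCA), per-clade novelty density, habitat breadth,
# and mobility aggregation with the breadth-mobility association.

#' Last common ancestor lineage of a family
#'
#' The deepest lineage prefix shared by at least `support` of the
#' members' genomes. `support = 1` is the strict LCA; lowering it guards
#' against a small fraction of misannotated genes dragging the LCA to
#' very basal ranks.
#'
#' @param members character vector of member gene_ids.
#' @param genes a [gene_table()].
#' @param taxonomy a taxonomy table.
#' @param support minimum member fraction that must share the lineage.
#' @return list with `rank` (one of domain..species, or `"root"` when
#'   even the domain is not shared at the required support) and
#'   `lineage` (the shared prefix, `;`-joined; empty for root).
#' @export
family_lca <- function(members, genes, taxonomy, support = 1.0) {
  genomes <- genes$genome_id[match(members, genes$gene_id)]
  lin <- taxonomy[match(genomes, taxonomy$genome_id), GTDB_RANKS,
                  drop = FALSE]
  n <- nrow(lin)
  for (d in rev(seq_along(GTDB_RANKS))) {
    prefix <- apply(lin[, seq_len(d), drop = FALSE], 1, paste,
                    collapse = ";")
    tab <- table(prefix)
    if (max(tab) / n >= support) {
      return(list(rank = GTDB_RANKS[d], lineage = names(tab)[which.max(tab)]))
    }
  }
  list(rank = "root", lineage = "")
}

#' Novel-family density per clade
#'
#' For each clade at the given rank: the mean and standard deviation,
#' over the clade's genomes, of the number of distinct families present
#' in the genome, and the fraction of genomes flagged uncultivated.
#'
#' @param families data.frame with `family_id` and `members` list-column.
#' @param genes a [gene_table()].
#' @param taxonomy a taxonomy table (with `uncultivated`).
#' @param rank taxonomic rank to aggregate at.
#' @return data.frame (`clade`, `n_genomes`, `mean_families`,
#'   `sd_families`, `fraction_uncultivated`).
#' @export
novelty_density <- function(families, genes, taxonomy, rank = "order") {
  fam_genomes <- lapply(families$members, function(m)
    unique(genes$genome_id[match(m, genes$gene_id)]))
  per_genome <- table(unlist(fam_genomes))
  counts <- as.numeric(per_genome[taxonomy$genome_id])
  counts[is.na(counts)] <- 0
  clades <- split(seq_len(nrow(taxonomy)), taxonomy[[rank]])
  rows <- lapply(names(clades), function(cl) {
    i <- clades[[cl]]
    s <- if (length(i) > 1) stats::sd(counts[i]) else 0
    data.frame(clade = cl, n_genomes = length(i),
               mean_families = mean(counts[i]), sd_families = s,
               fraction_uncultivated = mean(taxonomy$uncultivated[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Family-level mobility flags from contig predictions
#'
#' A family is flagged as plasmid-borne (resp. viral) when the fraction
#' of its members on plasmid-flagged (resp. viral) contigs is strictly
#' greater than `member_fraction`. The default 0 reproduces the
#' "at least one member" rule; 0.3 gives the stricter variant.
#'
#' @param members character vector of member gene_ids.
#' @param genes a [gene_table()].
#' @param contig_flags data.frame with `contig_id`, `plasmid`, `viral`.
#' @param member_fraction fraction cutoff (exclusive).
#' @return named logical vector `c(mobile_plasmid=, mobile_viral=)`.
#' @export
mobility_flags <- function(members, genes, contig_flags,
                           member_fraction = 0.0) {
  contigs <- genes$contig_id[match(members, genes$gene_id)]
  i <- match(contigs, contig_flags$contig_id)
  plas <- contig_flags$plasmid[i]; plas[is.na(plas)] <- FALSE
  vir <- contig_flags$viral[i]; vir[is.na(vir)] <- FALSE
  c(mobile_plasmid = mean(plas) > member_fraction,
    mobile_viral = mean(vir) > member_fraction)
}

#' Habitat breadth of families from sample detections
#'
#' Counts, per family, distinct detection samples and distinct habitats
#' (after optional coarse grouping); a family is broadly distributed when
#' detected in strictly more than `min_samples` samples spanning at least
#' `min_habitats` habitats.
#'
#' @param detections data.frame (`family_id`, `sample_id`); duplicate
#'   rows are ignored.
#' @param sample_meta data.frame (`sample_id`, `habitat`).
#' @param habitat_groups optional named character vector mapping raw
#'   habitat -> coarse group; unmapped habitats become `"Other"`.
#' @param min_samples sample-count cutoff (exclusive).
#' @param min_habitats habitat-count cutoff (inclusive).
#' @return data.frame (`family_id`, `n_samples`, `n_habitats`,
#'   `broad_flag`).
#' @export
habitat_breadth <- function(detections, sample_meta, habitat_groups = NULL,
                            min_samples = 10, min_habitats = 2) {
  det <- unique(detections[, c("family_id", "sample_id")])
  hab <- sample_meta$habitat[match(det$sample_id, sample_meta$sample_id)]
  if (!is.null(habitat_groups)) {
    mapped <- habitat_groups[hab]
    hab <- ifelse(is.na(mapped), "Other", mapped)
  }
  sp <- split(seq_len(nrow(det)), det$family_id)
  rows <- lapply(names(sp), function(f) {
    i <- sp[[f]]
    ns <- length(unique(det$sample_id[i]))
    nh <- length(unique(hab[i]))
    data.frame(family_id = f, n_samples = ns, n_habitats = nh,
               broad_flag = ns > min_samples && nh >= min_habitats,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load the default coarse habitat grouping
#'
#' Ten ecological groups ("Human gut", "Marine", ..., "Other") shipped as
#' an editable YAML map from raw habitat labels to groups.
#'
#' @param path optional custom YAML file.
#' @return named character vector raw habitat -> group.
#' @export
default_habitat_groups <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "habitat_groups.yaml", package = "novfams")
  m <- yaml::read_yaml(path)
  unlist(m)
}

#' Association between habitat breadth and mobility
#'
#' Spearman correlation, across families, between the number of habitats
#' a family is detected in and its mobility flag, plus a binned summary
#' (default: tertiles of detection-sample counts as rareness levels)
#' giving the mobile proportion and mean habitat count per bin.
#'
#' @param breadth data.frame from [habitat_breadth()].
#' @param mobile named logical vector keyed by family_id.
#' @param n_bins number of rareness bins.
#' @return list with `rho` (0 with `degenerate = TRUE` when either
#'   variable is constant), `p`, `degenerate`, and data.frame `bins`
#'   (`bin`, `n`, `prop_mobile`, `mean_habitats`).
#' @export
breadth_mobility_association <- function(breadth, mobile, n_bins = 3) {
  m <- as.logical(mobile[breadth$family_id])
  m[is.na(m)] <- FALSE
  x <- breadth$n_habitats
  degenerate <- length(unique(x)) < 2 || length(unique(m)) < 2
  if (degenerate) {
    rho <- 0; pval <- NA_real_
  } else {
    ct <- suppressWarnings(stats::cor.test(x, as.numeric(m),
                                           method = "spearman"))
    rho <- unname(ct$estimate); pval <- ct$p.value
  }
  q <- stats::quantile(breadth$n_samples, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(breadth$n_samples, breaks = unique(q), include.lowest = TRUE,
             labels = FALSE)
  bins <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    data.frame(bin = b, n = sum(i), prop_mobile = mean(m[i]),
               mean_habitats = mean(x[i]))
  }))
  list(rho = rho, p = pval, degenerate = degenerate, bins = bins)
}
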