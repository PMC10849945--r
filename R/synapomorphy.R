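# Clade coverage/specificity scan for clade-defining (synapomorphic)
# gene families.

#' Clade coverage of a family
#'
#' Number of clade genomes containing at least one member gene, divided
#' by the number of genomes under the clade.
#'
#' @param member_genomes character vector: genome of each member gene.
#' @param clade_genomes character vector of genome_ids under the clade.
#' @return fraction in \[0, 1\] (`NA` for an empty clade).
#' @export
clade_coverage <- function(member_genomes, clade_genomes) {
  if (length(clade_genomes) == 0) return(NA_real_)
  length(intersect(unique(member_genomes), clade_genomes)) /
    length(clade_genomes)
}

#' Clade specificity of a family
#'
#' Fraction of member genes whose genome belongs to the clade.
#'
#' @inheritParams clade_coverage
#' @return fraction in \[0, 1\].
#' @export
clade_specificity <- function(member_genomes, clade_genomes) {
  if (length(member_genomes) == 0) return(NA_real_)
  mean(member_genomes %in% clade_genomes)
}

#' Scan families for synapomorphic distributions
#'
#' For every family and every clade at the requested ranks, emits a hit
#' when the family has strictly more than `min_members` member genes,
#' coverage strictly above `min_cov` and specificity at least `min_spec`.
#' The strict regime of the catalogue uses `min_cov = 0.9`,
#' `min_spec = 1.0`, `min_members = 10`; the broad validation scan uses
#' `min_cov = 0.7`, `min_spec = 0.9`, `min_members = 0`.
#'
#' @param families data.frame with `family_id` and `members` list-column.
#' @param genes a [gene_table()] (maps gene -> genome).
#' @param taxonomy a taxonomy table.
#' @param min_cov coverage cutoff (exclusive).
#' @param min_spec specificity cutoff (inclusive).
#' @param min_members member-count cutoff (exclusive).
#' @param ranks taxonomic ranks scanned.
#' @return data.frame (`family_id`, `rank`, `clade`, `coverage`,
#'   `specificity`, `n_members`).
#' @export
scan_synapomorphies <- function(families, genes, taxonomy,
                                min_cov = 0.9, min_spec = 1.0,
                                min_members = 10,
                                ranks = c("phylum", "class", "order")) {
  rows <- list()
  for (rk in ranks) {
    clades <- unique(taxonomy[[rk]])
    clade_genomes <- split(taxonomy$genome_id, taxonomy[[rk]])
    for (f in seq_len(nrow(families))) {
      members <- families$members[[f]]
      if (length(members) <= min_members) next
      mg <- genes$genome_id[match(members, genes$gene_id)]
      for (cl in clades) {
        cg <- clade_genomes[[cl]]
        if (length(cg) == 0) { warning("clade ", cl, " has no genomes"); next }
        spec <- clade_specificity(mg, cg)
        if (is.na(spec) || spec < min_spec) next
        cov <- clade_coverage(mg, cg)
        if (is.na(cov) || cov <= min_cov) next
        rows[[length(rows) + 1]] <- data.frame(
          family_id = families$family_id[f], rank = rk, clade = cl,
          coverage = cov, specificity = spec,
          n_members = length(members), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(family_id = character(0), rank = character(0),
                      clade = character(0), coverage = numeric(0),
                      specificity = numeric(0), n_members = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coverage/specificity table of all families against all clades
#'
#' The unfiltered companion of [scan_synapomorphies()]: every
#' (family, clade) pair at the requested ranks with its coverage and
#' specificity, suitable for export.
#'
#' @inheritParams scan_synapomorphies
#' @return data.frame (`family_id`, `rank`, `clade`, `coverage`,
#'   `specificity`, `n_members`).
#' @export
coverage_specificity_table <- function(families, genes, taxonomy,
                                       ranks = c("phylum", "class", "order")) {
  rows <- list()
  for (rk in ranks) {
    clade_genomes <- split(taxonomy$genome_id, taxonomy[[rk]])
    for (f in seq_len(nrow(families))) {
      members <- families$members[[f]]
      mg <- genes$genome_id[match(members, genes$gene_id)]
      for (cl in names(clade_genomes)) {
        cg <- clade_genomes[[cl]]
        rows[[length(rows) + 1]] <- data.frame(
          family_id = families$family_id[f], rank = rk, clade = cl,
          coverage = clade_coverage(mg, cg),
          specificity = clade_specificity(mg, cg),
          n_members = length(members), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
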