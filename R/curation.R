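# Family-level candidacy filters: complete-gene/species counts, conserved
# alignment domains, external-hit screens, and sequence-feature aggregation.

#' Select candidate gene families from raw clusters
#'
#' Retains clusters with at least `min_complete_genes` complete member
#' genes drawn from at least `min_species` distinct species (the GTDB
#' species rank of the member's genome). Clusters failing either rule are
#' dropped with a machine-readable reason code (`too_few_complete`,
#' `orphan`).
#'
#' @param clusters named list family_id -> member gene_ids.
#' @param genes a [gene_table()].
#' @param taxonomy a taxonomy table ([read_taxonomy_tsv()]).
#' @param min_complete_genes minimum number of complete member genes.
#' @param min_species minimum number of distinct species.
#' @return data.frame of retained families (`family_id`, `members`
#'   list-column, `n_members`, `n_complete`, `n_species`), with the
#'   dropped families and their reason codes in `attr(, "dropped")`.
#' @export
select_candidate_families <- function(clusters, genes, taxonomy,
                                      min_complete_genes = 3,
                                      min_species = 2) {
  if (length(clusters) == 0) {
    out <- data.frame(family_id = character(0))
    out$members <- list()
    attr(out, "dropped") <- data.frame(family_id = character(0),
                                       reason = character(0))
    return(out)
  }
  idx <- match(unlist(clusters, use.names = FALSE), genes$gene_id)
  if (anyNA(idx)) {
    fam_of <- rep(names(clusters), lengths(clusters))
    stop("family ", fam_of[is.na(idx)][1],
         " has member gene(s) absent from the gene table")
  }
  species_of_genome <- taxonomy$species[match(genes$genome_id,
                                              taxonomy$genome_id)]
  stats <- lapply(clusters, function(members) {
    i <- match(members, genes$gene_id)
    complete <- genes$is_complete[i]
    sp <- species_of_genome[i][complete]
    c(n_members = length(members),
      n_complete = sum(complete),
      n_species = length(unique(sp[!is.na(sp)])))
  })
  m <- do.call(rbind, stats)
  reason <- rep(NA_character_, length(clusters))
  reason[m[, "n_complete"] < min_complete_genes] <- "too_few_complete"
  reason[is.na(reason) & m[, "n_species"] < min_species] <- "orphan"
  keep <- is.na(reason)
  out <- data.frame(family_id = names(clusters)[keep],
                    n_members = m[keep, "n_members"],
                    n_complete = m[keep, "n_complete"],
                    n_species = m[keep, "n_species"],
                    stringsAsFactors = FALSE)
  out$members <- unname(clusters[keep])
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(family_id = names(clusters)[!keep],
                                     reason = reason[!keep],
                                     stringsAsFactors = FALSE)
  out
}

#' Find the most conserved domain of an alignment
#'
#' The conserved domain is the longest run of consecutive alignment
#' columns in which the fraction of non-gap residues is at least
#' `min_occupancy` (gaps are `-` and `.`). Ties are broken by the
#' leftmost run.
#'
#' @param alignment named character vector of equal-length aligned
#'   amino-acid sequences.
#' @param min_occupancy minimum per-column non-gap fraction.
#' @return integer vector `c(col_start, col_end)`, a 0-based half-open
#'   column interval, or `NULL` when no column qualifies.
#' @export
find_conserved_domain <- function(alignment, min_occupancy = 0.8) {
  if (length(alignment) == 0) return(NULL)
  mat <- do.call(rbind, strsplit(unname(alignment), ""))
  occ <- colMeans(mat != "-" & mat != ".")
  ok <- occ >= min_occupancy
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]  # which.max: leftmost tie-break
  c(starts[best] - 1L, ends[best])
}

#' Filter families by conserved-domain length
#'
#' Keeps families whose most conserved domain spans at least `min_len`
#' aligned residues; families with no qualifying domain are dropped.
#'
#' @param families data.frame with a `domain` list-column of
#'   `c(start, end)` intervals (or `NULL`s), e.g. filled by
#'   [find_conserved_domain()].
#' @param min_len minimum domain length in residues.
#' @return the retained rows.
#' @export
filter_by_domain <- function(families, min_len = 20) {
  len <- vapply(families$domain, function(d)
    if (is.null(d)) 0L else as.integer(d[2] - d[1]), integer(1))
  families[len >= min_len, , drop = FALSE]
}

#' Drop families with significant external database hits
#'
#' Families with a qualifying hit in any screened database are considered
#' non-novel and removed. Sequence-search hits qualify with E-value
#' strictly below `evalue_max` and coverage strictly above `min_coverage`;
#' HMM-screen hits (database names in `hmm_databases`) with E-value
#' strictly below `hmm_evalue_max`.
#'
#' @param families data.frame with `family_id`.
#' @param hit_table data.frame with columns `family_id`, `database`,
#'   `evalue`, `coverage` (may have zero rows).
#' @param evalue_max,min_coverage,hmm_evalue_max significance cutoffs.
#' @param hmm_databases databases screened with profile HMMs.
#' @return the families without qualifying hits; dropped ids in
#'   `attr(, "dropped")`.
#' @export
drop_flagged_families <- function(families, hit_table,
                                  evalue_max = 1e-3, min_coverage = 0.5,
                                  hmm_evalue_max = 1e-5,
                                  hmm_databases = c("antifam", "pvog")) {
  if (is.null(hit_table) || nrow(hit_table) == 0) {
    attr(families, "dropped") <- character(0)
    return(families)
  }
  is_hmm <- tolower(hit_table$database) %in% hmm_databases
  sig <- ifelse(is_hmm,
                hit_table$evalue < hmm_evalue_max,
                hit_table$evalue < evalue_max & hit_table$coverage > min_coverage)
  flagged <- unique(hit_table$family_id[sig])
  keep <- !(families$family_id %in% flagged)
  out <- families[keep, , drop = FALSE]
  attr(out, "dropped") <- intersect(families$family_id, flagged)
  out
}

#' Aggregate per-gene prediction flags to the family level
#'
#' A family is flagged (e.g. secreted, transmembrane) when at least
#' `min_fraction` of its members carry the per-gene flag.
#'
#' @param members character vector of member gene_ids.
#' @param per_gene_flags named logical vector keyed by gene_id.
#' @param min_fraction member fraction required (>= comparison).
#' @return logical scalar.
#' @export
aggregate_member_flags <- function(members, per_gene_flags,
                                   min_fraction = 0.8) {
  flags <- per_gene_flags[members]
  flags[is.na(flags)] <- FALSE
  mean(flags) >= min_fraction
}

#' Flag small-peptide families
#'
#' A family is a small-peptide family when its longest member protein is
#' strictly shorter than `max_len` residues.
#'
#' @param families data.frame with a `members` list-column.
#' @param genes a [gene_table()] with `protein_seq`.
#' @param max_len length cutoff in residues (exclusive).
#' @return `families` with a logical `small_peptide` column.
#' @export
flag_small_peptides <- function(families, genes, max_len = 50) {
  families$small_peptide <- vapply(families$members, function(m) {
    len <- family_length_members(m, genes)
    !is.na(len) && len < max_len
  }, logical(1))
  families
}

#' Length of a gene family
#'
#' The length of a family is the length in residues of its longest member
#' protein.
#'
#' @param members character vector of member gene_ids.
#' @param genes a [gene_table()] with `protein_seq`.
#' @return integer length, `NA` when no member has a protein sequence.
#' @export
family_length <- function(members, genes) {
  family_length_members(members, genes)
}

family_length_members <- function(members, genes) {
  seqs <- genes$protein_seq[match(members, genes$gene_id)]
  seqs <- seqs[!is.na(seqs)]
  if (length(seqs) == 0) return(NA_integer_)
  max(nchar(seqs))
}

#' Mean pairwise amino-acid identity of an alignment
#'
#' Identity of a pair is computed over columns where neither sequence has
#' a gap; the family value is the mean over all member pairs.
#'
#' @param alignment named character vector of aligned sequences.
#' @return fraction in \[0, 1\], `NA` for fewer than 2 sequences.
#' @export
mean_pairwise_identity <- function(alignment) {
  n <- length(alignment)
  if (n < 2) return(NA_real_)
  mat <- do.call(rbind, strsplit(unname(alignment), ""))
  gap <- mat == "-" | mat == "."
  ids <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    use <- !gap[i, ] & !gap[j, ]
    if (!any(use)) next
    ids <- c(ids, mean(mat[i, use] == mat[j, use]))
  }
  if (length(ids) == 0) NA_real_ else mean(ids)
}
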