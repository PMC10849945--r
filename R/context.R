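# Calibrated genomic-context ("guilt-by-association") pathway predictor.
# Four conservation scores are computed per (family, pathway) over +-3
# gene windows, compared against per-pathway thresholds calibrated on
# families of known function.

#' Extract the genomic neighbourhood of a gene
#'
#' Returns the up to `window` genes on each side of the focal gene on its
#' contig (by gene rank), with relative positions, strand agreement with
#' the focal gene, annotations, and the chain of intergenic gaps linking
#' each neighbour back to the focal gene. Windows are truncated at contig
#' ends. Gaps are `start(g) - end(previous gene)` in half-open
#' coordinates and may be negative for overlapping genes.
#'
#' @param gene_id focal gene.
#' @param genes a [gene_table()] (annotated).
#' @param window number of genes per side.
#' @return list with `gene_id`, `strand`, and data.frame `neighbours`
#'   (`rel_pos`, `gene_id`, `same_strand`, `is_resistance`, `ko`,
#'   `pathways` list-column, `gap_chain` list-column of numeric gaps).
#' @export
extract_neighborhood <- function(gene_id, genes, window = 3) {
  i <- match(gene_id, genes$gene_id)
  if (is.na(i)) stop("gene ", gene_id, " not in gene table")
  contig <- genes$contig_id[i]
  on_contig <- genes[genes$contig_id == contig, , drop = FALSE]
  on_contig <- on_contig[order(on_contig$rank_on_contig), , drop = FALSE]
  focal_rank <- on_contig$rank_on_contig[match(gene_id, on_contig$gene_id)]
  # gap between gene at rank r and rank r-1
  gaps <- c(NA_real_, on_contig$start[-1] - on_contig$end[-nrow(on_contig)])
  rel <- on_contig$rank_on_contig - focal_rank
  keep <- rel != 0 & abs(rel) <= window
  nb <- on_contig[keep, , drop = FALSE]
  rel <- rel[keep]
  gap_chain <- lapply(rel, function(r) {
    if (r > 0) gaps[(focal_rank + 2):(focal_rank + 1 + r)]
    else gaps[(focal_rank + 1 + r + 1):(focal_rank + 1)]
  })
  ord <- order(rel)
  out <- data.frame(rel_pos = rel[ord], gene_id = nb$gene_id[ord],
                    same_strand = nb$strand[ord] == genes$strand[i],
                    is_resistance = nb$is_resistance[ord],
                    ko = nb$ko[ord], stringsAsFactors = FALSE)
  out$pathways <- nb$pathways[ord]
  out$gap_chain <- gap_chain[ord]
  list(gene_id = gene_id, strand = genes$strand[i], neighbours = out)
}

#' Neighbourhoods for all members of a family
#' @param members character vector of member gene_ids.
#' @param genes a [gene_table()].
#' @param window genes per side.
#' @return list of [extract_neighborhood()] results.
#' @export
family_neighborhoods <- function(members, genes, window = 3) {
  lapply(members, extract_neighborhood, genes = genes, window = window)
}

#' Synteny conservation of a family for a pathway
#'
#' Fraction of family members whose window contains at least one gene
#' annotated to the pathway.
#'
#' @param neighborhoods list from [family_neighborhoods()].
#' @param pathway KEGG pathway id.
#' @return fraction in \[0, 1\].
#' @export
synteny_conservation <- function(neighborhoods, pathway) {
  if (length(neighborhoods) == 0) return(0)
  hit <- vapply(neighborhoods, function(nb)
    any(has_pathway(nb$neighbours$pathways, pathway)), logical(1))
  mean(hit)
}

#' Functional relatedness of a family for a pathway
#'
#' Pooled over all members: the number of neighbour genes annotated to
#' the pathway divided by the total number of neighbour genes
#' (unannotated neighbours count in the denominator). 0 when there are
#' no neighbours.
#'
#' @inheritParams synteny_conservation
#' @return fraction in \[0, 1\].
#' @export
functional_relatedness <- function(neighborhoods, pathway) {
  tot <- 0L; inp <- 0L
  for (nb in neighborhoods) {
    tot <- tot + nrow(nb$neighbours)
    inp <- inp + sum(has_pathway(nb$neighbours$pathways, pathway))
  }
  if (tot == 0) return(0)
  inp / tot
}

#' Strand conservation of a family for a pathway
#'
#' Among pathway-annotated neighbours pooled over members, the fraction
#' lying on the same strand as their focal member gene. 0 when there are
#' no pathway-annotated neighbours.
#'
#' @inheritParams synteny_conservation
#' @return fraction in \[0, 1\].
#' @export
strand_conservation <- function(neighborhoods, pathway) {
  n <- 0L; same <- 0L
  for (nb in neighborhoods) {
    inp <- has_pathway(nb$neighbours$pathways, pathway)
    n <- n + sum(inp)
    same <- same + sum(nb$neighbours$same_strand[inp])
  }
  if (n == 0) return(0)
  same / n
}

#' Distance conservation of a family for a pathway
#'
#' Among pathway-annotated neighbours pooled over members, the fraction
#' reachable from the focal gene through consecutive intergenic gaps each
#' at most `max_gap` nucleotides (negative gaps, i.e. overlaps, always
#' qualify). 0 when there are no pathway-annotated neighbours.
#'
#' @inheritParams synteny_conservation
#' @param max_gap largest intergenic distance in nucleotides.
#' @return fraction in \[0, 1\].
#' @export
distance_conservation <- function(neighborhoods, pathway, max_gap = 100) {
  n <- 0L; near <- 0L
  for (nb in neighborhoods) {
    inp <- which(has_pathway(nb$neighbours$pathways, pathway))
    n <- n + length(inp)
    for (k in inp)
      if (all(nb$neighbours$gap_chain[[k]] <= max_gap)) near <- near + 1L
  }
  if (n == 0) return(0)
  near / n
}

#' All four context scores of a family against one pathway
#'
#' @inheritParams distance_conservation
#' @return one-row data.frame (`pathway`, `synteny`, `relatedness`,
#'   `strand`, `distance`, `n_members_scored`).
#' @export
context_profile <- function(neighborhoods, pathway, max_gap = 100) {
  data.frame(pathway = pathway,
             synteny = synteny_conservation(neighborhoods, pathway),
             relatedness = functional_relatedness(neighborhoods, pathway),
             strand = strand_conservation(neighborhoods, pathway),
             distance = distance_conservation(neighborhoods, pathway, max_gap),
             n_members_scored = length(neighborhoods),
             stringsAsFactors = FALSE)
}

# pathways appearing anywhere in the windows of a family
window_pathways <- function(neighborhoods) {
  unique(unlist(lapply(neighborhoods, function(nb)
    unlist(nb$neighbours$pathways))))
}

#' Calibrate per-pathway score thresholds on known families
#'
#' For every pathway with at least `n_min` known (truly annotated)
#' families, determines — independently for each of the four context
#' scores — the score threshold at which the given fraction of known
#' families of that pathway is recovered: the empirical `(1 - level)`
#' quantile with lower interpolation of the known families' scores. By
#' construction the threshold at a higher recovery level is never
#' stricter than at a lower one.
#'
#' @param known_scores data.frame with columns `family_id`, `pathway`,
#'   `synteny`, `relatedness`, `strand`, `distance`: the context scores
#'   of known families against their true pathway.
#' @param levels recovery (confidence) levels.
#' @param n_min minimum known families per pathway; pathways below it are
#'   reported in `attr(, "uncalibrated")` and cannot be predicted.
#' @return data.frame (`pathway`, `level`, `thr_synteny`,
#'   `thr_relatedness`, `thr_strand`, `thr_distance`, `n_known`).
#' @export
calibrate_thresholds <- function(known_scores, levels = c(0.5, 0.9),
                                 n_min = 5) {
  score_cols <- c("synteny", "relatedness", "strand", "distance")
  pws <- unique(known_scores$pathway)
  counts <- table(known_scores$pathway)
  ok <- pws[counts[pws] >= n_min]
  rows <- list()
  for (p in ok) {
    sub <- known_scores[known_scores$pathway == p, , drop = FALSE]
    for (lv in levels) {
      thr <- vapply(score_cols, function(col)
        recovery_threshold(sub[[col]], lv), numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        pathway = p, level = lv,
        thr_synteny = thr["synteny"], thr_relatedness = thr["relatedness"],
        thr_strand = thr["strand"], thr_distance = thr["distance"],
        n_known = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(pathway = character(0), level = numeric(0),
               thr_synteny = numeric(0), thr_relatedness = numeric(0),
               thr_strand = numeric(0), thr_distance = numeric(0),
               n_known = integer(0))
  rownames(out) <- NULL
  attr(out, "uncalibrated") <- setdiff(pws, ok)
  out
}

# Empirical (1 - level) quantile, lower interpolation (type 1): the
# score above which at least `level` of the known families lie.
recovery_threshold <- function(scores, level) {
  s <- sort(scores)
  k <- max(1L, ceiling(length(s) * (1 - level)))
  s[k]
}

#' Predict pathway associations for a family
#'
#' A family is associated with a pathway at a confidence level when all
#' four of its context scores reach that pathway's thresholds at the
#' level; the highest level met is reported. Results are sorted by
#' confidence (descending) then synteny conservation (descending).
#'
#' @param neighborhoods list from [family_neighborhoods()].
#' @param calibrations data.frame from [calibrate_thresholds()].
#' @param max_gap intergenic distance cutoff for the distance score.
#' @return data.frame (`pathway`, `confidence`, `synteny`, `relatedness`,
#'   `strand`, `distance`), zero rows when nothing qualifies.
#' @export
predict_pathway_associations <- function(neighborhoods, calibrations,
                                         max_gap = 100) {
  candidates <- intersect(window_pathways(neighborhoods),
                          unique(calibrations$pathway))
  rows <- list()
  for (p in candidates) {
    prof <- context_profile(neighborhoods, p, max_gap)
    cal <- calibrations[calibrations$pathway == p, , drop = FALSE]
    cal <- cal[order(-cal$level), , drop = FALSE]
    for (r in seq_len(nrow(cal))) {
      if (prof$synteny >= cal$thr_synteny[r] &&
          prof$relatedness >= cal$thr_relatedness[r] &&
          prof$strand >= cal$thr_strand[r] &&
          prof$distance >= cal$thr_distance[r]) {
        rows[[length(rows) + 1]] <- data.frame(
          pathway = p, confidence = cal$level[r],
          synteny = prof$synteny, relatedness = prof$relatedness,
          strand = prof$strand, distance = prof$distance,
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(pathway = character(0), confidence = numeric(0),
                      synteny = numeric(0), relatedness = numeric(0),
                      strand = numeric(0), distance = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$confidence, -out$synteny), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count conserved resistance-gene neighbour positions
#'
#' The number of relative window positions (-3..-1, +1..+3) at which at
#' least `min_member_fraction` of family members have a
#' resistance-flagged neighbour.
#'
#' @param neighborhoods list from [family_neighborhoods()].
#' @param min_member_fraction member fraction required per position.
#' @return integer count of conserved positions.
#' @export
count_resistance_neighbors <- function(neighborhoods,
                                       min_member_fraction = 0.5) {
  n <- length(neighborhoods)
  if (n == 0) return(0L)
  positions <- c(-3:-1, 1:3)
  conserved <- 0L
  for (pos in positions) {
    k <- sum(vapply(neighborhoods, function(nb) {
      i <- match(pos, nb$neighbours$rel_pos)
      !is.na(i) && nb$neighbours$is_resistance[i]
    }, logical(1)))
    if (k / n >= min_member_fraction) conserved <- conserved + 1L
  }
  conserved
}

#' Positional synteny of adjacent neighbours
#'
#' For each requested relative position, the fraction of family members
#' whose neighbour at that position carries the position's most frequent
#' annotation label (default: KO); members lacking a neighbour or a label
#' there count against conservation. The family value is the mean across
#' positions.
#'
#' @param neighborhoods list from [family_neighborhoods()].
#' @param positions relative positions to score (default -1 and +1).
#' @return fraction in \[0, 1\].
#' @export
positional_synteny <- function(neighborhoods, positions = c(-1, 1)) {
  n <- length(neighborhoods)
  if (n == 0) return(0)
  per_pos <- vapply(positions, function(pos) {
    labels <- vapply(neighborhoods, function(nb) {
      i <- match(pos, nb$neighbours$rel_pos)
      if (is.na(i)) NA_character_ else nb$neighbours$ko[i]
    }, character(1))
    labels <- labels[!is.na(labels)]
    if (length(labels) == 0) return(0)
    max(table(labels)) / n
  }, numeric(1))
  mean(per_pos)
}
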