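# Case/control differential-abundance discovery with study blocking:
# abundance aggregation, stratified (van Elteren) Wilcoxon rank-sum,
# Benjamini-Hochberg FDR, effect and prevalence summaries.

#' Aggregate significant hits into a family x sample abundance matrix
#'
#' A hit is significant when its E-value is strictly below `evalue_max`
#' and its coverage on the family sequence strictly above `min_coverage`.
#' The relative abundance of a family in a sample is the sum of the
#' abundances of its significant hits; (family, sample) pairs without
#' hits are 0.
#'
#' @param hit_table data.frame (`family_id`, `sample_id`, `evalue`,
#'   `coverage`, `abundance`).
#' @param families family ids to include as rows (defaults to those in
#'   the hit table).
#' @param samples sample ids to include as columns (defaults to those in
#'   the hit table).
#' @param evalue_max,min_coverage significance cutoffs.
#' @return numeric matrix families x samples.
#' @export
family_abundance <- function(hit_table, families = NULL, samples = NULL,
                             evalue_max = 1e-3, min_coverage = 0.5) {
  if (is.null(families)) families <- unique(hit_table$family_id)
  if (is.null(samples)) samples <- unique(hit_table$sample_id)
  mat <- matrix(0, length(families), length(samples),
                dimnames = list(families, samples))
  if (nrow(hit_table) > 0) {
    sig <- hit_table$evalue < evalue_max & hit_table$coverage > min_coverage
    h <- hit_table[sig & hit_table$family_id %in% families &
                     hit_table$sample_id %in% samples, , drop = FALSE]
    if (nrow(h) > 0) {
      agg <- stats::aggregate(abundance ~ family_id + sample_id, data = h,
                              FUN = sum)
      mat[cbind(agg$family_id, agg$sample_id)] <- agg$abundance
    }
  }
  mat
}

#' Stratified (van Elteren) Wilcoxon rank-sum test
#'
#' Within each block, values are midranked and the case rank-sum is
#' compared with its null expectation; block statistics are combined
#' with van Elteren's locally most powerful weights `1/(n_b + 1)`
#' (or unweighted), with tie-corrected variances, and referred to the
#' standard normal for a two-sided p-value. Blocks containing a single
#' condition contribute nothing. With one block the statistic reduces to
#' the ordinary normal-approximation rank-sum test.
#'
#' @param values numeric vector.
#' @param condition factor/character with levels case/control
#'   (`case_level` marks the cases).
#' @param block factor/character of block (study) labels.
#' @param case_level value of `condition` identifying cases.
#' @param weighting `"van_elteren"` or `"unweighted"`.
#' @return list with `Z`, `p`, `n_blocks_used`.
#' @export
blocked_wilcoxon <- function(values, condition, block,
                             case_level = "case",
                             weighting = c("van_elteren", "unweighted")) {
  weighting <- match.arg(weighting)
  stopifnot(length(values) == length(condition),
            length(values) == length(block))
  num <- 0; den <- 0; used <- 0L
  for (b in unique(block)) {
    i <- which(block == b)
    is_case <- condition[i] == case_level
    n1 <- sum(is_case); n2 <- sum(!is_case)
    if (n1 == 0 || n2 == 0) next
    N <- n1 + n2
    r <- rank(values[i])
    W <- sum(r[is_case])
    EW <- n1 * (N + 1) / 2
    # tie-corrected variance of the rank sum
    VW <- n1 * n2 / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
    if (VW <= 0) next  # all values tied within the block
    w <- if (weighting == "van_elteren") 1 / (N + 1) else 1
    num <- num + w * (W - EW)
    den <- den + w^2 * VW
    used <- used + 1L
  }
  if (used == 0L || den == 0)
    return(list(Z = 0, p = 1, n_blocks_used = used))
  Z <- num / sqrt(den)
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)), n_blocks_used = used)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjustment producing q-values in the original order (`NA`s
#' propagated).
#'
#' @param pvalues numeric vector of p-values.
#' @return numeric vector of q-values.
#' @export
fdr_bh <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Differentially abundant families between cases and controls
#'
#' Runs [blocked_wilcoxon()] per family (families never detected are
#' excluded from testing), corrects with [fdr_bh()], and splits
#' significant families by the sign of the across-block average of
#' per-block mean(case) - mean(control). Prevalence is the fraction of
#' samples with non-zero abundance.
#'
#' @param abundance numeric matrix families x samples.
#' @param condition,block per-sample labels aligned with the columns.
#' @param alpha q-value cutoff (exclusive).
#' @param case_level value of `condition` identifying cases.
#' @param weighting passed to [blocked_wilcoxon()].
#' @return data.frame (`family_id`, `Z`, `p`, `q`, `effect` (mean
#'   per-block case-control difference), `prevalence`, `direction`
#'   in {over, under, ns}), sorted by q.
#' @export
differential_families <- function(abundance, condition, block,
                                  alpha = 0.01, case_level = "case",
                                  weighting = "van_elteren") {
  stopifnot(ncol(abundance) == length(condition),
            ncol(abundance) == length(block))
  prevalence <- rowMeans(abundance > 0)
  testable <- which(prevalence > 0)
  res <- lapply(testable, function(f) {
    t <- blocked_wilcoxon(abundance[f, ], condition, block,
                          case_level = case_level, weighting = weighting)
    effs <- vapply(unique(block), function(b) {
      i <- block == b
      ca <- abundance[f, i & condition == case_level]
      co <- abundance[f, i & condition != case_level]
      if (length(ca) == 0 || length(co) == 0) NA_real_
      else mean(ca) - mean(co)
    }, numeric(1))
    data.frame(family_id = rownames(abundance)[f], Z = t$Z, p = t$p,
               effect = mean(effs, na.rm = TRUE),
               prevalence = prevalence[f], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(family_id = character(0), Z = numeric(0),
                      p = numeric(0), q = numeric(0), effect = numeric(0),
                      prevalence = numeric(0), direction = character(0)))
  out$q <- fdr_bh(out$p)
  out$direction <- ifelse(out$q >= alpha, "ns",
                          ifelse(out$effect > 0, "over", "under"))
  out <- out[order(out$q, out$p), c("family_id", "Z", "p", "q", "effect",
                                    "prevalence", "direction")]
  rownames(out) <- NULL
  out
}
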