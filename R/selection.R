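# Purifying-selection screen: Nei-Gojobori (1986) pairwise dN/dS with
# Jukes-Cantor correction, averaged over member pairs of a family.

NUCS <- c("A", "C", "G", "T")

genetic_code <- function() Biostrings::GENETIC_CODE

translate_codon <- function(codon, code = genetic_code()) {
  aa <- code[codon]
  ifelse(is.na(aa), NA_character_, unname(aa))
}

is_valid_codon <- function(codon, code = genetic_code()) {
  !is.na(code[codon]) & code[codon] != "*"
}

# Synonymous/non-synonymous site counts of one codon (NG86). For each
# position the three alternative nucleotides are considered; changes that
# create a stop codon are excluded from the denominator, so each position
# contributes syn/(non-stop alternatives) synonymous sites and the codon
# always carries 3 sites in total.
codon_sites <- function(codon, code = genetic_code()) {
  aa <- code[[codon]]
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; valid <- 0L
    for (nuc in setdiff(NUCS, chars[pos])) {
      alt <- chars; alt[pos] <- nuc
      alt_codon <- paste(alt, collapse = "")
      alt_aa <- code[[alt_codon]]
      if (alt_aa == "*") next
      valid <- valid + 1L
      if (alt_aa == aa) syn <- syn + 1L
    }
    if (valid > 0) s <- s + syn / valid
  }
  c(S = s, N = 3 - s)
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in all_permutations(x[-i]))
      out <- c(out, list(c(x[i], rest)))
  out
}

# Synonymous/non-synonymous difference counts between two codons,
# averaged over minimal mutational pathways. Pathways passing through a
# stop codon get zero weight (if every pathway is blocked, all are
# used, stop intermediates scored by amino-acid comparison). Among the
# admissible pathways, only those with the fewest non-synonymous steps
# are averaged — the parsimony flavour of pathway weighting, which makes
# the estimator exact on purely synonymous substitution histories (a
# pair of same-amino-acid codons connected by synonymous evolution
# always counts zero non-synonymous differences).
codon_differences <- function(codon_a, codon_b, code = genetic_code()) {
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diff_pos <- which(a != b)
  if (length(diff_pos) == 0) return(c(Sd = 0, Nd = 0))
  paths <- all_permutations(diff_pos)
  score_path <- function(order) {
    cur <- a
    sd <- 0L; nd <- 0L; blocked <- FALSE
    for (pos in order) {
      nxt <- cur; nxt[pos] <- b[pos]
      aa_cur <- code[[paste(cur, collapse = "")]]
      aa_nxt <- code[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*") blocked <- TRUE
      if (identical(aa_cur, aa_nxt)) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  }
  scored <- lapply(paths, score_path)
  open <- !vapply(scored, `[[`, logical(1), "blocked")
  use <- if (any(open)) scored[open] else scored
  nds <- vapply(use, `[[`, integer(1), "nd")
  use <- use[nds == min(nds)]
  c(Sd = mean(vapply(use, `[[`, integer(1), "sd")),
    Nd = mean(vapply(use, `[[`, integer(1), "nd")))
}

jukes_cantor <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(Inf)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Nei-Gojobori dN/dS components
#'
#' Counts synonymous and non-synonymous sites and differences between two
#' codon sequences following Nei and Gojobori (1986): site fractions per
#' codon averaged over the two sequences, multi-position codon
#' differences averaged over minimal mutational pathways (pathways
#' through stop codons get zero weight, and only pathways with the
#' fewest amino-acid changes are counted, so purely synonymous histories
#' yield dN = 0 exactly), and distances Jukes-Cantor corrected
#' (`d = -3/4 log(1 - 4p/3)`, `p >= 3/4` giving `Inf`).
#'
#' Codons containing gaps, ambiguity characters or stops in either
#' sequence are excluded pairwise.
#'
#' @param cds_a,cds_b equal-length codon sequences (length divisible by 3).
#' @return named list with `pN`, `pS`, `dN`, `dS`, `N`, `S` (site counts)
#'   and `n_codons_used`.
#' @export
ng86_pair <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b))
    stop("codon sequences have different lengths")
  if (nchar(cds_a) %% 3 != 0)
    stop("codon sequence length must be divisible by 3")
  code <- genetic_code()
  n_codons <- nchar(cds_a) %/% 3
  starts <- 3 * (seq_len(n_codons) - 1) + 1
  cods_a <- substring(cds_a, starts, starts + 2)
  cods_b <- substring(cds_b, starts, starts + 2)
  usable <- is_valid_codon(cods_a, code) & is_valid_codon(cods_b, code)
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (k in which(usable)) {
    sa <- codon_sites(cods_a[k], code)
    sb <- codon_sites(cods_b[k], code)
    S <- S + (sa["S"] + sb["S"]) / 2
    N <- N + (sa["N"] + sb["N"]) / 2
    d <- codon_differences(cods_a[k], cods_b[k], code)
    Sd <- Sd + d["Sd"]
    Nd <- Nd + d["Nd"]
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  list(pN = unname(pN), pS = unname(pS),
       dN = unname(jukes_cantor(pN)), dS = unname(jukes_cantor(pS)),
       N = unname(N), S = unname(S), n_codons_used = sum(usable))
}

#' Family-level dN/dS from a codon alignment
#'
#' Computes [ng86_pair()] for every member pair (alignment columns where
#' either sequence has a gap are excluded for that pair) and summarizes
#' the family as mean pairwise dN divided by mean pairwise dS. Pairs with
#' non-finite dN or dS (saturated) are excluded from both means.
#' Conventions: mean dS = 0 with mean dN = 0 gives ratio 0; mean dS = 0
#' with mean dN > 0 gives `Inf`.
#'
#' @param codon_alignment named character vector of equal-length aligned
#'   codon sequences (gaps `-`).
#' @return list with `dN`, `dS` (the pairwise means), `ratio` and
#'   `n_pairs_used`.
#' @export
family_dnds <- function(codon_alignment) {
  n <- length(codon_alignment)
  if (n < 2) stop("family_dnds needs at least 2 sequences")
  if (length(unique(nchar(codon_alignment))) != 1)
    stop("codon alignment is ragged")
  dNs <- c(); dSs <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    pair <- strip_pair_gap_codons(codon_alignment[[i]], codon_alignment[[j]])
    if (nchar(pair[1]) == 0) next
    r <- ng86_pair(pair[1], pair[2])
    if (is.finite(r$dN) && is.finite(r$dS)) {
      dNs <- c(dNs, r$dN); dSs <- c(dSs, r$dS)
    }
  }
  if (length(dNs) == 0)
    return(list(dN = NA_real_, dS = NA_real_, ratio = NA_real_,
                n_pairs_used = 0L))
  mdN <- mean(dNs); mdS <- mean(dSs)
  ratio <- if (mdS == 0) { if (mdN == 0) 0 else Inf } else mdN / mdS
  list(dN = mdN, dS = mdS, ratio = ratio, n_pairs_used = length(dNs))
}

# Drop codons where either sequence has a gap character.
strip_pair_gap_codons <- function(a, b) {
  n_codons <- nchar(a) %/% 3
  starts <- 3 * (seq_len(n_codons) - 1) + 1
  ca <- substring(a, starts, starts + 2)
  cb <- substring(b, starts, starts + 2)
  keep <- !grepl("[-.]", ca) & !grepl("[-.]", cb)
  c(paste(ca[keep], collapse = ""), paste(cb[keep], collapse = ""))
}

#' Filter families under the purifying-selection rule
#'
#' Families with dN/dS strictly greater than `max_ratio` are discarded;
#' the boundary value is kept.
#'
#' @param families data.frame with a numeric `dnds` column (`Inf`
#'   allowed; `NA` treated as failing).
#' @param max_ratio largest acceptable ratio.
#' @return the retained rows.
#' @export
filter_by_dnds <- function(families, max_ratio = 0.5) {
  keep <- !is.na(families$dnds) & families$dnds <= max_ratio
  families[keep, , drop = FALSE]
}
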