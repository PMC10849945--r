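# Independent oracles and tiny fixture builders shared across the suite.
# Oracles are deliberately naive (exhaustive scans and enumerations) and
# never call the implementation paths they check.

# --- conserved-domain oracle: test every column interval ----------------
oracle_domain <- function(alignment, min_occupancy = 0.8) {
  mat <- do.call(rbind, strsplit(unname(alignment), ""))
  nc <- ncol(mat)
  best <- NULL
  for (s in seq_len(nc)) for (e in s:nc) {
    ok <- TRUE
    for (j in s:e) {
      if (mean(mat[, j] != "-" & mat[, j] != ".") < min_occupancy) {
        ok <- FALSE; break
      }
    }
    if (ok && (is.null(best) || (e - s + 1) > (best[2] - best[1])))
      best <- c(s - 1L, e)  # 0-based half-open
  }
  best
}

random_alignment <- function(n_seq, n_col, gap_prob = 0.25) {
  rows <- vapply(seq_len(n_seq), function(i) {
    chars <- sample(c("A", "C", "D", "E", "F", "G"), n_col, replace = TRUE)
    chars[runif(n_col) < gap_prob] <- "-"
    paste(chars, collapse = "")
  }, character(1))
  names(rows) <- paste0("s", seq_len(n_seq))
  rows
}

# --- NG86 oracle: explicit enumeration, shared pathway convention -------
oracle_codon_table <- as.character(Biostrings::GENETIC_CODE)
names(oracle_codon_table) <- names(Biostrings::GENETIC_CODE)

oracle_sites <- function(codon) {
  aa <- oracle_codon_table[codon]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (nuc in c("A", "C", "G", "T")) {
      if (substr(codon, pos, pos) == nuc) next
      alt <- codon
      substr(alt, pos, pos) <- nuc
      if (oracle_codon_table[alt] == "*") next
      valid <- valid + 1
      if (oracle_codon_table[alt] == aa) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  s
}

oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in oracle_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

oracle_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (length(pos) == 0) return(c(0, 0))
  res <- list()
  for (perm in oracle_perms(pos)) {
    cur <- ca; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in perm) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (oracle_codon_table[nxt] == "*") blocked <- TRUE
      if (oracle_codon_table[nxt] == oracle_codon_table[cur]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    res[[length(res) + 1]] <- list(sd = sd, nd = nd, blocked = blocked)
  }
  open <- Filter(function(r) !r$blocked, res)
  if (length(open) > 0) res <- open
  nds <- vapply(res, function(r) r$nd, numeric(1))
  res <- res[nds == min(nds)]  # fewest amino-acid changes
  c(mean(vapply(res, function(r) r$sd, numeric(1))),
    mean(vapply(res, function(r) r$nd, numeric(1))))
}

oracle_ng86 <- function(a, b) {
  n <- nchar(a) / 3
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (k in seq_len(n)) {
    ca <- substr(a, 3 * k - 2, 3 * k)
    cb <- substr(b, 3 * k - 2, 3 * k)
    if (oracle_codon_table[ca] == "*" || oracle_codon_table[cb] == "*" ||
        is.na(oracle_codon_table[ca]) || is.na(oracle_codon_table[cb])) next
    sa <- oracle_sites(ca); sb <- oracle_sites(cb)
    S <- S + (sa + sb) / 2
    N <- N + (3 - sa + 3 - sb) / 2
    d <- oracle_diffs(ca, cb)
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  jc <- function(p) if (p >= 0.75) Inf else -0.75 * log(1 - 4 * p / 3)
  list(pN = Nd / N, pS = Sd / S, dN = jc(Nd / N), dS = jc(Sd / S),
       N = N, S = S)
}

random_sense_cds <- function(n_codons) {
  sense <- names(oracle_codon_table)[oracle_codon_table != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# mutate a CDS at random positions, avoiding stops
mutate_cds <- function(cds, n_mut) {
  s <- strsplit(cds, "")[[1]]
  for (i in seq_len(n_mut)) {
    repeat {
      p <- sample.int(length(s), 1)
      old <- s[p]
      s[p] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      ci <- (p - 1) %/% 3
      cod <- paste(s[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
      if (oracle_codon_table[cod] != "*") break
      s[p] <- old
    }
  }
  paste(s, collapse = "")
}

# --- Benjamini-Hochberg step-up by hand ---------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# --- normal-approximation rank-sum p (tie-corrected, no continuity) -----
oracle_ranksum <- function(case_vals, ctrl_vals) {
  x <- c(case_vals, ctrl_vals)
  n1 <- length(case_vals); n2 <- length(ctrl_vals); N <- n1 + n2
  r <- rank(x)
  W <- sum(r[seq_len(n1)])
  EW <- n1 * (N + 1) / 2
  VW <- n1 * n2 / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  Z <- (W - EW) / sqrt(VW)
  list(Z = Z, p = 2 * pnorm(-abs(Z)))
}

# --- compact gene-table builder for context tests -----------------------
# spec: data.frame(contig, start, end, strand, pathways (comma string),
#                  ko, resistance)
toy_genes <- function(spec, genome = "G1") {
  df <- data.frame(
    gene_id = sprintf("%s_g%02d", spec$contig, seq_len(nrow(spec))),
    genome_id = genome, contig_id = spec$contig,
    start = spec$start, end = spec$end, strand = spec$strand,
    is_complete = TRUE, stringsAsFactors = FALSE)
  if (!is.null(spec$ko)) df$ko <- spec$ko
  if (!is.null(spec$resistance)) df$is_resistance <- spec$resistance
  df$pathways <- if (!is.null(spec$pathways))
    lapply(strsplit(ifelse(is.na(spec$pathways), "", spec$pathways), ","),
           function(x) x[nzchar(x)])
  else replicate(nrow(spec), character(0), simplify = FALSE)
  gene_table(df)
}

# evenly spaced toy contig: n genes of length `len` with constant gaps
toy_contig <- function(n, len = 300, gap = 50, contig = "c1",
                       strand = rep("+", n)) {
  start <- (seq_len(n) - 1) * (len + gap)
  data.frame(contig = contig, start = start, end = start + len,
             strand = strand, stringsAsFactors = FALSE)
}

# small taxonomy for distribution/orthology tests
toy_taxonomy <- function(lineages, genome_ids = NULL) {
  if (is.null(genome_ids)) genome_ids <- sprintf("G%02d", seq_along(lineages))
  df <- data.frame(genome_id = genome_ids, lineage = lineages,
                   uncultivated = "1", stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_taxonomy_tsv(path)
}

lineage7 <- function(d = "D1", p = "P1", c = "C1", o = "O1", f = "F1",
                     g = "G1", s = "S1") {
  sprintf("d__%s;p__%s;c__%s;o__%s;f__%s;g__%s;s__%s", d, p, c, o, f, g, s)
}
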