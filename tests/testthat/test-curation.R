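make_curation_fixture <- function() {
  tax <- toy_taxonomy(c(lineage7(s = "S1"), lineage7(s = "S2"),
                        lineage7(s = "S3")),
                      genome_ids = c("GA", "GB", "GC"))
  df <- data.frame(
    gene_id = sprintf("g%d", 1:10),
    genome_id = c("GA", "GB", "GA", "GA", "GA", "GA", "GA", "GB", "GC", "GC"),
    contig_id = sprintf("c%d", 1:10),
    start = 0L, end = 300L, strand = "+",
    is_complete = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
                    TRUE))
  list(tax = tax, genes = gene_table(df))
}

test_that("candidate selection enforces complete-gene and species rules", {
  fx <- make_curation_fixture()
  clusters <- list(
    ok = c("g1", "g2", "g3"),          # 3 complete genes, 2 species
    orphan = c("g4", "g5", "g6", "g7"), # 4 complete genes, 1 species
    frag = c("g8", "g9", "g10"))       # only 2 complete genes
  fams <- select_candidate_families(clusters, fx$genes, fx$tax)
  expect_equal(fams$family_id, "ok")
  dropped <- attr(fams, "dropped")
  expect_equal(dropped$reason[dropped$family_id == "orphan"], "orphan")
  expect_equal(dropped$reason[dropped$family_id == "frag"],
               "too_few_complete")
})

test_that("unresolvable member gene ids name the family", {
  fx <- make_curation_fixture()
  expect_error(
    select_candidate_families(list(bad = c("g1", "missing")), fx$genes,
                              fx$tax),
    "bad")
})

test_that("conserved domain detection handles gapless, gapped and hopeless alignments", {
  gapless <- setNames(rep(strrep("A", 25), 3), paste0("s", 1:3))
  expect_equal(find_conserved_domain(gapless), c(0L, 25L))

  # 5 x 30, column 11 (1-based) has 2/5 gaps -> occupancy 0.6 < 0.8
  rows <- rep(strrep("A", 30), 5)
  substr(rows[1], 11, 11) <- "-"
  substr(rows[2], 11, 11) <- "-"
  aln <- setNames(rows, paste0("s", 1:5))
  expect_equal(find_conserved_domain(aln), c(11L, 30L))

  hopeless <- c(a = paste(rep(c("A", "-"), 10), collapse = ""),
                b = paste(rep(c("-", "A"), 10), collapse = ""))
  expect_null(find_conserved_domain(hopeless))
})

test_that("conserved domain agrees with the exhaustive interval oracle", {
  set.seed(11)
  for (i in 1:40) {
    aln <- random_alignment(sample(2:10, 1), sample(5:60, 1))
    expect_identical(find_conserved_domain(aln), oracle_domain(aln),
                     label = sprintf("alignment %d", i))
  }
})

test_that("domain-length filtering is boundary-exact and monotone", {
  fams <- data.frame(family_id = c("a", "b", "c"))
  fams$domain <- list(c(0L, 20L), c(0L, 19L), NULL)
  kept <- filter_by_domain(fams, min_len = 20)
  expect_equal(kept$family_id, "a")

  set.seed(2)
  fams2 <- data.frame(family_id = sprintf("f%d", 1:30))
  fams2$domain <- lapply(1:30, function(i) c(0L, sample(0:50, 1)))
  sizes <- vapply(seq(0, 50, 5), function(ml)
    nrow(filter_by_domain(fams2, ml)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("external-hit screening drops flagged families with strict boundaries", {
  fams <- data.frame(family_id = c("f1", "f2", "f3"))
  hits <- data.frame(family_id = c("f2", "f3", "f3"),
                     database = c("refseq", "refseq", "antifam"),
                     evalue = c(1e-5, 1e-3, 1e-4),
                     coverage = c(0.9, 0.9, NA))
  # f2: qualifying sequence hit; f3: E exactly at the sequence threshold
  # (not significant) and an HMM hit above the HMM threshold
  out <- drop_flagged_families(fams, hits)
  expect_setequal(out$family_id, c("f1", "f3"))
  expect_identical(drop_flagged_families(fams, hits[0, ])$family_id,
                   fams$family_id)
})

test_that("member flag aggregation uses the >=80% rule", {
  flags <- c(g1 = TRUE, g2 = TRUE, g3 = TRUE, g4 = TRUE, g5 = FALSE)
  expect_true(aggregate_member_flags(names(flags), flags))      # 4/5 = 0.8
  expect_false(aggregate_member_flags(names(flags),
                                      setNames(rep(FALSE, 5), names(flags))))
  expect_false(aggregate_member_flags(c("g1", "g2", "g3", "g4", "g5"),
                                      c(g1 = TRUE, g2 = TRUE, g3 = TRUE,
                                        g4 = FALSE, g5 = FALSE)))  # 3/5
})

test_that("small-peptide flagging keys on the longest member, strictly", {
  df <- data.frame(gene_id = c("a", "b", "c", "d"), genome_id = "G",
                   contig_id = "c", start = c(0, 400, 800, 1200),
                   end = c(300, 700, 1100, 1500), strand = "+",
                   is_complete = TRUE,
                   protein_seq = c(strrep("M", 36), strrep("M", 50),
                                   strrep("M", 12), strrep("M", 49)))
  gt <- gene_table(df)
  fams <- data.frame(family_id = c("short", "edge", "mixed"))
  fams$members <- list("a", "b", c("c", "d"))
  out <- flag_small_peptides(fams, gt)
  expect_equal(out$small_peptide, c(TRUE, FALSE, TRUE))
  expect_equal(family_length(c("c", "d"), gt), 49L)
  expect_equal(family_length("a", gt), 36L)
  # brute-force max over members
  expect_equal(family_length(c("a", "b", "c"), gt),
               max(nchar(df$protein_seq[1:3])))
})
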