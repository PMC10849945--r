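mk_genes_for <- function(genomes) {
  n <- length(genomes)
  gene_table(data.frame(
    gene_id = sprintf("g%02d", seq_len(n)), genome_id = genomes,
    contig_id = sprintf("ct%02d", seq_len(n)), start = 0L, end = 300L,
    strand = "+", is_complete = TRUE))
}

test_that("family LCA returns the deepest sufficiently supported prefix", {
  tax <- toy_taxonomy(c(
    lineage7(s = "S1"), lineage7(s = "S2"),              # same genus
    lineage7(p = "P2", c = "C2", o = "O2", f = "F2", g = "G2", s = "S3")),
    genome_ids = c("GA", "GB", "GC"))

  g <- mk_genes_for(c("GA", "GB"))
  expect_equal(family_lca(g$gene_id, g, tax)$rank, "genus")

  # 9 members in one phylum, 1 in another (same domain)
  g2 <- mk_genes_for(c(rep("GA", 9), "GC"))
  expect_equal(family_lca(g2$gene_id, g2, tax, support = 0.8)$rank,
               "species")  # 9/10 share the full GA lineage
  expect_equal(family_lca(g2$gene_id, g2, tax, support = 1.0)$rank,
               "domain")

  g3 <- mk_genes_for("GA")
  expect_equal(family_lca(g3$gene_id, g3, tax)$rank, "species")
})

test_that("lowering the LCA support never yields a less specific lineage", {
  tax <- generate_taxonomy(sim_config(genomes_per_order = 5))
  depth <- function(rank) match(rank, c("root", "domain", "phylum",
                                        "class", "order", "family",
                                        "genus", "species"))
  set.seed(81)
  for (i in 1:100) {
    genomes <- sample(tax$genome_id, sample(3:15, 1), replace = TRUE)
    g <- mk_genes_for(genomes)
    strict <- family_lca(g$gene_id, g, tax, support = 1.0)
    relaxed <- family_lca(g$gene_id, g, tax, support = 0.8)
    expect_gte(depth(relaxed$rank), depth(strict$rank))
  }
})

test_that("novelty density summarizes per-genome family counts by clade", {
  tax <- toy_taxonomy(c(lineage7(s = "S1"), lineage7(s = "S2"),
                        lineage7(o = "O2", s = "S3")),
                      genome_ids = c("GA", "GB", "GC"))
  g <- mk_genes_for(c("GA", "GA", "GA", "GB", "GB", "GB", "GB", "GB"))
  fams <- data.frame(family_id = sprintf("f%d", 1:8))
  fams$members <- as.list(g$gene_id)  # 3 families in GA, 5 in GB
  nd <- novelty_density(fams, g, tax, rank = "order")
  o1 <- nd[nd$clade == "o__O1", ]
  expect_equal(o1$mean_families, 4)
  expect_equal(o1$sd_families, sd(c(3, 5)))
  o2 <- nd[nd$clade == "o__O2", ]
  expect_equal(o2$mean_families, 0)
  expect_equal(o2$sd_families, 0)
  expect_equal(sum(nd$n_genomes), nrow(tax))
})

test_that("mobility flags follow the member-fraction rule strictly", {
  g <- mk_genes_for(rep("GA", 10))
  flags <- data.frame(contig_id = g$contig_id,
                      plasmid = c(TRUE, rep(FALSE, 9)),
                      viral = FALSE)
  m0 <- mobility_flags(g$gene_id, g, flags, member_fraction = 0)
  expect_true(m0[["mobile_plasmid"]])   # at least one member
  expect_false(m0[["mobile_viral"]])
  m3 <- mobility_flags(g$gene_id, g, flags, member_fraction = 0.3)
  expect_false(m3[["mobile_plasmid"]])  # 0.1 < 0.3
  none <- mobility_flags(g$gene_id, g,
                         data.frame(contig_id = g$contig_id,
                                    plasmid = FALSE, viral = FALSE))
  expect_false(any(none))
})

test_that("habitat breadth applies strict sample and habitat cutoffs", {
  meta <- data.frame(sample_id = sprintf("s%02d", 1:30),
                     habitat = rep(c("marine", "soil", "lake"), each = 10))
  det <- function(fam, samples)
    data.frame(family_id = fam, sample_id = samples)
  d <- rbind(det("broad", sprintf("s%02d", c(1:6, 11:15))),   # 11 x 2 hab
             det("narrow", sprintf("s%02d", 1:10)),           # 11 needs >10
             det("narrow", "s01"),                            # duplicate row
             det("edge", sprintf("s%02d", c(1:4, 11:14, 21, 22))))  # 10 x 3
  hb <- habitat_breadth(d, meta)
  hb <- hb[order(hb$family_id), ]
  expect_equal(hb$broad_flag[hb$family_id == "broad"], TRUE)
  expect_equal(hb$n_samples[hb$family_id == "narrow"], 10)  # dedup
  expect_equal(hb$broad_flag[hb$family_id == "narrow"], FALSE)
  expect_equal(hb$broad_flag[hb$family_id == "edge"], FALSE)  # strict >10

  grouped <- habitat_breadth(d, meta,
                             habitat_groups = c(marine = "Marine",
                                                lake = "Non-marine aquatic"))
  # soil unmapped -> Other, still a distinct habitat group
  expect_equal(grouped$n_habitats[grouped$family_id == "edge"], 3)
})

test_that("breadth-mobility association separates null from planted effects", {
  set.seed(91)
  n <- 1000
  breadth <- data.frame(family_id = sprintf("f%d", 1:n),
                        n_samples = rpois(n, 20) + 1,
                        n_habitats = sample(1:8, n, replace = TRUE))
  null_mob <- setNames(runif(n) < 0.3, breadth$family_id)
  res0 <- breadth_mobility_association(breadth, null_mob)
  expect_lt(abs(res0$rho), 0.1)
  expect_false(res0$degenerate)

  planted <- setNames(runif(n) < (breadth$n_habitats / 8)^2,
                      breadth$family_id)
  res1 <- breadth_mobility_association(breadth, planted)
  expect_gt(res1$rho, 0.5)

  const <- setNames(rep(TRUE, n), breadth$family_id)
  res2 <- breadth_mobility_association(breadth, const)
  expect_true(res2$degenerate)
  expect_equal(res2$rho, 0)
})
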