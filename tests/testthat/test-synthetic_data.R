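test_that("identical seeds give byte-identical collections on disk", {
  cfg <- sim_config(seed = 4, genomes_per_order = 4)
  d1 <- file.path(tempdir(), "col_a")
  d2 <- file.path(tempdir(), "col_b")
  write_collection(suppressWarnings(generate_collection(cfg)), d1)
  write_collection(suppressWarnings(generate_collection(cfg)), d2)
  files <- list.files(d1)
  expect_gt(length(files), 4)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  # a different seed changes the content
  write_collection(suppressWarnings(
    generate_collection(sim_config(seed = 5, genomes_per_order = 4))), d2)
  expect_false(identical(readLines(file.path(d1, "genes.gff")),
                         readLines(file.path(d2, "genes.gff"))))
})

test_that("generator outputs parse cleanly through the package readers", {
  cfg <- sim_config(seed = 8, genomes_per_order = 4)
  col <- suppressWarnings(generate_collection(cfg))
  dir <- file.path(tempdir(), "col_parse")
  write_collection(col, dir)

  genes <- read_gff(file.path(dir, "genes.gff"))
  expect_equal(nrow(genes), nrow(col$genes))
  reread <- genes[match(col$genes$gene_id, genes$gene_id), ]
  expect_equal(reread$start, col$genes$start)
  expect_equal(reread$end, col$genes$end)
  expect_equal(reread$strand, col$genes$strand)

  clusters <- read_cluster_tsv(file.path(dir, "clusters.tsv"))
  expect_identical(lengths(clusters), lengths(col$clusters))

  tax <- read_taxonomy_tsv(file.path(dir, "taxonomy.tsv"))
  expect_equal(tax$lineage, col$taxonomy$lineage)

  ann <- read_annotation_tsv(file.path(dir, "annotations.tsv"))
  expect_equal(nrow(ann), nrow(col$genes))

  flags <- read_contig_flags_tsv(file.path(dir, "contig_flags.tsv"))
  expect_equal(flags$plasmid, col$contig_flags$plasmid)
})

test_that("truth tables reflect the planted configuration", {
  cfg <- sim_config(seed = 12, n_synapomorphy_families = 1,
                    n_operon_families = 3, n_known_families = 6,
                    n_null_families = 2)
  col <- generate_collection(cfg)
  expect_equal(nrow(col$truth$synapomorphies), 1)
  expect_equal(nrow(col$truth$operons), 3)
  expect_equal(nrow(col$truth$known), 6)
  expect_equal(nrow(col$truth$nulls), 2)
  # all planted members resolve in the gene table
  expect_true(all(unlist(col$clusters) %in% col$genes$gene_id))
  # synapomorphy families have more than ten members, all inside the clade
  syn <- col$truth$synapomorphies
  members <- col$clusters[[syn$family_id[1]]]
  genomes <- col$genes$genome_id[match(members, col$genes$gene_id)]
  clade_genomes <- col$taxonomy$genome_id[col$taxonomy$order == syn$clade[1]]
  expect_gt(length(members), 10)
  expect_true(all(genomes %in% clade_genomes))
})

test_that("the embedded-member count follows the rounding rule", {
  cfg <- sim_config(seed = 14, members_per_family = 20,
                    n_operon_families = 1, n_known_families = 0,
                    n_null_families = 0, n_resistance_families = 0,
                    n_small_peptide_families = 0,
                    n_synapomorphy_families = 0,
                    operon_member_fraction = 0.9,
                    genomes_per_order = 6)
  col <- generate_collection(cfg)
  fam <- col$truth$operons$family_id[1]
  p <- col$truth$operons$pathway[1]
  nb <- family_neighborhoods(col$clusters[[fam]], col$genes)
  embedded <- vapply(nb, function(x) {
    idx <- match(c(-2, -1, 1, 2), x$neighbours$rel_pos)
    all(!is.na(idx)) &&
      all(vapply(x$neighbours$pathways[idx], function(pp) p %in% pp, TRUE))
  }, logical(1))
  expect_equal(sum(embedded), round(0.9 * 20))  # 18 of 20
})

test_that("codon evolution responds to branch lengths and omega", {
  tr0 <- "((a:0,b:0):0,(c:0,d:0):0);"
  aln0 <- evolve_codon_family(tr0, omega = 0.5, n_codons = 50, seed = 1)
  expect_equal(length(unique(aln0)), 1)  # zero branches: identical tips

  set.seed(15)
  tr <- "((a:0.3,b:0.3):0.1,(c:0.3,d:0.3):0.1);"
  means <- vapply(c(0.1, 0.5, 1.0), function(om)
    mean(replicate(10, family_dnds(
      evolve_codon_family(tr, omega = om, n_codons = 100))$ratio)),
    numeric(1))
  expect_true(all(diff(means) > 0))
  # alignments are gap-free, stop-free and in frame
  aln <- evolve_codon_family(tr, omega = 0.5, n_codons = 60, seed = 2)
  expect_true(all(nchar(aln) == 180))
  codons <- substring(aln[1], seq(1, 178, 3), seq(3, 180, 3))
  expect_false(any(Biostrings::GENETIC_CODE[codons] == "*"))
})

test_that("abundance generation honours prevalence and null specs", {
  cfg <- sim_config(seed = 16,
                    abundance = list(n_families = 500, n_samples = 60,
                                     n_blocks = 3, n_effect = 0,
                                     fold_change = 1, prevalence = 0.5,
                                     sdlog = 0.5, block_sd = 0.5))
  ab <- generate_abundance(cfg)
  expect_equal(nrow(ab$truth), 0)
  expect_lt(abs(mean(ab$abundance > 0) - 0.5), 0.05)
  expect_true(all(ab$abundance >= 0))
  expect_true(all(table(ab$meta$block) >= 2))
})
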