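# A 10-gene toy contig with controllable annotations drives most tests;
# windows are +-3 genes throughout.

test_that("neighbourhood extraction truncates at contig ends", {
  gt <- toy_genes(toy_contig(10))
  nb_first <- extract_neighborhood(gt$gene_id[gt$rank_on_contig == 0], gt)
  expect_equal(nb_first$neighbours$rel_pos, c(1, 2, 3))
  nb_mid <- extract_neighborhood(gt$gene_id[gt$rank_on_contig == 5], gt)
  expect_equal(nb_mid$neighbours$rel_pos, c(-3, -2, -1, 1, 2, 3))
})

test_that("intergenic gap chains match hand-computed start-end differences", {
  # 4 genes: [0,100) [130,230) [235,335) [500,600)
  spec <- data.frame(contig = "c1", start = c(0, 130, 235, 500),
                     end = c(100, 230, 335, 600), strand = "+")
  gt <- toy_genes(spec)
  nb <- extract_neighborhood(gt$gene_id[2], gt)
  gaps <- nb$neighbours$gap_chain
  names(gaps) <- nb$neighbours$rel_pos
  expect_equal(gaps[["-1"]], 30)        # 130 - 100
  expect_equal(gaps[["1"]], 5)          # 235 - 230
  expect_equal(gaps[["2"]], c(5, 165))  # chain to +2 crosses both gaps
})

# members on 4 separate contigs, with pathway P planted in some windows
context_fixture <- function() {
  specs <- lapply(1:4, function(k) {
    s <- toy_contig(7, contig = sprintf("m%d", k))
    s$pathways <- NA_character_
    s$ko <- NA_character_
    s
  })
  # members are the middle gene (rank 3) of each contig
  # contigs 1-3: a P neighbour at +1; contig 4: none
  for (k in 1:3) specs[[k]]$pathways[5] <- "P"
  spec <- do.call(rbind, specs)
  gt <- toy_genes(spec)
  members <- gt$gene_id[gt$rank_on_contig == 3]
  list(genes = gt, members = members,
       nb = family_neighborhoods(members, gt))
}

test_that("synteny conservation is the fraction of members with a pathway neighbour", {
  fx <- context_fixture()
  expect_equal(synteny_conservation(fx$nb, "P"), 0.75)  # 3 of 4 members
  expect_equal(synteny_conservation(fx$nb, "Q"), 0)
})

test_that("functional relatedness pools neighbour counts over members", {
  fx <- context_fixture()
  # 4 members x 6 neighbours = 24 pooled, 3 annotated to P
  expect_equal(functional_relatedness(fx$nb, "P"), 3 / 24)
  # worked case: 12 pooled neighbours, 6 in P
  spec <- toy_contig(7)
  spec$pathways <- c(NA, "P", "P", NA, "P", NA, NA)
  gt <- toy_genes(spec)
  nb <- family_neighborhoods(gt$gene_id[c(3, 5)], gt)  # ranks 2 and 4
  expect_equal(length(nb), 2)
  tot <- sum(vapply(nb, function(x) nrow(x$neighbours), 0L))
  expect_equal(functional_relatedness(nb, "P"),
               sum(vapply(nb, function(x)
                 sum(vapply(x$neighbours$pathways, function(p) "P" %in% p,
                            TRUE)), 0L)) / tot)
})

test_that("strand conservation scores pathway neighbours against the focal strand", {
  spec <- toy_contig(7, strand = c("+", "-", "+", "+", "+", "-", "+"))
  spec$pathways <- c(NA, "P", "P", NA, "P", "P", NA)
  gt <- toy_genes(spec)
  nb <- family_neighborhoods(gt$gene_id[4], gt)  # focal on +
  # P neighbours at ranks 1(-), 2(+), 4(+), 5(-): 2 of 4 on focal strand
  expect_equal(strand_conservation(nb, "P"), 0.5)
  expect_equal(strand_conservation(nb, "Q"), 0)
})

test_that("distance conservation requires an unbroken chain of short gaps", {
  # gaps: g1-g2 = 30, g2-g3 = 150, g3(focal)-g4 = 50, g4-g5 = -10 (overlap)
  spec <- data.frame(contig = "c1",
                     start = c(0, 130, 380, 530, 620),
                     end = c(100, 230, 480, 630, 720), strand = "+")
  spec$pathways <- c("P", "P", NA, "P", "P")
  gt <- toy_genes(spec)
  nb <- family_neighborhoods(gt$gene_id[3], gt)
  # +1 at gap 50 counts; +2 overlapping (negative gap) counts;
  # -1 at gap 150 breaks; -2 behind the broken gap breaks
  expect_equal(distance_conservation(nb, "P"), 0.5)
  expect_equal(distance_conservation(nb, "P", max_gap = 200), 1)
})

test_that("calibration thresholds reproduce the quantile worked examples", {
  known <- data.frame(family_id = sprintf("f%d", 1:4), pathway = "P",
                      synteny = c(1.0, 1.0, 0.8, 0.6),
                      relatedness = 1, strand = 1, distance = 1)
  cal <- calibrate_thresholds(known, n_min = 4)
  expect_equal(cal$thr_synteny[cal$level == 0.5], 0.8)
  expect_equal(cal$thr_synteny[cal$level == 0.9], 0.6)

  allones <- known
  allones$synteny <- 1
  cal2 <- calibrate_thresholds(allones, n_min = 4)
  expect_equal(cal2$thr_synteny, c(1, 1))

  few <- known[1:3, ]
  cal3 <- calibrate_thresholds(few, n_min = 5)
  expect_equal(nrow(cal3), 0)
  expect_equal(attr(cal3, "uncalibrated"), "P")
})

test_that("0.9-level thresholds are never stricter than 0.5-level ones", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    known <- data.frame(family_id = sprintf("f%d", 1:n), pathway = "P",
                        synteny = runif(n), relatedness = runif(n),
                        strand = runif(n), distance = runif(n))
    cal <- calibrate_thresholds(known)
    hi <- cal[cal$level == 0.9, ]
    lo <- cal[cal$level == 0.5, ]
    for (col in c("thr_synteny", "thr_relatedness", "thr_strand",
                  "thr_distance"))
      expect_lte(hi[[col]], lo[[col]])
  }
})

test_that("predictions report the highest confidence level met", {
  fx <- context_fixture()
  prof <- context_profile(fx$nb, "P")
  cal <- data.frame(pathway = "P", level = c(0.5, 0.9),
                    thr_synteny = c(0.7, 0.9),
                    thr_relatedness = c(0.1, 0.1),
                    thr_strand = c(0, 0), thr_distance = c(0, 0),
                    n_known = 10L)
  pred <- predict_pathway_associations(fx$nb, cal)
  # synteny 0.75 passes 0.5-level (0.7) but not 0.9-level (0.9)
  expect_equal(pred$pathway, "P")
  expect_equal(pred$confidence, 0.5)

  cal$thr_synteny <- c(0.7, 0.75)
  pred2 <- predict_pathway_associations(fx$nb, cal)
  expect_equal(pred2$confidence, 0.9)

  cal$thr_relatedness <- c(0.9, 0.9)  # unreachable
  expect_equal(nrow(predict_pathway_associations(fx$nb, cal)), 0)
})

test_that("conserved resistance-neighbour positions are counted per position", {
  specs <- lapply(1:3, function(k) {
    s <- toy_contig(7, contig = sprintf("r%d", k))
    s$resistance <- c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
    s
  })
  gt <- toy_genes(do.call(rbind, specs))
  nb <- family_neighborhoods(gt$gene_id[gt$rank_on_contig == 3], gt)
  # every member: resistance at -2 and +1
  expect_equal(count_resistance_neighbors(nb, 0.8), 2L)
  none <- toy_genes(toy_contig(7))
  nb0 <- family_neighborhoods(none$gene_id[4], none)
  expect_equal(count_resistance_neighbors(nb0, 0.5), 0L)
})

test_that("positional synteny averages modal-label conservation at -1/+1", {
  mk <- function(kos) {
    specs <- lapply(seq_along(kos), function(k) {
      s <- toy_contig(5, contig = sprintf("p%d%s", k, kos[[k]][1]))
      s$ko <- c(NA, kos[[k]][1], NA, kos[[k]][2], NA)
      s
    })
    gt <- toy_genes(do.call(rbind, specs))
    family_neighborhoods(gt$gene_id[gt$rank_on_contig == 2], gt)
  }
  # identical +-1 neighbours in all members
  nb <- mk(list(c("K1", "K2"), c("K1", "K2"), c("K1", "K2")))
  expect_equal(positional_synteny(nb), 1)
  # half of members share the +1 label, -1 unlabeled
  nb2 <- mk(list(c(NA, "K2"), c(NA, "K2"), c(NA, "K9"), c(NA, "K8")))
  expect_equal(positional_synteny(nb2), 0.25)
})

test_that("adding a pathway neighbour never decreases synteny or relatedness", {
  set.seed(61)
  for (i in 1:10) {
    spec <- toy_contig(7)
    spec$pathways <- ifelse(runif(7) < 0.4, "P", NA)
    spec$pathways[4] <- NA
    gt <- toy_genes(spec)
    nb <- family_neighborhoods(gt$gene_id[4], gt)
    s0 <- synteny_conservation(nb, "P")
    r0 <- functional_relatedness(nb, "P")
    free <- which(is.na(spec$pathways[-4]))
    if (length(free) == 0) next
    spec2 <- spec
    slot <- setdiff(1:7, 4)[free[1]]
    spec2$pathways[slot] <- "P"
    nb2 <- family_neighborhoods(toy_genes(spec2)$gene_id[4],
                                toy_genes(spec2))
    expect_gte(synteny_conservation(nb2, "P"), s0)
    expect_gte(functional_relatedness(nb2, "P"), r0)
  }
})
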