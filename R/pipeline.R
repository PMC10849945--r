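# End-to-end pipeline wiring on a (synthetic or loaded) collection, plus
# the thin command-line entry point shipped in inst/cli/novfams.R.

log_stage <- function(fmt, ..., timestamps = TRUE) {
  stamp <- if (timestamps) format(Sys.time(), "[%Y-%m-%d %H:%M:%S] ") else ""
  message(stamp, sprintf(fmt, ...))
}

#' Run the full analysis pipeline on a seeded synthetic collection
#'
#' Generates a collection, applies the candidate-family filters, scores
#' and predicts pathway associations with a calibration derived from the
#' collection's known families, scans for synapomorphies (strict
#' regime), summarizes taxonomic breadth and mobility, estimates dN/dS
#' on codon families evolved under the configured model, calls orthology
#' on per-family gene trees, and runs the blocked biomarker analysis on
#' a generated abundance matrix. All outputs are TSVs with provenance
#' headers; identical config and seed give byte-identical files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param timestamps stamp log lines (files are never stamped).
#' @return named list of output file paths, invisibly.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         timestamps = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  lg <- function(...) log_stage(..., timestamps = timestamps)
  outs <- list()

  lg("simulate: generating collection (seed %d)", seed)
  col <- generate_collection(config)
  write_collection(col, file.path(out_dir, "inputs"))
  lg("simulate: %d genomes, %d genes, %d clusters",
     nrow(col$taxonomy), nrow(col$genes), length(col$clusters))

  # curation funnel
  fams <- select_candidate_families(col$clusters, col$genes, col$taxonomy)
  lg("curate: %d/%d clusters pass the complete-gene/species filters",
     nrow(fams), length(col$clusters))
  fams <- flag_small_peptides(fams, col$genes)
  fams$length <- vapply(fams$members, family_length, integer(1),
                        genes = col$genes)
  mob <- t(vapply(fams$members, mobility_flags, logical(2),
                  genes = col$genes, contig_flags = col$contig_flags))
  fams$mobile_plasmid <- mob[, "mobile_plasmid"]
  fams$mobile_viral <- mob[, "mobile_viral"]
  lca <- lapply(fams$members, family_lca, genes = col$genes,
                taxonomy = col$taxonomy)
  fams$lca_rank <- vapply(lca, `[[`, "", "rank")
  fams$lca_lineage <- vapply(lca, `[[`, "", "lineage")
  outs$families <- file.path(out_dir, "families.tsv")
  write_results_tsv(fams[, setdiff(names(fams), "members")],
                    outs$families, seed = seed, config = config)

  # context calibration + prediction
  nbhd <- function(members) family_neighborhoods(members, col$genes)
  known <- col$truth$known
  known_scores <- do.call(rbind, lapply(seq_len(nrow(known)), function(i) {
    members <- col$clusters[[known$family_id[i]]]
    prof <- context_profile(nbhd(members), known$pathway[i])
    cbind(family_id = known$family_id[i], prof)
  }))
  names(known_scores)[names(known_scores) == "pathway"] <- "pathway"
  cal <- calibrate_thresholds(known_scores)
  outs$calibration <- file.path(out_dir, "calibration.tsv")
  write_results_tsv(cal, outs$calibration, seed = seed, config = config)
  lg("context: calibrated %d pathway/level thresholds on %d known families",
     nrow(cal), nrow(known))
  target <- c(col$truth$operons$family_id, col$truth$nulls$family_id)
  preds <- do.call(rbind, lapply(target, function(f) {
    pr <- predict_pathway_associations(nbhd(col$clusters[[f]]), cal)
    if (nrow(pr) == 0) return(NULL)
    cbind(family_id = f, pr)
  }))
  if (is.null(preds))
    preds <- data.frame(family_id = character(0), pathway = character(0),
                        confidence = numeric(0))
  outs$predictions <- file.path(out_dir, "predictions.tsv")
  write_results_tsv(preds, outs$predictions, seed = seed, config = config)
  lg("context: %d associations for %d candidate families",
     nrow(preds), length(target))

  # synapomorphy scan (strict catalogue regime)
  hits <- scan_synapomorphies(fams, col$genes, col$taxonomy)
  outs$synapomorphies <- file.path(out_dir, "synapomorphies.tsv")
  write_results_tsv(hits, outs$synapomorphies, seed = seed, config = config)
  lg("synapomorphy: %d strict-regime hits", nrow(hits))

  # dN/dS on codon families evolved under the configured model
  set.seed(seed + 2L)
  omega_grid <- c(0.1, 0.5, 1.0)
  dnds_rows <- do.call(rbind, lapply(seq_len(6), function(k) {
    om <- omega_grid[(k - 1) %% 3 + 1]
    aln <- evolve_codon_family("((a:0.3,b:0.3):0.1,(c:0.3,d:0.3):0.1);",
                               omega = om, n_codons = 100)
    r <- family_dnds(aln)
    data.frame(family_id = sprintf("SIMDNDS%02d", k), omega_true = om,
               dN = r$dN, dS = r$dS, ratio = r$ratio,
               pass = is.finite(r$ratio) && r$ratio <= 0.5)
  }))
  outs$dnds <- file.path(out_dir, "dnds.tsv")
  write_results_tsv(dnds_rows, outs$dnds, seed = seed, config = config)
  lg("dnds: %d simulated families, %d pass the purifying filter",
     nrow(dnds_rows), sum(dnds_rows$pass))

  # orthology on taxonomy-shaped gene trees
  set.seed(seed + 3L)
  ortho_rows <- do.call(rbind, lapply(seq_len(5), function(k) {
    gt <- generate_gene_tree(col$taxonomy,
                             sample(col$taxonomy$genome_id, 12))
    ev <- detect_duplications(midpoint_root(gt$newick), gt$gene_species,
                              gt$lineages)
    data.frame(tree = k, n_duplications = nrow(ev),
               basal_og = is_basal_orthologous_group(ev))
  }))
  outs$orthology <- file.path(out_dir, "orthology.tsv")
  write_results_tsv(ortho_rows, outs$orthology, seed = seed, config = config)

  # blocked biomarker discovery on the generated abundance matrix
  ab <- generate_abundance(config)
  diff <- differential_families(ab$abundance, ab$meta$condition,
                                ab$meta$block)
  outs$biomarkers <- file.path(out_dir, "biomarkers.tsv")
  write_results_tsv(diff, outs$biomarkers, seed = seed, config = config)
  lg("biomarker: %d/%d families significant at q<0.01",
     sum(diff$direction != "ns"), nrow(diff))

  invisible(outs)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file of [sim_config()] fields; unknown fields are an
#' error, missing fields keep their defaults.
#'
#' @param path YAML file.
#' @return a [sim_config()].
#' @export
read_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(sim_config, vals)
}
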