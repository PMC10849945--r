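#' @keywords internal
"_PACKAGE"

# Internal coordinate convention: 0-based, half-open [start, end).
# GFF3 I/O converts to/from the 1-based inclusive convention of the format.

GTDB_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")
GTDB_PREFIXES <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Construct a gene table
#'
#' A gene table is the package's central per-gene container: one row per
#' predicted CDS, with contig coordinates (internal 0-based half-open),
#' strand, completeness, functional annotations and mobility/prediction
#' flags. `rank_on_contig` gives the 0-based order of a gene along its
#' contig sorted by start position.
#'
#' @param df data.frame with at least `gene_id`, `genome_id`, `contig_id`,
#'   `start`, `end`, `strand`, `is_complete`. Optional columns
#'   (`protein_seq`, `cds_seq`, `pathways` (list of character vectors),
#'   `ko`, `is_resistance`, `is_secreted`, `is_transmembrane`,
#'   `is_expressed`) are filled with defaults when absent.
#' @return data.frame of class `gene_table` with `rank_on_contig` assigned.
#' @export
gene_table <- function(df) {
  required <- c("gene_id", "genome_id", "contig_id", "start", "end", "strand",
                "is_complete")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("gene table is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id in gene table: ",
         df$gene_id[duplicated(df$gene_id)][1])
  bad <- df$end <= df$start
  if (any(bad)) {
    warning(sum(bad), " gene record(s) with end <= start rejected")
    df <- df[!bad, , drop = FALSE]
  }
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  defaults <- list(protein_seq = NA_character_, cds_seq = NA_character_,
                   ko = NA_character_, is_resistance = FALSE,
                   is_secreted = FALSE, is_transmembrane = FALSE,
                   is_expressed = FALSE)
  for (col in names(defaults))
    if (is.null(df[[col]])) df[[col]] <- defaults[[col]]
  if (is.null(df$pathways)) df$pathways <- replicate(nrow(df), character(0),
                                                     simplify = FALSE)
  df <- assign_ranks(df)
  class(df) <- c("gene_table", "data.frame")
  df
}

# Sort genes by (contig, start) and assign 0-based per-contig ranks.
assign_ranks <- function(df) {
  ord <- order(df$contig_id, df$start, df$end, df$gene_id)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df$rank_on_contig <- stats::ave(df$start, df$contig_id,
                                  FUN = function(x) seq_along(x) - 1L)
  df$rank_on_contig <- as.integer(df$rank_on_contig)
  df
}

#' Read gene records from a GFF3 file
#'
#' Consumes CDS features with `ID` (gene identifier), `genome_id` and
#' `complete` attributes. GFF 1-based inclusive coordinates are converted
#' to internal 0-based half-open ones, and per-contig gene ranks are
#' assigned by start position.
#'
#' @param path GFF3 file.
#' @return A [gene_table()].
#' @export
read_gff <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9)) {
    lineno <- which(body)[which(nfield != 9)[1]]
    stop("malformed GFF line ", lineno, " in ", path, " (expected 9 fields)")
  }
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  g <- g[g$type == "CDS", , drop = FALSE]
  if (is.null(g$ID)) stop("GFF CDS features must carry an ID attribute")
  df <- data.frame(
    gene_id   = as.character(g$ID),
    genome_id = if (!is.null(g$genome_id)) as.character(g$genome_id) else NA_character_,
    contig_id = as.character(g$seqid),
    start     = as.integer(g$start) - 1L,  # 1-based inclusive -> 0-based half-open
    end       = as.integer(g$end),
    strand    = as.character(g$strand),
    is_complete = if (!is.null(g$complete)) as.character(g$complete) %in%
                    c("true", "TRUE", "1", "yes") else TRUE,
    stringsAsFactors = FALSE
  )
  gene_table(df)
}

#' Write gene records to GFF3
#'
#' Inverse of [read_gff()]: internal 0-based half-open coordinates are
#' written as 1-based inclusive, with `ID`, `genome_id` and `complete`
#' attributes on CDS features.
#'
#' @param genes a [gene_table()].
#' @param path output file.
#' @export
write_gff <- function(genes, path) {
  attrs <- sprintf("ID=%s;genome_id=%s;complete=%s", genes$gene_id,
                   genes$genome_id, ifelse(genes$is_complete, "true", "false"))
  lines <- sprintf("%s\tnovfams\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                   genes$contig_id, genes$start + 1L, genes$end,
                   genes$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a two-column cluster membership table
#'
#' @param path tab-delimited file with columns `family_id`, `gene_id`
#'   (header optional; detected from the first line). Duplicate
#'   (family, gene) pairs are collapsed. A gene assigned to two different
#'   families is an error: clusters must partition the gene set.
#' @return named list mapping family_id to character vector of member
#'   gene_ids, in file order.
#' @export
read_cluster_tsv <- function(path) {
  raw <- readLines(path)
  if (length(raw) == 0 || all(!nzchar(raw)))
    return(structure(list(), names = character(0)))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#", blank.lines.skip = TRUE)
  if (identical(tolower(tab[1, 1]), "family_id"))
    tab <- tab[-1, , drop = FALSE]
  if (ncol(tab) < 2) stop("cluster table must have two columns")
  names(tab)[1:2] <- c("family_id", "gene_id")
  tab <- tab[!duplicated(paste(tab$family_id, tab$gene_id, sep = "\r")), ,
             drop = FALSE]
  dup <- duplicated(tab$gene_id)
  if (any(dup))
    stop("gene ", tab$gene_id[dup][1],
         " listed in more than one family; clusters must be a partition")
  split_ord <- split(tab$gene_id, factor(tab$family_id,
                                         levels = unique(tab$family_id)))
  lapply(split_ord, as.character)
}

#' Read an aligned (or plain) FASTA file
#'
#' @param path FASTA file. For `aligned = TRUE`, all sequences must have
#'   equal length (gaps `-` or `.` allowed).
#' @param aligned enforce equal lengths.
#' @return named character vector of sequences.
#' @export
read_alignment_fasta <- function(path, aligned = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (aligned && length(seqs) > 1 && length(unique(nchar(seqs))) != 1)
    stop("ragged alignment in ", path, ": sequence lengths differ")
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80)
  invisible(path)
}

#' Read a GTDB-style taxonomy table
#'
#' @param path tab-delimited file with columns `genome_id`, `lineage`
#'   (7 ranks separated by `;`), and optionally `uncultivated` (0/1).
#' @return data.frame with `genome_id`, one column per rank
#'   (`domain` ... `species`), `lineage` and `uncultivated`.
#' @export
read_taxonomy_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "#")
  if (!all(c("genome_id", "lineage") %in% names(tab)))
    stop("taxonomy table needs 'genome_id' and 'lineage' columns")
  parts <- strsplit(tab$lineage, ";", fixed = TRUE)
  nr <- lengths(parts)
  if (any(nr != 7))
    stop("genome ", tab$genome_id[nr != 7][1], " has ", nr[nr != 7][1],
         " lineage ranks (expected 7)")
  mat <- do.call(rbind, parts)
  if (any(!nzchar(mat)))
    stop("genome ", tab$genome_id[which(rowSums(!nzchar(mat)) > 0)[1]],
         " has an empty lineage rank")
  out <- data.frame(genome_id = tab$genome_id, mat, stringsAsFactors = FALSE)
  names(out) <- c("genome_id", GTDB_RANKS)
  out$lineage <- tab$lineage
  out$uncultivated <- if (!is.null(tab$uncultivated))
    tab$uncultivated %in% c("1", "true", "TRUE") else TRUE
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

#' Write a taxonomy table
#' @param taxonomy as returned by [read_taxonomy_tsv()].
#' @param path output file.
#' @export
write_taxonomy_tsv <- function(taxonomy, path) {
  out <- data.frame(genome_id = taxonomy$genome_id,
                    lineage = taxonomy$lineage,
                    uncultivated = as.integer(taxonomy$uncultivated))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-gene functional annotation table
#'
#' @param path tab-delimited file with columns `gene_id`, `ko`,
#'   `pathways` (comma-separated KEGG pathway ids, may be empty) and
#'   `is_resistance` (0/1).
#' @return data.frame with a `pathways` list-column.
#' @export
read_annotation_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "#", na.strings = "")
  if (!"gene_id" %in% names(tab))
    stop("annotation table needs a 'gene_id' column")
  pw <- tab$pathways
  pw[is.na(pw)] <- ""
  tab$pathways <- lapply(strsplit(pw, ",", fixed = TRUE),
                         function(x) x[nzchar(x)])
  tab$is_resistance <- if (!is.null(tab$is_resistance))
    tab$is_resistance %in% c("1", "true", "TRUE") else FALSE
  tab
}

#' Attach per-gene annotations to a gene table
#'
#' @param genes a [gene_table()].
#' @param annotations data.frame from [read_annotation_tsv()].
#' @return the gene table with `ko`, `pathways`, `is_resistance` filled in.
#' @export
annotate_genes <- function(genes, annotations) {
  idx <- match(genes$gene_id, annotations$gene_id)
  hit <- !is.na(idx)
  if (!is.null(annotations$ko)) genes$ko[hit] <- annotations$ko[idx[hit]]
  genes$pathways[hit] <- annotations$pathways[idx[hit]]
  genes$is_resistance[hit] <- annotations$is_resistance[idx[hit]]
  genes
}

#' Read per-contig mobility flags
#' @param path tab-delimited file with columns `contig_id`, `plasmid`,
#'   `viral` (0/1).
#' @return data.frame with logical `plasmid`, `viral`.
#' @export
read_contig_flags_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
  tab$plasmid <- tab$plasmid %in% c("1", "true", "TRUE")
  tab$viral <- tab$viral %in% c("1", "true", "TRUE")
  tab
}

#' Write a results table with a provenance header
#'
#' All pipeline outputs go through this writer: a `#`-prefixed header
#' records the package version, the seed and a hash of the generating
#' configuration, so identical runs produce byte-identical files.
#'
#' @param df data.frame (list-columns are collapsed with commas).
#' @param path output file.
#' @param seed,config optional provenance fields.
#' @export
write_results_tsv <- function(df, path, seed = NULL, config = NULL) {
  df <- as.data.frame(df)
  for (col in names(df))
    if (is.list(df[[col]]))
      df[[col]] <- vapply(df[[col]], paste, "", collapse = ",")
  hdr <- sprintf("# novfams %s", as.character(utils::packageVersion("novfams")))
  if (!is.null(seed)) hdr <- paste0(hdr, " seed=", seed)
  if (!is.null(config)) hdr <- paste0(hdr, " config=", rlang::hash(config))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_results_tsv()]
#' @param path file path.
#' @return data.frame (header comment skipped).
#' @export
read_results_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    quote = "", stringsAsFactors = FALSE)
}

# internal: membership of pathway p in a list-column entry
has_pathway <- function(pathway_list, p) {
  vapply(pathway_list, function(x) p %in% x, logical(1))
}
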