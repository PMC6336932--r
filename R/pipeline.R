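#' Run the comparative mitogenome pipeline
#'
#' Orchestrates the analysis stages over one or more annotated genomes
#' described by a declarative configuration, writing machine-readable
#' outputs and returning the full report.
#'
#' The configuration is a JSON file (or an equivalent R list) with:
#' \describe{
#'   \item{genomes}{array of objects with \code{id},
#'     \code{feature_table} (path, required), \code{genome_length}
#'     (required) and optional \code{fasta} (path to the sequence).}
#'   \item{stages}{subset of \code{"annotation"}, \code{"composition"},
#'     \code{"codons"}, \code{"control_region"}, \code{"gene_order"},
#'     \code{"tree"}; default all.  Sequence-dependent stages are
#'     skipped with a marker for genomes without a \code{fasta}.}
#'   \item{out_dir}{output directory (default \code{"."}); the JSON
#'     report plus per-genome TSVs and the Newick tree land there.}
#'   \item{params}{optional stage thresholds: \code{min_period},
#'     \code{min_copies}, \code{min_identity}, \code{polyT_min},
#'     \code{taa_min_units}, \code{min_stem}, \code{max_loop}.}
#' }
#'
#' @param config path to a JSON configuration file, or a list.
#' @param out_dir overrides the configuration's output directory.
#' @param quiet suppress progress messages.
#' @return the report (a nested list, also written to
#'   \code{report.json}), invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("missing config file: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
  }
  genomes <- config$genomes
  if (is.null(genomes) || length(genomes) == 0L)
    stop("config lists no genomes")
  stages <- unlist(config$stages) %||% c("annotation", "composition", "codons",
                                         "control_region", "gene_order", "tree")
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prm <- config$params %||% list()
  say <- function(...) if (!quiet) message(...)

  report <- list(genomes = list())
  orders <- list()
  for (g in genomes) {
    if (is.null(g$feature_table)) stop("genome entry without feature_table")
    if (!file.exists(g$feature_table))
      stop("missing feature table: ", g$feature_table)
    if (is.null(g$genome_length)) stop("genome entry without genome_length")
    id <- g$id %||% basename(g$feature_table)
    say("genome ", id)
    ann <- parse_feature_table(g$feature_table, g$genome_length, genome_id = id)
    genome <- NULL
    if (!is.null(g$fasta)) {
      if (!file.exists(g$fasta)) stop("missing FASTA: ", g$fasta)
      genome <- read_fasta(g$fasta)
    }
    blk <- list(id = id, genome_length = ann$genome_length)

    if ("annotation" %in% stages) {
      s <- annotation_summary(ann)
      blk$annotation <- list(
        spacers = unclass(s$spacers),
        strand = as.list(s$strand),
        class_totals = as.list(s$class_totals))
      sp <- circular_spacers(ann)
      utils::write.table(sp, file.path(out_dir, paste0(id, "_spacers.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if ("composition" %in% stages) {
      if (is.null(genome)) blk$composition <- list(skipped = "no FASTA")
      else {
        ct <- composition_table(ann, genome)
        blk$composition <- ct
        utils::write.table(ct, file.path(out_dir, paste0(id, "_composition.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    if ("codons" %in% stages) {
      if (is.null(genome)) blk$codons <- list(skipped = "no FASTA")
      else {
        f <- ann$features[ann$features$feature_class == "PCG", ]
        cds <- vapply(seq_len(nrow(f)), function(i)
          extract_feature_sequence(genome, f[i, ]), character(1L))
        usage <- codon_usage(cds)
        tab <- codon_usage_table(usage)
        blk$codons <- list(
          start_stop = pcg_start_stop(ann, genome),
          absent_codons = absent_codons(usage),
          aa_ranking = aa_usage_ranking(usage))
        utils::write.table(tab, file.path(out_dir, paste0(id, "_codon_usage.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    if ("control_region" %in% stages) {
      if (is.null(genome)) blk$control_region <- list(skipped = "no FASTA")
      else {
        crs <- ann$features[ann$features$feature_class == "CR", ]
        blk$control_region <- lapply(seq_len(nrow(crs)), function(i) {
          seq <- extract_feature_sequence(genome, crs[i, ])
          rep <- do.call(control_region_report, c(list(seq), prm))
          c(list(gene = crs$gene[i], length = nchar(seq)), rep)
        })
      }
    }
    if ("gene_order" %in% stages) {
      ord <- to_signed_gene_order(ann)
      orders[[id]] <- ord
      anc <- ancestral_insect_order()
      same_set <- setequal(ord$labels, anc$labels)
      blk$gene_order <- list(
        order = format_gene_order(ord),
        vs_ancestral = if (!same_set) list(skipped = "gene set differs from ancestral order")
        else list(
          orientation_changes = orientation_changes(ord, anc),
          breakpoint_distance = breakpoint_distance(ord, anc),
          common_interval_count = nrow(common_intervals(ord, anc)),
          trnL2_cox2_adjacent = adjacency_present(ord, "trnL2", "cox2")))
    }
    report$genomes[[id]] <- blk
  }

  if ("tree" %in% stages && length(orders) >= 3L) {
    say("gene-order tree over ", length(orders), " genomes")
    d <- distance_matrix(orders)
    tree <- neighbor_joining(d)
    nwk <- write_newick(tree, file.path(out_dir, "gene_order_tree.nwk"))
    utils::write.table(d, file.path(out_dir, "gene_order_distances.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    report$tree <- list(newick = nwk,
                        distances = list(labels = rownames(d),
                                         matrix = unname(d)))
  }

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, dataframe = "rows", na = "null")
  writeLines(json, file.path(out_dir, "report.json"))
  invisible(report)
}

#' Structural validation of a pipeline report
#'
#' Checks the nested shape \code{run_pipeline} promises: a
#' \code{genomes} block with, per genome, the stage blocks that were
#' requested, each carrying its required fields.
#'
#' @param report list as returned by \code{\link{run_pipeline}} (or
#'   re-read from \code{report.json}).
#' @return TRUE, or an error describing the first violation.
#' @export
validate_report <- function(report) {
  if (!is.list(report) || is.null(report$genomes) || !length(report$genomes))
    stop("report has no genomes block")
  for (id in names(report$genomes)) {
    g <- report$genomes[[id]]
    if (is.null(g$genome_length)) stop("genome ", id, " lacks genome_length")
    if (!is.null(g$annotation)) {
      need <- c("spacers", "strand", "class_totals")
      miss <- setdiff(need, names(g$annotation))
      if (length(miss))
        stop("genome ", id, " annotation block lacks: ",
             paste(miss, collapse = ", "))
    }
  }
  TRUE
}
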