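#' Circular intergenic / overlap accounting
#'
#' For every pair of features adjacent on the circle (control regions
#' included, since they occupy sequence) computes the signed spacer
#' length between them: positive values are intergenic nucleotides,
#' negative values overlaps, zero abutting features.  Each record is
#' attributed to the upstream feature, and the final record wraps from
#' the last feature back to the first across the origin, so an
#' annotation of n features always yields exactly n records.
#'
#' @param ann a \code{\link{mito_annotation}} with features sorted by
#'   start (as the constructor guarantees).
#' @return data frame of class \code{spacer_table} with columns
#'   \code{upstream}, \code{downstream}, \code{length} and a logical
#'   \code{deep_overlap} flag set when an overlap exceeds the shorter
#'   feature's length.
#' @examples
#' ann <- read_nsamayunkur()
#' sp <- circular_spacers(ann)
#' sp[sp$upstream == "trnS2", ]  # the 41 bp wrap spacer back to cox1
#' @export
circular_spacers <- function(ann) {
  f <- ann$features
  n <- nrow(f)
  if (n < 1L) stop("no features")
  if (is.unsorted(f$start)) stop("features not sorted by start")
  L <- ann$genome_length
  nxt <- c(seq_len(n)[-1L], 1L)
  len <- integer(n)
  for (i in seq_len(n)) {
    j <- nxt[i]
    len[i] <- if (j != 1L) f$start[j] - f$end[i] - 1L
              else L - f$end[i] + f$start[1L] - 1L
  }
  deep <- -len > pmin(f$length, f$length[nxt])
  out <- data.frame(upstream = f$gene, downstream = f$gene[nxt],
                    length = len, deep_overlap = deep,
                    stringsAsFactors = FALSE)
  class(out) <- c("spacer_table", "data.frame")
  out
}

#' Summarize spacer records
#'
#' Totals, counts and extrema over the positive (intergenic) and
#' negative (overlap) spacer records.  Zero-length abutments count as
#' neither an intergenic location nor an overlap.
#'
#' @param spacers output of \code{\link{circular_spacers}}.
#' @return list of class \code{spacer_summary} with
#'   \code{total_intergenic}, \code{intergenic_locations},
#'   \code{min_intergenic}, \code{max_intergenic}, \code{overlap_pairs},
#'   \code{total_overlap}, \code{min_overlap}, \code{max_overlap}
#'   (overlap sizes reported as positive bp; extrema are \code{NA} for
#'   empty categories).
#' @export
spacer_summary <- function(spacers) {
  pos <- spacers$length[spacers$length > 0L]
  neg <- -spacers$length[spacers$length < 0L]
  structure(list(
    total_intergenic = as.integer(sum(pos)),
    intergenic_locations = length(pos),
    min_intergenic = if (length(pos)) min(pos) else NA_integer_,
    max_intergenic = if (length(pos)) max(pos) else NA_integer_,
    overlap_pairs = length(neg),
    total_overlap = as.integer(sum(neg)),
    min_overlap = if (length(neg)) min(neg) else NA_integer_,
    max_overlap = if (length(neg)) max(neg) else NA_integer_
  ), class = "spacer_summary")
}

#' @export
print.spacer_summary <- function(x, ...) {
  cat(sprintf("intergenic: %d bp across %d locations (%s-%s bp)\n",
              x$total_intergenic, x$intergenic_locations,
              x$min_intergenic, x$max_intergenic))
  cat(sprintf("overlaps:   %d pairs, %d bp total (%s-%s bp)\n",
              x$overlap_pairs, x$total_overlap, x$min_overlap, x$max_overlap))
  invisible(x)
}

#' Majority / minority strand gene counts
#'
#' Counts genes on each strand; control regions are excluded (they are
#' treated as unoriented).
#'
#' @param ann a \code{\link{mito_annotation}}.
#' @return named integer vector \code{c(majority = , minority = )}.
#' @export
strand_counts <- function(ann) {
  f <- ann$features[ann$features$feature_class != "CR", ]
  c(majority = sum(f$strand == "+"), minority = sum(f$strand == "-"))
}

#' Total length per feature class
#'
#' Sums raw feature spans (overlap bases are not subtracted: annotated
#' lengths are reported as printed in feature tables, so the circle
#' conservation identity \code{sum(class_totals) + intergenic - overlap
#' = genome length} holds exactly when the features tile the circle).
#'
#' @param ann a \code{\link{mito_annotation}}.
#' @return named integer vector over the classes present among
#'   \code{PCG}, \code{tRNA}, \code{rRNA}, \code{CR}.
#' @export
class_totals <- function(ann) {
  f <- ann$features
  tot <- tapply(f$length, factor(f$feature_class,
                                 levels = c("PCG", "tRNA", "rRNA", "CR")),
                sum)
  tot <- tot[!is.na(tot)]
  stats::setNames(as.integer(tot), names(tot))
}

#' Full annotation summary
#'
#' Convenience wrapper combining \code{\link{spacer_summary}},
#' \code{\link{strand_counts}} and \code{\link{class_totals}}.
#'
#' @param ann a \code{\link{mito_annotation}}.
#' @return list of class \code{annotation_summary} with components
#'   \code{spacers} (the summary), \code{strand} and \code{class_totals},
#'   plus \code{genome_length}.
#' @export
annotation_summary <- function(ann) {
  structure(list(
    genome_id = ann$genome_id,
    genome_length = ann$genome_length,
    spacers = spacer_summary(circular_spacers(ann)),
    strand = strand_counts(ann),
    class_totals = class_totals(ann)
  ), class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat(sprintf("<annotation_summary> %s (%d bp)\n", x$genome_id, x$genome_length))
  print(x$spacers)
  cat(sprintf("strands:    %d majority / %d minority\n",
              x$strand[["majority"]], x$strand[["minority"]]))
  cat("class bp:  ",
      paste(sprintf("%s %d", names(x$class_totals), x$class_totals),
            collapse = ", "), "\n")
  invisible(x)
}
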