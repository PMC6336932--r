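#' Strand-asymmetry skews
#'
#' AT skew = (A - T) / (A + T); GC skew = (G - C) / (G + C).  Inputs may
#' be counts or percentages: the skew is scale-free.  Positive AT skew
#' means an excess of A over T on the strand examined (conventionally
#' the majority strand).
#'
#' @param a,t,g,c counts or fractions of the respective bases.
#' @return skew value in [-1, 1], full precision.
#' @examples
#' at_skew(40.25, 37.17)  # 0.0398 -> prints as 0.04 at 2 decimals
#' gc_skew(10.98, 11.60)  # -0.0275 -> -0.03
#' @export
at_skew <- function(a, t) {
  if (any(a + t <= 0)) stop("AT skew undefined: A + T = 0")
  (a - t) / (a + t)
}

#' @rdname at_skew
#' @export
gc_skew <- function(g, c) {
  if (any(g + c <= 0)) stop("GC skew undefined: G + C = 0")
  (g - c) / (g + c)
}

#' Base composition of a sequence
#'
#' Counts A/C/G/T and tallies every other (ambiguity) character as
#' \code{other}; percentages are over the full length, while skews are
#' computed over unambiguous bases only.
#'
#' @param seq nucleotide string (uppercased internally).
#' @return object of class \code{composition_summary}: list with
#'   \code{counts} (named, incl. \code{other}), \code{length},
#'   \code{pct} (named percentages), \code{at_pct}, \code{gc_pct},
#'   \code{at_skew}, \code{gc_skew} (NA, with \code{skew_defined} FALSE,
#'   when a denominator is zero).
#' @export
base_counts <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  n <- nchar(s)
  if (n == 0L) stop("empty sequence")
  b <- str_bases(s)
  cnt <- c(A = sum(b == "A"), C = sum(b == "C"),
           G = sum(b == "G"), T = sum(b == "T"))
  other <- n - sum(cnt)
  pct <- 100 * cnt / n
  atd <- cnt[["A"]] + cnt[["T"]]; gcd <- cnt[["G"]] + cnt[["C"]]
  structure(list(
    counts = c(cnt, other = other),
    length = n,
    pct = pct,
    at_pct = pct[["A"]] + pct[["T"]],
    gc_pct = pct[["G"]] + pct[["C"]],
    at_skew = if (atd > 0) (cnt[["A"]] - cnt[["T"]]) / atd else NA_real_,
    gc_skew = if (gcd > 0) (cnt[["G"]] - cnt[["C"]]) / gcd else NA_real_,
    skew_defined = atd > 0 && gcd > 0
  ), class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, digits = 2, ...) {
  cat(sprintf("<composition_summary> %d bp  A %.2f%%  C %.2f%%  G %.2f%%  T %.2f%%\n",
              x$length, x$pct[["A"]], x$pct[["C"]], x$pct[["G"]], x$pct[["T"]]))
  cat(sprintf("  AT %.2f%%  GC %.2f%%  AT skew %s  GC skew %s\n",
              x$at_pct, x$gc_pct,
              format(round_half_up(x$at_skew, digits), nsmall = digits),
              format(round_half_up(x$gc_skew, digits), nsmall = digits)))
  invisible(x)
}

# round half away from zero (printed tables round 0.035 -> 0.04)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Composition per feature class and whole genome
#'
#' Each class summary is computed over the concatenated majority-strand
#' slices of that class's features (origin-spanning features wrap).
#' Slices are strand-agnostic: a minus-strand gene contributes its
#' majority-strand span, so that class rows are comparable across
#' genomes regardless of coding strand, and bases inside overlapping
#' features count once per class they belong to.  The whole-genome row
#' is the full majority strand.
#'
#' @param ann a \code{\link{mito_annotation}}.
#' @param genome the matching \code{\link{genome_sequence}}.
#' @return named list of \code{\link{base_counts}} summaries: one per
#'   feature class present, plus \code{whole}.
#' @export
composition_by_class <- function(ann, genome) {
  if (genome$length != ann$genome_length)
    stop("annotation genome_length disagrees with sequence length")
  f <- ann$features
  out <- list(whole = base_counts(genome$seq))
  for (cls in c("PCG", "tRNA", "rRNA", "CR")) {
    rows <- which(f$feature_class == cls)
    if (length(rows) == 0L) next
    slices <- vapply(rows, function(i) {
      ft <- f[i, ]; ft$strand <- "+"  # majority-strand slice
      extract_feature_sequence(genome, ft)
    }, character(1L))
    out[[cls]] <- base_counts(paste(slices, collapse = ""))
  }
  out
}

#' Composition table across classes
#'
#' Flattens \code{\link{composition_by_class}} into a data frame in the
#' layout of published mitogenome composition tables (size, base
#' percentages, AT/GC content and skews), rounding half away from zero
#' to \code{digits} decimals.
#'
#' @param ann,genome as for \code{\link{composition_by_class}}.
#' @param digits decimal places for percentages and skews (default 2).
#' @return data frame with one row per region.
#' @export
composition_table <- function(ann, genome, digits = 2) {
  cs <- composition_by_class(ann, genome)
  do.call(rbind, lapply(names(cs), function(nm) {
    x <- cs[[nm]]
    data.frame(region = nm, size_bp = x$length,
               A = round_half_up(x$pct[["A"]], digits),
               G = round_half_up(x$pct[["G"]], digits),
               T = round_half_up(x$pct[["T"]], digits),
               C = round_half_up(x$pct[["C"]], digits),
               GC = round_half_up(x$gc_pct, digits),
               AT = round_half_up(x$at_pct, digits),
               AT_skew = round_half_up(x$at_skew, digits),
               GC_skew = round_half_up(x$gc_skew, digits),
               stringsAsFactors = FALSE)
  }))
}
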