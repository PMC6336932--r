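#' Construct a genome sequence object
#'
#' A light container for a (typically circular) nucleotide sequence.
#' The sequence is uppercased and U is mapped to T on construction.
#'
#' @param seq nucleotide string.
#' @param id text label.
#' @param circular logical; circular molecule (default TRUE, as for
#'   animal mitogenomes).
#' @return object of class \code{genome_sequence} with elements
#'   \code{id}, \code{seq}, \code{circular}, \code{length}.
#' @export
genome_sequence <- function(seq, id = "genome", circular = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("u", "t", seq)
  s <- toupper(chartr("U", "T", s))
  if (nchar(s) == 0L) stop("empty sequence")
  if (grepl("[^ACGTNRYSWKMBDHV]", s))
    stop("sequence contains non-IUPAC characters")
  structure(list(id = as.character(id), seq = s,
                 circular = isTRUE(circular), length = nchar(s)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s: %d bp%s\n", x$id, x$length,
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Read a single-record FASTA file
#'
#' @param path path to a FASTA file holding exactly one record.
#' @param circular logical flag stored on the result.
#' @return a \code{\link{genome_sequence}}; the id is the first token of
#'   the header.
#' @export
read_fasta <- function(path, circular = TRUE) {
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  if (length(recs) > 1L)
    stop("expected a single FASTA record, found ", length(recs))
  genome_sequence(as.character(recs[[1L]]), id = names(recs)[1L],
                  circular = circular)
}

#' Write a genome sequence to FASTA
#'
#' @param genome a \code{\link{genome_sequence}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(genome, path) {
  seqinr::write.fasta(sequences = genome$seq, names = genome$id,
                      file.out = path, as.string = TRUE)
  invisible(path)
}

# ---- annotations ----------------------------------------------------------

#' Construct a mitogenome annotation
#'
#' An annotation is an ordered set of features (genes plus control
#' regions) on a circular genome, with 1-based inclusive coordinates on
#' the majority strand.  Features whose span crosses the sequence origin
#' are encoded with \code{start > end}.
#'
#' @param features data frame with columns \code{gene}, \code{strand}
#'   (\code{"+"}/\code{"-"}), \code{start}, \code{end} and optionally
#'   \code{anticodon}, \code{start_codon}, \code{stop_codon} and a
#'   logical \code{wrap} column marking origin-spanning features
#'   (required whenever \code{start > end}).
#' @param genome_length total genome length in bp.
#' @param genome_id text label.
#' @param canonicalize resolve gene-name dialects via
#'   \code{\link{canonical_gene_name}} (default TRUE).
#' @return object of class \code{mito_annotation}: a list with
#'   \code{genome_id}, \code{genome_length} and \code{features}, a data
#'   frame sorted by start coordinate with added columns
#'   \code{feature_class} and \code{length}.
#' @export
mito_annotation <- function(features, genome_length, genome_id = "genome",
                            canonicalize = TRUE) {
  stopifnot(is.data.frame(features))
  need <- c("gene", "strand", "start", "end")
  if (!all(need %in% names(features)))
    stop("features must have columns: ", paste(need, collapse = ", "))
  if (nrow(features) == 0L) stop("no features")
  f <- features
  f$gene <- if (canonicalize) canonical_gene_name(f$gene) else as.character(f$gene)
  if (anyDuplicated(f$gene))
    stop("duplicate gene name(s): ",
         paste(unique(f$gene[duplicated(f$gene)]), collapse = ", "))
  if (!all(f$strand %in% c("+", "-")))
    stop("unknown strand symbol(s): ",
         paste(unique(f$strand[!f$strand %in% c("+", "-")]), collapse = ", "))
  f$start <- as.integer(f$start); f$end <- as.integer(f$end)
  L <- as.integer(genome_length)
  bad <- f$start < 1L | f$start > L | f$end < 1L | f$end > L
  if (any(bad))
    stop("coordinates outside [1, ", L, "] for: ",
         paste(f$gene[bad], collapse = ", "))
  if (is.null(f$wrap)) f$wrap <- FALSE
  f$wrap <- !is.na(f$wrap) & as.logical(f$wrap)
  rev_bad <- f$start > f$end & !f$wrap
  if (any(rev_bad))
    stop("start > end without the origin-spanning wrap flag for: ",
         paste(f$gene[rev_bad], collapse = ", "))
  for (col in c("anticodon", "start_codon", "stop_codon"))
    if (is.null(f[[col]])) f[[col]] <- NA_character_ else
      f[[col]] <- ifelse(f[[col]] %in% c("", "-", "—"), NA_character_,
                         as.character(f[[col]]))
  f$feature_class <- feature_class_of(f$gene)
  f$length <- ifelse(f$start <= f$end, f$end - f$start + 1L,
                     (L - f$start + 1L) + f$end)
  f <- f[order(f$start), c("gene", "strand", "start", "end", "length",
                           "feature_class", "anticodon", "start_codon",
                           "stop_codon", "wrap")]
  rownames(f) <- NULL
  structure(list(genome_id = as.character(genome_id), genome_length = L,
                 features = f),
            class = "mito_annotation")
}

#' @export
print.mito_annotation <- function(x, ...) {
  cls <- table(x$features$feature_class)
  cat(sprintf("<mito_annotation> %s: %d bp, %d features (%s)\n",
              x$genome_id, x$genome_length, nrow(x$features),
              paste(sprintf("%s %d", names(cls), cls), collapse = ", ")))
  invisible(x)
}

#' Parse a tab-separated feature table
#'
#' Reads an annotation table with header columns \code{gene},
#' \code{strand}, \code{start}, \code{end} and optionally
#' \code{anticodon}, \code{start_codon}, \code{stop_codon}.  Incomplete
#' stop-codon notation such as \code{"T(AA)"} is preserved verbatim.
#' Feature class is inferred from the canonical name (trn* = tRNA,
#' rrn* = rRNA, CR* = control region, otherwise protein-coding).
#'
#' @param path path to the TSV file.
#' @param genome_length total genome length in bp.
#' @param genome_id label for the annotation.
#' @return a \code{\link{mito_annotation}}.
#' @export
parse_feature_table <- function(path, genome_length, genome_id = "genome") {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#", quote = "")
  if (nrow(tab) == 0L) stop("no features in ", path)
  mito_annotation(tab, genome_length = genome_length, genome_id = genome_id)
}

#' Write an annotation back to the feature-table TSV format
#'
#' Inverse of \code{\link{parse_feature_table}}: the written file
#' re-parses to an identical annotation.
#'
#' @param ann a \code{\link{mito_annotation}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(ann, path) {
  f <- ann$features[, c("gene", "strand", "start", "end", "anticodon",
                        "start_codon", "stop_codon", "wrap")]
  utils::write.table(f, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Extract the coding-strand sequence of a feature
#'
#' Returns the 5'-to-3' sequence of the feature as read on its own
#' coding strand: plus-strand features are the plain slice of the
#' majority strand, minus-strand features its reverse complement.
#' Features with \code{start > end} span the origin of the circular
#' sequence and are assembled as tail + head before orientation.
#'
#' @param genome a \code{\link{genome_sequence}}.
#' @param feature one-row data frame (a row of
#'   \code{annotation$features}) or a list with \code{start}, \code{end},
#'   \code{strand}.
#' @return nucleotide string.
#' @export
extract_feature_sequence <- function(genome, feature) {
  s <- as.integer(feature$start); e <- as.integer(feature$end)
  L <- genome$length
  if (s < 1L || s > L || e < 1L || e > L) stop("feature coordinates outside genome")
  if (s <= e) {
    frag <- substr(genome$seq, s, e)
  } else {
    if (!genome$circular) stop("origin-spanning feature on a linear sequence")
    frag <- paste0(substr(genome$seq, s, L), substr(genome$seq, 1L, e))
  }
  if (nchar(frag) > L) stop("feature longer than genome")
  if (identical(as.character(feature$strand), "-")) revcomp(frag) else frag
}

# ---- signed gene orders ---------------------------------------------------

#' Construct a signed circular gene order
#'
#' A gene order is a circular permutation of unique gene labels with a
#' per-gene orientation sign.  On construction the order is
#' canonicalized: it is rotated so that the anchor gene is first, and if
#' the anchor carries sign -1 the entire order is reflected (reversed
#' with all signs flipped) so the anchor reads +1.  Two orders that are
#' equal as signed circular sequences therefore have identical canonical
#' representations.
#'
#' @param labels character vector of gene labels (no duplicates).
#' @param signs integer vector of +1/-1, one per label (default all +1).
#' @param anchor label used as position 1 (default the first label).
#' @return object of class \code{gene_order} with elements
#'   \code{labels}, \code{signs}, \code{anchor}.
#' @export
gene_order <- function(labels, signs = rep(1L, length(labels)),
                       anchor = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("empty gene order")
  if (anyDuplicated(labels))
    stop("duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  signs <- as.integer(signs)
  if (length(signs) != length(labels) || !all(signs %in% c(-1L, 1L)))
    stop("signs must be +1/-1, one per label")
  if (is.null(anchor)) anchor <- labels[1L]
  i <- match(anchor, labels)
  if (is.na(i)) stop("anchor gene '", anchor, "' not in order")
  n <- length(labels)
  rot <- mod1(seq_len(n) + i - 1L, n)
  labels <- labels[rot]; signs <- signs[rot]
  if (signs[1L] == -1L) {  # reflect so the anchor reads +
    labels <- c(labels[1L], rev(labels[-1L]))
    signs <- -c(signs[1L], rev(signs[-1L]))
  }
  structure(list(labels = labels, signs = signs, anchor = as.character(anchor)),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat("<gene_order>", format_gene_order(x), "\n")
  invisible(x)
}

#' Format / parse one-line signed gene orders
#'
#' The text form is a space-separated list of labels with a leading
#' \code{-} on minority-strand genes, e.g. \code{"cox1 -trnQ trnM"}.
#'
#' @param x a \code{gene_order} (for \code{format_gene_order}) or a
#'   character scalar (for \code{parse_gene_order}).
#' @param anchor optional anchor passed to \code{\link{gene_order}}.
#' @return a character scalar, or a \code{gene_order}.
#' @export
format_gene_order <- function(x) {
  paste0(ifelse(x$signs < 0L, "-", ""), x$labels, collapse = " ")
}

#' @rdname format_gene_order
#' @export
parse_gene_order <- function(x, anchor = NULL) {
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1L]]
  signs <- ifelse(startsWith(toks, "-"), -1L, 1L)
  labels <- sub("^[-+]", "", toks)
  gene_order(labels, signs, anchor = anchor)
}

#' Signed gene-order equality (circular, reflection-aware)
#'
#' @param a,b \code{gene_order} objects.
#' @return TRUE if a and b are equal as signed circular orders once both
#'   are anchored at the same gene.
#' @export
gene_order_equal <- function(a, b) {
  if (length(a$labels) != length(b$labels)) return(FALSE)
  if (!all(sort(a$labels) == sort(b$labels))) return(FALSE)
  b2 <- gene_order(b$labels, b$signs, anchor = a$labels[1L])
  identical(a$labels, b2$labels) && identical(a$signs, b2$signs)
}

#' Derive the signed gene order of an annotation
#'
#' Genes are taken in ascending start-coordinate order around the
#' circle; control regions are excluded.  The result is anchored at
#' \code{cox1} with \code{cox1} forced to orientation +1 (the whole
#' order is reflected if cox1 lies on the minority strand).
#'
#' @param ann a \code{\link{mito_annotation}} containing cox1.
#' @param anchor anchor gene (default \code{"cox1"}).
#' @return a \code{\link{gene_order}}.
#' @export
to_signed_gene_order <- function(ann, anchor = "cox1") {
  f <- ann$features[ann$features$feature_class != "CR", ]
  if (nrow(f) == 0L) stop("annotation has no genes")
  if (nrow(f) > 1L && !(anchor %in% f$gene))
    stop("anchor gene '", anchor, "' missing from annotation")
  if (nrow(f) == 1L)
    return(gene_order(f$gene, 1L))
  gene_order(f$gene, ifelse(f$strand == "+", 1L, -1L), anchor = anchor)
}

#' The ancestral insect (Drosophila-like) mitochondrial gene order
#'
#' The 37-gene signed order used as the outgroup reference for
#' rearrangement analysis, anchored at cox1 on the majority strand.
#'
#' @return a \code{\link{gene_order}} of 37 genes, 14 of them on the
#'   minority strand.
#' @examples
#' anc <- ancestral_insect_order()
#' adjacency_present(anc, "trnL2", "cox2")  # TRUE
#' @export
ancestral_insect_order <- function() {
  parse_gene_order(paste(
    "cox1 trnL2 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 trnA trnR trnN",
    "trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4L trnT -trnP nad6 cytb",
    "trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS trnI -trnQ trnM nad2 trnW",
    "-trnC -trnY"), anchor = "cox1")
}
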