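#' The invertebrate mitochondrial genetic code (translation table 5)
#'
#' Builds the codon table used throughout the codon-usage analyses.
#' Relative to the standard code, translation table 5 reassigns AGA and
#' AGG to serine, ATA to methionine, and TGA to tryptophan; TAA and TAG
#' remain the only termination codons.  Alternative initiation codons of
#' the table (ATN plus TTG and GTG) are carried alongside.
#'
#' @return an object of class \code{genetic_code}: a list with
#'   \item{id}{table identifier (5).}
#'   \item{name}{human-readable name.}
#'   \item{codons}{named character vector of 64 codons mapping to
#'     one-letter amino-acid codes, with \code{"*"} for stop.}
#'   \item{start_codons}{character vector of initiation codons.}
#'   \item{stop_codons}{\code{c("TAA", "TAG")}.}
#' @examples
#' gc <- invertebrate_mito_code()
#' gc$codons[["AGA"]]  # "S"
#' gc$codons[["TGA"]]  # "W"
#' @export
invertebrate_mito_code <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  # NCBI amino-acid string for translation table 5, codon order TTT..GGG
  aa <- strsplit(
    "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSSSSVVVVAAAADDEEGGGG",
    "", fixed = TRUE)[[1L]]
  map <- stats::setNames(aa, codons)
  structure(list(
    id = 5L,
    name = "invertebrate mitochondrial",
    codons = map,
    start_codons = c("ATT", "ATC", "ATA", "ATG", "TTG", "GTG"),
    stop_codons = c("TAA", "TAG")
  ), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", x$name, sprintf("(table %d)\n", x$id))
  cat("  stop codons: ", paste(x$stop_codons, collapse = ", "), "\n")
  cat("  start codons:", paste(x$start_codons, collapse = ", "), "\n")
  invisible(x)
}

#' Translate a coding sequence
#'
#' Frame-0 translation over complete triplets; trailing bases that do not
#' fill a codon are ignored.  Codons containing characters outside
#' A/C/G/T translate to \code{"X"}.
#'
#' @param cds coding-strand nucleotide string.
#' @param code a \code{genetic_code}; defaults to translation table 5.
#' @return character vector of one-letter amino-acid codes ("*" = stop).
#' @export
translate_cds <- function(cds, code = invertebrate_mito_code()) {
  cods <- split_codons(cds)
  out <- unname(code$codons[cods])
  out[is.na(out)] <- "X"
  out
}

# complete triplets of a sequence, frame 0; trailing remainder dropped
split_codons <- function(cds) {
  s <- toupper(cds)
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# ---- gene-name canonicalization ------------------------------------------

# canonical labels used across the package
.canonical_genes <- c(
  paste0("cox", 1:3), paste0("nad", 1:6), "nad4L", "atp6", "atp8", "cytb",
  "rrnS", "rrnL",
  paste0("trn", c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "K",
                  "M", "F", "P", "T", "W", "Y", "V")),
  "trnL1", "trnL2", "trnS1", "trnS2", "CR1", "CR2"
)

# alias table: lowercase dialect form -> canonical label
.gene_aliases <- c(
  "coi" = "cox1", "coii" = "cox2", "coiii" = "cox3",
  "co1" = "cox1", "co2" = "cox2", "co3" = "cox3",
  "cob" = "cytb", "cytB" = "cytb",
  "nd1" = "nad1", "nd2" = "nad2", "nd3" = "nad3", "nd4" = "nad4",
  "nd4l" = "nad4L", "nd5" = "nad5", "nd6" = "nad6",
  "12s" = "rrnS", "16s" = "rrnL", "srrna" = "rrnS", "lrrna" = "rrnL",
  "rrn12" = "rrnS", "rrn16" = "rrnL",
  "trnl-cun" = "trnL1", "trnl-uur" = "trnL2", "trnl(cun)" = "trnL1",
  "trnl(uur)" = "trnL2", "trns-agn" = "trnS1", "trns-ucn" = "trnS2",
  "trns(agn)" = "trnS1", "trns(ucn)" = "trnS2",
  "cr" = "CR1", "d-loop" = "CR1", "control region" = "CR1"
)

#' Canonicalize mitochondrial gene names
#'
#' Case-insensitive resolution of common GenBank naming dialects
#' (COI/COX1, ND2/nad2, 12S/rrnS, trnL-UUR/trnL2, ...) to the canonical
#' label set cox1-3, nad1-6, nad4L, atp6/8, cytb, rrnS/rrnL, trnX
#' (with L1/L2/S1/S2 variants) and CR1/CR2.  Names that are already
#' canonical up to case are accepted; anything unresolvable errors.
#'
#' @param name character vector of gene names.
#' @return character vector of canonical names.
#' @export
canonical_gene_name <- function(name) {
  low <- tolower(trimws(name))
  canon <- .canonical_genes[match(low, tolower(.canonical_genes))]
  alias <- unname(.gene_aliases[low])
  out <- ifelse(is.na(canon), alias, canon)
  if (anyNA(out))
    stop("unknown gene name(s): ", paste(unique(name[is.na(out)]), collapse = ", "))
  out
}

# feature class from canonical name
feature_class_of <- function(name) {
  ifelse(grepl("^trn", name), "tRNA",
    ifelse(grepl("^rrn", name), "rRNA",
      ifelse(grepl("^CR", name), "CR", "PCG")))
}
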