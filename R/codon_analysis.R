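#' Start / stop codon record of a coding sequence
#'
#' Mitochondrial protein-coding genes frequently end on an incomplete
#' termination codon (a trailing T or TA completed to TAA by mRNA
#' polyadenylation).  This classifies a coding-strand CDS: the start is
#' the first triplet; a length divisible by 3 ending in TAA/TAG is a
#' complete stop; a remainder of 1 ending in T, or of 2 ending in TA,
#' is an incomplete stop rendered \code{"T(AA)"} / \code{"TA(A)"};
#' anything else is flagged anomalous.
#'
#' @param cds coding-strand nucleotide string, length >= 6.
#' @param gene gene name carried through to the record.
#' @return list of class \code{start_stop_record} with \code{gene},
#'   \code{start_codon}, \code{stop_codon} (display form),
#'   \code{complete_stop}, \code{remainder}, \code{anomalous}.
#' @export
start_stop_codons <- function(cds, gene = NA_character_) {
  s <- toupper(cds)
  n <- nchar(s)
  if (n < 6L) stop("CDS shorter than 6 nt")
  start <- substr(s, 1L, 3L)
  rem <- n %% 3L
  stop_codon <- NA_character_; complete <- FALSE; anomalous <- FALSE
  if (rem == 0L) {
    last <- substr(s, n - 2L, n)
    if (last %in% c("TAA", "TAG")) {
      stop_codon <- last; complete <- TRUE
    } else anomalous <- TRUE
  } else if (rem == 1L && substr(s, n, n) == "T") {
    stop_codon <- "T(AA)"
  } else if (rem == 2L && substr(s, n - 1L, n) == "TA") {
    stop_codon <- "TA(A)"
  } else anomalous <- TRUE
  structure(list(gene = gene, start_codon = start, stop_codon = stop_codon,
                 complete_stop = complete, remainder = rem,
                 anomalous = anomalous),
            class = "start_stop_record")
}

#' Codon usage over a set of coding sequences
#'
#' Counts complete frame-0 triplets over all sequences (start codons
#' included; trailing incomplete codons ignored).  Termination codons
#' are counted but excluded from synonymous families, which are defined
#' by the genetic code in use (under the invertebrate mitochondrial
#' code leucine has 6 synonymous codons and serine 8).
#'
#' @param cds_list character vector or list of coding-strand sequences.
#' @param code a \code{genetic_code} (default translation table 5).
#' @return object of class \code{codon_usage}: list with
#'   \code{counts} (named over all 64 codons), \code{aa} (codon to
#'   amino-acid map), \code{family_counts} (per amino acid),
#'   \code{total_sense} and \code{code}.
#' @export
codon_usage <- function(cds_list, code = invertebrate_mito_code()) {
  cods <- unlist(lapply(cds_list, split_codons), use.names = FALSE)
  counts <- stats::setNames(integer(length(code$codons)), names(code$codons))
  if (length(cods)) {
    tab <- table(factor(cods, levels = names(code$codons)))
    counts[names(tab)] <- as.integer(tab)
  }
  aa <- code$codons
  sense <- aa != "*"
  fam <- tapply(counts[sense], aa[sense], sum)
  structure(list(counts = counts, aa = aa,
                 family_counts = stats::setNames(as.integer(fam), names(fam)),
                 total_sense = sum(counts[sense]),
                 code = code),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("<codon_usage> %d sense codons over %d used codon types\n",
              x$total_sense, sum(x$counts > 0)))
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' For codon c in synonymous family F (all sense codons translating to
#' the same amino acid): RSCU(c) = count(c) * |F| / sum of counts over
#' F, i.e. the observed count divided by the count expected under
#' uniform use of the family.  Families with zero total usage get RSCU
#' 0 and are listed in the \code{zero_families} attribute.
#'
#' @param usage a \code{\link{codon_usage}}.
#' @return named numeric vector of RSCU values over sense codons, with
#'   attribute \code{zero_families}.
#' @export
rscu <- function(usage) {
  aa <- usage$aa
  sense <- names(aa)[aa != "*"]
  vals <- stats::setNames(numeric(length(sense)), sense)
  zero <- character(0)
  for (a in unique(aa[sense])) {
    fam <- sense[aa[sense] == a]
    tot <- sum(usage$counts[fam])
    if (tot == 0) {
      zero <- c(zero, a)
      vals[fam] <- 0
    } else {
      vals[fam] <- usage$counts[fam] * length(fam) / tot
    }
  }
  attr(vals, "zero_families") <- zero
  vals
}

#' Sense codons never used
#'
#' @param usage a \code{\link{codon_usage}}.
#' @return sorted character vector of sense codons with zero count
#'   (termination codons are not considered).
#' @export
absent_codons <- function(usage) {
  sense <- names(usage$aa)[usage$aa != "*"]
  sort(sense[usage$counts[sense] == 0])
}

#' Amino acids ranked by usage
#'
#' @param usage a \code{\link{codon_usage}}.
#' @return character vector of one-letter amino-acid codes sorted by
#'   family count descending, ties broken alphabetically.
#' @export
aa_usage_ranking <- function(usage) {
  fc <- usage$family_counts
  names(fc)[order(-fc, names(fc))]
}

#' Tabulate codon usage with RSCU
#'
#' @param usage a \code{\link{codon_usage}}.
#' @return data frame with columns \code{codon}, \code{aa},
#'   \code{count}, \code{rscu}, sorted by amino acid then codon;
#'   termination codons appear with \code{rscu = NA}.
#' @export
codon_usage_table <- function(usage) {
  r <- rscu(usage)
  codons <- names(usage$aa)
  out <- data.frame(codon = codons, aa = unname(usage$aa),
                    count = unname(usage$counts[codons]),
                    rscu = unname(r[codons]),
                    stringsAsFactors = FALSE)
  out[order(out$aa, out$codon), ]
}

#' Start/stop census across an annotated genome
#'
#' Extracts every protein-coding gene's coding-strand sequence and
#' classifies its start and stop codons.
#'
#' @param ann a \code{\link{mito_annotation}}.
#' @param genome the matching \code{\link{genome_sequence}}.
#' @return data frame with one row per PCG: \code{gene},
#'   \code{start_codon}, \code{stop_codon}, \code{complete_stop},
#'   \code{anomalous}.
#' @export
pcg_start_stop <- function(ann, genome) {
  f <- ann$features[ann$features$feature_class == "PCG", ]
  recs <- lapply(seq_len(nrow(f)), function(i) {
    r <- start_stop_codons(extract_feature_sequence(genome, f[i, ]),
                           gene = f$gene[i])
    data.frame(gene = r$gene, start_codon = r$start_codon,
               stop_codon = r$stop_codon, complete_stop = r$complete_stop,
               anomalous = r$anomalous, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}
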