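# Seeded generators.  Every generator is a pure function of its
# arguments plus a single integer seed; the caller's RNG state is left
# untouched (see with_seed).

#' Random nucleotide sequence with given base probabilities
#'
#' @param length sequence length in bp.
#' @param probs named numeric vector of probabilities for A, C, G, T
#'   (must sum to 1); default is the uniform distribution.
#' @param seed integer seed.
#' @param id label for the resulting \code{\link{genome_sequence}}.
#' @param circular circularity flag.
#' @return a \code{\link{genome_sequence}} of i.i.d. draws.
#' @export
synth_sequence <- function(length, probs = c(A = .25, C = .25, G = .25, T = .25),
                           seed = 1, id = "synthetic", circular = TRUE) {
  if (length < 1L) stop("length must be positive")
  probs <- probs[c("A", "C", "G", "T")]
  if (anyNA(probs) || any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("probs must be nonnegative over A,C,G,T and sum to 1")
  s <- with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = probs),
          collapse = ""))
  genome_sequence(s, id = id, circular = circular)
}

# one random CDS honoring frame, start and (possibly incomplete) stop
.synth_cds <- function(len, codon_weights, start_codon = NULL,
                       stop_codon = NULL) {
  code <- invertebrate_mito_code()
  sense <- names(code$codons)[code$codons != "*"]
  w <- codon_weights[sense]; w[is.na(w)] <- 0
  incomplete <- !is.null(stop_codon) && grepl("\\(", stop_codon)
  tail_nt <- if (incomplete) sub("\\(.*", "", stop_codon) else NULL
  stop_nt <- if (incomplete) "" else
    if (is.null(stop_codon)) "TAA" else stop_codon
  if (incomplete) {
    if (len %% 3L != nchar(tail_nt))
      stop("CDS length ", len, " incompatible with incomplete stop ", stop_codon)
  } else if (len %% 3L != 0L)
    stop("CDS length ", len, " not a multiple of 3 for a complete stop")
  if (is.null(start_codon))
    start_codon <- sample(c("ATA", "ATT", "ATG", "ATC"), 1L)
  n_body <- (len - nchar(tail_nt %||% "") - 3L - nchar(stop_nt)) %/% 3L
  body <- sample(sense, max(0L, n_body), replace = TRUE, prob = w)
  paste0(start_codon, paste(body, collapse = ""), stop_nt, tail_nt %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specification for a synthetic annotated mitogenome
#'
#' The defaults emulate a thrips-like mitogenome at reduced scale: 13
#' protein-coding genes, 22 tRNAs, two rRNAs and two control regions
#' on an AT-rich molecule (whole-genome base frequencies
#' A .40 / C .12 / G .11 / T .37), a majority of plus-strand genes,
#' short intergenic spacers of 0-41 bp with occasional small overlaps
#' between tRNA pairs, and codon usage biased toward A/T-rich codons.
#'
#' @param n_pcg,n_trna,n_rrna,n_cr feature counts per class.
#' @param pcg_len,trna_len,rrna_len,cr_len length ranges (2-vectors;
#'   PCG lengths are rounded to complete codons).
#' @param probs background base probabilities (A, C, G, T).
#' @param codon_weights optional named sampling weight per sense codon;
#'   default weights each codon by the product of \code{probs} over its
#'   bases (an AT-rich bias).
#' @param spacer_pool integer pool the planted spacers are drawn from
#'   (negative values become overlaps; overlaps are only planted
#'   between consecutive tRNAs).
#' @param minus_frac fraction of genes placed on the minority strand.
#' @param seed integer seed recorded in the spec.
#' @return list of class \code{synth_spec}.
#' @export
synth_spec <- function(n_pcg = 13, n_trna = 22, n_rrna = 2, n_cr = 2,
                       pcg_len = c(216, 1536), trna_len = c(58, 72),
                       rrna_len = c(700, 1100), cr_len = c(280, 640),
                       probs = c(A = .40, C = .12, G = .11, T = .37),
                       codon_weights = NULL,
                       spacer_pool = c(0:20, 25, 41, -1, -3),
                       minus_frac = 7 / 37, seed = 1) {
  probs <- probs / sum(probs)
  if (is.null(codon_weights)) {
    code <- invertebrate_mito_code()
    sense <- names(code$codons)[code$codons != "*"]
    codon_weights <- vapply(sense, function(cd) {
      prod(probs[str_bases(cd)])
    }, numeric(1L))
  }
  structure(list(n_pcg = n_pcg, n_trna = n_trna, n_rrna = n_rrna, n_cr = n_cr,
                 pcg_len = pcg_len, trna_len = trna_len, rrna_len = rrna_len,
                 cr_len = cr_len, probs = probs,
                 codon_weights = codon_weights, spacer_pool = spacer_pool,
                 minus_frac = minus_frac, seed = seed),
            class = "synth_spec")
}

#' Generate a synthetic annotated mitogenome
#'
#' Lays out the planted features around the circle with the planted
#' spacers, fills each with class-appropriate sequence (PCGs get a
#' valid ATN start, codon-bias-sampled body and TAA/TAG stop; planted
#' overlaps are restricted to non-PCG neighbours so codon structure
#' survives), and returns the genome, its annotation and a placement
#' log holding the planted ground truth.
#'
#' @param spec a \code{\link{synth_spec}}; or arguments to build one.
#' @param features optional explicit feature plan: data frame with
#'   columns \code{gene}, \code{strand}, \code{length},
#'   \code{spacer_after} (signed bp to the next feature; the last row's
#'   value closes the circle).  When supplied it overrides the random
#'   layout and genome length is derived from it.
#' @return list with \code{genome} (\code{\link{genome_sequence}}),
#'   \code{annotation} (\code{\link{mito_annotation}}) and \code{log}
#'   (planted spacers, start/stop codons, per-class lengths).
#' @export
synth_mitogenome <- function(spec = synth_spec(), features = NULL) {
  with_seed(spec$seed, {
    if (is.null(features)) features <- .random_feature_plan(spec)
    n <- nrow(features)
    if (any(features$length < 1L)) stop("planted feature length < 1")
    # coordinates from the planted layout
    starts <- integer(n); ends <- integer(n)
    pos <- 1L
    for (i in seq_len(n)) {
      starts[i] <- pos
      ends[i] <- pos + features$length[i] - 1L
      pos <- ends[i] + 1L + features$spacer_after[i]
    }
    if (features$spacer_after[n] < 0L)
      stop("infeasible spec: the wrap spacer (after the last feature) must be >= 0")
    L <- ends[n] + features$spacer_after[n]
    if (any(starts < 1L) || any(ends > L))
      stop("infeasible spec: planted spacers/overlaps do not fit the circle")
    cls <- feature_class_of(features$gene)
    ov <- which(features$spacer_after < 0L)
    if (length(ov)) {
      nxt <- ifelse(ov == n, 1L, ov + 1L)
      if (any(cls[ov] == "PCG" & cls[nxt] == "PCG"))
        stop("infeasible spec: overlap between two PCGs")
    }
    # background, then non-coding features, then PCGs (PCGs win overlaps)
    base <- str_bases(synth_sequence(L, spec$probs, seed = sample.int(2^31 - 1L, 1L))$seq)
    put <- function(s, e, frag) {
      idx <- if (s <= e) s:e else c(s:L, 1:e)
      base[idx] <<- str_bases(frag)
    }
    starts_codons <- stop_codons <- rep(NA_character_, n)
    for (pass in 1:2) for (i in seq_len(n)) {
      is_pcg <- cls[i] == "PCG"
      if ((pass == 1L) == is_pcg) next
      if (is_pcg) {
        sc <- if ("start_codon" %in% names(features)) features$start_codon[i] else NULL
        pc <- if ("stop_codon" %in% names(features)) features$stop_codon[i] else NULL
        if (!is.null(sc) && is.na(sc)) sc <- NULL
        if (!is.null(pc) && is.na(pc)) pc <- NULL
        cds <- .synth_cds(features$length[i], spec$codon_weights, sc, pc)
        r <- start_stop_codons(cds)
        starts_codons[i] <- r$start_codon; stop_codons[i] <- r$stop_codon
        frag <- if (features$strand[i] == "-") revcomp(cds) else cds
        put(starts[i], ends[i], frag)
      }
      # non-PCG features keep the background draw (already in place)
    }
    genome <- genome_sequence(paste(base, collapse = ""), id = "synthetic")
    ann <- mito_annotation(
      data.frame(gene = features$gene, strand = features$strand,
                 start = starts, end = ends,
                 start_codon = starts_codons, stop_codon = stop_codons,
                 stringsAsFactors = FALSE),
      genome_length = L, genome_id = "synthetic")
    list(genome = genome, annotation = ann,
         log = list(features = cbind(features, start = starts, end = ends),
                    spacers = stats::setNames(features$spacer_after, features$gene),
                    start_codons = stats::setNames(starts_codons, features$gene),
                    stop_codons = stats::setNames(stop_codons, features$gene),
                    genome_length = L, seed = spec$seed))
  })
}

# random feature plan honoring a synth_spec
.random_feature_plan <- function(spec) {
  pcg_names <- c(paste0("cox", 1:3), paste0("nad", 1:6), "nad4L", "atp6",
                 "atp8", "cytb")[seq_len(spec$n_pcg)]
  trna_names <- paste0("trn", c("A", "R", "N", "D", "C", "E", "Q", "G", "H",
                                "I", "K", "M", "F", "P", "T", "W", "Y", "V",
                                "L1", "L2", "S1", "S2"))[seq_len(spec$n_trna)]
  rrna_names <- c("rrnS", "rrnL")[seq_len(spec$n_rrna)]
  cr_names <- c("CR1", "CR2")[seq_len(spec$n_cr)]
  gene <- c(pcg_names, trna_names, rrna_names, cr_names)
  len <- c(
    3L * (sample(spec$pcg_len[1]:spec$pcg_len[2], spec$n_pcg, TRUE) %/% 3L),
    sample(spec$trna_len[1]:spec$trna_len[2], spec$n_trna, TRUE),
    sample(spec$rrna_len[1]:spec$rrna_len[2], spec$n_rrna, TRUE),
    sample(spec$cr_len[1]:spec$cr_len[2], spec$n_cr, TRUE))
  cls <- feature_class_of(gene)
  ord <- sample.int(length(gene))
  gene <- gene[ord]; len <- len[ord]; cls <- cls[ord]
  strand <- ifelse(stats::runif(length(gene)) < spec$minus_frac, "-", "+")
  strand[cls == "CR"] <- "+"
  spacer <- sample(spec$spacer_pool, length(gene), TRUE)
  # overlaps only between consecutive tRNAs, and keep them shallow
  nxt_cls <- c(cls[-1L], cls[1L])
  bad <- spacer < 0L & !(cls == "tRNA" & nxt_cls == "tRNA")
  spacer[bad] <- abs(spacer[bad])
  spacer[length(spacer)] <- abs(spacer[length(spacer)])  # wrap spacer >= 0
  data.frame(gene = gene, strand = strand, length = len,
             spacer_after = spacer, stringsAsFactors = FALSE)
}

#' Apply (or sample) rearrangement events with a logged scenario
#'
#' @param ref a \code{\link{gene_order}}.
#' @param events either a list of \code{\link{rearrangement_event}}s to
#'   apply in order, or a single integer: the number of random events
#'   to sample (uniformly over the admissible anchor-fixed events of
#'   the requested kinds, rejecting no-ops).
#' @param seed integer seed (used only when sampling).
#' @param kinds event kinds sampled from when \code{events} is a count.
#' @return list with \code{order} (the rearranged
#'   \code{\link{gene_order}}) and \code{scenario} (the logged
#'   \code{\link{scenario}} from \code{ref} to it).
#' @export
synth_rearranged <- function(ref, events, seed = 1,
                             kinds = c("inversion", "transposition",
                                       "inverse_transposition", "tdrl")) {
  if (is.numeric(events) && length(events) == 1L) {
    pool <- enumerate_events(length(ref$labels), kinds)
    if (length(pool) == 0L) stop("no admissible events for this order size")
    events <- with_seed(seed, {
      picks <- list()
      cur <- .encode(ref, ref$labels)
      for (k in seq_len(events)) {
        repeat {
          e <- pool[[sample.int(length(pool), 1L)]]
          nxt <- .apply_encoded(cur, e)
          if (!identical(nxt, cur)) { cur <- nxt; break }
        }
        picks[[k]] <- e
      }
      picks
    })
  }
  cur <- ref
  for (e in events) cur <- apply_event(cur, e)
  list(order = cur, scenario = scenario(events, ref, cur))
}

#' Synthesize a control region with planted repeats and motifs
#'
#' Builds an AT-rich random background, plants \code{copies} tandem
#' copies of \code{unit} mutated to approximately the requested
#' identity (per-copy point substitutions, no indels), and writes the
#' requested motif strings upstream of the repeat block, each separated
#' by short random spacers.  All placements are reported in the log.
#'
#' @param length total region length in bp.
#' @param unit repeat-unit sequence.
#' @param copies number of tandem copies (>= 2 to be detectable).
#' @param identity target percent identity of copies 2..k to the first
#'   copy (100 = exact).
#' @param motifs character vector of motif strings to plant 5' of the
#'   repeats (e.g. \code{c("TTTTTT", "TATA", "GAT")}).
#' @param seed integer seed.
#' @param probs background base probabilities.
#' @return list with \code{seq} (the region) and \code{log} (motif
#'   positions, repeat starts, realized per-copy identities).
#' @export
synth_control_region <- function(length, unit, copies = 3, identity = 100,
                                 motifs = character(0), seed = 1,
                                 probs = c(A = .34, C = .14, G = .15, T = .37)) {
  unit <- toupper(unit)
  p <- nchar(unit)
  need <- copies * p + sum(nchar(motifs)) + 3L * (length(motifs) + 1L)
  if (need > length)
    stop("infeasible packing: need at least ", need, " bp, have ", length)
  with_seed(seed, {
    b <- str_bases(synth_sequence(length, probs / sum(probs),
                                  seed = sample.int(2^31 - 1L, 1L))$seq)
    pos <- 1L
    motif_at <- integer(0)
    for (m in motifs) {
      b[pos:(pos + nchar(m) - 1L)] <- str_bases(toupper(m))
      motif_at <- c(motif_at, pos)
      pos <- pos + nchar(m) + 3L
    }
    rep_start <- pos + 3L
    starts <- rep_start + p * (seq_len(copies) - 1L)
    ids <- numeric(copies)
    ub <- str_bases(unit)
    for (k in seq_len(copies)) {
      cp <- ub
      if (k > 1L && identity < 100) {
        nmut <- max(0L, round(p * (100 - identity) / 100))
        at <- sample.int(p, min(nmut, p))
        for (a in at)
          cp[a] <- sample(setdiff(c("A", "C", "G", "T"), cp[a]), 1L)
      }
      ids[k] <- 100 * mean(cp == ub)
      b[starts[k]:(starts[k] + p - 1L)] <- cp
    }
    list(seq = paste(b, collapse = ""),
         log = list(motifs = stats::setNames(motif_at, motifs),
                    repeat_starts = starts, unit = unit, period = p,
                    copies = copies, realized_identity = ids, seed = seed))
  })
}
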