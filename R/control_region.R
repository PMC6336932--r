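#' Tandem-repeat discovery in a control region
#'
#' Scans for families of two or more approximate tandem copies of a
#' repeat unit.  For every candidate period the sequence is scanned
#' left to right; a family grows by matching successive windows against
#' the first unit (per-position identity, no indels) and copies may be
#' separated by a short gap (near-tandem, at most a quarter of the unit
#' length).  Every phase and period is scanned; the overlapping reports
#' this produces are then reduced greedily: families are ranked by total
#' span (descending), then mean copy identity (descending), then period
#' and start, and a family is kept only if less than half of its span
#' is covered by an already-kept family.
#'
#' @param seq control-region sequence.
#' @param min_period minimum unit length in bp (default 20).
#' @param min_copies minimum copies to report a family (default 2).
#' @param min_identity minimum percent identity of each copy to the
#'   first unit (default 80).
#' @return data frame of class \code{repeat_families} with one row per
#'   family: \code{period}, \code{copies}, \code{start}, \code{end},
#'   \code{span}, \code{mean_identity} (mean identity of copies 2..k to
#'   the first unit), \code{starts} (comma-separated copy starts).
#'   Empty (0 rows) when no family qualifies or the sequence is shorter
#'   than twice \code{min_period}.
#' @export
tandem_repeats <- function(seq, min_period = 20, min_copies = 2,
                           min_identity = 80) {
  s <- toupper(seq)
  L <- nchar(s)
  fams <- list()
  if (L >= 2L * min_period) {
    b <- str_bases(s)
    for (p in seq.int(min_period, L %/% 2L)) {
      max_gap <- p %/% 4L
      i <- 1L
      while (i + 2L * p - 1L <= L) {
        unit <- b[i:(i + p - 1L)]
        starts <- i
        ids <- numeric(0)
        pos <- i + p
        repeat {
          found <- FALSE
          for (g in 0:max_gap) {
            s2 <- pos + g
            if (s2 + p - 1L > L) break
            idw <- 100 * mean(b[s2:(s2 + p - 1L)] == unit)
            if (idw >= min_identity) {
              starts <- c(starts, s2); ids <- c(ids, idw)
              pos <- s2 + p
              found <- TRUE
              break
            }
          }
          if (!found) break
        }
        if (length(starts) >= min_copies) {
          fams[[length(fams) + 1L]] <- data.frame(
            period = p, copies = length(starts), start = starts[1L],
            end = starts[length(starts)] + p - 1L,
            span = starts[length(starts)] + p - starts[1L],
            mean_identity = mean(ids),
            starts = paste(starts, collapse = ","),
            stringsAsFactors = FALSE)
        }
        i <- i + 1L  # every phase is scanned; ranking picks the best
      }
    }
  }
  if (length(fams) == 0L) {
    out <- data.frame(period = integer(0), copies = integer(0),
                      start = integer(0), end = integer(0), span = integer(0),
                      mean_identity = numeric(0), starts = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("repeat_families", "data.frame")
    return(out)
  }
  all <- do.call(rbind, fams)
  all <- all[order(-all$span, -all$mean_identity, all$period, all$start), ]
  keep <- logical(nrow(all))
  cover <- integer(0)  # positions covered by kept families
  for (r in seq_len(nrow(all))) {
    pos <- all$start[r]:all$end[r]
    if (sum(pos %in% cover) < length(pos) / 2) {
      keep[r] <- TRUE
      cover <- union(cover, pos)
    }
  }
  out <- all[keep, ]
  rownames(out) <- NULL
  class(out) <- c("repeat_families", "data.frame")
  out
}

#' Global pairwise identity of two sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1,
#' gap -2 (end gaps penalized like any other), followed by identity =
#' matches / alignment columns * 100.  Traceback prefers diagonal over
#' vertical over horizontal moves, making the reported alignment
#' deterministic.
#'
#' @param a,b nucleotide strings.
#' @return percent identity (numeric scalar) with attributes
#'   \code{matches} and \code{columns}.
#' @examples
#' pairwise_identity("ACGTACGT", "ACGACGT")  # 87.5
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  x <- str_bases(toupper(a)); y <- str_bases(toupper(b))
  n <- length(x); m <- length(y)
  gap <- -2L
  S <- matrix(0L, n + 1L, m + 1L)
  S[, 1L] <- gap * 0:n
  S[1L, ] <- gap * 0:m
  for (i in seq_len(n)) {
    sub <- ifelse(x[i] == y, 1L, -1L)
    row_prev <- S[i, ]
    row_cur <- S[i + 1L, ]
    for (j in seq_len(m)) {
      row_cur[j + 1L] <- max(row_prev[j] + sub[j],
                             row_prev[j + 1L] + gap,
                             row_cur[j] + gap)
    }
    S[i + 1L, ] <- row_cur
  }
  # traceback: diagonal > up (gap in b) > left (gap in a)
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0L || j > 0L) {
    cols <- cols + 1L
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] + (if (x[i] == y[j]) 1L else -1L)) {
      if (x[i] == y[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  out <- 100 * matches / cols
  attr(out, "matches") <- matches
  attr(out, "columns") <- cols
  out
}

#' Scan a control region for conserved motifs
#'
#' Reports the motif inventory typical of insect mitochondrial control
#' regions: maximal poly-T runs (flagged as 5' when starting within the
#' first 10\% of the region), TA(A)n-like stretches (maximal
#' concatenations of at least \code{taa_min_units} units matching
#' \code{TA+}), and exact TATA and GAT hits.
#'
#' @param seq control-region sequence.
#' @param polyT_min minimum poly-T run length (default 5).
#' @param taa_min_units minimum TA+ units in a TA(A)n stretch
#'   (default 3).
#' @return data frame with columns \code{motif} (\code{polyT},
#'   \code{TAAn}, \code{TATA}, \code{GAT}), \code{start}, \code{length},
#'   \code{five_prime} (polyT only, NA otherwise).
#' @export
motif_scan <- function(seq, polyT_min = 5, taa_min_units = 3) {
  s <- toupper(seq)
  if (nchar(s) == 0L) stop("empty sequence")
  hits <- list()
  add <- function(motif, start, len, five = NA) {
    if (length(start) == 0L) return()
    hits[[length(hits) + 1L]] <<- data.frame(
      motif = motif, start = start, length = len, five_prime = five,
      stringsAsFactors = FALSE)
  }
  grab <- function(pattern) {
    m <- gregexpr(pattern, s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) list(start = integer(0), len = integer(0))
    else list(start = as.integer(m), len = attr(m, "match.length"))
  }
  pt <- grab(sprintf("T{%d,}", polyT_min))
  add("polyT", pt$start, pt$len, pt$start <= max(1L, nchar(s) %/% 10L))
  ta <- grab(sprintf("(?:TA+){%d,}", taa_min_units))
  add("TAAn", ta$start, ta$len)
  tata <- grab("(?=TATA)")
  add("TATA", tata$start, rep(4L, length(tata$start)))
  gat <- grab("GAT")
  add("GAT", gat$start, gat$len)
  if (length(hits) == 0L)
    return(data.frame(motif = character(0), start = integer(0),
                      length = integer(0), five_prime = logical(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

# TRUE where bases a and b are Watson-Crick complementary
.wc_comp <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
  (a == "G" & b == "C") | (a == "C" & b == "G")
}

#' Combinatorial stem-loop (hairpin) search
#'
#' Finds all maximal stems: pairs of reverse-complementary arms
#' separated by a loop of 3 to \code{max_loop} nt.  A stem is maximal
#' when it can be extended neither outward (flanking bases pair) nor
#' inward (next bases pair and the loop would stay at least 3 nt).
#' Purely combinatorial; no thermodynamics.
#'
#' @param seq nucleotide string.
#' @param min_stem minimum stem length in bp (default 4).
#' @param max_loop maximum loop length in nt (default 20).
#' @return data frame sorted by stem length (descending) then position:
#'   \code{arm1_start}, \code{arm1_end}, \code{arm2_start},
#'   \code{arm2_end}, \code{stem}, \code{loop}.  Overlapping hairpins
#'   are all reported.
#' @export
hairpin_scan <- function(seq, min_stem = 4, max_loop = 20) {
  s <- toupper(seq)
  if (nchar(s) == 0L) stop("empty sequence")
  b <- str_bases(s)
  L <- length(b)
  res <- list()
  min_span <- 2L * min_stem + 3L
  for (i in seq_len(L)) {
    if (i + min_span - 1L > L) break
    for (q in seq.int(i + min_span - 1L, L)) {
      if (!.wc_comp(b[i], b[q])) next
      # outer-maximality: flanks must not pair
      if (i > 1L && q < L && .wc_comp(b[i - 1L], b[q + 1L])) next
      span <- q - i + 1L
      kmax <- (span - 3L) %/% 2L  # keep loop >= 3
      k <- 1L
      while (k < kmax && .wc_comp(b[i + k], b[q - k])) k <- k + 1L
      loop <- span - 2L * k
      if (k >= min_stem && loop <= max_loop)
        res[[length(res) + 1L]] <- c(i, i + k - 1L, q - k + 1L, q, k, loop)
    }
  }
  if (length(res) == 0L)
    return(data.frame(arm1_start = integer(0), arm1_end = integer(0),
                      arm2_start = integer(0), arm2_end = integer(0),
                      stem = integer(0), loop = integer(0)))
  m <- do.call(rbind, res)
  out <- data.frame(arm1_start = m[, 1], arm1_end = m[, 2],
                    arm2_start = m[, 3], arm2_end = m[, 4],
                    stem = m[, 5], loop = m[, 6])
  out <- out[order(-out$stem, out$arm1_start, out$arm2_start), ]
  rownames(out) <- NULL
  out
}

#' Full control-region report
#'
#' Bundles \code{\link{tandem_repeats}}, \code{\link{motif_scan}} and
#' \code{\link{hairpin_scan}} for one control-region sequence.
#'
#' @param seq control-region sequence.
#' @param ... threshold arguments forwarded to the scanners
#'   (\code{min_period}, \code{min_copies}, \code{min_identity},
#'   \code{polyT_min}, \code{taa_min_units}, \code{min_stem},
#'   \code{max_loop}).
#' @return list with \code{repeats}, \code{motifs}, \code{hairpins}.
#' @export
control_region_report <- function(seq, ...) {
  args <- list(...)
  pick <- function(f, names) do.call(f, c(list(seq), args[intersect(names(args), names)]))
  list(
    repeats = pick(tandem_repeats, c("min_period", "min_copies", "min_identity")),
    motifs = pick(motif_scan, c("polyT_min", "taa_min_units")),
    hairpins = pick(hairpin_scan, c("min_stem", "max_loop"))
  )
}
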