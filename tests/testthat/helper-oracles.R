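# Independent brute-force oracles used to cross-check the package's
# algorithms on small instances.  These deliberately re-derive results
# from first principles rather than calling the implementation paths
# they validate.

# --- signed circular adjacency set, as a sorted character vector ----------
# An adjacency between signed genes x and y is the unordered junction
# {(x,y), (-y,-x)}; we store the lexicographically smaller rendering.
oracle_adjacencies <- function(labels, signs) {
  n <- length(labels)
  sg <- function(i) paste0(ifelse(signs[i] < 0, "-", ""), labels[i])
  ng <- function(s) if (startsWith(s, "-")) substring(s, 2) else paste0("-", s)
  keys <- character(n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- paste(sg(i), sg(j), sep = ">")
    b <- paste(ng(sg(j)), ng(sg(i)), sep = ">")
    keys[i] <- min(a, b)
  }
  sort(keys)
}

oracle_breakpoint <- function(o1, o2) {
  k1 <- oracle_adjacencies(o1$labels, o1$signs)
  k2 <- oracle_adjacencies(o2$labels, o2$signs)
  length(k1) - length(intersect(k1, k2))
}

# --- O(n^3) common-interval enumerator ------------------------------------
# windows of a (linearized) checked for contiguity in b by recomputing
# min/max positions from scratch for every window
oracle_common_intervals <- function(a_labels, b_labels) {
  n <- length(a_labels)
  posb <- match(a_labels, b_labels)
  out <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    size <- j - i + 1L
    if (size < 2L || size > n - 1L || j > n) next
    p <- posb[i:j]
    if (max(p) - min(p) == size - 1L) out <- out + 1L
  }
  out
}

# --- exponential global-alignment score oracle ----------------------------
# maximal score under match +1 / mismatch -1 / gap -2, tiny strings only
oracle_align_score <- function(a, b) {
  if (nchar(a) == 0) return(-2L * nchar(b))
  if (nchar(b) == 0) return(-2L * nchar(a))
  a1 <- substr(a, 1, 1); b1 <- substr(b, 1, 1)
  ra <- substr(a, 2, nchar(a)); rb <- substr(b, 2, nchar(b))
  max(oracle_align_score(ra, rb) + (if (a1 == b1) 1L else -1L),
      oracle_align_score(ra, b) - 2L,
      oracle_align_score(a, rb) - 2L)
}

# --- exhaustive maximal-hairpin enumerator --------------------------------
oracle_hairpins <- function(seq, min_stem = 4, max_loop = 20) {
  b <- strsplit(toupper(seq), "")[[1]]
  L <- length(b)
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  pairs <- function(i, j) !is.na(comp[b[i]]) && comp[b[i]] == b[j]
  res <- list()
  for (i in seq_len(L)) for (k in seq.int(min_stem, L)) {
    for (loop in 3:max_loop) {
      j <- i + k + loop          # arm2 start
      e2 <- j + k - 1L
      if (e2 > L) next
      ok <- all(vapply(0:(k - 1L), function(t) pairs(i + t, e2 - t), logical(1)))
      if (!ok) next
      # maximality: no outward extension, no inward extension with loop >= 3
      outward <- i > 1L && e2 < L && pairs(i - 1L, e2 + 1L)
      inward <- loop >= 5L && pairs(i + k, j - 1L)
      if (!outward && !inward)
        res[[length(res) + 1L]] <- c(i, i + k - 1L, j, e2, k, loop)
    }
  }
  if (!length(res)) return(matrix(integer(0), 0, 6))
  m <- unique(do.call(rbind, res))
  m[order(m[, 1], m[, 3], m[, 5]), , drop = FALSE]
}

# --- shortest inversion-only scenario by breadth-first search -------------
# operates on plain signed integer vectors; position 1 held fixed
oracle_min_inversions <- function(sv, tv, max_d = 2) {
  n <- length(sv)
  key <- function(v) paste(v, collapse = ",")
  frontier <- list(sv)
  seen <- new.env()
  assign(key(sv), TRUE, envir = seen)
  if (identical(sv, tv)) return(0L)
  for (d in seq_len(max_d)) {
    nxt <- list()
    for (v in frontier) for (i in 2:n) for (j in i:n) {
      w <- v
      w[i:j] <- -rev(w[i:j])
      if (identical(w, tv)) return(d)
      k <- key(w)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        nxt[[length(nxt) + 1L]] <- w
      }
    }
    frontier <- nxt
  }
  NA_integer_
}

# --- shared tiny fixtures -------------------------------------------------
toy_annotation <- function() {
  # 60 bp circle tiled by a PCG, a tRNA, a CR and spacers/overlap
  mito_annotation(data.frame(
    gene = c("cox1", "trnW", "CR1", "nad2"),
    strand = c("+", "-", "+", "+"),
    start = c(1, 22, 31, 45),
    end = c(18, 30, 46, 59),
    stringsAsFactors = FALSE
  ), genome_length = 60, genome_id = "toy")
}
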