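# signed-adjacency machinery -----------------------------------------------

# signed string form of gene at position i, e.g. "cox1" / "-trnQ"
.sg <- function(order, i) {
  paste0(ifelse(order$signs[i] < 0L, "-", ""), order$labels[i])
}

.sg_neg <- function(x) ifelse(startsWith(x, "-"), substring(x, 2L), paste0("-", x))

# canonical keys of the n oriented circular adjacencies of an order;
# an adjacency (x, y) and its reflection (-y, -x) share one key
adjacency_keys <- function(order) {
  n <- length(order$labels)
  x <- .sg(order, seq_len(n))
  y <- x[c(seq_len(n)[-1L], 1L)]
  fwd <- paste(x, y, sep = ">")
  rev <- paste(.sg_neg(y), .sg_neg(x), sep = ">")
  ifelse(fwd <= rev, fwd, rev)
}

.check_same_genes <- function(a, b) {
  miss <- setdiff(a$labels, b$labels)
  extra <- setdiff(b$labels, a$labels)
  if (length(miss) || length(extra))
    stop("gene sets differ: missing [",
         paste(miss, collapse = ", "), "], extra [",
         paste(extra, collapse = ", "), "]")
}

#' Is gene b immediately downstream of gene a?
#'
#' Orientation-sensitive circular adjacency test: TRUE when reading the
#' majority-strand direction gene \code{b} directly follows \code{a}
#' with both in their + orientation, or the reflected adjacency
#' (-b, -a) is present (the same physical junction read on the other
#' strand).
#'
#' @param order a \code{\link{gene_order}}.
#' @param a,b gene labels.
#' @return logical.
#' @export
adjacency_present <- function(order, a, b) {
  if (!(a %in% order$labels) || !(b %in% order$labels))
    stop("gene(s) not in order: ",
         paste(setdiff(c(a, b), order$labels), collapse = ", "))
  n <- length(order$labels)
  if (n < 2L) return(FALSE)
  key <- paste(a, b, sep = ">")
  refl <- paste(.sg_neg(b), .sg_neg(a), sep = ">")
  min(key, refl) %in% adjacency_keys(order)
}

#' Genes whose orientation differs between two orders
#'
#' Both orders are re-anchored at the same gene (the first gene of
#' \code{order}, with positive sign) before signs are compared, so the
#' result is independent of how either order was linearized.
#'
#' @param order,ref \code{\link{gene_order}} objects over the same gene
#'   set.
#' @return sorted character vector of genes with differing sign.
#' @export
orientation_changes <- function(order, ref) {
  .check_same_genes(order, ref)
  ref2 <- gene_order(ref$labels, ref$signs, anchor = order$labels[1L])
  s1 <- stats::setNames(order$signs, order$labels)
  s2 <- stats::setNames(ref2$signs, ref2$labels)
  sort(names(s1)[s1 != s2[names(s1)]])
}

#' Breakpoint distance between signed circular gene orders
#'
#' The number of oriented adjacencies of \code{a} (including the
#' closing circular adjacency) that are absent from \code{b}; an
#' adjacency and its reflection count as the same junction.  Zero for
#' equal orders and invariant under rotation and reflection.
#'
#' @param a,b \code{\link{gene_order}} objects over the same gene set.
#' @return integer count in [0, n].
#' @export
breakpoint_distance <- function(a, b) {
  .check_same_genes(a, b)
  ka <- adjacency_keys(a)
  kb <- adjacency_keys(b)
  length(ka) - sum(ka %in% kb)
}

#' Common intervals of two gene orders
#'
#' A common interval is a set of genes occupying contiguous positions
#' (irrespective of internal order or orientation) in both orders once
#' both are linearized at the same anchor (the first gene of \code{a}).
#' All intervals of size 2 to n-1 are reported.
#'
#' @param a,b \code{\link{gene_order}} objects over the same gene set.
#' @return data frame sorted by size then position in \code{a}:
#'   \code{size}, \code{start_a} (window start in the linearized
#'   \code{a}), \code{genes} (comma-separated, in \code{a}'s order).
#' @export
common_intervals <- function(a, b) {
  .check_same_genes(a, b)
  b2 <- gene_order(b$labels, b$signs, anchor = a$labels[1L])
  n <- length(a$labels)
  posb <- match(a$labels, b2$labels)
  out <- list()
  for (i in seq_len(n - 1L)) {
    mn <- posb[i]; mx <- posb[i]
    jmax <- min(n, i + n - 2L)  # size capped at n - 1
    for (j in seq.int(i + 1L, length.out = max(0L, jmax - i))) {
      p <- posb[j]
      if (p < mn) mn <- p
      if (p > mx) mx <- p
      if (mx - mn == j - i)
        out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (length(out) == 0L)
    return(data.frame(size = integer(0), start_a = integer(0),
                      genes = character(0), stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  res <- data.frame(size = m[, 2] - m[, 1] + 1L, start_a = m[, 1],
                    genes = vapply(seq_len(nrow(m)), function(r)
                      paste(a$labels[m[r, 1]:m[r, 2]], collapse = ","),
                      character(1L)),
                    stringsAsFactors = FALSE)
  res <- res[order(res$size, res$start_a), ]
  rownames(res) <- NULL
  res
}
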