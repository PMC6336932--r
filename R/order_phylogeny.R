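#' Breakpoint-distance matrix across gene orders
#'
#' Pairwise \code{\link{breakpoint_distance}} over a set of signed
#' circular gene orders with identical gene content.
#'
#' @param orders named list of \code{\link{gene_order}} objects (at
#'   least 3; names become taxon labels).
#' @return symmetric numeric matrix with zero diagonal and taxon
#'   dimnames.
#' @export
distance_matrix <- function(orders) {
  k <- length(orders)
  if (k < 3L) stop("need at least 3 gene orders")
  labs <- names(orders)
  if (is.null(labs) || any(labs == ""))
    labs <- paste0("taxon", seq_len(k))
  d <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    dij <- tryCatch(breakpoint_distance(orders[[i]], orders[[j]]),
                    error = function(e)
                      stop("gene-set mismatch between '", labs[i], "' and '",
                           labs[j], "': ", conditionMessage(e)))
    d[i, j] <- dij; d[j, i] <- dij
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbor joining, implemented directly: at each
#' step the pair (i, j) minimizing the Q criterion
#' Q(i, j) = (r - 2) d(i, j) - R_i - R_j (with R the row sums and r the
#' number of active clusters) is joined; ties are broken by the
#' smallest (row, column) index pair in the current matrix.  Branch
#' lengths follow the standard formulas; negative estimates are clamped
#' to zero and flagged.  The last three clusters are joined in an
#' unrooted trifurcation.
#'
#' @param d symmetric numeric matrix with zero diagonal and labeled
#'   dimnames (from \code{\link{distance_matrix}} or any distance).
#' @return an unrooted tree of class \code{phylo} (ape-compatible) with
#'   attribute \code{negative_branches} giving how many branch-length
#'   estimates were clamped to zero.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be a square matrix")
  if (max(abs(d - t(d))) > 1e-8) stop("d must be symmetric")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))

  n_nodes <- 2L * n - 2L             # tips + internal nodes (unrooted)
  edge <- matrix(0L, 0L, 2L)
  elen <- numeric(0)
  clamped <- 0L
  add_edge <- function(parent, child, len) {
    if (len < 0) { clamped <<- clamped + 1L; len <- 0 }
    edge <<- rbind(edge, c(parent, child))
    elen <<- c(elen, len)
  }

  active <- seq_len(n)               # node ids of active clusters
  D <- d
  next_node <- 2L * n - 2L           # internal ids assigned downward
  # ape convention: root/internal ids start at n + 1; we assign the
  # final trifurcation n + 1, so earlier joins get the larger ids
  while (length(active) > 3L) {
    r <- length(active)
    R <- rowSums(D)
    q_best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(r - 1L)) for (j in (i + 1L):r) {
      q <- (r - 2) * D[i, j] - R[i] - R[j]
      if (q < q_best - 1e-12) { q_best <- q; bi <- i; bj <- j }
    }
    vi <- D[bi, bj] / 2 + (R[bi] - R[bj]) / (2 * (r - 2))
    vj <- D[bi, bj] - vi
    node <- next_node; next_node <- next_node - 1L
    add_edge(node, active[bi], vi)
    add_edge(node, active[bj], vj)
    newd <- (D[bi, ] + D[bj, ] - D[bi, bj]) / 2
    keep <- setdiff(seq_len(r), c(bi, bj))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    active <- c(active[keep], node)
  }
  # final unrooted trifurcation
  center <- n + 1L
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  add_edge(center, active[1L], v1)
  add_edge(center, active[2L], v2)
  add_edge(center, active[3L], v3)

  tree <- structure(list(edge = edge, edge.length = elen,
                         tip.label = labs, Nnode = n - 2L),
                    class = "phylo", order = NULL)
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "negative_branches") <- clamped
  tree
}

#' Write / read Newick
#'
#' Thin wrappers over the standard Newick serialization, with branch
#' lengths kept at 6 significant digits on output.
#'
#' @param tree a \code{phylo} tree.
#' @param path optional output file; when NULL the Newick string is
#'   returned.
#' @return \code{write_newick}: the Newick string (invisibly when
#'   written to a file); \code{read_newick}: a \code{phylo}.
#' @export
write_newick <- function(tree, path = NULL) {
  t2 <- tree
  t2$edge.length <- signif(t2$edge.length, 6)
  txt <- ape::write.tree(t2)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname write_newick
#' @param x Newick string or path to a Newick file.
#' @export
read_newick <- function(x) {
  if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
}

#' Gene-order phylogeny in one step
#'
#' Breakpoint-distance matrix plus neighbor joining.
#'
#' @param orders named list of \code{\link{gene_order}} objects.
#' @return list with \code{distances} (matrix) and \code{tree}
#'   (\code{phylo}).
#' @export
gene_order_phylogeny <- function(orders) {
  d <- distance_matrix(orders)
  list(distances = d, tree = neighbor_joining(d))
}
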