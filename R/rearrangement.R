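#' Construct a rearrangement event
#'
#' Events act on the linear representation of a gene order (positions
#' 1..n of the linearized circle):
#' \describe{
#'   \item{inversion}{block [i..j] is reversed and all its signs flip.}
#'   \item{transposition}{block [i..j] is excised unchanged and
#'     reinserted so that it starts at position \code{to} of the
#'     resulting order.}
#'   \item{inverse_transposition}{as transposition, but the block is
#'     reinserted reversed with signs flipped.}
#'   \item{tdrl}{tandem duplication-random loss over span [i..j]: the
#'     span is duplicated in tandem and one copy of each gene is lost;
#'     genes with \code{keep = TRUE} survive in the first copy, the
#'     rest in the second, so the span becomes
#'     span[keep] followed by span[!keep], signs unchanged.}
#' }
#'
#' @param kind one of \code{"inversion"}, \code{"transposition"},
#'   \code{"inverse_transposition"}, \code{"tdrl"}.
#' @param i,j 1-based block/span bounds, \code{i <= j}.
#' @param to target start position of the moved block in the resulting
#'   order (transpositions only).
#' @param keep logical vector of length \code{j - i + 1} (tdrl only):
#'   the keep/lose bipartition of the duplicated span.
#' @return object of class \code{rearrangement_event}.
#' @export
rearrangement_event <- function(kind, i, j, to = NULL, keep = NULL) {
  kind <- match.arg(kind, c("inversion", "transposition",
                            "inverse_transposition", "tdrl"))
  i <- as.integer(i); j <- as.integer(j)
  if (i < 1L || j < i) stop("invalid block [", i, "..", j, "]")
  if (kind %in% c("transposition", "inverse_transposition")) {
    if (is.null(to)) stop(kind, " requires an insertion point 'to'")
    to <- as.integer(to)
  }
  if (kind == "tdrl") {
    if (is.null(keep) || length(keep) != j - i + 1L || !is.logical(keep))
      stop("tdrl requires a logical 'keep' of the span length")
  }
  structure(list(kind = kind, i = i, j = j, to = to, keep = keep),
            class = "rearrangement_event")
}

#' @export
print.rearrangement_event <- function(x, ...) {
  extra <- switch(x$kind,
    transposition = ,
    inverse_transposition = sprintf(" -> %d", x$to),
    tdrl = sprintf(" keep1={%s}", paste(which(x$keep), collapse = ",")),
    "")
  cat(sprintf("<event> %s [%d..%d]%s\n", x$kind, x$i, x$j, extra))
  invisible(x)
}

#' Apply a rearrangement event to a gene order
#'
#' The event acts on the linear positions of the order's canonical
#' representation; the result is re-canonicalized (rotated/reflected to
#' the same anchor) so equal circular orders stay identical.
#'
#' @param order a \code{\link{gene_order}}.
#' @param e a \code{\link{rearrangement_event}}.
#' @return the rearranged \code{\link{gene_order}}.
#' @examples
#' o <- gene_order(as.character(1:4))
#' format_gene_order(apply_event(o, rearrangement_event("inversion", 2, 3)))
#' @export
apply_event <- function(order, e) {
  n <- length(order$labels)
  if (e$j > n) stop("block [", e$i, "..", e$j, "] outside order of length ", n)
  lab <- order$labels; sgn <- order$signs
  blk <- e$i:e$j
  if (e$kind == "inversion") {
    lab[blk] <- rev(lab[blk])
    sgn[blk] <- -rev(sgn[blk])
  } else if (e$kind %in% c("transposition", "inverse_transposition")) {
    len <- length(blk)
    if (e$to < 1L || e$to > n - len + 1L)
      stop("insertion point ", e$to, " invalid for block of length ", len)
    bl <- lab[blk]; bs <- sgn[blk]
    if (e$kind == "inverse_transposition") { bl <- rev(bl); bs <- -rev(bs) }
    rl <- lab[-blk]; rs <- sgn[-blk]
    at <- e$to - 1L
    lab <- append(rl, bl, after = at)
    sgn <- append(rs, bs, after = at)
  } else {  # tdrl
    kp <- e$keep
    lab[blk] <- c(lab[blk][kp], lab[blk][!kp])
    sgn[blk] <- c(sgn[blk][kp], sgn[blk][!kp])
  }
  anchor <- if (order$anchor %in% lab) order$anchor else lab[1L]
  gene_order(lab, sgn, anchor = anchor)
}

#' Construct / replay a rearrangement scenario
#'
#' A scenario is an ordered list of events transforming a source order
#' into a target order.  \code{replay_scenario} folds
#' \code{\link{apply_event}} over the events and checks the result
#' against the recorded target.
#'
#' @param events list of \code{\link{rearrangement_event}}s.
#' @param source,target \code{\link{gene_order}} objects.
#' @return \code{scenario}: list with \code{events}, \code{source},
#'   \code{target}.
#' @export
scenario <- function(events, source, target) {
  structure(list(events = events, source = source, target = target),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %d event(s)\n", length(x$events)))
  for (e in x$events) print(e)
  invisible(x)
}

#' @rdname scenario
#' @param scen a \code{scenario}.
#' @return \code{replay_scenario}: the final \code{\link{gene_order}},
#'   with attribute \code{valid} (TRUE when it equals the recorded
#'   target).
#' @export
replay_scenario <- function(scen) {
  cur <- scen$source
  for (e in scen$events) cur <- apply_event(cur, e)
  attr(cur, "valid") <- gene_order_equal(cur, scen$target)
  cur
}

# ---- event enumeration (anchor held fixed at position 1) ------------------

# all events over positions 2..n that change the order, as parameter lists
enumerate_events <- function(n, kinds = c("inversion", "transposition",
                                          "inverse_transposition", "tdrl")) {
  ev <- list()
  if (n < 3L) return(ev)
  if ("inversion" %in% kinds) {
    for (i in 2:n) for (j in i:n)
      ev[[length(ev) + 1L]] <- rearrangement_event("inversion", i, j)
  }
  for (kind in intersect(c("transposition", "inverse_transposition"), kinds)) {
    for (i in 2:n) for (j in i:n) {
      len <- j - i + 1L
      if (len >= n - 1L) next  # nothing to move past
      for (k in 2:(n - len + 1L)) {
        if (k == i) next  # identity move / plain inversion
        ev[[length(ev) + 1L]] <- rearrangement_event(kind, i, j, to = k)
      }
    }
  }
  if ("tdrl" %in% kinds) {
    for (i in 2:(n - 1L)) for (j in (i + 1L):n) {
      len <- j - i + 1L
      for (mask in 1:(2^len - 2L)) {
        kp <- as.logical(bitwAnd(mask, 2^(0:(len - 1L))) > 0L)
        # skip identity bipartitions (all kept genes form a prefix)
        if (all(diff(kp) <= 0L)) next
        ev[[length(ev) + 1L]] <- rearrangement_event("tdrl", i, j, keep = kp)
      }
    }
  }
  ev
}

# signed-integer encoding of an order relative to a reference label set
.encode <- function(order, labels) {
  order$signs * match(order$labels, labels)
}

# events (anchor fixed) turning signed vector sv into tv in one step;
# returns a list of rearrangement_events (possibly several)
one_event_between <- function(sv, tv, kinds = c("inversion", "transposition",
                                                "inverse_transposition",
                                                "tdrl")) {
  found <- list()
  if (identical(sv, tv)) return(found)
  d <- which(sv != tv)
  l <- d[1L]; r <- d[length(d)]
  if (l == 1L) return(found)  # the anchor never moves
  sw <- sv[l:r]; tw <- tv[l:r]
  wl <- r - l + 1L
  if ("inversion" %in% kinds && identical(tw, -rev(sw)))
    found[[length(found) + 1L]] <- rearrangement_event("inversion", l, r)
  if (any(c("transposition", "inverse_transposition") %in% kinds) && wl >= 2L) {
    for (m in 1:(wl - 1L)) {
      A <- sw[1:m]; B <- sw[(m + 1L):wl]
      if ("transposition" %in% kinds && identical(tw, c(B, A))) {
        # A moved to the end of the window (or equivalently B to its start)
        found[[length(found) + 1L]] <-
          rearrangement_event("transposition", l, l + m - 1L,
                              to = r - m + 1L)
      }
      if ("inverse_transposition" %in% kinds) {
        if (identical(tw, c(B, -rev(A))))
          found[[length(found) + 1L]] <-
            rearrangement_event("inverse_transposition", l, l + m - 1L,
                                to = r - m + 1L)
        if (identical(tw, c(-rev(B), A)))
          found[[length(found) + 1L]] <-
            rearrangement_event("inverse_transposition", l + m, r, to = l)
      }
    }
  }
  if ("tdrl" %in% kinds && wl >= 2L) {
    for (m in 0:wl) {
      p1 <- if (m >= 1L) tw[1:m] else integer(0)
      p2 <- if (m < wl) tw[(m + 1L):wl] else integer(0)
      i1 <- match(p1, sw); i2 <- match(p2, sw)
      if (anyNA(i1) || anyNA(i2)) next
      if (is.unsorted(i1, strictly = TRUE) || is.unsorted(i2, strictly = TRUE))
        next
      kp <- logical(wl); kp[i1] <- TRUE
      if (all(diff(kp) <= 0L)) next  # identity bipartition
      found[[length(found) + 1L]] <-
        rearrangement_event("tdrl", l, r, keep = kp)
    }
  }
  found
}

#' Infer minimum-length rearrangement scenarios
#'
#' Exact search for the shortest event sequences transforming
#' \code{ref} into \code{target}.  Both orders are put on the same
#' anchor (the first gene of \code{ref}); the search holds that anchor
#' fixed, which loses no generality on a circular order because every
#' rearrangement has an anchor-avoiding representation up to circular
#' equivalence.  Depths 0 and 1 are solved analytically; at greater
#' depth the search enumerates leading events breadth-first and solves
#' the final step analytically.  Intended for small orders (n of about
#' 15 or less) and scenarios of at most 4 events: the event space grows
#' exponentially in both n and depth.
#'
#' @param ref,target \code{\link{gene_order}} objects over the same
#'   gene set.
#' @param max_events maximum scenario length to consider (default 4).
#' @param kinds event kinds admitted into scenarios.
#' @param max_scenarios cap on the number of alternative minimal
#'   scenarios collected (default 100; the result carries attribute
#'   \code{truncated} if the cap was hit).
#' @return list of \code{\link{scenario}} objects, all of the same
#'   minimal length; empty list with attribute \code{unsolved = TRUE}
#'   when no scenario of at most \code{max_events} events exists.
#'   Equal orders yield one empty scenario.
#' @export
infer_scenario <- function(ref, target, max_events = 4,
                           kinds = c("inversion", "transposition",
                                     "inverse_transposition", "tdrl"),
                           max_scenarios = 100) {
  .check_same_genes(ref, target)
  t2 <- gene_order(target$labels, target$signs, anchor = ref$labels[1L])
  sv <- .encode(ref, ref$labels)
  tv <- .encode(t2, ref$labels)
  n <- length(sv)
  truncated <- FALSE

  if (identical(sv, tv))
    return(list(scenario(list(), ref, target)))

  solve_d <- function(cur, d) {
    # returns list of event lists of exactly length d from cur to tv
    if (d == 1L) {
      evs <- one_event_between(cur, tv, kinds)
      return(lapply(evs, list))
    }
    out <- list()
    for (e in enumerate_events(n, kinds)) {
      nxt <- .apply_encoded(cur, e)
      if (identical(nxt, cur)) next
      subs <- solve_d(nxt, d - 1L)
      for (s in subs) {
        out[[length(out) + 1L]] <- c(list(e), s)
        if (length(out) >= max_scenarios) { truncated <<- TRUE; return(out) }
      }
    }
    out
  }

  for (d in seq_len(max_events)) {
    paths <- solve_d(sv, d)
    if (length(paths)) {
      scens <- lapply(paths, function(p) scenario(p, ref, target))
      # order scenarios by their event-kind preference for stable reporting
      pref <- c(inversion = 1L, transposition = 2L,
                inverse_transposition = 3L, tdrl = 4L)
      key <- vapply(scens, function(s)
        paste(sprintf("%d:%03d:%03d", pref[vapply(s$events, `[[`, "", "kind")],
                      vapply(s$events, `[[`, 1L, "i"),
                      vapply(s$events, `[[`, 1L, "j")), collapse = "|"),
        character(1L))
      scens <- scens[order(key)]
      attr(scens, "truncated") <- truncated
      return(scens)
    }
  }
  out <- list()
  attr(out, "unsolved") <- TRUE
  out
}

# apply an event to a signed integer vector (anchor-fixed linear form)
.apply_encoded <- function(sv, e) {
  blk <- e$i:e$j
  if (e$kind == "inversion") {
    sv[blk] <- -rev(sv[blk])
  } else if (e$kind %in% c("transposition", "inverse_transposition")) {
    b <- sv[blk]
    if (e$kind == "inverse_transposition") b <- -rev(b)
    rest <- sv[-blk]
    sv <- append(rest, b, after = e$to - 1L)
  } else {
    sv[blk] <- c(sv[blk][e$keep], sv[blk][!e$keep])
  }
  sv
}
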