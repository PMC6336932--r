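#' Run code with a temporary RNG seed
#'
#' Evaluates \code{code} with the global random-number generator seeded at
#' \code{seed}, then restores the previous RNG state.  All stochastic
#' functions in the package route their randomness through this helper so
#' that a single integer seed makes every generator reproducible without
#' clobbering the caller's RNG.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Reverse complement of a nucleotide string
#'
#' @param seq character scalar over A, C, G, T, U, N and IUPAC ambiguity
#'   codes (uppercase or lowercase; output is uppercase, U becomes A's
#'   complement as for T).
#' @return the reverse complement, uppercase.
#' @examples
#' revcomp("ATGC")  # "GCAT"
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  comp <- chartr("ACGTUNRYSWKMBDHV", "TGCAANYRSWMKVHDB", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# split a string into a character vector of single bases
str_bases <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

# %% that maps onto 1..n instead of 0..(n-1)
mod1 <- function(i, n) ((i - 1L) %% n) + 1L
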