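# internal helpers shared across modules

# run code under a temporary RNG state; NULL seed leaves the RNG alone
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Reverse-complement a nucleotide string
#'
#' @param x a character vector of A/C/G/T/N strings.
#' @return the reverse complement of each element.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) chartr("ACGTacgtN", "TGCAtgcaN", x)

#' Convert 1-based inclusive intervals to 0-based half-open
#'
#' External formats (VCF, GFF3) are 1-based inclusive; all internal interval
#' arithmetic is 0-based half-open.  These two converters are inverses.
#'
#' @param start,end 1-based inclusive bounds.
#' @return a list with `start` (0-based) and `end` (exclusive).
#' @export
to_zero_based <- function(start, end) list(start = start - 1L, end = end)

#' Convert 0-based half-open intervals to 1-based inclusive
#'
#' @param start 0-based start; @param end exclusive end.
#' @return a list with 1-based inclusive `start` and `end`.
#' @rdname to_zero_based
#' @export
to_one_based <- function(start, end) list(start = start + 1L, end = end)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
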