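#' @import methods
#' @import data.table
#' @importFrom stats rnorm runif median p.adjust fisher.test dpois dhyper setNames
#' @importFrom utils adist head tail
NULL

# strand-aware complement on plain character vectors of A/C/G/T/N
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Junction key strings
#'
#' A junction is identified by chromosome and the 1-based inclusive interval
#' of its intron (first to last intronic base). `junction_key()` renders the
#' canonical `"chrom:start-end"` string used to join junction tables.
#'
#' @param chrom character vector of chromosome names
#' @param start,end integer vectors, first and last intronic base (1-based)
#' @return character vector of keys
#' @export
junction_key <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_format <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_format(...)
  invisible(TRUE)
}
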