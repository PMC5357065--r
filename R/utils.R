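## small internal helpers shared across modules

BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Complement nucleotide bases
#'
#' Vectorised single-base complement; `N` maps to `N`.
#'
#' @param base character vector of single bases (A/C/G/T/N).
#' @return character vector of complements.
#' @export
complement_base <- function(base) {
  chartr("ACGTN", "TGCAN", toupper(base))
}

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## deterministic integer seed derived from a user seed and a stream label;
## kept below 2^31 so it is a valid R integer
derive_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream)) %% 10000L
  as.integer((as.integer(seed) %% 2000000L) * 1000L + offs)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
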