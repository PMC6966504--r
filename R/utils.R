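#' @importFrom data.table data.table as.data.table setDT setkey setorder copy
#'   fread fwrite rbindlist setnames :=
#' @importFrom methods is
#' @importFrom stats runif setNames
#' @importFrom tools md5sum
#' @importFrom utils head tail modifyList
NULL

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b else a

#' Normalize a chromosome name
#'
#' Strips a leading "chr" prefix and surrounding whitespace so that caller
#' output ("chr17"), cytoband files ("chr17") and ISCN karyotypes ("17")
#' agree on a single naming scheme.
#'
#' @param x character vector of chromosome names.
#' @return character vector without the "chr" prefix.
#' @export
norm_chrom <- function(x) {
  sub("^chr", "", trimws(as.character(x)), ignore.case = TRUE)
}

#' Normalize a gene symbol
#'
#' Upper-cases and strips a trailing version suffix (e.g. "Zeb2.2" ->
#' "ZEB2"); symbol matching throughout the package is case-insensitive.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
norm_symbol <- function(x) {
  toupper(sub("\\.[0-9]+$", "", trimws(as.character(x))))
}

#' Reverse-complement a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return reverse-complemented sequences, upper-case.
#' @export
revcomp <- function(x) {
  up <- toupper(x)
  comp <- chartr("ACGTN", "TGCAN", up)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

# deterministic child seed derived from a user seed and a label; stays < 2^31
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
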