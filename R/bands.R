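# Cytoband map handling and band-label arithmetic.
#
# Band labels follow the standard cytogenetic grammar: arm (p or q), major
# band digits, optional sub-band digits after a dot ("q22.3").  Cytogenetic
# breakpoints from karyotypes may also be ranges ("q14-q23") or concatenated
# pairs ("p11p15"); those are handled by the parsers below.

#' Parse cytoband labels
#'
#' Splits labels such as `"q22.3"` into arm, major band number and sub-band.
#' Range labels (`"q14-q23"`) report the major-band range; the sub-band of a
#' range is dropped.
#'
#' @param x character vector of band labels.
#' @return a `data.table` with columns `label`, `arm`, `major`, `sub`,
#'   `major_lo`, `major_hi` (equal to `major` for non-range labels).
#' @export
parse_band <- function(x) {
  x <- trimws(as.character(x))
  one <- function(lab) {
    m <- regmatches(lab, regexec("^([pq])([0-9]+)(?:\\.([0-9]+))?(?:-([pq])?([0-9]+)(?:\\.[0-9]+)?)?$", lab))[[1]]
    if (length(m) == 0L) {
      return(data.table(label = lab, arm = NA_character_, major = NA_integer_,
                        sub = NA_character_, major_lo = NA_integer_, major_hi = NA_integer_))
    }
    arm <- m[2]
    major <- as.integer(m[3])
    sub <- if (nzchar(m[4])) m[4] else NA_character_
    hi <- major
    if (nzchar(m[6])) {
      # a range; only meaningful when both ends are on the same arm
      arm2 <- if (nzchar(m[5])) m[5] else arm
      if (identical(arm2, arm)) hi <- as.integer(m[6])
    }
    data.table(label = lab, arm = arm, major = major, sub = sub,
               major_lo = min(major, hi), major_hi = max(major, hi))
  }
  rbindlist(lapply(x, one))
}

#' Distance between two cytoband labels
#'
#' Distance is defined on major-band integers of the same chromosome arm:
#' `q22.3` vs `q21` has distance 1; sub-band precision is ignored. Labels on
#' different arms, or unparseable labels, are incomparable (`Inf`). Either
#' side may be a range label (`"q14-q23"`); the minimum distance over the
#' range is returned.
#'
#' @param a,b band labels (scalars).
#' @return non-negative integer distance, or `Inf` when incomparable.
#' @export
band_distance <- function(a, b) {
  pa <- parse_band(a); pb <- parse_band(b)
  if (is.na(pa$arm) || is.na(pb$arm) || pa$arm != pb$arm) return(Inf)
  if (pa$major_hi < pb$major_lo) return(pb$major_lo - pa$major_hi)
  if (pb$major_hi < pa$major_lo) return(pa$major_lo - pb$major_hi)
  0L
}

new_cytoband_map <- function(dt) {
  stopifnot(all(c("chrom", "band", "start", "end") %in% names(dt)))
  dt <- as.data.table(dt)[, .(chrom = norm_chrom(chrom), band = as.character(band),
                              start = as.integer(start), end = as.integer(end))]
  setorder(dt, chrom, start)
  # invariants: contiguity and non-overlap within each chromosome
  bad <- dt[, {
    ok <- if (.N > 1L) all(start[-1L] == end[-.N] + 1L) else TRUE
    list(ok = ok)
  }, by = chrom][!(ok)]
  if (nrow(bad) > 0L) {
    stopf("cytoband map error: gap or overlap between consecutive bands on chromosome %s",
          paste(bad$chrom, collapse = ", "))
  }
  chk <- parse_band(dt$band)
  if (anyNA(chk$arm)) {
    stopf("cytoband map error: unparseable band label(s): %s",
          paste(unique(dt$band[is.na(chk$arm)]), collapse = ", "))
  }
  structure(dt, class = c("cytoband_map", class(dt)))
}

#' Read a UCSC-style cytoband file
#'
#' Expects the `cytoBand.txt` column layout (chrom, chromStart, chromEnd,
#' name, gieStain), tab-separated, no header. UCSC coordinates are 0-based
#' half-open and are converted to the package-wide 1-based inclusive
#' convention at this boundary. Bands may appear out of order; they are
#' sorted. A gap or overlap between consecutive bands of one chromosome is
#' an error.
#'
#' @param path path to the cytoband file.
#' @return a `cytoband_map`: a `data.table` with columns `chrom`, `band`,
#'   `start`, `end` (1-based inclusive).
#' @export
read_cytobands <- function(path) {
  if (!file.exists(path)) stopf("cytoband file not found: %s", path)
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(dt) < 4L) stopf("cytoband file %s: expected >= 4 tab-separated columns", path)
  setnames(dt, 1:4, c("chrom", "start0", "end0", "band"))
  new_cytoband_map(dt[, .(chrom, band, start = start0 + 1L, end = end0)])
}

#' Write a cytoband map back to UCSC dialect
#'
#' Inverse of [read_cytobands()]: converts the internal 1-based inclusive
#' intervals back to 0-based half-open starts.
#'
#' @param map a `cytoband_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytobands <- function(map, path) {
  out <- data.table(chrom = map$chrom, start0 = map$start - 1L, end0 = map$end,
                    band = map$band, stain = "gneg")
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Look up the band containing a genomic position
#'
#' @param map a `cytoband_map`.
#' @param chrom chromosome name (with or without "chr" prefix).
#' @param pos 1-based position.
#' @return the band label, or `NA_character_` if the position falls outside
#'   the map; unknown chromosome is an error.
#' @export
band_at <- function(map, chrom, pos) {
  ch <- norm_chrom(chrom)
  sub <- map[map$chrom == ch, ]
  if (nrow(sub) == 0L) stopf("chromosome %s absent from cytoband map", ch)
  hit <- sub[pos >= sub$start & pos <= sub$end, ]
  if (nrow(hit) == 0L) return(NA_character_)
  hit$band[1L]
}
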