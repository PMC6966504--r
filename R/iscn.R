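# ISCN karyotype parsing.
#
# Covers the subset of ISCN 2016 needed for concordance checks:
# translocations t(A;B)(bandA;bandB) including three-way forms, inversions,
# deletions, additions, gains/losses, markers, and derivative chromosomes
# with embedded translocation tokens. Everything outside this grammar
# degrades to kind = "other" with the raw token preserved, never dropped:
# concordance matching later ignores "other" tokens, so the parser never
# guesses cytogenetic intent.

EVENT_KINDS <- c("translocation", "inversion", "deletion", "derivative",
                 "gain", "loss", "marker", "addition", "other")

new_event <- function(kind, chroms = character(), bands = character(), raw = "",
                      embedded = NULL) {
  stopifnot(kind %in% EVENT_KINDS)
  structure(list(kind = kind, chroms = as.character(chroms),
                 bands = as.character(bands), raw = raw, embedded = embedded),
            class = "iscn_event")
}

#' @export
print.iscn_event <- function(x, ...) {
  cat(sprintf("<iscn_event> %s: %s\n", x$kind, x$raw))
  invisible(x)
}

# split a string on commas that sit outside any parentheses
split_top_commas <- function(s) {
  depth <- 0L; cuts <- integer()
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
    if (depth < 0L) stopf("karyotype parse error: unbalanced parentheses at offset %d", i)
  }
  if (depth != 0L) stopf("karyotype parse error: unbalanced parentheses (depth %d at end)", depth)
  starts <- c(1L, cuts + 1L); ends <- c(cuts - 1L, nchar(s))
  vapply(seq_along(starts), function(k) substr(s, starts[k], ends[k]), "")
}

# split a band segment like "q21;q32", "q24q25", "p21;p13,q12" into labels
split_bands <- function(s) {
  parts <- unlist(strsplit(s, "[;,]"))
  out <- character()
  for (p in parts) {
    m <- regmatches(p, gregexpr("[pq][0-9]+(\\.[0-9]+)?(-[pq]?[0-9]+(\\.[0-9]+)?)?", p))[[1]]
    out <- c(out, if (length(m) > 0L) m else p)
  }
  out
}

CHROM_RE <- "([0-9]+|X|Y)"

parse_event_token <- function(tok) {
  # gain/loss of a whole chromosome
  m <- regmatches(tok, regexec(paste0("^([+-])", CHROM_RE, "$"), tok))[[1]]
  if (length(m) > 0L) {
    return(new_event(if (m[2] == "+") "gain" else "loss", chroms = m[3], raw = tok))
  }
  # marker chromosomes, incl. uncertain counts (+1~3mar)
  if (grepl("^\\+?([0-9]+(~[0-9]+)?)?mar$", tok)) {
    return(new_event("marker", raw = tok))
  }
  # t(A;B;C)(b1;b2;b3)
  m <- regmatches(tok, regexec("^t\\(([^()]*)\\)\\(([^()]*)\\)$", tok))[[1]]
  if (length(m) > 0L) {
    chroms <- trimws(unlist(strsplit(m[2], ";")))
    bands <- split_bands(m[3])
    if (length(bands) == length(chroms) && length(chroms) >= 2L) {
      return(new_event("translocation", chroms = chroms, bands = bands, raw = tok))
    }
    return(new_event("other", raw = tok))
  }
  # inv/del/add/dup with band segment
  m <- regmatches(tok, regexec(paste0("^(inv|del|add|dup)\\(", CHROM_RE, "\\)(\\(([^()]*)\\))?$"), tok))[[1]]
  if (length(m) > 0L) {
    kind <- switch(m[2], inv = "inversion", del = "deletion", add = "addition", dup = "other")
    bands <- if (nzchar(m[4])) split_bands(m[5]) else character()
    return(new_event(kind, chroms = m[3], bands = bands, raw = tok))
  }
  # derivative chromosomes; embedded t(...)(...) tokens are parsed out
  m <- regmatches(tok, regexec(paste0("^der\\(", CHROM_RE, "\\)(.*)$"), tok))[[1]]
  if (length(m) > 0L) {
    rest <- m[3]
    emb <- list()
    tm <- regmatches(rest, gregexpr("t\\([^()]*\\)\\([^()]*\\)", rest))[[1]]
    for (tt in tm) {
      ev <- parse_event_token(tt)
      if (ev$kind == "translocation") emb <- c(emb, list(ev))
    }
    if (length(emb) > 0L) {
      return(new_event("derivative", chroms = m[2], raw = tok, embedded = emb))
    }
    return(new_event("other", raw = tok))  # e.g. bare der(X): never guess intent
  }
  new_event("other", raw = tok)
}

#' Parse an ISCN karyotype string
#'
#' Clones are separated by `/`; a trailing `[n]` on a clone gives its cell
#' count. Whitespace anywhere in the string is ignored. The modal chromosome
#' number and sex-chromosome tokens form the clone description; every other
#' token becomes a structural event. Unrecognized tokens are preserved as
#' events of kind `"other"` — nothing is silently dropped, and
#' `serialize_karyotype()` reconstructs the (whitespace-stripped) input.
#'
#' @param text ISCN string, e.g. `"46,XX,t(2;14)(q21;q32)[17]/46,XX[3]"`.
#' @param sample_id optional sample identifier carried on the result.
#' @return an object of class `karyotype`: list with `sample_id` and
#'   `clones`; each clone has `description`, `events` (list of `iscn_event`),
#'   `cell_count` (integer or `NA`) and `tokens` (all raw tokens in order).
#' @export
parse_karyotype <- function(text, sample_id = NA_character_) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stopf("karyotype parse error: empty string")
  }
  s <- gsub("[[:space:]]+", "", text)
  clones <- lapply(strsplit(s, "/", fixed = TRUE)[[1]], function(cl) {
    cnt <- NA_integer_
    m <- regmatches(cl, regexec("^(.*)\\[([0-9]+)\\]$", cl))[[1]]
    if (length(m) > 0L) { cl <- m[2]; cnt <- as.integer(m[3]) }
    toks <- split_top_commas(cl)
    is_modal <- grepl("^[0-9]+(~[0-9]+)?$", toks)
    is_sex <- grepl("^[XY]+$", toks) & !is_modal
    desc_idx <- seq_along(toks) <= 2L & (is_modal | is_sex)
    events <- lapply(toks[!desc_idx], parse_event_token)
    list(description = paste(toks[desc_idx], collapse = ","),
         events = events, cell_count = cnt, tokens = toks)
  })
  structure(list(sample_id = sample_id, clones = clones), class = "karyotype")
}

#' Serialize a karyotype back to ISCN text
#'
#' Uses the preserved raw tokens, so `parse -> serialize -> parse` is the
#' identity on the parsed representation.
#'
#' @param k a `karyotype`.
#' @return single ISCN string.
#' @export
serialize_karyotype <- function(k) {
  paste(vapply(k$clones, function(cl) {
    s <- paste(cl$tokens, collapse = ",")
    if (!is.na(cl$cell_count)) s <- sprintf("%s[%d]", s, cl$cell_count)
    s
  }, ""), collapse = "/")
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("<karyotype> %s: %s\n", x$sample_id %||% "?", serialize_karyotype(x)))
  invisible(x)
}

#' Extract translocation-like events from a karyotype
#'
#' Returns translocations, inversions, and translocations embedded in
#' derivative-chromosome tokens, across all clones, deduplicated by raw
#' token. These are the events against which fusion/karyotype concordance is
#' checked; gains, losses, markers and unrecognized tokens never match.
#'
#' @param k a `karyotype`.
#' @return list of `iscn_event` objects of kind `"translocation"` or
#'   `"inversion"`.
#' @export
extract_translocation_like <- function(k) {
  out <- list(); seen <- character()
  for (cl in k$clones) {
    for (ev in cl$events) {
      cand <- list()
      if (ev$kind %in% c("translocation", "inversion")) cand <- list(ev)
      if (ev$kind == "derivative" && length(ev$embedded) > 0L) cand <- ev$embedded
      for (ce in cand) {
        if (!ce$raw %in% seen) { out <- c(out, list(ce)); seen <- c(seen, ce$raw) }
      }
    }
  }
  out
}
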