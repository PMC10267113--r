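#' Parse a protein mutation string
#'
#' Parses a comma-separated, HGVS-protein-style mutation string into atomic
#' mutation events and classifies the set into one of six types. Supported
#' token forms:
#' \itemize{
#'   \item substitution: `"V600E"`
#'   \item deletion: `"V600del"` or `"E746_A750del"`
#'   \item insertion: `"A123_B124insXYZ"` (between two flanking residues)
#'   \item indel: `"T123delinsAG"` or `"D580_P585delinsW"`
#' }
#' Events are sorted by start position and must not overlap; the formatted
#' canonical string (see [formatMutation()]) is the key used for grouping
#' and deduplication. For multi-residue deletions and indels only the
#' flanking wild-type residues are named in the token; interior residues
#' are stored as `X` (unknown).
#'
#' A one-residue `delins` whose replacement is also one residue is
#' normalized to a substitution event.
#'
#' @param raw Non-empty mutation string.
#' @return A [MutationSet].
#' @export
#' @examples
#' parseMutation("V600E")
#' mutationType(parseMutation("T315I,E255K"))
#' formatMutation(parseMutation("K601N,V600E"))  # canonical order
parseMutation <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw))
    stop("mutation string must be a single non-empty character value")
  tokens <- strsplit(raw, ",", fixed = TRUE)[[1]]
  tokens <- trimws(tokens)
  if (any(!nzchar(tokens))) stop("empty mutation token in: ", raw)
  ev <- do.call(rbind, lapply(tokens, .parse_token))
  ev <- ev[order(ev$start, ev$end), , drop = FALSE]
  rownames(ev) <- NULL
  new("MutationSet", events = ev, mtype = classifyEvents(ev), raw = raw)
}

.parse_token <- function(tok) {
  aa <- "[A-Z]"
  event <- function(kind, start, end, ref, alt, flanks = "")
    data.frame(kind = kind, start = start, end = end, ref = ref, alt = alt,
               flanks = flanks)
  pad_ref <- function(first, last, span) {
    if (span == 1L) return(first)
    paste0(first, strrep("X", span - 2L), last)
  }
  chk <- function(letters) {
    letters <- letters[nzchar(letters)]
    bad <- !strsplit(paste(letters, collapse = ""), "")[[1]] %in% .aa_levels
    if (any(bad))
      stop("unknown amino-acid letter in token: ", tok)
  }
  # range indel: A123_C127delinsXY
  m <- regmatches(tok, regexec(
    paste0("^(", aa, ")([0-9]+)_(", aa, ")([0-9]+)delins(", aa, "+)$"), tok))[[1]]
  if (length(m)) {
    s <- as.integer(m[3]); e <- as.integer(m[5])
    if (e <= s) stop("invalid range in token: ", tok)
    chk(c(m[2], m[4], m[6]))
    return(event("indel", s, e, pad_ref(m[2], m[4], e - s + 1L), m[6]))
  }
  # single-residue indel: A123delinsXY
  m <- regmatches(tok, regexec(
    paste0("^(", aa, ")([0-9]+)delins(", aa, "+)$"), tok))[[1]]
  if (length(m)) {
    chk(c(m[2], m[4]))
    s <- as.integer(m[3])
    if (nchar(m[4]) == 1L)  # one-for-one replacement is a substitution
      return(event("substitution", s, s, m[2], m[4]))
    return(event("indel", s, s, m[2], m[4]))
  }
  # range deletion: A123_C127del
  m <- regmatches(tok, regexec(
    paste0("^(", aa, ")([0-9]+)_(", aa, ")([0-9]+)del$"), tok))[[1]]
  if (length(m)) {
    s <- as.integer(m[3]); e <- as.integer(m[5])
    if (e <= s) stop("invalid range in token: ", tok)
    chk(c(m[2], m[4]))
    return(event("deletion", s, e, pad_ref(m[2], m[4], e - s + 1L), ""))
  }
  # single deletion: A123del
  m <- regmatches(tok, regexec(paste0("^(", aa, ")([0-9]+)del$"), tok))[[1]]
  if (length(m)) {
    chk(m[2])
    s <- as.integer(m[3])
    return(event("deletion", s, s, m[2], ""))
  }
  # insertion: A123_B124insXYZ
  m <- regmatches(tok, regexec(
    paste0("^(", aa, ")([0-9]+)_(", aa, ")([0-9]+)ins(", aa, "+)$"), tok))[[1]]
  if (length(m)) {
    s <- as.integer(m[3]); e <- as.integer(m[5])
    if (e != s + 1L)
      stop("insertion flanks must be adjacent residues in token: ", tok)
    chk(c(m[2], m[4], m[6]))
    return(event("insertion", s, e, "", m[6], paste0(m[2], "_", m[4])))
  }
  # substitution: A123B
  m <- regmatches(tok, regexec(paste0("^(", aa, ")([0-9]+)(", aa, ")$"), tok))[[1]]
  if (length(m)) {
    chk(c(m[2], m[4]))
    if (m[2] == m[4]) stop("synonymous token is not a mutation: ", tok)
    s <- as.integer(m[3])
    return(event("substitution", s, s, m[2], m[4]))
  }
  stop("malformed mutation token: ", tok)
}

#' Classify mutation events into the six-way type
#'
#' One substitution gives `single_substitution`; two or more substitutions
#' (and nothing else) give `multiple_substitution`; exactly one deletion,
#' insertion or indel gives that label; any mixture of kinds, or two or
#' more non-substitution events, gives `complex`.
#'
#' @param ev Event `data.frame` as in the `events` slot of a
#'   [MutationSet], or a [MutationSet].
#' @return One of the six type labels.
#' @export
#' @examples
#' classifyEvents(events(parseMutation("V600E,D580_P585del")))
classifyEvents <- function(ev) {
  if (is(ev, "MutationSet")) ev <- ev@events
  if (!is.data.frame(ev) || nrow(ev) == 0L)
    stop("cannot classify an empty event list")
  kinds <- ev$kind
  if (all(kinds == "substitution"))
    return(if (nrow(ev) == 1L) "single_substitution" else "multiple_substitution")
  if (nrow(ev) == 1L)
    return(kinds)  # deletion / insertion / indel
  "complex"
}

#' Format a MutationSet canonically
#'
#' Serializes events in canonical (position-sorted) order joined by commas.
#' `parseMutation(formatMutation(x))` reproduces `x`'s events, and
#' formatting is the canonicalization used to key mutant cell-line buckets
#' and CoreSet deduplication.
#'
#' @param x A [MutationSet].
#' @return Canonical mutation string.
#' @export
formatMutation <- function(x) {
  stopifnot(is(x, "MutationSet"))
  ev <- x@events
  toks <- vapply(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    switch(e$kind,
      substitution = paste0(e$ref, e$start, e$alt),
      deletion = if (e$start == e$end) paste0(e$ref, e$start, "del") else
        paste0(substr(e$ref, 1, 1), e$start, "_",
               substr(e$ref, nchar(e$ref), nchar(e$ref)), e$end, "del"),
      indel = if (e$start == e$end) paste0(e$ref, e$start, "delins", e$alt) else
        paste0(substr(e$ref, 1, 1), e$start, "_",
               substr(e$ref, nchar(e$ref), nchar(e$ref)), e$end,
               "delins", e$alt),
      insertion = {
        fl <- strsplit(e$flanks, "_", fixed = TRUE)[[1]]
        paste0(fl[1], e$start, "_", fl[2], e$end, "ins", e$alt)
      })
  }, character(1))
  paste(toks, collapse = ",")
}

#' Canonicalize a raw mutation string
#'
#' Convenience composition `formatMutation(parseMutation(raw))`, optionally
#' merging several raw strings (e.g. all mutation rows of one cell line on
#' one protein) into a single canonical string.
#'
#' @param raw Character vector of mutation strings to merge.
#' @return A single canonical mutation string.
#' @export
#' @examples
#' canonicalMutation(c("K601N", "V600E"))
canonicalMutation <- function(raw) {
  formatMutation(parseMutation(paste(raw, collapse = ",")))
}
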