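#' Mutation-type breakdown of a sample table
#'
#' Counts samples per mutation type, with percentages of the total
#' (rounded to one decimal place) and an `others` roll-up aggregating the
#' four rarer types (deletion, insertion, indel, complex).
#'
#' @param x Sample `data.frame` with a `mutation_type` column, or a
#'   character vector of type labels, or a named numeric vector of
#'   pre-tabulated counts per type.
#' @return List with `counts` (named integer vector over the six types),
#'   `percent` (same names, 1 d.p.), `others_percent`, `total` and
#'   `empty` flag.
#' @export
#' @examples
#' counts <- c(single_substitution = 84038, multiple_substitution = 11977,
#'             deletion = 3228, insertion = 355, indel = 243, complex = 696)
#' mutationTypeBreakdown(counts)$percent[1:2]
mutationTypeBreakdown <- function(x) {
  if (is.numeric(x)) {
    counts <- integer(length(.mutation_types))
    names(counts) <- .mutation_types
    bad <- setdiff(names(x), .mutation_types)
    if (length(bad)) stop("unknown mutation type(s): ",
                          paste(bad, collapse = ", "))
    counts[names(x)] <- as.integer(x)
  } else {
    types <- if (is.data.frame(x)) x$mutation_type else as.character(x)
    counts <- table(factor(types, levels = .mutation_types))
    counts <- stats::setNames(as.integer(counts), .mutation_types)
  }
  total <- sum(counts)
  if (total == 0L)
    return(list(counts = counts, percent = counts * 0,
                others_percent = 0, total = 0L, empty = TRUE))
  pct <- round(100 * counts / total, 1)
  others <- c("deletion", "insertion", "indel", "complex")
  list(counts = counts, percent = pct,
       others_percent = round(100 * sum(counts[others]) / total, 1),
       total = total, empty = FALSE)
}

#' Amino-acid substitution matrix
#'
#' Tabulates, over all substitution-type samples (single and multiple),
#' the number of atomic substitution events from each wild-type amino
#' acid to each mutant amino acid. Each atomic event counts once; the
#' diagonal is structurally zero.
#'
#' @param samples Sample `data.frame` with a `mutation` column (canonical
#'   mutation strings) or a list of [MutationSet]s.
#' @return 20x20 integer matrix, rows wild-type, columns mutant.
#' @export
substitutionMatrix <- function(samples) {
  m <- matrix(0L, 20, 20, dimnames = list(.aa_levels, .aa_levels))
  sets <- if (is.data.frame(samples)) {
    lapply(samples$mutation, parseMutation)
  } else samples
  for (ms in sets) {
    ev <- events(ms)
    ev <- ev[ev$kind == "substitution", , drop = FALSE]
    for (i in seq_len(nrow(ev)))
      m[ev$ref[i], ev$alt[i]] <- m[ev$ref[i], ev$alt[i]] + 1L
  }
  m
}

#' Within-group and across-group substitution fractions
#'
#' Fraction of substitution events whose wild-type and mutant residues
#' fall in the same amino-acid property group versus different groups.
#'
#' @param m Substitution matrix from [substitutionMatrix()].
#' @return Named numeric vector `c(within = ..., across = ...)`,
#'   summing to 1.
#' @export
groupTransitionFractions <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(20, 20)))
  if (sum(m) == 0) stop("empty substitution matrix")
  same <- outer(aaGroup(rownames(m)), aaGroup(colnames(m)), "==")
  within <- sum(m[same]) / sum(m)
  c(within = within, across = 1 - within)
}

#' Expected amino-acid frequencies from codon counts
#'
#' Expected frequency of each amino acid under the assumption that every
#' sense codon is equally likely: the number of codons encoding the amino
#' acid divided by the number of sense codons (61 in the standard genetic
#' code, taken from `Biostrings::GENETIC_CODE`).
#'
#' @param code Named character vector mapping codons to one-letter amino
#'   acids (`"*"` for stop), default the standard genetic code.
#' @return Normalized numeric vector of length 20 over [aminoAcidTable()]
#'   order.
#' @export
#' @examples
#' codonExpectedFrequencies()["L"]  # 6/61
codonExpectedFrequencies <- function(code = Biostrings::GENETIC_CODE) {
  if (is.null(names(code)) || !all(nchar(names(code)) == 3L))
    stop("malformed genetic-code table")
  sense <- code[code != "*"]
  if (!all(sense %in% .aa_levels)) stop("malformed genetic-code table")
  counts <- table(factor(sense, levels = .aa_levels))
  v <- as.numeric(counts) / length(sense)
  names(v) <- .aa_levels
  v
}

#' Observed amino-acid frequencies from a substitution matrix
#'
#' Row margins give the pre-mutation (wild-type) spectrum, column margins
#' the post-mutation spectrum; frequencies are event-count normalized.
#'
#' @param m Substitution matrix.
#' @param margin `"wildtype"` (rows) or `"mutant"` (columns).
#' @return Normalized numeric vector of length 20.
#' @export
aaFrequencies <- function(m, margin = c("wildtype", "mutant")) {
  margin <- match.arg(margin)
  v <- if (margin == "wildtype") rowSums(m) else colSums(m)
  if (sum(v) == 0) stop("empty substitution matrix")
  v / sum(v)
}

#' Pearson correlation between observed and expected spectra
#'
#' @param observed,expected Numeric vectors of length 20 (frequencies).
#' @return Pearson r, or `NA` with a warning when either vector has zero
#'   variance.
#' @export
spectrumCorrelation <- function(observed, expected) {
  stopifnot(length(observed) == 20, length(expected) == 20)
  if (stats::sd(observed) == 0 || stats::sd(expected) == 0) {
    warning("zero-variance frequency vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(observed, expected)
}
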