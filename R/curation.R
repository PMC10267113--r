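#' Gas constant in kcal mol^-1 K^-1
#' @export
GAS_CONSTANT_KCAL <- 1.9872e-3

#' Resistance threshold in kcal mol^-1
#'
#' A mutation is called resistant when its ddG exceeds this value, which
#' corresponds to a more-than-10-fold drop in binding affinity at 298.15 K.
#' @export
RESISTANCE_THRESHOLD <- 1.36

#' Thermodynamic constants
#'
#' @param temperature Temperature in Kelvin (default 298.15, at which a
#'   10-fold IC50 ratio corresponds to 1.36 kcal mol^-1).
#' @return List with elements `R` (kcal mol^-1 K^-1) and `T` (K).
#' @export
thermoConstants <- function(temperature = 298.15) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            temperature > 0)
  list(R = GAS_CONSTANT_KCAL, T = temperature)
}

#' Binding free-energy change from an IC50 ratio
#'
#' Computes `ddG = R * T * ln(IC50_mut / IC50_wt)` in kcal mol^-1, using
#' the mutant/wild-type IC50 ratio as a proxy for the inhibition-constant
#' ratio. Antisymmetric under swapping the arguments and additive over
#' chained ratios.
#'
#' @param ic50Mut,ic50Wt IC50 values in micromolar (any common unit;
#'   only the ratio matters). Must be positive.
#' @param temperature Temperature in Kelvin.
#' @return ddG in kcal mol^-1.
#' @export
#' @examples
#' computeDdg(10, 1)              # 1.36 at 298.15 K
#' computeDdg(10, 1, temperature = 300)  # 1.37, the "1.4 at 300 K" scale
computeDdg <- function(ic50Mut, ic50Wt, temperature = 298.15) {
  if (any(!is.finite(ic50Mut) | ic50Mut <= 0) ||
      any(!is.finite(ic50Wt) | ic50Wt <= 0))
    stop("IC50 values must be finite and positive")
  const <- thermoConstants(temperature)
  const$R * const$T * log(ic50Mut / ic50Wt)
}

#' Resistance label from ddG
#'
#' Strictly-greater comparison against the 1.36 kcal mol^-1 cutoff
#' (a more-than-10-fold affinity drop).
#'
#' @param ddg ddG in kcal mol^-1.
#' @param threshold Cutoff, default [RESISTANCE_THRESHOLD].
#' @return Logical vector.
#' @export
labelResistant <- function(ddg, threshold = RESISTANCE_THRESHOLD) {
  if (any(!is.finite(ddg))) stop("ddg must be finite")
  ddg > threshold
}

#' Aggregate IC50 measurements
#'
#' @param x Positive IC50 values in micromolar.
#' @param mode `"arithmetic"` (mean in linear concentration space, the
#'   default) or `"geometric"`.
#' @return Aggregated IC50 in micromolar.
#' @export
#' @examples
#' aggregateIC50(c(1, 2, 3))
#' aggregateIC50(c(1, 100), mode = "geometric")
aggregateIC50 <- function(x, mode = c("arithmetic", "geometric")) {
  mode <- match.arg(mode)
  if (length(x) == 0L) stop("cannot aggregate an empty IC50 list")
  if (any(!is.finite(x) | x <= 0)) stop("IC50 values must be positive")
  if (mode == "arithmetic") mean(x) else exp(mean(log(x)))
}

#' Construct screen tables
#'
#' @param sensitivity `data.frame` with `cell_line`, `drug`, `ic50_um` and
#'   optionally `source`.
#' @param cellMutations `data.frame` with `cell_line`, `uniprot_id`,
#'   `mutation`.
#' @param drugTargets `data.frame` with `drug`, `uniprot_id`.
#' @return A [ScreenTables].
#' @export
screenTables <- function(sensitivity, cellMutations, drugTargets) {
  if (is.null(sensitivity$source)) sensitivity$source <- "screen"
  new("ScreenTables", sensitivity = as.data.frame(sensitivity),
      cellMutations = as.data.frame(cellMutations),
      drugTargets = as.data.frame(drugTargets))
}

# canonical per-cell-line mutation strings on one protein; unparseable rows
# are recorded so those cell lines can be excluded from wild-type controls
.cell_line_mutations <- function(protein, tables) {
  cm <- tables@cellMutations
  cm <- cm[cm$uniprot_id == protein, , drop = FALSE]
  out <- list(canonical = character(0), unparseable = character(0))
  if (!nrow(cm)) return(out)
  canonical <- character(0)
  unparseable <- character(0)
  for (cl in unique(cm$cell_line)) {
    raws <- cm$mutation[cm$cell_line == cl]
    key <- tryCatch(canonicalMutation(raws), error = function(e) NA_character_)
    if (is.na(key)) {
      # retry keeping only individually parseable tokens
      toks <- unlist(strsplit(raws, ",", fixed = TRUE))
      ok <- vapply(toks, function(t)
        !inherits(tryCatch(parseMutation(t), error = identity), "error"),
        logical(1))
      if (any(ok)) {
        key <- tryCatch(canonicalMutation(toks[ok]),
                        error = function(e) NA_character_)
      }
      if (is.na(key) || !any(ok)) { unparseable <- c(unparseable, cl); next }
    }
    canonical[cl] <- key
  }
  list(canonical = canonical, unparseable = unparseable)
}

#' Group cell lines into wild-type and mutant buckets for a protein
#'
#' Cell lines with no recorded mutation on the protein are wild-type
#' controls; cell lines with at least one parseable mutation are grouped
#' into mutant buckets keyed by the canonical merged mutation string. Cell
#' lines whose only recorded mutations on the protein fail to parse are
#' neither (they are not demonstrably wild-type) and are reported
#' separately.
#'
#' @param protein UniProt id.
#' @param tables A [ScreenTables].
#' @param cellLines Optional character vector restricting the universe of
#'   cell lines (defaults to all cell lines in the sensitivity table).
#' @return List with `wildType` (character vector), `mutant` (named list of
#'   character vectors keyed by canonical mutation string) and
#'   `unparseable` (character vector).
#' @export
groupCellLines <- function(protein, tables, cellLines = NULL) {
  stopifnot(is(tables, "ScreenTables"))
  if (is.null(cellLines))
    cellLines <- unique(tables@sensitivity$cell_line)
  mut <- .cell_line_mutations(protein, tables)
  canonical <- mut$canonical[names(mut$canonical) %in% cellLines]
  unparseable <- intersect(mut$unparseable, cellLines)
  mut_lines <- names(canonical)
  wt <- setdiff(cellLines, c(mut_lines, unparseable))
  buckets <- split(names(canonical), unname(canonical))
  list(wildType = wt, mutant = buckets, unparseable = unparseable)
}

#' Target-exclusivity filter for multi-target drugs
#'
#' For a drug with several known protein targets, a cell line is usable
#' only if exactly zero (wild-type control) or exactly one of the targets
#' carries mutations in that cell line; a cell line mutated in two or more
#' targets is discarded because the IC50 change cannot be attributed to a
#' single protein.
#'
#' @param drug Drug name.
#' @param cellLine Cell-line name.
#' @param tables A [ScreenTables].
#' @return `TRUE` (keep) or `FALSE` (discard).
#' @export
targetExclusivityFilter <- function(drug, cellLine, tables) {
  stopifnot(is(tables, "ScreenTables"))
  targets <- tables@drugTargets$uniprot_id[tables@drugTargets$drug == drug]
  if (!length(targets)) stop("drug has no known protein targets: ", drug)
  cm <- tables@cellMutations
  mutated <- unique(cm$uniprot_id[cm$cell_line == cellLine &
                                  cm$uniprot_id %in% targets])
  length(mutated) <= 1L
}

#' Curate raw screen tables into ddG-labelled samples
#'
#' Runs the full curation pipeline: for every (drug, target protein) pair,
#' cell lines with sensitivity data for the drug are split into wild-type
#' controls and mutant buckets ([groupCellLines()]); cell lines mutated in
#' more than one target of a multi-target drug are discarded
#' ([targetExclusivityFilter()]); replicate IC50 measurements are averaged
#' per cell line, then across cell lines per bucket ([aggregateIC50()]);
#' ddG is computed from the mutant/wild-type IC50 ratio ([computeDdg()])
#' and resistance labelled at the 1.36 kcal mol^-1 cutoff.
#'
#' @param tables A [ScreenTables].
#' @param temperature Temperature in Kelvin.
#' @param averaging IC50 averaging mode, see [aggregateIC50()].
#' @return List with `samples` (a sample `data.frame`, see
#'   [writeSampleTable()] for the column schema) and `log` (named integer
#'   counts of records per curation rule: `emitted_samples`,
#'   `sensitivity_records_used`, `drug_without_targets`,
#'   `multi_target_discard`, `unparseable_mutation`, `no_wildtype_control`,
#'   `no_mutant_bucket`).
#' @export
curateSamples <- function(tables, temperature = 298.15,
                          averaging = c("arithmetic", "geometric")) {
  stopifnot(is(tables, "ScreenTables"))
  averaging <- match.arg(averaging)
  sens <- tables@sensitivity
  log <- c(emitted_samples = 0L, sensitivity_records_used = 0L,
           drug_without_targets = 0L, multi_target_discard = 0L,
           unparseable_mutation = 0L, no_wildtype_control = 0L,
           no_mutant_bucket = 0L)
  rows <- list()
  drugs <- unique(sens$drug)
  tmap <- split(tables@drugTargets$uniprot_id, tables@drugTargets$drug)
  for (drug in drugs) {
    dsens <- sens[sens$drug == drug, , drop = FALSE]
    targets <- tmap[[drug]]
    if (is.null(targets) || !length(targets)) {
      log["drug_without_targets"] <- log["drug_without_targets"] + nrow(dsens)
      next
    }
    lines <- unique(dsens$cell_line)
    keep <- vapply(lines, targetExclusivityFilter, logical(1),
                   drug = drug, tables = tables)
    n_discard <- sum(dsens$cell_line %in% lines[!keep])
    lines <- lines[keep]
    # per-cell-line replicate aggregation
    cl_ic50 <- vapply(lines, function(cl)
      aggregateIC50(dsens$ic50_um[dsens$cell_line == cl], averaging),
      numeric(1))
    src <- dsens$source[1L]
    for (protein in targets) {
      grp <- groupCellLines(protein, tables, cellLines = lines)
      log["multi_target_discard"] <- log["multi_target_discard"] + n_discard
      log["unparseable_mutation"] <- log["unparseable_mutation"] +
        sum(dsens$cell_line %in% grp$unparseable)
      if (!length(grp$mutant)) {
        log["no_mutant_bucket"] <- log["no_mutant_bucket"] +
          sum(dsens$cell_line %in% grp$wildType)
        next
      }
      if (!length(grp$wildType)) {
        log["no_wildtype_control"] <- log["no_wildtype_control"] +
          sum(dsens$cell_line %in% unlist(grp$mutant))
        next
      }
      ic50_wt <- aggregateIC50(cl_ic50[grp$wildType], averaging)
      for (key in names(grp$mutant)) {
        mlines <- grp$mutant[[key]]
        ic50_mut <- aggregateIC50(cl_ic50[mlines], averaging)
        ddg <- computeDdg(ic50_mut, ic50_wt, temperature)
        ms <- parseMutation(key)
        rows[[length(rows) + 1L]] <- data.frame(
          uniprot_id = protein, drug = drug, mutation = key,
          mutation_type = mutationType(ms),
          ddg_kcal_mol = ddg, resistant = labelResistant(ddg),
          ic50_wt_um = ic50_wt, ic50_mut_um = ic50_mut,
          n_wt = length(grp$wildType), n_mut = length(mlines),
          source = src, structure_source = "none")
        log["emitted_samples"] <- log["emitted_samples"] + 1L
        log["sensitivity_records_used"] <- log["sensitivity_records_used"] +
          sum(dsens$cell_line %in% mlines)
      }
      log["sensitivity_records_used"] <- log["sensitivity_records_used"] +
        sum(dsens$cell_line %in% grp$wildType)
    }
  }
  samples <- if (length(rows)) do.call(rbind, rows) else .empty_sample_table()
  rownames(samples) <- NULL
  list(samples = samples, log = log)
}

.empty_sample_table <- function() {
  data.frame(uniprot_id = character(0), drug = character(0),
             mutation = character(0), mutation_type = character(0),
             ddg_kcal_mol = numeric(0), resistant = logical(0),
             ic50_wt_um = numeric(0), ic50_mut_um = numeric(0),
             n_wt = integer(0), n_mut = integer(0),
             source = character(0), structure_source = character(0))
}

#' Deduplicate samples into a CoreSet
#'
#' Keeps at most one sample per unique (protein, drug, canonical mutation)
#' triple. The representative is chosen by structure-source priority
#' (`cocrystal` > `pymol_mutated` > `alphafold_folded` > `docked` >
#' `none`), ties broken by first-seen order.
#'
#' @param samples Sample `data.frame` as produced by [curateSamples()].
#' @return Deduplicated sample `data.frame`.
#' @export
coresetDedup <- function(samples) {
  if (!nrow(samples)) return(samples)
  prio <- c(cocrystal = 1L, pymol_mutated = 2L, alphafold_folded = 3L,
            docked = 4L, none = 5L)
  p <- prio[samples$structure_source]
  p[is.na(p)] <- 6L
  key <- paste(samples$uniprot_id, samples$drug, samples$mutation, sep = "\r")
  ord <- order(p, seq_len(nrow(samples)))
  s <- samples[ord, , drop = FALSE]
  out <- s[!duplicated(paste(s$uniprot_id, s$drug, s$mutation, sep = "\r")), ,
           drop = FALSE]
  out <- out[order(match(paste(out$uniprot_id, out$drug, out$mutation,
                               sep = "\r"), unique(key))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Structure-quality filter on predicted models
#'
#' A predicted model passes when its mean per-residue pLDDT is strictly
#' greater than 70 and every mutated-site residue has pLDDT of at least
#' 50 (a site in a poorly predicted region, pLDDT < 50, fails the model).
#'
#' @param model A predicted [StructureModel].
#' @param mutatedSites Integer vector of mutated residue numbers.
#' @return List with `pass` (logical) and `reason` (`""`, `"global"` or
#'   `"site"`).
#' @export
plddtFilter <- function(model, mutatedSites) {
  stopifnot(is(model, "StructureModel"))
  if (model@provenance != "predicted")
    stop("pLDDT filtering applies to predicted models only")
  pl <- residuePlddt(model)
  missing <- setdiff(as.character(mutatedSites), names(pl))
  if (length(missing))
    stop("mutated site(s) absent from model: ", paste(missing, collapse = ", "))
  if (!(mean(pl) > 70)) return(list(pass = FALSE, reason = "global"))
  if (any(pl[as.character(mutatedSites)] < 50))
    return(list(pass = FALSE, reason = "site"))
  list(pass = TRUE, reason = "")
}

#' Residues usable for wild-type/mutant superposition
#'
#' Returns the residue numbers (shared numbering, excluding the mutated
#' sites) whose pLDDT exceeds 70 in both the wild-type and the mutant
#' model — the set of backbone positions a superposition engine should
#' fit on.
#'
#' @param wt,mt Predicted [StructureModel]s.
#' @param mutatedSites Residue numbers to exclude (numbering may differ
#'   there).
#' @return Integer vector of residue numbers; empty with a warning when no
#'   residue qualifies.
#' @export
alignmentResidueMask <- function(wt, mt, mutatedSites = integer(0)) {
  stopifnot(is(wt, "StructureModel"), is(mt, "StructureModel"))
  pw <- residuePlddt(wt); pm <- residuePlddt(mt)
  shared <- intersect(names(pw), names(pm))
  keep <- shared[pw[shared] > 70 & pm[shared] > 70]
  keep <- setdiff(as.integer(keep), as.integer(mutatedSites))
  if (!length(keep))
    warning("no residues qualify for alignment (pLDDT > 70 in both models)")
  sort(keep)
}
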