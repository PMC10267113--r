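#' @import methods
NULL

.mutation_types <- c("single_substitution", "multiple_substitution",
                     "deletion", "insertion", "indel", "complex")

#' MutationSet: parsed protein mutation events
#'
#' Holds the atomic mutation events parsed from a protein-level mutation
#' string, together with the six-way type classification. Events are kept
#' sorted by start position and may not overlap.
#'
#' @slot events `data.frame` with columns `kind` (substitution, deletion,
#'   insertion, indel), `start`, `end` (1-based residue indices, `end >=
#'   start`), `ref` (wild-type residues; empty for insertions) and `alt`
#'   (replacement residues; empty for deletions).
#' @slot mtype One of `single_substitution`, `multiple_substitution`,
#'   `deletion`, `insertion`, `indel`, `complex`.
#' @slot raw The original mutation string.
#' @export
setClass("MutationSet",
  representation(events = "data.frame", mtype = "character", raw = "character"))

setValidity("MutationSet", function(object) {
  ev <- object@events
  need <- c("kind", "start", "end", "ref", "alt")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns", paste(need, collapse = ", ")))
  if (nrow(ev) == 0L) return("a MutationSet must contain at least one event")
  if (!all(ev$kind %in% c("substitution", "deletion", "insertion", "indel")))
    return("invalid event kind")
  if (any(ev$end < ev$start)) return("event end < start")
  if (is.unsorted(ev$start)) return("events must be sorted by start position")
  if (nrow(ev) > 1L) {
    # insertions occupy the inter-residue gap (start, end = flanking residues)
    # and may share flanks with nothing else; all spans must be disjoint
    for (i in seq_len(nrow(ev) - 1L))
      if (ev$end[i] >= ev$start[i + 1L]) return("overlapping events")
  }
  sub <- ev$kind == "substitution"
  if (any(nchar(ev$ref[sub]) != 1L | nchar(ev$alt[sub]) != 1L))
    return("substitution must have single-residue ref and alt")
  del <- ev$kind == "deletion"
  if (any(nchar(ev$alt[del]) != 0L) ||
      any(nchar(ev$ref[del]) != ev$end[del] - ev$start[del] + 1L))
    return("deletion must have empty alt and ref spanning start..end")
  ins <- ev$kind == "insertion"
  if (any(nchar(ev$ref[ins]) != 0L) || any(nchar(ev$alt[ins]) == 0L))
    return("insertion must have empty ref and non-empty alt")
  ind <- ev$kind == "indel"
  if (any(nchar(ev$ref[ind]) == 0L) || any(nchar(ev$alt[ind]) == 0L))
    return("indel must have non-empty ref and alt")
  if (!identical(object@mtype, classifyEvents(ev)))
    return("mtype does not match classification of events")
  TRUE
})

#' ScreenTables: raw drug-sensitivity screen input
#'
#' Container for the three raw tables a curation run consumes: drug
#' sensitivity records, cell-line mutation records, and the drug-to-target
#' map.
#'
#' @slot sensitivity `data.frame` with columns `cell_line`, `drug`,
#'   `ic50_um` (IC50 in micromolar, strictly positive) and `source`;
#'   `(cell_line, drug)` pairs may repeat (replicates).
#' @slot cellMutations `data.frame` with columns `cell_line`, `uniprot_id`
#'   and `mutation` (a mutation string).
#' @slot drugTargets `data.frame` with columns `drug` and `uniprot_id`,
#'   one row per drug-target pair.
#' @export
setClass("ScreenTables",
  representation(sensitivity = "data.frame", cellMutations = "data.frame",
                 drugTargets = "data.frame"))

setValidity("ScreenTables", function(object) {
  if (!all(c("cell_line", "drug", "ic50_um") %in% names(object@sensitivity)))
    return("sensitivity needs columns cell_line, drug, ic50_um")
  if (nrow(object@sensitivity) &&
      any(!is.finite(object@sensitivity$ic50_um) |
          object@sensitivity$ic50_um <= 0))
    return("all IC50 values must be finite and positive")
  if (!all(c("cell_line", "uniprot_id", "mutation") %in%
           names(object@cellMutations)))
    return("cellMutations needs columns cell_line, uniprot_id, mutation")
  if (!all(c("drug", "uniprot_id") %in% names(object@drugTargets)))
    return("drugTargets needs columns drug, uniprot_id")
  TRUE
})

#' StructureModel: a protein structure with optional pLDDT
#'
#' A lightweight atom-table view of one protein chain: residue numbering,
#' atom names, Cartesian coordinates, and per-residue confidence (pLDDT,
#' carried in the PDB B-factor column for predicted models).
#'
#' @slot atoms `data.frame` with columns `resno`, `resid` (3-letter residue
#'   name), `elety` (atom name), `x`, `y`, `z` (Angstrom), `b` (B-factor /
#'   pLDDT).
#' @slot provenance `"experimental"` or `"predicted"`; pLDDT semantics of
#'   the `b` column apply only to predicted models.
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", provenance = "character"))

setValidity("StructureModel", function(object) {
  need <- c("resno", "resid", "elety", "x", "y", "z", "b")
  if (!all(need %in% names(object@atoms)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  if (!object@provenance %in% c("experimental", "predicted"))
    return("provenance must be 'experimental' or 'predicted'")
  if (object@provenance == "predicted" && nrow(object@atoms) &&
      (any(object@atoms$b < 0) || any(object@atoms$b > 100)))
    return("pLDDT must lie in [0, 100] for predicted models")
  TRUE
})

#' ComplexStructure: protein plus posed ligand
#'
#' A protein [StructureModel] together with a posed small-molecule ligand
#' in the same coordinate frame. The ligand is stored as an atom table
#' (element, coordinates, formal charge) and a bond table so interaction
#' typing (donors, acceptors, aromatic rings, charges, halogens) can be
#' derived from the molecular graph.
#'
#' @slot protein A [StructureModel].
#' @slot ligandAtoms `data.frame` with columns `element`, `x`, `y`, `z`,
#'   `charge`; zero rows for an apo structure.
#' @slot ligandBonds `data.frame` with columns `a1`, `a2` (1-based atom
#'   indices) and `order`.
#' @slot apo `TRUE` when no ligand heavy atom lies within 10 Angstrom of
#'   the ligand centroid criterion, or when no ligand is present.
#' @export
setClass("ComplexStructure",
  representation(protein = "StructureModel", ligandAtoms = "data.frame",
                 ligandBonds = "data.frame", apo = "logical"))

setValidity("ComplexStructure", function(object) {
  if (nrow(object@ligandAtoms) &&
      !all(c("element", "x", "y", "z", "charge") %in% names(object@ligandAtoms)))
    return("ligandAtoms needs columns element, x, y, z, charge")
  TRUE
})

#' FeatureVector: named biochemical features in blocks
#'
#' An ordered, named numeric feature vector partitioned into blocks:
#' `ligand` (absolute descriptors, never differenced), `aa_change`,
#' `environment`, `interactions` and `plugin` (mutant-minus-wild-type delta
#' semantics after [featureDelta()]).
#'
#' @slot values Named numeric vector.
#' @slot blocks Character vector parallel to `values` giving the block of
#'   each feature.
#' @slot delta `TRUE` once the mt - wt delta convention has been applied to
#'   the non-ligand blocks.
#' @export
setClass("FeatureVector",
  representation(values = "numeric", blocks = "character", delta = "logical"))

setValidity("FeatureVector", function(object) {
  if (length(object@values) != length(object@blocks))
    return("values and blocks must have equal length")
  if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
    return("feature names must be present and unique")
  ok <- c("ligand", "aa_change", "environment", "interactions", "plugin")
  if (length(object@blocks) && !all(object@blocks %in% ok))
    return("unknown feature block")
  TRUE
})

#' ScenarioReport: benchmark results
#'
#' Per-estimator RMSE / Pearson / AUPRC summaries (mean and standard
#' deviation over repetitions), the per-repetition raw metric values, and
#' the experimental-vs-calculated scatter data.
#'
#' @slot summary `data.frame` with columns `estimator`, `metric`, `mean`, `sd`.
#' @slot raw `data.frame` with columns `estimator`, `repetition`, `seed`,
#'   `rmse`, `pearson`, `auprc`.
#' @slot scatter `data.frame` with columns `estimator`, `repetition`,
#'   `truth`, `pred`.
#' @slot scenario Scenario id (1, 2 or 3).
#' @export
setClass("ScenarioReport",
  representation(summary = "data.frame", raw = "data.frame",
                 scatter = "data.frame", scenario = "numeric"))

setMethod("show", "MutationSet", function(object) {
  cat("MutationSet:", object@raw, "\n")
  cat("  type:", object@mtype, "|", nrow(object@events), "event(s)\n")
})

setMethod("show", "ScreenTables", function(object) {
  cat("ScreenTables:",
      nrow(object@sensitivity), "sensitivity records,",
      nrow(object@cellMutations), "cell-line mutation records,",
      nrow(object@drugTargets), "drug-target pairs\n")
})

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel (", object@provenance, "): ",
      nrow(object@atoms), " atoms, ",
      length(unique(object@atoms$resno)), " residues",
      if (object@provenance == "predicted")
        sprintf(", mean pLDDT %.1f", meanPlddt(object)) else "",
      "\n", sep = "")
})

setMethod("show", "ComplexStructure", function(object) {
  cat("ComplexStructure:", nrow(object@protein@atoms), "protein atoms,",
      nrow(object@ligandAtoms), "ligand atoms",
      if (object@apo) "(apo)" else "", "\n")
})

setMethod("show", "FeatureVector", function(object) {
  tab <- table(factor(object@blocks,
                      c("ligand", "aa_change", "environment",
                        "interactions", "plugin")))
  cat("FeatureVector (", length(object@values), " features, ",
      if (object@delta) "delta applied" else "per-structure", "):\n", sep = "")
  print(tab)
})

setMethod("show", "ScenarioReport", function(object) {
  cat("ScenarioReport for scenario", object@scenario, "\n")
  print(object@summary)
})

# ---- accessors ----

#' @describeIn MutationSet-accessors Event table of a MutationSet.
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @describeIn MutationSet-accessors Six-way mutation-type label.
#' @export
setGeneric("mutationType", function(x) standardGeneric("mutationType"))

#' Accessors for MutationSet
#'
#' @param x A [MutationSet].
#' @return `events()` the event `data.frame`; `mutationType()` the type label.
#' @name MutationSet-accessors
NULL

#' @rdname MutationSet-accessors
#' @export
setMethod("events", "MutationSet", function(x) x@events)
#' @rdname MutationSet-accessors
#' @export
setMethod("mutationType", "MutationSet", function(x) x@mtype)

#' Atom table of a structure
#' @param x A [StructureModel] or [ComplexStructure].
#' @return `data.frame` of atoms.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname atoms
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)
#' @rdname atoms
#' @export
setMethod("atoms", "ComplexStructure", function(x) x@protein@atoms)

#' Mean pLDDT of a structure model
#'
#' Per-residue confidence averaged over residues (each residue counted
#' once, using its per-residue value from the B-factor column).
#'
#' @param x A [StructureModel].
#' @return Numeric scalar.
#' @export
setGeneric("meanPlddt", function(x) standardGeneric("meanPlddt"))
#' @rdname meanPlddt
#' @export
setMethod("meanPlddt", "StructureModel", function(x) {
  mean(residuePlddt(x))
})

#' Per-residue pLDDT
#'
#' @param x A [StructureModel].
#' @return Named numeric vector, names the residue numbers.
#' @export
residuePlddt <- function(x) {
  stopifnot(is(x, "StructureModel"))
  tapply(x@atoms$b, x@atoms$resno, function(v) v[1L])[
    as.character(sort(unique(x@atoms$resno)))]
}

#' Feature values and blocks
#' @param x A [FeatureVector].
#' @return `featureValues()` the named numeric vector; `featureBlocks()`
#'   the block labels.
#' @export
featureValues <- function(x) { stopifnot(is(x, "FeatureVector")); x@values }

#' @rdname featureValues
#' @export
featureBlocks <- function(x) { stopifnot(is(x, "FeatureVector")); x@blocks }
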