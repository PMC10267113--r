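#' Construct a FeatureVector
#'
#' @param values Named numeric vector.
#' @param blocks Character vector (recycled) of block labels, one of
#'   `ligand`, `aa_change`, `environment`, `interactions`, `plugin`.
#' @param delta Whether the mt - wt convention has been applied.
#' @return A [FeatureVector].
#' @export
featureVector <- function(values, blocks, delta = FALSE) {
  new("FeatureVector", values = values,
      blocks = rep(blocks, length.out = length(values)), delta = delta)
}

#' Per-structure feature vector of one complex
#'
#' Assembles the native per-structure feature blocks for a wild-type or
#' mutant complex: the 18 absolute ligand descriptors, the 21
#' mutation-environment features and the 6 interaction counts (45
#' features). The 12 amino-acid-change features are deltas by definition
#' and are appended by [sampleFeatures()] after differencing.
#'
#' @param cx A [ComplexStructure].
#' @param sites Mutated residue numbers.
#' @param ligand Ligand specification for the descriptor block (SMILES,
#'   SDF path or parsed ligand); defaults to the posed ligand of `cx`.
#' @return A [FeatureVector] with blocks `ligand`, `environment`,
#'   `interactions`.
#' @export
complexFeatures <- function(cx, sites, ligand = NULL) {
  stopifnot(is(cx, "ComplexStructure"))
  if (is.null(ligand)) {
    if (!nrow(cx@ligandAtoms)) stop("no ligand available for descriptors")
    ligand <- list(atoms = cx@ligandAtoms, bonds = cx@ligandBonds)
  }
  ld <- ligandDescriptors(ligand)
  env <- environmentFeatures(cx, sites)
  ip <- interactionProfile(cx)
  featureVector(c(ld, env, ip),
                c(rep("ligand", length(ld)),
                  rep("environment", length(env)),
                  rep("interactions", length(ip))))
}

#' Mutant-minus-wild-type feature delta
#'
#' Applies the delta convention: the ligand block is copied verbatim
#' (asserted equal between the two inputs, the drug does not change upon
#' protein mutation); every other block becomes `mt - wt` elementwise.
#'
#' @param mt,wt [FeatureVector]s over identical feature panels.
#' @return A [FeatureVector] with `delta = TRUE`.
#' @export
featureDelta <- function(mt, wt) {
  stopifnot(is(mt, "FeatureVector"), is(wt, "FeatureVector"))
  if (!identical(names(mt@values), names(wt@values)) ||
      !identical(mt@blocks, wt@blocks))
    stop("feature panels differ between mutant and wild-type vectors")
  lig <- mt@blocks == "ligand"
  if (any(lig) && any(abs(mt@values[lig] - wt@values[lig]) > 1e-8))
    stop("ligand descriptor blocks differ between mutant and wild-type")
  out <- mt@values - wt@values
  out[lig] <- mt@values[lig]
  featureVector(out, mt@blocks, delta = TRUE)
}

#' Append plugin features under the delta convention
#'
#' Evaluates an external feature callable (e.g. a scoring-function term
#' provider) on the wild-type and mutant complexes and appends the
#' differenced outputs as the `plugin` block. The callable must return a
#' consistently named numeric vector for any complex. With `plugin =
#' NULL` the plugin block is empty and only the native features are
#' emitted.
#'
#' @param fv A delta [FeatureVector] (native blocks).
#' @param cxWt,cxMt Wild-type and mutant [ComplexStructure]s.
#' @param plugin `NULL` or `function(cx) -> named numeric`.
#' @return A [FeatureVector] including the plugin block.
#' @export
pluginFeatures <- function(fv, cxWt, cxMt, plugin = NULL) {
  stopifnot(is(fv, "FeatureVector"))
  if (is.null(plugin)) return(fv)
  wt <- plugin(cxWt); mt <- plugin(cxMt)
  if (!identical(names(wt), names(mt)) || is.null(names(wt)))
    stop("plugin output schema differs between calls")
  featureVector(c(fv@values, mt - wt),
                c(fv@blocks, rep("plugin", length(wt))), delta = fv@delta)
}

#' Full native feature vector for one mutation sample
#'
#' Composes the 57 native features of a sample: 18 absolute ligand
#' descriptors, 12 amino-acid-change deltas, 21 environment deltas and 6
#' interaction-count deltas (mt - wt), plus any plugin block.
#'
#' @param cxWt,cxMt Wild-type and mutant [ComplexStructure]s.
#' @param wtAA,mtAA One-letter codes of the substituted residue (for
#'   single substitutions); for other mutation types pass vectors of equal
#'   length and the per-site changes are averaged.
#' @param sites Mutated residue numbers.
#' @param ligand Optional ligand override for the descriptor block.
#' @param plugin Optional plugin callable, see [pluginFeatures()].
#' @return A delta [FeatureVector] of 57 native features (+ plugin).
#' @export
sampleFeatures <- function(cxWt, cxMt, wtAA, mtAA, sites, ligand = NULL,
                           plugin = NULL) {
  stopifnot(length(wtAA) == length(mtAA))
  fwt <- complexFeatures(cxWt, sites, ligand)
  fmt <- complexFeatures(cxMt, sites, ligand)
  dv <- featureDelta(fmt, fwt)
  aach <- rowMeans(vapply(seq_along(wtAA), function(i)
    aaChangeFeatures(wtAA[i], mtAA[i]), numeric(12)))
  names(aach) <- names(aaChangeFeatures(wtAA[1], mtAA[1]))
  lig <- dv@blocks == "ligand"
  vals <- c(dv@values[lig], aach, dv@values[!lig])
  blocks <- c(dv@blocks[lig], rep("aa_change", length(aach)),
              dv@blocks[!lig])
  out <- featureVector(vals, blocks, delta = TRUE)
  pluginFeatures(out, cxWt, cxMt, plugin)
}
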