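.sample_schema_version <- "mutddg-sample-1"
.feature_schema_version <- "mutddg-feature-1"

.read_tsv <- function(path, mandatory) {
  if (!file.exists(path)) stop("input file not found: ", path)
  d <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(mandatory, names(d))
  if (length(missing))
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  d
}

.write_tsv <- function(d, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read screen tables from TSV files
#'
#' Reads the three curation inputs. All files are tab-separated with a
#' header line; unknown columns are preserved. Malformed sensitivity rows
#' (non-positive or non-numeric IC50) are rejected, not fatal, and
#' returned with reasons.
#'
#' Units: IC50 in micromolar (`ic50_um`).
#'
#' @param sensitivityPath TSV with `cell_line`, `drug`, `ic50_um` and
#'   optional `source`.
#' @param mutationsPath TSV with `cell_line`, `uniprot_id`, `mutation`.
#' @param targetsPath TSV with `drug`, `uniprot_id` (one row per pair).
#' @param rejectPath Optional path to write rejected rows with a `reason`
#'   column.
#' @return List with `tables` (a [ScreenTables]) and `rejects`
#'   (`data.frame`).
#' @export
readScreenTables <- function(sensitivityPath, mutationsPath, targetsPath,
                             rejectPath = NULL) {
  sens <- .read_tsv(sensitivityPath, c("cell_line", "drug", "ic50_um"))
  sens$ic50_um <- suppressWarnings(as.numeric(sens$ic50_um))
  bad <- !is.finite(sens$ic50_um) | sens$ic50_um <= 0
  rejects <- if (any(bad)) {
    data.frame(sens[bad, , drop = FALSE], reason = "non-positive IC50")
  } else {
    data.frame()
  }
  if (!is.null(rejectPath) && nrow(rejects)) .write_tsv(rejects, rejectPath)
  sens <- sens[!bad, , drop = FALSE]
  muts <- .read_tsv(mutationsPath, c("cell_line", "uniprot_id", "mutation"))
  targ <- .read_tsv(targetsPath, c("drug", "uniprot_id"))
  list(tables = screenTables(sens, muts, targ), rejects = rejects)
}

#' Write screen tables to TSV files
#'
#' @param tables A [ScreenTables].
#' @param sensitivityPath,mutationsPath,targetsPath Output paths.
#' @return Invisibly, the three paths.
#' @export
writeScreenTables <- function(tables, sensitivityPath, mutationsPath,
                              targetsPath) {
  stopifnot(is(tables, "ScreenTables"))
  .write_tsv(tables@sensitivity, sensitivityPath,
             "units: ic50_um in micromolar")
  .write_tsv(tables@cellMutations, mutationsPath)
  .write_tsv(tables@drugTargets, targetsPath)
  invisible(c(sensitivityPath, mutationsPath, targetsPath))
}

#' Write a sample table to TSV
#'
#' Serializes curated samples in the release schema: `uniprot_id`, `drug`,
#' `mutation`, `mutation_type`, `ddg_kcal_mol` (4 d.p.), `resistant`,
#' `ic50_wt_um`, `ic50_mut_um`, `n_wt`, `n_mut`, `source`,
#' `structure_source`, with a schema-version header comment. Units:
#' energies in kcal mol^-1, concentrations in micromolar, residue indices
#' 1-based.
#'
#' @param samples Sample `data.frame` from [curateSamples()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSampleTable <- function(samples, path) {
  s <- samples
  s$ddg_kcal_mol <- sprintf("%.4f", s$ddg_kcal_mol)
  s$ic50_wt_um <- sprintf("%.6g", s$ic50_wt_um)
  s$ic50_mut_um <- sprintf("%.6g", s$ic50_mut_um)
  .write_tsv(s, path, paste0("schema: ", .sample_schema_version,
                             "; units: kcal/mol, micromolar; 1-based residues"))
}

#' Read a sample table from TSV
#'
#' @param path Path written by [writeSampleTable()].
#' @return Sample `data.frame` with typed columns.
#' @export
readSampleTable <- function(path) {
  d <- .read_tsv(path, c("uniprot_id", "drug", "mutation", "mutation_type",
                         "ddg_kcal_mol", "resistant"))
  d$ddg_kcal_mol <- as.numeric(d$ddg_kcal_mol)
  if (!is.null(d$ic50_wt_um)) d$ic50_wt_um <- as.numeric(d$ic50_wt_um)
  if (!is.null(d$ic50_mut_um)) d$ic50_mut_um <- as.numeric(d$ic50_mut_um)
  d$resistant <- as.logical(d$resistant)
  d
}

#' Write a feature matrix with its sidecar schema
#'
#' One row per sample; a sidecar file (`<path>.schema.tsv`) names every
#' feature and its block and semantics (absolute for the ligand block,
#' mt - wt delta otherwise).
#'
#' @param fvs Named list of [FeatureVector]s (names are sample ids), all
#'   over the same panel.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(fvs, path) {
  stopifnot(length(fvs) >= 1)
  panel <- names(featureValues(fvs[[1]]))
  m <- t(vapply(fvs, function(f) {
    stopifnot(identical(names(featureValues(f)), panel))
    featureValues(f)
  }, numeric(length(panel))))
  d <- data.frame(sample_id = names(fvs), m, check.names = FALSE)
  .write_tsv(d, path, paste0("schema: ", .feature_schema_version))
  blocks <- featureBlocks(fvs[[1]])
  schema <- data.frame(feature = panel, block = blocks,
                       semantics = ifelse(blocks == "ligand", "absolute",
                                          "delta_mt_minus_wt"))
  .write_tsv(schema, paste0(path, ".schema.tsv"))
  invisible(path)
}
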