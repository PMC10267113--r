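.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Configuration for a synthetic drug-sensitivity screen
#'
#' Describes a screen with planted ground-truth ddG values. The noise
#' model inverts the ddG relation: for a cell line,
#' `ln IC50 = ln base + [mutant] * ddg / (R*T) + Normal(0, noiseSigma)`,
#' so concentrations are lognormal and strictly positive, and with
#' `noiseSigma = 0` curation recovers the planted ddG exactly under any
#' averaging mode.
#'
#' @param nProteins,nDrugs Number of proteins and drugs (each drug
#'   targets one protein, cycled; a fraction gains a second target).
#' @param nWtCellLines Wild-type control cell lines per protein.
#' @param nMutCellLines Cell lines per mutant bucket.
#' @param nMutationsPerPair Planted mutations per (protein, drug) pair
#'   when `planted` is not supplied.
#' @param multiTargetFraction Fraction of drugs with a second target.
#' @param planted Optional `data.frame` with columns `uniprot_id`, `drug`,
#'   `mutation`, `ddg` overriding the generated planted map.
#' @param baseIC50 Base (wild-type) IC50 in micromolar.
#' @param noiseSigma Standard deviation of the Gaussian on ln IC50.
#' @param plantedSd Standard deviation of generated planted ddG values
#'   (kcal mol^-1).
#' @param temperature Temperature in Kelvin used for the inversion.
#' @param seed Integer seed fixing all randomness.
#' @return List of class `screenConfig`.
#' @export
screenConfig <- function(nProteins = 3, nDrugs = 3, nWtCellLines = 5,
                         nMutCellLines = 3, nMutationsPerPair = 2,
                         multiTargetFraction = 0, planted = NULL,
                         baseIC50 = 1, noiseSigma = 0.3, plantedSd = 1.5,
                         temperature = 298.15, seed = 1) {
  stopifnot(baseIC50 > 0, noiseSigma >= 0, nProteins >= 1, nDrugs >= 1)
  structure(as.list(environment()), class = "screenConfig")
}

#' Generate a synthetic screen with planted ddG
#'
#' @param cfg A [screenConfig()].
#' @return List with `tables` (a [ScreenTables]), `planted` (`data.frame`
#'   of `uniprot_id`, `drug`, `mutation`, `ddg` for every planted triple)
#'   and `targets` (the drug-target map used).
#' @export
#' @examples
#' out <- genScreen(screenConfig(noiseSigma = 0, seed = 7))
#' cur <- curateSamples(out$tables)
#' head(cur$samples)
genScreen <- function(cfg) {
  stopifnot(inherits(cfg, "screenConfig"))
  .with_seed(cfg$seed, {
    proteins <- sprintf("P%05d", seq_len(cfg$nProteins))
    drugs <- sprintf("DRUG%03d", seq_len(cfg$nDrugs))
    tmap <- data.frame(drug = drugs,
                       uniprot_id = proteins[(seq_len(cfg$nDrugs) - 1L) %%
                                             cfg$nProteins + 1L])
    n_multi <- round(cfg$multiTargetFraction * cfg$nDrugs)
    if (n_multi > 0 && cfg$nProteins > 1) {
      for (d in drugs[seq_len(n_multi)]) {
        first <- tmap$uniprot_id[tmap$drug == d][1]
        second <- sample(setdiff(proteins, first), 1)
        tmap <- rbind(tmap, data.frame(drug = d, uniprot_id = second))
      }
    }
    planted <- cfg$planted
    if (is.null(planted)) {
      rows <- list()
      for (d in drugs) {
        p <- tmap$uniprot_id[tmap$drug == d][1]
        pos <- sample(100:899, cfg$nMutationsPerPair)
        for (k in seq_len(cfg$nMutationsPerPair)) {
          ref <- sample(.aa_levels, 1)
          alt <- sample(setdiff(.aa_levels, ref), 1)
          rows[[length(rows) + 1L]] <- data.frame(
            uniprot_id = p, drug = d,
            mutation = paste0(ref, pos[k], alt),
            ddg = stats::rnorm(1, 0, cfg$plantedSd))
        }
      }
      planted <- do.call(rbind, rows)
    }
    planted$mutation <- vapply(planted$mutation, canonicalMutation,
                               character(1))
    rt <- GAS_CONSTANT_KCAL * cfg$temperature
    sens <- list(); cmut <- list()
    for (p in unique(c(tmap$uniprot_id, planted$uniprot_id))) {
      wt_lines <- sprintf("CL_%s_wt%03d", p, seq_len(cfg$nWtCellLines))
      pmut <- unique(planted$mutation[planted$uniprot_id == p])
      mut_lines <- list()
      for (m in pmut) {
        lines <- sprintf("CL_%s_m%s_%02d", p,
                         substr(digest_key(m), 1, 6), seq_len(cfg$nMutCellLines))
        mut_lines[[m]] <- lines
        for (cl in lines)
          cmut[[length(cmut) + 1L]] <- data.frame(
            cell_line = cl, uniprot_id = p, mutation = m)
      }
      for (d in tmap$drug[tmap$uniprot_id == p]) {
        for (cl in wt_lines)
          sens[[length(sens) + 1L]] <- data.frame(
            cell_line = cl, drug = d,
            ic50_um = cfg$baseIC50 *
              exp(stats::rnorm(1, 0, cfg$noiseSigma)),
            source = "synthetic")
        for (m in pmut) {
          ddg <- planted$ddg[planted$uniprot_id == p & planted$drug == d &
                             planted$mutation == m]
          eff <- if (length(ddg)) ddg[1] / rt else 0
          for (cl in mut_lines[[m]])
            sens[[length(sens) + 1L]] <- data.frame(
              cell_line = cl, drug = d,
              ic50_um = cfg$baseIC50 *
                exp(eff + stats::rnorm(1, 0, cfg$noiseSigma)),
              source = "synthetic")
        }
      }
    }
    tables <- screenTables(do.call(rbind, sens), do.call(rbind, cmut), tmap)
    list(tables = tables, planted = planted, targets = tmap)
  })
}

# short deterministic key for embedding a mutation string in identifiers
digest_key <- function(x) {
  v <- utf8ToInt(x)
  sprintf("%06x", sum(v * seq_along(v) * 131L) %% 16777216L)
}

#' Generate a random mutation corpus with controlled type composition
#'
#' Draws raw mutation strings whose six-way type composition follows the
#' given probabilities; useful for parser and statistics property tests.
#'
#' @param n Number of strings.
#' @param typeProbs Named probabilities over the six types.
#' @param seed Integer seed.
#' @return `data.frame` with `mutation` and `mutation_type` (the intended
#'   type).
#' @export
genMutationCorpus <- function(n,
    typeProbs = c(single_substitution = 0.6, multiple_substitution = 0.2,
                  deletion = 0.08, insertion = 0.04, indel = 0.04,
                  complex = 0.04),
    seed = 1) {
  stopifnot(all(names(typeProbs) %in% .mutation_types))
  .with_seed(seed, {
    sub_tok <- function(pos) {
      ref <- sample(.aa_levels, 1)
      paste0(ref, pos, sample(setdiff(.aa_levels, ref), 1))
    }
    del_tok <- function(pos, span) {
      if (span == 1) paste0(sample(.aa_levels, 1), pos, "del") else
        paste0(sample(.aa_levels, 1), pos, "_", sample(.aa_levels, 1),
               pos + span - 1, "del")
    }
    ins_tok <- function(pos)
      paste0(sample(.aa_levels, 1), pos, "_", sample(.aa_levels, 1),
             pos + 1, "ins",
             paste(sample(.aa_levels, sample(1:3, 1), replace = TRUE),
                   collapse = ""))
    indel_tok <- function(pos, span) {
      alt <- paste(sample(.aa_levels, sample(2:3, 1), replace = TRUE),
                   collapse = "")
      if (span == 1) paste0(sample(.aa_levels, 1), pos, "delins", alt) else
        paste0(sample(.aa_levels, 1), pos, "_", sample(.aa_levels, 1),
               pos + span - 1, "delins", alt)
    }
    gen_one <- function(type) {
      pos <- sort(sample(seq(10, 900, by = 10), 4))  # widely spaced
      switch(type,
        single_substitution = sub_tok(pos[1]),
        multiple_substitution = paste(sub_tok(pos[1]), sub_tok(pos[2]),
                                      sep = ","),
        deletion = del_tok(pos[1], sample(1:4, 1)),
        insertion = ins_tok(pos[1]),
        indel = indel_tok(pos[1], sample(1:4, 1)),
        complex = paste(sub_tok(pos[1]), del_tok(pos[3], sample(1:4, 1)),
                        sep = ","))
    }
    types <- sample(names(typeProbs), n, replace = TRUE, prob = typeProbs)
    data.frame(mutation = vapply(types, gen_one, character(1)),
               mutation_type = types, row.names = NULL)
  })
}

# ---- toy complexes ----

.residue_templates <- list(
  GLY = data.frame(elety = c("N", "CA", "C", "O"),
                   x = c(-1.2, 0, 1.2, 1.8), y = c(0, 0, 0, 1.0),
                   z = 0),
  ALA = data.frame(elety = c("N", "CA", "C", "O", "CB"),
                   x = c(-1.2, 0, 1.2, 1.8, 0), y = c(0, 0, 0, 1.0, 1.4),
                   z = 0),
  SER = data.frame(elety = c("N", "CA", "C", "O", "CB", "OG"),
                   x = c(-1.2, 0, 1.2, 1.8, 0, 0),
                   y = c(0, 0, 0, 1.0, 1.4, 2.8), z = 0),
  ASP = data.frame(elety = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
                   x = c(-1.2, 0, 1.2, 1.8, 0, 0, -1.1, 1.1),
                   y = c(0, 0, 0, 1.0, 1.4, 2.9, 3.6, 3.6), z = 0),
  LYS = data.frame(elety = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE",
                             "NZ"),
                   x = c(-1.2, 0, 1.2, 1.8, 0, 0, 0, 0, 0),
                   y = c(0, 0, 0, 1.0, 1.4, 2.9, 4.4, 5.9, 7.3), z = 0),
  ARG = data.frame(elety = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE",
                             "CZ", "NH1", "NH2"),
                   x = c(-1.2, 0, 1.2, 1.8, 0, 0, 0, 0, 0, -1.1, 1.1),
                   y = c(0, 0, 0, 1.0, 1.4, 2.9, 4.4, 5.8, 7.0, 7.7, 7.7),
                   z = 0),
  PHE = local({
    ang <- seq(90, 390, by = 60)[1:6] * pi / 180
    data.frame(elety = c("N", "CA", "C", "O", "CB",
                         "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
               x = c(-1.2, 0, 1.2, 1.8, 0,
                     1.39 * cos(ang[c(4, 3, 5, 2, 6, 1)])),
               y = c(0, 0, 0, 1.0, 1.4,
                     3.3 + 1.39 * sin(ang[c(4, 3, 5, 2, 6, 1)])),
               z = 0)
  }))

.rotation_matrix <- function(theta, phi) {
  rz <- matrix(c(cos(theta), -sin(theta), 0,
                 sin(theta), cos(theta), 0, 0, 0, 1), 3, byrow = TRUE)
  ry <- matrix(c(cos(phi), 0, sin(phi), 0, 1, 0,
                 -sin(phi), 0, cos(phi)), 3, byrow = TRUE)
  rz %*% ry
}

.place_residue <- function(resid, resno, center, theta = 0, phi = 0,
                           b = 90) {
  tpl <- .residue_templates[[resid]]
  if (is.null(tpl)) stop("no template for residue ", resid)
  xyz <- as.matrix(tpl[, c("x", "y", "z")]) %*% t(.rotation_matrix(theta, phi))
  data.frame(resno = resno, resid = resid, elety = tpl$elety,
             x = xyz[, 1] + center[1], y = xyz[, 2] + center[2],
             z = xyz[, 3] + center[3], b = b)
}

.ligand_templates <- list(
  benzene = list(
    atoms = data.frame(element = "C",
                       x = 1.39 * cos(seq(0, 300, 60) * pi / 180),
                       y = 1.39 * sin(seq(0, 300, 60) * pi / 180),
                       z = 0, charge = 0),
    bonds = data.frame(a1 = 1:6, a2 = c(2:6, 1),
                       order = c(2, 1, 2, 1, 2, 1))),
  acetate = list(
    atoms = data.frame(element = c("C", "C", "O", "O"),
                       x = c(0, 1.5, 2.1, 2.1),
                       y = c(0, 0, 1.05, -1.05), z = 0,
                       charge = c(0, 0, 0, -1)),
    bonds = data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4),
                       order = c(1, 2, 1))),
  methylammonium = list(
    atoms = data.frame(element = c("C", "N"), x = c(0, 1.5), y = 0, z = 0,
                       charge = c(0, 1)),
    bonds = data.frame(a1 = 1, a2 = 2, order = 1)),
  chloromethane = list(
    atoms = data.frame(element = c("C", "Cl"), x = c(0, 1.78), y = 0,
                       z = 0, charge = 0),
    bonds = data.frame(a1 = 1, a2 = 2, order = 1)),
  ethanol = list(
    atoms = data.frame(element = c("C", "C", "O"), x = c(0, 1.5, 2.2),
                       y = c(0, 0, 1.2), z = 0, charge = 0),
    bonds = data.frame(a1 = c(1, 2), a2 = c(2, 3), order = 1)))

#' Specification of a toy protein-ligand complex
#'
#' Defines an exactly realizable toy geometry: a mutation-site residue
#' (side-chain centroid at the origin), lone-atom protein shell residues
#' at prescribed distances from the site point, optional full-residue
#' neighbors, and a ligand assembled from small templates placed at a
#' prescribed distance.
#'
#' @param siteResidue Residue type of the mutation site (default `"ALA"`).
#' @param siteResno Residue number of the site.
#' @param shellDistances Numeric vector: one lone-CA protein shell atom is
#'   placed at each distance from the site point.
#' @param neighborResidues Optional `data.frame` with columns `resid`,
#'   `distance` placing full template residues with C-alpha at the given
#'   distance in a random direction.
#' @param ligandTemplate One of `"benzene"`, `"acetate"`,
#'   `"methylammonium"`, `"chloromethane"`, `"ethanol"`, or `"none"`.
#' @param ligandDistance Distance from the site point to the first ligand
#'   atom.
#' @param plddt B-factor / pLDDT assigned to all atoms.
#' @param seed Seed fixing the random placement directions.
#' @return List of class `toyComplexSpec`.
#' @export
toyComplexSpec <- function(siteResidue = "ALA", siteResno = 50,
                           shellDistances = c(3, 3, 3, 5, 7),
                           neighborResidues = NULL,
                           ligandTemplate = "benzene",
                           ligandDistance = 5, plddt = 90, seed = 1) {
  stopifnot(siteResidue %in% names(.residue_templates),
            ligandTemplate %in% c(names(.ligand_templates), "none"))
  structure(as.list(environment()), class = "toyComplexSpec")
}

#' Generate a toy protein-ligand complex
#'
#' Realizes a [toyComplexSpec()] as an in-memory [ComplexStructure] and,
#' optionally, as PDB and SDF files parseable by [readStructure()] and
#' [readLigandSDF()]. Shell atoms are placed exactly at their prescribed
#' distances from the mutation-site point, so intended shell counts are
#' realized by construction.
#'
#' @param spec A [toyComplexSpec()].
#' @param pdbPath,sdfPath Optional output paths.
#' @return List with `complex` (a [ComplexStructure]), `site` (the site
#'   residue number), `sitePoint` (coordinates of the site reference
#'   point), and the file paths when written.
#' @export
genToyComplex <- function(spec, pdbPath = NULL, sdfPath = NULL) {
  stopifnot(inherits(spec, "toyComplexSpec"))
  .with_seed(spec$seed, {
    rand_dir <- function() {
      v <- stats::rnorm(3)
      v / sqrt(sum(v^2))
    }
    site <- .place_residue(spec$siteResidue, spec$siteResno, c(0, 0, 0),
                           b = spec$plddt)
    # shift so that the side-chain centroid sits at the origin
    sc <- site[!site$elety %in% .backbone_atoms, , drop = FALSE]
    ref <- if (nrow(sc)) colMeans(as.matrix(sc[, c("x", "y", "z")])) else
      as.numeric(site[site$elety == "CA", c("x", "y", "z")])
    site$x <- site$x - ref[1]; site$y <- site$y - ref[2]
    site$z <- site$z - ref[3]
    atoms <- site
    rn <- spec$siteResno
    for (d in spec$shellDistances) {
      rn <- rn + 1L
      u <- rand_dir() * d
      atoms <- rbind(atoms, data.frame(resno = rn, resid = "GLY",
                                       elety = "CA", x = u[1], y = u[2],
                                       z = u[3], b = spec$plddt))
    }
    if (!is.null(spec$neighborResidues)) {
      for (i in seq_len(nrow(spec$neighborResidues))) {
        rn <- rn + 1L
        u <- rand_dir() * spec$neighborResidues$distance[i]
        atoms <- rbind(atoms, .place_residue(
          spec$neighborResidues$resid[i], rn, u,
          theta = stats::runif(1, 0, 2 * pi),
          phi = stats::runif(1, 0, pi), b = spec$plddt))
      }
    }
    prot <- new("StructureModel", atoms = atoms, provenance = "predicted")
    lig <- NULL
    if (spec$ligandTemplate != "none") {
      tpl <- .ligand_templates[[spec$ligandTemplate]]
      u <- rand_dir() * spec$ligandDistance
      la <- tpl$atoms
      la$x <- la$x - la$x[1] + u[1]
      la$y <- la$y - la$y[1] + u[2]
      la$z <- la$z - la$z[1] + u[3]
      lig <- list(atoms = la, bonds = tpl$bonds)
    }
    cx <- complexStructure(prot, lig)
    out <- list(complex = cx, site = spec$siteResno, sitePoint = c(0, 0, 0))
    if (!is.null(pdbPath)) {
      writeStructure(prot, pdbPath)
      out$pdbPath <- pdbPath
    }
    if (!is.null(sdfPath) && !is.null(lig)) {
      writeLigandSDF(lig, sdfPath)
      out$sdfPath <- sdfPath
    }
    out
  })
}

#' Generate a synthetic feature table with linear signal
#'
#' Produces a feature matrix `X` with standard-normal entries, targets
#' `y = X w + Normal(0, noiseSigma)`, and a tagged sample table arranged
#' so every benchmark scenario filter is non-degenerate: a `tki`-tagged
#' test stratum, `platinum`-tagged rows with and without the
#' tyrosine-kinase protein flag, a `gdsc` stratum, and a sprinkling of
#' non-substitution mutation types outside the test set.
#'
#' @param n Number of samples.
#' @param weights Numeric coefficient vector (its length sets the feature
#'   count).
#' @param noiseSigma Noise standard deviation on y.
#' @param seed Integer seed.
#' @param tkiFraction,platinumFraction Fractions of rows tagged `tki`
#'   and `platinum` (the remainder is `gdsc`).
#' @param resistantFraction Optional target fraction of resistant labels;
#'   when given, y is shifted so the empirical resistant prevalence
#'   matches it.
#' @return List with `features` (matrix), `ddg` (numeric), `samples`
#'   (tagged sample `data.frame` including `ddg_kcal_mol` and
#'   `resistant`).
#' @export
genFeatureTable <- function(n, weights = c(1.5, -1, 0.8, 0, 0.5),
                            noiseSigma = 0.2, seed = 1,
                            tkiFraction = 0.2, platinumFraction = 0.4,
                            resistantFraction = NULL) {
  stopifnot(n >= 1)
  .with_seed(seed, {
    p <- length(weights)
    x <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    y <- as.numeric(x %*% weights) + stats::rnorm(n, 0, noiseSigma)
    if (!is.null(resistantFraction))
      y <- y - stats::quantile(y, 1 - resistantFraction) + RESISTANCE_THRESHOLD +
        1e-9
    src <- rep("gdsc", n)
    n_tki <- max(1L, round(tkiFraction * n))
    n_plat <- max(2L, round(platinumFraction * n))
    src[seq_len(n_tki)] <- "tki"
    src[n_tki + seq_len(min(n_plat, n - n_tki))] <- "platinum"
    tk <- rep(FALSE, n)
    plat_idx <- which(src == "platinum")
    tk[src == "tki"] <- TRUE
    if (length(plat_idx) > 1)
      tk[plat_idx[seq_len(floor(length(plat_idx) / 3))]] <- TRUE
    mtype <- rep("single_substitution", n)
    non_tki <- which(src != "tki")
    if (length(non_tki) >= 10) {
      picks <- non_tki[seq_len(max(1L, floor(length(non_tki) * 0.1)))]
      mtype[picks] <- rep(c("deletion", "insertion", "indel", "complex",
                            "multiple_substitution"),
                          length.out = length(picks))
    }
    samples <- data.frame(
      sample_id = sprintf("S%05d", seq_len(n)),
      uniprot_id = sprintf("P%05d", (seq_len(n) - 1L) %% 20 + 1L),
      drug = sprintf("DRUG%03d", (seq_len(n) - 1L) %% 10 + 1L),
      mutation = sprintf("A%dG", seq_len(n) * 7L),
      mutation_type = mtype,
      source = src, tyrosine_kinase = tk,
      ddg_kcal_mol = y, resistant = labelResistant(y))
    list(features = x, ddg = y, samples = samples)
  })
}
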