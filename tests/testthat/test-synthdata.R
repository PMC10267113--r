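test_that("noise-free screens are recovered exactly", {
  out <- genScreen(screenConfig(noiseSigma = 0, seed = 7))
  cur <- curateSamples(out$tables)
  s <- cur$samples
  expect_true(nrow(s) == nrow(out$planted))
  merged <- merge(s, out$planted,
                  by = c("uniprot_id", "drug", "mutation"))
  expect_equal(nrow(merged), nrow(out$planted))
  expect_true(max(abs(merged$ddg_kcal_mol - merged$ddg)) <= 1e-9)
  # nothing is excluded in a clean noise-free screen
  excl <- cur$log[c("drug_without_targets", "multi_target_discard",
                    "unparseable_mutation", "no_wildtype_control",
                    "no_mutant_bucket")]
  expect_true(all(excl == 0L))
})

test_that("screen generation is seed-deterministic and seed-sensitive", {
  a <- genScreen(screenConfig(seed = 5))
  b <- genScreen(screenConfig(seed = 5))
  c <- genScreen(screenConfig(seed = 6))
  expect_identical(a$tables@sensitivity, b$tables@sensitivity)
  expect_identical(a$planted, b$planted)
  expect_false(identical(a$tables@sensitivity$ic50_um,
                         c$tables@sensitivity$ic50_um))
  # generators restore the caller's RNG state
  set.seed(123); before <- .Random.seed
  invisible(genScreen(screenConfig(seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("recovery error shrinks as cell-line counts grow", {
  err_for <- function(n_lines) {
    errs <- vapply(1:8, function(seed) {
      cfg <- screenConfig(nProteins = 1, nDrugs = 1, nMutationsPerPair = 2,
                          nWtCellLines = n_lines, nMutCellLines = n_lines,
                          noiseSigma = 0.3, seed = seed)
      out <- genScreen(cfg)
      s <- curateSamples(out$tables, averaging = "geometric")$samples
      merged <- merge(s, out$planted,
                      by = c("uniprot_id", "drug", "mutation"))
      mean(abs(merged$ddg_kcal_mol - merged$ddg))
    }, numeric(1))
    mean(errs)
  }
  e2 <- err_for(2); e8 <- err_for(8); e32 <- err_for(32)
  expect_true(e8 < e2)
  expect_true(e32 < e8)
})

test_that("multi-target screens exercise the exclusivity path", {
  cfg <- screenConfig(nProteins = 3, nDrugs = 4, multiTargetFraction = 0.5,
                      noiseSigma = 0, seed = 13)
  out <- genScreen(cfg)
  # at least one drug has two targets
  t_per_drug <- table(out$targets$drug)
  expect_true(any(t_per_drug >= 2))
  cur <- curateSamples(out$tables)
  # planted ddGs still recovered exactly for their own (drug, protein) pair
  merged <- merge(cur$samples, out$planted,
                  by = c("uniprot_id", "drug", "mutation"))
  expect_true(nrow(merged) >= 1)
  expect_true(max(abs(merged$ddg_kcal_mol - merged$ddg)) <= 1e-9)
})

test_that("mutation corpus respects requested type composition", {
  corpus <- genMutationCorpus(400, typeProbs = c(deletion = 0.5,
                                                 insertion = 0.5),
                              seed = 2)
  expect_setequal(unique(corpus$mutation_type), c("deletion", "insertion"))
  expect_identical(corpus, genMutationCorpus(400,
    typeProbs = c(deletion = 0.5, insertion = 0.5), seed = 2))
})

test_that("toy complexes realize their spec exactly", {
  spec <- toyComplexSpec(shellDistances = c(3, 5, 7), seed = 17)
  toy <- genToyComplex(spec)
  pa <- atoms(toy$complex)
  expect_identical(toy$sitePoint, c(0, 0, 0))
  shell <- pa[pa$resid == "GLY" & pa$elety == "CA" &
              pa$resno != toy$site, , drop = FALSE]
  d <- sort(sqrt(shell$x^2 + shell$y^2 + shell$z^2))
  expect_equal(d, c(3, 5, 7), tolerance = 1e-12)
  # the realized complex matches its written files
  pdb <- tempfile(fileext = ".pdb"); sdf <- tempfile(fileext = ".sdf")
  toy2 <- genToyComplex(spec, pdbPath = pdb, sdfPath = sdf)
  reread <- complexStructure(readStructure(pdb, provenance = "predicted"),
                             sdf)
  expect_equal(atoms(reread)$x, atoms(toy2$complex)$x, tolerance = 1e-3)
  expect_equal(reread@ligandAtoms$element,
               toy2$complex@ligandAtoms$element)
  unlink(c(pdb, sdf))
})

test_that("feature tables carry the advertised linear signal", {
  w <- c(2, -1)
  gen <- genFeatureTable(500, weights = w, noiseSigma = 0, seed = 19)
  expect_equal(gen$ddg, as.numeric(gen$features %*% w))
  expect_equal(gen$samples$ddg_kcal_mol, gen$ddg)
  expect_equal(gen$samples$resistant, gen$ddg > RESISTANCE_THRESHOLD)
  # a requested resistant prevalence is hit
  gen2 <- genFeatureTable(1000, resistantFraction = 0.25, seed = 20)
  expect_equal(mean(gen2$samples$resistant), 0.25, tolerance = 0.02)
  # every scenario stratum is populated
  expect_true(all(c("tki", "platinum", "gdsc") %in% gen2$samples$source))
  expect_true(any(gen2$samples$tyrosine_kinase) &&
              any(!gen2$samples$tyrosine_kinase))
})
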