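test_that("computeDdg matches the analytic form and is additive", {
  const <- thermoConstants()
  expect_equal(const$R, 1.9872e-3)
  expect_equal(const$T, 298.15)
  # antisymmetry and additivity over chained ratios
  expect_equal(computeDdg(5, 2), -computeDdg(2, 5), tolerance = 1e-12)
  expect_equal(computeDdg(8, 2), computeDdg(8, 4) + computeDdg(4, 2),
               tolerance = 1e-10)
  expect_equal(computeDdg(1, 1), 0)
  expect_error(computeDdg(0, 1), "positive")
  expect_error(computeDdg(1, -2), "positive")
})

test_that("a 10-fold ratio sits exactly at the resistance boundary", {
  d10 <- computeDdg(10, 1)
  expect_equal(round(d10, 2), 1.36)
  expect_equal(RESISTANCE_THRESHOLD, 1.36)
  # strictly-greater labelling: the rounded boundary value itself is not
  # resistant, anything above is
  expect_false(labelResistant(1.36))
  expect_true(labelResistant(d10))       # 1.3637... > 1.36
  expect_true(labelResistant(1.3601))
  expect_false(labelResistant(-5))
  expect_error(labelResistant(NaN), "finite")
})

test_that("IC50 aggregation modes behave as documented", {
  expect_equal(aggregateIC50(c(1, 2, 3)), 2)
  expect_equal(aggregateIC50(c(1, 100), mode = "geometric"), 10)
  expect_equal(aggregateIC50(5), 5)
  expect_error(aggregateIC50(numeric(0)), "empty")
  expect_error(aggregateIC50(c(1, -1)), "positive")
})

test_that("cell lines group into wild-type and canonical mutant buckets", {
  tables <- screenTables(
    sensitivity = data.frame(
      cell_line = c("wt1", "wt2", "mA1", "mA2", "mBad"),
      drug = "D1", ic50_um = 1),
    cellMutations = data.frame(
      cell_line = c("mA1", "mA2", "mA2", "mBad"),
      uniprot_id = "P1",
      # mA1 and mA2 carry the same mutations written differently
      mutation = c("K601N,V600E", "V600E", "K601N", "garbage!!")),
    drugTargets = data.frame(drug = "D1", uniprot_id = "P1"))
  grp <- groupCellLines("P1", tables)
  expect_setequal(grp$wildType, c("wt1", "wt2"))
  expect_equal(names(grp$mutant), "V600E,K601N")
  expect_setequal(grp$mutant[["V600E,K601N"]], c("mA1", "mA2"))
  # a cell line whose only mutation fails to parse is neither wt nor mutant
  expect_equal(grp$unparseable, "mBad")
})

test_that("target exclusivity discards doubly-mutated lines only", {
  tables <- screenTables(
    sensitivity = data.frame(cell_line = c("c1", "c2", "c3"),
                             drug = "D1", ic50_um = 1),
    cellMutations = data.frame(
      cell_line = c("c2", "c3", "c3"),
      uniprot_id = c("P1", "P1", "P2"),
      mutation = c("V600E", "V600E", "T315I")),
    drugTargets = data.frame(drug = "D1", uniprot_id = c("P1", "P2")))
  expect_true(targetExclusivityFilter("D1", "c1", tables))   # wild-type
  expect_true(targetExclusivityFilter("D1", "c2", tables))   # one target
  expect_false(targetExclusivityFilter("D1", "c3", tables))  # two targets
  expect_error(targetExclusivityFilter("D9", "c1", tables), "no known")
})

test_that("curation reproduces a hand-computed worked example", {
  # wt replicates average to 2; mutant cell lines average to 20 and 20,
  # cross-line average 20 -> ratio 10 -> ddG = 1.3637..., resistant
  tables <- screenTables(
    sensitivity = data.frame(
      cell_line = c("wt1", "wt1", "wt2", "wt3", "m1", "m2"),
      drug = "D1",
      ic50_um = c(1, 3, 2, 2, 20, 20)),
    cellMutations = data.frame(cell_line = c("m1", "m2"), uniprot_id = "P1",
                               mutation = "V600E"),
    drugTargets = data.frame(drug = "D1", uniprot_id = "P1"))
  cur <- curateSamples(tables)
  s <- cur$samples
  expect_equal(nrow(s), 1L)
  expect_equal(s$mutation, "V600E")
  expect_equal(s$mutation_type, "single_substitution")
  expect_equal(s$ic50_wt_um, 2)
  expect_equal(s$ic50_mut_um, 20)
  expect_equal(s$ddg_kcal_mol, computeDdg(10, 1), tolerance = 1e-12)
  expect_true(s$resistant)
  expect_equal(s$n_wt, 3L)
  expect_equal(s$n_mut, 2L)
  expect_equal(unname(cur$log["emitted_samples"]), 1L)
  # all 6 sensitivity records feed the one emitted sample
  expect_equal(unname(cur$log["sensitivity_records_used"]), 6L)
})

test_that("curation log partitions the sensitivity records", {
  out <- genScreen(screenConfig(nProteins = 2, nDrugs = 3,
                                multiTargetFraction = 0.5, seed = 11))
  tables <- out$tables
  # corrupt one cell line's mutation and add a drug with no targets
  tables@cellMutations$mutation[1] <- "not-a-mutation"
  extra <- data.frame(cell_line = "orphan", drug = "DRUG_NO_TARGET",
                      ic50_um = 1, source = "synthetic")
  tables@sensitivity <- rbind(tables@sensitivity, extra)
  cur <- curateSamples(tables)
  log <- cur$log
  expect_true(log["unparseable_mutation"] > 0)
  expect_equal(unname(log["drug_without_targets"]), 1L)
  # every (drug, target) stream classifies each record exactly once, so
  # the log categories (less the emitted-sample counter) sum to at least
  # the number of sensitivity records
  expect_true(sum(log[setdiff(names(log), "emitted_samples")]) >=
              nrow(tables@sensitivity))
  expect_equal(unname(log["emitted_samples"]), nrow(cur$samples))
})

test_that("geometric averaging is equivalent for replicate-free screens", {
  out <- genScreen(screenConfig(noiseSigma = 0, seed = 3))
  a <- curateSamples(out$tables, averaging = "arithmetic")$samples
  g <- curateSamples(out$tables, averaging = "geometric")$samples
  # with sigma = 0 every cell line in a bucket has an identical IC50, so
  # the averaging mode cannot matter
  expect_equal(a$ddg_kcal_mol, g$ddg_kcal_mol, tolerance = 1e-12)
})

test_that("CoreSet dedup keeps the best structure source, first seen", {
  s <- data.frame(
    uniprot_id = "P1", drug = "D1", mutation = "V600E",
    mutation_type = "single_substitution",
    ddg_kcal_mol = c(1, 2, 3, 4), resistant = FALSE,
    ic50_wt_um = 1, ic50_mut_um = 1, n_wt = 1L, n_mut = 1L,
    source = "s",
    structure_source = c("docked", "cocrystal", "pymol_mutated",
                         "cocrystal"))
  out <- coresetDedup(s)
  expect_equal(nrow(out), 1L)
  expect_equal(out$ddg_kcal_mol, 2)  # first cocrystal wins
  # distinct triples are all kept, in first-seen order
  s2 <- s
  s2$drug <- c("D1", "D2", "D3", "D4")
  expect_equal(nrow(coresetDedup(s2)), 4L)
  expect_equal(coresetDedup(s2)$drug, c("D1", "D2", "D3", "D4"))
  expect_equal(nrow(coresetDedup(s[0, ])), 0L)
})

test_that("pLDDT filter applies the global and site rules", {
  mk <- function(b) new("StructureModel", provenance = "predicted",
    atoms = data.frame(resno = seq_along(b), resid = "ALA", elety = "CA",
                       x = 0, y = 0, z = 0, b = b))
  # mean 80, all sites fine
  f <- plddtFilter(mk(c(80, 80, 80)), 2)
  expect_true(f$pass)
  expect_equal(f$reason, "")
  # mean exactly 70 fails the strict global rule
  f <- plddtFilter(mk(c(70, 70, 70)), 2)
  expect_false(f$pass)
  expect_equal(f$reason, "global")
  # good mean but a poorly predicted site (pLDDT < 50)
  f <- plddtFilter(mk(c(95, 49, 95)), 2)
  expect_false(f$pass)
  expect_equal(f$reason, "site")
  # site pLDDT exactly 50 passes (strictly-below-50 fails)
  f <- plddtFilter(mk(c(95, 50, 95)), 2)
  expect_true(f$pass)
  expect_error(plddtFilter(mk(c(80, 80)), 99), "absent")
  exp_model <- new("StructureModel", provenance = "experimental",
                   atoms = mk(80)@atoms)
  expect_error(plddtFilter(exp_model, 1), "predicted models only")
})

test_that("alignment mask needs pLDDT > 70 in both models", {
  mk <- function(b) new("StructureModel", provenance = "predicted",
    atoms = data.frame(resno = seq_along(b), resid = "ALA", elety = "CA",
                       x = 0, y = 0, z = 0, b = b))
  wt <- mk(c(90, 60, 75, 72, 90))
  mt <- mk(c(90, 95, 65, 80, 90))
  # residue 2 fails in wt, residue 3 fails in mt, residue 1 is mutated
  expect_equal(alignmentResidueMask(wt, mt, mutatedSites = 1), c(4L, 5L))
  expect_equal(alignmentResidueMask(wt, mt), c(1L, 4L, 5L))
  low <- mk(c(10, 10, 10, 10, 10))
  expect_warning(res <- alignmentResidueMask(low, low), "no residues")
  expect_length(res, 0)
})
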