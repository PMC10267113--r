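# manual minimal residue builders for constructed interaction fixtures
.mk_prot <- function(atoms) {
  new("StructureModel", atoms = atoms, provenance = "predicted")
}

.asp_at <- function(resno = 1, b = 90) {
  data.frame(resno = resno, resid = "ASP",
             elety = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
             x = c(-1.2, 0, 1.2, 1.8, 0, 0, -1.1, 1.1),
             y = c(0, 0, 0, 1.0, 1.4, 2.9, 3.6, 3.6), z = 0, b = b)
}

test_that("aa-change features are antisymmetric with hand-checked values", {
  gw <- aaChangeFeatures("G", "W")
  expect_length(gw, 12L)
  expect_equal(unname(gw["d_side_chain_heavy_atoms"]), 10)  # 0 -> 10
  expect_equal(unname(gw["d_aromatic"]), 1)
  expect_equal(gw, -aaChangeFeatures("W", "G"))
  de <- aaChangeFeatures("D", "K")
  expect_equal(unname(de["d_formal_charge"]), 2)  # -1 -> +1
  expect_equal(unname(aaChangeFeatures("A", "A")["d_hydropathy"]), 0)
  expect_error(aaChangeFeatures("B", "A"), "unknown")
  # hydropathy delta straight from the Kyte-Doolittle scale
  expect_equal(unname(aaChangeFeatures("I", "R")["d_hydropathy"]),
               -4.5 - 4.5)
})

test_that("exactly-placed shell atoms give exact environment counts", {
  toy <- genToyComplex(toyComplexSpec(shellDistances = c(3, 3, 3, 5, 7),
                                      ligandTemplate = "none", seed = 5))
  env <- environmentFeatures(toy$complex, toy$site)
  expect_equal(unname(env["prot_atoms_4A"]), 3)
  expect_equal(unname(env["prot_atoms_6A"]), 4)
  expect_equal(unname(env["prot_atoms_8A"]), 5)
  expect_equal(unname(env["prot_atoms_12A"]), 5)
  expect_equal(unname(env["res6_total"]), 4)
  expect_equal(unname(env["res6_special"]), 4)       # lone-CA shells are GLY
  expect_equal(unname(env["backbone_atoms_6A"]), 4)  # CA is backbone
  expect_equal(unname(env["sidechain_atoms_6A"]), 0)
  expect_equal(unname(env["buriedness_8A"]), 5 / (4 / 3 * pi * 8^3))
  # apo sentinel values
  expect_equal(unname(env["min_lig_dist"]), 99.0)
  expect_equal(unname(env["lig_centroid_dist"]), 99.0)
  expect_equal(unname(env["lig_atoms_8A"]), 0)
})

test_that("shell counts are monotone in radius on random complexes", {
  for (seed in 1:10) {
    toy <- genToyComplex(random_toy_spec(seed))
    env <- environmentFeatures(toy$complex, toy$site)
    expect_true(env["prot_atoms_4A"] <= env["prot_atoms_6A"])
    expect_true(env["prot_atoms_6A"] <= env["prot_atoms_8A"])
    expect_true(env["prot_atoms_8A"] <= env["prot_atoms_12A"])
    expect_true(env["lig_atoms_4A"] <= env["lig_atoms_6A"])
    expect_true(env["lig_atoms_6A"] <= env["lig_atoms_8A"])
    expect_true(env["res6_total"] ==
                sum(env[c("res6_positively_charged", "res6_negatively_charged",
                          "res6_polar", "res6_hydrophobic", "res6_special")]))
  }
})

test_that("environment and interactions are rigid-motion invariant", {
  rot <- function(theta) matrix(c(cos(theta), -sin(theta), 0,
                                  sin(theta), cos(theta), 0,
                                  0, 0, 1), 3, byrow = TRUE)
  move <- function(cx, R, t) {
    pa <- cx@protein@atoms
    pxyz <- as.matrix(pa[, c("x", "y", "z")]) %*% t(R)
    pa$x <- pxyz[, 1] + t[1]; pa$y <- pxyz[, 2] + t[2]
    pa$z <- pxyz[, 3] + t[3]
    la <- cx@ligandAtoms
    if (nrow(la)) {
      lxyz <- as.matrix(la[, c("x", "y", "z")]) %*% t(R)
      la$x <- lxyz[, 1] + t[1]; la$y <- lxyz[, 2] + t[2]
      la$z <- lxyz[, 3] + t[3]
    }
    new("ComplexStructure",
        protein = new("StructureModel", atoms = pa,
                      provenance = cx@protein@provenance),
        ligandAtoms = la, ligandBonds = cx@ligandBonds, apo = cx@apo)
  }
  toy <- genToyComplex(toyComplexSpec(ligandTemplate = "benzene",
                                      ligandDistance = 4, seed = 8))
  moved <- move(toy$complex, rot(0.7), c(13.5, -4.2, 7.7))
  expect_equal(environmentFeatures(moved, toy$site),
               environmentFeatures(toy$complex, toy$site), tolerance = 1e-9)
  expect_equal(interactionProfile(moved), interactionProfile(toy$complex))
})

test_that("interaction profile is all zero for apo complexes", {
  toy <- genToyComplex(toyComplexSpec(ligandTemplate = "none", seed = 2))
  ip <- interactionProfile(toy$complex)
  expect_equal(sum(ip), 0)
  expect_named(ip, c("hbonds", "hydrophobic_contacts", "salt_bridges",
                     "pi_stacking", "cation_pi", "halogen_bonds"))
})

test_that("a constructed salt bridge is detected once", {
  # ASP carboxylate centroid at (0, 3.6, 0); methylammonium N+ at
  # (1.5, 6, 0): distance sqrt(1.5^2 + 2.4^2) = 2.83 <= 5.5
  prot <- .mk_prot(.asp_at())
  lig <- list(atoms = data.frame(element = c("C", "N"), x = c(0, 1.5),
                                 y = 6, z = 0, charge = c(0, 1)),
              bonds = data.frame(a1 = 1, a2 = 2, order = 1))
  cx <- complexStructure(prot, lig)
  expect_equal(unname(interactionProfile(cx)["salt_bridges"]), 1)
  # move the ligand out of range: no salt bridge
  lig$atoms$y <- lig$atoms$y + 20
  # keep the complex holo by construction for the negative control
  cx2 <- new("ComplexStructure", protein = prot,
             ligandAtoms = lig$atoms, ligandBonds = lig$bonds, apo = FALSE)
  expect_equal(unname(interactionProfile(cx2)["salt_bridges"]), 0)
})

test_that("a constructed hydrogen bond is detected", {
  ser <- data.frame(resno = 1, resid = "SER",
                    elety = c("N", "CA", "C", "O", "CB", "OG"),
                    x = c(-1.2, 0, 1.2, 1.8, 0, 0),
                    y = c(0, 0, 0, 1.0, 1.4, 2.8), z = 0, b = 90)
  # ethanol oxygen 3.0 Angstrom above the serine OG
  lig <- list(atoms = data.frame(element = c("C", "C", "O"),
                                 x = c(-2.2, -0.7, 0),
                                 y = c(4.6, 4.6, 5.8), z = 0, charge = 0),
              bonds = data.frame(a1 = c(1, 2), a2 = c(2, 3), order = 1))
  cx <- complexStructure(.mk_prot(ser), lig)
  d <- sqrt(sum((c(0, 2.8, 0) - c(0, 5.8, 0))^2))
  expect_equal(d, 3.0)
  expect_equal(unname(interactionProfile(cx)["hbonds"]), 1)
})

test_that("a constructed parallel pi-stack is detected", {
  ang <- seq(90, 390, by = 60)[1:6] * pi / 180
  phe <- data.frame(resno = 1, resid = "PHE",
                    elety = c("N", "CA", "C", "O", "CB",
                              "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                    x = c(-1.2, 0, 1.2, 1.8, 0,
                          1.39 * cos(ang[c(4, 3, 5, 2, 6, 1)])),
                    y = c(0, 0, 0, 1.0, 1.4,
                          3.3 + 1.39 * sin(ang[c(4, 3, 5, 2, 6, 1)])),
                    z = 0, b = 90)
  benz <- list(
    atoms = data.frame(element = "C",
                       x = 1.39 * cos(seq(0, 300, 60) * pi / 180),
                       y = 3.3 + 1.39 * sin(seq(0, 300, 60) * pi / 180),
                       z = 3.5, charge = 0),
    bonds = data.frame(a1 = 1:6, a2 = c(2:6, 1),
                       order = c(2, 1, 2, 1, 2, 1)))
  cx <- complexStructure(.mk_prot(phe), benz)
  ip <- interactionProfile(cx)
  expect_equal(unname(ip["pi_stacking"]), 1)
  expect_equal(unname(ip["cation_pi"]), 0)
  expect_true(ip["hydrophobic_contacts"] > 0)  # stacked carbons within 4 A
})

test_that("a constructed halogen bond is detected", {
  # chloromethane Cl 3.2 Angstrom from the ASP OD1 acceptor at (-1.1, 3.6, 0)
  prot <- .mk_prot(.asp_at())
  lig <- list(atoms = data.frame(element = c("C", "Cl"),
                                 x = c(-1.1 - 1.78, -1.1),
                                 y = c(6.8, 6.8), z = 0, charge = 0),
              bonds = data.frame(a1 = 1, a2 = 2, order = 1))
  cx <- complexStructure(prot, lig)
  expect_equal(unname(interactionProfile(cx)["halogen_bonds"]), 1)
})

test_that("feature vectors compose, difference and accept plugins", {
  toyW <- genToyComplex(toyComplexSpec(siteResidue = "ALA", seed = 4))
  toyM <- genToyComplex(toyComplexSpec(siteResidue = "SER", seed = 4))
  # identical seeds: the ligand pose and shells coincide, only the site
  # residue differs
  fv <- sampleFeatures(toyW$complex, toyM$complex, "A", "S", toyW$site)
  expect_s4_class(fv, "FeatureVector")
  expect_length(featureValues(fv), 57L)
  expect_equal(as.integer(table(factor(featureBlocks(fv),
    c("ligand", "aa_change", "environment", "interactions", "plugin")))),
    c(18L, 12L, 21L, 6L, 0L))
  expect_true(fv@delta)
  # aa-change block equals the direct computation
  expect_equal(featureValues(fv)[featureBlocks(fv) == "aa_change"],
               aaChangeFeatures("A", "S"))
  # ligand block is absolute (copied), not differenced to zero
  lig_vals <- featureValues(fv)[featureBlocks(fv) == "ligand"]
  expect_true(lig_vals["heavy_atoms"] > 0)

  # swapping mutant and wild type flips all delta blocks
  fv_rev <- sampleFeatures(toyM$complex, toyW$complex, "S", "A", toyW$site)
  non_lig <- featureBlocks(fv) != "ligand"
  expect_equal(featureValues(fv)[non_lig], -featureValues(fv_rev)[non_lig],
               tolerance = 1e-9)
  expect_equal(featureValues(fv)[!non_lig], featureValues(fv_rev)[!non_lig])

  # plugin block under the same delta convention
  plug <- function(cx) c(n_prot_atoms = nrow(atoms(cx)))
  fvp <- sampleFeatures(toyW$complex, toyM$complex, "A", "S", toyW$site,
                        plugin = plug)
  expect_length(featureValues(fvp), 58L)
  expect_equal(unname(featureValues(fvp)["n_prot_atoms"]),
               nrow(atoms(toyM$complex)) - nrow(atoms(toyW$complex)))
  bad_plug <- function(cx) stats::setNames(1, paste0("f", nrow(atoms(cx))))
  expect_error(sampleFeatures(toyW$complex, toyM$complex, "A", "S",
                              toyW$site, plugin = bad_plug), "schema")
})

test_that("featureDelta refuses mismatched panels and ligands", {
  a <- featureVector(c(x = 1, y = 2), c("ligand", "environment"))
  b <- featureVector(c(x = 1, y = 5), c("ligand", "environment"))
  d <- featureDelta(b, a)
  expect_equal(unname(featureValues(d)), c(1, 3))
  expect_true(d@delta)
  c1 <- featureVector(c(x = 9, y = 5), c("ligand", "environment"))
  expect_error(featureDelta(c1, a), "ligand descriptor blocks differ")
  c2 <- featureVector(c(z = 1, y = 5), c("ligand", "environment"))
  expect_error(featureDelta(c2, a), "panels differ")
})
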