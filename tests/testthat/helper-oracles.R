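# Independent brute-force oracles for the geometric feature code.
#
# Every distance computation here is a plain double loop over atoms
# (O(N^2) scans with explicit sqrt(sum((a - b)^2))), written without the
# vectorized machinery of the package, so agreement between the two is a
# meaningful check. Typing tables (donor/acceptor atom names and so on)
# are shared with the package on purpose: the rules are definitions, the
# scans are what the oracle re-derives.

.o_dist <- function(a, b) sqrt(sum((as.numeric(a) - as.numeric(b))^2))

.o_three2one <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.o_backbone <- c("N", "CA", "C", "O", "OXT")

.o_element <- function(elety) {
  e <- sub("^[0-9]*", "", trimws(elety))
  f2 <- substr(e, 1, 2)
  ifelse(f2 %in% c("CL", "BR", "FE", "ZN", "MG", "SE"), f2, substr(e, 1, 1))
}

# site reference point: side-chain centroid, CA fallback
.o_site_point <- function(pa, site) {
  res <- pa[pa$resno == site, , drop = FALSE]
  sc <- res[!res$elety %in% .o_backbone, , drop = FALSE]
  if (!nrow(sc)) sc <- res[res$elety == "CA", , drop = FALSE]
  if (!nrow(sc)) sc <- res
  # sum/n (not mean()) so the accumulation matches colMeans bit-for-bit
  n <- nrow(sc)
  c(sum(sc$x) / n, sum(sc$y) / n, sum(sc$z) / n)
}

# brute-force recomputation of the 21 environment features for one site
oracle_env_one_site <- function(cx, site) {
  pa <- mutddg::atoms(cx)
  point <- .o_site_point(pa, site)
  counts <- c(p4 = 0, p6 = 0, p8 = 0, p12 = 0, bb6 = 0, sc6 = 0,
              pol6 = 0, apol6 = 0)
  res6 <- character(0)
  for (i in seq_len(nrow(pa))) {
    if (pa$resno[i] == site) next
    d <- .o_dist(c(pa$x[i], pa$y[i], pa$z[i]), point)
    if (d <= 4) counts["p4"] <- counts["p4"] + 1
    if (d <= 6) {
      counts["p6"] <- counts["p6"] + 1
      res6 <- union(res6, as.character(pa$resno[i]))
      if (pa$elety[i] %in% .o_backbone) counts["bb6"] <- counts["bb6"] + 1
      else counts["sc6"] <- counts["sc6"] + 1
      el <- .o_element(pa$elety[i])
      if (el %in% c("N", "O")) counts["pol6"] <- counts["pol6"] + 1
      if (el %in% c("C", "S")) counts["apol6"] <- counts["apol6"] + 1
    }
    if (d <= 8) counts["p8"] <- counts["p8"] + 1
    if (d <= 12) counts["p12"] <- counts["p12"] + 1
  }
  grp <- c(positively_charged = 0, negatively_charged = 0, polar = 0,
           hydrophobic = 0, special = 0)
  arom <- 0
  for (rn in res6) {
    one <- .o_three2one[pa$resid[pa$resno == as.integer(rn)][1]]
    g <- mutddg::aaGroup(one)
    grp[g] <- grp[g] + 1
    if (one %in% c("F", "W", "Y", "H")) arom <- arom + 1
  }
  la <- cx@ligandAtoms
  has_lig <- !cx@apo && nrow(la) > 0
  l4 <- l6 <- l8 <- 0
  minl <- 99.0
  cdist <- 99.0
  if (has_lig) {
    la <- la[la$element != "H", , drop = FALSE]
    for (i in seq_len(nrow(la))) {
      d <- .o_dist(c(la$x[i], la$y[i], la$z[i]), point)
      if (d <= 4) l4 <- l4 + 1
      if (d <= 6) l6 <- l6 + 1
      if (d <= 8) l8 <- l8 + 1
    }
    minl <- min(vapply(seq_len(nrow(la)), function(i)
      .o_dist(c(la$x[i], la$y[i], la$z[i]), point), numeric(1)))
    nl <- nrow(la)
    cdist <- .o_dist(c(sum(la$x) / nl, sum(la$y) / nl, sum(la$z) / nl),
                     point)
  }
  c(prot_atoms_4A = unname(counts["p4"]),
    prot_atoms_6A = unname(counts["p6"]),
    prot_atoms_8A = unname(counts["p8"]),
    lig_atoms_4A = l4, lig_atoms_6A = l6, lig_atoms_8A = l8,
    min_lig_dist = minl,
    res6_positively_charged = unname(grp["positively_charged"]),
    res6_negatively_charged = unname(grp["negatively_charged"]),
    res6_polar = unname(grp["polar"]),
    res6_hydrophobic = unname(grp["hydrophobic"]),
    res6_special = unname(grp["special"]),
    res6_total = length(res6),
    buriedness_8A = unname(counts["p8"]) / (4 / 3 * pi * 8^3),
    prot_atoms_12A = unname(counts["p12"]),
    backbone_atoms_6A = unname(counts["bb6"]),
    sidechain_atoms_6A = unname(counts["sc6"]),
    polar_atoms_6A = unname(counts["pol6"]),
    apolar_atoms_6A = unname(counts["apol6"]),
    lig_centroid_dist = cdist,
    aromatic_res_6A = arom)
}

oracle_environment <- function(cx, sites) {
  per <- vapply(sites, function(s) oracle_env_one_site(cx, s), numeric(21))
  v <- rowMeans(per)
  names(v) <- rownames(per)
  v
}

# brute-force recomputation of the 6 interaction counts, using the
# package's typing tables but independent pairwise loops
oracle_interactions <- function(cx) {
  zero <- c(hbonds = 0, hydrophobic_contacts = 0, salt_bridges = 0,
            pi_stacking = 0, cation_pi = 0, halogen_bonds = 0)
  if (cx@apo || !nrow(cx@ligandAtoms)) return(zero)
  pa <- mutddg::atoms(cx)
  pt <- mutddg:::.protein_typing(pa)
  lt <- mutddg:::.ligand_typing(cx)
  la <- cx@ligandAtoms
  pxyz <- function(i) c(pa$x[i], pa$y[i], pa$z[i])
  lxyz <- function(i) c(la$x[i], la$y[i], la$z[i])
  hb <- 0
  for (i in pt$donors) for (j in lt$acceptors)
    if (.o_dist(pxyz(i), lxyz(j)) <= 3.5) hb <- hb + 1
  for (i in pt$acceptors) for (j in lt$donors)
    if (.o_dist(pxyz(i), lxyz(j)) <= 3.5 &&
        # avoid double-counting a pair already matched donor->acceptor
        !(i %in% pt$donors && j %in% lt$acceptors &&
          .o_dist(pxyz(i), lxyz(j)) <= 3.5)) hb <- hb + 1
  hph <- 0
  for (i in pt$hydrophobic) for (j in lt$hydrophobic)
    if (.o_dist(pxyz(i), lxyz(j)) <= 4.0) hph <- hph + 1
  salt <- 0
  for (p in c(pt$positive, pt$negative))
    for (l in c(lt$positive, lt$negative))
      if (p$sign * l$sign < 0 && .o_dist(p$xyz, l$xyz) <= 5.5)
        salt <- salt + 1
  plane <- function(xyz) {
    cen <- colMeans(xyz)
    sv <- svd(sweep(xyz, 2, cen))
    list(centroid = cen, normal = sv$v[, 3])
  }
  ang_deg <- function(n1, n2) {
    ca <- abs(sum(n1 * n2)) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
    acos(min(max(ca, -1), 1)) * 180 / pi
  }
  pr <- lapply(pt$rings, plane)
  lr <- lapply(lt$rings, plane)
  pist <- 0
  for (p in pr) for (l in lr)
    if (.o_dist(p$centroid, l$centroid) <= 5.5) {
      a <- ang_deg(p$normal, l$normal)
      if (a <= 30 || (a >= 60 && a <= 90)) pist <- pist + 1
    }
  cpi <- 0
  for (p in pt$positive) for (l in lr)
    if (.o_dist(p$xyz, l$centroid) <= 6.0) cpi <- cpi + 1
  for (l in lt$positive) for (p in pr)
    if (.o_dist(l$xyz, p$centroid) <= 6.0) cpi <- cpi + 1
  xb <- 0
  for (i in pt$acceptors) for (j in lt$halogens)
    if (.o_dist(pxyz(i), lxyz(j)) <= 3.5) xb <- xb + 1
  c(hbonds = hb, hydrophobic_contacts = hph, salt_bridges = salt,
    pi_stacking = pist, cation_pi = cpi, halogen_bonds = xb)
}

# random toy-complex spec generator for property tests
random_toy_spec <- function(seed) {
  set.seed(seed)
  nshell <- sample(2:6, 1)
  nneigh <- sample(0:3, 1)
  neigh <- NULL
  if (nneigh > 0)
    neigh <- data.frame(
      resid = sample(c("GLY", "ALA", "SER", "ASP", "LYS", "ARG", "PHE"),
                     nneigh, replace = TRUE),
      distance = runif(nneigh, 4, 12))
  toyComplexSpec(
    siteResidue = sample(c("ALA", "SER", "ASP", "LYS", "ARG", "PHE"), 1),
    siteResno = sample(20:200, 1),
    shellDistances = runif(nshell, 2.5, 12),
    neighborResidues = neigh,
    ligandTemplate = sample(c("benzene", "acetate", "methylammonium",
                              "chloromethane", "ethanol", "none"), 1),
    ligandDistance = runif(1, 3, 10),
    plddt = sample(60:95, 1),
    seed = seed + 1000L)
}
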