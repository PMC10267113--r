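.three2one <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

#' The 12 amino-acid-change features
#'
#' Differences (mutant minus wild-type) of 12 per-residue scalar
#' properties from [aminoAcidTable()]: hydropathy, side-chain heavy-atom
#' count, side-chain volume, monoisotopic residue mass, formal charge at
#' pH 7, side-chain H-bond donor and acceptor counts, aromatic flag,
#' polar flag, flexibility index, isoelectric point, and sulfur-content
#' flag. Antisymmetric: `aaChangeFeatures(a, b) == -aaChangeFeatures(b, a)`.
#'
#' @param wt,mt One-letter amino-acid codes.
#' @return Named numeric vector of length 12.
#' @export
#' @examples
#' aaChangeFeatures("G", "W")["d_side_chain_heavy_atoms"]
aaChangeFeatures <- function(wt, mt) {
  .check_aa(wt); .check_aa(mt)
  props <- c("hydropathy", "side_chain_heavy_atoms", "side_chain_volume",
             "residue_mass", "formal_charge", "hbd", "hba", "aromatic",
             "polar_flag", "flexibility", "isoelectric_point", "sulfur")
  v <- as.numeric(.aa_table[mt, props]) - as.numeric(.aa_table[wt, props])
  names(v) <- paste0("d_", props)
  v
}

.site_point <- function(prot_atoms, site) {
  res <- prot_atoms[prot_atoms$resno == site, , drop = FALSE]
  if (!nrow(res)) stop("mutated site absent from structure: residue ", site)
  sc <- res[!res$elety %in% .backbone_atoms, , drop = FALSE]
  if (!nrow(sc)) sc <- res[res$elety == "CA", , drop = FALSE]
  if (!nrow(sc)) sc <- res
  colMeans(as.matrix(sc[, c("x", "y", "z")]))
}

.dist_to_point <- function(coords, point) {
  if (!nrow(coords)) return(numeric(0))
  sqrt(colSums((t(as.matrix(coords)) - point)^2))
}

#' The 21 mutation-environment features
#'
#' Geometric descriptors of the protein and ligand neighborhood of the
#' mutation site. The site reference point is the side-chain centroid of
#' the mutated residue (C-alpha for glycine); the site residue's own atoms
#' are excluded from the protein neighbor counts. The panel:
#' protein heavy atoms within 4/6/8 Angstrom; ligand heavy atoms within
#' 4/6/8 Angstrom; minimum site-ligand heavy-atom distance; residues with
#' any atom within 6 Angstrom counted per the five property groups plus
#' the total; a buriedness proxy (protein atoms within 8 Angstrom divided
#' by the 8-Angstrom sphere volume); protein atoms within a wider
#' 12-Angstrom shell; backbone versus side-chain neighbor atoms within 6
#' Angstrom; polar (N/O) versus apolar (C/S) neighbor atoms within 6
#' Angstrom; distance to the ligand centroid; and aromatic residues
#' (F/W/Y/H) within 6 Angstrom. Multi-site mutations are averaged over
#' sites. For apo structures the ligand-dependent distances take the
#' sentinel value 99.0 and the ligand counts are zero.
#'
#' @param cx A [ComplexStructure].
#' @param sites Integer vector of mutated residue numbers.
#' @return Named numeric vector of length 21.
#' @export
environmentFeatures <- function(cx, sites) {
  stopifnot(is(cx, "ComplexStructure"), length(sites) >= 1L)
  per_site <- vapply(sites, function(s) .env_one_site(cx, s), numeric(21))
  v <- rowMeans(per_site)
  names(v) <- rownames(per_site)
  v
}

.env_one_site <- function(cx, site) {
  pa <- cx@protein@atoms
  point <- .site_point(pa, site)
  other <- pa[pa$resno != site, , drop = FALSE]
  dp <- .dist_to_point(other[, c("x", "y", "z")], point)
  has_lig <- !cx@apo && nrow(cx@ligandAtoms) > 0
  if (has_lig) {
    la <- cx@ligandAtoms[cx@ligandAtoms$element != "H", , drop = FALSE]
    dl <- .dist_to_point(la[, c("x", "y", "z")], point)
    lig_centroid <- colMeans(as.matrix(la[, c("x", "y", "z")]))
    centroid_dist <- sqrt(sum((lig_centroid - point)^2))
  } else {
    dl <- numeric(0)
    centroid_dist <- 99.0
  }
  within6 <- other[dp <= 6, , drop = FALSE]
  res6 <- unique(within6$resno)
  grp6 <- table(factor(
    aaGroup(unname(.three2one[pa$resid[match(res6, pa$resno)]])),
    levels = c("positively_charged", "negatively_charged", "polar",
               "hydrophobic", "special")))
  arom6 <- sum(.three2one[pa$resid[match(res6, pa$resno)]] %in%
               c("F", "W", "Y", "H"))
  c(prot_atoms_4A = sum(dp <= 4),
    prot_atoms_6A = sum(dp <= 6),
    prot_atoms_8A = sum(dp <= 8),
    lig_atoms_4A = sum(dl <= 4),
    lig_atoms_6A = sum(dl <= 6),
    lig_atoms_8A = sum(dl <= 8),
    min_lig_dist = if (length(dl)) min(dl) else 99.0,
    res6_positively_charged = as.numeric(grp6["positively_charged"]),
    res6_negatively_charged = as.numeric(grp6["negatively_charged"]),
    res6_polar = as.numeric(grp6["polar"]),
    res6_hydrophobic = as.numeric(grp6["hydrophobic"]),
    res6_special = as.numeric(grp6["special"]),
    res6_total = length(res6),
    buriedness_8A = sum(dp <= 8) / (4 / 3 * pi * 8^3),
    prot_atoms_12A = sum(dp <= 12),
    backbone_atoms_6A = sum(within6$elety %in% .backbone_atoms),
    sidechain_atoms_6A = sum(!within6$elety %in% .backbone_atoms),
    polar_atoms_6A = sum(.element_of(within6$elety) %in% c("N", "O")),
    apolar_atoms_6A = sum(.element_of(within6$elety) %in% c("C", "S")),
    lig_centroid_dist = centroid_dist,
    aromatic_res_6A = arom6)
}

# ---- interaction typing tables ----

.donor_atoms <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
  TYR = "OH", CYS = "SG")

.acceptor_atoms <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD")

.hydrophobic_atoms <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"), MET = "CB",
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  PRO = c("CB", "CG"), LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"),
  GLU = c("CB", "CG"), GLN = c("CB", "CG"), THR = "CG2")

.ring_atoms <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))

.protein_typing <- function(pa) {
  sel <- function(tab, backbone = NULL) {
    idx <- integer(0)
    for (i in seq_len(nrow(pa))) {
      r <- pa$resid[i]
      if (!is.null(tab[[r]]) && pa$elety[i] %in% tab[[r]])
        idx <- c(idx, i)
    }
    if (!is.null(backbone))
      idx <- sort(union(idx, which(pa$elety %in% backbone &
                                   !(pa$elety == "N" & pa$resid == "PRO"))))
    idx
  }
  donors <- sel(.donor_atoms, backbone = "N")
  acceptors <- sel(.acceptor_atoms, backbone = c("O", "OXT"))
  hydrophobic <- sel(.hydrophobic_atoms)
  centers <- function(resid, atomsets, sign) {
    out <- list()
    for (rn in unique(pa$resno[pa$resid == resid])) {
      res <- pa[pa$resno == rn & pa$resid == resid, , drop = FALSE]
      got <- res[res$elety %in% atomsets, , drop = FALSE]
      if (nrow(got))
        out[[length(out) + 1L]] <- list(
          xyz = colMeans(as.matrix(got[, c("x", "y", "z")])), sign = sign)
    }
    out
  }
  pos <- c(centers("ARG", c("NH1", "NH2", "NE"), 1),
           centers("LYS", "NZ", 1),
           centers("HIS", c("ND1", "NE2"), 1))
  neg <- c(centers("ASP", c("OD1", "OD2"), -1),
           centers("GLU", c("OE1", "OE2"), -1))
  rings <- list()
  for (resid in names(.ring_atoms)) {
    for (rn in unique(pa$resno[pa$resid == resid])) {
      res <- pa[pa$resno == rn & pa$resid == resid, , drop = FALSE]
      for (set in .ring_atoms[[resid]]) {
        got <- res[res$elety %in% set, , drop = FALSE]
        if (nrow(got) == length(set))
          rings[[length(rings) + 1L]] <- as.matrix(got[, c("x", "y", "z")])
      }
    }
  }
  list(donors = donors, acceptors = acceptors, hydrophobic = hydrophobic,
       positive = pos, negative = neg, rings = rings)
}

.ligand_typing <- function(cx) {
  la <- cx@ligandAtoms
  lb <- cx@ligandBonds
  n <- nrow(la)
  adj <- .adjacency(n, lb)
  lig <- list(atoms = la, bonds = lb)
  h <- .implicit_h(lig)
  elem <- la$element
  donors <- which(elem %in% c("N", "O") & h >= 1 & la$charge >= 0 |
                  elem == "N" & la$charge > 0 & h >= 1)
  acceptors <- which(elem == "O" & la$charge <= 0 |
                     elem == "N" & la$charge <= 0 & h == 0)
  hydrophobic <- which(elem == "C" & vapply(seq_len(n), function(i)
    !any(elem[adj[[i]]] %in% c("N", "O", "S")), logical(1)))
  halogens <- which(elem %in% c("Cl", "Br", "I") & vapply(seq_len(n),
    function(i) any(elem[adj[[i]]] == "C"), logical(1)))
  pos <- lapply(which(la$charge > 0), function(i)
    list(xyz = as.numeric(la[i, c("x", "y", "z")]), sign = 1))
  neg <- list()
  for (i in which(la$charge < 0)) {
    grp <- i
    if (elem[i] == "O") {
      cnb <- adj[[i]][elem[adj[[i]]] == "C"]
      if (length(cnb))  # carboxylate-like: centroid over the O siblings
        grp <- unique(c(i, intersect(adj[[cnb[1]]], which(elem == "O"))))
    }
    neg[[length(neg) + 1L]] <- list(
      xyz = colMeans(as.matrix(la[grp, c("x", "y", "z")])), sign = -1)
  }
  rings <- .ligand_aromatic_rings(lig)
  list(donors = donors, acceptors = acceptors, hydrophobic = hydrophobic,
       halogens = halogens, positive = pos, negative = neg, rings = rings)
}

# aromatic rings of a (kekulized) ligand graph: smallest rings of size 5-6
# in which every atom is C/N/O/S and ring bond orders alternate (each ring
# atom touches exactly one in-ring double bond, or the ring carries
# explicit aromatic bond order 4); heavy-atom geometry only
.ligand_aromatic_rings <- function(lig) {
  n <- nrow(lig$atoms)
  nb <- nrow(lig$bonds)
  if (nb - n + 1 <= 0 && nb < n) return(list())
  ring_sets <- list()
  for (i in seq_len(nb)) {
    path <- .shortest_cycle(n, lig$bonds, i)
    if (!is.null(path) && length(path) %in% 5:6) {
      key <- paste(sort(path), collapse = ",")
      ring_sets[[key]] <- path
    }
  }
  out <- list()
  for (path in ring_sets) {
    elems <- lig$atoms$element[path]
    if (!all(elems %in% c("C", "N", "O", "S"))) next
    orders <- integer(0)
    k <- length(path)
    ok <- TRUE
    dbl <- integer(k)
    for (j in seq_len(k)) {
      a <- path[j]; b <- path[if (j == k) 1L else j + 1L]
      o <- lig$bonds$order[(lig$bonds$a1 == a & lig$bonds$a2 == b) |
                           (lig$bonds$a1 == b & lig$bonds$a2 == a)]
      if (!length(o)) { ok <- FALSE; break }
      orders <- c(orders, o[1])
    }
    if (!ok) next
    aromatic <- all(orders == 4) ||
      (sum(orders == 2) >= floor(length(path) / 2) &&
       all(orders %in% c(1, 2)))
    if (aromatic)
      out[[length(out) + 1L]] <- as.matrix(
        lig$atoms[path, c("x", "y", "z")])
  }
  out
}

.shortest_cycle <- function(n, bonds, bond_idx) {
  from <- bonds$a1[bond_idx]; to <- bonds$a2[bond_idx]
  adj <- .adjacency(n, bonds[-bond_idx, , drop = FALSE])
  prev <- rep(NA_integer_, n)
  dist <- rep(Inf, n); dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) break
    for (w in adj[[v]]) if (!is.finite(dist[w])) {
      dist[w] <- dist[v] + 1; prev[w] <- v
      queue <- c(queue, w)
    }
  }
  if (!is.finite(dist[to])) return(NULL)
  path <- to
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  path
}

.ring_plane <- function(xyz) {
  centroid <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, centroid))
  list(centroid = centroid, normal = sv$v[, 3])
}

.interplanar_angle <- function(n1, n2) {
  cosang <- abs(sum(n1 * n2)) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' The 6-count protein-ligand interaction profile
#'
#' Counts six interaction types between a protein and its posed ligand by
#' geometric rules on heavy atoms (hydrogen positions are not required):
#' \itemize{
#'   \item hydrogen bonds: donor and acceptor heavy atoms within 3.5 Angstrom
#'     (unique protein-ligand atom pairs, either direction);
#'   \item hydrophobic contacts: apolar carbon pairs within 4.0 Angstrom;
#'   \item salt bridges: oppositely charged group centroids within 5.5 Angstrom;
#'   \item pi-stacking: aromatic ring centroids within 5.5 Angstrom with
#'     interplanar angle at most 30 degrees (parallel) or between 60 and 90
#'     degrees (T-shaped);
#'   \item cation-pi: a cationic center within 6.0 Angstrom of an aromatic
#'     ring centroid of the other molecule;
#'   \item halogen bonds: a carbon-bound Cl/Br/I within 3.5 Angstrom of a
#'     protein acceptor.
#' }
#'
#' @param cx A [ComplexStructure] with a posed ligand.
#' @return Named numeric vector of 6 counts (all zero for an apo complex).
#' @export
interactionProfile <- function(cx) {
  stopifnot(is(cx, "ComplexStructure"))
  zero <- c(hbonds = 0, hydrophobic_contacts = 0, salt_bridges = 0,
            pi_stacking = 0, cation_pi = 0, halogen_bonds = 0)
  if (cx@apo || !nrow(cx@ligandAtoms)) return(zero)
  pa <- cx@protein@atoms
  if (!nrow(pa)) return(zero)
  if (anyNA(cx@ligandAtoms$x)) stop("ligand coordinates missing")
  pt <- .protein_typing(pa)
  lt <- .ligand_typing(cx)
  pxyz <- as.matrix(pa[, c("x", "y", "z")])
  lxyz <- as.matrix(cx@ligandAtoms[, c("x", "y", "z")])
  pair_count <- function(pidx, lidx, cutoff) {
    if (!length(pidx) || !length(lidx)) return(matrix(numeric(0), 0, 2))
    d <- as.matrix(dist(rbind(pxyz[pidx, , drop = FALSE],
                              lxyz[lidx, , drop = FALSE])))
    d <- d[seq_along(pidx), length(pidx) + seq_along(lidx), drop = FALSE]
    which(d <= cutoff, arr.ind = TRUE)
  }
  hb1 <- pair_count(pt$donors, lt$acceptors, 3.5)
  hb2 <- pair_count(pt$acceptors, lt$donors, 3.5)
  hb_pairs <- unique(rbind(
    if (nrow(hb1)) cbind(pt$donors[hb1[, 1]], lt$acceptors[hb1[, 2]]),
    if (nrow(hb2)) cbind(pt$acceptors[hb2[, 1]], lt$donors[hb2[, 2]])))
  hb_count <- if (is.null(hb_pairs)) 0 else nrow(hb_pairs)
  hphob <- pair_count(pt$hydrophobic, lt$hydrophobic, 4.0)
  salt <- 0
  for (p in c(pt$positive, pt$negative))
    for (l in c(lt$positive, lt$negative))
      if (p$sign * l$sign < 0 &&
          sqrt(sum((p$xyz - l$xyz)^2)) <= 5.5) salt <- salt + 1
  prings <- lapply(pt$rings, .ring_plane)
  lrings <- lapply(lt$rings, .ring_plane)
  pistack <- 0
  for (p in prings) for (l in lrings) {
    if (sqrt(sum((p$centroid - l$centroid)^2)) <= 5.5) {
      ang <- .interplanar_angle(p$normal, l$normal)
      if (ang <= 30 || (ang >= 60 && ang <= 90)) pistack <- pistack + 1
    }
  }
  catpi <- 0
  for (p in pt$positive) for (l in lrings)
    if (sqrt(sum((p$xyz - l$centroid)^2)) <= 6.0) catpi <- catpi + 1
  for (l in lt$positive) for (p in prings)
    if (sqrt(sum((l$xyz - p$centroid)^2)) <= 6.0) catpi <- catpi + 1
  xb <- pair_count(pt$acceptors, lt$halogens, 3.5)
  c(hbonds = hb_count, hydrophobic_contacts = nrow(hphob),
    salt_bridges = salt, pi_stacking = pistack, cation_pi = catpi,
    halogen_bonds = nrow(xb))
}
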