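#' Parse and standardize a ligand
#'
#' Accepts a SMILES string, a path to an SDF file, or already-parsed
#' atom/bond tables, and applies the standardization used before
#' descriptor calculation: counter-ions and salt fragments are stripped
#' (the largest connected fragment by heavy-atom count is kept) and formal
#' charges are neutralized where an implicit-hydrogen adjustment can
#' balance them (anions, and cations with a removable proton); permanent
#' cations such as quaternary nitrogens keep their charge.
#'
#' @param mol SMILES string, SDF path, or list with `atoms` and `bonds`.
#' @param standardize Apply salt stripping and neutralization (default
#'   `TRUE`).
#' @return List with `atoms` (`element`, `x`, `y`, `z`, `charge`) and
#'   `bonds` (`a1`, `a2`, `order`).
#' @export
parseLigand <- function(mol, standardize = TRUE) {
  lig <- if (is.list(mol)) {
    list(atoms = as.data.frame(mol$atoms), bonds = as.data.frame(mol$bonds))
  } else if (is.character(mol) && length(mol) == 1L) {
    if (file.exists(mol) || grepl("\\.sdf$", mol, ignore.case = TRUE)) {
      readLigandSDF(mol)
    } else {
      txt <- tryCatch(
        ChemmineOB::convertFormat("SMI", "SDF", paste0(mol, "\tmol")),
        error = function(e)
          stop("cannot parse SMILES: ", mol, " (", conditionMessage(e), ")"))
      if (!nzchar(txt)) stop("cannot parse SMILES: ", mol)
      tmp <- tempfile(fileext = ".sdf")
      on.exit(unlink(tmp), add = TRUE)
      writeLines(txt, tmp)
      readLigandSDF(tmp)
    }
  } else stop("mol must be a SMILES string, an SDF path, or atom/bond tables")
  if (is.null(lig$atoms$charge)) lig$atoms$charge <- 0
  if (standardize) lig <- .neutralize(.strip_salts(lig))
  lig
}

# keep the largest connected fragment by heavy-atom count
.strip_salts <- function(lig) {
  n <- nrow(lig$atoms)
  if (n <= 1L || !nrow(lig$bonds)) {
    if (n > 1L) {  # disconnected atoms only: keep the heaviest single atom
      keep <- which.max(lig$atoms$element != "H")
      lig$atoms <- lig$atoms[keep, , drop = FALSE]
    }
    return(lig)
  }
  comp <- .components(n, lig$bonds)
  sizes <- tapply(lig$atoms$element != "H", comp, sum)
  keep_comp <- as.integer(names(sizes)[which.max(sizes)])
  keep <- which(comp == keep_comp)
  remap <- match(seq_len(n), keep)
  b <- lig$bonds[lig$bonds$a1 %in% keep & lig$bonds$a2 %in% keep, , drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  lig$atoms <- lig$atoms[keep, , drop = FALSE]
  rownames(lig$atoms) <- NULL
  lig$bonds <- b
  lig
}

.components <- function(n, bonds) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(bonds))) {
      a <- bonds$a1[i]; b <- bonds$a2[i]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

.heavy_degree <- function(lig) {
  n <- nrow(lig$atoms)
  deg <- integer(n)
  for (i in seq_len(nrow(lig$bonds))) {
    deg[lig$bonds$a1[i]] <- deg[lig$bonds$a1[i]] + 1L
    deg[lig$bonds$a2[i]] <- deg[lig$bonds$a2[i]] + 1L
  }
  deg
}

.neutralize <- function(lig) {
  deg <- .heavy_degree(lig)
  ch <- lig$atoms$charge
  # anions: protonate (drop the charge; implicit H fills the valence)
  ch[ch < 0] <- 0
  # cations with a removable proton (explicit heavy degree below full
  # valence): deprotonate; quaternary N+ keeps its charge
  full <- c(N = 4L, O = 3L, S = 3L, P = 4L)
  for (i in which(ch > 0)) {
    fv <- full[lig$atoms$element[i]]
    if (!is.na(fv) && deg[i] < fv) ch[i] <- 0
  }
  lig$atoms$charge <- ch
  lig
}

.lig_sdfset <- function(lig) {
  tmp <- tempfile(fileext = ".sdf")
  writeLigandSDF(lig, tmp)
  sdfs <- ChemmineR::read.SDFset(tmp)
  unlink(tmp)
  sdfs
}

#' The 18-descriptor ligand panel
#'
#' Computes the fixed panel of 18 ligand descriptors on a standardized
#' molecule (see [parseLigand()]): logP, molecular weight, hydrogen-bond
#' acceptor and donor counts, TPSA, rotatable bonds, ring count, aromatic
#' ring count, heavy-atom count, fraction of sp3 carbons, net formal
#' charge, halogen count, nitrogen/oxygen/sulfur counts, potential
#' stereocenter count, largest-ring size, and molar refractivity. logP,
#' TPSA, molar refractivity, molecular weight and the H-bond counts come
#' from Open Babel (via \pkg{ChemmineOB}); the remaining counts are
#' computed on the molecular graph. Ligand descriptors are absolute values
#' and are never differenced between wild-type and mutant samples.
#'
#' Stereocenters are detected by an iterative neighborhood-refinement of
#' atom labels (potential tetrahedral centers with four distinguishable
#' substituents), not a full CIP assignment.
#'
#' @param mol A SMILES string, SDF path, or parsed ligand (see
#'   [parseLigand()]).
#' @return Named numeric vector of length 18.
#' @export
#' @examples
#' ligandDescriptors("c1ccccc1")["aromatic_rings"]
ligandDescriptors <- function(mol) {
  lig <- parseLigand(mol)
  if (!nrow(lig$atoms)) stop("empty molecule after standardization")
  if (!nrow(lig$bonds))
    stop("descriptor panel requires a molecule with at least one bond")
  sdfs <- .lig_sdfset(lig)
  ob <- tryCatch(ChemmineR::propOB(sdfs),
                 error = function(e) stop("unsanitizable molecule: ",
                                          conditionMessage(e)))
  smarts <- function(p) as.numeric(ChemmineR::smartsSearchOB(sdfs, p,
                                                             uniqueMatches = TRUE))
  heavy <- sum(lig$atoms$element != "H")
  n_c <- smarts("[#6]")
  ringinfo <- .ring_info(lig, sdfs)
  c(logp = as.numeric(ob$logP),
    mol_weight = as.numeric(ob$MW),
    hba = as.numeric(ob$HBA1),
    hbd = as.numeric(ob$HBD),
    tpsa = as.numeric(ob$TPSA),
    rotatable_bonds = smarts("[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"),
    rings = ringinfo$count,
    aromatic_rings = ringinfo$aromatic,
    heavy_atoms = heavy,
    fraction_csp3 = if (n_c > 0) smarts("[CX4]") / n_c else 0,
    formal_charge = sum(lig$atoms$charge),
    halogens = smarts("[F,Cl,Br,I]"),
    n_atoms = smarts("[#7]"),
    o_atoms = smarts("[#8]"),
    s_atoms = smarts("[#16]"),
    stereocenters = .stereocenter_count(lig),
    largest_ring = ringinfo$largest,
    molar_refractivity = as.numeric(ob$MR))
}

# ring count (cyclomatic number), aromatic ring count (aromatic rings of
# size <= 6 from ChemmineR ring perception) and largest smallest-ring size
.ring_info <- function(lig, sdfs) {
  n <- nrow(lig$atoms)
  nb <- nrow(lig$bonds)
  ncomp <- if (nb) length(unique(.components(n, lig$bonds))) else n
  count <- nb - n + ncomp
  aromatic <- 0
  if (count > 0) {
    r <- tryCatch(ChemmineR::rings(sdfs[[1]], type = "all", arom = TRUE),
                  error = function(e) NULL)
    if (!is.null(r) && length(r$RINGS))
      aromatic <- sum(r$AROMATIC & lengths(r$RINGS) <= 6)
  }
  largest <- 0
  if (count > 0) {
    for (i in seq_len(nb)) {
      len <- .shortest_path_len(n, lig$bonds[-i, , drop = FALSE],
                                lig$bonds$a1[i], lig$bonds$a2[i])
      if (is.finite(len)) largest <- max(largest, len + 1)
    }
  }
  list(count = count, aromatic = aromatic, largest = largest)
}

.adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds$a1[i]]] <- c(adj[[bonds$a1[i]]], bonds$a2[i])
    adj[[bonds$a2[i]]] <- c(adj[[bonds$a2[i]]], bonds$a1[i])
  }
  adj
}

.shortest_path_len <- function(n, bonds, from, to) {
  adj <- .adjacency(n, bonds)
  dist <- rep(Inf, n)
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) return(dist[v])
    for (w in adj[[v]]) if (!is.finite(dist[w])) {
      dist[w] <- dist[v] + 1
      queue <- c(queue, w)
    }
  }
  Inf
}

.standard_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                       Br = 1, I = 1, B = 3, Si = 4, Se = 2, H = 1)

.implicit_h <- function(lig) {
  n <- nrow(lig$atoms)
  bo <- numeric(n)
  for (i in seq_len(nrow(lig$bonds))) {
    o <- lig$bonds$order[i]
    if (o == 4) o <- 1.5
    bo[lig$bonds$a1[i]] <- bo[lig$bonds$a1[i]] + o
    bo[lig$bonds$a2[i]] <- bo[lig$bonds$a2[i]] + o
  }
  v <- .standard_valence[lig$atoms$element]
  v[is.na(v)] <- 0
  h <- round(v + lig$atoms$charge * ifelse(lig$atoms$element %in%
                                           c("O", "S"), -1, 1) - bo)
  pmax(h, 0)
}

# Weisfeiler-Lehman style refinement; potential stereocenter = tetravalent
# carbon whose four substituents (heavy branches + at most one implicit H)
# carry pairwise-distinct converged labels
.stereocenter_count <- function(lig) {
  n <- nrow(lig$atoms)
  if (n < 4L) return(0)
  adj <- .adjacency(n, lig$bonds)
  h <- .implicit_h(lig)
  lab <- match(paste(lig$atoms$element, lig$atoms$charge, lengths(adj), h),
               unique(paste(lig$atoms$element, lig$atoms$charge,
                            lengths(adj), h)))
  for (it in seq_len(n)) {
    sig <- vapply(seq_len(n), function(i)
      paste(lab[i], paste(sort(lab[adj[[i]]]), collapse = ","), sep = "|"),
      character(1))
    new_lab <- match(sig, unique(sig))
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  count <- 0
  for (i in seq_len(n)) {
    if (lig$atoms$element[i] != "C") next
    nbrs <- adj[[i]]
    if (length(nbrs) + h[i] != 4L || h[i] > 1L) next
    branch <- lab[nbrs]
    if (anyDuplicated(branch)) next
    count <- count + 1
  }
  count
}
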