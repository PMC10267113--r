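.solvent_resids <- c("HOH", "WAT", "DOD", "SOL", "TIP", "TIP3", "TIP4",
                     "GOL", "EDO", "PEG", "PG4", "DMS", "ACT", "SO4", "PO4",
                     "TRS", "MPD", "BME", "FMT", "EOH", "IPA")
.ion_resids <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "FE2", "CU",
                 "CO", "NI", "CD", "HG", "BR", "IOD", "CS", "LI", "SR", "BA")

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records with \pkg{bio3d}, removes water, solvent and ion
#' records, keeps the longest protein chain when several are present, and
#' surfaces the B-factor column as per-residue pLDDT for predicted models.
#'
#' @param path Path to a PDB file.
#' @param provenance `"experimental"` or `"predicted"` (pLDDT in the
#'   B-factor column).
#' @return A [StructureModel].
#' @export
readStructure <- function(path, provenance = c("experimental", "predicted")) {
  provenance <- match.arg(provenance)
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!at$resid %in% c(.solvent_resids, .ion_resids), , drop = FALSE]
  at <- at[!grepl("^[0-9]*H", trimws(at$elety)), , drop = FALSE]
  if (!nrow(at)) stop("no protein ATOM records in: ", path)
  if (anyNA(at$chain)) at$chain[is.na(at$chain)] <- "A"
  chains <- tapply(at$resno, at$chain, function(r) length(unique(r)))
  longest <- names(chains)[which.max(chains)]
  at <- at[at$chain == longest, , drop = FALSE]
  dup <- tapply(at$resid, at$resno, function(r) length(unique(r)))
  if (any(dup > 1L))
    stop("duplicate residue numbering at residue(s): ",
         paste(names(dup)[dup > 1L], collapse = ", "))
  new("StructureModel",
      atoms = data.frame(resno = at$resno, resid = at$resid,
                         elety = trimws(at$elety),
                         x = at$x, y = at$y, z = at$z, b = at$b),
      provenance = provenance)
}

#' Write a StructureModel to a PDB file
#'
#' Serializes the atom table through \pkg{bio3d}, carrying the pLDDT /
#' B-factor column.
#'
#' @param model A [StructureModel].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(model, path) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   chain = rep("A", nrow(a)), b = a$b,
                   o = rep(1, nrow(a)))
  invisible(path)
}

.element_of <- function(elety) {
  e <- sub("^[0-9]*", "", trimws(elety))
  first2 <- substr(e, 1, 2)
  ifelse(first2 %in% c("CL", "BR", "FE", "ZN", "MG", "SE"), first2,
         substr(e, 1, 1))
}

#' Assemble a protein-ligand complex
#'
#' Combines a protein [StructureModel] with a posed ligand given either as
#' an SDF file/text (coordinates taken from the SDF, which must be in the
#' protein frame) or as already-parsed ligand atom/bond tables. The
#' complex is flagged apo when no protein atom lies within 10 Angstrom of
#' the ligand centroid, or when no ligand is supplied.
#'
#' @param protein A [StructureModel].
#' @param ligand `NULL` (apo), a path to an SDF file, or a list with
#'   elements `atoms` (`element`, `x`, `y`, `z`, `charge`) and `bonds`
#'   (`a1`, `a2`, `order`).
#' @return A [ComplexStructure].
#' @export
complexStructure <- function(protein, ligand = NULL) {
  stopifnot(is(protein, "StructureModel"))
  empty_atoms <- data.frame(element = character(0), x = numeric(0),
                            y = numeric(0), z = numeric(0),
                            charge = numeric(0))
  empty_bonds <- data.frame(a1 = integer(0), a2 = integer(0),
                            order = integer(0))
  if (is.null(ligand))
    return(new("ComplexStructure", protein = protein,
               ligandAtoms = empty_atoms, ligandBonds = empty_bonds,
               apo = TRUE))
  if (is.character(ligand)) ligand <- readLigandSDF(ligand)
  la <- as.data.frame(ligand$atoms)
  lb <- as.data.frame(ligand$bonds)
  if (is.null(la$charge)) la$charge <- 0
  centroid <- colMeans(la[, c("x", "y", "z")])
  p <- as.matrix(protein@atoms[, c("x", "y", "z")])
  d <- sqrt(colSums((t(p) - centroid)^2))
  apo <- !any(d <= 10)
  new("ComplexStructure", protein = protein, ligandAtoms = la,
      ligandBonds = lb, apo = apo)
}

#' Read a ligand from an SDF (V2000) file
#'
#' Parses the first molecule of an SDF file (fixed-column V2000 molfile
#' format) and returns plain atom and bond tables, including formal
#' charges from the `M  CHG` block and the atom-block charge column.
#' Molecules with no bonds (single atoms) are supported.
#'
#' @param path Path to an SDF file.
#' @return List with `atoms` (`element`, `x`, `y`, `z`, `charge`) and
#'   `bonds` (`a1`, `a2`, `order`).
#' @export
readLigandSDF <- function(path) {
  if (!file.exists(path)) stop("SDF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) stop("not a V2000 molfile: ", path)
  nAtoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  nBonds <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(nAtoms) || is.na(nBonds) || nAtoms < 1 ||
      length(lines) < 4 + nAtoms + nBonds)
    stop("malformed V2000 counts line in: ", path)
  al <- lines[4 + seq_len(nAtoms)]
  # molfile charge codes in columns 37-39: 1 = +3, 2 = +2, 3 = +1,
  # 5 = -1, 6 = -2, 7 = -3; M CHG records below override them
  code <- suppressWarnings(as.integer(substr(al, 37, 39)))
  chg <- c(`3` = 1, `5` = -1, `1` = 3, `2` = 2, `6` = -2, `7` = -3)
  idx <- match(as.character(code), names(chg))
  atoms <- data.frame(element = trimws(substr(al, 32, 34)),
                      x = as.numeric(substr(al, 1, 10)),
                      y = as.numeric(substr(al, 11, 20)),
                      z = as.numeric(substr(al, 21, 30)),
                      charge = ifelse(is.na(idx), 0, chg[idx]),
                      row.names = NULL)
  if (anyNA(atoms$x) || any(!nzchar(atoms$element)))
    stop("malformed V2000 atom block in: ", path)
  bl <- lines[4 + nAtoms + seq_len(nBonds)]
  bonds <- data.frame(a1 = as.integer(substr(bl, 1, 3)),
                      a2 = as.integer(substr(bl, 4, 6)),
                      order = as.integer(substr(bl, 7, 9)),
                      row.names = NULL)
  if (nBonds && (anyNA(bonds$a1) || any(bonds$a1 < 1) ||
                 any(pmax(bonds$a1, bonds$a2) > nAtoms)))
    stop("malformed V2000 bond block in: ", path)
  endRec <- c(grep("^\\$\\$\\$\\$", lines), length(lines))[1]
  mchg <- .sdf_m_chg(lines[seq_len(endRec)])
  if (nrow(mchg)) {  # M CHG supersedes the whole atom-block charge column
    atoms$charge <- 0
    atoms$charge[mchg$atom] <- mchg$charge
  }
  list(atoms = atoms, bonds = bonds)
}

.sdf_m_chg <- function(lines) {
  lines <- grep("^M  CHG", lines, value = TRUE)
  out <- data.frame(atom = integer(0), charge = integer(0))
  for (l in lines) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)), "\\s+")[[1]])
    n <- f[1]
    for (i in seq_len(n))
      out <- rbind(out, data.frame(atom = f[2 * i], charge = f[2 * i + 1]))
  }
  out
}

#' Write ligand atom/bond tables as an SDF (V2000) file
#'
#' Emits a minimal V2000 molfile (counts line, atom block, bond block,
#' `M  CHG` records for charged atoms) readable by [readLigandSDF()] and
#' any standard SDF parser.
#'
#' @param ligand List with `atoms` and `bonds` as in [readLigandSDF()].
#' @param path Output path.
#' @param title Molecule title line.
#' @return `path`, invisibly.
#' @export
writeLigandSDF <- function(ligand, path, title = "ligand") {
  a <- as.data.frame(ligand$atoms)
  b <- as.data.frame(ligand$bonds)
  lines <- c(title, "  mutddg", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(a), nrow(b)))
  for (i in seq_len(nrow(a)))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              a$x[i], a$y[i], a$z[i], a$element[i]))
  for (i in seq_len(nrow(b)))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              b$a1[i], b$a2[i], b$order[i]))
  if (is.null(a$charge)) a$charge <- 0
  charged <- which(a$charge != 0)
  if (length(charged)) {
    for (grp in split(charged, ceiling(seq_along(charged) / 8)))
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
                               paste0(sprintf("%4d%4d", grp, a$charge[grp]),
                                      collapse = "")))
  }
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, path)
  invisible(path)
}
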