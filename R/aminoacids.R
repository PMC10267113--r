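#' Amino-acid property table
#'
#' A fixed table of the 20 standard amino acids with the per-residue scalar
#' properties used by the amino-acid-change feature block and the property
#' grouping used throughout the mutation statistics.
#'
#' Columns:
#' \describe{
#'   \item{one}{one-letter code}
#'   \item{three}{three-letter code}
#'   \item{group}{one of `positively_charged`, `negatively_charged`, `polar`,
#'     `hydrophobic`, `special`; the five groups partition the alphabet and
#'     the special group holds exactly three members (G, C, P)}
#'   \item{side_chain_heavy_atoms}{heavy (non-hydrogen) atoms in the side chain}
#'   \item{side_chain_volume}{residue volume in cubic Angstrom (Zamyatnin)}
#'   \item{hydropathy}{Kyte-Doolittle hydropathy index}
#'   \item{residue_mass}{monoisotopic residue mass in Da}
#'   \item{formal_charge}{formal side-chain charge at pH 7 (R/K +1, D/E -1)}
#'   \item{hbd}{side-chain hydrogen-bond donor group count}
#'   \item{hba}{side-chain hydrogen-bond acceptor group count}
#'   \item{aromatic}{1 for F, W, Y, H}
#'   \item{polar_flag}{1 if the side chain is charged or polar (can H-bond)}
#'   \item{flexibility}{average flexibility index (Bhaskaran-Ponnuswamy)}
#'   \item{isoelectric_point}{pI of the free amino acid}
#'   \item{sulfur}{1 for C and M}
#' }
#'
#' @return A 20-row `data.frame`, one row per amino acid, rownames the
#'   one-letter codes.
#' @export
#' @examples
#' aa <- aminoAcidTable()
#' aa["W", "side_chain_heavy_atoms"]
aminoAcidTable <- function() .aa_table

.aa_levels <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.aa_groups <- c(
  R = "positively_charged", K = "positively_charged", H = "positively_charged",
  D = "negatively_charged", E = "negatively_charged",
  S = "polar", T = "polar", N = "polar", Q = "polar", Y = "polar",
  A = "hydrophobic", V = "hydrophobic", L = "hydrophobic", I = "hydrophobic",
  M = "hydrophobic", F = "hydrophobic", W = "hydrophobic",
  G = "special", C = "special", P = "special"
)

.aa_table <- local({
  one <- .aa_levels
  three <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
             "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
             "Tyr", "Val")
  d <- data.frame(
    one = one, three = three,
    group = unname(.aa_groups[one]),
    side_chain_heavy_atoms = c(1, 7, 4, 4, 2, 5, 5, 0, 6, 4,
                               4, 5, 4, 7, 3, 2, 3, 10, 8, 3),
    side_chain_volume = c(88.6, 173.4, 114.1, 111.1, 108.5, 143.8, 138.4,
                          60.1, 153.2, 166.7, 166.7, 168.6, 162.9, 189.9,
                          112.7, 89.0, 116.1, 227.8, 193.6, 140.0),
    hydropathy = c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
                   3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2),
    residue_mass = c(71.03711, 156.10111, 114.04293, 115.02694, 103.00919,
                     128.05858, 129.04259, 57.02146, 137.05891, 113.08406,
                     113.08406, 128.09496, 131.04049, 147.06841, 97.05276,
                     87.03203, 101.04768, 186.07931, 163.06333, 99.06841),
    formal_charge = c(0, 1, 0, -1, 0, 0, -1, 0, 0, 0,
                      0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    hbd = c(0, 3, 1, 0, 1, 1, 0, 0, 1, 0,
            0, 1, 0, 0, 0, 1, 1, 1, 1, 0),
    hba = c(0, 0, 1, 2, 0, 1, 2, 0, 1, 0,
            0, 0, 0, 0, 0, 1, 1, 0, 1, 0),
    aromatic = as.numeric(one %in% c("F", "W", "Y", "H")),
    flexibility = c(0.357, 0.529, 0.463, 0.511, 0.346, 0.493, 0.497, 0.544,
                    0.323, 0.462, 0.365, 0.466, 0.295, 0.314, 0.509, 0.507,
                    0.444, 0.305, 0.420, 0.386),
    isoelectric_point = c(6.00, 10.76, 5.41, 2.77, 5.07, 5.65, 3.22, 5.97,
                          7.59, 6.02, 5.98, 9.74, 5.74, 5.48, 6.30, 5.68,
                          5.60, 5.89, 5.66, 5.96),
    sulfur = as.numeric(one %in% c("C", "M")),
    row.names = one
  )
  d$polar_flag <- as.numeric(d$group %in%
    c("positively_charged", "negatively_charged", "polar"))
  d
})

#' Property group of an amino acid
#'
#' Returns the property-group label (`positively_charged`,
#' `negatively_charged`, `polar`, `hydrophobic` or `special`) for one-letter
#' amino-acid codes. The grouping is the five-way partition used for the
#' substitution-matrix analytics: R/K/H positive, D/E negative, S/T/N/Q/Y
#' polar, A/V/L/I/M/F/W hydrophobic, and G/C/P as the three special cases.
#'
#' @param aa Character vector of one-letter codes.
#' @return Character vector of group labels.
#' @export
#' @examples
#' aaGroup(c("R", "D", "G"))
aaGroup <- function(aa) {
  aa <- as.character(aa)
  bad <- !aa %in% .aa_levels
  if (any(bad))
    stop("unknown amino-acid letter(s): ", paste(unique(aa[bad]), collapse = ", "))
  unname(.aa_groups[aa])
}

.check_aa <- function(aa) {
  if (length(aa) != 1L || !aa %in% .aa_levels)
    stop("unknown amino-acid letter: ", aa)
  invisible(aa)
}
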