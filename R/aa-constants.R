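# Packaged per-residue constants. All tables are keyed by the 20 canonical
# one-letter codes; anything else is rejected upstream. Scale tables are a
# pluggable registry (see register_residue_table): the workflow is agnostic to
# the table provider, and users can swap in their own curated values.

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' The non-polar (NPR) residue group
#'
#' Residues treated as non-polar when splitting surface area and surface
#' properties into hydrophobic and polar contributions: Ala, Gly, Ile, Leu,
#' Met, Phe, Pro, Trp, Val. The complementary [PLR_RESIDUES] set covers the
#' remaining 11 canonical residues, so the two groups partition the alphabet.
#' @format Character vector of one-letter codes.
#' @export
NPR_RESIDUES <- c("A", "G", "I", "L", "M", "F", "P", "W", "V")

#' The polar (PLR) residue group
#' @seealso [NPR_RESIDUES]
#' @format Character vector of one-letter codes.
#' @export
PLR_RESIDUES <- c("R", "N", "D", "C", "Q", "E", "H", "K", "S", "T", "Y")

# Kyte-Doolittle hydropathy (J Mol Biol 1982). Used as C^KD weights in the
# surface-property descriptors and as a registered sequence property table.
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Theoretical maximum accessible surface area (A^2) of residue X in an
# extended Gly-X-Gly tripeptide, "theoretical" column of Tien et al. 2013.
MAX_ASA_TIEN <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

# Average residue masses (Da); a peptide's molecular weight is the residue
# sum plus one water.
AA_RESIDUE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)
MASS_WATER <- 18.01524

# EMBOSS-style pKa values for the charge / isoelectric-point model.
PKA_TABLE <- list(
  nterm = 8.6, cterm = 3.6,
  C = 8.5, D = 3.9, E = 4.1, Y = 10.1,   # acidic side chains (C/Y deprotonate)
  H = 6.5, K = 10.8, R = 12.5           # basic side chains
)

# EMBOSS pepstats residue classes.
AA_CLASS <- list(
  tiny     = c("A", "C", "G", "S", "T"),
  small    = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),
  aromatic = c("F", "H", "W", "Y"),
  polar    = c("D", "E", "H", "K", "N", "Q", "R", "S", "T"),
  nonpolar = c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W", "Y")
)

# Five-component Z-scale (Sandberg et al. 1998): hydrophilicity, steric bulk,
# polarity/charge and two electronic components.
ZSCALE5 <- matrix(c(
   0.24, -2.32,  0.60, -0.14,  1.30,   # A
   3.52,  2.50, -3.50,  1.99, -0.17,   # R
   3.05,  1.62,  1.04, -1.15,  1.61,   # N
   3.98,  0.93,  1.93, -2.46,  0.75,   # D
   0.84, -1.67,  3.71,  0.18, -2.65,   # C
   1.75,  0.50, -1.44, -1.34,  0.66,   # Q
   3.11,  0.26, -0.11, -3.04, -0.25,   # E
   2.05, -4.06,  0.36, -0.82, -0.38,   # G
   2.47,  1.95,  0.26,  3.90,  0.09,   # H
  -3.89, -1.73, -1.71, -0.84,  0.26,   # I
  -4.28, -1.30, -1.49, -0.72,  0.84,   # L
   2.29,  0.89, -2.49,  1.49,  0.31,   # K
  -2.85, -0.22,  0.47,  1.94, -0.98,   # M
  -4.22,  1.94,  1.06,  0.54, -0.62,   # F
  -1.66,  0.27,  1.84,  0.70,  2.00,   # P
   2.39, -1.07,  1.15, -1.39,  0.67,   # S
   0.75, -2.18, -1.12, -1.46, -0.40,   # T
  -4.36,  3.94,  0.59,  3.44, -1.59,   # W
  -2.54,  2.44,  0.43,  0.04, -1.47,   # Y
  -2.59, -2.64, -1.54, -0.85, -0.02    # V
), nrow = 20, byrow = TRUE,
  dimnames = list(AA_LETTERS, paste0("z", 1:5)))

# Five-component topological T-scale (Tian et al. 2007).
TSCALE5 <- matrix(c(
  -9.11, -1.63,  0.63,  1.04,  2.26,   # A
   0.23,  3.89, -1.16, -0.39, -0.06,   # R
  -4.62,  0.66,  1.16, -0.22,  0.93,   # N
  -4.65,  0.75,  1.39, -0.40,  1.05,   # D
  -7.35, -0.86, -0.33,  0.80,  0.98,   # C
  -3.00,  1.72,  0.28, -0.39,  0.33,   # Q
  -3.03,  1.82,  0.51, -0.58,  0.43,   # E
 -10.61, -1.21, -0.12,  0.75,  3.25,   # G
  -1.01, -1.31,  0.01, -1.81, -0.21,   # H
  -4.25, -0.28, -0.15,  1.40, -0.21,   # I
  -4.38,  0.28, -0.49,  1.45,  0.02,   # L
  -2.59,  2.34, -1.69,  0.41, -0.21,   # K
  -4.08,  0.98, -2.34,  1.64, -0.79,   # M
   0.49, -0.94, -0.63, -1.27, -0.44,   # F
  -5.11, -3.54, -0.53, -0.36, -0.29,   # P
  -7.44, -0.65,  0.68, -0.17,  1.58,   # S
  -5.97, -0.62,  1.11,  0.31,  0.95,   # T
   5.73, -2.67, -0.07, -1.96, -0.54,   # W
   2.08, -0.47,  0.07, -1.67, -0.35,   # Y
  -5.87, -0.94,  0.28,  1.10,  0.48    # V
), nrow = 20, byrow = TRUE,
  dimnames = list(AA_LETTERS, paste0("t", 1:5)))

# Three-component MS-WHIM scale (Zaliani & Gancia 1999), derived from
# molecular-surface electrostatic potentials.
MSWHIM3 <- matrix(c(
  -0.73,  0.20, -0.62,   # A
  -0.22,  0.27,  1.00,   # R
   0.14,  0.20, -0.66,   # N
   0.11, -1.00, -0.96,   # D
  -0.66,  0.26, -0.27,   # C
   0.30,  1.00, -0.30,   # Q
   0.24, -0.39, -0.04,   # E
  -0.31, -0.28, -0.75,   # G
   0.84,  0.67, -0.78,   # H
  -0.91,  0.83, -0.25,   # I
  -0.74,  0.72, -0.16,   # L
  -0.51,  0.08,  0.60,   # K
  -0.70,  1.00, -0.32,   # M
   0.76,  0.85, -0.34,   # F
  -0.43,  0.73, -0.60,   # P
  -0.80,  0.61, -1.00,   # S
  -0.58,  0.85, -0.89,   # T
   1.00,  0.98, -0.47,   # W
   0.97,  0.66, -0.16,   # Y
  -1.00,  0.79, -0.58    # V
), nrow = 20, byrow = TRUE,
  dimnames = list(AA_LETTERS, paste0("w", 1:3)))

# Thermodynamic-style per-residue tables standing in for descriptor-software
# outputs: gc = side-chain conformational entropy cost (kcal/mol,
# Pickett & Sternberg-style), wf = estimated first-shell hydration number,
# dgw = water->octanol transfer free energy (Fauchere & Pliska, kcal/mol).
GC_CONF_ENTROPY <- c(
  A = 0.00, R = 2.03, N = 1.57, D = 1.25, C = 0.55,
  Q = 2.11, E = 1.81, G = 0.00, H = 0.96, I = 0.89,
  L = 0.78, K = 1.94, M = 1.61, F = 0.58, P = 0.00,
  S = 1.71, T = 1.63, W = 0.97, Y = 0.99, V = 0.51
)
WF_HYDRATION <- c(
  A = 1.5, R = 7.0, N = 5.0, D = 5.0, C = 1.5,
  Q = 5.5, E = 5.5, G = 1.0, H = 5.0, I = 1.0,
  L = 1.0, K = 4.5, M = 1.5, F = 0.5, P = 2.0,
  S = 3.0, T = 2.5, W = 2.0, Y = 3.0, V = 1.0
)
DGW_TRANSFER <- c(
  A =  0.31, R = -1.01, N = -0.60, D = -0.77, C =  1.54,
  Q = -0.22, E = -0.64, G =  0.00, H =  0.13, I =  1.80,
  L =  1.70, K = -0.99, M =  1.23, F =  1.79, P =  0.72,
  S = -0.04, T =  0.26, W =  2.25, Y =  0.96, V =  1.22
)

# Van der Waals radii (A) for SASA, plus per-residue pseudo-radii for
# reduced (one sphere per residue) models, sized so that an isolated sphere
# reproduces the residue's theoretical maximum ASA with a 1.4 A probe.
ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

pseudo_radius <- function(aa, probe_radius = 1.4) {
  sqrt(MAX_ASA_TIEN[aa] / (4 * pi)) - probe_radius
}

# Human IgG1 CH1 constant domain (IGHG1*01 allele, 98 residues) and human
# kappa constant domain (IGKC allele, 107 residues). Both chains of every
# IgG1-kappa Fab in scope share these constant sequences.
IGHG1_CH1 <- paste0(
  "ASTKGPSVFPLAPSSKSTSGGTAALGCLVKDYFPEPVTVSWNSGALTSGVHTFPAVLQ",
  "SSGLYSLSSVVTVPSSSLGTQTYICNVNHKPSNTKVDKKV"
)
IGKC_CL <- paste0(
  "RTVAAPSVFIFPPSDEQLKSGTASVVCLLNNFYPREAKVQWKVDNALQSGNSQESVTE",
  "QDSKDSTYSLSSTLTLSKADYEKHKVYACEVTHQGLSSPVTKSFNRGEC"
)

# Seven beta-strand windows (A-G) per constant domain, 0-based half-open on
# the packaged allele sequences, following the IMGT C-domain strand layout.
C_STRAND_BOUNDS <- list(
  CH1 = data.frame(
    strand = LETTERS[1:7],
    start  = c(3L, 14L, 30L, 43L, 57L, 71L, 86L),
    end    = c(12L, 25L, 38L, 51L, 67L, 80L, 96L),
    stringsAsFactors = FALSE
  ),
  CL = data.frame(
    strand = LETTERS[1:7],
    start  = c(3L, 15L, 32L, 45L, 60L, 76L, 94L),
    end    = c(12L, 26L, 40L, 53L, 70L, 86L, 104L),
    stringsAsFactors = FALSE
  )
)

# --- residue property table registry -----------------------------------------

.fq_registry <- new.env(parent = emptyenv())

.init_registry <- function() {
  .fq_registry$tables <- list(
    kd  = KD_HYDROPATHY,
    gc  = GC_CONF_ENTROPY,
    wf  = WF_HYDRATION,
    dgw = DGW_TRANSFER
  )
}

#' Register a per-residue property table
#'
#' Adds (or replaces) a named per-residue table in the registry used by
#' [residue_property_sum()] and the descriptor builders. A table must supply
#' one finite value for each of the 20 canonical residues.
#'
#' @param name Table identifier.
#' @param table Named numeric vector over the 20 one-letter codes.
#' @return The table, invisibly.
#' @export
register_residue_table <- function(name, table) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!all(AA_LETTERS %in% names(table)) || any(!is.finite(table[AA_LETTERS]))) {
    stop("table must provide a finite value for all 20 canonical residues")
  }
  if (is.null(.fq_registry$tables)) .init_registry()
  .fq_registry$tables[[name]] <- table[AA_LETTERS]
  invisible(table)
}

#' List or fetch registered residue property tables
#'
#' @param name Optional table name; if omitted, returns the names of all
#'   registered tables. Packaged defaults: `kd` (Kyte-Doolittle hydropathy),
#'   `gc` (side-chain conformational entropy), `wf` (hydration number),
#'   `dgw` (water-octanol transfer energy).
#' @return Character vector of names, or the named numeric table.
#' @export
residue_tables <- function(name = NULL) {
  if (is.null(.fq_registry$tables)) .init_registry()
  if (is.null(name)) return(names(.fq_registry$tables))
  tab <- .fq_registry$tables[[name]]
  if (is.null(tab)) stop("UnknownTable: no registered residue table '", name, "'")
  tab
}

#' Packaged amino-acid scales
#'
#' Returns the packaged multi-component amino-acid scales as a named list of
#' `property_scale` objects: `z5` (5-component Z-scale), `t5` (5-component
#' T-scale) and `mswhim` (3-component MS-WHIM).
#' @return Named list of [property_scale()] objects.
#' @export
aa_scales <- function() {
  list(
    z5     = property_scale("z5", ZSCALE5),
    t5     = property_scale("t5", TSCALE5),
    mswhim = property_scale("mswhim", MSWHIM3)
  )
}

#' Theoretical maximum accessible surface areas
#'
#' Per-residue maximum ASA (in square Angstroms) of residue X in an extended
#' Gly-X-Gly tripeptide (theoretical values of Tien et al. 2013), the
#' denominator of relative solvent accessibility.
#' @return Named numeric vector over the 20 canonical residues.
#' @export
max_asa_table <- function() MAX_ASA_TIEN

.assert_canonical <- function(seq, what = "sequence") {
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), AA_LETTERS)
  if (length(bad)) {
    stop("UnknownResidue: ", what, " contains non-canonical letters: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
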