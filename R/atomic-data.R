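# Atomic masses and isotope abundances: CODATA/IUPAC 2013 values as tabulated
# in the NIST Atomic Weights and Isotopic Compositions database. Restricted to
# C/H/N/O/S, the elements of unmodified and carbamidomethylated peptides.

# Per element: isotope nominal offset from the lightest isotope, exact mass
# (Da), relative abundance (mole fraction).
.ELEMENT_ISOTOPES <- list(
  C = data.frame(
    offset = c(0L, 1L),
    mass = c(12.0000000, 13.00335484),
    abundance = c(0.9893, 0.0107)
  ),
  H = data.frame(
    offset = c(0L, 1L),
    mass = c(1.0078250319, 2.0141017781),
    abundance = c(0.999885, 0.000115)
  ),
  N = data.frame(
    offset = c(0L, 1L),
    mass = c(14.0030740052, 15.0001088984),
    abundance = c(0.99636, 0.00364)
  ),
  O = data.frame(
    offset = c(0L, 1L, 2L),
    mass = c(15.9949146221, 16.9991315, 17.9991604),
    abundance = c(0.99757, 0.00038, 0.00205)
  ),
  S = data.frame(
    offset = c(0L, 1L, 2L, 4L),
    mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
    abundance = c(0.9499, 0.0075, 0.0425, 0.0001)
  )
)

.ELEMENTS <- names(.ELEMENT_ISOTOPES)

#' Physical constants used throughout the package
#'
#' Proton (charge carrier) mass, the mass of a water molecule, and the
#' hydrogen-atom mass used for disulfide accounting.  All values in Da.
#'
#' @name constants
#' @keywords internal
NULL

PROTON_MASS <- 1.007276466
H_ATOM_MASS <- 1.0078250319
WATER_MASS <- 2 * 1.0078250319 + 15.9949146221
# 13C - 12C spacing used for isotope-cluster detection; adequate below 10 kDa
C13_SPACING <- 1.00336

# Residue (amino-acid minus water) elemental compositions, canonical 20.
# Rows: C H N O S.
.RESIDUE_COMP <- {
  m <- rbind(
    G = c(2, 3, 1, 1, 0),
    A = c(3, 5, 1, 1, 0),
    S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),
    V = c(5, 9, 1, 1, 0),
    T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),
    L = c(6, 11, 1, 1, 0),
    I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0),
    E = c(5, 7, 1, 3, 0),
    M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),
    F = c(9, 9, 1, 1, 0),
    R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),
    W = c(11, 10, 2, 1, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  storage.mode(m) <- "integer"
  m
}

.AA_LETTERS <- rownames(.RESIDUE_COMP)

# Monoisotopic residue masses derived from the composition table above so a
# single authoritative source feeds every mass in the package.
.RESIDUE_MONO <- {
  lightest <- vapply(.ELEMENT_ISOTOPES, function(d) d$mass[1], numeric(1))
  as.numeric(.RESIDUE_COMP %*% lightest[colnames(.RESIDUE_COMP)])
}
names(.RESIDUE_MONO) <- .AA_LETTERS

# Kyte-Doolittle hydropathy scale (signal-peptide core detection).
.KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Wimley-White interface hydrophobicity scale (kcal/mol, water -> POPC
# interface transfer free energy; negative = favourable/hydrophobic).
# Ionised forms used for D, E, H.
.WIMLEY_WHITE_INTERFACE <- c(
  A = 0.17, R = 0.81, N = 0.42, D = 1.23, C = -0.24, Q = 0.58, E = 2.02,
  G = 0.01, H = 0.96, I = -0.31, L = -0.56, K = 0.99, M = -0.23,
  F = -1.13, P = 0.45, S = 0.13, T = 0.14, W = -1.85, Y = -0.94, V = 0.07
)

# One representative codon per residue for reverse translation of synthetic
# precursors (frequent E. coli codons; no optimisation is attempted).
.REVERSE_CODON <- c(
  A = "GCG", R = "CGT", N = "AAT", D = "GAT", C = "TGC", Q = "CAG",
  E = "GAA", G = "GGC", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCG", S = "TCC", T = "ACC", W = "TGG",
  Y = "TAT", V = "GTG"
)

.validate_protein <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% .AA_LETTERS)
  if (length(bad) > 0) {
    stop(sprintf(
      "non-canonical residue '%s' at position %d of %s",
      chars[bad[1]], bad[1], what
    ), call. = FALSE)
  }
  invisible(chars)
}
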