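#' Residue composition and volume table
#'
#' Per-residue (in-chain, i.e. amino acid minus water) heavy-atom and
#' hydrogen composition, labile (exchangeable) hydrogen count, partial
#' volume, average mass and typical abundance for the 20 standard amino
#' acids.  Volumes are displaced-solvent residue volumes after Fraser,
#' MacRae and Suzuki (J Appl Cryst 1978), the table adopted by standard
#' solution-scattering software; the displaced volume (not the
#' crystal-packing volume) is the quantity that enters the excess
#' scattering length.  Abundances are overall frequencies in sequence
#' databases.  Exchangeable hydrogens are all O-H, N-H and S-H hydrogens
#' of the neutral residue (backbone amide plus side chain).
#'
#' A pseudo-residue `AVE`, the abundance-weighted mean composition, is
#' appended for synthetic bead models that carry no real sequence.
#'
#' @return A data frame with one row per residue: `resname`, element
#'   counts `C`, `H`, `N`, `O`, `S`, exchangeable-hydrogen count `Hexch`,
#'   `volume` (cubic Angstrom), `mass` (Da), `electrons`, `abundance`.
#' @export
residue_table <- function() {
  .residue_table
}

.residue_table_build <- function() {
  # resname  C  H  N  O  S Hexch  volume abundance
  raw <- c(
    "GLY", 2,  3, 1, 1, 0, 1,  66.4, 7.07,
    "ALA", 3,  5, 1, 1, 0, 1,  91.5, 8.25,
    "SER", 3,  5, 1, 2, 0, 2,  99.1, 6.56,
    "PRO", 5,  7, 1, 1, 0, 0, 129.3, 4.70,
    "VAL", 5,  9, 1, 1, 0, 1, 141.7, 6.87,
    "THR", 4,  7, 1, 2, 0, 2, 122.1, 5.34,
    "CYS", 3,  5, 1, 1, 1, 2, 105.6, 1.37,
    "LEU", 6, 11, 1, 1, 0, 1, 167.9, 9.66,
    "ILE", 6, 11, 1, 1, 0, 1, 168.8, 5.96,
    "ASN", 4,  6, 2, 2, 0, 3, 135.2, 4.06,
    "ASP", 4,  5, 1, 3, 0, 2, 113.6, 5.45,
    "GLN", 5,  8, 2, 2, 0, 3, 161.1, 3.93,
    "LYS", 6, 12, 2, 1, 0, 3, 176.2, 5.84,
    "GLU", 5,  7, 1, 3, 0, 2, 140.6, 6.75,
    "MET", 5,  9, 1, 1, 1, 1, 170.8, 2.42,
    "HIS", 6,  7, 3, 1, 0, 2, 167.3, 2.27,
    "PHE", 9,  9, 1, 1, 0, 1, 203.4, 3.86,
    "ARG", 6, 12, 4, 1, 0, 5, 180.8, 5.53,
    "TYR", 9,  9, 1, 2, 0, 2, 203.6, 2.92,
    "TRP", 11, 10, 2, 1, 0, 2, 237.6, 1.08
  )
  m <- matrix(raw, ncol = 9, byrow = TRUE)
  tab <- data.frame(
    resname = m[, 1],
    C = as.numeric(m[, 2]), H = as.numeric(m[, 3]),
    N = as.numeric(m[, 4]), O = as.numeric(m[, 5]),
    S = as.numeric(m[, 6]), Hexch = as.numeric(m[, 7]),
    volume = as.numeric(m[, 8]), abundance = as.numeric(m[, 9]) / 100,
    stringsAsFactors = FALSE
  )
  amass <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)
  z <- c(C = 6, H = 1, N = 7, O = 8, S = 16)
  tab$mass <- as.numeric(as.matrix(tab[, c("C", "H", "N", "O", "S")]) %*% amass)
  tab$electrons <- as.numeric(as.matrix(tab[, c("C", "H", "N", "O", "S")]) %*% z)
  # abundance-weighted mean pseudo-residue
  w <- tab$abundance / sum(tab$abundance)
  ave <- data.frame(
    resname = "AVE",
    C = sum(w * tab$C), H = sum(w * tab$H), N = sum(w * tab$N),
    O = sum(w * tab$O), S = sum(w * tab$S), Hexch = sum(w * tab$Hexch),
    volume = sum(w * tab$volume), abundance = 0,
    mass = sum(w * tab$mass), electrons = sum(w * tab$electrons),
    stringsAsFactors = FALSE
  )
  rbind(tab, ave)
}

.residue_table <- .residue_table_build()

#' Coherent neutron scattering lengths and solvent constants
#'
#' Bound coherent scattering lengths (fm) for the elements occurring in
#' proteins, plus deuterium, and reference solvent densities.
#'
#' @return Named list with `b` (named numeric vector of scattering
#'   lengths, fm), `water_volume` (cubic Angstrom per molecule) and
#'   `water_edens` (electrons per cubic Angstrom of liquid water).
#' @export
scattering_constants <- function() {
  list(
    b = c(H = -3.7390, D = 6.6710, C = 6.6460, N = 9.3600,
          O = 5.8030, S = 2.8470),
    water_volume = 29.9,
    water_edens = 0.334
  )
}

.lookup_residues <- function(resnames) {
  tab <- .residue_table
  idx <- match(resnames, tab$resname)
  if (anyNA(idx)) {
    stop("unknown residue name(s): ",
         paste(unique(resnames[is.na(idx)]), collapse = ", "))
  }
  tab[idx, , drop = FALSE]
}

#' Neutron scattering-length density of an H2O/D2O mixture
#'
#' @param d2o D2O volume fraction in `[0, 1]`.
#' @return Scattering-length density in fm per cubic Angstrom.
#' @export
solvent_sld <- function(d2o) {
  stopifnot(d2o >= 0, d2o <= 1)
  k <- scattering_constants()
  b_mol <- 2 * ((1 - d2o) * k$b[["H"]] + d2o * k$b[["D"]]) + k$b[["O"]]
  b_mol / k$water_volume
}
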