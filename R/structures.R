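#' Read an atomic structure from PDB or mmCIF
#'
#' Thin wrapper over [bio3d::read.pdb()] / [bio3d::read.cif()] returning a
#' plain per-atom data frame (`atom_model`).  All chains of the first
#' model are returned unless `chain` / `model` select otherwise.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param chain Optional character vector of chain ids to keep.
#' @param model Model number to read (default 1).
#' @return An `atom_model`: data frame with columns `element`, `name`,
#'   `resid`, `resname`, `chain`, `x`, `y`, `z`, `occupancy` and an
#'   attribute `source`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           chain = NULL, model = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- if (format == "cif") {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, multi = (model > 1), verbose = FALSE)
  }
  at <- pdb$atom
  if (model > 1) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model) {
      stop("model ", model, " not present in ", path)
    }
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  elem <- at$elesy
  fix <- is.na(elem) | !nzchar(trimws(elem))
  if (any(fix)) elem[fix] <- substr(gsub("[0-9 ]", "", at$elety[fix]), 1, 1)
  out <- data.frame(
    element = trimws(elem), name = trimws(at$elety),
    resid = at$resno, resname = trimws(at$resid),
    chain = as.character(at$chain),
    x = at$x, y = at$y, z = at$z,
    occupancy = if (!is.null(at$o)) at$o else 1,
    stringsAsFactors = FALSE
  )
  if (!is.null(chain)) out <- out[out$chain %in% chain, , drop = FALSE]
  if (nrow(out) == 0L) stop("no atoms after selection in ", path)
  if (!all(is.finite(out$x) & is.finite(out$y) & is.finite(out$z))) {
    stop("non-finite coordinates in ", path)
  }
  attr(out, "source") <- path
  class(out) <- c("atom_model", class(out))
  out
}

#' Construct a bead model from explicit columns
#'
#' The residue-level bead representation used throughout the package: one
#' bead per residue carrying position, mass, a component label (which
#' protein the bead belongs to), a domain label and a deuteration
#' fraction of its non-exchangeable hydrogens.
#'
#' @param x,y,z Coordinates in Angstrom.
#' @param resname Residue names (rows of [residue_table()]).
#' @param resid Residue indices.
#' @param chain Chain ids.
#' @param mass Bead masses in Da; defaults to the residue-table mass.
#' @param component Component label per bead (e.g. `"A"`, `"B"`, `"C"`,
#'   `"linker"`).
#' @param domain Domain label per bead.
#' @param deut Deuteration fraction of non-exchangeable hydrogens, in
#'   `[0, 1]`.
#' @return A `bead_model` data frame.
#' @export
bead_model <- function(x, y, z, resname = "AVE", resid = seq_along(x),
                       chain = "A", mass = NULL, component = "A",
                       domain = component, deut = 0) {
  n <- length(x)
  if (is.null(mass)) mass <- .lookup_residues(rep_len(resname, n))$mass
  out <- data.frame(
    chain = rep_len(chain, n), resid = rep_len(resid, n),
    resname = rep_len(resname, n),
    x = x, y = y, z = z, mass = rep_len(mass, n),
    component = rep_len(component, n), domain = rep_len(domain, n),
    deut = rep_len(deut, n), stringsAsFactors = FALSE
  )
  stopifnot(all(out$deut >= 0 & out$deut <= 1),
            all(is.finite(out$x)), all(is.finite(out$y)),
            all(is.finite(out$z)))
  class(out) <- c("bead_model", class(out))
  out
}

.as_xyz <- function(model) {
  cbind(model$x, model$y, model$z)
}

.set_xyz <- function(model, xyz) {
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

.rebead <- function(df) {
  class(df) <- unique(c("bead_model", class(df)))
  df
}

#' Coarse-grain an atomic model to one bead per residue
#'
#' @param model An `atom_model` from [read_structure()].
#' @param placement `"com"` places each bead at the mass-weighted centroid
#'   of its residue's atoms (closest one-bead surrogate of the scattering
#'   mass distribution, the default); `"CA"` uses the alpha-carbon.
#' @param component,domain Either a single label or a function
#'   `f(chain, resname, resid)` returning per-residue labels.
#' @return A `bead_model` with one bead per residue; masses are standard
#'   residue masses and deuteration defaults to 0.
#' @export
coarse_grain <- function(model, placement = c("com", "CA"),
                         component = "A", domain = component) {
  placement <- match.arg(placement)
  key <- paste(model$chain, model$resid, sep = "\r")
  idx <- split(seq_len(nrow(model)), factor(key, levels = unique(key)))
  amass <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06,
             P = 30.974, FE = 55.845, ZN = 65.38, MG = 24.305)
  rows <- lapply(idx, function(i) {
    sub <- model[i, , drop = FALSE]
    if (placement == "CA") {
      j <- which(sub$name == "CA")
      if (length(j) == 0L) {
        stop("residue ", sub$chain[1], ":", sub$resid[1], " has no CA atom")
      }
      pos <- c(sub$x[j[1]], sub$y[j[1]], sub$z[j[1]])
    } else {
      w <- amass[toupper(sub$element)]
      w[is.na(w)] <- 12
      pos <- c(sum(w * sub$x), sum(w * sub$y), sum(w * sub$z)) / sum(w)
    }
    c(pos, i[1])
  })
  m <- do.call(rbind, rows)
  first <- m[, 4]
  resname <- model$resname[first]
  known <- resname %in% .residue_table$resname
  mass <- numeric(length(resname))
  mass[known] <- .lookup_residues(resname[known])$mass
  mass[!known] <- 110  # fallback for unknown residue types
  lab <- function(l) {
    if (is.function(l)) l(model$chain[first], resname, model$resid[first])
    else rep_len(l, length(first))
  }
  bead_model(
    x = m[, 1], y = m[, 2], z = m[, 3],
    resname = resname, resid = model$resid[first],
    chain = model$chain[first], mass = mass,
    component = lab(component), domain = lab(domain), deut = 0
  )
}

#' Mass-weighted centre of mass
#'
#' @param model A `bead_model` (or any data frame with `x`, `y`, `z` and
#'   `mass`).
#' @param select Optional logical or integer index of beads.
#' @return Numeric xyz of the mass-weighted centroid.
#' @export
com <- function(model, select = NULL) {
  if (!is.null(select)) model <- model[select, , drop = FALSE]
  if (nrow(model) == 0L) stop("empty selection")
  w <- model$mass
  c(sum(w * model$x), sum(w * model$y), sum(w * model$z)) / sum(w)
}

#' Write / read bead models as plain tabular text
#'
#' One row per bead: chain, resid, resname, x, y, z, mass, component,
#' domain, deuteration.  The format round-trips exactly.
#'
#' @param model A `bead_model`.
#' @param path Output (input) file.
#' @return `read_beads` returns the `bead_model`; `write_beads` its path,
#'   invisibly.
#' @export
write_beads <- function(model, path) {
  df <- as.data.frame(model)[, c("chain", "resid", "resname", "x", "y", "z",
                                 "mass", "component", "domain", "deut")]
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_beads
#' @export
read_beads <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = list(chain = "character"))
  .rebead(df)
}

#' Write one or more bead models as a multi-model PDB
#'
#' Each bead becomes a CA pseudo-atom; each model/frame a `MODEL` block.
#' Chain ids longer than one character are compressed to single letters
#' (PDB column limits); the tabular format of [write_beads()] is the
#' lossless alternative.
#'
#' @param models A `bead_model` or list of them (identical topology).
#' @param path Output file.
#' @export
write_beads_pdb <- function(models, path) {
  if (inherits(models, "bead_model")) models <- list(models)
  chains <- unique(models[[1]]$chain)
  letters62 <- c(LETTERS, letters, 0:9)
  cmap <- stats::setNames(rep_len(letters62, length(chains)), chains)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    b <- models[[m]]
    lines <- sprintf(
      "ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(b)) %% 100000, substr(b$resname, 1, 3),
      cmap[b$chain], b$resid %% 10000, b$x, b$y, b$z, 1, 0
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
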