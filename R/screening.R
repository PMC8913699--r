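#' Screening thresholds
#'
#' The staged chi-square acceptance thresholds: stage A on SAXS, stage B
#' on iCM-SANS for stage-A survivors, then the tighter refined and
#' post-linker stages.  Defaults are the study-design values (10.0 / 3.0,
#' then 6.0 / 1.5, then 5.0 / 1.5).
#'
#' @param saxs,sans Stage A / B maxima.
#' @param refined Length-2 `(saxs, sans)` maxima for the refined stage.
#' @param post_linker Length-2 `(saxs, sans)` maxima after linker
#'   completion.
#' @return A `screen_thresholds` object.
#' @export
screen_thresholds <- function(saxs = 10.0, sans = 3.0,
                              refined = c(6.0, 1.5),
                              post_linker = c(5.0, 1.5)) {
  stopifnot(saxs > 0, sans > 0, all(refined > 0), all(post_linker > 0))
  structure(list(saxs = saxs, sans = sans, refined = refined,
                 post_linker = post_linker), class = "screen_thresholds")
}

#' Two-stage chi-square screening of candidate models
#'
#' Stage A computes the SAXS chi-square of every candidate and keeps
#' those under the SAXS threshold; stage B computes the iCM-SANS
#' chi-square *only* for stage-A survivors (short-circuit, as the
#' staging prescribes) and keeps those under the SANS threshold.  All
#' computed scores are recorded; SANS scores of stage-A failures are
#' `NA`.
#'
#' @param candidates List of [candidate_model()]s.
#' @param exp_saxs,exp_sans Experimental `sas_profile`s with `sigma`.
#' @param thresholds A [screen_thresholds()].
#' @param spec A [contrast_spec()] for the SANS channel.
#' @param method,bin Passed to [debye_profile()].
#' @return A `screen_report`: list with `candidates` (the input),
#'   `table` (per-candidate data frame: `id`, `chi2_saxs`, `pass_saxs`,
#'   `chi2_sans`, `pass_sans`, `pass`, `combined`, `rank`) and `summary`
#'   (stage counts).  Ranks order passing candidates by combined
#'   chi-square (SAXS + SANS), then non-passing ones.
#' @export
two_stage_screen <- function(candidates, exp_saxs, exp_sans,
                             thresholds = screen_thresholds(),
                             spec = contrast_spec(),
                             method = "histogram", bin = 0.5) {
  if (length(candidates) == 0L) stop("empty candidate set")
  if (is.null(exp_saxs$sigma) || is.null(exp_sans$sigma)) {
    stop("experimental profiles must carry sigma")
  }
  n <- length(candidates)
  chi_x <- numeric(n); chi_n <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    full <- expand_candidate(candidates[[i]])
    calc <- debye_profile(full, exp_saxs$Q, channel = "xray",
                          method = method, bin = bin)
    chi_x[i] <- chi2_score(calc, exp_saxs)$chi2
    if (chi_x[i] < thresholds$saxs) {
      calc_n <- icm_sans_profile(full, exp_sans$Q, spec = spec,
                                 method = method, bin = bin)
      chi_n[i] <- chi2_score(calc_n, exp_sans)$chi2
    }
  }
  pass_a <- chi_x < thresholds$saxs
  pass_b <- !is.na(chi_n) & chi_n < thresholds$sans
  combined <- ifelse(pass_a & pass_b, chi_x + chi_n, Inf)
  ord <- order(!(pass_a & pass_b), combined, chi_x)
  rank <- integer(n); rank[ord] <- seq_len(n)
  ids <- vapply(candidates, function(cd) as.numeric(cd$id), numeric(1))
  tab <- data.frame(id = ids, chi2_saxs = chi_x, pass_saxs = pass_a,
                    chi2_sans = chi_n, pass_sans = pass_b,
                    pass = pass_a & pass_b,
                    combined = ifelse(is.finite(combined), combined, NA),
                    rank = rank)
  structure(list(candidates = candidates, table = tab,
                 thresholds = thresholds,
                 summary = c(n = n, pass_saxs = sum(pass_a),
                             pass_both = sum(pass_a & pass_b))),
            class = "screen_report")
}

#' Re-apply tighter thresholds to an existing screen report
#'
#' Screening is monotone in the thresholds, so the refined and
#' post-linker stages reuse the recorded scores.  Candidates whose SANS
#' score was short-circuited away cannot pass.
#'
#' @param report A `screen_report`.
#' @param saxs,sans New maxima.
#' @return Logical vector of survivors under the tighter thresholds.
#' @export
rethreshold <- function(report, saxs, sans) {
  with(report$table,
       chi2_saxs < saxs & !is.na(chi2_sans) & chi2_sans < sans)
}

#' Position type of a candidate relative to the reference plane
#'
#' Type 1: both mobile-domain centres of mass strictly below the
#' reference plane `z0`; Type 2: exactly one below; Type 3: both at or
#' above.
#'
#' @param cand A `candidate_model`.
#' @param frame Defaults to the candidate's frame.
#' @return Integer 1, 2 or 3.
#' @export
classify_type <- function(cand, frame = cand$frame) {
  z1 <- cylindrical(.domain_com(cand, 1), frame)[, "z"]
  z2 <- cylindrical(.domain_com(cand, 2), frame)[, "z"]
  below <- c(z1 < frame$z0, z2 < frame$z0)
  c(3L, 2L, 1L)[sum(below) + 1L]
}

.domain_com <- function(cand, which_domain) {
  tpl <- if (which_domain == 1) cand$templates$N1A else cand$templates$N2A
  p <- if (which_domain == 1) cand$pose1 else cand$pose2
  placed <- .place_template(tpl, p, cand$frame)
  matrix(com(placed), 1)
}

#' Cylindrical cell grid for mobile-domain classification
#'
#' Cells live in the cylindrical coordinates of the complex frame with
#' the azimuth folded into one symmetry sector (`theta mod 360/sym`).
#' Two rings (U above, L below a dividing height) each hold two named
#' cells.  All bins are half-open `[lo, hi)`.
#'
#' @param cells Data frame with columns `cell` (e.g. `"U1"`), `rmin`,
#'   `rmax`, `thmin`, `thmax` (folded degrees), `zmin`, `zmax`.
#' @param sym Symmetry order used for the azimuth folding.
#' @return A `cell_grid` object.
#' @export
cell_grid <- function(cells, sym = 6) {
  need <- c("cell", "rmin", "rmax", "thmin", "thmax", "zmin", "zmax")
  stopifnot(all(need %in% names(cells)))
  structure(list(cells = cells, sym = sym), class = "cell_grid")
}

#' Data-driven cell grid from survivor positions
#'
#' Splits positions into U/L rings at the midpoint of the z range, then
#' 2-means clusters each ring in folded `(r sin, r cos, z)` to locate the
#' two cells, and draws half-open boxes at the cluster boundaries.  A
#' convenience for exploratory work; classification against a designed
#' grid should construct [cell_grid()] explicitly.
#'
#' @param coms n x 3 matrix of lab-frame domain centres of mass.
#' @param frame A [complex_frame()].
#' @param sym Symmetry order.
#' @return A `cell_grid`.
#' @export
fit_cell_grid <- function(coms, frame, sym = 6) {
  cyl <- cylindrical(coms, frame)
  fold <- cyl[, "theta"] %% (360 / sym)
  zsplit <- mean(range(cyl[, "z"]))
  mk <- function(idx, ring) {
    if (length(idx) < 2) return(NULL)
    km <- stats::kmeans(cbind(fold[idx], cyl[idx, "z"]), centers = 2,
                        nstart = 5)
    ord <- order(km$centers[, 1])
    do.call(rbind, lapply(seq_along(ord), function(i) {
      m <- idx[km$cluster == ord[i]]
      data.frame(cell = paste0(ring, i),
                 rmin = min(cyl[m, "r"]) - 5, rmax = max(cyl[m, "r"]) + 5,
                 thmin = max(0, min(fold[m]) - 2),
                 thmax = min(360 / sym, max(fold[m]) + 2),
                 zmin = min(cyl[m, "z"]) - 5, zmax = max(cyl[m, "z"]) + 5)
    }))
  }
  up <- which(cyl[, "z"] >= zsplit); lo <- which(cyl[, "z"] < zsplit)
  cell_grid(rbind(mk(up, "U"), mk(lo, "L")), sym = sym)
}

#' Assign mobile-domain centres of mass to cells
#'
#' Each position is converted to cylindrical frame coordinates, the
#' azimuth folded into one sector, and matched against the grid's
#' half-open cells; positions in no cell are `"unclassified"`.
#'
#' @param coms Length-3 vector or n x 3 matrix of lab coordinates.
#' @param grid A [cell_grid()].
#' @param frame A [complex_frame()].
#' @return Data frame with `cell`, `ring`, `sector`, `r`, `theta`, `z`.
#' @export
assign_cells <- function(coms, grid, frame) {
  if (!is.matrix(coms)) coms <- matrix(coms, ncol = 3)
  cyl <- cylindrical(coms, frame)
  sector_width <- 360 / grid$sym
  fold <- cyl[, "theta"] %% sector_width
  sector <- floor(cyl[, "theta"] / sector_width)
  cells <- rep("unclassified", nrow(cyl))
  for (i in seq_len(nrow(grid$cells))) {
    cdef <- grid$cells[i, ]
    hit <- cyl[, "r"] >= cdef$rmin & cyl[, "r"] < cdef$rmax &
      fold >= cdef$thmin & fold < cdef$thmax &
      cyl[, "z"] >= cdef$zmin & cyl[, "z"] < cdef$zmax &
      cyl[, "r"] > 1e-9
    cells[hit & cells == "unclassified"] <- cdef$cell
  }
  data.frame(cell = cells, ring = substr(cells, 1, 1),
             sector = ifelse(cells == "unclassified", NA, sector),
             r = cyl[, "r"], theta = cyl[, "theta"], z = cyl[, "z"],
             stringsAsFactors = FALSE)
}

#' Classify a list of candidates by type, cells and group
#'
#' Convenience wrapper applying [classify_type()], [assign_cells()] and
#' [classify_group()] to each candidate.
#'
#' @param candidates List of `candidate_model`s.
#' @param grid A [cell_grid()].
#' @param sector_offset Passed to [classify_group()].
#' @return Data frame with `id`, `type`, `cell_n1a`, `cell_n2a`,
#'   `sector_n1a`, `sector_n2a`, `group`.
#' @export
classify_candidates <- function(candidates, grid, sector_offset = 0) {
  rows <- lapply(candidates, function(cd) {
    a1 <- assign_cells(.domain_com(cd, 1), grid, cd$frame)
    a2 <- assign_cells(.domain_com(cd, 2), grid, cd$frame)
    data.frame(id = as.numeric(cd$id), type = classify_type(cd),
               cell_n1a = a1$cell, cell_n2a = a2$cell,
               sector_n1a = a1$sector, sector_n2a = a2$sector,
               group = classify_group(a1$cell, a2$cell, sector_offset),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default sector-offset tables for group labelling
#'
#' Maps the azimuthal sector offset between an N-domain and its own
#' C-domain to a group label, per cell combination.  The offsets
#' distinguishing the groups that share a cell pair come from the
#' supplementary classification scheme and are configurable; this
#' default maps offsets 0 / +1 / -1 to the first / second / third label.
#'
#' @return Named list of offset tables keyed by `"cellN1A|cellN2A"`.
#' @export
default_group_offsets <- function() {
  list(
    "U1|L1" = c("0" = "I", "1" = "II", "-1" = "III"),
    "L1|U1" = c("0" = "III'", "1" = "III'", "-1" = "III'"),
    "U1|L2" = c("0" = "IV", "1" = "V", "-1" = "V"),
    "L2|U1" = c("0" = "V'", "1" = "V'", "-1" = "V'"),
    "U2|L2" = c("0" = "VI", "1" = "VI", "-1" = "VI")
  )
}

#' Group label of a candidate from its cells and linker connectivity
#'
#' The label depends only on the cells of the two mobile domains and on
#' which C-domain each links to, expressed as the sector offset between
#' the N1A domain and its own C-domain.  Cell pairs outside the table
#' (including unclassified cells) are `"unclassified"`.
#'
#' @param cell_n1a,cell_n2a Cell names (`"U1"`, `"U2"`, `"L1"`, `"L2"`).
#' @param sector_offset Integer azimuthal sector offset of N1A relative
#'   to its connected C-domain, folded to -1/0/+1.
#' @param offsets Offset tables, see [default_group_offsets()].
#' @return Group label string (`"I"` .. `"VI"`, `"III'"`, `"V'"`, or
#'   `"unclassified"`).
#' @export
classify_group <- function(cell_n1a, cell_n2a, sector_offset = 0,
                           offsets = default_group_offsets()) {
  key <- paste(cell_n1a, cell_n2a, sep = "|")
  tab <- offsets[[key]]
  if (is.null(tab)) return("unclassified")
  off <- as.character(((sector_offset + 1) %% 3) - 1)
  lab <- tab[[off]]
  if (is.null(lab) || is.na(lab)) "unclassified" else lab
}

#' Cell-correlation count map over survivors
#'
#' Counts surviving models per (N1A cell, N2A cell) pair; the matrix
#' total equals the number of survivors.
#'
#' @param cells_n1a,cells_n2a Character vectors of cell names, one entry
#'   per survivor.
#' @return Integer matrix, rows = N1A cells, columns = N2A cells.
#' @export
cell_correlation_map <- function(cells_n1a, cells_n2a) {
  if (length(cells_n1a) == 0L) stop("empty survivor set")
  stopifnot(length(cells_n1a) == length(cells_n2a))
  lev <- c("U1", "U2", "L1", "L2", "unclassified")
  tab <- table(factor(cells_n1a, levels = lev),
               factor(cells_n2a, levels = lev))
  m <- matrix(as.integer(tab), nrow = length(lev), ncol = length(lev),
              dimnames = dimnames(tab))
  m
}
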