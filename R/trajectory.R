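#' Trajectory of a bead model
#'
#' Ordered frames sharing one topology: coordinates are held as an
#' `n_beads x 3 x n_frames` array over a single `bead_model` topology.
#'
#' @param topology A `bead_model` (labels, masses; its coordinates are
#'   ignored in favour of `coords`).
#' @param coords `n_beads x 3 x n_frames` numeric array.
#' @param dt Frame interval in ps (metadata, optional).
#' @return A `bead_trajectory` object.
#' @export
bead_trajectory <- function(topology, coords, dt = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[1] == nrow(topology),
            dim(coords)[2] == 3)
  if (dim(coords)[3] < 2) stop("a trajectory needs at least 2 frames")
  structure(list(topology = topology, coords = coords, dt = dt,
                 aligned = FALSE), class = "bead_trajectory")
}

#' @rdname bead_trajectory
#' @param traj A `bead_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname bead_trajectory
#' @param i Frame index.
#' @return `frame_model()`: the topology with frame-`i` coordinates.
#' @export
frame_model <- function(traj, i) {
  .set_xyz(traj$topology, traj$coords[, , i])
}

#' Read a trajectory from multi-model PDB or DCD
#'
#' Multi-model PDB files are read with one frame per `MODEL` block; DCD
#' files need a PDB topology.  Atomic frames are coarse-grained to
#' residue beads on load (the per-residue weights are computed once, so
#' this commutes with coarse-graining each frame separately).
#'
#' @param topology_path PDB file defining the topology.
#' @param frames_path Optional DCD file; omit to take frames from the
#'   multi-model topology file itself.
#' @param coarse Coarse-grain placement, as in [coarse_grain()], or
#'   `"none"` if the file already holds one atom per bead.
#' @param dt Frame interval metadata (ps).
#' @param ... Labelling arguments forwarded to [coarse_grain()].
#' @return A `bead_trajectory`.
#' @export
read_trajectory <- function(topology_path, frames_path = NULL,
                            coarse = c("com", "CA", "none"), dt = NULL,
                            ...) {
  coarse <- match.arg(coarse)
  pdb <- bio3d::read.pdb(topology_path, multi = TRUE, verbose = FALSE)
  xyz <- if (is.null(frames_path)) {
    pdb$xyz
  } else {
    bio3d::read.dcd(frames_path, verbose = FALSE)
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_at <- nrow(pdb$atom)
  if (ncol(xyz) != 3 * n_at) {
    stop("frame coordinate count (", ncol(xyz) / 3,
         ") does not match topology atom count (", n_at, ")")
  }
  if (nrow(xyz) < 2) stop("a trajectory needs at least 2 frames")
  amod <- read_structure(topology_path)
  if (coarse == "none") {
    topo <- coarse_grain(amod, placement = "CA", ...)
    sel <- which(amod$name == "CA")
    if (length(sel) != nrow(topo)) sel <- seq_len(nrow(amod))
    coords <- array(NA_real_, c(nrow(topo), 3, nrow(xyz)))
    for (f in seq_len(nrow(xyz))) {
      m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      coords[, , f] <- m[sel, , drop = FALSE]
    }
  } else {
    topo <- coarse_grain(amod, placement = coarse, ...)
    key <- paste(amod$chain, amod$resid, sep = "\r")
    grp <- match(key, unique(key))
    amass <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)
    w <- if (coarse == "com") {
      wt <- amass[toupper(amod$element)]; wt[is.na(wt)] <- 12; wt
    } else {
      as.numeric(amod$name == "CA")
    }
    wsum <- tapply(w, grp, sum)
    coords <- array(NA_real_, c(nrow(topo), 3, nrow(xyz)))
    for (f in seq_len(nrow(xyz))) {
      m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      for (k in 1:3) {
        coords[, k, f] <- as.numeric(tapply(w * m[, k], grp, sum) / wsum)
      }
    }
  }
  bead_trajectory(topo, coords, dt = dt)
}

.align_frames <- function(coords, align_idx, mass = NULL, ref = NULL) {
  nf <- dim(coords)[3]
  if (is.null(ref)) ref <- coords[align_idx, , 1, drop = TRUE]
  out <- coords
  for (f in seq_len(nf)) {
    sp <- superpose(coords[align_idx, , f], ref)
    out[, , f] <- apply_transform(coords[, , f], sp$transform)
  }
  out
}

#' Center-of-mass RMSF per domain over a trajectory
#'
#' Frames are least-squares aligned on a rigid core selection, then for
#' each domain selection the root-mean-square fluctuation of its
#' mass-weighted centre of mass about its trajectory mean is computed.
#'
#' @param traj A `bead_trajectory`.
#' @param selections Named list of bead index vectors (one per domain).
#' @param align Bead indices of the rigid core used for alignment; `NULL`
#'   skips alignment.
#' @return List with `rmsf` (named per-domain values, Angstrom), `mean`,
#'   `se` (standard error of the per-domain mean).
#' @export
rmsf_com <- function(traj, selections, align = NULL) {
  if (length(selections) == 0L) stop("empty selection list")
  coords <- traj$coords
  if (!is.null(align)) coords <- .align_frames(coords, align)
  nf <- dim(coords)[3]
  mass <- traj$topology$mass
  rmsf <- vapply(selections, function(sel) {
    if (length(sel) == 0L) stop("empty domain selection")
    w <- mass[sel] / sum(mass[sel])
    cm <- t(vapply(seq_len(nf), function(f) {
      colSums(matrix(coords[sel, , f], ncol = 3) * w)
    }, numeric(3)))
    mu <- colMeans(cm)
    sqrt(mean(rowSums(sweep(cm, 2, mu)^2)))
  }, numeric(1))
  list(rmsf = rmsf, mean = mean(rmsf),
       se = stats::sd(rmsf) / sqrt(length(rmsf)))
}

#' Dynamical cross-correlation map
#'
#' Normalized covariance of positional fluctuations,
#' `c_ij / sqrt(c_ii c_jj)` with
#' `c_ij = <(r_i - <r_i>) . (r_j - <r_j>)>`, computed after alignment.
#' Alignment is either global (one index vector) or per group (a list of
#' `list(align =, members =)`, e.g. each dimer RMS-fitted on its own
#' rigid domains so the motions of all dimers are compared in a common
#' internal frame).
#'
#' Beads with zero positional variance get `NA` rows/columns with a
#' warning rather than propagating NaN.
#'
#' @param traj A `bead_trajectory`.
#' @param selection Bead indices over which the map is computed.
#' @param align Index vector, list of groups, or `NULL`.
#' @return A symmetric matrix with unit diagonal (class `dccm_matrix`),
#'   entries in `[-1, 1]`.
#' @export
dccm <- function(traj, selection = seq_len(nrow(traj$topology)),
                 align = NULL) {
  coords <- traj$coords
  if (!is.null(align)) {
    if (is.list(align)) {
      ref_done <- FALSE
      ref <- NULL
      for (g in align) {
        sub <- coords[g$members, , , drop = FALSE]
        nf <- dim(coords)[3]
        loc <- match(g$align, g$members)
        if (anyNA(loc)) stop("group align indices must be members")
        if (!ref_done) {  # common reference: first group's first frame
          ref <- sub[loc, , 1, drop = TRUE]
          ref_done <- TRUE
        }
        for (f in seq_len(nf)) {
          sp <- superpose(sub[loc, , f], ref)
          sub[, , f] <- apply_transform(sub[, , f], sp$transform)
        }
        coords[g$members, , ] <- sub
      }
    } else {
      coords <- .align_frames(coords, align)
    }
  }
  X <- coords[selection, , , drop = FALSE]
  nf <- dim(X)[3]
  mu <- apply(X, c(1, 2), mean)
  D <- X - array(mu, dim(X))
  n <- length(selection)
  C <- matrix(0, n, n)
  for (k in 1:3) {
    Dk <- matrix(D[, k, ], nrow = n)
    C <- C + tcrossprod(Dk) / nf
  }
  v <- diag(C)
  bad <- v < 1e-12
  if (any(bad)) {
    warning(sum(bad), " zero-variance bead(s); entries set to NA")
  }
  s <- sqrt(ifelse(bad, NA, v))
  M <- C / outer(s, s)
  dg <- diag(M); dg[!bad] <- 1; diag(M) <- dg
  rownames(M) <- colnames(M) <- selection
  class(M) <- c("dccm_matrix", class(M))
  M
}

#' Per-frame and ensemble-averaged scattering of a trajectory
#'
#' Computes per-frame SAXS and iCM-SANS Debye profiles on the
#' experimental grids, the chi-square time series against both
#' experiments, the ensemble-averaged profiles (unweighted mean
#' intensity over frames), the chi-squares of the averaged profiles and
#' the per-frame Guinier radii.
#'
#' @param traj A `bead_trajectory`.
#' @param exp_saxs,exp_sans Experimental `sas_profile`s with `sigma`.
#' @param spec A [contrast_spec()].
#' @param every Use every `every`-th frame.
#' @param method,bin Passed to [debye_profile()].
#' @return List with `chi2_saxs_t`, `chi2_sans_t`, `rg_saxs_t`,
#'   `rg_sans_t`, `avg_saxs`, `avg_sans` (profiles), `avg_chi2_saxs`,
#'   `avg_chi2_sans`, `mean_rg_saxs`, `mean_rg_sans`, `frames`.
#' @export
profile_series <- function(traj, exp_saxs, exp_sans,
                           spec = contrast_spec(), every = 1,
                           method = "histogram", bin = 0.5) {
  frames <- seq(1, n_frames(traj), by = every)
  nf <- length(frames)
  Ix <- matrix(NA_real_, length(exp_saxs$Q), nf)
  In <- matrix(NA_real_, length(exp_sans$Q), nf)
  chi_x <- chi_n <- rg_x <- rg_n <- numeric(nf)
  for (i in seq_len(nf)) {
    m <- frame_model(traj, frames[i])
    px <- debye_profile(m, exp_saxs$Q, channel = "xray", method = method,
                        bin = bin)
    pn <- icm_sans_profile(m, exp_sans$Q, spec = spec, method = method,
                           bin = bin)
    Ix[, i] <- px$I; In[, i] <- pn$I
    chi_x[i] <- chi2_score(px, exp_saxs)$chi2
    chi_n[i] <- chi2_score(pn, exp_sans)$chi2
    rg_x[i] <- guinier_fit(px)$Rg
    rg_n[i] <- guinier_fit(pn)$Rg
  }
  avg_saxs <- sas_profile(exp_saxs$Q, rowMeans(Ix), label = "avg xray")
  avg_sans <- sas_profile(exp_sans$Q, rowMeans(In), label = "avg sans")
  list(
    frames = frames, chi2_saxs_t = chi_x, chi2_sans_t = chi_n,
    rg_saxs_t = rg_x, rg_sans_t = rg_n,
    avg_saxs = avg_saxs, avg_sans = avg_sans,
    avg_chi2_saxs = chi2_score(avg_saxs, exp_saxs)$chi2,
    avg_chi2_sans = chi2_score(avg_sans, exp_sans)$chi2,
    mean_rg_saxs = mean(rg_x), mean_rg_sans = mean(rg_n)
  )
}

#' Asterisk grading of time-averaged model fits
#'
#' Grades each of the four averaged quantities with 0, 1 or 2 asterisks:
#' for chi-square, 0 if `chi2 <= chi0`, 1 if `chi0 < chi2 <= 1.2 chi0`,
#' 2 if `chi2 > 1.2 chi0` (with `chi0` = 5.0 for SAXS and 1.5 for SANS
#' by default); for Rg, with `dRg = Rg_model - Rg_exp`, 0 if
#' `|dRg| <= Error`, 1 if `Error < |dRg| <= 2 Error`, 2 if
#' `|dRg| > 2 Error`.  Fewer asterisks mean better agreement.
#'
#' @param chi2_saxs,chi2_sans Time-averaged chi-squares.
#' @param rg_saxs,rg_sans Time-averaged model radii of gyration.
#' @param rg_exp_saxs,rg_exp_sans Experimental radii.
#' @param err_saxs,err_sans Experimental Rg errors (> 0).
#' @param chi0 Named reference chi-squares `c(saxs =, sans =)`.
#' @return A `model_grade`: list of the inputs plus `grades`, a named
#'   integer vector (`chi2_saxs`, `rg_saxs`, `chi2_sans`, `rg_sans`) of
#'   asterisk counts, and `total`.
#' @export
grade_model <- function(chi2_saxs, chi2_sans, rg_saxs, rg_sans,
                        rg_exp_saxs, err_saxs, rg_exp_sans, err_sans,
                        chi0 = c(saxs = 5.0, sans = 1.5)) {
  stopifnot(err_saxs > 0, err_sans > 0)
  g_chi <- function(x, x0) {
    if (x <= x0) 0L else if (x <= 1.2 * x0) 1L else 2L
  }
  g_rg <- function(rg, rg_exp, err) {
    d <- abs(rg - rg_exp)
    if (d <= err) 0L else if (d <= 2 * err) 1L else 2L
  }
  grades <- c(chi2_saxs = g_chi(chi2_saxs, chi0[["saxs"]]),
              rg_saxs = g_rg(rg_saxs, rg_exp_saxs, err_saxs),
              chi2_sans = g_chi(chi2_sans, chi0[["sans"]]),
              rg_sans = g_rg(rg_sans, rg_exp_sans, err_sans))
  structure(list(chi2_saxs = chi2_saxs, chi2_sans = chi2_sans,
                 rg_saxs = rg_saxs, rg_sans = rg_sans,
                 grades = grades, total = sum(grades)),
            class = "model_grade")
}
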