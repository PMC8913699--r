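#' Quasi-uniform bead fill of a sphere
#'
#' Deterministic volume fill: bead `i` sits at radius
#' `R ((i - 1/2) / n)^(1/3)` (exact uniform-in-volume radial law, so the
#' radius of gyration converges to `sqrt(3/5) R`) along a direction from
#' a 2-D low-discrepancy (R2) sequence on the sphere, decoupled from the
#' radial index so the fill is isotropic.  No randomness.
#'
#' @param n Number of beads.
#' @param R Sphere radius (Angstrom).
#' @return n x 3 coordinate matrix centred on the origin.
#' @export
fill_sphere <- function(n, R) {
  i <- seq_len(n) - 0.5
  # R2 additive recurrence (generalized golden ratio) for (cos theta, phi)
  g <- 1.324717957244746  # plastic number
  a1 <- 1 / g; a2 <- 1 / g^2
  z <- 2 * ((i * a1) %% 1) - 1
  th <- 2 * pi * ((i * a2) %% 1)
  s <- sqrt(pmax(1 - z^2, 0))
  dir <- cbind(s * cos(th), s * sin(th), z)
  r <- R * (i / n)^(1 / 3)
  dir * r
}

#' Cylinder bead fill (for disk-like toy scatterers)
#'
#' @param n Approximate bead count.
#' @param radius,height Cylinder dimensions (Angstrom).
#' @return Coordinate matrix on a regular grid clipped to the cylinder,
#'   centred on the origin.
#' @export
fill_cylinder <- function(n, radius, height) {
  s <- (pi * radius^2 * height / n)^(1 / 3)
  gx <- seq(-radius, radius, by = s)
  gz <- seq(-height / 2, height / 2, by = s)
  if (length(gz) < 2) gz <- c(-height / 4, height / 4)
  g <- expand.grid(x = gx, y = gx, z = gz)
  g <- g[g$x^2 + g$y^2 <= radius^2, ]
  as.matrix(g)
}

#' Specification of the synthetic toy complex
#'
#' Parameters of a C6-symmetric toy assembly that emulates the
#' architecture of the real complex at residue-bead resolution: a rigid
#' double ring of large domains (component C), a single ring on top of
#' it (component B), a peripheral collar of paired small domains
#' (component A, domains C1A/C2A), and two mobile domains per dimer
#' (N1A, N2A) tethered by a linker.  All lengths in Angstrom.
#'
#' @param ring_radius Radii of the CII/CI/B/collar rings.
#' @param ring_z Heights of those rings.
#' @param domain_radius Radii of the spherical pseudo-domains (CII, CI,
#'   B, CA, NA).
#' @param domain_mass Total masses (Da) of the pseudo-domains.
#' @param n_bead Beads per pseudo-domain.
#' @param collar_split Azimuthal offsets (deg) of C1A and C2A within a
#'   sector.
#' @param truth_n1a,truth_n2a Ground-truth cylindrical poses
#'   `(r, theta, z)` of the mobile domains; `z` is measured from the
#'   reference plane (top of the B ring), negative below it.
#' @param linker_len Linker length in residues.
#' @param deuteration Component deuteration map for the iCM-SANS
#'   channel.
#' @param resname Residue name assigned to all beads (`"AVE"`, the mean
#'   residue, keeps contrasts deterministic).
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(ring_radius = c(CII = 45, CI = 42, B = 40, CA = 48),
                     ring_z = c(CII = -60, CI = -30, B = 0, CA = 18),
                     domain_radius = c(CII = 14, CI = 13, B = 11, CA = 9,
                                       NA_dom = 11),
                     domain_mass = c(CII = 29000, CI = 29000, B = 12000,
                                     CA = 11000, NA_dom = 18000),
                     n_bead = c(core = 24, mobile = 24),
                     collar_split = c(C1A = 10, C2A = 30),
                     truth_n1a = c(r = 62, theta = 25, z = -10),
                     truth_n2a = c(r = 65, theta = 15, z = -40),
                     linker_len = 20,
                     deuteration = c(A = 0, B = 0.75, C = 0.75),
                     resname = "AVE") {
  spec <- list(ring_radius = ring_radius, ring_z = ring_z,
               domain_radius = domain_radius, domain_mass = domain_mass,
               n_bead = n_bead, collar_split = collar_split,
               truth_n1a = truth_n1a, truth_n2a = truth_n2a,
               linker_len = linker_len, deuteration = deuteration,
               resname = resname)
  stopifnot(all(ring_radius > 0), all(domain_radius > 0),
            all(domain_mass > 0), all(n_bead > 0))
  class(spec) <- "toy_spec"
  spec
}

.toy_domain <- function(center, radius, n, mass, resname, chain,
                        component, domain) {
  X <- fill_sphere(n, radius)
  bead_model(X[, 1] + center[1], X[, 2] + center[2], X[, 3] + center[3],
             resname = resname, resid = seq_len(n), chain = chain,
             mass = mass / n, component = component, domain = domain)
}

#' Build the ground-truth toy complex
#'
#' Constructs the rigid core (C double ring + B ring + A collar), the
#' two mobile-domain templates and the ground-truth candidate model, and
#' verifies the construction is clash-free.  Deterministic: the
#' generator contains no randomness.
#'
#' @param spec A [toy_spec()].
#' @param clash_cutoff Construction is checked clash-free at this
#'   cutoff.
#' @return List with `core` (`bead_model`), `frame`
#'   (a [complex_frame()]), `templates` (N1A/N2A `bead_model`s centred
#'   at the origin), `truth` (the ground-truth `candidate_model`),
#'   `grid` (the designed [cell_grid()] of the toy), `truth_cells`
#'   (cells of the true poses) and `spec`.
#' @export
make_toy_complex <- function(spec = toy_spec(), clash_cutoff = 3.5) {
  rn <- spec$resname
  nb <- spec$n_bead[["core"]]
  # build the asymmetric unit at theta = 0, then rotate true C6 copies
  asu <- list()
  for (dom in c("CII", "CI", "B")) {
    ctr <- c(spec$ring_radius[[dom]], 0, spec$ring_z[[dom]])
    asu[[dom]] <- .toy_domain(
      ctr, spec$domain_radius[[dom]], nb, spec$domain_mass[[dom]], rn,
      chain = dom, component = if (dom == "B") "B" else "C", domain = dom)
  }
  for (dom in c("C1A", "C2A")) {
    a <- spec$collar_split[[dom]] * pi / 180
    ctr <- c(spec$ring_radius[["CA"]] * cos(a),
             spec$ring_radius[["CA"]] * sin(a), spec$ring_z[["CA"]])
    asu[[dom]] <- .toy_domain(
      ctr, spec$domain_radius[["CA"]], nb, spec$domain_mass[["CA"]], rn,
      chain = dom, component = "A", domain = dom)
  }
  unit <- .rebead(do.call(rbind, lapply(asu, as.data.frame)))
  parts <- lapply(0:5, function(k) {
    cp <- apply_transform(unit,
                          rigid_transform(rotation_about(c(0, 0, 1), k * 60)))
    cp$chain <- paste0(cp$chain, "_", k + 1)
    as.data.frame(cp)
  })
  core <- .rebead(do.call(rbind, parts))
  frame <- frame_from_core(core)
  nm <- spec$n_bead[["mobile"]]
  tpl <- function(dom) {
    X <- fill_sphere(nm, spec$domain_radius[["NA_dom"]])
    bead_model(X[, 1], X[, 2], X[, 3], resname = rn, resid = seq_len(nm),
               chain = dom, mass = spec$domain_mass[["NA_dom"]] / nm,
               component = "A", domain = dom)
  }
  templates <- list(N1A = tpl("N1A"), N2A = tpl("N2A"))
  # spec heights are relative to the reference plane; poses live in
  # frame coordinates (origin at the core COM)
  truth <- candidate_model(
    core, frame, templates,
    pose(spec$truth_n1a[["r"]], spec$truth_n1a[["theta"]],
         spec$truth_n1a[["z"]] + frame$z0),
    pose(spec$truth_n2a[["r"]], spec$truth_n2a[["theta"]],
         spec$truth_n2a[["z"]] + frame$z0),
    id = 0)
  full <- expand_candidate(truth)
  cl <- clash_check(full, clash_cutoff, partition = attr(full, "body"))
  if (cl$clash) {
    stop("toy specification is geometrically impossible: ",
         cl$n_violations, " core/domain overlaps at cutoff ", clash_cutoff)
  }
  grid <- cell_grid(data.frame(
    cell = c("U1", "U2", "L1", "L2"),
    rmin = c(45, 45, 45, 45), rmax = c(85, 85, 85, 85),
    thmin = c(0, 30, 0, 30), thmax = c(30, 60, 30, 60),
    zmin = frame$z0 + c(-25, -25, -60, -60),
    zmax = frame$z0 + c(0, 0, -25, -25)))
  truth_cells <- c(
    N1A = assign_cells(.domain_com(truth, 1), grid, frame)$cell,
    N2A = assign_cells(.domain_com(truth, 2), grid, frame)$cell)
  list(core = core, frame = frame, templates = templates, truth = truth,
       grid = grid, truth_cells = truth_cells, spec = spec)
}

#' Noise model for simulated experiments
#'
#' Relative Gaussian noise growing linearly in Q, echoing typical
#' size-exclusion-coupled scattering statistics: 2% of I at the low-Q
#' end rising to 10% at the high-Q end by default.
#'
#' @param rel_lo,rel_hi Relative sigma at the ends of the Q range.
#' @param n Number of grid points.
#' @param qmin,qmax Q range (inverse Angstrom).
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(rel_lo = 0.02, rel_hi = 0.10, n = 200,
                       qmin = 0.005, qmax = 0.18) {
  stopifnot(rel_lo > 0, rel_hi > 0, n > 2, qmin > 0, qmax > qmin)
  structure(list(rel_lo = rel_lo, rel_hi = rel_hi, n = n, qmin = qmin,
                 qmax = qmax), class = "noise_spec")
}

#' Simulate a noisy scattering experiment from a model
#'
#' Computes the true Debye profile of the model on the noise-spec grid
#' and perturbs it multiplicatively: `I_obs = I_true (1 + eps)` with
#' `eps ~ N(0, rel(Q))`; the reported sigma is the true `rel(Q) I_true`
#' (the generating noise level, honestly).
#'
#' @param model `bead_model` (or a `candidate_model`, which is
#'   expanded).
#' @param channel `"xray"` or `"neutron"`.
#' @param spec A [contrast_spec()] (neutron channel).
#' @param noise A [noise_spec()]; `NULL` for a noiseless profile.
#' @param seed RNG seed.
#' @param method,bin Passed to [debye_profile()].
#' @return A `sas_profile` with `sigma`.
#' @export
simulate_experiment <- function(model, channel = c("xray", "neutron"),
                                spec = contrast_spec(),
                                noise = noise_spec(), seed = 1,
                                method = "histogram", bin = 0.5) {
  channel <- match.arg(channel)
  if (inherits(model, "candidate_model")) model <- expand_candidate(model)
  ns <- if (is.null(noise)) noise_spec() else noise
  Q <- seq(ns$qmin, ns$qmax, length.out = ns$n)
  truth <- debye_profile(model, Q, channel = channel, spec = spec,
                         method = method, bin = bin)
  rel <- ns$rel_lo + (ns$rel_hi - ns$rel_lo) * (Q - ns$qmin) /
    (ns$qmax - ns$qmin)
  if (is.null(noise)) {
    return(sas_profile(Q, truth$I, sigma = rel * truth$I,
                       label = paste("noiseless", channel)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  eps <- stats::rnorm(ns$n, 0, rel)
  sas_profile(Q, truth$I * (1 + eps), sigma = rel * truth$I,
              label = paste("simulated", channel))
}

#' Decoy candidate set around a ground truth
#'
#' Perturbs the true poses of both mobile domains by random cylindrical
#' displacements (with a minimum displacement, so decoys are genuinely
#' wrong) and random reorientations, keeping only clash-free decoys.
#' The true pose is included exactly once, as the first candidate.
#'
#' @param truth The ground-truth `candidate_model`.
#' @param k Number of decoys (>= 1).
#' @param seed RNG seed; the decoy set is a deterministic function of
#'   it.
#' @param min_shift,max_shift Displacement bounds per domain (Angstrom).
#' @param cutoff Clash cutoff.
#' @param max_attempts Placement attempts per decoy.
#' @return List of `k + 1` candidates, the truth first (ids 0, 1..k).
#' @export
make_decoys <- function(truth, k, seed = 1, min_shift = 10, max_shift = 40,
                        cutoff = 3.5, max_attempts = 200) {
  stopifnot(k >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perturb <- function(p) {
    xyz0 <- as.numeric(from_cylindrical(p$r, p$theta, p$z, truth$frame))
    shift <- stats::runif(1, min_shift, max_shift) * .sample_sphere()
    xyz <- xyz0 + shift
    cyl <- cylindrical(matrix(xyz, 1), truth$frame)
    ax <- .sample_sphere()
    pose(cyl[1, "r"], cyl[1, "theta"], cyl[1, "z"],
         rot = rotation_about(ax, stats::runif(1, 0, 360)))
  }
  out <- vector("list", k + 1)
  out[[1]] <- truth
  for (i in seq_len(k)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      cand <- candidate_model(truth$core, truth$frame, truth$templates,
                              perturb(truth$pose1), perturb(truth$pose2),
                              sym = truth$sym, id = i)
      full <- expand_candidate(cand)
      cl <- clash_check(full, cutoff, partition = attr(full, "body"),
                        stop_at = 1)
      if (!cl$clash) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place clash-free decoy ", i, " in ",
                  max_attempts, " attempts")
    out[[i + 1]] <- cand
  }
  out
}

#' Synthetic "jiggle" trajectory around a candidate model
#'
#' The rigid core is held fixed while each mobile-domain copy's centre
#' of mass follows an independent seeded stationary first-order
#' autoregressive walk (a bounded random walk) whose 3-D RMS amplitude
#' matches the requested value, plus a small random reorientation per
#' frame.  Topology is constant across frames, so the result feeds
#' every trajectory metric.
#'
#' @param cand A `candidate_model`.
#' @param amplitudes Named RMS amplitudes (Angstrom) per domain label
#'   (`N1A`, `N2A`); 0 freezes a domain.
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @param phi AR(1) memory per frame (0 < phi < 1); larger is smoother.
#' @param rot_sd Std. dev. (degrees) of the per-frame orientation
#'   wobble.
#' @return A `bead_trajectory` whose topology is the expanded candidate.
#' @export
make_jiggle_trajectory <- function(cand, amplitudes = c(N1A = 8, N2A = 5),
                                   n_frames = 500, seed = 1, phi = 0.9,
                                   rot_sd = 2) {
  stopifnot(all(amplitudes >= 0), n_frames >= 2, phi > 0, phi < 1)
  topo <- expand_candidate(cand)
  body <- attr(topo, "body")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  coords <- array(rep(.as_xyz(topo), n_frames),
                  c(nrow(topo), 3, n_frames))
  mobile <- unique(body[body != "core"])
  for (bd in mobile) {
    sel <- which(body == bd)
    dom <- topo$domain[sel[1]]
    a <- amplitudes[[dom]]
    if (is.null(a) || is.na(a)) a <- 0
    ctr <- com(topo, sel)
    X0 <- sweep(.as_xyz(topo)[sel, , drop = FALSE], 2, ctr)
    # stationary AR(1) per coordinate: sd a/sqrt(3) gives 3-D RMS a
    sd_c <- a / sqrt(3)
    innov_sd <- sd_c * sqrt(1 - phi^2)
    disp <- matrix(0, n_frames, 3)
    if (a > 0) {
      disp[1, ] <- stats::rnorm(3, 0, sd_c)
      for (f in 2:n_frames) {
        disp[f, ] <- phi * disp[f - 1, ] + stats::rnorm(3, 0, innov_sd)
      }
    }
    for (f in seq_len(n_frames)) {
      R <- if (rot_sd > 0) {
        rotation_about(.sample_sphere(), stats::rnorm(1, 0, rot_sd))
      } else diag(3)
      coords[sel, , f] <- X0 %*% t(R) +
        matrix(ctr + disp[f, ], length(sel), 3, byrow = TRUE)
    }
  }
  bead_trajectory(topo, coords)
}
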