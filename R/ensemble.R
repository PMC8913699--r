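#' Assemble the N-domain-less core complex by superposition
#'
#' Places six copies of a ternary subcomplex onto a hexamer: for each
#' hexamer chain, the ternary's CI-domain beads are superposed (by
#' domain label and residue index) onto that chain's CI domain and the
#' whole ternary copy is transformed accordingly.  Duplicated CI beads
#' are resolved in favour of the hexamer copy, so the result contains
#' the hexamer plus six B and six C1A/C2A attachments and no N-domains.
#' Appended chains are suffixed `_k` (k = 1..6), which later identifies
#' the six dimer positions.
#'
#' @param hexamer `bead_model` of the C6 hexamer (component `"C"`,
#'   domains `CI`/`CII`).
#' @param ternary `bead_model` of the ternary unit with domains `CI`,
#'   `B`, `C1A`, `C2A`.
#' @return Combined `bead_model` ("Complex 1").
#' @export
build_complex1 <- function(hexamer, ternary) {
  if (!any(ternary$domain == "CI")) stop("ternary lacks a CI domain")
  chains <- unique(hexamer$chain[hexamer$domain == "CI"])
  if (length(chains) == 0L) stop("hexamer lacks CI domains")
  placed <- lapply(seq_along(chains), function(k) {
    target <- hexamer[hexamer$chain == chains[k] & hexamer$domain == "CI", ]
    pr <- pair_by_domain(ternary, target, domains = "CI")
    if (nrow(pr) < 3) stop("cannot map ternary CI onto hexamer chain ",
                           chains[k])
    tf <- superpose(ternary, target, pr)$transform
    copy <- apply_transform(ternary, tf)
    copy <- copy[copy$domain != "CI", , drop = FALSE]
    copy$chain <- paste0(copy$chain, "_", k)
    copy
  })
  .rebead(rbind(as.data.frame(hexamer), do.call(rbind, placed)))
}

#' Add full-length dimers to Complex 1 in the crystal arrangement
#'
#' For each of the six dimer positions (chain suffix `_k`), a full-length
#' dimer model is superposed via its C1A/C2A domains onto the placed
#' copies, and only its N1A/N2A beads are appended.  Steric clashes are
#' deliberately not resolved: the overlap of the crystal-arrangement
#' N-domains with the B ring is a finding this construction exposes.
#'
#' @param complex1 Output of [build_complex1()].
#' @param a2_full `bead_model` of the full-length dimer with domains
#'   `N1A`, `N2A`, `C1A`, `C2A`.
#' @return Combined `bead_model` ("Complex 2").
#' @export
build_complex2 <- function(complex1, a2_full) {
  need <- c("C1A", "C2A")
  if (!all(need %in% a2_full$domain)) stop("dimer model lacks C1A/C2A domains")
  ca <- complex1[complex1$domain %in% need, , drop = FALSE]
  ks <- unique(sub(".*_", "", ca$chain))
  placed <- lapply(ks, function(k) {
    target <- ca[grepl(paste0("_", k, "$"), ca$chain), , drop = FALSE]
    pr <- pair_by_domain(a2_full, target, domains = need)
    if (nrow(pr) < 3) stop("cannot map C1A/C2A for dimer position ", k)
    tf <- superpose(a2_full, target, pr)$transform
    copy <- apply_transform(a2_full, tf)
    copy <- copy[copy$domain %in% c("N1A", "N2A"), , drop = FALSE]
    copy$chain <- paste0(copy$chain, "_", k)
    copy
  })
  .rebead(rbind(as.data.frame(complex1), do.call(rbind, placed)))
}

#' Inter-body steric clash check
#'
#' Counts pairs of beads from *different* rigid bodies closer than
#' `cutoff`; intra-body pairs are ignored.  A uniform spatial grid keeps
#' the cost near-linear in the number of beads.
#'
#' @param model A `bead_model`.
#' @param cutoff Distance cutoff in Angstrom (pairs strictly closer
#'   clash).
#' @param partition Per-bead rigid-body labels (any vector); defaults to
#'   the `domain` column.
#' @param stop_at Stop counting after this many violations (0 = count
#'   all).
#' @return List with `clash` (logical) and `n_violations`.
#' @export
clash_check <- function(model, cutoff = 3.5, partition = model$domain,
                        stop_at = 0) {
  stopifnot(cutoff > 0, length(partition) == nrow(model))
  n <- .clash_count(.as_xyz(model), as.integer(factor(partition)), cutoff,
                    as.integer(stop_at))
  list(clash = n > 0, n_violations = n)
}

#' Rigid-body pose and pose grid
#'
#' A pose places a (centred) domain template: its centre of mass goes to
#' the cylindrical position `(r, theta, z)` in the complex frame and the
#' template is rotated by the given matrix.  `pose_grid` enumerates the
#' Cartesian product of cylindrical positions and a finite orientation
#' set; its size is `length(r) * length(theta) * length(z) *
#' length(orientations)`.
#'
#' @param r,theta,z Cylindrical coordinates of the domain centre
#'   (Angstrom / degrees), each a vector of grid values for `pose_grid`.
#' @param rot 3x3 rotation applied to the centred template.
#' @param orientations List of rotation matrices.
#' @return `pose()`: a `pose` object; `pose_grid()`: a `pose_grid`.
#' @export
pose <- function(r, theta, z, rot = diag(3)) {
  structure(list(r = r, theta = theta, z = z, rot = rot), class = "pose")
}

#' @rdname pose
#' @export
pose_grid <- function(r, theta, z, orientations = list(diag(3))) {
  stopifnot(length(r) > 0, length(theta) > 0, length(z) > 0,
            length(orientations) > 0)
  structure(list(r = r, theta = theta, z = z, orientations = orientations),
            class = "pose_grid")
}

#' @rdname pose
#' @param grid A `pose_grid`.
#' @export
grid_poses <- function(grid) {
  combos <- expand.grid(io = seq_along(grid$orientations),
                        iz = seq_along(grid$z),
                        it = seq_along(grid$theta),
                        ir = seq_along(grid$r))
  lapply(seq_len(nrow(combos)), function(i) {
    pose(grid$r[combos$ir[i]], grid$theta[combos$it[i]],
         grid$z[combos$iz[i]], grid$orientations[[combos$io[i]]])
  })
}

.place_template <- function(template, p, frame) {
  ctr <- com(template)
  X <- sweep(.as_xyz(template), 2, ctr)
  pos <- as.numeric(from_cylindrical(p$r, p$theta, p$z, frame))
  .set_xyz(template, X %*% t(p$rot) +
             matrix(pos, nrow(template), 3, byrow = TRUE))
}

#' Candidate rigid-body model of the full complex
#'
#' Holds the rigid core, the poses of the two mobile domains of the
#' asymmetric unit, and the symmetry order; [expand_candidate()] builds
#' the full bead model by placing both domains and replicating them by
#' the cyclic symmetry (the identical pose is applied in every sector,
#' as the generation scheme prescribes).
#'
#' @param core Core `bead_model`.
#' @param frame The core's [complex_frame()].
#' @param templates Named list with `N1A` and `N2A` domain templates.
#' @param pose1,pose2 [pose()]s of the N1A and N2A domains.
#' @param sym Symmetry order (default 6).
#' @param id Optional identifier.
#' @return A `candidate_model` object.
#' @export
candidate_model <- function(core, frame, templates, pose1, pose2, sym = 6,
                            id = NA) {
  stopifnot(all(c("N1A", "N2A") %in% names(templates)))
  structure(list(core = core, frame = frame, templates = templates,
                 pose1 = pose1, pose2 = pose2, sym = sym, id = id,
                 scores = list(), linker_status = "absent"),
            class = "candidate_model")
}

#' @rdname candidate_model
#' @param cand A `candidate_model`.
#' @return `expand_candidate()`: the full `bead_model`, with attribute
#'   `body` labelling rigid bodies (core plus each domain copy).
#' @export
expand_candidate <- function(cand) {
  d1 <- .place_template(cand$templates$N1A, cand$pose1, cand$frame)
  d2 <- .place_template(cand$templates$N2A, cand$pose2, cand$frame)
  d1$domain <- "N1A"; d2$domain <- "N2A"
  parts <- list(as.data.frame(cand$core))
  body <- list(rep("core", nrow(cand$core)))
  for (k in seq_len(cand$sym) - 1L) {
    R <- rotation_about(cand$frame$ez, k * 360 / cand$sym)
    t <- as.numeric(cand$frame$origin - R %*% cand$frame$origin)
    tf <- rigid_transform(R, t)
    c1 <- apply_transform(d1, tf); c2 <- apply_transform(d2, tf)
    c1$chain <- paste0("N1_", k + 1); c2$chain <- paste0("N2_", k + 1)
    parts <- c(parts, list(as.data.frame(c1), as.data.frame(c2)))
    body <- c(body, list(rep(paste0("N1_", k + 1), nrow(c1)),
                         rep(paste0("N2_", k + 1), nrow(c2))))
  }
  out <- .rebead(do.call(rbind, parts))
  attr(out, "body") <- unlist(body)
  out
}

#' Enumerate clash-free candidate models over a pose grid
#'
#' All pose pairs of the two mobile domains are visited in a fixed
#' deterministic order (pose1-major); each pair is placed, replicated by
#' the cyclic symmetry and kept only when no inter-body bead pair is
#' closer than `cutoff`.
#'
#' @param core,frame,templates As in [candidate_model()].
#' @param grid1,grid2 [pose_grid()]s for the N1A and N2A domains
#'   (`grid2` defaults to `grid1`).
#' @param cutoff Clash cutoff in Angstrom.
#' @param sym Symmetry order.
#' @return List of clash-free `candidate_model`s, ids recording the
#'   enumeration index.
#' @export
enumerate_candidates <- function(core, frame, templates, grid1,
                                 grid2 = grid1, cutoff = 3.5, sym = 6) {
  p1 <- grid_poses(grid1); p2 <- grid_poses(grid2)
  if (length(p1) == 0L || length(p2) == 0L) stop("empty pose grid")
  out <- vector("list", length(p1) * length(p2))
  nkeep <- 0L
  idx <- 0L
  for (i in seq_along(p1)) {
    for (j in seq_along(p2)) {
      idx <- idx + 1L
      cand <- candidate_model(core, frame, templates, p1[[i]], p2[[j]],
                              sym = sym, id = idx)
      full <- expand_candidate(cand)
      cl <- clash_check(full, cutoff, partition = attr(full, "body"),
                        stop_at = 1)
      if (!cl$clash) {
        nkeep <- nkeep + 1L
        out[[nkeep]] <- cand
      }
    }
  }
  out[seq_len(nkeep)]
}

#' Linker length feasibility test
#'
#' A linker of `n_res` residues can bridge two anchor points iff their
#' Euclidean distance is at most `n_res * per_res_max` (boundary
#' inclusive); 3.8 Angstrom is the virtual CA-CA bond length.
#'
#' @param anchor_a,anchor_b Anchor coordinates (length-3).
#' @param n_res Number of linker residues (the canonical inter-domain
#'   linker has 20).
#' @param per_res_max Maximum span per residue (Angstrom).
#' @return Logical.
#' @export
linker_feasible <- function(anchor_a, anchor_b, n_res = 20,
                            per_res_max = 3.8) {
  sqrt(sum((anchor_a - anchor_b)^2)) <= n_res * per_res_max
}

.sample_sphere <- function() {
  repeat {
    v <- stats::runif(3, -1, 1)
    n2 <- sum(v^2)
    if (n2 > 1e-6 && n2 <= 1) return(v / sqrt(n2))
  }
}

.walk_linker <- function(anchor_a, anchor_b, n_res, step, obstacle_xyz,
                         clash, max_dir = 40) {
  p <- anchor_a
  path <- matrix(NA_real_, n_res, 3)
  for (i in seq_len(n_res)) {
    m <- n_res + 1 - i  # bonds remaining after placing bead i
    if (i == n_res) {
      # close the walk on the circle at distance `step` from both the
      # previous bead and anchor_b
      u <- anchor_b - p
      d <- sqrt(sum(u^2))
      if (d > 2 * step || d < 1e-9) return(NULL)
      u <- u / d
      rho <- sqrt(max(step^2 - (d / 2)^2, 0))
      a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      v1 <- a - sum(a * u) * u; v1 <- v1 / sqrt(sum(v1^2))
      v2 <- c(u[2] * v1[3] - u[3] * v1[2], u[3] * v1[1] - u[1] * v1[3],
              u[1] * v1[2] - u[2] * v1[1])
      ok <- FALSE
      for (tr in seq_len(max_dir)) {
        ang <- stats::runif(1, 0, 2 * pi)
        q <- p + (d / 2) * u + rho * (cos(ang) * v1 + sin(ang) * v2)
        if (is.null(obstacle_xyz) ||
            min(rowSums(sweep(obstacle_xyz, 2, q)^2)) >= clash^2) {
          ok <- TRUE; break
        }
      }
      if (!ok) return(NULL)
      path[i, ] <- q
      break
    }
    target <- anchor_b - p
    dist_t <- sqrt(sum(target^2))
    ok <- FALSE
    for (tr in seq_len(max_dir)) {
      # bias towards the target harder as slack runs out
      slack <- m * step - dist_t
      lambda <- min(1, max(0, 1 - slack / (4 * step)))
      dir <- lambda * target / max(dist_t, 1e-9) +
        (1 - lambda) * .sample_sphere()
      dir <- dir / sqrt(sum(dir^2))
      q <- p + step * dir
      if (sqrt(sum((anchor_b - q)^2)) > (m - 1) * step + 1e-9) next
      if (!is.null(obstacle_xyz) &&
          min(rowSums(sweep(obstacle_xyz, 2, q)^2)) < clash^2) next
      if (i > 1 && any(rowSums(sweep(path[seq_len(i - 1), , drop = FALSE],
                                     2, q)^2) < (0.8 * step)^2)) next
      ok <- TRUE; break
    }
    if (!ok) return(NULL)
    path[i, ] <- q
    p <- q
  }
  path
}

#' Build a bead linker between two anchors
#'
#' Generates up to `k` linker conformations by a guided self-avoiding
#' random walk (step 3.8 Angstrom, biased towards the far anchor, steric
#' cutoff respected against the rest of the model) and returns the best:
#' when an experimental profile is supplied the conformer minimizing
#' chi-square of the full model against it, otherwise the most direct
#' conformer (smallest maximum deviation from the anchor-anchor line).
#'
#' @param model `bead_model` the linker must avoid (anchoring domains
#'   included).
#' @param anchor_a,anchor_b Anchor points (length-3, Angstrom).
#' @param n_res Number of linker residues.
#' @param seed RNG seed; a fixed seed reproduces the linker exactly.
#' @param k Number of conformers to generate (default 100).
#' @param exp_profile Optional experimental SAXS `sas_profile` (with
#'   sigma) used to select the conformer.
#' @param step Bond length (Angstrom).
#' @param clash Steric cutoff between linker beads and model beads;
#'   model beads within `2 * step` of an anchor are exempt (the linker
#'   necessarily starts against its anchoring domain).
#' @param max_attempts Total walk attempts before giving up.
#' @return `bead_model` of `n_res` linker beads (component and domain
#'   `"linker"`), with attribute `n_conformers` (how many were built).
#'   Errors if no conformer can be built, signalling infeasible
#'   geometry.
#' @export
build_linker <- function(model, anchor_a, anchor_b, n_res = 20, seed = 1,
                         k = 100, exp_profile = NULL, step = 3.8,
                         clash = 3.0, max_attempts = 20 * k) {
  if (!linker_feasible(anchor_a, anchor_b, n_res, step)) {
    stop("anchors farther apart than the linker can span")
  }
  obst <- .as_xyz(model)
  near <- rowSums(sweep(obst, 2, anchor_a)^2) < (2 * step)^2 |
    rowSums(sweep(obst, 2, anchor_b)^2) < (2 * step)^2
  obst <- obst[!near, , drop = FALSE]
  if (nrow(obst) == 0L) obst <- NULL
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  conf <- list()
  att <- 0
  while (length(conf) < k && att < max_attempts) {
    att <- att + 1
    w <- .walk_linker(anchor_a, anchor_b, n_res, step, obst, clash)
    if (!is.null(w)) conf[[length(conf) + 1]] <- w
  }
  if (length(conf) == 0L) stop("no linker conformer found in ", max_attempts,
                               " attempts (infeasible geometry)")
  as_beads <- function(w) {
    bead_model(w[, 1], w[, 2], w[, 3], resname = "GLY",
               resid = seq_len(nrow(w)), chain = "lnk", component = "linker",
               domain = "linker")
  }
  best <- if (!is.null(exp_profile)) {
    scores <- vapply(conf, function(w) {
      full <- .rebead(rbind(as.data.frame(model), as.data.frame(as_beads(w))))
      calc <- debye_profile(full, exp_profile$Q, channel = "xray",
                            method = "histogram")
      chi2_score(calc, exp_profile)$chi2
    }, numeric(1))
    which.min(scores)
  } else {
    u <- anchor_b - anchor_a; u <- u / sqrt(sum(u^2))
    dev <- vapply(conf, function(w) {
      rel <- sweep(w, 2, anchor_a)
      max(sqrt(rowSums((rel - (rel %*% u) %*% t(u))^2)))
    }, numeric(1))
    which.min(dev)
  }
  out <- as_beads(conf[[best]])
  attr(out, "n_conformers") <- length(conf)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
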