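test_that("trajectory container validates its inputs", {
  toy <- toy_small()
  n <- nrow(toy$core)
  coords <- array(rep(cbind(toy$core$x, toy$core$y, toy$core$z), 3),
                  c(n, 3, 3))
  tr <- bead_trajectory(toy$core, coords)
  expect_equal(n_frames(tr), 3)
  expect_equal(frame_model(tr, 2)$x, toy$core$x)
  expect_error(bead_trajectory(toy$core, coords[, , 1, drop = FALSE]),
               "at least 2")
  expect_error(bead_trajectory(toy$core, coords[1:10, , ]))
})

test_that("atomic multi-model PDB loads commute with coarse-graining", {
  # two residues, three frames, frame f translated by (f-1) along x
  block <- function(dx) {
    c(sprintf("ATOM      1  N   GLY A   1    %8.3f%8.3f%8.3f  1.00  0.00           N",
              0 + dx, 0, 0),
      sprintf("ATOM      2  CA  GLY A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
              1.5 + dx, 0, 0),
      sprintf("ATOM      3  N   ALA A   2    %8.3f%8.3f%8.3f  1.00  0.00           N",
              5 + dx, 1, 0),
      sprintf("ATOM      4  CA  ALA A   2    %8.3f%8.3f%8.3f  1.00  0.00           C",
              6.5 + dx, 1, 0))
  }
  path <- tempfile(fileext = ".pdb")
  writeLines(c(unlist(lapply(0:2, function(f) {
    c(sprintf("MODEL     %4d", f + 1), block(f), "ENDMDL")
  })), "END"), path)
  tr <- read_trajectory(path, coarse = "com")
  expect_equal(n_frames(tr), 3)
  expect_equal(nrow(tr$topology), 2)
  # frame-2 bead positions equal coarse-graining frame 2 by hand
  w <- c(14.007, 12.011)
  expect_equal(tr$coords[1, 1, 2], sum(w * c(1, 2.5)) / sum(w),
               tolerance = 1e-6)
  expect_equal(tr$coords[2, 1, 3], sum(w * c(7, 8.5)) / sum(w),
               tolerance = 1e-6)
  # single-frame file is not a trajectory
  single <- tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1", block(0), "ENDMDL", "END"), single)
  expect_error(read_trajectory(single, coarse = "com"), "at least 2")
})

test_that("rmsf_com is zero for static motion and exact for dwell", {
  toy <- toy_small()
  full <- expand_candidate(toy$truth)
  body <- attr(full, "body")
  n <- nrow(full)
  static <- bead_trajectory(full, array(rep(cbind(full$x, full$y, full$z), 4),
                                        c(n, 3, 4)))
  sels <- split(seq_len(n), body)
  r0 <- rmsf_com(static, sels[names(sels) != "core"],
                 align = sels$core)
  expect_equal(unname(r0$rmsf), rep(0, length(r0$rmsf)), tolerance = 1e-9)

  # one domain oscillating +/- a along x with equal dwell: RMSF = a
  a <- 2.5
  coords <- array(rep(cbind(full$x, full$y, full$z), 8), c(n, 3, 8))
  sel <- sels[["N1_1"]]
  for (f in 1:8) {
    coords[sel, 1, f] <- coords[sel, 1, f] + a * ifelse(f %% 2 == 0, 1, -1)
  }
  tr <- bead_trajectory(full, coords)
  r <- rmsf_com(tr, list(mv = sel), align = sels$core)
  expect_equal(unname(r$rmsf["mv"]), a, tolerance = 1e-9)
})

test_that("rmsf_com is invariant under a global rigid motion", {
  toy <- toy_small()
  tr <- make_jiggle_trajectory(toy$truth, amplitudes = c(N1A = 5, N2A = 3),
                               n_frames = 40, seed = 14)
  body <- attr(tr$topology, "body")
  sels <- split(seq_len(nrow(tr$topology)), body)
  doms <- sels[names(sels) != "core"]
  base <- rmsf_com(tr, doms, align = sels$core)
  moved <- tr$coords
  tf <- rigid_transform(rotation_about(c(1, 2, 0.5), 25), c(10, -4, 7))
  for (f in seq_len(dim(moved)[3])) {
    moved[, , f] <- apply_transform(moved[, , f], tf)
  }
  tr2 <- bead_trajectory(tr$topology, moved)
  r2 <- rmsf_com(tr2, doms, align = sels$core)
  expect_equal(r2$rmsf, base$rmsf, tolerance = 1e-6)
})

test_that("dccm has unit diagonal, symmetry, bounds and co-motion = 1", {
  set.seed(15)
  n <- 6; nf <- 300
  base <- matrix(rnorm(n * 3, sd = 10), n, 3)
  coords <- array(rep(base, nf), c(n, 3, nf))
  drive <- matrix(rnorm(nf * 3, sd = 1), nf, 3)
  # beads 1 and 2 co-translate rigidly; beads 3..6 move independently
  for (f in seq_len(nf)) {
    coords[1, , f] <- coords[1, , f] + drive[f, ]
    coords[2, , f] <- coords[2, , f] + drive[f, ]
    for (i in 3:6) coords[i, , f] <- coords[i, , f] + rnorm(3, sd = 1)
  }
  topo <- bead_model(base[, 1], base[, 2], base[, 3], resname = "AVE",
                     chain = "X")
  M <- dccm(bead_trajectory(topo, coords))
  expect_true(isSymmetric(unclass(M)))
  expect_equal(unname(diag(M)), rep(1, n), tolerance = 1e-9)
  expect_true(all(M >= -1 - 1e-12 & M <= 1 + 1e-12))
  expect_equal(unname(M[1, 2]), 1, tolerance = 1e-9)
})

test_that("independent bounded walks decorrelate at many frames", {
  set.seed(16)
  nf <- 10000
  phi <- 0.9; innov <- sqrt(1 - phi^2)
  walk <- function() {
    x <- matrix(0, nf, 3)
    x[1, ] <- rnorm(3)
    for (f in 2:nf) x[f, ] <- phi * x[f - 1, ] + rnorm(3, 0, innov)
    x
  }
  coords <- array(0, c(2, 3, nf))
  coords[1, , ] <- t(walk())
  coords[2, , ] <- t(walk() + 50)  # well separated, independent
  topo <- bead_model(c(0, 50), c(0, 50), c(0, 50), resname = "AVE",
                     chain = "X")
  M <- dccm(bead_trajectory(topo, coords))
  expect_lt(abs(M[1, 2]), 0.1)
})

test_that("zero-variance beads are masked with a warning, not NaN", {
  n <- 3; nf <- 50
  coords <- array(0, c(n, 3, nf))
  coords[1, , ] <- rnorm(3 * nf)
  coords[2, , ] <- rnorm(3 * nf)
  # bead 3 frozen
  topo <- bead_model(1:3, 1:3, 1:3, resname = "AVE", chain = "X")
  expect_warning(M <- dccm(bead_trajectory(topo, coords)), "zero-variance")
  expect_true(is.na(M[3, 1]))
  expect_true(is.na(M[3, 3]))
  expect_false(anyNA(M[1:2, 1:2]))
})

test_that("profile series averages profiles pointwise and stays constant
           for identical frames", {
  toy <- toy_small()
  full <- expand_candidate(toy$truth)
  exp_x <- simulate_experiment(toy$truth, "xray",
                               noise = noise_spec(n = 80, qmin = 0.004,
                                                  qmax = 0.12), seed = 41)
  exp_n <- simulate_experiment(toy$truth, "neutron",
                               noise = noise_spec(rel_lo = 0.03,
                                                  rel_hi = 0.1, n = 60,
                                                  qmin = 0.008, qmax = 0.12),
                               seed = 42)
  n <- nrow(full)
  xyz <- cbind(full$x, full$y, full$z)
  coords <- array(rep(xyz, 3), c(n, 3, 3))
  tr <- bead_trajectory(full, coords)
  ps <- profile_series(tr, exp_x, exp_n)
  expect_equal(ps$chi2_saxs_t, rep(ps$chi2_saxs_t[1], 3))
  expect_equal(ps$chi2_sans_t, rep(ps$chi2_sans_t[1], 3))
  expect_equal(ps$avg_chi2_saxs, ps$chi2_saxs_t[1], tolerance = 1e-9)

  # distinct frames: the average profile is the pointwise frame mean
  coords[, , 2] <- apply_transform(xyz, rigid_transform(t = c(0, 0, 12)))
  coords2 <- coords
  tr2 <- bead_trajectory(full, coords2)
  ps2 <- profile_series(tr2, exp_x, exp_n)
  f1 <- debye_profile(frame_model(tr2, 1), exp_x$Q, method = "histogram")
  f2 <- debye_profile(frame_model(tr2, 2), exp_x$Q, method = "histogram")
  f3 <- debye_profile(frame_model(tr2, 3), exp_x$Q, method = "histogram")
  expect_equal(ps2$avg_saxs$I, (f1$I + f2$I + f3$I) / 3, tolerance = 1e-9)
})

test_that("asterisk grades follow the threshold rules exactly", {
  g <- function(...) grade_model(...)$grades
  base <- list(rg_exp_saxs = 69.5, err_saxs = 0.3, rg_exp_sans = 78.1,
               err_sans = 1.0)
  # chi-square rules at the reference 5.0 (SAXS)
  expect_equal(do.call(g, c(list(4.0, 1.0, 69.5, 78.1), base))[["chi2_saxs"]], 0L)
  expect_equal(do.call(g, c(list(5.5, 1.0, 69.5, 78.1), base))[["chi2_saxs"]], 1L)
  expect_equal(do.call(g, c(list(6.5, 1.0, 69.5, 78.1), base))[["chi2_saxs"]], 2L)
  # boundaries are inclusive on the small side
  expect_equal(do.call(g, c(list(5.0, 1.0, 69.5, 78.1), base))[["chi2_saxs"]], 0L)
  expect_equal(do.call(g, c(list(6.0, 1.0, 69.5, 78.1), base))[["chi2_saxs"]], 1L)
  # SANS reference 1.5
  expect_equal(do.call(g, c(list(4.0, 1.5, 69.5, 78.1), base))[["chi2_sans"]], 0L)
  expect_equal(do.call(g, c(list(4.0, 1.7, 69.5, 78.1), base))[["chi2_sans"]], 1L)
  expect_equal(do.call(g, c(list(4.0, 1.9, 69.5, 78.1), base))[["chi2_sans"]], 2L)
  # Rg rules with the experimental error 0.3
  expect_equal(do.call(g, c(list(4, 1, 69.5 + 0.25, 78.1), base))[["rg_saxs"]], 0L)
  expect_equal(do.call(g, c(list(4, 1, 69.5 + 0.45, 78.1), base))[["rg_saxs"]], 1L)
  expect_equal(do.call(g, c(list(4, 1, 69.5 - 0.70, 78.1), base))[["rg_saxs"]], 2L)
  # pure function: same inputs, same grades
  a <- do.call(grade_model, c(list(5.3, 1.55, 69.0, 77.0), base))
  b <- do.call(grade_model, c(list(5.3, 1.55, 69.0, 77.0), base))
  expect_identical(a$grades, b$grades)
  expect_error(grade_model(1, 1, 1, 1, 1, 0, 1, 1))
})
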