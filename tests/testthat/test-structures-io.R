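test_that("read_structure parses a minimal PDB and honours selections", {
  path <- write_fixture_pdb()
  m <- read_structure(path)
  expect_s3_class(m, "atom_model")
  expect_equal(length(unique(paste(m$chain, m$resid))), 3)
  expect_equal(unique(m$chain), "A")
  expect_true(all(is.finite(m$x)))
  expect_error(read_structure(path, chain = "Z"), "no atoms")
  empty <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    EMPTY", "END"), empty)
  expect_error(read_structure(empty))
})

test_that("coarse_grain gives one bead per residue with standard masses", {
  m <- read_structure(write_fixture_pdb())
  b <- coarse_grain(m, placement = "com")
  expect_equal(nrow(b), 3)
  # masses from an independent atomic-mass sum over residue formulas
  gly <- 2 * 12.011 + 3 * 1.008 + 14.007 + 15.999
  trp <- 11 * 12.011 + 10 * 1.008 + 2 * 14.007 + 15.999
  expect_equal(b$mass[b$resname == "GLY"], gly, tolerance = 0.1 / gly)
  expect_equal(b$mass[b$resname == "TRP"], trp, tolerance = 0.1 / trp)
  expect_gt(b$mass[b$resname == "TRP"], b$mass[b$resname == "GLY"])
  expect_equal(b$deut, rep(0, 3))
})

test_that("residue-COM placement is the mass-weighted atom centroid", {
  m <- read_structure(write_fixture_pdb())
  b <- coarse_grain(m, placement = "com")
  gly <- m[m$resid == 1, ]
  w <- c(N = 14.007, C = 12.011, O = 15.999)[gly$element]
  expect_equal(b$x[1], sum(w * gly$x) / sum(w), tolerance = 1e-9)
  expect_equal(b$z[1], sum(w * gly$z) / sum(w), tolerance = 1e-9)
})

test_that("CA placement requires an alpha carbon", {
  m <- read_structure(write_fixture_pdb())
  m2 <- m[m$name != "CA" | m$resid != 2, ]
  class(m2) <- class(m)
  expect_error(coarse_grain(m2, placement = "CA"), "no CA")
  b <- coarse_grain(m, placement = "CA")
  expect_equal(b$x[2], m$x[m$resid == 2 & m$name == "CA"])
})

test_that("coarse_grain conserves residue count and total mass", {
  m <- read_structure(write_fixture_pdb())
  b <- coarse_grain(m)
  tab <- residue_table()
  expected <- sum(tab$mass[match(c("GLY", "ALA", "TRP"), tab$resname)])
  expect_equal(sum(b$mass), expected, tolerance = 0.5 * 3 / 100 / expected)
})

test_that("superpose recovers exact transforms and is rotation invariant", {
  set.seed(1)
  X <- matrix(rnorm(30), ncol = 3)
  id <- superpose(X, X)
  expect_equal(id$rmsd, 0, tolerance = 1e-9)
  expect_equal(id$transform$R, diag(3), tolerance = 1e-9)

  R90 <- rotation_about(c(0, 0, 1), 90)
  t <- c(3, -2, 7)
  Y <- X %*% t(R90) + matrix(t, nrow(X), 3, byrow = TRUE)
  fit <- superpose(X, Y)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$transform$R, R90, tolerance = 1e-8)
  expect_equal(fit$transform$t, t, tolerance = 1e-8)

  # rmsd invariant under arbitrary proper pre-rotation of the mobile set
  set.seed(2)
  Yn <- Y + matrix(rnorm(30, 0, 0.5), ncol = 3)
  base <- superpose(X, Yn)$rmsd
  for (ax in list(c(1, 0, 0), c(1, 1, 0), c(0.3, -1, 2))) {
    Rp <- rotation_about(ax, 37)
    expect_equal(superpose(X %*% t(Rp), Yn)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("superpose never returns an improper rotation", {
  set.seed(3)
  X <- matrix(rnorm(24), ncol = 3)
  Y <- X %*% diag(c(-1, 1, 1))  # mirror image
  fit <- superpose(X, Y)
  expect_equal(det(fit$transform$R), 1, tolerance = 1e-9)
  expect_error(superpose(X[1:2, ], Y[1:2, ]), "at least 3")
  collin <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superpose(collin, collin + 1), "degenerate")
})

test_that("superpose agrees with the bio3d least-squares fit", {
  set.seed(4)
  X <- matrix(rnorm(45), ncol = 3)
  Y <- X %*% t(rotation_about(c(1, 2, 3), 55)) +
    matrix(c(1, 2, 3), 15, 3, byrow = TRUE) + matrix(rnorm(45, 0, 0.3), ncol = 3)
  ours <- superpose(X, Y)
  xyz_fit <- bio3d::fit.xyz(as.numeric(t(Y)), as.numeric(t(X)),
                            fixed.inds = 1:45, mobile.inds = 1:45)
  ref_rmsd <- sqrt(mean(rowSums((matrix(xyz_fit, ncol = 3, byrow = TRUE) - Y)^2)))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("apply_transform is an isometry with exact inverse", {
  toy <- toy_small()
  tf <- rigid_transform(rotation_about(c(1, 1, 1), 40), c(5, -3, 2))
  m <- toy$core
  m2 <- apply_transform(m, tf)
  expect_equal(m2$domain, m$domain)
  back <- apply_transform(m2, invert_transform(tf))
  expect_equal(back$x, m$x, tolerance = 1e-9)
  expect_equal(back$z, m$z, tolerance = 1e-9)
  i <- c(1, 50, 200); j <- c(30, 80, 400)
  d0 <- sqrt((m$x[i] - m$x[j])^2 + (m$y[i] - m$y[j])^2 + (m$z[i] - m$z[j])^2)
  d1 <- sqrt((m2$x[i] - m2$x[j])^2 + (m2$y[i] - m2$y[j])^2 +
               (m2$z[i] - m2$z[j])^2)
  expect_equal(d1, d0, tolerance = 1e-9)
  idm <- apply_transform(m, rigid_transform())
  expect_equal(idm$x, m$x)
})

test_that("symmetry_mates produce a closed regular arrangement", {
  fr <- complex_frame(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  one <- bead_model(10, 0, 0, resname = "AVE", chain = "X")
  expect_identical(symmetry_mates(one, 1, fr)[[1]], one)
  mates <- symmetry_mates(one, 6, fr)
  pts <- t(vapply(mates, function(m) c(m$x, m$y, m$z), numeric(3)))
  expect_equal(sqrt(rowSums(pts[, 1:2]^2)), rep(10, 6), tolerance = 1e-9)
  ang <- sort((atan2(pts[, 2], pts[, 1]) * 180 / pi) %% 360)
  expect_equal(ang, seq(0, 300, by = 60), tolerance = 1e-9)
  # closure: rotating the union by 60 degrees permutes it
  rot <- apply_transform(pts, rigid_transform(rotation_about(c(0, 0, 1), 60)))
  d <- as.matrix(stats::dist(rbind(pts, rot)))[1:6, 7:12]
  expect_lt(max(apply(d, 1, min)), 1e-9)
  expect_error(symmetry_mates(one, 0, fr), ">= 1")
})

test_that("com is the mass-weighted centroid", {
  b <- bead_model(c(0, 4), 0, 0, resname = "AVE", chain = "X",
                  mass = c(1, 3))
  expect_equal(com(b), c(3, 0, 0))
  expect_equal(com(b, 1), c(0, 0, 0))
  b2 <- bead_model(c(0, 4), c(2, 2), 0, resname = "AVE", chain = "X",
                   mass = c(2, 2))
  expect_equal(com(b2), c(2, 2, 0))
  expect_error(com(b, integer(0)), "empty")
})

test_that("cylindrical coordinates round-trip and fold correctly", {
  fr <- complex_frame(c(1, 2, 3), c(0, 0, 1), c(1, 0, 0))
  p <- from_cylindrical(10, 90, 5, fr)
  cyl <- cylindrical(p, fr)
  expect_equal(as.numeric(cyl), c(10, 90, 5), tolerance = 1e-9)
  expect_equal(as.numeric(cylindrical(c(1, 2, 10), fr)), c(0, 0, 7),
               tolerance = 1e-9)
  rot <- apply_transform(p, rigid_transform(rotation_about(c(0, 0, 1), 60),
                                            c(1, 2, 3) - as.numeric(rotation_about(c(0, 0, 1), 60) %*% c(1, 2, 3))))
  expect_equal(cylindrical(rot, fr)[, "theta"],
               (cyl[, "theta"] + 60) %% 360, tolerance = 1e-9,
               ignore_attr = TRUE)
  # random round trips away from the axis
  set.seed(5)
  for (i in 1:10) {
    r <- runif(1, 1, 80); th <- runif(1, 0, 360); z <- runif(1, -50, 50)
    back <- cylindrical(from_cylindrical(r, th, z, fr), fr)
    expect_equal(as.numeric(back), c(r, th, z), tolerance = 1e-9)
  }
})

test_that("bead models round-trip through the tabular text format", {
  toy <- toy_small()
  path <- tempfile(fileext = ".beads")
  write_beads(toy$core, path)
  back <- read_beads(path)
  expect_equal(back$x, toy$core$x)
  expect_equal(back$component, toy$core$component)
  expect_equal(back$mass, toy$core$mass)
})

test_that("multi-model PDB export is readable as a trajectory", {
  toy <- toy_small()
  m <- toy$core[1:30, ]
  class(m) <- class(toy$core)
  frames <- list(m, apply_transform(m, rigid_transform(t = c(1, 0, 0))),
                 apply_transform(m, rigid_transform(t = c(2, 0, 0))))
  path <- tempfile(fileext = ".pdb")
  write_beads_pdb(frames, path)
  tr <- read_trajectory(path, coarse = "CA")
  expect_equal(n_frames(tr), 3)
  expect_equal(dim(tr$coords)[1], 30)
  expect_equal(tr$coords[1, 1, 2] - tr$coords[1, 1, 1], 1, tolerance = 1e-3)
})
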