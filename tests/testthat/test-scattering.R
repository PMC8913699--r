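test_that("x-ray residue contrast follows the composition table", {
  tab <- residue_table()
  gly <- tab[tab$resname == "GLY", ]
  # in-chain glycine: C2H3NO = 30 electrons
  expect_equal(gly$electrons, 30)
  expect_equal(bead_xray_contrast("GLY"), 30 - 0.334 * gly$volume,
               tolerance = 1e-9)
  # zero-volume limit: excess equals the electron count
  expect_equal(bead_xray_contrast("GLY", solvent_edens = 0), 30)
  # match point: solvent density equal to the residue mean density
  rho <- gly$electrons / gly$volume
  expect_equal(bead_xray_contrast("GLY", solvent_edens = rho), 0,
               tolerance = 1e-9)
  expect_error(bead_xray_contrast("XXX"), "unknown residue")
})

test_that("hydrogenated residues have positive neutron contrast in H2O", {
  res <- residue_table()$resname[1:20]
  ex <- bead_neutron_contrast(res, deut = 0, contrast_spec(d2o = 0))
  expect_true(all(ex > 0))
})

test_that("75% deuteration contrast-matches 100% D2O on average", {
  tab <- residue_table()[1:20, ]
  sp <- contrast_spec(d2o = 1)
  w <- tab$abundance / sum(tab$abundance)
  e_h <- bead_neutron_contrast(tab$resname, 0, sp)
  e_d <- bead_neutron_contrast(tab$resname, 0.75, sp)
  expect_lt(abs(sum(w * e_d)), 0.05 * sum(w * abs(e_h)))
})

test_that("Debye profile closed forms hold", {
  one <- bead_model(0, 0, 0, resname = "AVE", chain = "X")
  Q <- c(0.01, 0.05, 0.2)
  p1 <- debye_profile(one, Q, b = 2)
  expect_equal(p1$I, rep(4, 3))
  d <- 25
  two <- bead_model(c(0, d), 0, 0, resname = "AVE", chain = "X")
  p2 <- debye_profile(two, Q, b = c(1, 1), method = "direct")
  expect_equal(p2$I, 2 * (1 + sin(Q * d) / (Q * d)), tolerance = 1e-12)
  expect_error(debye_profile(two, c(-0.1, 0.1)), "positive")
  expect_error(debye_profile(two, Q, b = c(0, 0)), "nonzero contrast")
})

test_that("I(0) limit equals the squared total scattering length", {
  toy <- toy_small()
  m <- toy$core
  b <- bead_xray_contrast(m$resname)
  p <- debye_profile(m, 1e-6, channel = "xray", method = "direct")
  expect_equal(p$I, sum(b)^2, tolerance = 1e-6)
})

test_that("histogram Debye agrees with the exact double sum", {
  toy <- toy_small()
  Q <- seq(0.005, 0.2, length.out = 40)
  pd <- debye_profile(toy$core, Q, method = "direct")
  ph <- debye_profile(toy$core, Q, method = "histogram", bin = 0.25)
  expect_equal(ph$I / pd$I, rep(1, 40), tolerance = 0.005)
})

test_that("Debye sum is invariant under the C6 rotation", {
  toy <- toy_small()
  full <- expand_candidate(toy$truth)
  fr <- toy$frame
  R <- rotation_about(fr$ez, 60)
  rot <- apply_transform(full, rigid_transform(R, fr$origin - as.numeric(R %*% fr$origin)))
  Q <- seq(0.01, 0.15, length.out = 20)
  p0 <- debye_profile(full, Q, method = "direct")
  p1 <- debye_profile(rot, Q, method = "direct")
  expect_equal(p1$I / p0$I, rep(1, 20), tolerance = 1e-10)
})

test_that("zeroed non-A contrasts reproduce the A-only profile exactly", {
  toy <- toy_small()
  full <- expand_candidate(toy$truth)
  sp <- contrast_spec()
  b <- bead_neutron_contrast(full$resname, contrastscreen:::.deut_of(full, sp), sp)
  bz <- ifelse(full$component == "A", b, 0)
  Q <- seq(0.01, 0.15, length.out = 25)
  isA <- full$component == "A"
  aonly <- full[isA, ]
  class(aonly) <- class(full)
  for (meth in c("direct", "histogram")) {
    pz <- debye_profile(full, Q, b = bz, method = meth)
    pa <- debye_profile(aonly, Q, b = b[isA], method = meth)
    expect_identical(pz$I, pa$I)
  }
})

test_that("iCM profile of the deuterated toy matches the A-only profile", {
  toy <- toy_default()
  full <- expand_candidate(toy$truth)
  Q <- seq(0.008, 0.15, length.out = 80)
  p_icm <- icm_sans_profile(full, Q, spec = contrast_spec(), method = "direct")
  isA <- full$component == "A"
  aonly <- full[isA, ]
  class(aonly) <- class(full)
  p_a <- debye_profile(aonly, Q, channel = "neutron",
                       spec = contrast_spec(deuteration = c(A = 0)),
                       method = "direct")
  dev <- max(abs(p_icm$I / p_icm$I[1] - p_a$I / p_a$I[1]))
  expect_lt(dev, 0.05)
})

test_that("Guinier fit inverts an exact Guinier curve", {
  Q <- seq(0.002, 0.05, length.out = 100)
  p <- sas_profile(Q, 7 * exp(-Q^2 * 50^2 / 3))
  g <- guinier_fit(p)
  expect_equal(g$Rg, 50, tolerance = 1e-9)
  expect_equal(g$I0, 7, tolerance = 1e-9)
  expect_equal(g$Rg_err, 0, tolerance = 1e-6)
  expect_true(g$q_range[2] * g$Rg <= 1.3)
})

test_that("Guinier Rg of a noiseless toy profile matches rg_direct", {
  toy <- toy_default()
  full <- expand_candidate(toy$truth)
  rg_ref <- rg_direct(full, weighting = "contrast", channel = "xray")
  Q <- seq(0.002, 0.03, length.out = 120)
  p <- debye_profile(full, Q, channel = "xray", method = "histogram",
                     bin = 0.25)
  # validity window: the Guinier law itself is only ~1%-accurate well
  # below the 1.3 working limit for compact bodies
  g <- guinier_fit(p, limit = 0.8)
  expect_equal(g$Rg, rg_ref, tolerance = 0.01)
  i0_ref <- sum(bead_xray_contrast(full$resname))^2
  expect_equal(g$I0, i0_ref, tolerance = 0.01)
})

test_that("Guinier fit error conditions are reported", {
  Q <- seq(0.01, 0.05, length.out = 30)
  expect_error(guinier_fit(sas_profile(Q, exp(Q^2 * 100))), "slope")
  flat <- sas_profile(Q, c(rep(1, 29), -1) + 1e-9)
  expect_error(guinier_fit(flat), "non-positive")
  p <- sas_profile(Q, 7 * exp(-Q^2 * 50^2 / 3))
  expect_error(guinier_fit(p, min_points = 200), "underflow")
})

test_that("rg_direct closed forms hold", {
  pt <- bead_model(rep(1, 5), rep(2, 5), rep(3, 5), resname = "AVE",
                   chain = "X")
  expect_equal(rg_direct(pt), 0)
  th <- seq(0, 2 * pi, length.out = 401)[-401]
  ring <- bead_model(30 * cos(th), 30 * sin(th), 0, resname = "AVE",
                     chain = "X")
  expect_equal(rg_direct(ring), 30, tolerance = 1e-9)
  X <- fill_sphere(8000, 40)
  sph <- bead_model(X[, 1], X[, 2], X[, 3], resname = "AVE", chain = "X")
  expect_equal(rg_direct(sph), sqrt(3 / 5) * 40, tolerance = 0.01)
})

test_that("chi2 score is exact for scaled data and near 1 for noise", {
  Q <- seq(0.01, 0.2, length.out = 200)
  I <- 1000 * exp(-Q^2 * 900)
  calc <- sas_profile(Q, I)
  exp1 <- sas_profile(Q, I, sigma = 0.02 * I)
  s <- chi2_score(calc, exp1)
  expect_equal(s$chi2, 0, tolerance = 1e-12)
  expect_equal(s$scale, 1, tolerance = 1e-12)
  calc2 <- sas_profile(Q, 2 * I)
  s2 <- chi2_score(calc2, exp1)
  expect_equal(s2$chi2, 0, tolerance = 1e-12)
  expect_equal(s2$scale, 0.5, tolerance = 1e-12)
  set.seed(7)
  sigma <- 0.03 * I
  noisy <- sas_profile(Q, I + rnorm(200, 0, sigma), sigma = sigma)
  s3 <- chi2_score(calc, noisy)
  expect_gt(s3$chi2, 0.7)
  expect_lt(s3$chi2, 1.4)
  # invariance to any positive rescaling of calc
  calc3 <- sas_profile(Q, 0.037 * I)
  expect_equal(chi2_score(calc3, noisy)$chi2, s3$chi2, tolerance = 1e-9)
  expect_error(chi2_score(calc, sas_profile(Q, I)), "sigma")
  expect_error(chi2_score(sas_profile(Q + 10, I), exp1), "overlap")
})

test_that("smearing is the identity at zero width and fills minima", {
  Q <- seq(0.01, 0.2, length.out = 250)
  X <- fill_sphere(3000, 50)
  sph <- bead_model(X[, 1], X[, 2], X[, 3], resname = "AVE", chain = "X")
  p <- debye_profile(sph, Q, method = "direct")
  expect_equal(smear(p, 0)$I, p$I)
  flat <- sas_profile(Q, rep(5, 250))
  expect_equal(smear(flat, 0.01)$I, rep(5, 250), tolerance = 1e-9)
  dip <- function(prof) min(prof$I[Q > 0.07 & Q < 0.11])
  depths <- c(dip(p), dip(smear(p, 0.002)), dip(smear(p, 0.005)),
              dip(smear(p, 0.01)))
  expect_true(all(diff(depths) > 0))
})

test_that("forward-scattering contributions are weight-mass products", {
  one <- forward_contribution(1, 5e5)
  expect_equal(one$t, 1)
  two <- forward_contribution(c(0.5, 0.5), c(2e5, 4e5))
  expect_equal(two$t, c(1 / 3, 2 / 3))
  set.seed(8)
  r <- runif(6); M <- runif(6, 1e4, 1e6)
  expect_equal(sum(forward_contribution(r, M)$t), 1, tolerance = 1e-12)
  expect_error(forward_contribution(c(0, 0), c(1, 1)), "all-zero")
})

test_that("power-law slopes are recovered", {
  Q <- exp(seq(log(0.01), log(0.1), length.out = 50))
  expect_equal(powerlaw_slope(sas_profile(Q, Q^-2)), -2, tolerance = 1e-9)
  expect_equal(powerlaw_slope(sas_profile(Q, rep(3, 50))), 0,
               tolerance = 1e-9)
  expect_error(powerlaw_slope(sas_profile(Q, Q - 0.05)), "non-positive")
})

test_that("thin-disk toy model shows the Q^-2 diagnostic", {
  X <- fill_cylinder(4000, 90, 10)
  disk <- bead_model(X[, 1], X[, 2], X[, 3], resname = "AVE", chain = "d")
  Q <- exp(seq(log(1 / 90), log(1 / 10), length.out = 60))
  p <- debye_profile(disk, Q, method = "histogram", bin = 0.25)
  sl <- powerlaw_slope(p)
  expect_gt(sl, -2.3)
  expect_lt(sl, -1.7)
})

test_that("profiles round-trip through the text format with headers", {
  Q <- seq(0.01, 0.1, length.out = 20)
  p <- sas_profile(Q, exp(-Q^2 * 100), sigma = rep(0.01, 20),
                   dQ = rep(0.001, 20))
  path <- tempfile(fileext = ".dat")
  write_profile(p, path, comment = "simulated profile")
  back <- read_profile(path)
  expect_equal(back$Q, p$Q)
  expect_equal(back$I, p$I)
  expect_equal(back$sigma, p$sigma)
  expect_equal(back$dQ, p$dQ)
  # csv dialect with hash headers
  csv <- tempfile(fileext = ".dat")
  writeLines(c("# Sample description", "# Q I err",
               paste(Q, p$I, p$sigma, sep = ",")), csv)
  back2 <- read_profile(csv)
  expect_equal(back2$I, p$I)
})
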