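#' Scattering profile container
#'
#' @param Q Momentum transfer grid (inverse Angstrom), strictly
#'   increasing and positive.
#' @param I Intensities.
#' @param sigma Optional 1-sigma uncertainties (same units as `I`).
#' @param dQ Optional instrumental resolution (std. dev. in Q).
#' @param label Optional label.
#' @return A `sas_profile` data frame with columns `Q`, `I` and
#'   optionally `sigma`, `dQ`.
#' @export
sas_profile <- function(Q, I, sigma = NULL, dQ = NULL, label = NULL) {
  stopifnot(length(Q) == length(I), all(Q > 0), all(diff(Q) > 0))
  out <- data.frame(Q = Q, I = I)
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(Q), all(sigma > 0))
    out$sigma <- sigma
  }
  if (!is.null(dQ)) {
    stopifnot(length(dQ) == length(Q), all(dQ >= 0))
    out$dQ <- dQ
  }
  attr(out, "label") <- label
  class(out) <- c("sas_profile", class(out))
  out
}

#' Read / write 1-D scattering profiles
#'
#' Whitespace- or comma-separated text with 3 columns (Q, I, sigma) or 4
#' (+ dQ); lines starting with `#` (and blank lines) are skipped, which
#' covers the common deposited-profile dialects.
#'
#' @param path File path.
#' @return A `sas_profile`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lines <- gsub(",", " ", lines, fixed = TRUE)
  df <- utils::read.table(text = lines, header = FALSE, fill = TRUE)
  df <- df[stats::complete.cases(df[, 1:2]), , drop = FALSE]
  sas_profile(df[[1]], df[[2]],
              sigma = if (ncol(df) >= 3 && all(is.finite(df[[3]]))) df[[3]],
              dQ = if (ncol(df) >= 4 && all(is.finite(df[[4]]))) df[[4]],
              label = basename(path))
}

#' @rdname read_profile
#' @param profile A `sas_profile`.
#' @param comment Optional header comment (written after `#`).
#' @export
write_profile <- function(profile, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines(paste("#", paste(names(profile), collapse = " ")), con)
  utils::write.table(as.data.frame(profile), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Contrast specification for neutron scattering
#'
#' @param d2o Solvent D2O volume fraction in `[0, 1]`.
#' @param deuteration Named numeric vector: non-exchangeable-hydrogen
#'   deuteration fraction per component label (components absent from the
#'   vector default to 0).
#' @param exchange Fraction of exchangeable hydrogens that actually
#'   exchange with the solvent (default 1).
#' @return A `contrast_spec` object.
#' @export
contrast_spec <- function(d2o = 1,
                          deuteration = c(A = 0, B = 0.75, C = 0.75),
                          exchange = 1) {
  stopifnot(d2o >= 0, d2o <= 1, all(deuteration >= 0 & deuteration <= 1),
            exchange >= 0, exchange <= 1)
  structure(list(d2o = d2o, deuteration = deuteration, exchange = exchange),
            class = "contrast_spec")
}

.deut_of <- function(model, spec) {
  d <- spec$deuteration[model$component]
  d[is.na(d)] <- 0
  # an explicit per-bead deuteration overrides the component map
  ifelse(model$deut > 0, model$deut, as.numeric(d))
}

#' X-ray excess scattering length of residues
#'
#' Excess electrons: residue electron count minus solvent electron
#' density times displaced residue volume.
#'
#' @param resnames Residue names.
#' @param solvent_edens Solvent electron density (electrons per cubic
#'   Angstrom), default liquid water.
#' @return Numeric vector, electrons.
#' @export
bead_xray_contrast <- function(resnames, solvent_edens = 0.334) {
  tab <- .lookup_residues(resnames)
  tab$electrons - solvent_edens * tab$volume
}

#' Neutron excess scattering length of residues
#'
#' Coherent scattering length of the residue with non-exchangeable
#' hydrogens mixed as `(1-d) b_H + d b_D` and exchangeable hydrogens
#' mixed by the solvent D fraction (scaled by the exchange fraction),
#' minus the solvent scattering-length density times the displaced
#' residue volume.
#'
#' @param resnames Residue names.
#' @param deut Deuteration fraction(s) of non-exchangeable hydrogens.
#' @param spec A [contrast_spec()] (its `d2o` and `exchange` are used).
#' @return Numeric vector, fm.
#' @export
bead_neutron_contrast <- function(resnames, deut = 0, spec = contrast_spec()) {
  tab <- .lookup_residues(resnames)
  k <- scattering_constants()$b
  deut <- rep_len(deut, nrow(tab))
  f_ex <- spec$d2o * spec$exchange
  b_ex <- (1 - f_ex) * k[["H"]] + f_ex * k[["D"]]
  b_non <- (1 - deut) * k[["H"]] + deut * k[["D"]]
  b <- tab$C * k[["C"]] + tab$N * k[["N"]] + tab$O * k[["O"]] +
    tab$S * k[["S"]] + tab$Hexch * b_ex + (tab$H - tab$Hexch) * b_non
  b - solvent_sld(spec$d2o) * tab$volume
}

.bead_contrasts <- function(model, channel, spec) {
  if (channel == "xray") {
    bead_xray_contrast(model$resname)
  } else {
    bead_neutron_contrast(model$resname, .deut_of(model, spec), spec)
  }
}

#' Debye scattering profile of a bead model
#'
#' `I(Q) = sum_i sum_j b_i b_j sin(Q d_ij) / (Q d_ij)` with the i = j
#' term `b_i^2`.  Beads are point scatterers by default; a Gaussian
#' per-bead form factor of radius `bead_radius` can be applied, which
#' multiplies the profile by `exp(-(Q R_b)^2)`.
#'
#' `method = "direct"` evaluates the double sum exactly;
#' `"histogram"` bins pair distances (width `bin` Angstrom) first, which
#' is near-linear in memory and fast for repeated large models, at the
#' cost of a phase error of order `Q * bin / 2`.  `"auto"` picks direct
#' for small models.
#'
#' @param model A `bead_model` with at least one bead of nonzero
#'   contrast.
#' @param Q Momentum-transfer grid (inverse Angstrom, > 0).
#' @param channel `"xray"` or `"neutron"`.
#' @param spec A [contrast_spec()] (neutron channel).
#' @param solvent_edens Solvent electron density (x-ray channel).
#' @param method `"auto"`, `"direct"` or `"histogram"`.
#' @param bin Histogram bin width in Angstrom.
#' @param bead_radius Optional Gaussian bead radius (Angstrom); `NULL`
#'   for point beads.
#' @param b Optional explicit per-bead scattering lengths, overriding the
#'   channel/contrast computation.
#' @return A `sas_profile`.
#' @export
debye_profile <- function(model, Q, channel = c("xray", "neutron"),
                          spec = contrast_spec(), solvent_edens = 0.334,
                          method = c("auto", "direct", "histogram"),
                          bin = 0.5, bead_radius = NULL, b = NULL) {
  channel <- match.arg(channel)
  method <- match.arg(method)
  if (nrow(model) == 0L) stop("empty model")
  if (any(Q <= 0)) stop("Q must be positive")
  if (is.null(b)) {
    b <- if (channel == "xray") {
      bead_xray_contrast(model$resname, solvent_edens)
    } else {
      bead_neutron_contrast(model$resname, .deut_of(model, spec), spec)
    }
  }
  if (all(b == 0)) stop("no bead with nonzero contrast")
  xyz <- .as_xyz(model)
  if (method == "auto") method <- if (nrow(xyz) <= 1500) "direct" else "histogram"
  I <- if (method == "direct") {
    .debye_direct(xyz, b, Q)
  } else {
    h <- .pair_hist(xyz, b, bin)
    keep <- h$w != 0
    x <- outer(Q, h$d[keep])
    as.numeric(h$self + (ifelse(x < 1e-12, 1, sin(x) / x)) %*% h$w[keep])
  }
  if (!is.null(bead_radius)) I <- I * exp(-(Q * bead_radius)^2)
  sas_profile(Q, I, label = channel)
}

#' Inverse contrast-matching SANS profile
#'
#' Neutron Debye profile with per-component deuteration: components whose
#' deuteration brings their scattering-length density to that of the
#' solvent contribute only their residual excess, so a 75%-deuterated
#' component in 100% D2O is essentially invisible and the profile reports
#' the hydrogenated component(s) alone.
#'
#' @inheritParams debye_profile
#' @export
icm_sans_profile <- function(model, Q, spec = contrast_spec(),
                             method = c("auto", "direct", "histogram"),
                             bin = 0.5, bead_radius = NULL) {
  debye_profile(model, Q, channel = "neutron", spec = spec,
                method = match.arg(method), bin = bin,
                bead_radius = bead_radius)
}

#' Direct (real-space) radius of gyration
#'
#' `Rg = sqrt( sum w_i |x_i - xbar|^2 / sum w_i )` with mass or contrast
#' weights; the independent oracle for Guinier fits.
#'
#' @param model A `bead_model`.
#' @param weighting `"mass"` or `"contrast"`.
#' @param channel,spec Contrast weighting options.
#' @return Rg in Angstrom.
#' @export
rg_direct <- function(model, weighting = c("mass", "contrast"),
                      channel = "xray", spec = contrast_spec()) {
  weighting <- match.arg(weighting)
  w <- if (weighting == "mass") model$mass else
    .bead_contrasts(model, channel, spec)
  if (abs(sum(w)) < 1e-12) stop("zero total weight")
  xyz <- .as_xyz(model)
  ctr <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w))
}

#' Guinier fit of a scattering profile
#'
#' Linear least squares of `ln I` against `Q^2` over a low-Q window,
#' iterated from the low-Q end: points are dropped from the high-Q side
#' until `Q_max * Rg <= limit`.  `Rg = sqrt(-3 * slope)`; parameter
#' errors are propagated from the (sigma-weighted, when present)
#' regression covariance.
#'
#' @param profile A `sas_profile`.
#' @param limit The `Q * Rg` validity limit (default 1.3).
#' @param qmin Points below this Q are discarded before fitting.
#' @param min_points Minimum number of points in the converged window.
#' @return List with `Rg`, `Rg_err`, `I0`, `I0_err`, `q_range`,
#'   `n_points`, `residual` (rms of ln-I residuals).
#' @export
guinier_fit <- function(profile, limit = 1.3, qmin = 0, min_points = 5) {
  keep <- profile$Q >= qmin
  Q <- profile$Q[keep]; I <- profile$I[keep]
  sg <- if (!is.null(profile$sigma)) profile$sigma[keep] else NULL
  n <- length(Q)
  repeat {
    if (n < min_points) stop("Guinier window underflow (< ", min_points,
                             " points before convergence)")
    Qw <- Q[1:n]; Iw <- I[1:n]
    if (any(Iw <= 0)) stop("non-positive intensities in Guinier window")
    y <- log(Iw); x <- Qw^2
    w <- if (is.null(sg)) rep(1, n) else (Iw / sg[1:n])^2
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    slope <- fit$coefficients[2]
    if (slope >= 0) stop("non-negative Guinier slope: no real Rg")
    rg <- sqrt(-3 * slope)
    if (Qw[n] * rg <= limit) {
      XtWXinv <- solve(crossprod(cbind(1, x) * sqrt(w)))
      dof <- max(n - 2, 1)
      s2 <- sum(w * fit$residuals^2) / dof
      se <- sqrt(diag(XtWXinv) * s2)
      i0 <- exp(fit$coefficients[1])
      return(list(Rg = as.numeric(rg),
                  Rg_err = as.numeric(3 / (2 * rg) * se[2]),
                  I0 = as.numeric(i0),
                  I0_err = as.numeric(i0 * se[1]),
                  q_range = c(Qw[1], Qw[n]), n_points = n,
                  residual = sqrt(mean(fit$residuals^2))))
    }
    n <- n - 1
  }
}

#' Reduced chi-square of a computed against an experimental profile
#'
#' The computed profile is interpolated onto the experimental Q grid
#' (linearly in (Q, log I)), an analytic scale factor `c` minimizing the
#' weighted residual is applied, and
#' `chi2 = 1/(N-1) * sum(((c I_calc - I_exp) / sigma)^2)`.
#'
#' @param calc Computed `sas_profile`.
#' @param exp Experimental `sas_profile` with `sigma`.
#' @param background If `TRUE`, additionally fit a constant background
#'   (off by default).
#' @return List with `chi2`, `scale`, `background`, `n`.
#' @export
chi2_score <- function(calc, exp, background = FALSE) {
  if (is.null(exp$sigma)) stop("experimental profile lacks sigma")
  keep <- exp$Q >= min(calc$Q) & exp$Q <= max(calc$Q)
  if (!any(keep)) stop("no overlap between calc and exp Q ranges")
  Qe <- exp$Q[keep]; Ie <- exp$I[keep]; sg <- exp$sigma[keep]
  Ic <- if (all(calc$I > 0)) {
    exp(stats::approx(calc$Q, log(calc$I), xout = Qe)$y)
  } else {
    stats::approx(calc$Q, calc$I, xout = Qe)$y
  }
  w <- 1 / sg^2
  n <- length(Qe)
  if (background) {
    A <- cbind(Ic, 1)
    beta <- solve(crossprod(A * sqrt(w)), colSums(A * w * Ie))
    cc <- beta[1]; bg <- beta[2]
  } else {
    cc <- sum(w * Ic * Ie) / sum(w * Ic^2)
    bg <- 0
  }
  chi2 <- sum(((cc * Ic + bg - Ie) / sg)^2) / (n - 1)
  list(chi2 = as.numeric(chi2), scale = as.numeric(cc),
       background = as.numeric(bg), n = n)
}

#' Gaussian resolution smearing
#'
#' Convolves the profile with a Gaussian in Q of standard deviation
#' `dQ(Q)`; `dQ = 0` is the identity.  The convolution is evaluated on
#' the profile's own grid with trapezoid weights, renormalized so a
#' constant profile is unchanged.
#'
#' @param profile A `sas_profile`.
#' @param dQ Scalar, vector along the grid, or function of Q.
#' @return Smeared `sas_profile`.
#' @export
smear <- function(profile, dQ) {
  Q <- profile$Q
  if (is.function(dQ)) dQ <- dQ(Q)
  dQ <- rep_len(dQ, length(Q))
  stopifnot(all(is.finite(dQ)), all(dQ >= 0))
  wq <- c(diff(Q)[1], (Q[3:length(Q)] - Q[1:(length(Q) - 2)]) / 2,
          diff(Q)[length(Q) - 1])
  I <- profile$I
  Is <- vapply(seq_along(Q), function(k) {
    if (dQ[k] == 0) return(I[k])
    g <- exp(-(Q - Q[k])^2 / (2 * dQ[k]^2)) * wq
    sum(g * I) / sum(g)
  }, numeric(1))
  out <- profile
  out$I <- Is
  out
}

#' Forward-scattering contribution ratios of a mixture
#'
#' For components with weight fractions `r` and molar masses `M`, the
#' forward intensity of each scales as `r * M`, so the contribution
#' ratio is `t_i = r_i M_i / sum_j r_j M_j`.
#'
#' @param r Weight fractions (>= 0).
#' @param M Molar masses (Da, > 0).
#' @param labels Optional component labels.
#' @return Data frame with `label`, `r`, `M`, `t`; `sum(t) == 1`.
#' @export
forward_contribution <- function(r, M, labels = NULL) {
  stopifnot(length(r) == length(M), all(r >= 0), all(M > 0))
  if (sum(r * M) == 0) stop("all-zero mixture")
  data.frame(label = if (is.null(labels)) seq_along(r) else labels,
             r = r, M = M, t = r * M / sum(r * M),
             stringsAsFactors = FALSE)
}

#' Log-log power-law slope of a profile
#'
#' Least-squares slope of `log I` against `log Q` over a Q window; a
#' slope near -2 is the classical signature of a disk-like scatterer.
#'
#' @param profile A `sas_profile`.
#' @param qrange Length-2 window `[Qlo, Qhi]`.
#' @return The fitted slope.
#' @export
powerlaw_slope <- function(profile, qrange = range(profile$Q)) {
  keep <- profile$Q >= qrange[1] & profile$Q <= qrange[2]
  if (sum(keep) < 3) stop("window contains fewer than 3 points")
  if (any(profile$I[keep] <= 0)) stop("non-positive intensities in window")
  unname(stats::coef(stats::lm(log(profile$I[keep]) ~ log(profile$Q[keep])))[2])
}
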