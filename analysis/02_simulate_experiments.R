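#!/usr/bin/env Rscript
# Step 2: simulated scattering experiments on the ground-truth toy
# complex.  Produces the SEC-SAXS-like and SEC-iCM-SANS-like profiles
# used by the screening steps, their Guinier parameters, the disk-slope
# diagnostic of the contrast-matched channel, and a forward-scattering
# contribution table for a mixture of oligomeric species.

suppressMessages(library(contrastscreen))
dir.create("results", showWarnings = FALSE)
seed <- 1

toy <- make_toy_complex()
full <- expand_candidate(toy$truth)
cat(sprintf("ground-truth toy complex: %d beads, direct Rg = %.1f A\n",
            nrow(full), rg_direct(full)))

exp_saxs <- simulate_experiment(toy$truth, "xray",
                                noise = noise_spec(n = 200),
                                seed = seed * 100 + 1)
exp_sans <- simulate_experiment(
  toy$truth, "neutron",
  noise = noise_spec(rel_lo = 0.03, rel_hi = 0.12, n = 150,
                     qmin = 0.008, qmax = 0.15), seed = seed * 100 + 2)
write_profile(exp_saxs, "results/sim_saxs.dat",
              comment = "simulated SEC-SAXS of the toy complex (Q I sigma)")
write_profile(exp_sans, "results/sim_icm_sans.dat",
              comment = "simulated SEC-iCM-SANS (hA visible, dB/dC matched)")

gx <- guinier_fit(exp_saxs)
gn <- guinier_fit(exp_sans)
cat(sprintf("Guinier SAXS:     Rg = %.1f +/- %.1f A, I0 = %.3g\n",
            gx$Rg, gx$Rg_err, gx$I0))
cat(sprintf("Guinier iCM-SANS: Rg = %.1f +/- %.1f A, I0 = %.3g\n",
            gn$Rg, gn$Rg_err, gn$I0))
cat("the contrast-matched channel reports a larger Rg: the visible\n",
    "peripheral component is an annulus, not the compact core.\n")

# disk-like fall-off of the contrast-matched channel at mid Q
win <- c(0.02, 0.08)
sl <- powerlaw_slope(exp_sans, win)
cat(sprintf("log-log slope of the iCM-SANS profile over [%.3f, %.3f]: %.2f\n",
            win[1], win[2], sl))

# forward-scattering contribution ratios for a nominal mixture
mix <- forward_contribution(
  r = c(0.10, 0.05, 0.15, 0.70),
  M = c(2 * 18000 + 2 * 11000, 4 * 12000, 6 * 12000 + 6 * 58000,
        12 * 29000 + 6 * 12000 + 6 * 58000),
  labels = c("free dimer", "B tetramer", "B6C6 subcomplex", "full complex"))
print(mix, row.names = FALSE)
utils::write.csv(mix, "results/forward_contributions.csv", row.names = FALSE)
cat("wrote results/sim_saxs.dat, results/sim_icm_sans.dat,",
    "results/forward_contributions.csv\n")
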