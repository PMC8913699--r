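# Shared fixtures, all built in code.

# spherical pseudo-domain of n beads at a centre
mkdom <- function(ctr, n, chain, comp, dom, r = 10, resname = "AVE") {
  X <- fill_sphere(n, r)
  bead_model(X[, 1] + ctr[1], X[, 2] + ctr[2], X[, 3] + ctr[3],
             resname = resname, resid = seq_len(n), chain = chain,
             component = comp, domain = dom)
}

bind_beads <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  class(df) <- c("bead_model", class(df))
  df
}

# toy hexamer: six chains, each a CII and a CI pseudo-domain; chain 1 is
# built explicitly and the others are true rotation copies
fixture_hexamer <- function(nb = 20) {
  unit <- bind_beads(mkdom(c(40, 0, -25), nb, "C", "C", "CII"),
                     mkdom(c(38, 0, 0), nb, "C", "C", "CI"))
  parts <- lapply(0:5, function(k) {
    cp <- apply_transform(unit,
                          rigid_transform(rotation_about(c(0, 0, 1), k * 60)))
    cp$chain <- paste0("C", k + 1)
    cp
  })
  do.call(bind_beads, parts)
}

# ternary unit: a CI copy matching hexamer chain 1, plus B and paired CA
fixture_ternary <- function(nb = 20) {
  bind_beads(
    mkdom(c(38, 0, 0), nb, "tC", "C", "CI"),
    mkdom(c(38, 0, 18), 15, "tB", "B", "B", r = 8),
    mkdom(c(44, 8, 32), 12, "tA1", "A", "C1A", r = 7),
    mkdom(c(44, 24, 32), 12, "tA2", "A", "C2A", r = 7))
}

# full-length dimer: CA pair in the ternary arrangement plus N-domains;
# n2a_ctr defaults to the B-attachment position, so the rigid placement
# interpenetrates the B ring (the crystal-arrangement overlap)
fixture_a2 <- function(n2a_ctr = c(38, 0, 18)) {
  bind_beads(
    mkdom(c(44, 8, 32), 12, "a1", "A", "C1A", r = 7),
    mkdom(c(44, 24, 32), 12, "a2", "A", "C2A", r = 7),
    mkdom(c(62, 0, 45), 15, "a3", "A", "N1A", r = 9),
    mkdom(n2a_ctr, 15, "a4", "A", "N2A", r = 9))
}

# small cached toy complex for tests that only need geometry
toy_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_toy_complex(
        spec = toy_spec(n_bead = c(core = 12, mobile = 12)))
    }
    cache
  }
})

toy_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_complex()
    cache
  }
})

# minimal 3-residue, 1-chain atomic PDB text
fixture_pdb_text <- function() {
  c("HEADER    TEST",
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  N   ALA A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      6  CA  ALA A   2       3.988   2.839   0.000  1.00  0.00           C",
    "ATOM      7  CB  ALA A   2       5.420   2.700   0.520  1.00  0.00           C",
    "ATOM      8  C   ALA A   2       4.001   3.504   1.377  1.00  0.00           C",
    "ATOM      9  O   ALA A   2       4.340   4.680   1.500  1.00  0.00           O",
    "ATOM     10  N   TRP A   3       3.625   2.780   2.430  1.00  0.00           N",
    "ATOM     11  CA  TRP A   3       3.600   3.320   3.790  1.00  0.00           C",
    "ATOM     12  C   TRP A   3       2.800   4.620   3.860  1.00  0.00           C",
    "ATOM     13  O   TRP A   3       3.050   5.480   4.710  1.00  0.00           O",
    "END")
}

write_fixture_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(fixture_pdb_text(), path)
  path
}
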