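# Shared fixtures: compositions, generator truths and the external
# wormlike-chain oracle. Everything is built in code at test time.

chitin_composition <- function() {
  molecular_composition("C8H13NO5", labile_h = 3, density = 1.5,
                        label = "anhydro-GlcNAc")
}

# Nanofiber-like truth for recovery studies: rigid chain (b = 318 A) with a
# 16 A cross-section, a Porod upturn confined to the lowest decade of q,
# and a small flat background.
fiber_truth <- function() {
  flexcyl_params(alpha1 = 5, radius = 16, kuhn = 318, contour = 5000,
                 alpha2 = 1e-9, decay = 4, background = 0.01)
}

# Two-level aggregate truth with Beaucage-consistent Porod constants.
aggregate_truth <- function(G1 = 2000, Rg1 = 1800, D1 = 2.6,
                            G2 = 5, Rg2 = 125, D2 = 2.6,
                            background = 0.01) {
  beaucage_params(
    G = c(G1, G2), Rg = c(Rg1, Rg2),
    B = c(beaucage_consistent_B(G1, Rg1, D1),
          beaucage_consistent_B(G2, Rg2, D2)),
    D = c(D1, D2), background = background)
}

# Independent Python implementation of the wormlike-chain form factor
# (numpy/scipy), used as a cross-check oracle.
wlc_oracle <- function(contour, kuhn, radius, q) {
  script <- system.file("oracle", "wlc_reference.py", package = "sanstools")
  qf <- tempfile(fileext = ".txt")
  writeLines(sprintf("%.15e", q), qf)
  out <- suppressWarnings(
    system2("python", c(script, contour, kuhn, radius, qf), stdout = TRUE))
  on.exit(unlink(qf))
  as.numeric(out)
}

rel_err <- function(est, truth) abs(est / truth - 1)
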