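#!/usr/bin/env Rscript
# Featurizes a medium-sized XPD fixture ensemble (Calpha and DNA-P distance
# features), fits TICA, and exports the 2D free-energy surface over
# (IC1, IC2) together with the per-frame projections.
#
# The landscape shows the metastable basins of the translocation cycle; the
# two apo registers (S1, S7) appear as separate minima only because the
# features include protein-DNA distances -- with include_dna = FALSE their
# basins merge, which is the behavior this script reports at the end.

suppressPackageStartupMessages(library(helimsm))
dir.create("results", showWarnings = FALSE)

fx <- build_xpd_fixture()
cfg <- pipeline_config("xpd", n_traj = 30L, n_frames = 2000L, k_micro = 100L,
                       seed = 2L)
spec <- build_feature_spec(fx$topology, stride = cfg$feature_stride,
                           include_dna = TRUE)
feats <- list(); labs <- list()
emit_ensemble(fx$fixture, cfg$n_traj, cfg$n_frames, seed = cfg$seed,
              sigma = cfg$sigma, callback = function(i, traj, lab) {
  feats[[i]] <<- compute_features(traj, spec)
  labs[[i]] <<- lab
})
tica <- fit_tica(feats, lag = cfg$tica_lag, n_components = cfg$n_ics)
Y <- do.call(rbind, lapply(feats, function(X) tica_project(tica, X)))
fes <- free_energy_surface(Y[, 1:2], kT = 0.596, bins = 60)
write_fes(fes, "results/xpd_fes_ic12.txt")
keep <- seq(1, nrow(Y), by = 20)   # strided subsample keeps the table small
write.csv(data.frame(ic1 = Y[keep, 1], ic2 = Y[keep, 2],
                     state = unlist(labs)[keep]),
          "results/xpd_projections.csv", row.names = FALSE)
cat(sprintf("TICA eigenvalues (top 5): %s\n",
            paste(sprintf("%.3f", head(tica$eigenvalues, 5)), collapse = " ")))
cat(sprintf("occupied FES bins: %d; free-energy range %.2f kcal/mol\n",
            sum(!is.na(fes$F)), max(fes$F, na.rm = TRUE)))

# protein-only projection: the apo registers overlap
spec0 <- build_feature_spec(fx$topology, stride = cfg$feature_stride,
                            include_dna = FALSE)
f0 <- lapply(seq_along(feats), function(i) NULL)
feats0 <- list()
emit_ensemble(fx$fixture, 10L, 1500L, seed = cfg$seed, sigma = cfg$sigma,
              callback = function(i, traj, lab) {
  feats0[[i]] <<- compute_features(traj, spec0)
  f0[[i]] <<- lab
})
t0 <- fit_tica(feats0, lag = cfg$tica_lag, n_components = 4)
Y0 <- do.call(rbind, lapply(feats0, function(X) tica_project(t0, X)))
lab0 <- unlist(f0[!vapply(f0, is.null, TRUE)])
sep <- function(Y, lab, a, b) {
  d <- colMeans(Y[lab == a, , drop = FALSE]) -
       colMeans(Y[lab == b, , drop = FALSE])
  sqrt(sum(d^2))
}
cat(sprintf("S1-S7 separation in IC space: %.2f with DNA features, %.2f without\n",
            sep(Y, unlist(labs), "S1", "S7"), sep(Y0, lab0, "S1", "S7")))
cat("wrote results/xpd_fes_ic12.txt, results/xpd_projections.csv\n")
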