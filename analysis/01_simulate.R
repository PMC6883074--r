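#!/usr/bin/env Rscript
# Build the synthetic study systems: a sealed wild-type-like valve, a
# moderately leaky single-mutant-like valve and a strongly leaky double-
# mutant-like valve (three replicates each, 6 x 6 x 12 nm box, barrier at
# z = 6 nm, 10-ps frames), plus a tethered-fluctuation system and valve
# distance-pair systems for the geometry and flexibility analyses. Every
# system is written to disk (PDB topology + multi-frame GRO + ground-truth
# JSON) so the downstream drivers consume files, exactly as they would
# consume real MD output.

suppressMessages(library(valvewatch))
out <- "results/fixtures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed0 <- 20260927L %% 100000L

constructs <- list(
  WT = 0,              # hydrophobic seal: no crossings
  L554A = 0.25,        # single alanine: moderate leak
  L554A_L555A = 0.70   # double alanine: strong leak
)

cat("== synthetic barrier systems (80 waters, 600 frames = 6 ns) ==\n")
for (label in names(constructs)) {
  for (rep in 1:3) {
    sys <- generate_barrier_system(barrier_params(
      n_waters = 80, crossing_probability = constructs[[label]],
      n_frames = 600, spacing_ps = 10,
      seed = seed0 + 10L * match(label, names(constructs)) + rep))
    paths <- write_synthetic_system(
      sys, file.path(out, sprintf("%s_rep%d", label, rep)))
    cat(sprintf("  %s replicate %d: %4d true crossings -> %s\n", label, rep,
                nrow(sys$ground_truth$events), paths[["trajectory"]]))
  }
}

cat("== tethered-fluctuation system (sigmas 0.02/0.05/0.10 nm) ==\n")
tet <- generate_tethered_system(c(0.02, 0.05, 0.10), n_frames = 5000,
                                seed = seed0 + 50L)
invisible(write_synthetic_system(tet, file.path(out, "tethered")))

cat("== valve distance-pair systems ==\n")
inward <- generate_distance_pair_system(1.05, 0.02, n_frames = 5000,
                                        seed = seed0 + 60L)
invisible(write_synthetic_system(inward, file.path(out, "pair_inward")))
outward <- generate_distance_pair_system(c(1.1, 1.5), c(0.05, 0.05),
                                         n_frames = 5000,
                                         seed = seed0 + 61L)
invisible(write_synthetic_system(outward, file.path(out, "pair_outward")))

cat("== static transporter stand-ins (inward / outward) ==\n")
for (state in c("inward", "outward")) {
  st <- make_synthetic_transporter(state)
  write_pdb_structure(st$topology, st$frame,
                      file.path(out, paste0("transporter_", state, ".pdb")))
}
cat("done; fixtures under", out, "\n")
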