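#!/usr/bin/env Rscript
# Valve and roof geometry: cross-dimer Calpha distances of the valve
# leucines in the inward- and outward-facing stand-ins, the axial valve
# shift between the two states, distance probability distributions of the
# synthetic inward/outward valve pair systems, boxplot statistics
# (mean-centred convention), and the R426-E585 roof salt bridge.

suppressMessages(library(valvewatch))
fx <- "results/fixtures"
if (!dir.exists(fx)) stop("run analysis/01_simulate.R first")
dir.create("results/geometry", showWarnings = FALSE)

inw <- load_structure(file.path(fx, "transporter_inward.pdb"))
out <- load_structure(file.path(fx, "transporter_outward.pdb"))

cat("== cross-dimer valve Calpha distances (nm) ==\n")
d_in <- valve_calpha_distances(inw$topology, inw$frame)
d_out <- valve_calpha_distances(out$topology, out$frame)
print(round(rbind(inward = d_in, outward = d_out), 3))
cat(sprintf("backbone-centroid distance: inward %.2f nm, outward %.2f nm\n",
            valve_backbone_distance(inw$topology, inw$frame),
            valve_backbone_distance(out$topology, out$frame)))

vsel <- select_atoms(inw$topology, VALVE_SELECTION)
core <- select_atoms(inw$topology, "resid 400-410 and name CA")
shift <- valve_axial_shift(inw$frame, out$frame, vsel,
                           align_selection = core)
cat(sprintf("axial valve shift inward -> outward: %+.2f nm\n", shift))

cat("== valve distance distributions (5000 samples each) ==\n")
stats_rows <- list()
for (state in c("inward", "outward")) {
  st <- load_structure(file.path(fx, sprintf("pair_%s.pdb", state)))
  traj <- load_trajectory(st$topology,
                          file.path(fx, sprintf("pair_%s.gro", state)))
  ser <- distance_series(traj, "A/554:CA-B/554:CA", stride_ns = 0.01)[[1L]]
  bs <- boxplot_stats(ser$distance_nm)
  stats_rows[[state]] <- data.frame(
    state = state, mean = bs$mean, q1 = bs$q1, q3 = bs$q3,
    min = bs$min, max = bs$max, n = bs$n)
  dist <- distance_probability(list(ser), bin_width = 0.05)
  utils::write.csv(data.frame(mid_nm = dist$mids, prob = dist$prob),
                   sprintf("results/geometry/valve_distance_prob_%s.csv",
                           state), row.names = FALSE)
  cat(sprintf("  %-8s mean %.3f nm, Q1 %.3f, Q3 %.3f, range %.2f-%.2f\n",
              state, bs$mean, bs$q1, bs$q3, bs$min, bs$max))
}
utils::write.csv(do.call(rbind, stats_rows),
                 "results/geometry/valve_distance_boxplots.csv",
                 row.names = FALSE)

cat("== roof salt bridge R426-E585 ==\n")
tr <- vw_trajectory(inw$topology,
                    array(inw$frame$xyz, dim = c(nrow(inw$frame$xyz), 3, 2)),
                    inw$frame$box, c(0, 10))
for (chains in list(c("A", "A"), c("B", "B"))) {
  sb <- detect_salt_bridge(tr, 426, 585, chains[1L], chains[2L])
  cat(sprintf("  chain %s: min N-O distance %.2f nm, bridged fraction %.2f\n",
              chains[1L], min(sb$min_distance_nm), sb$fraction))
}
cat("tables under results/geometry/\n")
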