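#!/usr/bin/env Rscript
# Water flux through the valve: anchor the 2 x 2 x 4 nm flux box on the
# valve marker atoms, count upper<->central exchanges in consecutive frames
# 10 ps apart, and compare constructs as replicate mean +/- SEM — the sealed
# wild-type-like system should show (near) zero events, the leaky mutants
# progressively more.

suppressMessages(library(valvewatch))
fx <- "results/fixtures"
if (!dir.exists(fx)) stop("run analysis/01_simulate.R first")
dir.create("results/flux", showWarnings = FALSE)

constructs <- c("WT", "L554A", "L554A_L555A")
summary_rows <- list()
for (label in constructs) {
  recs <- list()
  for (rep in 1:3) {
    prefix <- file.path(fx, sprintf("%s_rep%d", label, rep))
    st <- load_structure(paste0(prefix, ".pdb"))
    traj <- load_trajectory(st$topology, paste0(prefix, ".gro"))
    boxes <- anchor_boxes(get_frame(traj, 1L),
                          select_atoms(st$topology, VALVE_SELECTION))
    rec <- count_crossings(traj, boxes, stride_ps = 10)
    recs[[rep]] <- rec
    utils::write.csv(rec$cumulative,
                     sprintf("results/flux/%s_rep%d_cumulative.csv",
                             label, rep), row.names = FALSE)
  }
  s <- flux_summary(recs)
  summary_rows[[label]] <- data.frame(
    construct = label, mean = s$mean, sem = s$sem, n = s$n,
    counts = paste(s$counts, collapse = "/"))
  cat(sprintf("%-12s crossings over 6 ns: %s  (mean %.2f +/- %.2f SEM)\n",
              label, paste(s$counts, collapse = ", "), s$mean, s$sem))
}
tab <- do.call(rbind, summary_rows)
utils::write.csv(tab, "results/flux/flux_summary.csv", row.names = FALSE)

stopifnot(tab$mean[tab$construct == "WT"] <=
            tab$mean[tab$construct == "L554A"],
          tab$mean[tab$construct == "L554A"] <
            tab$mean[tab$construct == "L554A_L555A"])
cat("leak ordering WT <= single mutant < double mutant confirmed;",
    "tables under results/flux/\n")
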