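#!/usr/bin/env Rscript
# Skeletal kinematics: gape, hyoid depression and opercula abduction traces
# in the anatomical frame, and the ordering of their peaks in the intake and
# reverse-flow windows of every cohort trial.

library(xptflow)

dirs <- list.dirs("scratch/cohort", recursive = FALSE)
if (!length(dirs)) stop("run analysis/01_generate_cohort.R first")

rows <- list()

# read a cohort fixture directory written by write_fixture()
read_fixture_frame <- function(d) {
  ts <- read_trajectories(file.path(d, "trajectories.csv"))
  cfg <- jsonlite::read_json(file.path(d, "config.json"), simplifyVector = TRUE)
  neuro <- as.matrix(cfg$neuro_reference[, c("x", "y", "z")])
  rownames(neuro) <- cfg$neuro_reference$marker
  lm <- anatomical_landmarks(cfg$landmarks$origin,
                             as.matrix(cfg$landmarks$x_axis_pair),
                             cfg$landmarks$y_hint)
  at <- anatomical_transform(ts, paste0("neuro_", rownames(neuro)), neuro, lm)
  list(anat = at$anatomical, cfg = cfg,
       phases = segment_phases(aggregate_water_velocity(at$anatomical)))
}

for (d in dirs) {
  fx <- read_fixture_frame(d)
  anat <- fx$anat
  pt <- fx$phases
  appr <- pt[pt$label == "approach", ]
  rest_win <- c(appr$start_time[1], appr$end_time[1])
  traces <- list(
    gape_trace(anat$points$upperjaw, anat$points$lowerjaw, anat$frame_rate),
    hyoid_depression_trace(anat$points$hyoid, rest_win, anat$frame_rate),
    opercula_abduction_trace(anat$points$operculum, rest_win, anat$frame_rate))
  for (phase in c("intake", "rf")) {
    n_inst <- sum(pt$label == phase)
    for (inst in seq_len(n_inst)) {
      ps <- peak_sequence(traces, pt, phase, which = inst)
      rows[[length(rows) + 1]] <- data.frame(
        trial = basename(d), phase = phase, instance = inst,
        order = paste(ps$order$variable, collapse = " > "),
        label = ps$label)
    }
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/peak_sequences.csv", row.names = FALSE)

cat("peak-order classification by phase:\n")
print(table(tab$phase, tab$label))
ok_intake <- mean(tab$label[tab$phase == "intake"] == "intake_like")
ok_rf <- mean(tab$label[tab$phase == "rf"] == "rf_like")
cat(sprintf("intake windows intake_like: %.0f%%; rf windows rf_like: %.0f%%\n",
            100 * ok_intake, 100 * ok_rf))
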