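#!/usr/bin/env Rscript
# Segment every cohort trial into approach / intake / stasis / rf / bf from
# the mean water-tracer anteroposterior velocity, and summarize intake
# durations and rf/bf transition periodicity per species.

library(xptflow)

dirs <- list.dirs("scratch/cohort", recursive = FALSE)
if (!length(dirs)) stop("run analysis/01_generate_cohort.R first")

all_phases <- list()
summ <- list()

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
  pt <- fx$phases
  pt$trial <- basename(d)
  all_phases[[d]] <- pt
  it <- pt[pt$label == "intake", ]
  tp <- transition_periodicity(pt)
  summ[[d]] <- data.frame(
    trial = basename(d),
    species = sub("_.*", "", basename(d)),
    intake_duration = it$end_time[1] - it$start_time[1],
    intake_peak = it$peak_ap_velocity[1],
    rf_bf_period = tp$mean, rf_bf_period_sd = tp$sd)
}
phases <- do.call(rbind, all_phases)
summary_tab <- do.call(rbind, summ)
rownames(summary_tab) <- NULL
write.csv(phases, "results/phase_tables.csv", row.names = FALSE)
write.csv(summary_tab, "results/phase_summary.csv", row.names = FALSE)

for (sp in unique(summary_tab$species)) {
  s <- summary_tab[summary_tab$species == sp, ]
  cat(sprintf("%s (%d trials): intake %.3f +/- %.3f s, peak %.1f +/- %.1f cm/s, rf/bf every %.3f +/- %.3f s\n",
              sp, nrow(s), mean(s$intake_duration), sd(s$intake_duration),
              mean(s$intake_peak), sd(s$intake_peak),
              mean(s$rf_bf_period), sd(s$rf_bf_period)))
}
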