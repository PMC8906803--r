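#!/usr/bin/env Rscript
# Path-line geometry: dorsoventral-plane curvature of water vs food tracers
# over the intake (Kruskal-Wallis), lateromedial side preservation across the
# intake (Kendall), per-phase travel distances and flow-pattern labels.

library(xptflow)

dirs <- list.dirs("scratch/cohort", recursive = FALSE)
if (!length(dirs)) stop("run analysis/01_generate_cohort.R first")


# read a cohort fixture directory written by write_fixture()
load_trial <- function(d) {
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


profiles <- list()
kendall <- list()
patterns <- list()
distances <- list()
for (d in dirs) {
  tr <- load_trial(d)
  anat <- tr$anat
  it <- tr$phases[tr$phases$label == "intake", ]
  t <- time_axis(anat)
  idx <- which(t >= it$start_time[1] & t <= it$end_time[1])
  for (nm in names(anat$points)) {
    kind <- anat$track_kind[[nm]]
    if (!kind %in% c("water_tracer", "food_tracer")) next
    p <- anat$points[[nm]][idx, , drop = FALSE]
    prof <- interval_max_curvature(menger_curvature(p, anat$frame_rate),
                                   p[, 1], n_bins = 10,
                                   tracer = paste(basename(d), nm))
    prof$kind <- kind
    prof$trial <- basename(d)
    profiles[[length(profiles) + 1]] <- prof
    if (kind == "water_tracer") {
      patterns[[length(patterns) + 1]] <- data.frame(
        trial = basename(d), tracer = nm,
        pattern = classify_flow_pattern(anat$points[[nm]], tr$phases,
                                        cavity_halfwidth =
                                          tr$cfg$preset$cavity_halfwidth))
    }
    dd <- suppressWarnings(phase_distance(anat$points[[nm]], tr$phases, t))
    dd$trial <- basename(d)
    dd$tracer <- nm
    dd$kind <- kind
    distances[[length(distances) + 1]] <- dd
  }
  r <- positional_correlation(anat, tr$phases, "z_begin_vs_z_end")
  kendall[[length(kendall) + 1]] <- data.frame(
    trial = basename(d), tau = r$statistic, p_value = r$p_value, n = r$n)
}

prof_tab <- do.call(rbind, profiles)
write.csv(prof_tab, "results/curvature_profiles.csv", row.names = FALSE)
write.csv(do.call(rbind, kendall), "results/side_preservation.csv",
          row.names = FALSE)
write.csv(do.call(rbind, patterns), "results/flow_patterns.csv",
          row.names = FALSE)
dist_tab <- do.call(rbind, distances)
write.csv(dist_tab, "results/phase_distances.csv", row.names = FALSE)

for (sp in c("carp", "tilapia")) {
  sel <- grepl(sp, prof_tab$trial)
  w <- split(prof_tab[sel & prof_tab$kind == "water_tracer", ],
             prof_tab$tracer[sel & prof_tab$kind == "water_tracer"])
  f <- split(prof_tab[sel & prof_tab$kind == "food_tracer", ],
             prof_tab$tracer[sel & prof_tab$kind == "food_tracer"])
  w <- lapply(w, function(x) structure(x, class = c("curvature_profile",
                                                    "data.frame")))
  f <- lapply(f, function(x) structure(x, class = c("curvature_profile",
                                                    "data.frame")))
  cmp <- compare_curvature(w, f)
  cat(sprintf("%s: water vs food curvature H = %.1f, p = %.3g (%s; medians %.4f vs %.4f /mm)\n",
              sp, cmp$statistic, cmp$p_value, cmp$direction,
              cmp$median_water, cmp$median_food))
}
kd <- do.call(rbind, kendall)
cat(sprintf("side preservation: tau %.2f-%.2f, all p < %.2g\n",
            min(kd$tau), max(kd$tau), max(kd$p_value)))
cat("flow patterns:\n")
print(table(do.call(rbind, patterns)$pattern))
# pooled travel distance during the moving phases, water vs food
mov <- dist_tab[dist_tab$label %in% c("intake", "rf", "bf"), ]
tot <- tapply(mov$total_distance_mm, list(mov$trial, mov$tracer, mov$kind), sum)
wtot <- unlist(tapply(mov$total_distance_mm[mov$kind == "water_tracer"],
                      paste(mov$trial, mov$tracer)[mov$kind == "water_tracer"],
                      sum))
ftot <- unlist(tapply(mov$total_distance_mm[mov$kind == "food_tracer"],
                      paste(mov$trial, mov$tracer)[mov$kind == "food_tracer"],
                      sum))
cat(sprintf("pooled moving-phase distance: water median %.0f mm, food median %.0f mm\n",
            median(wtot), median(ftot)))
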