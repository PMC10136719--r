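# Shared fixtures: small deterministic objects used across test files.

fast_reference <- function(cadence = 40) gait_reference(cadence = cadence)

# able-bodied profile: zero tracking error everywhere
zero_error_patient <- function() patient_profile(0)

# deterministic impaired profile with uniform deviation magnitude
uniform_patient <- function(c_deg, variability = 0) {
  patient_profile(c_deg, session_variability = variability)
}

# wrap a single adaptive block as a two-leg training session (the right leg
# reuses the same trajectories, relabelled)
blk_session <- function(blk) {
  blkR <- blk
  blkR$active_leg <- "right"
  blkR$phase <- "adaptive-right"
  structure(list(blocks = list(adaptive_left = blk, adaptive_right = blkR)),
            class = "ags_training_session")
}

# a small complete study for pipeline-level tests
tiny_study <- function(n = 3, seed = 7, keep_deviation = FALSE,
                       simulate_conventional = FALSE) {
  set.seed(seed)
  cohort <- sample_cohort(n)
  simulate_study(
    cohort,
    schedule = study_schedule(extra_session_prob = 0,
                              warmup_min = 1, conventional_min = 2,
                              simulate_conventional = simulate_conventional),
    keep_deviation = keep_deviation
  )
}

# independent oracle: subphase means by naive row grouping over log rows,
# deriving each row's subphase from its window column by majority overlap
naive_subphase_means <- function(log) {
  nw <- max(log$window) + 1L
  edges <- seq(0, 1, length.out = nw + 1L)
  cuts <- c(0, 0.625, 0.730, 0.870, 1.0)
  labels <- c("stance", "IS", "MS", "TS")
  win_label <- sapply(seq_len(nw), function(w) {
    ov <- sapply(1:4, function(p) {
      max(0, min(edges[w + 1L], cuts[p + 1L]) - max(edges[w], cuts[p]))
    })
    labels[which.max(ov)]
  })
  log$sp <- win_label[log$window + 1L]
  rows <- log[log$sp != "stance", ]
  out <- list()
  for (leg in unique(rows$leg)) {
    for (cyc in unique(rows$cycle_index)) {
      for (sp in c("IS", "MS", "TS")) {
        sub <- rows[rows$leg == leg & rows$cycle_index == cyc & rows$sp == sp, ]
        if (nrow(sub) == 0) next
        for (ch in c("k_hip", "b_hip", "k_knee", "b_knee")) {
          out[[length(out) + 1L]] <- data.frame(
            leg = leg, cycle = cyc, subphase = sp, channel = ch,
            value = mean(sub[[ch]])
          )
        }
      }
    }
  }
  do.call(rbind, out)
}
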