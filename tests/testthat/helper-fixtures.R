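# small constructors shared across test files

# deterministic single-channel test tone
test_tone <- function(freq = 10, amp = 1, dur = 5, fs = 250) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  amp * cos(2 * pi * freq * t)
}

# hand-built measure table with a clean wake >> sedation separation and no
# class structure, bypassing EEG synthesis (fast statistical-layer fixture)
toy_measure_table <- function(n = 20, seed = 1) {
  set.seed(seed)
  pid <- sprintf("P%02d", 1:n)
  cls <- sample(c("experience", "no_information", "no_experience"), 3 * n,
                replace = TRUE)
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      participant_id = pid[i],
      condition = c("wake_eo", "wake_ec", "wake_ec",
                    paste0("sedation_", 1:3), paste0("sedation_", 1:3)),
      measure = c("lzc", "lzc", "pcist", rep("lzc", 3), rep("pcist", 3)),
      value = c(0.33 + rnorm(1, 0, 0.01), 0.31 + rnorm(1, 0, 0.01),
                54 + rnorm(1, 0, 10),
                0.27 + rnorm(3, 0, 0.01), 22 + rnorm(3, 0, 4)),
      experience_class = c(NA, NA, NA, cls[(i - 1) * 3 + 1:3],
                           cls[(i - 1) * 3 + 1:3])
    )
  }
  as_measure_table(dplyr::bind_rows(rows))
}

# tiny pipeline configuration for orchestration tests
tiny_config <- function(seed = 1, output_dir = NULL) {
  run_config(seed = seed, n_channels = 4L, wake_duration = 10,
             sedation_duration = 10,
             awakening_counts = c(2L, 2L, 1L), n_tms_participants = 2L,
             n_trials = 12L, output_dir = output_dir)
}
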