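# Shared fixtures: all data is generated in code at test time.

tiny_cohort <- function(seed = 1, np = 6, days = 8, T = 60) {
  generate_cohort(cohort_config(n_participants = np, days_mean = days,
                                days_sd = 0, T = T, seed = seed))
}

# next-day pairs from a cohort, via the full scoring pipeline
tiny_pairs <- function(coh) {
  eng <- engineer_features(coh$daily)
  hs <- health_score(eng)
  build_pairs(eng, coh$minutes, hs$score)
}

# a small network configuration for fast unit tests
tiny_net_config <- function(T, ...) {
  base <- list(T = T, h = 8L, n_heads = 2L,
               conv_filters = c(4L, 6L, 8L), conv_kernels = c(5L, 3L, 3L),
               mlp_dims = c(6L, 7L), ffn_hidden = c(10L, 12L),
               head_hidden = 8L, max_epochs = 3L, patience = 3L,
               seed = 7L)
  do.call(fatnet_config, utils::modifyList(base, list(...)))
}

# hand-built minimal cohort object for imputation tests
manual_cohort <- function(hr_fun, n_days = 3, T = 20, id = "P001") {
  minutes <- do.call(rbind, lapply(seq_len(n_days), function(d)
    data.frame(participant_id = id, day_index = d,
               minute_index = seq_len(T), hr_bpm = hr_fun(d, seq_len(T)),
               music_on = 0L)))
  daily <- data.frame(
    participant_id = id, day_index = seq_len(n_days),
    panas = 30L, sleep_efficiency = 85, rmssd = 35, sdnn = 45, rhr = 65,
    waso = 30, total_sleep_time = 420L, listening_duration = 30,
    mean_tempo = 110, valence = 5, arousal = 5, age = 70L,
    gender = "female", bmi = 25, hypertension = 0L, diabetes = 0L,
    day_missing = FALSE, stringsAsFactors = FALSE)
  truth <- data.frame(participant_id = id, day_index = seq_len(n_days),
                      wellness = 0, g_raw = 0, g_std = 0, rating = 5L,
                      stringsAsFactors = FALSE)
  profiles <- data.frame(participant_id = id, age = 70L, gender = "female",
                         bmi = 25, hypertension = 0L, diabetes = 0L,
                         baseline_rhr = 65, music_preference_tempo = 100,
                         stringsAsFactors = FALSE)
  structure(list(profiles = profiles, minutes = minutes, daily = daily,
                 truth = truth,
                 config = cohort_config(n_participants = 1, T = T)),
            class = "fatnet_cohort")
}
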