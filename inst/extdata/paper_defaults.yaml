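# Default synthetic-cohort calibration: group-level typing and clinical
# score distributions for healthy controls, de novo PD and early PD.
# il_sd / hl_sd are fluctuation-statistic targets (subject-level mean/sd);
# the generator maps them to log-normal sigmas via sigma = target / sqrt(2).
# speed_link_rho / words_link_rho are Spearman targets tying typing speed and
# session length to UPDRS-III severity.
groups:
  control:
    n_subjects: 43
    il_sd: {mean: 1.15, sd: 0.15}
    hl_sd: {mean: 0.50, sd: 0.16}
    updrs3: {mean: 1.92, sd: 1.79, min: 0, max: 6}
    stap: {mean: 170.85, sd: 16.45, min: 0}
    aftap: {mean: 128.99, sd: 27.85, min: 0, n_missing: 4}
    nqi: {mean: 0.06, sd: 0.06, min: 0}
    typing_speed: {mean: 112.34, sd: 58.75, min: 25, max: 220}
    n_keystrokes: {mean: 1634.33, sd: 793.04, min: 300}
    outlier_rate: 0.003
    rollover_prob: 0.002
    space_rate: 0.167
    speed_link_rho: 0.0
    words_link_rho: 0.0
  de_novo_pd:
    n_subjects: 24
    il_sd: {mean: 1.28, sd: 0.11}
    hl_sd: {mean: 0.57, sd: 0.15}
    updrs3: {mean: 19.33, sd: 6.70, min: 7, max: 36}
    stap: {mean: 165.48, sd: 24.24, min: 0}
    aftap: {mean: 94.85, sd: 23.54, min: 0, n_missing: 0}
    nqi: {mean: 0.12, sd: 0.10, min: 0}
    typing_speed: {mean: 97.20, sd: 42.53, min: 25, max: 220}
    n_keystrokes: {mean: 1454.21, sd: 497.72, min: 300}
    outlier_rate: 0.002
    rollover_prob: 0.002
    space_rate: 0.167
    speed_link_rho: -0.37
    words_link_rho: -0.45
  early_pd:
    n_subjects: 18
    il_sd: {mean: 1.27, sd: 0.16}
    hl_sd: {mean: 0.53, sd: 0.15}
    updrs3: {mean: 22.32, sd: 8.69, min: 11, max: 40}
    stap: {mean: 159.42, sd: 24.13, min: 0}
    aftap: {mean: 96.33, sd: 19.75, min: 0, n_missing: 5}
    nqi: {mean: 0.14, sd: 0.06, min: 0}
    typing_speed: {mean: 98.86, sd: 45.94, min: 25, max: 220}
    n_keystrokes: {mean: 1320.56, sd: 581.98, min: 300}
    outlier_rate: 0.0017
    rollover_prob: 0.002
    space_rate: 0.167
    speed_link_rho: -0.76
    words_link_rho: -0.73
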