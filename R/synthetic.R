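#' Typist profile for the synthetic keystroke generator
#'
#' The generator models a typist as independent log-normal hold times and
#' interkey gaps: `HL ~ lognormal(mu_log_hl, sigma_log_hl)`,
#' `IL ~ lognormal(mu_log_il, sigma_log_il)`. For iid log-normal intervals
#' the log-ratio fluctuation statistic converges to `sqrt(2) * sigma`, so a
#' target group IL fluctuation of 1.15 corresponds to
#' `sigma_log_il = 1.15 / sqrt(2)`. Two realistic disturbances are overlaid:
#' rollover events (with probability `rollover_prob` an interkey gap is
#' replaced by a negative overlap, the next key going down before the current
#' one is released) and rare recording glitches (with probability
#' `outlier_rate` an interval is replaced by an extreme value, 30–100 times
#' the typist's median interval).
#'
#' @param n_keystrokes Session length (>= 10 keystrokes).
#' @param mu_log_hl,sigma_log_hl Log-scale location/scale of hold times (s).
#' @param mu_log_il,sigma_log_il Log-scale location/scale of interkey gaps
#'   (s). `mu_log_il` is ignored when `words_per_min` is given.
#' @param rollover_prob Probability an interkey gap is a negative overlap.
#' @param outlier_rate Probability an interval is an extreme glitch value.
#' @param space_rate Probability a keystroke is the space bar (other keys are
#'   letters).
#' @param words_per_min Optional target typing speed; when given, the
#'   interkey location is solved so the expected realised speed matches it.
#' @return A `typist_profile` object.
#' @export
typist_profile <- function(n_keystrokes = 1500,
                           mu_log_hl = log(0.025), sigma_log_hl = 0.35,
                           mu_log_il = log(0.06), sigma_log_il = 0.81,
                           rollover_prob = 0.002, outlier_rate = 0.003,
                           space_rate = 1 / 6, words_per_min = NULL) {
  if (!is.numeric(n_keystrokes) || n_keystrokes < 10) {
    abort("`n_keystrokes` must be >= 10")
  }
  if (sigma_log_hl <= 0 || sigma_log_il <= 0) abort("sigmas must be > 0")
  for (p in c(rollover_prob, outlier_rate, space_rate)) {
    if (p < 0 || p > 1) abort("probabilities must lie in [0, 1]")
  }
  structure(list(n_keystrokes = as.integer(round(n_keystrokes)),
                 mu_log_hl = mu_log_hl, sigma_log_hl = sigma_log_hl,
                 mu_log_il = mu_log_il, sigma_log_il = sigma_log_il,
                 rollover_prob = rollover_prob, outlier_rate = outlier_rate,
                 space_rate = space_rate, words_per_min = words_per_min),
            class = "typist_profile")
}

# solve the interkey log-location hitting a words-per-minute target:
# expected elapsed = n*E[HL] + (n-1)*E[IL]; words = space_rate*n + 1
solve_mu_log_il <- function(profile) {
  n <- profile$n_keystrokes
  e_hl <- exp(profile$mu_log_hl + profile$sigma_log_hl^2 / 2)
  words <- profile$space_rate * n + 1
  t_target <- 60 * words / profile$words_per_min
  e_il <- (t_target - n * e_hl) / (n - 1)
  if (e_il <= 0.002) {
    abort(sprintf("typing speed target %.0f words/min unattainable at this hold-time profile",
                  profile$words_per_min))
  }
  log(e_il) - profile$sigma_log_il^2 / 2
}

#' Simulate one typing session
#'
#' Press times are cumulative: `P[i+1] = P[i] + HL[i] + IL[i]`,
#' `R[i] = P[i] + HL[i]`. Rollover gaps are drawn as `-u * HL[i]` with
#' `u ~ U(0.05, 0.6)`, so press order is always preserved. Glitch outliers
#' replace the interval with `exp(mu) * U(30, 100)`. Fully deterministic
#' given `seed`.
#'
#' @param profile A [typist_profile()].
#' @param seed Optional integer seed (uses and restores the RNG state); when
#'   `NULL` the current RNG stream is consumed.
#' @param subject_id,visit_index Session identity stamped on the events.
#' @return Event tibble (see [read_keystrokes()]) with attribute
#'   `"truth"` holding the injected outlier/rollover positions per stream.
#' @export
simulate_session <- function(profile, seed = NULL, subject_id = "S1",
                             visit_index = 1L) {
  if (!inherits(profile, "typist_profile")) abort("need a typist_profile")
  run <- function() {
    n <- profile$n_keystrokes
    mu_il <- if (!is.null(profile$words_per_min)) {
      solve_mu_log_il(profile)
    } else {
      profile$mu_log_il
    }
    hl <- rlnorm(n, profile$mu_log_hl, profile$sigma_log_hl)
    il <- rlnorm(n - 1, mu_il, profile$sigma_log_il)
    out_hl <- runif(n) < profile$outlier_rate
    hl[out_hl] <- exp(profile$mu_log_hl) * runif(sum(out_hl), 30, 100)
    out_il <- runif(n - 1) < profile$outlier_rate
    il[out_il] <- exp(mu_il) * runif(sum(out_il), 30, 100)
    roll <- runif(n - 1) < profile$rollover_prob & !out_il
    il[roll] <- -runif(sum(roll), 0.05, 0.6) * hl[seq_len(n - 1)][roll]
    press <- cumsum(c(0, hl[-n] + il))
    release <- press + hl
    keys <- ifelse(runif(n) < profile$space_rate, "space",
                   sample(letters, n, replace = TRUE))
    ev <- tibble(subject_id = subject_id,
                 visit_index = as.integer(visit_index),
                 key_id = keys, press_time = press, release_time = release)
    structure(ev, truth = list(outlier_hl = which(out_hl),
                               outlier_il = which(out_il),
                               rollover_il = which(roll),
                               mu_log_il = mu_il))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Cohort specification for the synthetic study
#'
#' `cohort_spec()` validates a per-group parameter list; `paper_cohort_spec()`
#' loads the calibration shipped at
#' `inst/extdata/paper_defaults.yaml`, whose group means/SDs (sample sizes
#' 43/24/18, interkey fluctuation 1.15/1.28/1.27, alternating-finger tapping
#' 128.99/94.85/96.33 ms, outlier removal around 0.5%, severity-speed rank
#' correlations) match published control / de novo PD / early PD cohorts.
#'
#' Each group entry carries: `n_subjects`; `il_sd` and `hl_sd` (mean/sd of
#' the subject-level fluctuation targets, mapped to log-normal sigmas via
#' `sigma = target / sqrt(2)`); clinical score distributions `updrs3`,
#' `stap`, `aftap` (with `n_missing` subjects unable to complete it), `nqi`;
#' `typing_speed` and `n_keystrokes` (truncated normals); `outlier_rate`,
#' `rollover_prob`, `space_rate`; and Gaussian-copula rank-correlation
#' targets `speed_link_rho`, `words_link_rho` tying typing speed and session
#' length to UPDRS-III severity.
#'
#' @param groups Named list of group parameter lists (names are the group
#'   labels `control`, `de_novo_pd`, `early_pd`).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(groups) {
  ok <- c("control", "de_novo_pd", "early_pd")
  if (!all(names(groups) %in% ok)) {
    abort(sprintf("group names must be among: %s", paste(ok, collapse = ", ")))
  }
  for (g in names(groups)) {
    gp <- groups[[g]]
    need <- c("n_subjects", "il_sd", "hl_sd", "updrs3", "stap", "aftap",
              "nqi", "typing_speed", "n_keystrokes", "outlier_rate",
              "rollover_prob", "space_rate", "speed_link_rho",
              "words_link_rho")
    miss <- setdiff(need, names(gp))
    if (length(miss) > 0) {
      abort(sprintf("group '%s' missing field(s): %s", g,
                    paste(miss, collapse = ", ")))
    }
    if (gp$n_subjects < 2) abort("each group needs n_subjects >= 2")
  }
  structure(list(groups = groups), class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param path Path to a YAML cohort spec; defaults to the shipped
#'   calibration.
#' @export
paper_cohort_spec <- function(path = system.file("extdata",
                                                 "paper_defaults.yaml",
                                                 package = "keyfluc")) {
  cohort_spec(yaml::read_yaml(path)$groups)
}

group_prefixes <- c(control = "C", de_novo_pd = "D", early_pd = "E")

# clamped normal draw helper for spec entries {mean, sd, min, max}
draw_spec <- function(entry, z) {
  x <- entry$mean + entry$sd * z
  pmin(pmax(x, entry$min %||% -Inf), entry$max %||% Inf)
}

#' Simulate a full synthetic cohort
#'
#' Subject-level typing profiles are jittered around their group profile;
#' clinical scores are drawn from truncated group normals; typing speed and
#' session length are tied to UPDRS-III severity through a Gaussian copula at
#' the group's rank-correlation targets. Ground truth (every latent
#' parameter) is recorded so the pipeline's parameter recovery can be tested.
#' Output is fully determined by `spec` and `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A `keystroke_cohort`: list with `events` (all sessions, canonical
#'   columns), `metadata` (per-subject table) and `truth` (latent
#'   parameters), plus the spec and seed.
#' @export
simulate_cohort <- function(spec, seed = 1L) {
  if (!inherits(spec, "cohort_spec")) abort("need a cohort_spec")
  withr::with_seed(seed, {
    events <- list()
    meta <- list()
    truth <- list()
    for (g in names(spec$groups)) {
      gp <- spec$groups[[g]]
      n <- gp$n_subjects
      ids <- sprintf("%s%02d", group_prefixes[[g]], seq_len(n))

      z_u <- rnorm(n)
      updrs <- round(draw_spec(gp$updrs3, z_u))
      copula_draw <- function(rho_s, entry) {
        rho_p <- 2 * sin(pi * rho_s / 6)   # rank -> Pearson on the copula
        z <- rho_p * z_u + sqrt(1 - rho_p^2) * rnorm(n)
        draw_spec(entry, z)
      }
      speed <- copula_draw(gp$speed_link_rho, gp$typing_speed)
      n_keys <- round(copula_draw(gp$words_link_rho, gp$n_keystrokes))
      stap <- draw_spec(gp$stap, rnorm(n))
      aftap <- draw_spec(gp$aftap, rnorm(n))
      n_miss <- gp$aftap$n_missing %||% 0
      if (n_miss > 0) aftap[sample.int(n, n_miss)] <- NA_real_
      nqi <- draw_spec(gp$nqi, rnorm(n))
      sig_il <- pmin(pmax((gp$il_sd$mean + gp$il_sd$sd * rnorm(n)) / sqrt(2),
                          0.07), 1.2)
      sig_hl <- pmin(pmax((gp$hl_sd$mean + gp$hl_sd$sd * rnorm(n)) / sqrt(2),
                          0.05), 0.75)
      seeds <- sample.int(.Machine$integer.max - 1L, n)

      sess <- vector("list", n)
      for (i in seq_len(n)) {
        prof <- typist_profile(
          n_keystrokes = n_keys[i],
          sigma_log_hl = sig_hl[i], sigma_log_il = sig_il[i],
          rollover_prob = gp$rollover_prob, outlier_rate = gp$outlier_rate,
          space_rate = gp$space_rate, words_per_min = speed[i]
        )
        sess[[i]] <- simulate_session(prof, seed = seeds[i],
                                      subject_id = ids[i])
      }
      events[[g]] <- dplyr::bind_rows(sess)
      meta[[g]] <- tibble(subject_id = ids, group = g, updrs3 = updrs,
                          stap = stap, aftap = aftap, nqi = nqi,
                          visit_index = 1L)
      truth[[g]] <- tibble(
        subject_id = ids, group = g,
        sigma_log_hl = sig_hl, sigma_log_il = sig_il,
        expected_hl_sd = sqrt(2) * sig_hl,
        expected_il_sd = sqrt(2) * sig_il,
        outlier_rate = gp$outlier_rate, rollover_prob = gp$rollover_prob,
        n_keystrokes = n_keys, target_speed = speed, updrs3 = updrs
      )
    }
    structure(list(events = dplyr::bind_rows(events),
                   metadata = dplyr::bind_rows(meta),
                   truth = dplyr::bind_rows(truth),
                   spec = spec, seed = seed),
              class = "keystroke_cohort")
  })
}

#' @export
print.keystroke_cohort <- function(x, ...) {
  cat(sprintf("Synthetic keystroke cohort (seed %d): %d subjects, %d events\n",
              x$seed, nrow(x$metadata), nrow(x$events)))
  print(dplyr::count(x$metadata, .data$group))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the canonical keystroke CSV, the metadata CSV and the ground-truth
#' CSV into a directory.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_keystrokes(cohort$events, file.path(dir, "keystrokes.csv"))
  readr::write_csv(cohort$metadata, file.path(dir, "metadata.csv"), na = "")
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"), na = "")
  invisible(dir)
}
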