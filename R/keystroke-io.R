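#' Describe a keystroke-log dialect
#'
#' A dialect maps the columns of a source file onto the canonical event
#' fields (`key_id`, `press_time`, `release_time`), declares the time unit,
#' and — for datasets stored as one file per subject — how to recover the
#' subject identifier from the file name. The canonical dialect is a CSV with
#' header `subject_id,visit_index,key_id,press_time,release_time`, times in
#' seconds.
#'
#' @param key_id,press_time,release_time Source column names holding the key
#'   label and the press/release timestamps.
#' @param subject_id,visit_index Source column names, or `NULL` when the file
#'   does not carry them (the reader then takes them from its arguments or
#'   from the file name).
#' @param time_unit `"s"` or `"ms"`; timestamps are normalised to seconds.
#' @param delim Field delimiter.
#' @param file_glob For per-subject layouts, a glob selecting data files
#'   inside a directory.
#' @param subject_pattern Regex with one capture group extracting the subject
#'   id from a file name.
#' @return A `keystroke_dialect` object (a validated list).
#' @export
#' @examples
#' keystroke_dialect()                      # canonical CSV
#' keystroke_dialect(time_unit = "ms")      # same columns, millisecond clock
keystroke_dialect <- function(key_id = "key_id",
                              press_time = "press_time",
                              release_time = "release_time",
                              subject_id = "subject_id",
                              visit_index = "visit_index",
                              time_unit = c("s", "ms"),
                              delim = ",",
                              file_glob = "*.csv",
                              subject_pattern = "^([^_.]+)") {
  time_unit <- match.arg(time_unit)
  for (f in c(key_id, press_time, release_time)) {
    if (!is.character(f) || length(f) != 1L || !nzchar(f)) {
      abort("dialect column names must be non-empty strings")
    }
  }
  structure(
    list(key_id = key_id, press_time = press_time,
         release_time = release_time,
         subject_id = subject_id, visit_index = visit_index,
         time_unit = time_unit, delim = delim,
         file_glob = file_glob, subject_pattern = subject_pattern),
    class = "keystroke_dialect"
  )
}

#' Read a dialect definition from a YAML/JSON config file
#'
#' @param path Path to a key-value config file; keys are the arguments of
#'   [keystroke_dialect()]. The adapter for the PhysioNet `nqmitcsxpd`
#'   archive ships with the package:
#'   `system.file("extdata", "nqmitcsxpd.yaml", package = "keyfluc")`.
#' @return A `keystroke_dialect`.
#' @export
read_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(keystroke_dialect))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown dialect field(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(keystroke_dialect, cfg)
}

# normalise one raw session table to canonical events; returns events + reject count
normalize_events <- function(df, dialect, subject_id, visit_index, source) {
  need <- c(dialect$key_id, dialect$press_time, dialect$release_time)
  stopifnot_cols(df, need, sprintf("keystroke file '%s'", source))

  press <- df[[dialect$press_time]]
  release <- df[[dialect$release_time]]
  bad_num <- which(is.na(suppressWarnings(as.numeric(press))) |
                     is.na(suppressWarnings(as.numeric(release))))
  if (length(bad_num) > 0) {
    abort(sprintf("non-numeric timestamp in '%s' at data row(s) %s",
                  source, paste(head(bad_num, 5), collapse = ", ")))
  }
  press <- as.numeric(press)
  release <- as.numeric(release)
  if (dialect$time_unit == "ms") {
    press <- press / 1000
    release <- release / 1000
  }
  key <- normalize_key(df[[dialect$key_id]])
  if (any(!nzchar(key))) abort(sprintf("empty key_id in '%s'", source))

  sid <- if (!is.null(dialect$subject_id) && dialect$subject_id %in% names(df)) {
    as.character(df[[dialect$subject_id]])
  } else {
    rep(as.character(subject_id), nrow(df))
  }
  vis <- if (!is.null(dialect$visit_index) && dialect$visit_index %in% names(df)) {
    as.integer(df[[dialect$visit_index]])
  } else {
    rep(as.integer(visit_index), nrow(df))
  }

  ev <- tibble(subject_id = sid, visit_index = vis, key_id = key,
               press_time = press, release_time = release)
  rejected <- ev$release_time < ev$press_time
  report <- dplyr::count(ev[rejected, ], .data$subject_id, .data$visit_index,
                         name = "n_rejected")
  ev <- ev[!rejected, ]
  ev <- dplyr::arrange(ev, .data$subject_id, .data$visit_index,
                       .data$press_time, .data$release_time, .data$key_id)
  # session-relative clock: only intervals matter downstream
  ev <- dplyr::mutate(
    dplyr::group_by(ev, .data$subject_id, .data$visit_index),
    release_time = .data$release_time - min(.data$press_time),
    press_time = .data$press_time - min(.data$press_time)
  )
  ev <- dplyr::ungroup(ev)
  list(events = ev, report = report)
}

normalize_key <- function(key) {
  key <- tolower(trimws(as.character(key)))
  key[key == " "] <- "space"
  key
}

#' Read keystroke logs
#'
#' `read_keystrokes()` reads one delimited log file; `read_keystroke_dir()`
#' reads a per-subject directory layout using the dialect's `file_glob` and
#' `subject_pattern`. Events with `release_time < press_time` are dropped at
#' read time and counted in the read report (retrieve it with
#' [read_report()] before further piping — dplyr verbs drop attributes).
#' Timestamps are normalised to seconds and re-expressed relative to the
#' first press of each session; key labels are lower-cased with named
#' specials (`"space"`, `"backspace"`, ...).
#'
#' @param path A delimited text file (or, for `read_keystroke_dir`, a
#'   directory of per-subject files).
#' @param dialect A [keystroke_dialect()].
#' @param subject_id,visit_index Used when the file does not carry these
#'   columns.
#' @return A tibble of events with columns `subject_id`, `visit_index`,
#'   `key_id`, `press_time`, `release_time`, sorted by press time within
#'   session, with a `read_report` attribute.
#' @export
read_keystrokes <- function(path, dialect = keystroke_dialect(),
                            subject_id = "S1", visit_index = 1L) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_delim(path, delim = dialect$delim, show_col_types = FALSE,
                          progress = FALSE, trim_ws = TRUE)
  out <- normalize_events(df, dialect, subject_id, visit_index, path)
  structure(out$events, read_report = out$report, source = path)
}

#' @rdname read_keystrokes
#' @export
read_keystroke_dir <- function(path, dialect = keystroke_dialect()) {
  if (!dir.exists(path)) abort(sprintf("directory not found: %s", path))
  files <- Sys.glob(file.path(path, dialect$file_glob))
  if (length(files) == 0) abort(sprintf("no files matching '%s' in %s",
                                        dialect$file_glob, path))
  parts <- lapply(files, function(f) {
    sid <- sub(paste0(dialect$subject_pattern, ".*"), "\\1", basename(f))
    df <- readr::read_delim(f, delim = dialect$delim, show_col_types = FALSE,
                            progress = FALSE, trim_ws = TRUE)
    normalize_events(df, dialect, sid, 1L, f)
  })
  events <- dplyr::bind_rows(lapply(parts, `[[`, "events"))
  report <- dplyr::bind_rows(lapply(parts, `[[`, "report"))
  structure(events, read_report = report, source = path)
}

#' Retrieve the read report attached by the keystroke readers
#'
#' @param events The tibble returned by [read_keystrokes()].
#' @return Tibble of per-session rejected-row counts (empty when nothing was
#'   rejected).
#' @export
read_report <- function(events) {
  rep <- attr(events, "read_report")
  if (is.null(rep)) {
    tibble(subject_id = character(), visit_index = integer(),
           n_rejected = integer())
  } else {
    as_tibble(rep)
  }
}

#' Write events in the canonical keystroke CSV dialect
#'
#' @param events Event tibble (see [read_keystrokes()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_keystrokes <- function(events, path) {
  stopifnot_cols(events, c("subject_id", "visit_index", "key_id",
                           "press_time", "release_time"), "events")
  readr::write_csv(events[, c("subject_id", "visit_index", "key_id",
                              "press_time", "release_time")], path)
  invisible(path)
}

#' Read a subject metadata table
#'
#' Canonical CSV with header
#' `subject_id,group,updrs3,stap,aftap,nqi,visit_index`; `group` must be one
#' of `control`, `de_novo_pd`, `early_pd`. Missing clinical scores are empty
#' fields and stay `NA` — they are never coerced to zero.
#'
#' @param path CSV file.
#' @return Tibble of per-subject metadata.
#' @export
read_subject_metadata <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(df, c("subject_id", "group"), "metadata")
  validate_metadata(df)
}

validate_metadata <- function(df) {
  ok <- c("control", "de_novo_pd", "early_pd")
  bad <- setdiff(unique(df$group), ok)
  if (length(bad) > 0) {
    abort(sprintf("unknown group label(s): %s (expected %s)",
                  paste(bad, collapse = ", "), paste(ok, collapse = "/")))
  }
  for (col in c("updrs3", "stap", "aftap", "nqi")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
  }
  df$subject_id <- as.character(df$subject_id)
  as_tibble(df)
}

#' Keep each subject's first recorded typing session
#'
#' Typing tests are commonly repeated; to avoid imprinting/adaptation effects
#' analyses use the earliest visit only. Keeps, per subject, all events of
#' the minimum `visit_index` present.
#'
#' @param events Event tibble.
#' @return Event tibble restricted to one session per subject.
#' @export
select_first_visit <- function(events) {
  stopifnot_cols(events, c("subject_id", "visit_index"), "events")
  sess <- dplyr::distinct(events, .data$subject_id, .data$visit_index)
  dup <- sess[duplicated(sess), ]
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate (subject, visit) pairs: %s",
                  paste(dup$subject_id, dup$visit_index, sep = "/",
                        collapse = ", ")))
  }
  dplyr::ungroup(dplyr::filter(
    dplyr::group_by(events, .data$subject_id),
    .data$visit_index == min(.data$visit_index)
  ))
}

feature_columns <- c(
  "subject_id", "group", "hl_sd", "il_sd", "pl_sd", "rl_sd", "sd_restricted",
  "typing_speed", "word_count", "n_keystrokes",
  "updrs3", "stap", "aftap", "nqi"
)

#' Write / read the per-subject feature table
#'
#' One row per subject, stable column order, missing values as empty fields;
#' round-trips losslessly at the written precision.
#'
#' @param features Feature tibble from [compute_features()].
#' @param path CSV file.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the feature tibble.
#' @export
write_feature_table <- function(features, path) {
  if (nrow(features) == 0) abort("empty feature table")
  cols <- intersect(feature_columns, names(features))
  extra <- setdiff(names(features), cols)
  readr::write_csv(features[, c(cols, extra)], path, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in names(df)) {
    df[[col]] <- if (col %in% c("subject_id", "group")) {
      as.character(df[[col]])
    } else {
      as.numeric(df[[col]])
    }
  }
  as_tibble(df)
}
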