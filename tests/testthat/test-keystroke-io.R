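canon_csv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  writeLines(c("subject_id,visit_index,key_id,press_time,release_time",
               lines), f)
  f
}

test_that("canonical CSV reads back identically, with unit conversion", {
  f <- canon_csv(c("S1,1,a,0.00,0.10", "S1,1,b,0.50,0.65", "S1,1,c,0.60,0.80"))
  ev <- read_keystrokes(f)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$press_time, c(0, 0.5, 0.6))
  expect_equal(ev$release_time, c(0.1, 0.65, 0.8))
  expect_equal(ev$key_id, c("a", "b", "c"))

  fms <- canon_csv(c("S1,1,a,0,100", "S1,1,b,500,650", "S1,1,c,600,800"))
  ev_ms <- read_keystrokes(fms, keystroke_dialect(time_unit = "ms"))
  expect_equal(ev_ms$press_time, ev$press_time)
  expect_equal(ev_ms$release_time, ev$release_time)
})

test_that("events with release before press are dropped and counted", {
  f <- canon_csv(c("S1,1,a,0.00,0.10", "S1,1,b,0.50,0.40", "S1,1,c,0.60,0.80"))
  ev <- read_keystrokes(f)
  expect_equal(nrow(ev), 2)
  rep <- read_report(ev)
  expect_equal(rep$n_rejected, 1L)
})

test_that("event ordering is invariant to input row shuffling and the clock
           is session-relative", {
  rows <- c("S1,1,c,5.60,5.80", "S1,1,a,5.00,5.10", "S1,1,b,5.50,5.65")
  ev <- read_keystrokes(canon_csv(rows))
  ev_shuf <- read_keystrokes(canon_csv(rows[c(2, 3, 1)]))
  attr(ev, "source") <- attr(ev_shuf, "source") <- NULL
  expect_identical(as.data.frame(ev), as.data.frame(ev_shuf))
  expect_equal(ev$press_time[1], 0)          # first press anchors the clock
  expect_equal(ev$press_time, c(0, 0.5, 0.6))
})

test_that("read errors name the problem: missing column, bad timestamp", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,visit_index,key_id,press_time", "S1,1,a,0"), f)
  expect_error(read_keystrokes(f), "release_time")
  f2 <- canon_csv(c("S1,1,a,0.00,0.10", "S1,1,b,oops,0.65"))
  expect_error(read_keystrokes(f2), "non-numeric timestamp")
})

test_that("first-visit selection keeps the minimum visit per subject", {
  ev <- dplyr::bind_rows(
    make_session(c(0, 1), c(0.1, 1.1), visit = 1, subject = "A"),
    make_session(c(0, 1), c(0.1, 1.1), visit = 2, subject = "A"),
    make_session(c(0, 1), c(0.1, 1.1), visit = 2, subject = "B")
  )
  out <- select_first_visit(ev)
  sess <- dplyr::distinct(out, subject_id, visit_index)
  expect_equal(nrow(sess), 2)
  expect_equal(sess$visit_index[sess$subject_id == "A"], 1L)
  # a subject whose earliest available visit is 2 keeps visit 2
  expect_equal(sess$visit_index[sess$subject_id == "B"], 2L)
})

test_that("feature table round-trips losslessly with missing values as
           empty fields", {
  feats <- tibble::tibble(
    subject_id = c("A", "B"), group = c("control", "early_pd"),
    hl_sd = c(0.5, NA), il_sd = c(1.151234, 1.3), pl_sd = c(1, 1),
    rl_sd = c(1.1, 1.2), sd_restricted = c(0.3, 0.4),
    typing_speed = c(100.5, 90), word_count = c(200, 180),
    n_keystrokes = c(1500, 1400),
    updrs3 = c(1, 25), stap = c(170, NA), aftap = c(NA, 95), nqi = c(0.05, NA)
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(feats, f)
  back <- read_feature_table(f)
  expect_equal(as.data.frame(back), as.data.frame(feats))
  expect_true(is.na(back$aftap[1]))
  raw <- readLines(f)
  expect_match(raw[2], ",,", fixed = TRUE)   # missing cells are empty
})

test_that("metadata reader enforces the three group labels and keeps NA", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,updrs3,stap,aftap,nqi,visit_index",
               "A,control,1,170,,0.05,1",
               "B,de_novo_pd,20,165,95,0.12,1"), f)
  md <- read_subject_metadata(f)
  expect_true(is.na(md$aftap[1]))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group", "A,parkinsons"), f2)
  expect_error(read_subject_metadata(f2), "unknown group label")
})

test_that("the nqmitcsxpd dialect adapter reads a per-subject directory", {
  dialect <- read_dialect(system.file("extdata", "nqmitcsxpd.yaml",
                                      package = "keyfluc"))
  expect_equal(dialect$time_unit, "ms")
  d <- withr::local_tempdir()
  writeLines(c("Key,Press,Release", "a,0,100", "B,500,650", "c,600,800"),
             file.path(d, "1001_1.csv"))
  writeLines(c("Key,Press,Release", "x,0,90", "y,400,520"),
             file.path(d, "1002_1.csv"))
  ev <- read_keystroke_dir(d, dialect)
  expect_setequal(unique(ev$subject_id), c("1001", "1002"))
  expect_equal(ev$release_time[ev$subject_id == "1001"][1], 0.1)
  expect_equal(ev$key_id[2], "b")            # keys are lower-cased
})
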