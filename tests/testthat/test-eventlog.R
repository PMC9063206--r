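# Event-log conversion: the per-admission event emission rules with their
# millisecond offsets, artificial-event abstraction, and the XES round
# trip.

MS <- 1e-3

log_events_for <- function(log, case = 1) {
  ev <- log$events[log$events$case_id == case, ]
  rownames(ev) <- NULL
  ev
}

test_that("admission, insurance and discharge events carry the stated offsets", {
  tabs <- tiny_member_tables()
  m <- select_cohort(tabs)
  log <- build_event_log(tabs, m)
  ev <- log_events_for(log)
  adm <- tabs$admissions
  for (h in c(101, 102)) {
    a <- adm[adm$HADM_ID == h, ]
    i <- which(ev$name == paste0("Admission_", a$ADMISSION_TYPE) &
               ev$timestamp == a$ADMITTIME)
    expect_length(i, 1L)
    expect_equal(ev$name[i + 1L], paste0("Insurance_", a$INSURANCE))
    expect_equal(ev$timestamp[i + 1L], a$ADMITTIME + MS)
    expect_true(any(ev$name == "Discharge" & ev$timestamp == a$DISCHTIME))
  }
  # exactly one admission-type, insurance and discharge event per admission
  expect_equal(sum(startsWith(ev$name, "Admission_")), 2L)
  expect_equal(sum(startsWith(ev$name, "Insurance_")), 2L)
  expect_equal(sum(ev$name == "Discharge"), 2L)
  # the TSS marker sits on the index admission's discharge
  expect_equal(ev$name[log$cases$tss_index], "Discharge")
  expect_equal(ev$timestamp[log$cases$tss_index],
               adm$DISCHTIME[adm$HADM_ID == 102])
})

test_that("lab events: single measurement puts std 1 ms after mean; repeated puts std at the last time", {
  t1 <- T0 + 40 * DAY + 3600          # inside index admission 102
  labs1 <- data.frame(HADM_ID = 102, ITEMID = 50001, CHARTTIME = t1,
                      VALUENUM = 30)
  tabs <- tiny_member_tables(labevents = labs1)
  ev <- log_events_for(build_event_log(tabs, select_cohort(tabs)))
  expect_equal(ev$timestamp[ev$name == "BUN_mean"], t1)
  expect_equal(ev$timestamp[ev$name == "BUN_std"], t1 + MS)

  t2 <- t1 + c(0, 7200, 90000)
  labs2 <- data.frame(HADM_ID = 102, ITEMID = 50003, CHARTTIME = t2,
                      VALUENUM = c(138, 140, 139))
  tabs2 <- tiny_member_tables(labevents = labs2)
  ev2 <- log_events_for(build_event_log(tabs2, select_cohort(tabs2)))
  expect_equal(ev2$timestamp[ev2$name == "Sodium_mean"], t2[1])
  expect_equal(ev2$timestamp[ev2$name == "Sodium_std"], t2[3])
})

test_that("comorbidity events sit just before discharge with +1 ms steps, in canonical order", {
  # three groups in the index admission: CHF, DMcx (2504), Hypothyroid (2409)
  tabs <- tiny_member_tables(index_codes = c("4280", "2504", "2409"))
  m <- select_cohort(tabs)
  ev <- log_events_for(build_event_log(tabs, m))
  D <- tabs$admissions$DISCHTIME[tabs$admissions$HADM_ID == 102]
  ce <- ev[startsWith(ev$name, "Elix_") & ev$timestamp > T0 + 40 * DAY, ]
  expect_equal(nrow(ce), 3L)
  expect_equal(ce$timestamp, c(D - 3 * MS, D - 2 * MS, D - MS))
  # canonical group order: CHF (1) < DiabetesComplicated (12) < Hypothyroidism (13)
  expect_equal(ce$name, paste0("Elix_", c("CongestiveHeartFailure",
                                          "DiabetesComplicated",
                                          "Hypothyroidism")))
  # all strictly before the discharge event
  expect_true(all(ce$timestamp < D))
})

test_that("comorbidity offsets stay strictly ordered for any group count", {
  emap <- read.csv(system.file("extdata", "elixhauser_quan_icd9.csv",
                               package = "dreamHF"))
  reps <- emap$icd9_prefix[!duplicated(emap$group)][1:20]
  tabs <- tiny_member_tables(index_codes = c("4280", reps))
  ev <- log_events_for(build_event_log(tabs, select_cohort(tabs)))
  ce <- ev[startsWith(ev$name, "Elix_"), ]
  D <- tabs$admissions$DISCHTIME[tabs$admissions$HADM_ID == 102]
  expect_true(all(diff(ev$timestamp) > 0))
  expect_true(all(ce$timestamp < D))
})

test_that("artificial events: one per admission with codes, anchored and clipped before discharge", {
  pr <- data.frame(HADM_ID = c(102, 102), SEQ_NUM = 1:2,
                   ICD9_CODE = c("3961", "3615"))
  tabs <- tiny_member_tables(procedures = pr)
  m <- select_cohort(tabs)
  art <- suppressWarnings(fit_artificial_events(tabs, m, k = 2, seed = 1))
  ev <- log_events_for(build_event_log(tabs, m, art))
  ae <- ev[startsWith(ev$name, "Artificial_"), ]
  expect_equal(nrow(ae), 1L)   # only admission 102 has codes
  admit <- tabs$admissions$ADMITTIME[tabs$admissions$HADM_ID == 102]
  # anchor: procedures observed at admission; +1 ms, bumped past insurance
  expect_equal(ae$timestamp, admit + 2 * MS)

  # identical code sequences receive the same artificial event name
  seqs <- list(c("A", "B"), c("A", "B"), c("C"))
  cl <- dreamHF:::predict_artificial_clusters(art, seqs)
  expect_equal(cl[1], cl[2])
  # empty sequence yields no artificial event
  expect_true(is.na(dreamHF:::predict_artificial_clusters(art, list(character(0)))))
})

test_that("artificial vocabulary is capped at k names corpus-wide", {
  sp <- small_pipeline()
  log <- build_event_log(sp$tables, sp$split$train, sp$art)
  art_names <- unique(grep("^Artificial_", log$events$name, value = TRUE))
  expect_lte(length(art_names), 30L)
  expect_gt(length(art_names), 1L)
})

test_that("fewer distinct sequences than k reduces k with a warning", {
  pr <- data.frame(HADM_ID = c(101, 102), SEQ_NUM = c(1, 1),
                   ICD9_CODE = c("3961", "3961"))
  tabs <- tiny_member_tables(procedures = pr)
  m <- select_cohort(tabs)
  expect_warning(art <- fit_artificial_events(tabs, m, k = 5, seed = 1),
                 "reduced")
  expect_lt(art$k, 5)
})

test_that("conversion is a pure function of its inputs", {
  sp <- small_pipeline()
  l1 <- build_event_log(sp$tables, sp$split$train, sp$art)
  l2 <- build_event_log(sp$tables, sp$split$train, sp$art)
  expect_identical(l1, l2)
})

test_that("within-trace timestamps are strictly increasing", {
  sp <- small_pipeline()
  log <- build_event_log(sp$tables, sp$split$validation, sp$art)
  d <- ave(log$events$timestamp, log$events$case_id, FUN = function(t)
    c(1, diff(t)))
  expect_true(all(d > 0))
})

test_that("XES round trip preserves names, millisecond timestamps and labels", {
  sp <- small_pipeline()
  log <- build_event_log(sp$tables, sp$split$validation, sp$art)
  f <- withr::local_tempfile(fileext = ".xes")
  write_xes(log, f)
  back <- read_xes(f)
  expect_equal(back$events$name, log$events$name)
  expect_equal(round(back$events$timestamp * 1000),
               round(log$events$timestamp * 1000))
  expect_identical(back$cases$label, log$cases$label)
  expect_identical(back$cases$tss_index, log$cases$tss_index)

  # writer refuses unordered traces
  bad <- log
  bad$events$timestamp[2] <- bad$events$timestamp[1] - 1
  expect_error(write_xes(bad, f), class = "dreamHF_invariant_error")
  # malformed XML is a format error
  writeLines("<log><trace></log>", f)
  expect_error(read_xes(f), class = "dreamHF_format_error")
})
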