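anchor <- as.Date("2006-11-08")

test_that("absolute expressions normalize independently of the anchor", {
  cases <- list(
    list("2006-11-08", "2006-11-08"),
    list("29 Aug 2008", "2008-08-29"),
    list("29th August 2008", "2008-08-29"),
    list("Aug 29, 2008", "2008-08-29"),
    list("15/8/2009", "2009-08-15"),
    list("2009/8/15", "2009-08-15")
  )
  for (case in cases) {
    for (a in c("2006-11-08", "1999-01-01")) {
      tp <- normalize_date(case[[1]], anchor = a)
      expect_s3_class(tp, "time_point")
      expect_identical(format(tp), case[[2]])
    }
  }
})

test_that("ambiguous numeric dates parse day-first by default, month-first on request", {
  expect_identical(format(normalize_date("3/4/2006", anchor)), "2006-04-03")
  expect_identical(format(normalize_date("3/4/2006", anchor, month_first = TRUE)),
                   "2006-03-04")
  expect_error(normalize_date("15/8/2009", anchor, month_first = TRUE),
               class = "spatzone_normalization_error")
})

test_that("relative day expressions resolve against the anchor", {
  expect_identical(format(normalize_date("yesterday", anchor)), "2006-11-07")
  expect_identical(format(normalize_date("today", anchor)), "2006-11-08")
  expect_identical(format(normalize_date("tomorrow", anchor)), "2006-11-09")
  expect_identical(format(normalize_date("3 days ago", anchor)), "2006-11-05")
  # 2006-11-08 is a Wednesday
  expect_identical(format(normalize_date("last Tuesday", anchor)), "2006-11-07")
  expect_identical(format(normalize_date("last Wednesday", anchor)), "2006-11-01")
  expect_identical(format(normalize_date("next Monday", anchor)), "2006-11-13")
})

test_that("coarse expressions return day-granular periods", {
  p <- normalize_date("October 2006", anchor)
  expect_s3_class(p, "date_period")
  expect_identical(format(p), "2006-10-01..2006-10-31")
  expect_identical(format(normalize_date("last week of October 2006", anchor)),
                   "2006-10-25..2006-10-31")
  expect_identical(format(normalize_date("this week", anchor)),
                   "2006-11-06..2006-11-12")
  expect_identical(format(normalize_date("last week", anchor)),
                   "2006-10-30..2006-11-05")
  expect_identical(format(normalize_date("last month", anchor)),
                   "2006-10-01..2006-10-31")
  expect_identical(format(normalize_date("next year", anchor)),
                   "2007-01-01..2007-12-31")
  expect_identical(format(normalize_date("February", as.Date("2008-11-01"))),
                   "2008-02-01..2008-02-29")
})

test_that("unparseable expressions raise a normalization error carrying the surface", {
  err <- tryCatch(normalize_date("the other day", anchor), condition = identity)
  expect_s3_class(err, "spatzone_normalization_error")
  expect_match(conditionMessage(err), "the other day", fixed = TRUE)
  expect_error(normalize_date("32 Aug 2008", anchor),
               class = "spatzone_normalization_error")
})

test_that("normalize_date is idempotent on its own absolute outputs", {
  for (expr in c("29 Aug 2008", "yesterday", "3 days ago", "last Tuesday")) {
    once <- normalize_date(expr, anchor)
    again <- normalize_date(format(once), anchor = anchor + 500)
    expect_identical(format(again), format(once))
  }
})

test_that("day-offset expressions are translation-equivariant in the anchor", {
  for (expr in c("today", "yesterday", "tomorrow", "5 days ago")) {
    base <- normalize_date(expr, anchor)$date
    for (d in c(-30L, 1L, 365L)) {
      shifted <- normalize_date(expr, anchor + d)$date
      expect_identical(as.integer(shifted - base), d)
    }
  }
})

test_that("the 13 TimeML relations collapse onto exactly 3 direction classes", {
  rels <- c("simultaneous", "including", "being included", "during",
            "being held during", "beginning", "begun by", "ending", "end by",
            "before", "immediately before", "after", "immediately after")
  expect_length(rels, 13L)
  mapped <- map_timeml_relation(rels)
  expect_setequal(unique(mapped), temporal_directions())
  expect_identical(map_timeml_relation("simultaneous"), "AS_OF")
  expect_identical(map_timeml_relation("immediately before"), "BEFORE")
  expect_identical(map_timeml_relation("after"), "AFTER")
  expect_error(map_timeml_relation("overlaps"), class = "spatzone_vocabulary_error")
})

test_that("anchor resolution follows the direct-speech rule", {
  doc <- make_flat_doc(list(
    c(list(event_type = "Event_Report", anchor_val = "2006-11-24",
           val = "PAST_REF", stime = time_point(date = "2006-11-20"),
           etime = time_point(date = "2006-11-20"),
           stime_dir = "AS_OF", etime_dir = "AS_OF")),
    normal_attrs(anchor = "2006-11-20", stime = "2006-11-01", etime = "2006-11-19")
  ), pub = "2006-11-24")
  doc$event_predicates[[2]]$in_direct_speech_of <- "e1"

  expect_identical(resolve_anchor(doc$event_predicates[[1]], doc),
                   as.Date("2006-11-24"))
  expect_identical(resolve_anchor(doc$event_predicates[[2]], doc),
                   as.Date("2006-11-20"))

  dangling <- doc$event_predicates[[2]]
  dangling$in_direct_speech_of <- "nope"
  expect_error(resolve_anchor(dangling, doc), class = "spatzone_link_error")

  # symbolic reporting time falls back to the document date with a warning
  doc$event_predicates[[1]]$stime <- time_point(symbol = "PAST")
  doc$event_predicates[[1]]$etime <- time_point(symbol = "PAST")
  expect_warning(res <- resolve_anchor(doc$event_predicates[[2]], doc),
                 "no absolute time")
  expect_identical(res, as.Date("2006-11-24"))
})

test_that("temporal consistency checking flags contradictions only", {
  consistent <- do.call(event_predicate, c(
    list(id = "x", span = c(0L, 4L)),
    normal_attrs(loc = character(), stime = "2006-11-01", etime = "2006-11-20")))
  expect_identical(check_temporal_consistency(consistent), character(0))

  contradiction <- consistent
  contradiction$val <- "FUTURE_REF"
  expect_match(check_temporal_consistency(contradiction), "FUTURE_REF", all = FALSE)

  # ongoing-event pattern: started in the past, continues at speech time
  ongoing <- consistent
  ongoing$val <- "PRESENT_REF"
  ongoing$stime <- time_point(symbol = "PAST")
  ongoing$etime <- time_point(symbol = "PRESENT")
  expect_identical(check_temporal_consistency(ongoing), character(0))

  inverted <- consistent
  inverted$stime <- time_point(date = "2006-11-21")
  expect_match(check_temporal_consistency(inverted), "stime is after", all = FALSE)

  info <- event_predicate("y", c(0L, 4L), "Event_Info")
  expect_error(check_temporal_consistency(info), class = "spatzone_domain_error")
})
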