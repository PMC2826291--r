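# Temporal-expression normalization and anchor resolution.
#
# All output is at day granularity: single days become absolute time_points,
# coarser spans (a named month, "last week") become date_periods covering the
# span's first and last day. Month and weekday names are resolved through
# fixed English tables rather than the C library locale.

MONTH_NAMES <- c(january = 1, february = 2, march = 3, april = 4, may = 5,
                 june = 6, july = 7, august = 8, september = 9, october = 10,
                 november = 11, december = 12,
                 jan = 1, feb = 2, mar = 3, apr = 4, jun = 6, jul = 7,
                 aug = 8, sep = 9, sept = 9, oct = 10, nov = 11, dec = 12)

WEEKDAY_NAMES <- c(monday = 1, tuesday = 2, wednesday = 3, thursday = 4,
                   friday = 5, saturday = 6, sunday = 7,
                   mon = 1, tue = 2, tues = 2, wed = 3, thu = 4, thur = 4,
                   thurs = 4, fri = 5, sat = 6, sun = 7)

normalization_error <- function(surface) {
  spatzone_error(sprintf("cannot normalize temporal expression \"%s\"", surface),
                 "spatzone_normalization_error")
}

make_date <- function(y, m, d, surface) {
  out <- tryCatch(as.Date(sprintf("%04d-%02d-%02d", y, m, d)),
                  error = function(e) NA)
  if (length(out) != 1L || is.na(out)) normalization_error(surface)
  out
}

month_bounds <- function(y, m) {
  first <- make_date(y, m, 1, sprintf("%04d-%02d", y, m))
  nxt <- if (m == 12) make_date(y + 1, 1, 1, "") else make_date(y, m + 1, 1, "")
  c(first, nxt - 1)
}

expand_year <- function(y) {
  y <- as.integer(y)
  if (y >= 100) y else if (y <= 68) 2000L + y else 1900L + y
}

iso_dow <- function(d) as.integer(format(d, "%u")) # 1 = Monday

#' Normalize a temporal expression to day granularity
#'
#' Parses absolute expressions (`"2006-11-08"`, `"29 Aug 2008"`,
#' `"15/8/2009"`) independently of the anchor and resolves relative
#' expressions (`"yesterday"`, `"last Tuesday"`, `"3 days ago"`,
#' `"next week"`) against it. Expressions denoting spans coarser than a day
#' (a named month, `"last week of October 2006"`) return a [date_period()]
#' covering the span's first and last day; single days return an absolute
#' [time_point()].
#'
#' The supported relative vocabulary is a fixed grammar: `today`,
#' `yesterday`, `tomorrow`, `last/next <weekday>`, `last/this/next
#' week|month|year`, `<n> days ago`, a named month with optional year, and
#' `last week of <month> [<year>]`. `last <weekday>` is the most recent
#' strictly earlier such weekday; weeks are ISO Monday-Sunday weeks; `last
#' week of <month>` is the month's final seven days. Anything outside the
#' grammar raises a normalization error carrying the surface string.
#'
#' @param expr the expression: a character string, or a list with a
#'   `surface` element (a temporal-expression record).
#' @param anchor the reference date relative expressions resolve against.
#' @param month_first parse ambiguous numeric dates (`"9/8/2009"`) as
#'   month/day/year instead of the day-first default.
#' @return a [time_point()] (absolute) or a [date_period()].
#' @examples
#' normalize_date("29 Aug 2008", anchor = "2006-11-08")
#' normalize_date("yesterday", anchor = "2006-11-08")
#' normalize_date("last week of October 2006", anchor = "2006-11-08")
#' @export
normalize_date <- function(expr, anchor, month_first = FALSE) {
  surface <- if (is.list(expr)) expr$surface else expr
  if (!is.character(surface) || length(surface) != 1L || !nzchar(trimws(surface)))
    normalization_error(paste(surface, collapse = " "))
  anchor <- as.Date(anchor)
  if (length(anchor) != 1L || is.na(anchor))
    spatzone_error("normalize_date: invalid anchor date", "spatzone_type_error")
  s <- tolower(trimws(gsub("\\s+", " ", surface)))

  # ISO 8601
  if (grepl("^\\d{4}-\\d{1,2}-\\d{1,2}$", s)) {
    p <- as.integer(strsplit(s, "-")[[1]])
    return(time_point(date = make_date(p[1], p[2], p[3], surface)))
  }
  # numeric y/m/d or d/m/y (m/d/y with month_first)
  if (grepl("^\\d{1,4}[/.]\\d{1,2}[/.]\\d{2,4}$", s)) {
    p <- strsplit(s, "[/.]")[[1]]
    if (nchar(p[1]) == 4L) {
      return(time_point(date = make_date(as.integer(p[1]), as.integer(p[2]),
                                         as.integer(p[3]), surface)))
    }
    y <- expand_year(p[3])
    d <- as.integer(p[if (month_first) 2 else 1])
    m <- as.integer(p[if (month_first) 1 else 2])
    if (m < 1 || m > 12) normalization_error(surface)
    return(time_point(date = make_date(y, m, d, surface)))
  }
  # "29 aug 2008", "29th august 2008"
  m1 <- regmatches(s, regexec("^(\\d{1,2})(?:st|nd|rd|th)? ([a-z]+),? (\\d{4})$", s))[[1]]
  if (length(m1) && !is.na(MONTH_NAMES[m1[3]])) {
    return(time_point(date = make_date(as.integer(m1[4]), MONTH_NAMES[[m1[3]]],
                                       as.integer(m1[2]), surface)))
  }
  # "aug 29, 2008"
  m2 <- regmatches(s, regexec("^([a-z]+) (\\d{1,2})(?:st|nd|rd|th)?,? (\\d{4})$", s))[[1]]
  if (length(m2) && !is.na(MONTH_NAMES[m2[2]])) {
    return(time_point(date = make_date(as.integer(m2[4]), MONTH_NAMES[[m2[2]]],
                                       as.integer(m2[3]), surface)))
  }
  # day offsets
  if (s == "today") return(time_point(date = anchor))
  if (s == "yesterday") return(time_point(date = anchor - 1))
  if (s == "tomorrow") return(time_point(date = anchor + 1))
  m3 <- regmatches(s, regexec("^(\\d+) days? ago$", s))[[1]]
  if (length(m3)) return(time_point(date = anchor - as.integer(m3[2])))
  # last/next <weekday>
  m4 <- regmatches(s, regexec("^(last|next) ([a-z]+)$", s))[[1]]
  if (length(m4) && !is.na(WEEKDAY_NAMES[m4[3]])) {
    target <- WEEKDAY_NAMES[[m4[3]]]
    cur <- iso_dow(anchor)
    if (m4[2] == "last") {
      back <- (cur - target) %% 7L
      if (back == 0L) back <- 7L
      return(time_point(date = anchor - back))
    }
    fwd <- (target - cur) %% 7L
    if (fwd == 0L) fwd <- 7L
    return(time_point(date = anchor + fwd))
  }
  # last/this/next week|month|year
  m5 <- regmatches(s, regexec("^(last|this|next) (week|month|year)$", s))[[1]]
  if (length(m5)) {
    shift <- c(last = -1L, this = 0L, next. = 1L)[[sub("next", "next.", m5[2])]]
    if (m5[3] == "week") {
      monday <- anchor - (iso_dow(anchor) - 1L) + 7L * shift
      return(date_period(monday, monday + 6L))
    }
    y <- as.integer(format(anchor, "%Y"))
    if (m5[3] == "year") return(date_period(make_date(y + shift, 1, 1, surface),
                                            make_date(y + shift, 12, 31, surface)))
    m <- as.integer(format(anchor, "%m")) + shift
    if (m == 0L) { m <- 12L; y <- y - 1L } else if (m == 13L) { m <- 1L; y <- y + 1L }
    b <- month_bounds(y, m)
    return(date_period(b[1], b[2]))
  }
  # "last week of <month> [<year>]"
  m6 <- regmatches(s, regexec("^last week of ([a-z]+)( \\d{4})?$", s))[[1]]
  if (length(m6) && !is.na(MONTH_NAMES[m6[2]])) {
    y <- if (nzchar(m6[3])) as.integer(trimws(m6[3])) else as.integer(format(anchor, "%Y"))
    b <- month_bounds(y, MONTH_NAMES[[m6[2]]])
    return(date_period(b[2] - 6L, b[2]))
  }
  # named month, optional year
  m7 <- regmatches(s, regexec("^([a-z]+)( \\d{4})?$", s))[[1]]
  if (length(m7) && !is.na(MONTH_NAMES[m7[2]])) {
    y <- if (nzchar(m7[3])) as.integer(trimws(m7[3])) else as.integer(format(anchor, "%Y"))
    b <- month_bounds(y, MONTH_NAMES[[m7[2]]])
    return(date_period(b[1], b[2]))
  }
  normalization_error(surface)
}

#' Resolve the temporal anchor of an event-predicate
#'
#' The default anchor is the document's publication date. For a predicate
#' inside direct speech, the timing of quoted material is interpreted
#' relative to the time of speaking, so the occurrence date of the governing
#' Reporting event-predicate (its absolute `stime`, or failing that its
#' absolute `etime`) is used instead. A governing Reporting predicate with
#' only symbolic time falls back to the document date with a warning; a
#' dangling reference raises a link error.
#'
#' @param ep an [event_predicate()].
#' @param doc the containing [annotated_document()].
#' @return a calendar date.
#' @export
resolve_anchor <- function(ep, doc) {
  ref <- ep$in_direct_speech_of
  if (is.null(ref) || is.na(ref)) return(doc$publication_date)
  gov <- find_predicate(doc, ref)
  if (is.null(gov))
    spatzone_error(sprintf("%s: dangling in_direct_speech_of reference \"%s\"", ep$id, ref),
                   "spatzone_link_error")
  occ <- NULL
  if (!is.null(gov$stime) && gov$stime$kind == "absolute") occ <- gov$stime$date
  else if (!is.null(gov$etime) && gov$etime$kind == "absolute") occ <- gov$etime$date
  if (is.null(occ)) {
    warning(sprintf("%s: governing Reporting event-predicate \"%s\" has no absolute time; anchoring to document date",
                    ep$id, ref), call. = FALSE)
    return(doc$publication_date)
  }
  occ
}

TIMEML_RELATION_MAP <- c(
  "simultaneous" = "AS_OF", "including" = "AS_OF", "being included" = "AS_OF",
  "during" = "AS_OF", "being held during" = "AS_OF", "beginning" = "AS_OF",
  "begun by" = "AS_OF", "ending" = "AS_OF", "end by" = "AS_OF",
  "before" = "BEFORE", "immediately before" = "BEFORE",
  "after" = "AFTER", "immediately after" = "AFTER"
)

#' Collapse a TimeML temporal relation onto the three direction classes
#'
#' The thirteen fine-grained TimeML event-time relations are grouped into
#' three classes: the overlap-like relations (simultaneous, including, being
#' included, during, being held during, beginning, begun by, ending, end by)
#' map to `AS_OF`; before and immediately before map to `BEFORE`; after and
#' immediately after map to `AFTER`.
#'
#' @param relation character vector of TimeML relation names
#'   (case-insensitive).
#' @return character vector of direction classes; an unknown name raises a
#'   vocabulary error.
#' @examples
#' map_timeml_relation("simultaneous")
#' map_timeml_relation(c("before", "immediately after"))
#' @export
map_timeml_relation <- function(relation) {
  key <- tolower(trimws(relation))
  out <- TIMEML_RELATION_MAP[key]
  if (anyNA(out))
    spatzone_error(sprintf("unknown TimeML relation name(s): %s",
                           paste(unique(relation[is.na(out)]), collapse = ", ")),
                   "spatzone_vocabulary_error")
  unname(out)
}

tp_sign <- function(tp, anchor) {
  if (is.null(tp)) return(NA_integer_)
  if (tp$kind == "symbolic")
    return(c(PAST = -1L, PRESENT = 0L, FUTURE = 1L)[[tp$symbol]])
  as.integer(sign(as.numeric(tp$date - anchor)))
}

#' Check an event-predicate's temporal attributes for internal consistency
#'
#' Flags contradictions between the `val` relation and the start/end times,
#' using the sign of each time point relative to the anchor (symbolic
#' `PAST`/`PRESENT`/`FUTURE` count as -/0/+): `PAST_REF` with a start or end
#' strictly after the anchor, `FUTURE_REF` with a start or end strictly
#' before it, `PRESENT_REF` with an end before or a start after the anchor,
#' and an absolute start later than an absolute end. Warnings are returned
#' as data; nothing is mutated.
#'
#' @param ep a temporally locatable [event_predicate()] with `anchor_val`.
#' @return character vector of warnings (empty when consistent).
#' @export
check_temporal_consistency <- function(ep) {
  if (!is_locatable_type(ep$event_type) || is.null(ep$anchor_val))
    spatzone_error(sprintf("%s: temporal consistency check requires a temporally locatable predicate with anchor_val",
                           ep$id), "spatzone_domain_error")
  w <- character()
  ss <- tp_sign(ep$stime, ep$anchor_val)
  es <- tp_sign(ep$etime, ep$anchor_val)
  if (!is.null(ep$val)) {
    if (ep$val == "PAST_REF" && (isTRUE(ss > 0L) || isTRUE(es > 0L)))
      w <- c(w, sprintf("%s: val=PAST_REF but stime/etime lies after anchor_val", ep$id))
    if (ep$val == "FUTURE_REF" && (isTRUE(ss < 0L) || isTRUE(es < 0L)))
      w <- c(w, sprintf("%s: val=FUTURE_REF but stime/etime lies before anchor_val", ep$id))
    if (ep$val == "PRESENT_REF" && (isTRUE(es < 0L) || isTRUE(ss > 0L)))
      w <- c(w, sprintf("%s: val=PRESENT_REF but occurrence period excludes anchor_val", ep$id))
  }
  if (!is.null(ep$stime) && !is.null(ep$etime) &&
      ep$stime$kind == "absolute" && ep$etime$kind == "absolute" &&
      ep$stime$date > ep$etime$date)
    w <- c(w, sprintf("%s: absolute stime is after absolute etime", ep$id))
  w
}
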