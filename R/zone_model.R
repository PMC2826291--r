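# Domain types for the spatiotemporal zoning annotation scheme.
#
# An event-predicate is a clause-level linguistic unit (verb, predicative
# adjective or prepositional phrase) denoting a single event. Each carries an
# event class, day-granularity temporal attributes (for temporally locatable
# classes) and a set of location surface strings. Character spans are 0-based,
# half-open intervals over the raw document text.

EVENT_TYPES <- c("Event_Normal", "Event_Report", "Event_Hypothetical", "Event_Info")
LOCATABLE_TYPES <- c("Event_Normal", "Event_Report")
NONLOCATABLE_TYPES <- c("Event_Hypothetical", "Event_Info")
TEMPORAL_DIRECTIONS <- c("AS_OF", "BEFORE", "AFTER")
RELATIVE_VALS <- c("PRESENT_REF", "PAST_REF", "FUTURE_REF")
TIME_SYMBOLS <- c("PAST", "PRESENT", "FUTURE")
TEMPORAL_FIELDS <- c("anchor_val", "val", "stime", "etime", "stime_dir", "etime_dir")

#' Controlled vocabularies of the zoning scheme
#'
#' The scheme admits exactly four event classes: `Event_Normal` and
#' `Event_Report` are temporally locatable (happened, ongoing, or will
#' definitely happen; Reporting events are communicative events such as
#' "said" that re-anchor quoted material), while `Event_Hypothetical`
#' (possible-world events) and `Event_Info` (generic knowledge, requests,
#' copular descriptions) cannot be placed on a timeline and carry no
#' temporal attributes.
#'
#' @return `event_types()` the four event-class labels;
#'   `temporal_directions()` the three collapsed temporal-relation classes
#'   (`AS_OF`, `BEFORE`, `AFTER`); `relative_vals()` the three reference-time
#'   relations (`PRESENT_REF`, `PAST_REF`, `FUTURE_REF`); `time_symbols()`
#'   the symbolic time values (`PAST`, `PRESENT`, `FUTURE`) usable where no
#'   explicit date is available.
#' @export
event_types <- function() EVENT_TYPES

#' @rdname event_types
#' @export
temporal_directions <- function() TEMPORAL_DIRECTIONS

#' @rdname event_types
#' @export
relative_vals <- function() RELATIVE_VALS

#' @rdname event_types
#' @export
time_symbols <- function() TIME_SYMBOLS

#' Is an event class temporally locatable?
#'
#' @param event_type character vector of event-class labels.
#' @return logical vector; `TRUE` for `Event_Normal`/`Event_Report`.
#' @export
is_locatable_type <- function(event_type) event_type %in% LOCATABLE_TYPES

spatzone_error <- function(msg, class, call. = FALSE) {
  stop(structure(class = c(class, "spatzone_error", "error", "condition"),
                 list(message = msg, call = if (call.) sys.call(-1))))
}

#' A time point at day granularity
#'
#' A time point is either an absolute calendar date (day resolution; no finer
#' granularity is representable) or one of the symbolic values `PAST`,
#' `PRESENT`, `FUTURE`, interpreted relative to the predicate's anchor date.
#' Exactly one of `date`/`symbol` must be given.
#'
#' @param date a calendar date (coerced with [as.Date()]), or `NULL`.
#' @param symbol one of `"PAST"`, `"PRESENT"`, `"FUTURE"`, or `NULL`.
#' @return an object of class `time_point` with fields `kind`
#'   (`"absolute"` or `"symbolic"`), and `date` or `symbol`.
#' @examples
#' time_point(date = "2006-11-08")
#' time_point(symbol = "PAST")
#' @export
time_point <- function(date = NULL, symbol = NULL) {
  if (is.null(date) == is.null(symbol))
    spatzone_error("time_point: exactly one of `date`/`symbol` must be given",
                   "spatzone_type_error")
  if (!is.null(date)) {
    d <- as.Date(date)
    if (length(d) != 1L || is.na(d))
      spatzone_error("time_point: `date` is not a valid calendar date",
                     "spatzone_type_error")
    out <- list(kind = "absolute", date = d, symbol = NULL)
  } else {
    if (!is.character(symbol) || length(symbol) != 1L || !symbol %in% TIME_SYMBOLS)
      spatzone_error(sprintf("time_point: `symbol` must be one of {%s}",
                             paste(TIME_SYMBOLS, collapse = ", ")),
                     "spatzone_type_error")
    out <- list(kind = "symbolic", date = NULL, symbol = symbol)
  }
  structure(out, class = "time_point")
}

#' @export
format.time_point <- function(x, ...) {
  if (x$kind == "absolute") format(x$date, "%Y-%m-%d") else x$symbol
}

#' @export
print.time_point <- function(x, ...) {
  cat("<time_point ", format(x), ">\n", sep = "")
  invisible(x)
}

is_time_point <- function(x) inherits(x, "time_point")

#' Compare two time points (or NULLs) for equality
#'
#' Absent values (`NULL`) compare equal to each other; a symbolic value never
#' equals an absolute date, even when the date coincides with the anchor.
#'
#' @param a,b `time_point` objects or `NULL`.
#' @return logical scalar.
#' @export
time_points_equal <- function(a, b) {
  if (is.null(a) && is.null(b)) return(TRUE)
  if (is.null(a) || is.null(b)) return(FALSE)
  if (a$kind != b$kind) return(FALSE)
  if (a$kind == "absolute") a$date == b$date else a$symbol == b$symbol
}

#' A calendar-day period
#'
#' Coarse temporal expressions (a named month, "last week of October 2006")
#' normalize to a start/end day pair rather than a single day.
#'
#' @param start,end calendar dates (coerced with [as.Date()]); `start <= end`.
#' @return object of class `date_period` with fields `start`, `end`.
#' @export
date_period <- function(start, end) {
  s <- as.Date(start); e <- as.Date(end)
  if (length(s) != 1L || length(e) != 1L || is.na(s) || is.na(e))
    spatzone_error("date_period: invalid calendar date", "spatzone_type_error")
  if (s > e)
    spatzone_error("date_period: start must not be after end", "spatzone_type_error")
  structure(list(start = s, end = e), class = "date_period")
}

#' @export
format.date_period <- function(x, ...) {
  paste0(format(x$start, "%Y-%m-%d"), "..", format(x$end, "%Y-%m-%d"))
}

#' @export
print.date_period <- function(x, ...) {
  cat("<date_period ", format(x), ">\n", sep = "")
  invisible(x)
}

check_span <- function(span, what = "span") {
  if (!is.numeric(span) || length(span) != 2L || anyNA(span) || span[1] > span[2])
    spatzone_error(sprintf("%s must be a numeric (start, end) pair with start <= end", what),
                   "spatzone_structural_error")
  as.integer(span)
}

#' Construct an event-predicate
#'
#' Enum-valued fields are stored as given; conformance to the controlled
#' vocabularies is checked by [validate_event_predicate()], which reports
#' violations as data rather than refusing to represent them (annotation
#' tools must be able to hold a malformed annotation in order to flag it).
#'
#' @param id unique identifier within the document.
#' @param span 0-based half-open character interval `c(start, end)`.
#' @param event_type one of [event_types()].
#' @param anchor_val reference date for temporal interpretation (the document
#'   date, or the governing Reporting event's date inside direct speech).
#' @param val relation of the event to the anchor date; see [relative_vals()].
#' @param stime,etime approximate start/end of the occurrence period, as
#'   [time_point()] objects (or `NULL`).
#' @param stime_dir,etime_dir collapsed temporal relation between the event
#'   and `stime`/`etime`; see [temporal_directions()].
#' @param locations character vector of location surface strings exactly as
#'   they appear in the document text (de-duplicated, document order kept).
#' @param in_direct_speech_of id of the governing Reporting event-predicate
#'   when this predicate sits inside quoted speech, else `NA`.
#' @return object of class `event_predicate`.
#' @export
event_predicate <- function(id, span, event_type,
                            anchor_val = NULL, val = NULL,
                            stime = NULL, etime = NULL,
                            stime_dir = NULL, etime_dir = NULL,
                            locations = character(),
                            in_direct_speech_of = NA_character_) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    spatzone_error("event_predicate: `id` must be a non-empty string",
                   "spatzone_structural_error")
  span <- check_span(span, "event_predicate span")
  if (span[1] == span[2])
    spatzone_error("event_predicate span must be non-empty",
                   "spatzone_structural_error")
  if (!is.null(anchor_val)) {
    anchor_val <- as.Date(anchor_val)
    if (length(anchor_val) != 1L || is.na(anchor_val))
      spatzone_error("event_predicate: `anchor_val` is not a valid date",
                     "spatzone_type_error")
  }
  structure(list(
    id = id, span = span, event_type = as.character(event_type),
    anchor_val = anchor_val,
    val = if (is.null(val)) NULL else as.character(val),
    stime = stime, etime = etime,
    stime_dir = if (is.null(stime_dir)) NULL else as.character(stime_dir),
    etime_dir = if (is.null(etime_dir)) NULL else as.character(etime_dir),
    locations = unique(as.character(locations)),
    in_direct_speech_of =
      if (is.null(in_direct_speech_of)) NA_character_ else as.character(in_direct_speech_of)
  ), class = "event_predicate")
}

#' @export
print.event_predicate <- function(x, ...) {
  cat(sprintf("<event_predicate %s [%d,%d) %s>\n", x$id, x$span[1], x$span[2], x$event_type))
  invisible(x)
}

#' Construct a zone
#'
#' A zone is a maximal run of consecutive event-predicates that share the
#' event class, the location set, and (for temporally locatable classes) all
#' six temporal attributes.
#'
#' @param zone_id identifier.
#' @param event_predicates non-empty character vector of member predicate ids,
#'   in traversal order.
#' @param span 0-based half-open character interval covered by the zone.
#' @param shared named list of the attributes shared by all members
#'   (`event_type`, and for locatable classes `anchor_val`, `val`, `stime`,
#'   `etime`, `stime_dir`, `etime_dir`, plus `locations`).
#' @return object of class `zone`.
#' @export
zone <- function(zone_id, event_predicates, span, shared) {
  if (length(event_predicates) < 1L)
    spatzone_error("zone: `event_predicates` must be non-empty",
                   "spatzone_structural_error")
  structure(list(zone_id = as.character(zone_id),
                 event_predicates = as.character(event_predicates),
                 span = check_span(span, "zone span"),
                 shared = shared),
            class = "zone")
}

#' @export
print.zone <- function(x, ...) {
  cat(sprintf("<zone %s [%d,%d) %s: %s>\n", x$zone_id, x$span[1], x$span[2],
              x$shared$event_type, paste(x$event_predicates, collapse = ", ")))
  invisible(x)
}

entity_frame <- function(x, what) {
  if (is.null(x)) x <- data.frame(start = integer(), end = integer(),
                                  surface = character())
  x <- as.data.frame(x)
  need <- c("start", "end", "surface")
  if (!all(need %in% names(x)))
    spatzone_error(sprintf("%s must have columns start, end, surface", what),
                   "spatzone_structural_error")
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  x$surface <- as.character(x$surface)
  x[need]
}

#' Construct an annotated document
#'
#' Holds the raw text together with the pre-marked elements an upstream
#' pipeline provides (location/temporal entity spans, clause boundaries),
#' the annotated event-predicates and, optionally, generated zones.
#'
#' @param doc_id document identifier.
#' @param publication_date the news report date (default temporal anchor).
#' @param text raw document text.
#' @param location_entities,temporal_entities data frames with columns
#'   `start`, `end`, `surface` (0-based half-open spans).
#' @param clause_units data frame with columns `start`, `end`; clauses may
#'   nest (a subordinate clause's span lies inside its matrix clause's span)
#'   and must be listed in document order of their starts.
#' @param event_predicates list of [event_predicate()] objects in document
#'   order.
#' @param zones optional list of [zone()] objects.
#' @return object of class `annotated_document`.
#' @export
annotated_document <- function(doc_id, publication_date, text,
                               location_entities = NULL,
                               temporal_entities = NULL,
                               clause_units = NULL,
                               event_predicates = list(),
                               zones = NULL) {
  pd <- as.Date(publication_date)
  if (length(pd) != 1L || is.na(pd))
    spatzone_error("annotated_document: invalid publication_date",
                   "spatzone_type_error")
  if (!is.character(text) || length(text) != 1L)
    spatzone_error("annotated_document: `text` must be a single string",
                   "spatzone_structural_error")
  if (is.null(clause_units))
    clause_units <- data.frame(start = integer(), end = integer())
  clause_units <- as.data.frame(clause_units)[c("start", "end")]
  clause_units$start <- as.integer(clause_units$start)
  clause_units$end <- as.integer(clause_units$end)
  structure(list(
    doc_id = as.character(doc_id),
    publication_date = pd,
    text = text,
    location_entities = entity_frame(location_entities, "location_entities"),
    temporal_entities = entity_frame(temporal_entities, "temporal_entities"),
    clause_units = clause_units,
    event_predicates = event_predicates,
    zones = zones
  ), class = "annotated_document")
}

#' @export
print.annotated_document <- function(x, ...) {
  cat(sprintf("<annotated_document %s (%s): %d chars, %d clauses, %d event-predicates%s>\n",
              x$doc_id, format(x$publication_date, "%Y-%m-%d"), nchar(x$text),
              nrow(x$clause_units), length(x$event_predicates),
              if (is.null(x$zones)) "" else sprintf(", %d zones", length(x$zones))))
  invisible(x)
}

find_predicate <- function(doc, id) {
  for (ep in doc$event_predicates) if (ep$id == id) return(ep)
  NULL
}

#' @keywords internal
location_set_key <- function(locations) paste(sort(unique(locations)), collapse = "\x1f")

null_safe_equal <- function(a, b) {
  if (is.null(a) && is.null(b)) return(TRUE)
  if (is.null(a) || is.null(b)) return(FALSE)
  isTRUE(a == b)
}

# Full attribute identity between two predicates: event class, location set,
# and (for locatable classes) all six temporal attributes. Empty location
# sets compare equal.
identical_attributes <- function(a, b) {
  if (!identical(a$event_type, b$event_type)) return(FALSE)
  if (location_set_key(a$locations) != location_set_key(b$locations)) return(FALSE)
  if (!is_locatable_type(a$event_type)) return(TRUE)
  null_safe_equal(a$anchor_val, b$anchor_val) &&
    null_safe_equal(a$val, b$val) &&
    time_points_equal(a$stime, b$stime) &&
    time_points_equal(a$etime, b$etime) &&
    null_safe_equal(a$stime_dir, b$stime_dir) &&
    null_safe_equal(a$etime_dir, b$etime_dir)
}

enum_violation <- function(field, value, allowed) {
  sprintf("%s: value not in {%s} (got \"%s\")",
          field, paste(allowed, collapse = ", "), value)
}

#' Validate a single event-predicate against the scheme
#'
#' Checks the class-dependent attribute constraints: non-locatable classes
#' (`Event_Info`, `Event_Hypothetical`) must carry no temporal attributes;
#' locatable classes must carry an anchor date; enum-valued fields must use
#' the controlled vocabularies; location strings must be non-empty and appear
#' verbatim in the document text. Violations are returned as data, not
#' raised; only a structurally impossible span (outside the document text)
#' raises an error.
#'
#' @param ep an [event_predicate()].
#' @param doc the [annotated_document()] the predicate belongs to.
#' @return character vector of violation messages (empty when compliant).
#' @export
validate_event_predicate <- function(ep, doc) {
  n <- nchar(doc$text)
  if (ep$span[1] < 0L || ep$span[2] > n)
    spatzone_error(sprintf("event-predicate %s: span [%d,%d) outside document text (%d chars)",
                           ep$id, ep$span[1], ep$span[2], n),
                   "spatzone_structural_error")
  v <- character()
  bad <- function(msg) v <<- c(v, sprintf("%s: %s", ep$id, msg))

  if (!ep$event_type %in% EVENT_TYPES)
    bad(enum_violation("event_type", ep$event_type, EVENT_TYPES))

  present <- vapply(TEMPORAL_FIELDS, function(f) !is.null(ep[[f]]), logical(1))
  if (ep$event_type %in% NONLOCATABLE_TYPES && any(present))
    bad(sprintf("temporal attribute on non-locatable class (%s set on %s)",
                paste(TEMPORAL_FIELDS[present], collapse = ", "), ep$event_type))
  if (ep$event_type %in% LOCATABLE_TYPES && is.null(ep$anchor_val))
    bad("anchor_val: required for temporally locatable classes")

  if (!is.null(ep$val) && !ep$val %in% RELATIVE_VALS)
    bad(enum_violation("val", ep$val, RELATIVE_VALS))
  if (!is.null(ep$stime_dir) && !ep$stime_dir %in% TEMPORAL_DIRECTIONS)
    bad(enum_violation("stime_dir", ep$stime_dir, TEMPORAL_DIRECTIONS))
  if (!is.null(ep$etime_dir) && !ep$etime_dir %in% TEMPORAL_DIRECTIONS)
    bad(enum_violation("etime_dir", ep$etime_dir, TEMPORAL_DIRECTIONS))
  if (!is.null(ep$stime) && !is_time_point(ep$stime))
    bad("stime: not a time_point")
  if (!is.null(ep$etime) && !is_time_point(ep$etime))
    bad("etime: not a time_point")

  for (loc in ep$locations) {
    if (!nzchar(loc)) {
      bad("locations: empty location string")
    } else if (!grepl(loc, doc$text, fixed = TRUE)) {
      bad(sprintf("locations: \"%s\" does not appear verbatim in document text", loc))
    }
  }
  v
}

#' Validate an annotated document
#'
#' Runs [validate_event_predicate()] on every predicate and adds
#' document-level checks: unique predicate ids, predicate spans contained in
#' a clause unit, clause units in document order, direct-speech links that
#' resolve to a Reporting predicate, and zone membership/attribute
#' homogeneity when zones are present.
#'
#' @param doc an [annotated_document()].
#' @return character vector of violation messages (empty when the document is
#'   fully compliant).
#' @export
validate_document <- function(doc) {
  v <- character()
  ids <- vapply(doc$event_predicates, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) v <- c(v, sprintf("duplicate id: %s", d))

  for (ep in doc$event_predicates) {
    v <- c(v, validate_event_predicate(ep, doc))
    if (nrow(doc$clause_units) > 0L) {
      inside <- any(doc$clause_units$start <= ep$span[1] &
                      ep$span[2] <= doc$clause_units$end)
      if (!inside)
        v <- c(v, sprintf("%s: span not inside any clause unit", ep$id))
    }
    ref <- ep$in_direct_speech_of
    if (!is.na(ref)) {
      target <- find_predicate(doc, ref)
      if (is.null(target)) {
        v <- c(v, sprintf("%s: dangling in_direct_speech_of reference \"%s\"", ep$id, ref))
      } else if (!identical(target$event_type, "Event_Report")) {
        v <- c(v, sprintf("%s: in_direct_speech_of \"%s\" is not a Reporting event-predicate",
                          ep$id, ref))
      }
    }
  }

  cu <- doc$clause_units
  if (nrow(cu) > 1L && is.unsorted(cu$start))
    v <- c(v, "clause_units: not in document order")

  if (!is.null(doc$zones)) {
    seen <- character()
    for (z in doc$zones) {
      members <- lapply(z$event_predicates, find_predicate, doc = doc)
      missing <- z$event_predicates[vapply(members, is.null, logical(1))]
      for (m in missing)
        v <- c(v, sprintf("zone %s: references unknown event-predicate \"%s\"", z$zone_id, m))
      members <- members[!vapply(members, is.null, logical(1))]
      if (length(members) > 1L) {
        homog <- all(vapply(members[-1], identical_attributes, logical(1), b = members[[1]]))
        if (!homog)
          v <- c(v, sprintf("zone %s: zone not homogeneous", z$zone_id))
      }
      again <- intersect(seen, z$event_predicates)
      for (m in again)
        v <- c(v, sprintf("zone %s: event-predicate \"%s\" already in another zone", z$zone_id, m))
      seen <- c(seen, z$event_predicates)
    }
  }
  v
}
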