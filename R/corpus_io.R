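# Reading and writing the annotation XML dialect, corpus statistics, and the
# bundled agreement-study fixtures.
#
# Dialect: <doc id date> wraps a <text> element whose content is the raw
# document text with inline <clause>, <ne type="location|time"> and
# <ep ...> elements; zones, whose character spans may overlap, are stored
# standoff in a <zones> element. Serialization is canonical (fixed attribute
# order, minimal escaping), so write -> read -> write is byte-identical.

xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xml_escape_attr <- function(x) gsub('"', "&quot;", xml_escape_text(x), fixed = TRUE)

attr_string <- function(attrs) {
  attrs <- attrs[!vapply(attrs, is.null, logical(1))]
  keep <- vapply(attrs, function(v) !is.na(v) && nzchar(v), logical(1))
  attrs <- attrs[keep]
  if (!length(attrs)) return("")
  paste0(" ", paste(sprintf('%s="%s"', names(attrs),
                            vapply(attrs, xml_escape_attr, character(1))),
                    collapse = " "))
}

format_tp_attr <- function(tp) if (is.null(tp)) NULL else format(tp)

ep_attrs <- function(ep) {
  list(id = ep$id,
       type = ep$event_type,
       anchor_val = if (is.null(ep$anchor_val)) NULL else format(ep$anchor_val, "%Y-%m-%d"),
       val = ep$val,
       stime = format_tp_attr(ep$stime),
       etime = format_tp_attr(ep$etime),
       stime_dir = ep$stime_dir,
       etime_dir = ep$etime_dir,
       location = if (length(ep$locations)) paste(ep$locations, collapse = "|") else NULL,
       speech_of = if (is.na(ep$in_direct_speech_of)) NULL else ep$in_direct_speech_of)
}

render_inline <- function(text, spans) {
  if (!nrow(spans)) return(xml_escape_text(text))
  ord <- order(spans$start, -spans$end, spans$priority)
  spans <- spans[ord, , drop = FALSE]
  n_total <- nchar(text)
  rec <- function(lo, hi, idx) {
    out <- character()
    pos <- lo
    i <- 1L
    while (i <= length(idx)) {
      k <- idx[i]
      s <- spans$start[k]; e <- spans$end[k]
      if (s < pos)
        spatzone_error("inline serialization: crossing spans",
                       "spatzone_structural_error")
      out <- c(out, xml_escape_text(substr(text, pos + 1L, s)))
      j <- i + 1L
      kids <- integer()
      while (j <= length(idx) && spans$start[idx[j]] < e) {
        if (spans$end[idx[j]] > e)
          spatzone_error("inline serialization: crossing spans",
                         "spatzone_structural_error")
        kids <- c(kids, idx[j]); j <- j + 1L
      }
      out <- c(out, spans$open[k], rec(s, e, kids), spans$close[k])
      pos <- e
      i <- j
    }
    c(out, xml_escape_text(substr(text, pos + 1L, hi)))
  }
  paste0(rec(0L, n_total, seq_len(nrow(spans))), collapse = "")
}

doc_span_table <- function(doc) {
  rows <- list()
  add <- function(start, end, priority, open, close)
    rows[[length(rows) + 1L]] <<- data.frame(start = start, end = end,
                                             priority = priority,
                                             open = open, close = close)
  cu <- doc$clause_units
  for (i in seq_len(nrow(cu)))
    add(cu$start[i], cu$end[i], 0L, "<clause>", "</clause>")
  for (ep in doc$event_predicates)
    add(ep$span[1], ep$span[2], 1L,
        sprintf("<ep%s>", attr_string(ep_attrs(ep))), "</ep>")
  for (i in seq_len(nrow(doc$location_entities)))
    add(doc$location_entities$start[i], doc$location_entities$end[i], 2L,
        '<ne type="location">', "</ne>")
  for (i in seq_len(nrow(doc$temporal_entities)))
    add(doc$temporal_entities$start[i], doc$temporal_entities$end[i], 2L,
        '<ne type="time">', "</ne>")
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(), priority = integer(),
                      open = character(), close = character()))
  do.call(rbind, rows)
}

zone_xml <- function(z) {
  sh <- z$shared
  attrs <- list(id = z$zone_id,
                eps = paste(z$event_predicates, collapse = " "),
                start = as.character(z$span[1]),
                end = as.character(z$span[2]),
                type = sh$event_type,
                anchor_val = if (is.null(sh$anchor_val)) NULL else format(sh$anchor_val, "%Y-%m-%d"),
                val = sh$val,
                stime = format_tp_attr(sh$stime),
                etime = format_tp_attr(sh$etime),
                stime_dir = sh$stime_dir,
                etime_dir = sh$etime_dir,
                location = if (length(sh$locations)) paste(sh$locations, collapse = "|") else NULL)
  sprintf("<zone%s/>", attr_string(attrs))
}

#' Serialize an annotated document to the annotation XML dialect
#'
#' Produces the canonical inline serialization: the raw text with inline
#' `<clause>`, `<ne>` and `<ep>` elements inside a `<text>` element, and
#' zones (whose spans may overlap and therefore cannot nest inline) standoff
#' under `<zones>`. The document must pass [validate_document()]; violations
#' raise a contract error. Reading the output with [read_document()] yields a
#' structurally equal document, and re-serializing is byte-identical.
#'
#' @param doc an [annotated_document()].
#' @param path file path, or `NULL` to return the XML string.
#' @return the XML string (invisibly when written to `path`).
#' @export
write_document <- function(doc, path = NULL) {
  viol <- validate_document(doc)
  if (length(viol))
    spatzone_error(paste0("write_document requires a validated document; violations:\n  ",
                          paste(viol, collapse = "\n  ")),
                   "spatzone_contract_error")
  body <- render_inline(doc$text, doc_span_table(doc))
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sprintf('<doc id="%s" date="%s">',
                     xml_escape_attr(doc$doc_id),
                     format(doc$publication_date, "%Y-%m-%d")),
             paste0("<text>", body, "</text>"))
  if (!is.null(doc$zones)) {
    lines <- c(lines, "<zones>",
               vapply(doc$zones, zone_xml, character(1)),
               "</zones>")
  }
  out <- paste0(paste(c(lines, "</doc>"), collapse = "\n"), "\n")
  if (is.null(path)) return(out)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(out), con)
  invisible(out)
}

parse_error <- function(msg) spatzone_error(msg, "spatzone_parse_error")

parse_enum_attr <- function(value, field, allowed, id) {
  if (is.na(value)) return(NULL)
  if (!value %in% allowed)
    parse_error(sprintf("ep %s: attribute %s=\"%s\" not in {%s}",
                        id, field, value, paste(allowed, collapse = ", ")))
  value
}

parse_date_attr <- function(value, field, id) {
  if (is.na(value)) return(NULL)
  d <- tryCatch(as.Date(value), error = function(e) NA)
  if (length(d) != 1L || is.na(d) || !grepl("^\\d{4}-\\d{2}-\\d{2}$", value))
    parse_error(sprintf("ep %s: attribute %s=\"%s\" is not an ISO 8601 date",
                        id, field, value))
  d
}

parse_tp_attr <- function(value, field, id) {
  if (is.na(value)) return(NULL)
  if (value %in% TIME_SYMBOLS) return(time_point(symbol = value))
  time_point(date = parse_date_attr(value, field, id))
}

#' Read an annotated document from the annotation XML dialect
#'
#' Parses the inline markup, recomputing all character offsets from the
#' element structure, validates the attribute vocabularies and the scheme
#' constraints, and returns a validated document. Malformed XML, unknown
#' attribute values, and schema violations raise parse errors.
#'
#' @param x file path, XML string, or connection (anything [xml2::read_xml()]
#'   accepts).
#' @return a validated [annotated_document()].
#' @export
read_document <- function(x) {
  # keep whitespace-only text nodes (sentence separators between clauses)
  root <- xml2::read_xml(x, options = character())
  if (xml2::xml_name(root) != "doc") parse_error("root element must be <doc>")
  doc_id <- xml2::xml_attr(root, "id")
  date <- xml2::xml_attr(root, "date")
  if (is.na(doc_id) || is.na(date))
    parse_error("<doc> must carry id and date attributes")
  pub <- parse_date_attr(date, "date", doc_id)

  text_node <- xml2::xml_find_first(root, "./text")
  if (inherits(text_node, "xml_missing")) parse_error("missing <text> element")

  chars <- character()
  offset <- 0L
  clause_rows <- list(); ne_rows <- list(); eps <- list()

  walk <- function(node) {
    for (child in xml2::xml_contents(node)) {
      if (inherits(child, "xml_node") && xml2::xml_type(child) == "element") {
        name <- xml2::xml_name(child)
        start <- offset
        walk(child)
        end <- offset
        surface <- substr(paste0(chars, collapse = ""), start + 1L, end)
        if (name == "clause") {
          clause_rows[[length(clause_rows) + 1L]] <<-
            data.frame(start = start, end = end)
        } else if (name == "ne") {
          ne_rows[[length(ne_rows) + 1L]] <<-
            data.frame(start = start, end = end,
                       surface = surface,
                       type = xml2::xml_attr(child, "type"))
        } else if (name == "ep") {
          a <- function(nm) xml2::xml_attr(child, nm)
          id <- a("id")
          if (is.na(id)) parse_error("<ep> without id attribute")
          type <- a("type")
          if (is.na(type) || !type %in% EVENT_TYPES)
            parse_error(sprintf("ep %s: type=\"%s\" not in {%s}", id, type,
                                paste(EVENT_TYPES, collapse = ", ")))
          loc <- a("location")
          eps[[length(eps) + 1L]] <<- event_predicate(
            id = id, span = c(start, end), event_type = type,
            anchor_val = parse_date_attr(a("anchor_val"), "anchor_val", id),
            val = parse_enum_attr(a("val"), "val", RELATIVE_VALS, id),
            stime = parse_tp_attr(a("stime"), "stime", id),
            etime = parse_tp_attr(a("etime"), "etime", id),
            stime_dir = parse_enum_attr(a("stime_dir"), "stime_dir",
                                        TEMPORAL_DIRECTIONS, id),
            etime_dir = parse_enum_attr(a("etime_dir"), "etime_dir",
                                        TEMPORAL_DIRECTIONS, id),
            locations = if (is.na(loc)) character() else strsplit(loc, "|", fixed = TRUE)[[1]],
            in_direct_speech_of = a("speech_of"))
        } else {
          parse_error(sprintf("unknown inline element <%s>", name))
        }
      } else {
        s <- xml2::xml_text(child)
        chars <<- c(chars, s)
        offset <<- offset + nchar(s)
      }
    }
  }
  walk(text_node)
  text <- paste0(chars, collapse = "")

  nes <- if (length(ne_rows)) do.call(rbind, ne_rows) else
    data.frame(start = integer(), end = integer(), surface = character(),
               type = character())
  clause_units <- if (length(clause_rows)) do.call(rbind, clause_rows) else NULL
  if (!is.null(clause_units))
    clause_units <- clause_units[order(clause_units$start, clause_units$end), , drop = FALSE]

  zones <- NULL
  znodes <- xml2::xml_find_all(root, "./zones/zone")
  if (length(znodes)) {
    zones <- lapply(znodes, function(zn) {
      a <- function(nm) xml2::xml_attr(zn, nm)
      sh <- list(event_type = a("type"),
                 locations = if (is.na(a("location"))) character() else
                   strsplit(a("location"), "|", fixed = TRUE)[[1]])
      if (is_locatable_type(sh$event_type)) {
        zid <- a("id")
        sh$anchor_val <- parse_date_attr(a("anchor_val"), "anchor_val", zid)
        sh$val <- parse_enum_attr(a("val"), "val", RELATIVE_VALS, zid)
        sh$stime <- parse_tp_attr(a("stime"), "stime", zid)
        sh$etime <- parse_tp_attr(a("etime"), "etime", zid)
        sh$stime_dir <- parse_enum_attr(a("stime_dir"), "stime_dir",
                                        TEMPORAL_DIRECTIONS, zid)
        sh$etime_dir <- parse_enum_attr(a("etime_dir"), "etime_dir",
                                        TEMPORAL_DIRECTIONS, zid)
      }
      zone(zone_id = a("id"),
           event_predicates = strsplit(a("eps"), " ", fixed = TRUE)[[1]],
           span = c(as.integer(a("start")), as.integer(a("end"))),
           shared = sh)
    })
  }

  doc <- annotated_document(
    doc_id = doc_id, publication_date = pub, text = text,
    location_entities = nes[nes$type == "location", c("start", "end", "surface")],
    temporal_entities = nes[nes$type == "time", c("start", "end", "surface")],
    clause_units = clause_units,
    event_predicates = eps,
    zones = zones)
  viol <- validate_document(doc)
  if (length(viol))
    parse_error(paste0("document violates the annotation scheme:\n  ",
                       paste(viol, collapse = "\n  ")))
  doc
}

#' Read a set of annotated documents
#'
#' @param paths character vector of file paths.
#' @return list of [annotated_document()] objects.
#' @export
read_corpus <- function(paths) lapply(paths, read_document)

#' Export a document as standoff JSON
#'
#' Offsets-plus-attributes export for toolchain interoperability: the raw
#' text together with all spans and attribute records, no inline markup.
#'
#' @param doc an [annotated_document()].
#' @param path file path, or `NULL` to return the JSON string.
#' @export
write_standoff_json <- function(doc, path = NULL) {
  ep_record <- function(ep) {
    r <- list(id = ep$id, start = ep$span[1], end = ep$span[2],
              type = ep$event_type)
    if (!is.null(ep$anchor_val)) r$anchor_val <- format(ep$anchor_val, "%Y-%m-%d")
    if (!is.null(ep$val)) r$val <- ep$val
    if (!is.null(ep$stime)) r$stime <- format(ep$stime)
    if (!is.null(ep$etime)) r$etime <- format(ep$etime)
    if (!is.null(ep$stime_dir)) r$stime_dir <- ep$stime_dir
    if (!is.null(ep$etime_dir)) r$etime_dir <- ep$etime_dir
    if (length(ep$locations)) r$locations <- ep$locations
    if (!is.na(ep$in_direct_speech_of)) r$in_direct_speech_of <- ep$in_direct_speech_of
    r
  }
  obj <- list(doc_id = doc$doc_id,
              publication_date = format(doc$publication_date, "%Y-%m-%d"),
              text = doc$text,
              clause_units = doc$clause_units,
              location_entities = doc$location_entities,
              temporal_entities = doc$temporal_entities,
              event_predicates = lapply(doc$event_predicates, ep_record))
  if (!is.null(doc$zones)) {
    obj$zones <- lapply(doc$zones, function(z) {
      list(zone_id = z$zone_id, event_predicates = z$event_predicates,
           start = z$span[1], end = z$span[2],
           type = z$shared$event_type)
    })
  }
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Corpus statistics
#'
#' Document, clause-unit and event-predicate counts, plus per-annotator
#' event-class proportions (percent, 2 decimal places). Labels default to the
#' classes of the documents' own predicates under a single annotator name.
#'
#' @param docs list of [annotated_document()] objects.
#' @param per_annotator_labels optional named list mapping annotator name to
#'   that annotator's class-label vector.
#' @return object of class `corpus_stats`.
#' @export
corpus_stats <- function(docs, per_annotator_labels = NULL) {
  n_ep <- sum(vapply(docs, function(d) length(d$event_predicates), integer(1)))
  if (is.null(per_annotator_labels)) {
    labels <- unlist(lapply(docs, function(d)
      vapply(d$event_predicates, `[[`, character(1), "event_type")))
    per_annotator_labels <- if (length(labels)) list(annotator = labels) else list()
  }
  props <- lapply(per_annotator_labels, function(lab) {
    tab <- table(factor(lab, levels = EVENT_TYPES))
    round(100 * as.numeric(tab) / length(lab), 2) |>
      stats::setNames(EVENT_TYPES)
  })
  structure(list(
    n_documents = length(docs),
    n_clause_units = sum(vapply(docs, function(d) nrow(d$clause_units), integer(1))),
    n_event_predicates = n_ep,
    class_proportions = props
  ), class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf("Corpus: %d documents, %d clause units, %d event-predicates\n",
              x$n_documents, x$n_clause_units, x$n_event_predicates))
  for (ann in names(x$class_proportions)) {
    p <- x$class_proportions[[ann]]
    cat(sprintf("  %s: %s\n", ann,
                paste(sprintf("%s %.2f%%", names(p), p), collapse = ", ")))
  }
  invisible(x)
}

#' Per-annotator class proportions from a confusion matrix
#'
#' The marginals of a two-annotator confusion matrix give each annotator's
#' class distribution: column sums for annotator 1, row sums for annotator 2.
#'
#' @param m a [confusion_matrix()].
#' @param annotator which marginal to report.
#' @return named numeric vector of percentages rounded to 2 decimal places.
#' @export
class_proportions <- function(m, annotator = c("annotator1", "annotator2")) {
  annotator <- match.arg(annotator)
  margin <- if (annotator == "annotator1") colSums(m$counts) else rowSums(m$counts)
  round(100 * margin / m$n, 2)
}

#' Bundled confusion matrices from a published annotation-reliability study
#'
#' Event-class confusion matrices from a three-annotator reliability study of
#' spatiotemporal zoning on 100 outbreak news reports: `set1` compares
#' annotators A (columns) and B (rows) on 1086 event-predicates, `set2`
#' annotators A (columns) and C (rows) on 908. They serve as in-package test
#' data for the agreement suite (kappas of 0.87 and 0.90 at 2 dp).
#'
#' @return named list of two [confusion_matrix()] objects, `set1` and `set2`.
#' @export
zoning_confusion_matrices <- function() {
  read1 <- function(f)
    read_confusion_csv(system.file("extdata", f, package = "spatzone",
                                   mustWork = TRUE))
  list(set1 = read1("confusion_set1.csv"),
       set2 = read1("confusion_set2.csv"))
}
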