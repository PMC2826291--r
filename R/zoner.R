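# Zone-boundary generation: merge consecutive attribute-compatible
# event-predicates into maximal zones.

#' Are two event-predicates attribute-compatible?
#'
#' Compatible predicates share the event class and the location set; for
#' temporally locatable classes all six temporal attributes must also be
#' identical (a symbolic time never equals an absolute date). Two empty
#' location sets compare equal. Compatibility is exact attribute identity, so
#' it is an equivalence relation and greedy merging is order-independent
#' within a run.
#'
#' @param a,b validated [event_predicate()] objects.
#' @return logical scalar.
#' @export
attributes_compatible <- function(a, b) identical_attributes(a, b)

clause_parent <- function(cu) {
  # parent of clause i = smallest strictly containing clause, by span
  n <- nrow(cu)
  parent <- rep(NA_integer_, n)
  if (n < 2L) return(parent)
  for (i in seq_len(n)) {
    best <- NA_integer_; best_len <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      contains <- cu$start[j] <= cu$start[i] && cu$end[i] <= cu$end[j] &&
        (cu$end[j] - cu$start[j]) > (cu$end[i] - cu$start[i])
      if (contains && (cu$end[j] - cu$start[j]) < best_len) {
        best <- j; best_len <- cu$end[j] - cu$start[j]
      }
    }
    parent[i] <- best
  }
  parent
}

ep_clause_index <- function(ep, cu) {
  # smallest clause unit containing the predicate span
  hit <- which(cu$start <= ep$span[1] & ep$span[2] <= cu$end)
  if (!length(hit)) return(NA_integer_)
  hit[which.min(cu$end[hit] - cu$start[hit])]
}

#' Traversal order of a document's event-predicates
#'
#' `"depth_first"` (the default) visits matrix-clause predicates in textual
#' order and recurses into each subordinate clause immediately after its
#' governing predicate (the last matrix predicate starting before the
#' subordinate clause), reproducing the walk used for zone generation.
#' `"textual"` is plain left-to-right order of predicate spans.
#'
#' @param doc an [annotated_document()].
#' @param order traversal strategy.
#' @return the document's event-predicates as a list, in traversal order.
#' @export
traversal_order <- function(doc, order = c("depth_first", "textual")) {
  order <- match.arg(order)
  eps <- doc$event_predicates
  if (!length(eps)) return(list())
  starts <- vapply(eps, function(e) e$span[1], integer(1))
  if (order == "textual") return(eps[order(starts)])

  cu <- doc$clause_units
  if (!nrow(cu)) return(eps[order(starts)])
  parent <- clause_parent(cu)
  clause_of <- vapply(eps, ep_clause_index, integer(1), cu = cu)
  children <- lapply(seq_len(nrow(cu)), function(i) {
    kids <- which(!is.na(parent) & parent == i)
    kids[order(cu$start[kids])]
  })

  visit_clause <- function(ci) {
    own <- which(clause_of == ci)
    own <- own[order(starts[own])]
    kids <- children[[ci]]
    out <- integer()
    handled <- logical(length(kids))
    for (e in own) {
      out <- c(out, e)
      # subordinate clauses whose governing predicate is e: they start after
      # e and before the next direct predicate of this clause
      nxt <- own[own != e & starts[own] > starts[e]]
      limit <- if (length(nxt)) min(starts[nxt]) else Inf
      for (k in seq_along(kids)) {
        if (!handled[k] && cu$start[kids[k]] >= starts[e] && cu$start[kids[k]] < limit) {
          out <- c(out, visit_clause(kids[k]))
          handled[k] <- TRUE
        }
      }
    }
    for (k in seq_along(kids)) if (!handled[k]) out <- c(out, visit_clause(kids[k]))
    out
  }

  roots <- which(is.na(parent))
  roots <- roots[order(cu$start[roots])]
  idx <- unlist(lapply(roots, visit_clause))
  orphan <- setdiff(seq_along(eps), idx) # predicates outside every clause
  idx <- c(idx, orphan[order(starts[orphan])])
  eps[idx]
}

zone_span_for <- function(members, cu) {
  spans <- lapply(members, function(ep) {
    ci <- if (nrow(cu)) ep_clause_index(ep, cu) else NA_integer_
    if (is.na(ci)) ep$span else c(cu$start[ci], cu$end[ci])
  })
  c(min(vapply(spans, `[`, integer(1), 1)),
    max(vapply(spans, `[`, integer(1), 2)))
}

shared_record <- function(ep) {
  rec <- list(event_type = ep$event_type, locations = ep$locations)
  if (is_locatable_type(ep$event_type))
    rec <- c(rec, ep[TEMPORAL_FIELDS])
  rec
}

#' Generate zones from attributed event-predicates
#'
#' Traverses the event-predicates (see [traversal_order()]) and greedily
#' merges each predicate into the current zone iff it is
#' [attributes_compatible()] with the zone's shared attributes, otherwise
#' opens a new zone. Every predicate lands in exactly one zone, and adjacent
#' zones are never compatible (maximality). A zone's span is the minimal
#' character interval covering its members' clause units (the predicate's
#' own span when no clause contains it); spans of zones drawn from
#' interleaved clauses may overlap.
#'
#' @param doc an [annotated_document()] that passes [validate_document()]
#'   with no violations (violations raise a contract error).
#' @param order traversal strategy, see [traversal_order()].
#' @return ordered list of [zone()] objects.
#' @export
generate_zones <- function(doc, order = c("depth_first", "textual")) {
  viol <- validate_document(doc)
  if (length(viol))
    spatzone_error(paste0("generate_zones requires a validated document; violations:\n  ",
                          paste(viol, collapse = "\n  ")),
                   "spatzone_contract_error")
  eps <- traversal_order(doc, order)
  if (!length(eps)) return(list())

  zones <- list()
  current <- list(eps[[1]])
  flush <- function(members, k) {
    first <- members[[1]]
    zone(zone_id = sprintf("z%d", k),
         event_predicates = vapply(members, `[[`, character(1), "id"),
         span = zone_span_for(members, doc$clause_units),
         shared = shared_record(first))
  }
  for (ep in eps[-1]) {
    if (attributes_compatible(current[[1]], ep)) {
      current <- c(current, list(ep))
    } else {
      zones <- c(zones, list(flush(current, length(zones) + 1L)))
      current <- list(ep)
    }
  }
  c(zones, list(flush(current, length(zones) + 1L)))
}

#' Shared attributes of a zone
#'
#' Returns the attribute record common to every member predicate, as
#' serialized onto the zone tag: the event class, the location set, and, for
#' temporally locatable classes, the six temporal attributes. Raises a
#' homogeneity error if the members do not in fact share their attributes.
#'
#' @param z a [zone()].
#' @param doc the [annotated_document()] the zone's predicate ids refer to.
#' @return named list of shared attributes.
#' @export
zone_attribute_summary <- function(z, doc) {
  members <- lapply(z$event_predicates, find_predicate, doc = doc)
  if (any(vapply(members, is.null, logical(1))))
    spatzone_error(sprintf("zone %s: unknown event-predicate id", z$zone_id),
                   "spatzone_link_error")
  first <- members[[1]]
  homog <- all(vapply(members, identical_attributes, logical(1), b = first))
  if (!homog)
    spatzone_error(sprintf("zone %s is not attribute-homogeneous", z$zone_id),
                   "spatzone_homogeneity_error")
  shared_record(first)
}
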