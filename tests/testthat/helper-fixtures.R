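# Shared fixtures and independent oracles.
#
# Oracles are deliberately naive tally/enumeration implementations, written
# against the definitions rather than against the package code.

# --- independent oracles ----------------------------------------------------

oracle_kappa <- function(labels1, labels2, categories) {
  n <- length(labels1)
  agree <- 0
  for (i in seq_len(n)) if (labels1[i] == labels2[i]) agree <- agree + 1
  pr_a <- agree / n
  pr_e <- 0
  for (cat in categories) {
    p1 <- sum(labels1 == cat) / n
    p2 <- sum(labels2 == cat) / n
    pr_e <- pr_e + p1 * p2
  }
  (pr_a - pr_e) / (1 - pr_e)
}

oracle_pct <- function(labels1, labels2) {
  hits <- 0
  for (i in seq_along(labels1)) if (identical(labels1[[i]], labels2[[i]])) hits <- hits + 1
  hits / length(labels1)
}

# expected kappa by exhaustive enumeration over (gold, label1, label2) triples
oracle_expected_kappa <- function(p, m1, m2) {
  cats <- seq_along(p)
  pr_a <- 0
  joint1 <- numeric(length(cats)); joint2 <- numeric(length(cats))
  for (g in cats) for (c1 in cats) for (c2 in cats) {
    prob <- p[g] * m1[g, c1] * m2[g, c2]
    if (c1 == c2) pr_a <- pr_a + prob
  }
  for (g in cats) for (c1 in cats) joint1[c1] <- joint1[c1] + p[g] * m1[g, c1]
  for (g in cats) for (c2 in cats) joint2[c2] <- joint2[c2] + p[g] * m2[g, c2]
  pr_e <- sum(joint1 * joint2)
  (pr_a - pr_e) / (1 - pr_e)
}

# --- document fixtures ------------------------------------------------------

# A hand-laid-out two-sentence report: one Reporting predicate over a known
# period, one Normal predicate in the last week of October 2006, both located
# in Yei County. Offsets are computed from the text, not hard-coded.
make_report_doc <- function() {
  s1 <- "Officials reported 16 deaths in Yei County from 1 September to 8 November 2006."
  s2 <- "The disease crossed into Yei County in the last week of October 2006."
  text <- paste(s1, s2)
  span_of <- function(sub) {
    start <- regexpr(sub, text, fixed = TRUE)[1] - 1L
    c(start, start + nchar(sub))
  }
  ep1 <- event_predicate("e1", span_of("reported"), "Event_Report",
                         anchor_val = "2006-11-08", val = "PAST_REF",
                         stime = time_point(date = "2006-09-01"),
                         etime = time_point(date = "2006-11-08"),
                         stime_dir = "AS_OF", etime_dir = "AS_OF",
                         locations = "Yei County")
  ep2 <- event_predicate("e2", span_of("crossed"), "Event_Normal",
                         anchor_val = "2006-11-08", val = "PAST_REF",
                         stime = time_point(date = "2006-10-25"),
                         etime = time_point(date = "2006-10-31"),
                         stime_dir = "AS_OF", etime_dir = "AS_OF",
                         locations = "Yei County")
  loc_spans <- gregexpr("Yei County", text, fixed = TRUE)[[1]]
  annotated_document(
    doc_id = "report1", publication_date = "2006-11-08", text = text,
    location_entities = data.frame(start = as.integer(loc_spans) - 1L,
                                   end = as.integer(loc_spans) - 1L + 10L,
                                   surface = "Yei County"),
    clause_units = data.frame(start = c(0L, nchar(s1) + 1L),
                              end = c(nchar(s1), nchar(text))),
    event_predicates = list(ep1, ep2))
}

# Minimal single-clause document wrapping a supplied list of predicates whose
# attributes drive zoning tests. Text is synthesized so every location
# mentioned by a predicate appears verbatim.
make_flat_doc <- function(eps_spec, pub = "2006-11-24") {
  sentences <- character()
  eps <- list()
  clause <- list()
  off <- 0L
  for (i in seq_along(eps_spec)) {
    spec <- eps_spec[[i]]
    locs <- spec$locations %||% character()
    s <- sprintf("Event %d happened%s.", i,
                 if (length(locs)) paste0(" in ", paste(locs, collapse = " and ")) else "")
    vstart <- off + nchar(sprintf("Event %d ", i))
    ep_args <- c(list(id = sprintf("e%d", i),
                      span = c(vstart, vstart + nchar("happened"))),
                 spec)
    eps[[i]] <- do.call(event_predicate, ep_args)
    clause[[i]] <- data.frame(start = off, end = off + nchar(s))
    off <- off + nchar(s) + 1L
    sentences <- c(sentences, s)
  }
  annotated_document(doc_id = "flat", publication_date = pub,
                     text = paste(sentences, collapse = " "),
                     clause_units = do.call(rbind, clause),
                     event_predicates = eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

find_ep <- function(doc, id) {
  for (ep in doc$event_predicates) if (ep$id == id) return(ep)
  NULL
}

# naive re-zoning of an id sequence by greedy merging (test-side mirror of the
# partition/idempotence property, computed over ids only)
rezone_sequence <- function(doc, ids) {
  groups <- list()
  cur <- character()
  first <- NULL
  for (id in ids) {
    ep <- find_ep(doc, id)
    if (is.null(first) || attributes_compatible(first, ep)) {
      cur <- c(cur, id)
      if (is.null(first)) first <- ep
    } else {
      groups <- c(groups, list(cur))
      cur <- id
      first <- ep
    }
  }
  if (length(cur)) groups <- c(groups, list(cur))
  groups
}

normal_attrs <- function(loc = "Tokyo", anchor = "2006-11-24",
                         stime = "2006-11-01", etime = "2006-11-20") {
  list(event_type = "Event_Normal", anchor_val = anchor, val = "PAST_REF",
       stime = time_point(date = stime), etime = time_point(date = etime),
       stime_dir = "AS_OF", etime_dir = "AS_OF", locations = loc)
}

tiny_gazetteer <- function() {
  gazetteer(data.frame(
    name = c("Japan", "Tokyo", "Thailand", "Bangkok", "Vietnam", "Hanoi"),
    parent = c("", "Japan", "", "Thailand", "", "Vietnam")))
}
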