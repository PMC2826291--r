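test_that("attribute compatibility follows class, location and temporal identity", {
  a <- do.call(event_predicate, c(list(id = "a", span = c(0L, 4L)),
                                  normal_attrs(loc = "Tokyo")))
  b <- do.call(event_predicate, c(list(id = "b", span = c(5L, 9L)),
                                  normal_attrs(loc = "Tokyo")))
  expect_true(attributes_compatible(a, b))
  expect_true(attributes_compatible(a, a)) # reflexive

  info <- event_predicate("c", c(10L, 14L), "Event_Info", locations = "Tokyo")
  expect_false(attributes_compatible(a, info))

  b2 <- b; b2$etime <- time_point(symbol = "PRESENT")
  expect_false(attributes_compatible(a, b2))

  b3 <- b; b3$locations <- "Japan"
  expect_false(attributes_compatible(a, b3))

  # non-locatable classes compare on class + locations only
  h1 <- event_predicate("h1", c(0L, 4L), "Event_Hypothetical")
  h2 <- event_predicate("h2", c(5L, 9L), "Event_Hypothetical")
  expect_true(attributes_compatible(h1, h2)) # empty location sets are equal
})

test_that("compatibility is an equivalence relation on random predicates", {
  set.seed(11)
  pool <- lapply(1:30, function(i) {
    cls <- sample(event_types(), 1)
    args <- list(id = sprintf("p%d", i), span = c(0L, 4L), event_type = cls)
    if (is_locatable_type(cls)) {
      args <- c(args, list(
        anchor_val = as.Date("2006-01-01") + sample(0:1, 1),
        val = sample(relative_vals()[1:2], 1),
        stime = time_point(symbol = sample(c("PAST", "PRESENT"), 1)),
        etime = time_point(symbol = "PRESENT"),
        stime_dir = "AS_OF", etime_dir = sample(c("AS_OF", "BEFORE"), 1)))
    }
    args$locations <- sample(c("Tokyo", "Japan"), sample(0:1, 1))
    do.call(event_predicate, args)
  })
  for (x in pool) for (y in pool) {
    expect_identical(attributes_compatible(x, y), attributes_compatible(y, x))
    if (attributes_compatible(x, y)) {
      for (z in pool) if (attributes_compatible(y, z))
        expect_true(attributes_compatible(x, z))
    }
  }
})

test_that("zoning merges consecutive compatible predicates and splits otherwise", {
  doc <- make_flat_doc(list(
    c(list(event_type = "Event_Report", anchor_val = "2006-11-24",
           stime = time_point(date = "2006-11-24"), val = "PRESENT_REF",
           etime = time_point(date = "2006-11-24"),
           stime_dir = "AS_OF", etime_dir = "AS_OF")),
    list(event_type = "Event_Info"),
    normal_attrs(loc = "Tokyo"),
    normal_attrs(loc = "Tokyo")))
  zones <- generate_zones(doc)
  expect_length(zones, 3L)
  expect_identical(lapply(zones, `[[`, "event_predicates"),
                   list("e1", "e2", c("e3", "e4")))

  empty <- make_flat_doc(list())
  expect_identical(generate_zones(empty), list())

  merged <- make_flat_doc(list(normal_attrs("Tokyo"), normal_attrs("Tokyo"),
                               normal_attrs("Tokyo")))
  expect_length(generate_zones(merged), 1L)
})

test_that("zoning refuses unvalidated documents", {
  doc <- make_flat_doc(list(list(event_type = "Event_Normal"))) # missing anchor
  expect_error(generate_zones(doc), class = "spatzone_contract_error")
})

test_that("depth-first traversal visits subordinate-clause predicates after their governor", {
  # matrix clause: Report predicate; embedded clause carries an Info predicate
  # (textually before the next matrix-level Normal sentence)
  text <- "Officials confirmed that the fever is deadly. Ten people died in Tokyo."
  sub_start <- regexpr("the fever", text, fixed = TRUE)[1] - 1L
  sub_end <- regexpr(". Ten", text, fixed = TRUE)[1] - 1L
  span_of <- function(sub) {
    s <- regexpr(sub, text, fixed = TRUE)[1] - 1L
    c(s, s + nchar(sub))
  }
  doc <- annotated_document(
    doc_id = "nested", publication_date = "2006-11-24", text = text,
    clause_units = data.frame(start = c(0L, sub_start, 46L),
                              end = c(45L, sub_end, nchar(text))),
    event_predicates = list(
      event_predicate("rep", span_of("confirmed"), "Event_Report",
                      anchor_val = "2006-11-24", val = "PRESENT_REF",
                      stime = time_point(date = "2006-11-24"),
                      etime = time_point(date = "2006-11-24"),
                      stime_dir = "AS_OF", etime_dir = "AS_OF"),
      event_predicate("inf", span_of("is deadly"), "Event_Info"),
      event_predicate("nor", span_of("died"), "Event_Normal",
                      anchor_val = "2006-11-24", val = "PAST_REF",
                      stime = time_point(symbol = "PAST"),
                      etime = time_point(symbol = "PAST"),
                      stime_dir = "AS_OF", etime_dir = "AS_OF",
                      locations = "Tokyo")))
  expect_identical(validate_document(doc), character(0))
  ord <- vapply(traversal_order(doc), `[[`, character(1), "id")
  expect_identical(ord, c("rep", "inf", "nor"))
  expect_identical(vapply(traversal_order(doc, "textual"), `[[`, character(1), "id"),
                   c("rep", "inf", "nor"))
  zones <- generate_zones(doc)
  expect_length(zones, 3L)
})

test_that("zoning invariants hold on synthetic corpora", {
  corpus <- generate_corpus(generator_config(n_documents = 40, seed = 7))
  for (doc in corpus) {
    zones <- generate_zones(doc)
    traversal <- vapply(traversal_order(doc), `[[`, character(1), "id")
    flat <- unlist(lapply(zones, `[[`, "event_predicates"))
    # partition: traversal reproduced exactly once
    expect_identical(flat, traversal)
    # maximality: adjacent zones are incompatible
    if (length(zones) > 1L) {
      for (i in seq_len(length(zones) - 1L)) {
        last_ep <- find_ep(doc, utils::tail(zones[[i]]$event_predicates, 1))
        first_ep <- find_ep(doc, zones[[i + 1L]]$event_predicates[1])
        expect_false(attributes_compatible(last_ep, first_ep))
      }
    }
    # idempotence: re-zoning the zoned predicate sequence reproduces the zoning
    rezoned <- rezone_sequence(doc, flat)
    expect_identical(rezoned, lapply(zones, `[[`, "event_predicates"))
  }
})

test_that("zone summaries expose the shared record and reject heterogeneity", {
  doc <- make_report_doc()
  zones <- generate_zones(doc)
  expect_length(zones, 2L)
  sh <- zone_attribute_summary(zones[[1]], doc)
  expect_identical(sh$event_type, "Event_Report")
  expect_identical(format(sh$stime), "2006-09-01")
  expect_identical(format(sh$etime), "2006-11-08")
  expect_identical(sh$locations, "Yei County")
  sh2 <- zone_attribute_summary(zones[[2]], doc)
  expect_identical(format(sh2$stime), "2006-10-25")
  expect_identical(format(sh2$etime), "2006-10-31")

  bad <- zone("zx", c("e1", "e2"), c(0L, nchar(doc$text)),
              shared = list(event_type = "Event_Report"))
  expect_error(zone_attribute_summary(bad, doc),
               class = "spatzone_homogeneity_error")
})
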