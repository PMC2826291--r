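# Synthetic corpus generation and simulated annotator noise.
#
# The generator emulates outbreak news reports: a publication date,
# clause-segmented template text with verbatim location mentions drawn from a
# hierarchical gazetteer, and event-predicates over the four classes. The
# noise model perturbs a gold annotation independently for each simulated
# annotator (class relabeling by a row-stochastic confusion matrix, temporal
# flips, partitive location generalization), matching the conditional
# independence assumed by the chance-agreement term of Cohen's kappa.

with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

MONTH_FULL <- c("January", "February", "March", "April", "May", "June",
                "July", "August", "September", "October", "November", "December")

date_surface <- function(d) {
  sprintf("%d %s %s", as.integer(format(d, "%d")),
          MONTH_FULL[as.integer(format(d, "%m"))], format(d, "%Y"))
}

#' Default hierarchical gazetteer for synthetic corpora
#'
#' A small country > province > city tree whose names also appear in the
#' generated template text, so partitive location substitutions by the noise
#' model stay resolvable.
#'
#' @return a [gazetteer()].
#' @export
default_gazetteer <- function() {
  gazetteer(data.frame(
    name = c("Sudan", "Central Equatoria", "Yei County",
             "Pakistan", "Punjab", "Lahore", "Sindh", "Karachi",
             "Thailand", "Bangkok", "Khon Kaen",
             "Vietnam", "Lai Chau Province", "Can Tho",
             "Japan", "Tokyo",
             "Indonesia", "Jakarta",
             "Canada", "Ontario", "Toronto",
             "India", "West Bengal", "Murshidabad"),
    parent = c("", "Sudan", "Central Equatoria",
               "", "Pakistan", "Punjab", "Pakistan", "Sindh",
               "", "Thailand", "Thailand",
               "", "Vietnam", "Vietnam",
               "", "Japan",
               "", "Indonesia",
               "", "Canada", "Ontario",
               "", "India", "West Bengal")))
}

#' Configuration for the synthetic corpus generator
#'
#' Defaults emulate the annotated study corpus: the event-class distribution
#' is the Normal/Reporting/Hypothetical/Information split observed for one
#' annotator on a 1086-predicate news set (53.31/23.30/5.80/17.59 percent);
#' documents carry 6-25 predicates; publication dates fall in the window
#' where most of the corpus's articles were published.
#'
#' @param n_documents number of documents.
#' @param predicates_per_document inclusive integer range `c(min, max)`.
#' @param class_distribution probabilities over the four event classes, in
#'   [event_types()] order (must sum to 1).
#' @param gazetteer a [gazetteer()] supplying location names.
#' @param date_window inclusive calendar interval for publication dates.
#' @param p_direct_speech probability that a Reporting predicate governs the
#'   following predicate as quoted direct speech.
#' @param p_subordinate probability that a non-quoting Reporting predicate
#'   embeds the following predicate in a subordinate clause.
#' @param seed integer seed; generation is bit-reproducible given the
#'   configuration.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_documents = 50,
                             predicates_per_document = c(6, 25),
                             class_distribution = c(Event_Normal = 0.5331,
                                                    Event_Report = 0.2330,
                                                    Event_Hypothetical = 0.0580,
                                                    Event_Info = 0.1759),
                             gazetteer = default_gazetteer(),
                             date_window = as.Date(c("2005-07-01", "2006-12-31")),
                             p_direct_speech = 0.25,
                             p_subordinate = 0.3,
                             seed = 1L) {
  if (abs(sum(class_distribution) - 1) > 1e-8)
    spatzone_error("generator_config: class_distribution must sum to 1",
                   "spatzone_config_error")
  if (length(class_distribution) != 4L || any(class_distribution < 0))
    spatzone_error("generator_config: class_distribution needs 4 non-negative probabilities",
                   "spatzone_config_error")
  if (is.null(names(class_distribution))) names(class_distribution) <- EVENT_TYPES
  if (!setequal(names(class_distribution), EVENT_TYPES))
    spatzone_error("generator_config: class_distribution names must be the four event types",
                   "spatzone_config_error")
  if (!inherits(gazetteer, "gazetteer"))
    spatzone_error("generator_config: `gazetteer` must be a gazetteer object",
                   "spatzone_config_error")
  dw <- as.Date(date_window)
  if (length(dw) != 2L || anyNA(dw) || dw[1] > dw[2])
    spatzone_error("generator_config: invalid date_window", "spatzone_config_error")
  rng <- as.integer(predicates_per_document)
  if (length(rng) != 2L || anyNA(rng) || rng[1] < 1L || rng[1] > rng[2])
    spatzone_error("generator_config: invalid predicates_per_document range",
                   "spatzone_config_error")
  structure(list(n_documents = as.integer(n_documents),
                 predicates_per_document = rng,
                 class_distribution = class_distribution[EVENT_TYPES],
                 gazetteer = gazetteer,
                 date_window = dw,
                 p_direct_speech = p_direct_speech,
                 p_subordinate = p_subordinate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Annotator noise specification
#'
#' Models the disagreement modes seen between human annotators: event-class
#' relabeling (row-stochastic confusion over the four classes, dominated in
#' practice by Normal/Information confusions), temporal perturbations
#' (absolute dates moved by 1-3 days or a direction class swapped), and
#' partitive location generalization (a location replaced by its gazetteer
#' parent, e.g. "Tokyo" by "Japan").
#'
#' @param class_confusion 4x4 row-stochastic matrix over [event_types()]
#'   (rows = gold class, columns = assigned class); defaults to identity.
#' @param p_temporal_flip probability one temporal attribute of a locatable
#'   predicate is perturbed.
#' @param p_location_generalize probability each location is replaced by its
#'   gazetteer parent.
#' @param seed optional integer seed isolating this annotator's randomness.
#' @return object of class `annotator_noise_spec`.
#' @export
annotator_noise_spec <- function(class_confusion = diag(4),
                                 p_temporal_flip = 0,
                                 p_location_generalize = 0,
                                 seed = NULL) {
  m <- as.matrix(class_confusion)
  if (!all(dim(m) == c(4L, 4L)) || any(m < 0) ||
      any(abs(rowSums(m) - 1) > 1e-8))
    spatzone_error("annotator_noise_spec: class_confusion must be a 4x4 row-stochastic matrix",
                   "spatzone_config_error")
  dimnames(m) <- list(gold = EVENT_TYPES, assigned = EVENT_TYPES)
  structure(list(class_confusion = m,
                 p_temporal_flip = p_temporal_flip,
                 p_location_generalize = p_location_generalize,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "annotator_noise_spec")
}

sample_pub_date <- function(window) {
  window[1] + sample.int(as.integer(window[2] - window[1]) + 1L, 1L) - 1L
}

sample_location <- function(g, n = 1L) g$name[sample.int(length(g$name), n)]

NORMAL_VERBS <- c("fell ill", "died of the fever", "were hospitalized",
                  "tested positive", "were placed under quarantine")
REPORT_VERBS <- c("said", "reported", "announced", "confirmed")
HYP_VERBS <- c("could spread", "might reach", "would threaten")
INFO_VERBS <- c("is spread", "is carried", "is transmitted")

# builder over a character accumulator; spans are 0-based half-open
new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$buf <- character()
  env$off <- 0L
  env$emit <- function(s) {
    start <- env$off
    env$buf[[length(env$buf) + 1L]] <- s
    env$off <- env$off + nchar(s)
    c(start, env$off)
  }
  env
}

draw_temporal_attrs <- function(anchor) {
  val <- sample(c("PAST_REF", "PRESENT_REF", "FUTURE_REF"), 1L,
                prob = c(0.7, 0.2, 0.1))
  if (val == "PAST_REF") {
    d2 <- anchor - sample.int(11L, 1L) + 1L          # anchor-0..10
    d1 <- d2 - sample.int(21L, 1L) + 1L              # d2-0..20
    stime <- if (stats::runif(1) < 0.3) time_point(symbol = "PAST") else time_point(date = d1)
    etime <- time_point(date = d2)
  } else if (val == "PRESENT_REF") {
    stime <- if (stats::runif(1) < 0.5) time_point(symbol = "PAST")
             else time_point(date = anchor - sample.int(10L, 1L))
    etime <- if (stats::runif(1) < 0.5) time_point(symbol = "PRESENT")
             else time_point(date = anchor)
  } else {
    d1 <- anchor + sample.int(10L, 1L)
    d2 <- d1 + sample.int(11L, 1L) - 1L
    stime <- if (stats::runif(1) < 0.3) time_point(symbol = "FUTURE") else time_point(date = d1)
    etime <- if (stats::runif(1) < 0.3) time_point(symbol = "FUTURE") else time_point(date = d2)
  }
  list(val = val, stime = stime, etime = etime,
       stime_dir = sample(TEMPORAL_DIRECTIONS, 1L, prob = c(0.7, 0.15, 0.15)),
       etime_dir = sample(TEMPORAL_DIRECTIONS, 1L, prob = c(0.7, 0.15, 0.15)))
}

#' Generate a synthetic annotated corpus
#'
#' Produces documents that pass [validate_document()] with zero violations:
#' clause-segmented template text, verbatim location and date mentions
#' recorded as entity spans, and event-predicates whose classes are drawn
#' i.i.d. from the configured distribution. Reporting predicates sometimes
#' govern the following predicate as quoted direct speech (re-anchoring its
#' temporal attributes to the reporting date) or embed it in a subordinate
#' clause (exercising nested clause traversal). Bit-reproducible given
#' `cfg$seed`.
#'
#' @param cfg a [generator_config()].
#' @return list of [annotated_document()] objects.
#' @export
generate_corpus <- function(cfg) {
  if (!inherits(cfg, "generator_config"))
    spatzone_error("generate_corpus: `cfg` must be a generator_config",
                   "spatzone_config_error")
  with_seed(cfg$seed, function() {
    lapply(seq_len(cfg$n_documents), function(i) generate_document(cfg, i))
  })
}

generate_document <- function(cfg, index) {
  doc_id <- sprintf("synth%04d", index)
  pub <- sample_pub_date(cfg$date_window)
  rng <- cfg$predicates_per_document
  n_ep <- sample(seq(rng[1], rng[2]), 1L)
  classes <- sample(EVENT_TYPES, n_ep, replace = TRUE,
                    prob = cfg$class_distribution)

  b <- new_builder()
  clauses <- list(); locs <- list(); times <- list(); eps <- list()
  add_clause <- function(span) clauses[[length(clauses) + 1L]] <<-
    data.frame(start = span[1], end = span[2])
  add_loc <- function(span, surface) locs[[length(locs) + 1L]] <<-
    data.frame(start = span[1], end = span[2], surface = surface)
  add_time <- function(span, surface) times[[length(times) + 1L]] <<-
    data.frame(start = span[1], end = span[2], surface = surface)
  add_ep <- function(ep) eps[[length(eps) + 1L]] <<- ep
  ep_id <- function(k) sprintf("%s_e%d", doc_id, k)

  emit_loc <- function(name) { sp <- b$emit(name); add_loc(sp, name); name }
  emit_time <- function(d) { s <- date_surface(d); sp <- b$emit(s); add_time(sp, s) }

  # emits one predicate's core clause content (no trailing period); returns ep
  emit_predicate_body <- function(k, cls, anchor, speech_of = NA_character_) {
    g <- cfg$gazetteer
    if (cls == "Event_Normal") {
      locations <- sample_location(g, if (stats::runif(1) < 0.2) 2L else 1L)
      b$emit("In ")
      emit_loc(locations[1])
      if (length(locations) > 1L) { b$emit(" and "); emit_loc(locations[2]) }
      b$emit(sprintf(", %d people ", sample.int(200L, 1L)))
      vspan <- b$emit(sample(NORMAL_VERBS, 1L))
      tt <- draw_temporal_attrs(anchor)
      mention <- if (tt$etime$kind == "absolute") tt$etime$date else anchor
      b$emit(" on ")
      emit_time(mention)
      event_predicate(ep_id(k), vspan, cls, anchor_val = anchor, val = tt$val,
                      stime = tt$stime, etime = tt$etime,
                      stime_dir = tt$stime_dir, etime_dir = tt$etime_dir,
                      locations = locations, in_direct_speech_of = speech_of)
    } else if (cls == "Event_Report") {
      loc <- sample_location(g)
      b$emit("Health officials in ")
      emit_loc(loc)
      b$emit(" ")
      vspan <- b$emit(sample(REPORT_VERBS, 1L))
      rdate <- pub - sample.int(4L, 1L) + 1L
      b$emit(" on ")
      emit_time(rdate)
      event_predicate(ep_id(k), vspan, cls, anchor_val = anchor,
                      val = if (rdate < anchor) "PAST_REF" else "PRESENT_REF",
                      stime = time_point(date = rdate),
                      etime = time_point(date = rdate),
                      stime_dir = "AS_OF", etime_dir = "AS_OF",
                      locations = loc, in_direct_speech_of = speech_of)
    } else if (cls == "Event_Hypothetical") {
      with_loc <- stats::runif(1) < 0.5
      b$emit("The virus ")
      vspan <- b$emit(sample(HYP_VERBS, 1L))
      locations <- character()
      if (with_loc) {
        b$emit(" beyond ")
        locations <- emit_loc(sample_location(g))
      } else {
        b$emit(" further")
      }
      event_predicate(ep_id(k), vspan, cls, locations = locations,
                      in_direct_speech_of = speech_of)
    } else {
      with_loc <- stats::runif(1) < 0.5
      b$emit("The disease ")
      vspan <- b$emit(sample(INFO_VERBS, 1L))
      b$emit(" by mosquitoes")
      locations <- character()
      if (with_loc) {
        b$emit(" in ")
        locations <- emit_loc(sample_location(g))
      }
      event_predicate(ep_id(k), vspan, cls, locations = locations,
                      in_direct_speech_of = speech_of)
    }
  }

  k <- 1L
  first <- TRUE
  while (k <= n_ep) {
    if (!first) b$emit(" ")
    first <- FALSE
    sent_start <- b$off
    cls <- classes[k]
    if (cls == "Event_Report" && k < n_ep) {
      u <- stats::runif(1)
      if (u < cfg$p_direct_speech) {
        # quoted direct speech: the next predicate is re-anchored to the
        # reporting event's occurrence date
        b$emit("\"")
        sub_start <- b$off
        rep_id <- ep_id(k)
        report_date <- pub - sample.int(4L, 1L) + 1L
        quoted <- emit_predicate_body(k + 1L, classes[k + 1L],
                                      anchor = report_date,
                                      speech_of = rep_id)
        sub_end <- b$off
        add_clause(c(sub_start, sub_end))
        b$emit(",\" ")
        loc <- sample_location(cfg$gazetteer)
        b$emit("officials in ")
        emit_loc(loc)
        b$emit(" ")
        vspan <- b$emit(sample(REPORT_VERBS, 1L))
        b$emit(" on ")
        emit_time(report_date)
        b$emit(".")
        add_clause(c(sent_start, b$off))
        add_ep(event_predicate(rep_id, vspan, "Event_Report",
                               anchor_val = pub,
                               val = if (report_date < pub) "PAST_REF" else "PRESENT_REF",
                               stime = time_point(date = report_date),
                               etime = time_point(date = report_date),
                               stime_dir = "AS_OF", etime_dir = "AS_OF",
                               locations = loc))
        add_ep(quoted)
        k <- k + 2L
        next
      }
      if (u < cfg$p_direct_speech + cfg$p_subordinate) {
        # indirect report with a subordinate clause; the embedded predicate
        # keeps the document date as anchor
        loc <- sample_location(cfg$gazetteer)
        b$emit("Health officials in ")
        emit_loc(loc)
        b$emit(" ")
        vspan <- b$emit(sample(REPORT_VERBS, 1L))
        b$emit(" that ")
        sub_start <- b$off
        embedded <- emit_predicate_body(k + 1L, classes[k + 1L], anchor = pub)
        sub_end <- b$off
        add_clause(c(sub_start, sub_end))
        b$emit(".")
        add_clause(c(sent_start, b$off))
        rdate <- pub - sample.int(4L, 1L) + 1L
        add_ep(event_predicate(ep_id(k), vspan, "Event_Report",
                               anchor_val = pub,
                               val = if (rdate < pub) "PAST_REF" else "PRESENT_REF",
                               stime = time_point(date = rdate),
                               etime = time_point(date = rdate),
                               stime_dir = "AS_OF", etime_dir = "AS_OF",
                               locations = loc))
        add_ep(embedded)
        k <- k + 2L
        next
      }
    }
    ep <- emit_predicate_body(k, cls, anchor = pub)
    b$emit(".")
    add_clause(c(sent_start, b$off))
    add_ep(ep)
    k <- k + 1L
  }

  cu <- do.call(rbind, clauses)
  cu <- cu[order(cu$start, -cu$end), , drop = FALSE]
  annotated_document(
    doc_id = doc_id, publication_date = pub,
    text = paste0(b$buf, collapse = ""),
    location_entities = do.call(rbind, locs),
    temporal_entities = if (length(times)) do.call(rbind, times) else NULL,
    clause_units = cu,
    event_predicates = eps)
}

flatten_gold <- function(gold) {
  # -> list of list(ep = , doc_date = ), named by "<doc>/<ep id>"
  if (length(gold) && inherits(gold[[1]], "annotated_document")) {
    out <- list()
    for (doc in gold) {
      for (ep in doc$event_predicates)
        out[[paste(doc$doc_id, ep$id, sep = "/")]] <-
          list(ep = ep, doc_date = doc$publication_date)
    }
    return(out)
  }
  if (length(gold) && inherits(gold[[1]], "event_predicate")) {
    out <- lapply(gold, function(ep) list(ep = ep, doc_date = NULL))
    names(out) <- vapply(gold, `[[`, character(1), "id")
    return(out)
  }
  spatzone_error("simulate_annotator_pair: unsupported gold input",
                 "spatzone_config_error")
}

swap_direction <- function(d) sample(setdiff(TEMPORAL_DIRECTIONS, d), 1L)

shift_tp <- function(tp) {
  delta <- sample(c(-3:-1, 1:3), 1L)
  time_point(date = tp$date + delta)
}

perturb_predicate <- function(ep, spec, gaz, doc_date) {
  out <- ep
  gold_type <- ep$event_type
  out$event_type <- sample(EVENT_TYPES, 1L,
                           prob = spec$class_confusion[gold_type, ])
  if (!is_locatable_type(out$event_type)) {
    out[TEMPORAL_FIELDS] <- list(NULL, NULL, NULL, NULL, NULL, NULL)
  } else if (!is_locatable_type(gold_type)) {
    # the simulated annotator must invent temporal attributes
    out$anchor_val <- if (is.null(doc_date)) as.Date("2006-01-01") else doc_date
    out$val <- "PAST_REF"
    out$stime <- time_point(symbol = "PAST")
    out$etime <- time_point(symbol = "PRESENT")
    out$stime_dir <- "AS_OF"
    out$etime_dir <- "AS_OF"
  } else if (stats::runif(1) < spec$p_temporal_flip) {
    moves <- c(
      if (!is.null(out$stime) && out$stime$kind == "absolute") "stime",
      if (!is.null(out$etime) && out$etime$kind == "absolute") "etime",
      if (!is.null(out$stime_dir)) "stime_dir",
      if (!is.null(out$etime_dir)) "etime_dir")
    if (length(moves)) {
      mv <- if (length(moves) == 1L) moves else sample(moves, 1L)
      out[[mv]] <- switch(mv,
                          stime = shift_tp(out$stime),
                          etime = shift_tp(out$etime),
                          stime_dir = swap_direction(out$stime_dir),
                          etime_dir = swap_direction(out$etime_dir))
    }
  }
  if (spec$p_location_generalize > 0 && length(out$locations)) {
    out$locations <- unique(vapply(out$locations, function(loc) {
      if (stats::runif(1) < spec$p_location_generalize) {
        anc <- gazetteer_ancestors(gaz, loc)
        if (length(anc)) return(anc[1])
      }
      loc
    }, character(1), USE.NAMES = FALSE))
  }
  out
}

#' Simulate a pair of noisy annotators over a gold standard
#'
#' Each simulated annotator independently perturbs the gold annotation
#' according to its noise specification; item ids are preserved so the two
#' annotation sets stay aligned. The gold standard may be a corpus (list of
#' [annotated_document()]), a list of [event_predicate()] objects, or a bare
#' class-label vector (in which case only class relabeling applies and two
#' label vectors are returned).
#'
#' @param gold the gold standard (see above).
#' @param spec1,spec2 [annotator_noise_spec()] objects.
#' @param gazetteer a [gazetteer()] for location generalization; defaults to
#'   [default_gazetteer()].
#' @return list with elements `annotator1` and `annotator2`, each a named
#'   list of perturbed [event_predicate()]s (or a named label vector).
#' @export
simulate_annotator_pair <- function(gold, spec1, spec2,
                                    gazetteer = default_gazetteer()) {
  if (is.atomic(gold)) {
    labels <- as.character(gold)
    if (!all(labels %in% EVENT_TYPES))
      spatzone_error("simulate_annotator_pair: gold labels must be event types",
                     "spatzone_config_error")
    if (is.null(names(labels))) names(labels) <- sprintf("item%d", seq_along(labels))
    relabel <- function(spec) with_seed(spec$seed, function() {
      out <- vapply(labels, function(g)
        sample(EVENT_TYPES, 1L, prob = spec$class_confusion[g, ]), character(1))
      stats::setNames(out, names(labels))
    })
    return(list(annotator1 = relabel(spec1), annotator2 = relabel(spec2)))
  }
  items <- flatten_gold(gold)
  annotate <- function(spec) with_seed(spec$seed, function() {
    lapply(items, function(it)
      perturb_predicate(it$ep, spec, gazetteer, it$doc_date))
  })
  list(annotator1 = annotate(spec1), annotator2 = annotate(spec2))
}

#' Analytic expected kappa under the independent-perturbation noise model
#'
#' For gold classes drawn from `gold_class_distribution` and two annotators
#' relabeling independently through their confusion matrices, the expected
#' observed agreement is \eqn{\Pr(a) = \sum_g p_g \sum_c M_1[g,c] M_2[g,c]}
#' and the chance agreement \eqn{\Pr(e) = \sum_c q_1[c]\, q_2[c]} with
#' \eqn{q_k = p^\top M_k} the annotators' marginal label distributions —
#' the population twin of the sample kappa estimator.
#'
#' @param gold_class_distribution probabilities over [event_types()].
#' @param spec1,spec2 [annotator_noise_spec()] objects.
#' @return an `agreement_result` (with `n = NA`); degenerate marginals
#'   (`pr_e == 1`) raise the same error as [cohens_kappa()].
#' @export
expected_kappa <- function(gold_class_distribution, spec1, spec2) {
  p <- gold_class_distribution
  if (!is.null(names(p))) p <- p[EVENT_TYPES]
  p <- as.numeric(p)
  if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    spatzone_error("expected_kappa: invalid gold class distribution",
                   "spatzone_config_error")
  m1 <- spec1$class_confusion; m2 <- spec2$class_confusion
  pr_a <- sum(p * rowSums(m1 * m2))
  q1 <- as.numeric(p %*% m1); q2 <- as.numeric(p %*% m2)
  pr_e <- sum(q1 * q2)
  if (pr_e >= 1)
    spatzone_error("expected_kappa: degenerate marginals (chance agreement is certain)",
                   "spatzone_degenerate_error")
  agreement_result(pr_a = pr_a, pr_e = pr_e,
                   kappa = (pr_a - pr_e) / (1 - pr_e), n = NA_integer_)
}

#' Symmetric uniform-error noise specification
#'
#' Keeps the gold class with probability `1 - error_rate` and otherwise picks
#' one of the three other classes uniformly.
#'
#' @param error_rate misclassification probability in `[0, 0.75)`.
#' @param ... further arguments passed to [annotator_noise_spec()].
#' @return an [annotator_noise_spec()].
#' @export
uniform_error_spec <- function(error_rate, ...) {
  m <- matrix(error_rate / 3, 4, 4)
  diag(m) <- 1 - error_rate
  annotator_noise_spec(class_confusion = m, ...)
}

#' Calibrate a symmetric noise level to a target expected kappa
#'
#' Finds the uniform error rate at which two identically noisy annotators
#' have analytic [expected_kappa()] equal to the target, by root finding.
#'
#' @param target_kappa desired expected kappa in `(0, 1)`.
#' @param class_distribution gold class distribution over [event_types()].
#' @return list with `error_rate` and the corresponding
#'   [uniform_error_spec()] in `spec`.
#' @export
calibrate_noise_for_kappa <- function(target_kappa,
                                      class_distribution =
                                        generator_config()$class_distribution) {
  f <- function(e)
    expected_kappa(class_distribution, uniform_error_spec(e),
                   uniform_error_spec(e))$kappa - target_kappa
  root <- stats::uniroot(f, c(1e-9, 0.7499), tol = 1e-12)
  list(error_rate = root$root, spec = uniform_error_spec(root$root))
}

#' Bootstrap standard error of the sample kappa
#'
#' Resamples the aligned items with replacement and recomputes kappa.
#'
#' @param labels1,labels2 aligned label vectors.
#' @param B number of bootstrap replicates.
#' @param categories category set.
#' @return standard deviation of the bootstrap kappa distribution.
#' @export
bootstrap_kappa_se <- function(labels1, labels2, B = 200,
                               categories = event_types()) {
  n <- length(labels1)
  ks <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(cohens_kappa(build_confusion(unname(labels1[idx]), unname(labels2[idx]),
                                          categories))$kappa,
             error = function(e) NA_real_)
  }, numeric(1))
  stats::sd(ks, na.rm = TRUE)
}
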