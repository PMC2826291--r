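# Inter-annotator agreement suite: confusion matrices, Cohen's kappa,
# percentage agreement under pluggable comparators, per-class stratification.
#
# Kappa is reserved for the mutually exclusive event-class task; the spatial
# and temporal attributes are set-valued / composite, so simple percentage
# agreement is used for them.

align_items <- function(items1, items2) {
  n1 <- names(items1); n2 <- names(items2)
  if (!is.null(n1) && !is.null(n2)) {
    if (!setequal(n1, n2) || anyDuplicated(n1) || anyDuplicated(n2))
      spatzone_error("annotations do not cover the same item ids",
                     "spatzone_alignment_error")
    items2 <- items2[match(n1, n2)]
  } else if (length(items1) != length(items2)) {
    spatzone_error("unnamed annotations must have equal length",
                   "spatzone_alignment_error")
  }
  list(items1, items2)
}

#' Build a confusion matrix for two annotators
#'
#' Cell `[i, j]` counts the items annotator 2 labeled with category `i` and
#' annotator 1 labeled with category `j` (rows = annotator 2, columns =
#' annotator 1, matching the usual printed layout). Items are aligned by
#' name when both vectors are named, otherwise positionally.
#'
#' @param ann1,ann2 label vectors (character or factor), optionally named by
#'   item id.
#' @param categories category order; defaults to the sorted union of observed
#'   labels. A label outside `categories` is an error.
#' @return object of class `confusion_matrix` with fields `categories`,
#'   `counts` and `n`.
#' @export
build_confusion <- function(ann1, ann2, categories = NULL) {
  al <- align_items(ann1, ann2)
  a1 <- as.character(al[[1]]); a2 <- as.character(al[[2]])
  if (is.null(categories)) categories <- sort(unique(c(a1, a2)))
  if (!all(c(a1, a2) %in% categories))
    spatzone_error("labels outside the supplied categories",
                   "spatzone_alignment_error")
  counts <- table(factor(a2, levels = categories), factor(a1, levels = categories))
  counts <- matrix(as.integer(counts), nrow = length(categories),
                   dimnames = list(annotator2 = categories, annotator1 = categories))
  confusion_matrix(counts)
}

#' Construct a confusion matrix from counts
#'
#' @param counts square non-negative integer matrix; rows = annotator 2,
#'   columns = annotator 1. Row/column names supply the categories (row
#'   names take precedence).
#' @param categories optional category labels overriding the dimnames.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(counts, categories = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    spatzone_error("confusion matrix must be square", "spatzone_structural_error")
  if (any(counts < 0) || any(counts != round(counts)))
    spatzone_error("confusion matrix cells must be non-negative integers",
                   "spatzone_structural_error")
  if (is.null(categories))
    categories <- rownames(counts) %||% colnames(counts) %||%
      paste0("C", seq_len(nrow(counts)))
  dimnames(counts) <- list(annotator2 = categories, annotator1 = categories)
  structure(list(categories = categories,
                 counts = counts,
                 n = sum(counts)),
            class = "confusion_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix: %d categories, n = %d>\n",
              length(x$categories), x$n))
  print(x$counts)
  invisible(x)
}

#' Cohen's kappa for a two-annotator confusion matrix
#'
#' Computes the chance-corrected agreement coefficient
#' \eqn{\kappa = (\Pr(a) - \Pr(e)) / (1 - \Pr(e))}, where \eqn{\Pr(a)} is the
#' observed agreement (the diagonal proportion) and \eqn{\Pr(e)} the chance
#' agreement expected from the two annotators' marginal category
#' distributions. \eqn{\kappa \le 0} means no agreement beyond chance;
#' \eqn{\kappa = 1} complete agreement.
#'
#' @param m a [confusion_matrix()] or a plain square count matrix.
#' @return object of class `agreement_result` with fields `pr_a`, `pr_e`,
#'   `kappa` and `n`. Degenerate marginals making chance agreement certain
#'   (`pr_e == 1`) raise an error.
#' @examples
#' m <- confusion_matrix(matrix(c(25, 25, 25, 25), 2))
#' cohens_kappa(m)$kappa # 0: observed equals chance
#' @export
cohens_kappa <- function(m) {
  if (!inherits(m, "confusion_matrix")) m <- confusion_matrix(m)
  if (m$n == 0L)
    spatzone_error("cohens_kappa: empty confusion matrix", "spatzone_empty_input_error")
  counts <- m$counts
  pr_a <- sum(diag(counts)) / m$n
  pr_e <- sum((rowSums(counts) / m$n) * (colSums(counts) / m$n))
  if (pr_e >= 1)
    spatzone_error("cohens_kappa: degenerate marginals (chance agreement is certain)",
                   "spatzone_degenerate_error")
  agreement_result(pr_a = pr_a, pr_e = pr_e,
                   kappa = (pr_a - pr_e) / (1 - pr_e), n = m$n)
}

agreement_result <- function(pr_a, pr_e, kappa, n) {
  structure(list(pr_a = pr_a, pr_e = pr_e, kappa = kappa, n = n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, digits = 4, ...) {
  cat(sprintf("<agreement_result: kappa = %.*f (Pr(a) = %.*f, Pr(e) = %.*f, n = %s)>\n",
              digits, x$kappa, digits, x$pr_a, digits, x$pr_e,
              if (is.na(x$n)) "NA" else format(x$n)))
  invisible(x)
}

#' Percentage agreement under a pluggable comparator
#'
#' The proportion of aligned items on which the comparator holds. Used for
#' the set-valued spatial attribute and the composite temporal attributes,
#' where the annotation task is not a mutually exclusive classification and
#' kappa therefore does not apply.
#'
#' @param items1,items2 lists or vectors of annotations, optionally named by
#'   item id (aligned by name when both are named).
#' @param comparator predicate `function(a, b)` returning `TRUE` on
#'   agreement; defaults to [identical()].
#' @return proportion in `[0, 1]`. An empty item set is an error.
#' @export
percentage_agreement <- function(items1, items2, comparator = identical) {
  al <- align_items(items1, items2)
  if (length(al[[1]]) == 0L)
    spatzone_error("percentage_agreement: empty item set",
                   "spatzone_empty_input_error")
  hits <- mapply(function(a, b) isTRUE(comparator(a, b)), al[[1]], al[[2]],
                 SIMPLIFY = TRUE, USE.NAMES = FALSE)
  mean(hits)
}

#' Temporal agreement comparator
#'
#' Two annotations of an event-predicate are temporally agreed only when all
#' six temporal attributes (`anchor_val`, `val`, `stime`, `etime`,
#' `stime_dir`, `etime_dir`) were marked identically; a symbolic time point
#' never equals an absolute one.
#'
#' @param a,b [event_predicate()] annotations of the same item; both must be
#'   temporally locatable (otherwise a domain error is raised).
#' @return logical scalar.
#' @export
temporal_comparator <- function(a, b) {
  if (!is_locatable_type(a$event_type) || !is_locatable_type(b$event_type))
    spatzone_error("temporal_comparator: both annotations must be temporally locatable",
                   "spatzone_domain_error")
  null_safe_equal(a$anchor_val, b$anchor_val) &&
    null_safe_equal(a$val, b$val) &&
    time_points_equal(a$stime, b$stime) &&
    time_points_equal(a$etime, b$etime) &&
    null_safe_equal(a$stime_dir, b$stime_dir) &&
    null_safe_equal(a$etime_dir, b$etime_dir)
}

#' Normalize a location surface string for comparison
#'
#' Case-insensitive, whitespace-collapsed, with canonical comma spacing
#' (`"Bangkok , Thailand"` becomes `"bangkok, thailand"`). Normalization
#' keeps composite strings distinct from their parts, so
#' `"Bangkok, Thailand"` and `"Bangkok"` differ under exact comparison while
#' the approximate comparator can still match them.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_location <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\s+", " ", x)
  gsub("\\s*,\\s*", ", ", x)
}

get_locations <- function(x) {
  if (inherits(x, "event_predicate")) x$locations else as.character(x)
}

location_tokens <- function(x) {
  toks <- strsplit(x, "[,[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

token_subsequence <- function(a, b) {
  # tokens of a appear, in order, among tokens of b
  ta <- location_tokens(a); tb <- location_tokens(b)
  if (!length(ta) || length(ta) > length(tb)) return(FALSE)
  i <- 1L
  for (t in tb) {
    if (t == ta[i]) {
      i <- i + 1L
      if (i > length(ta)) return(TRUE)
    }
  }
  FALSE
}

#' Exact spatial agreement comparator
#'
#' Agreement requires the two location sets to be equal after
#' [normalize_location()]. Two empty sets (no location annotated by either
#' annotator) count as agreement.
#'
#' @param a,b [event_predicate()] objects or character vectors of location
#'   surface strings.
#' @return logical scalar.
#' @export
spatial_exact_comparator <- function(a, b) {
  setequal(normalize_location(get_locations(a)),
           normalize_location(get_locations(b)))
}

#' Approximate spatial agreement comparator
#'
#' Accepts partial agreement or partitive inclusion: two locations match when
#' they are equal after normalization, when one is an in-order token
#' subsequence of the other (`"Bangkok, Thailand"` vs `"Bangkok"`), or when
#' the gazetteer contains one within the other in either direction
#' (`"Tokyo"` within `"Japan"`). Locations absent from the gazetteer simply
#' disable the containment criterion for that pair. Under the default
#' lenient criterion (`mode = "some"`) the two sets agree when any pair
#' across them matches; `mode = "all"` requires every location on each side
#' to match something on the other side. Exact agreement implies approximate
#' agreement under either mode.
#'
#' @param a,b [event_predicate()] objects or character vectors of location
#'   surface strings.
#' @param gazetteer a [gazetteer()] providing partitive relations, or `NULL`
#'   to use only equality and token-subsequence matching.
#' @param mode matching criterion, `"some"` (default) or `"all"`.
#' @return logical scalar.
#' @export
spatial_approx_comparator <- function(a, b, gazetteer = NULL,
                                      mode = c("some", "all")) {
  mode <- match.arg(mode)
  A <- unique(normalize_location(get_locations(a)))
  B <- unique(normalize_location(get_locations(b)))
  if (!length(A) && !length(B)) return(TRUE)
  if (!length(A) || !length(B)) return(FALSE)
  pair_match <- function(x, y) {
    if (x == y) return(TRUE)
    if (token_subsequence(x, y) || token_subsequence(y, x)) return(TRUE)
    if (!is.null(gazetteer) &&
        (gazetteer_contains(gazetteer, x, y) || gazetteer_contains(gazetteer, y, x)))
      return(TRUE)
    FALSE
  }
  hits <- outer(A, B, Vectorize(pair_match))
  if (mode == "some") any(hits) else all(rowSums(hits) > 0) && all(colSums(hits) > 0)
}

#' Per-class percentage agreement
#'
#' Stratifies the items by event class and reports the percentage agreement
#' within each class plus the pooled value under `"All classes"`. By default
#' the stratum of an item is the class assigned by annotator 1; classes with
#' no items are omitted.
#'
#' @param items1,items2 aligned annotation lists/vectors (see
#'   [percentage_agreement()]).
#' @param comparator agreement predicate.
#' @param classes optional explicit class label vector (one per item);
#'   otherwise derived from the `event_type` of the stratifying annotator's
#'   items.
#' @param stratify_by which annotator's class defines the stratum when
#'   `classes` is not given.
#' @return named numeric vector of proportions, ending with `"All classes"`.
#' @export
per_class_agreement <- function(items1, items2, comparator = identical,
                                classes = NULL,
                                stratify_by = c("annotator1", "annotator2")) {
  stratify_by <- match.arg(stratify_by)
  al <- align_items(items1, items2)
  if (is.null(classes)) {
    src <- if (stratify_by == "annotator1") al[[1]] else al[[2]]
    classes <- vapply(src, function(x) {
      if (inherits(x, "event_predicate")) x$event_type else as.character(x)
    }, character(1))
  }
  if (length(classes) != length(al[[1]]))
    spatzone_error("per_class_agreement: `classes` length does not match items",
                   "spatzone_alignment_error")
  out <- numeric()
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    out[cl] <- percentage_agreement(al[[1]][idx], al[[2]][idx], comparator)
  }
  out["All classes"] <- percentage_agreement(al[[1]], al[[2]], comparator)
  out
}

#' Read/write confusion matrices as CSV
#'
#' The CSV carries a header row of category labels and one row per
#' annotator-2 category, with the category label in the first column.
#'
#' @param path file path.
#' @return `read_confusion_csv()` a [confusion_matrix()];
#'   `write_confusion_csv()` the path, invisibly.
#' @export
read_confusion_csv <- function(path) {
  x <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(x)
  if (!identical(rownames(m), colnames(m)))
    spatzone_error("confusion CSV: row and column categories differ",
                   "spatzone_structural_error")
  confusion_matrix(m)
}

#' @rdname read_confusion_csv
#' @param m a [confusion_matrix()].
#' @export
write_confusion_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m$counts[, , drop = FALSE]), path)
  invisible(path)
}

#' Write an agreement report as JSON
#'
#' @param report a named list or vector of agreement figures (e.g. the output
#'   of [per_class_agreement()] or [cohens_kappa()]).
#' @param path file path, or `NULL` to return the JSON string.
#' @export
write_agreement_json <- function(report, path = NULL) {
  if (inherits(report, "agreement_result")) report <- unclass(report)
  json <- jsonlite::toJSON(as.list(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
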