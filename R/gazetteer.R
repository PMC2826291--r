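# Hierarchical location gazetteer: partitive (contained-in) relations over
# location names, used for approximate spatial agreement.

#' Construct a gazetteer
#'
#' A gazetteer is a forest of location names linked by partitive
#' (contained-in) relations, e.g. city within province within country. Names
#' must be unique and the parent chains acyclic. Lookups are performed on
#' [normalize_location()] forms, so case and spacing differences do not
#' matter.
#'
#' @param x data frame with columns `name` and `parent` (empty string or `NA`
#'   for roots).
#' @return object of class `gazetteer`.
#' @export
gazetteer <- function(x) {
  x <- as.data.frame(x)
  if (!all(c("name", "parent") %in% names(x)))
    spatzone_error("gazetteer needs columns `name` and `parent`",
                   "spatzone_structural_error")
  x$name <- as.character(x$name)
  x$parent <- as.character(x$parent)
  x$parent[is.na(x$parent)] <- ""
  key <- normalize_location(x$name)
  if (anyDuplicated(key))
    spatzone_error("gazetteer: duplicate location names", "spatzone_structural_error")
  pkey <- normalize_location(x$parent)
  pkey[!nzchar(x$parent)] <- ""
  parent_idx <- match(pkey, key)
  # acyclicity: walk every chain; a chain longer than the node count loops
  for (i in seq_along(key)) {
    j <- i; steps <- 0L
    while (!is.na(j)) {
      j <- parent_idx[j]; steps <- steps + 1L
      if (steps > length(key))
        spatzone_error("gazetteer: containment cycle detected", "spatzone_structural_error")
    }
  }
  structure(list(name = x$name, key = key, parent_idx = parent_idx),
            class = "gazetteer")
}

#' @export
print.gazetteer <- function(x, ...) {
  cat(sprintf("<gazetteer: %d locations, %d roots>\n",
              length(x$name), sum(is.na(x$parent_idx))))
  invisible(x)
}

#' Read a gazetteer from a two-column TSV
#'
#' Each row is `name <TAB> parent-name`; root rows leave the parent empty.
#' No header row.
#'
#' @param path file path.
#' @return a [gazetteer()].
#' @export
read_gazetteer <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  gazetteer(data.frame(
    name = vapply(parts, `[`, character(1), 1),
    parent = vapply(parts, function(p) if (length(p) > 1L) p[2] else "",
                    character(1))))
}

#' Write a gazetteer to a two-column TSV
#'
#' @param g a [gazetteer()].
#' @param path file path.
#' @export
write_gazetteer <- function(g, path) {
  parent <- ifelse(is.na(g$parent_idx), "", g$name[g$parent_idx])
  utils::write.table(data.frame(g$name, parent), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Ancestors of a location in the gazetteer
#'
#' @param g a [gazetteer()].
#' @param name location name (matched after [normalize_location()]).
#' @return character vector of ancestor names from immediate parent to root;
#'   empty when the name is a root or absent from the gazetteer.
#' @export
gazetteer_ancestors <- function(g, name) {
  i <- match(normalize_location(name), g$key)
  out <- character()
  while (!is.na(i)) {
    i <- g$parent_idx[i]
    if (!is.na(i)) out <- c(out, g$name[i])
  }
  out
}

#' Partitive containment test
#'
#' @param g a [gazetteer()].
#' @param inner,outer location names.
#' @return `TRUE` iff `outer` is a (transitive) gazetteer ancestor of
#'   `inner`. Names absent from the gazetteer yield `FALSE`, never an error.
#' @export
gazetteer_contains <- function(g, inner, outer) {
  normalize_location(outer) %in% normalize_location(gazetteer_ancestors(g, inner))
}
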