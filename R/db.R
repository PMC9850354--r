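# Local candidate-structure database: a plain-text, tab-separated file
# with one record per line ("id<TAB>name<TAB>structure"), '#' comments.
# Stands in for an online glycan sequence repository so that candidate
# lookup works offline.

#' Read a glycan structure database
#'
#' @param path Path to a UTF-8 text file with one record per line:
#'   `id<TAB>name<TAB>structure` in condensed notation (see
#'   [parse_glycan()]). Lines starting with `#` and blank lines are
#'   ignored.
#' @param registry Monosaccharide registry.
#' @return A `glycan_db`: list with `records` (list of records, each
#'   holding `id`, `name`, `structure`, `glycan`, `native_mass`,
#'   `permethylated_mz`) in file order, plus lookup vectors.
#' @export
read_glycan_db <- function(path, registry = monosaccharide_registry()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("malformed database line ", i, ": expected id<TAB>name<TAB>structure",
           call. = FALSE)
    }
    g <- parse_glycan(f[3], registry = registry)
    comp <- glycan_composition_of(g, registry)
    records[[i]] <- list(
      id = f[1], name = f[2], structure = f[3], glycan = g,
      composition = comp,
      native_mass = native_mass(comp, registry),
      permethylated_mz = permethylated_mz(comp, registry)
    )
  }
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in database: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(
    list(records = records,
         id = ids,
         name = vapply(records, `[[`, character(1), "name"),
         native_mass = vapply(records, `[[`, numeric(1), "native_mass"),
         permethylated_mz = vapply(records, `[[`, numeric(1),
                                   "permethylated_mz")),
    class = "glycan_db"
  )
}

#' Packaged fixture databases
#'
#' `gips_db("standards")` loads the milk-oligosaccharide standards
#' (lacto-N-tetraose family, fucopentaoses, difucohexaoses, hexaoses,
#' blood-group and globo-series standards); `gips_db("hmo")` loads
#' human milk oligosaccharide backbone structures for degrees of
#' polymerization 4 to 9. Entries whose linkage assignment is a
#' constructed variant rather than a literature structure carry a
#' `syn` marker in their id.
#'
#' @param which `"standards"` or `"hmo"`.
#' @return A `glycan_db`.
#' @export
gips_db <- function(which = c("standards", "hmo")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".tsv"), package = "gipsmix",
                      mustWork = TRUE)
  read_glycan_db(path)
}

#' @export
print.glycan_db <- function(x, ...) {
  cat("<glycan_db> ", length(x$records), " records\n", sep = "")
  df <- data.frame(id = x$id, name = x$name,
                   permethylated_mz = round(x$permethylated_mz, 4))
  print(utils::head(df, 20), row.names = FALSE)
  if (length(x$records) > 20) cat("  ...\n")
  invisible(x)
}

#' Candidate lookup by observed precursor m/z
#'
#' Returns every database record whose permethylated, sodiated
#' molecular m/z lies within `tol` of the observed precursor, in
#' database (insertion) order. An empty list is a valid result.
#'
#' @param db A `glycan_db`.
#' @param precursor_mz Observed MNa+ m/z.
#' @param tol Matching tolerance in Da (default 0.5).
#' @return List of matching records.
#' @export
find_candidates <- function(db, precursor_mz, tol = 0.5) {
  stopifnot(inherits(db, "glycan_db"), tol > 0)
  hit <- abs(db$permethylated_mz - precursor_mz) <= tol
  db$records[hit]
}

#' Partition candidate records into branching patterns
#'
#' Groups records by rooted-tree isomorphism of their structures
#' (linkage annotations ignored) and returns one representative glycan
#' per pattern, in order of first occurrence. This is the collapse
#' from database isomers to distinct branching patterns.
#'
#' @param records List of records as returned by [find_candidates()],
#'   or a list of `glycan` objects.
#' @return A list of representative `glycan`s; each carries attributes
#'   `members` (indices of the input records in its class) and
#'   `member_ids` (their ids, when available).
#' @export
branching_pattern_classes <- function(records) {
  stopifnot(is.list(records), length(records) >= 1L)
  trees <- lapply(records, function(r) {
    if (inherits(r, "glycan")) r else r$glycan
  })
  sigs <- vapply(trees, glycan_signature, character(1))
  classes <- unique(sigs)
  out <- vector("list", length(classes))
  for (k in seq_along(classes)) {
    members <- which(sigs == classes[k])
    rep_tree <- trees[[members[1]]]
    attr(rep_tree, "members") <- members
    ids <- vapply(records[members], function(r) {
      if (inherits(r, "glycan")) NA_character_ else r$id
    }, character(1))
    attr(rep_tree, "member_ids") <- ids
    out[[k]] <- rep_tree
  }
  out
}
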