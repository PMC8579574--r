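# Generic engine for conjunctive threshold rule sets: an ordered list of
# paths, each a conjunction of (field, op, threshold) conditions mapping a
# record to IDA or BTT. A valid rule set partitions the record space:
# paths are mutually exclusive and jointly exhaustive (see audit_ruleset).

#' Build a conjunctive threshold rule set
#'
#' @param name Rule set name.
#' @param paths A list of paths; each path is
#'   `list(conditions = list(list(field=, op=, threshold=), ...), label =)`.
#'   `op` is `"<="` or `">"`; `label` is `"IDA"` or `"BTT"`.
#' @return An object of class `ruleset`.
#' @seealso [cruise_ruleset()], [predict_ruleset()], [audit_ruleset()]
#' @export
ruleset <- function(name, paths) {
  stopifnot(is.character(name), length(paths) >= 1)
  for (p in paths) {
    if (!p$label %in% CLASS_LEVELS) {
      abort(sprintf("Path label must be one of %s.",
                    paste(CLASS_LEVELS, collapse = ", ")))
    }
    for (cond in p$conditions) {
      if (!cond$op %in% c("<=", ">")) abort("Condition op must be '<=' or '>'.")
      if (!is.finite(cond$threshold)) abort("Condition threshold must be finite.")
      if (!is.character(cond$field)) abort("Condition field must be a string.")
    }
  }
  structure(list(name = name, paths = paths), class = "ruleset")
}

#' @export
print.ruleset <- function(x, ...) {
  cat(sprintf("Rule set '%s' (%d paths):\n", x$name, length(x$paths)))
  for (p in x$paths) {
    conds <- vapply(p$conditions,
                    function(cc) sprintf("%s %s %g", cc$field, cc$op, cc$threshold),
                    character(1))
    cat(sprintf("  %s -> %s\n", paste(conds, collapse = " & "), p$label))
  }
  invisible(x)
}

ruleset_fields <- function(rules) {
  unique(unlist(lapply(rules$paths, function(p)
    vapply(p$conditions, function(cc) cc$field, character(1)))))
}

#' The published six-leaf CRUISE decision rules
#'
#' The CRUISE classification-tree rule set for discriminating IDA from BTT
#' on MCV (fL), Hb (g/dL) and MCHC (g/dL). BTT is predicted for
#' MCV > 71.25; for 67.65 < MCV <= 71.25 with Hb <= 11.15; and for
#' MCV <= 67.65 with Hb <= 8.85 and MCHC <= 30.32. The remaining three
#' regions predict IDA. As printed, the first BTT condition overlaps the
#' second; the `MCV > 71.25` reading is the unique resolution yielding six
#' mutually exclusive, jointly exhaustive subgroups, and is what this
#' function implements.
#'
#' @return A [ruleset()] with 6 paths.
#' @export
#' @examples
#' audit_ruleset(cruise_ruleset())
cruise_ruleset <- function() {
  read_ruleset(system.file("extdata", "cruise.json",
                           package = "hemodiscrim", mustWork = TRUE))
}

#' Read / write rule sets as JSON
#'
#' Format: `{name, paths: [{conditions: [{field, op, threshold}], label}]}`.
#'
#' @param path File path.
#' @return `read_ruleset()`: a [ruleset()]. `write_ruleset()`: `path`,
#'   invisibly.
#' @export
read_ruleset <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ruleset(raw$name, raw$paths)
}

#' @rdname read_ruleset
#' @param rules A [ruleset()].
#' @export
write_ruleset <- function(rules, path) {
  jsonlite::write_json(unclass(rules), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

path_matches <- function(p, records) {
  ok <- rep(TRUE, nrow(records))
  for (cond in p$conditions) {
    v <- records[[cond$field]]
    ok <- ok & if (cond$op == "<=") v <= cond$threshold else v > cond$threshold
  }
  ok
}

#' Classify records with a rule set
#'
#' Each record must match exactly one path; zero or multiple matches signal
#' an invalid rule set and raise an error.
#'
#' @param rules A [ruleset()].
#' @param records Data frame with every field the rule set references.
#' @return Character vector of class labels (`"IDA"`/`"BTT"`), one per row.
#' @export
#' @examples
#' predict_ruleset(cruise_ruleset(),
#'                 data.frame(mcv = 70, hb = 11.5, mchc = 31))  # "IDA"
predict_ruleset <- function(rules, records) {
  stopifnot(inherits(rules, "ruleset"))
  records <- tibble::as_tibble(records)
  flds <- ruleset_fields(rules)
  missing_fld <- setdiff(flds, names(records))
  if (length(missing_fld) > 0) {
    abort(sprintf("Rule set '%s' requires missing field(s): %s.",
                  rules$name, paste(missing_fld, collapse = ", ")))
  }
  for (f in flds) {
    if (anyNA(records[[f]])) {
      abort(sprintf("Rule set '%s': field '%s' has missing values.",
                    rules$name, f))
    }
  }
  hits <- vapply(rules$paths, path_matches, logical(nrow(records)),
                 records = records)
  hits <- matrix(hits, nrow = nrow(records))
  n_hit <- rowSums(hits)
  if (any(n_hit != 1)) {
    abort(sprintf(
      "Rule set '%s' is not a partition: %d record(s) matched %s paths.",
      rules$name, sum(n_hit != 1),
      if (any(n_hit == 0)) "zero" else "multiple"))
  }
  labels <- vapply(rules$paths, function(p) p$label, character(1))
  labels[apply(hits, 1, which)]
}

#' Audit a rule set for exclusivity and exhaustiveness
#'
#' Enumerates every region of the grid induced by the rule set's thresholds
#' (one representative point per axis-aligned cell, including points exactly
#' at each threshold, which fall on the `<=` side) and counts matching
#' paths per region. The rule set is exclusive if no region matches more
#' than one path and exhaustive if every region matches at least one.
#'
#' @param rules A [ruleset()].
#' @return A list: `exclusive`, `exhaustive` (logical), `leaf_count`
#'   (number of paths), and `regions`, a tibble of representative points
#'   with their match counts.
#' @export
#' @examples
#' audit_ruleset(cruise_ruleset())[c("exclusive", "exhaustive", "leaf_count")]
audit_ruleset <- function(rules) {
  stopifnot(inherits(rules, "ruleset"))
  flds <- ruleset_fields(rules)
  reps <- lapply(flds, function(f) {
    th <- sort(unique(unlist(lapply(rules$paths, function(p) {
      vapply(Filter(function(cc) cc$field == f, p$conditions),
             function(cc) cc$threshold, numeric(1))
    }))))
    # one point per open interval between thresholds plus each threshold
    # itself (the boundary belongs to the '<=' side)
    pts <- c(th, th[1] - 1, th[length(th)] + 1)
    if (length(th) > 1) pts <- c(pts, (head(th, -1) + tail(th, -1)) / 2)
    sort(pts)
  })
  names(reps) <- flds
  grid <- tidyr::expand_grid(!!!reps)
  hits <- vapply(rules$paths, path_matches, logical(nrow(grid)),
                 records = grid)
  hits <- matrix(hits, nrow = nrow(grid))
  grid$n_matching <- rowSums(hits)
  list(exclusive = all(grid$n_matching <= 1),
       exhaustive = all(grid$n_matching >= 1),
       leaf_count = length(rules$paths),
       regions = grid)
}
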