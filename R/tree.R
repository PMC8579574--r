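# Demonstrative greedy classification tree: exhaustive axis-aligned
# threshold search at midpoints between consecutive distinct predictor
# values, best Gini decrease, recursive partitioning. Deterministic: ties
# are broken by the alphabetically lowest field name, then the lowest
# threshold. This is a pipeline stand-in, not a reimplementation of any
# published unbiased-split algorithm.

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  1 - sum(p^2)
}

# best (field, threshold, decrease) over all predictors for one node;
# decrease is the plain Gini decrease at the node (not weighted by node size)
best_split <- function(x, y, predictors, min_leaf) {
  n <- length(y)
  parent <- gini_impurity(table(y))
  best <- NULL
  for (f in predictors) {
    v <- x[[f]]
    ord <- order(v)
    vs <- v[ord]
    ys <- y[ord] == CLASS_LEVELS[2]  # BTT indicator
    distinct <- which(diff(vs) > 0)
    if (length(distinct) == 0) next
    cum_pos <- cumsum(ys)
    nl <- distinct
    nr <- n - nl
    ok <- nl >= min_leaf & nr >= min_leaf
    if (!any(ok)) next
    pos_l <- cum_pos[distinct]
    pos_r <- sum(ys) - pos_l
    gl <- 1 - ((pos_l / nl)^2 + ((nl - pos_l) / nl)^2)
    gr <- 1 - ((pos_r / nr)^2 + ((nr - pos_r) / nr)^2)
    dec <- parent - (nl / n) * gl - (nr / n) * gr
    dec[!ok] <- -Inf
    i <- which.max(dec)  # first (lowest threshold) among equal decreases
    cand <- list(field = f, threshold = (vs[distinct[i]] + vs[distinct[i] + 1]) / 2,
                 decrease = dec[i])
    if (is.null(best) || cand$decrease > best$decrease + 1e-12) best <- cand
    # equal decrease: keep existing (fields iterated in sorted order)
  }
  best
}

grow_node <- function(x, y, predictors, depth, max_depth, min_leaf, n_root) {
  counts <- table(factor(y, levels = CLASS_LEVELS))
  majority <- CLASS_LEVELS[which.max(counts)]  # tie -> IDA (first level)
  leaf <- list(type = "leaf", label = majority, n = length(y),
               counts = as.integer(counts))
  if (depth >= max_depth || length(unique(y)) == 1 || length(y) < 2 * min_leaf) {
    return(leaf)
  }
  sp <- best_split(x, y, predictors, min_leaf)
  if (is.null(sp) || sp$decrease <= 1e-12) return(leaf)
  go_left <- x[[sp$field]] <= sp$threshold
  list(type = "split", field = sp$field, threshold = sp$threshold,
       decrease = sp$decrease, weighted_decrease = sp$decrease * length(y) / n_root,
       n = length(y), counts = as.integer(counts),
       left = grow_node(x[go_left, , drop = FALSE], y[go_left], predictors,
                        depth + 1, max_depth, min_leaf, n_root),
       right = grow_node(x[!go_left, , drop = FALSE], y[!go_left], predictors,
                         depth + 1, max_depth, min_leaf, n_root))
}

#' Fit a greedy Gini classification tree
#'
#' @param cohort Labeled data frame; the `label` column holds
#'   `"IDA"`/`"BTT"`.
#' @param predictors Character vector of numeric predictor columns;
#'   defaults to the CBC panel columns present
#'   (`hb, hct, mcv, mch, mchc, rbc, rdw`).
#' @param max_depth Maximum tree depth (root = depth 0). Default 4.
#' @param min_leaf Minimum records per leaf. Default 5.
#' @return A `greedy_tree` object; see [predict.greedy_tree()],
#'   [variable_importance()], [as_ruleset()].
#' @export
#' @examples
#' coh <- generate_cohort(simulation_config(n_btt = 60, n_ida = 40, seed = 2))
#' tr <- fit_greedy_tree(coh, max_depth = 2)
#' variable_importance(tr)
fit_greedy_tree <- function(cohort, predictors = NULL, max_depth = 4,
                            min_leaf = 5) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    abort("`cohort` must be a non-empty labeled data frame.")
  }
  if (!"label" %in% names(cohort)) abort("`cohort` needs a `label` column.")
  y <- as.character(cohort$label)
  if (!all(y %in% CLASS_LEVELS)) {
    abort("Labels must be 'IDA' or 'BTT'.")
  }
  if (length(unique(y)) < 2) {
    abort("Fitting requires at least two classes in `cohort`.")
  }
  predictors <- predictors %||%
    intersect(c("hb", "hct", "mcv", "mch", "mchc", "rbc", "rdw"), names(cohort))
  predictors <- sort(predictors)
  if (length(predictors) == 0) abort("No numeric predictors available.")
  x <- as.data.frame(cohort[predictors])
  for (f in predictors) {
    if (!is.numeric(x[[f]]) || anyNA(x[[f]])) {
      abort(sprintf("Predictor '%s' must be numeric without missing values.", f))
    }
  }
  root <- grow_node(x, y, predictors, 0L, max_depth, min_leaf, nrow(x))
  structure(list(root = root, predictors = predictors,
                 params = list(max_depth = max_depth, min_leaf = min_leaf),
                 n = nrow(x)),
            class = "greedy_tree")
}

traverse <- function(node, records) {
  if (node$type == "leaf") return(rep(node$label, nrow(records)))
  out <- character(nrow(records))
  go_left <- records[[node$field]] <= node$threshold
  if (any(go_left)) out[go_left] <- traverse(node$left, records[go_left, , drop = FALSE])
  if (any(!go_left)) out[!go_left] <- traverse(node$right, records[!go_left, , drop = FALSE])
  out
}

#' @export
predict.greedy_tree <- function(object, newdata, ...) {
  newdata <- tibble::as_tibble(newdata)
  missing_fld <- setdiff(tree_fields(object$root), names(newdata))
  if (length(missing_fld) > 0) {
    abort(sprintf("Tree requires missing field(s): %s.",
                  paste(missing_fld, collapse = ", ")))
  }
  traverse(object$root, newdata)
}

tree_fields <- function(node) {
  if (node$type == "leaf") return(character(0))
  unique(c(node$field, tree_fields(node$left), tree_fields(node$right)))
}

tree_depth <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

tree_leaves <- function(node) {
  if (node$type == "leaf") return(1L)
  tree_leaves(node$left) + tree_leaves(node$right)
}

#' @export
print.greedy_tree <- function(x, ...) {
  cat(sprintf("Greedy Gini tree: %d leaves, depth %d, n = %d\n",
              tree_leaves(x$root), tree_depth(x$root), x$n))
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s* %s (n=%d)\n", pad, node$label, node$n))
    } else {
      cat(sprintf("%s%s <= %g:\n", pad, node$field, node$threshold))
      show(node$left, indent + 1)
      cat(sprintf("%s%s > %g:\n", pad, node$field, node$threshold))
      show(node$right, indent + 1)
    }
  }
  show(x$root, 0)
  invisible(x)
}

#' Normalized variable importance of a fitted tree
#'
#' Importance of a predictor is its total size-weighted Gini decrease over
#' all splits using it, rescaled so the largest value is 100. Predictors
#' the tree never uses (including all of them, for a single-leaf tree)
#' score 0.
#'
#' @param tree A [fit_greedy_tree()] object.
#' @return A tibble `field`, `importance`, sorted decreasing.
#' @export
variable_importance <- function(tree) {
  stopifnot(inherits(tree, "greedy_tree"))
  acc <- setNames(numeric(length(tree$predictors)), tree$predictors)
  walk <- function(node) {
    if (node$type == "split") {
      acc[node$field] <<- acc[node$field] + node$weighted_decrease
      walk(node$left); walk(node$right)
    }
  }
  walk(tree$root)
  if (max(acc) > 0) acc <- 100 * acc / max(acc)
  tibble::tibble(field = names(acc), importance = unname(acc)) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$field)
}

#' Convert a fitted tree to an equivalent rule set
#'
#' Enumerates root-to-leaf paths; predictions from the resulting
#' [ruleset()] agree with direct tree traversal on every record.
#'
#' @param tree A [fit_greedy_tree()] object.
#' @param name Name for the rule set.
#' @return A [ruleset()].
#' @export
as_ruleset <- function(tree, name = "greedy_tree") {
  stopifnot(inherits(tree, "greedy_tree"))
  paths <- list()
  walk <- function(node, conds) {
    if (node$type == "leaf") {
      paths[[length(paths) + 1]] <<- list(conditions = conds, label = node$label)
    } else {
      walk(node$left, c(conds, list(list(field = node$field, op = "<=",
                                         threshold = node$threshold))))
      walk(node$right, c(conds, list(list(field = node$field, op = ">",
                                          threshold = node$threshold))))
    }
  }
  walk(tree$root, list())
  ruleset(name, paths)
}

#' @method tidy greedy_tree
#' @export
tidy.greedy_tree <- function(x, ...) {
  rows <- list()
  walk <- function(nd, id, depth) {
    is_leaf <- nd$type == "leaf"
    rows[[length(rows) + 1]] <<- tibble::tibble(
      node = id, depth = depth, type = nd$type,
      field = if (is_leaf) NA_character_ else nd$field,
      threshold = if (is_leaf) NA_real_ else nd$threshold,
      decrease = if (is_leaf) NA_real_ else nd$weighted_decrease,
      n = nd$n,
      label = if (is_leaf) nd$label else NA_character_)
    if (!is_leaf) {
      walk(nd$left, 2 * id, depth + 1)
      walk(nd$right, 2 * id + 1, depth + 1)
    }
  }
  walk(x$root, 1L, 0L)
  dplyr::bind_rows(rows)
}

#' @method glance greedy_tree
#' @export
glance.greedy_tree <- function(x, ...) {
  tibble::tibble(n = x$n, n_leaves = tree_leaves(x$root),
                 depth = tree_depth(x$root),
                 max_depth = x$params$max_depth,
                 min_leaf = x$params$min_leaf)
}
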