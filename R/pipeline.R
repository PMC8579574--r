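# End-to-end comparison pipeline: classify a labeled cohort with every
# registry index, any rule sets and a freshly fitted greedy tree; score
# all methods with the accuracy suite; embed and cluster the per-method
# performance profiles.

#' Published per-method summary accuracy values
#'
#' Youden's index, accuracy, F-measure (all %) and AUC for the 52
#' discrimination methods (43 indices, 8 tree algorithms with CART/GUIDE
#' sharing one row, and an SVM) as printed by a published 1178-patient
#' comparative study (708 BTT, 470 IDA). With those class sizes each row's
#' Youden + accuracy determine the method's integer confusion matrix via
#' [recover_confusion_from_summary()], which makes the remaining printed
#' measures reproducible.
#'
#' @return A tibble: `method`, `type`, `youden`, `accuracy`, `f_measure`,
#'   `auc`.
#' @export
published_summary <- function() {
  path <- system.file("extdata", "published_summary.csv",
                      package = "hemodiscrim", mustWork = TRUE)
  readr::read_csv(path, col_types = "ccdddd") |>
    dplyr::mutate(dplyr::across(c("youden", "accuracy", "f_measure", "auc"),
                                as.numeric))
}

confusion_from_long <- function(preds, truth_tbl) {
  joined <- dplyr::inner_join(preds, truth_tbl, by = "patient_id")
  ok <- !is.na(joined$prediction)
  if (!any(ok)) return(NULL)
  confusion_matrix(joined$label[ok], joined$prediction[ok])
}

#' Run the full discrimination comparison on a labeled cohort
#'
#' For every registry index, every supplied rule set, and (optionally) a
#' greedy tree fitted to the cohort itself, computes the 13-measure
#' accuracy suite, the empirical ROC/AUC (continuous index values where
#' available, 0/1 predictions for rule sets and trees), the 10-measure
#' performance profiles, their classical MDS embedding, the
#' complete-linkage dendrogram, and the majority-vote cluster count.
#' Methods whose profile contains undefined measures (e.g. NLR with zero
#' specificity) are excluded from the similarity stage with a message.
#'
#' @param cohort Labeled cohort (e.g. from [generate_cohort()] or
#'   [apply_inclusion_exclusion()]).
#' @param registry Index registry; default the built-in 43.
#' @param rulesets List of [ruleset()] objects; default the CRUISE rules.
#' @param fit_tree Also fit and score a greedy tree on the cohort itself
#'   (training performance; demonstrative). Default TRUE.
#' @param ci Attach confidence intervals to the metric table (slower).
#' @param cap_quantile Cap rule for extreme profile entries passed to
#'   [profile_matrix()]; default 0.99.
#' @param k_candidates Candidate cluster counts, default `2:8`.
#' @param tree_args List of arguments for [fit_greedy_tree()].
#' @return A `discrimination_analysis` object: `metrics` (tibble),
#'   `confusions`, `roc`, `profiles`, `mds`, `hclust`, `k_selection`,
#'   `tree`, `balance_entropy`, `excluded_methods`.
#' @export
#' @examples
#' coh <- generate_cohort(simulation_config(n_btt = 80, n_ida = 60, seed = 3))
#' fit <- run_discrimination_pipeline(coh, k_candidates = 2:4)
#' glance(fit)
run_discrimination_pipeline <- function(cohort,
                                        registry = index_registry(),
                                        rulesets = list(cruise_ruleset()),
                                        fit_tree = TRUE,
                                        ci = FALSE,
                                        cap_quantile = 0.99,
                                        k_candidates = 2:8,
                                        tree_args = list()) {
  if (!"label" %in% names(cohort)) abort("`cohort` needs a gold-standard `label` column.")
  cohort <- tibble::as_tibble(cohort)
  if (!"patient_id" %in% names(cohort)) {
    cohort$patient_id <- paste0("P", seq_len(nrow(cohort)))
  }
  truth_tbl <- cohort[c("patient_id", "label")]

  preds <- classify_cohort(cohort, registry)
  confusions <- list(); rocs <- list()

  for (nm in registry$name) {
    sub <- preds[preds$method == nm, ]
    cm <- confusion_from_long(sub, truth_tbl)
    if (is.null(cm)) next
    confusions[[nm]] <- cm
    ok <- !is.na(sub$value)
    side <- registry$btt_side[registry$name == nm]
    rocs[[nm]] <- if (side == "outside") {
      joined <- dplyr::inner_join(sub[ok, ], truth_tbl, by = "patient_id")
      empirical_auc(as.integer(joined$prediction == "BTT"), joined$label)
    } else {
      joined <- dplyr::inner_join(sub[ok, ], truth_tbl, by = "patient_id")
      empirical_auc(joined$value, joined$label,
                    direction = if (side == "below") "lower-is-BTT" else "higher-is-BTT")
    }
  }

  for (rs in rulesets) {
    pred <- predict_ruleset(rs, cohort)
    confusions[[rs$name]] <- confusion_matrix(cohort$label, pred)
    rocs[[rs$name]] <- empirical_auc(as.integer(pred == "BTT"), cohort$label)
  }

  tree <- NULL
  if (isTRUE(fit_tree)) {
    tree <- do.call(fit_greedy_tree, c(list(cohort), tree_args))
    pred <- predict(tree, cohort)
    confusions[["greedy_tree"]] <- confusion_matrix(cohort$label, pred)
    rocs[["greedy_tree"]] <- empirical_auc(as.integer(pred == "BTT"),
                                           cohort$label)
  }

  metrics <- metric_report(confusions, ci = ci)
  metrics$auc_empirical <- vapply(metrics$method,
                                  function(nm) rocs[[nm]]$auc, numeric(1))

  profiles <- performance_profiles(confusions)
  # similarity uses the empirical (score-based) AUC, as a ROC analysis would
  profiles$auc <- metrics$auc_empirical[match(profiles$method, metrics$method)]
  finite_ok <- apply(profiles[PROFILE_MEASURES], 1, function(r) !any(is.na(r)))
  excluded <- profiles$method[!finite_ok]
  if (length(excluded) > 0) {
    inform(paste("Excluded from similarity analysis (undefined profile measures):",
                 paste(excluded, collapse = ", ")))
  }
  profiles_ok <- profiles[finite_ok, ]

  mds <- NULL; hc <- NULL; ksel <- NULL
  if (nrow(profiles_ok) >= 4) {
    pm <- profile_matrix(profiles_ok, cap_quantile = cap_quantile)
    mds <- classical_mds(pm$dist, k = 2)
    hc <- complete_linkage(pm$dist)
    ksel <- select_k_majority(pm, k_candidates = k_candidates)
    mds$points$cluster <- factor(ksel$clusters[mds$points$method])
  }

  structure(list(
    metrics = metrics, confusions = confusions, roc = rocs,
    profiles = profiles, mds = mds, hclust = hc, k_selection = ksel,
    tree = tree, balance_entropy = class_balance_entropy(cohort$label),
    excluded_methods = excluded,
    n = nrow(cohort), n_btt = sum(cohort$label == "BTT"),
    n_ida = sum(cohort$label == "IDA")
  ), class = "discrimination_analysis")
}

#' @export
print.discrimination_analysis <- function(x, ...) {
  cat(sprintf("Discrimination analysis: %d patients (%d BTT / %d IDA), balance %.4f\n",
              x$n, x$n_btt, x$n_ida, x$balance_entropy))
  cat(sprintf("%d methods scored; %d in similarity analysis",
              nrow(x$metrics), nrow(x$profiles) - length(x$excluded_methods)))
  if (!is.null(x$k_selection)) {
    cat(sprintf("; %d homogeneous method groups (majority vote)",
                x$k_selection$k))
  }
  cat("\n")
  best <- x$metrics[order(-x$metrics$youden), ][1, ]
  cat(sprintf("Best Youden: %s (%.2f%%, accuracy %.2f%%)\n",
              best$method, 100 * best$youden, 100 * best$accuracy))
  invisible(x)
}

#' @method tidy discrimination_analysis
#' @export
tidy.discrimination_analysis <- function(x, ...) x$metrics

#' @method glance discrimination_analysis
#' @export
glance.discrimination_analysis <- function(x, ...) {
  best <- x$metrics[order(-x$metrics$youden), ][1, ]
  tibble::tibble(n = x$n, n_btt = x$n_btt, n_ida = x$n_ida,
                 balance_entropy = x$balance_entropy,
                 n_methods = nrow(x$metrics),
                 k_clusters = if (is.null(x$k_selection)) NA_integer_ else x$k_selection$k,
                 best_method = best$method, best_youden = best$youden)
}

#' Reconstruct per-method confusion matrices from published summaries
#'
#' Applies [recover_confusion_from_summary()] to each row of a published
#' summary table ([published_summary()] by default), returning the
#' recovered matrices and the re-derived measures. A handful of printed
#' rows are internally inconsistent by one or two units in the last
#' printed digit (rounding in the source tables); those are recovered as
#' the nearest integer matrix and flagged in the `approx` column. Rows
#' that cannot be recovered within `tolerance` are reported in `failed`,
#' never silently dropped.
#'
#' @param summary Tibble with `method`, `youden`, `accuracy` (%).
#' @param n_pos,n_neg Class sizes; defaults 708 BTT / 470 IDA.
#' @param tolerance Passed to [recover_confusion_from_summary()];
#'   default 0.025 (two units in the last printed digit).
#' @return A list: `metrics` (tibble of recovered cells + `approx` flag +
#'   13 measures per method), `confusions` (named list), `failed` (tibble
#'   of unrecoverable rows with the error message).
#' @export
#' @examples
#' rec <- reconstruct_published_performance()
#' rec$metrics[rec$metrics$method == "CRUISE", c("tp", "fp", "fn", "tn")]
reconstruct_published_performance <- function(summary = published_summary(),
                                              n_pos = 708, n_neg = 470,
                                              tolerance = 0.025) {
  cms <- list(); fails <- list()
  for (i in seq_len(nrow(summary))) {
    nm <- summary$method[i]
    res <- tryCatch(
      recover_confusion_from_summary(summary$youden[i], summary$accuracy[i],
                                     n_pos, n_neg, tolerance = tolerance),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[nm]] <- tibble::tibble(method = nm,
                                    error = conditionMessage(res))
    } else {
      cms[[nm]] <- res
    }
  }
  metrics <- metric_report(cms)
  cells <- purrr::imap(cms, function(cm, nm) {
    tibble::tibble(method = nm, tp = cm$tp, fp = cm$fp, fn = cm$fn,
                   tn = cm$tn, approx = isTRUE(attr(cm, "approx")))
  }) |> dplyr::bind_rows()
  list(metrics = dplyr::left_join(cells, metrics, by = "method"),
       confusions = cms,
       failed = dplyr::bind_rows(fails))
}
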