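# Diagnostic accuracy suite. Positive class is beta-thalassemia trait
# (BTT) throughout: the published F-measures only reproduce from the
# printed Youden/accuracy pairs under that convention.

#' Confusion matrix with BTT as the positive class
#'
#' @param truth,predicted Label vectors (`"IDA"`/`"BTT"`), equal length.
#' @return A `confusion_matrix` object with integer fields
#'   `tp, fp, fn, tn`.
#' @export
#' @examples
#' confusion_matrix(c("BTT", "BTT", "IDA"), c("BTT", "IDA", "IDA"))
confusion_matrix <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  bad <- !c(truth, predicted) %in% CLASS_LEVELS
  if (any(bad)) {
    abort(sprintf("Unknown label(s): %s.",
                  paste(unique(c(truth, predicted)[bad]), collapse = ", ")))
  }
  new_confusion(tp = sum(truth == "BTT" & predicted == "BTT"),
                fp = sum(truth == "IDA" & predicted == "BTT"),
                fn = sum(truth == "BTT" & predicted == "IDA"),
                tn = sum(truth == "IDA" & predicted == "IDA"))
}

new_confusion <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("Confusion cells must be non-negative integers.")
  }
  structure(as.list(setNames(as.integer(cells), names(cells))),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (positive class BTT):\n")
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(truth = c("BTT", "IDA"),
                              predicted = c("BTT", "IDA")))
  print(m)
  invisible(x)
}

MEASURES <- c("sensitivity", "specificity", "fpr", "fnr", "ppv", "npv",
              "youden", "accuracy", "plr", "nlr", "dor", "f_measure", "auc")

metric_values <- function(tp, fp, fn, tn) {
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  plr <- if (spec < 1) sens / (1 - spec) else if (sens > 0) Inf else NA_real_
  nlr <- if (spec > 0) (1 - sens) / spec else NA_real_
  dor <- if (fp == 0 || fn == 0) {
    if (tp * tn > 0) Inf else NA_real_
  } else (tp * tn) / (fp * fn)
  f <- if (!is.na(ppv) && ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else NA_real_
  c(sensitivity = sens, specificity = spec, fpr = 1 - spec, fnr = 1 - sens,
    ppv = ppv, npv = npv, youden = sens + spec - 1,
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    plr = plr, nlr = nlr, dor = dor, f_measure = f,
    auc = (sens + spec) / 2)
}

#' The thirteen diagnostic accuracy measures of a confusion matrix
#'
#' Sensitivity, specificity, FPR, FNR, PPV, NPV, Youden's index
#' (sens + spec - 1), accuracy, PLR (sens/(1-spec)), NLR ((1-sens)/spec),
#' DOR (PLR/NLR = tp*tn/(fp*fn)), F-measure (harmonic mean of PPV and
#' sensitivity), and the hard-classifier AUC (sens + spec)/2. DOR is
#' `Inf` when `fp` or `fn` is 0 with a non-zero numerator; measures with a
#' genuinely undefined denominator are `NA`, never silent NaN.
#'
#' @param cm A [confusion_matrix()].
#' @return A `metric_set` object (named list of the 13 measures, carrying
#'   the matrix); [tidy()] turns it into a tibble.
#' @export
#' @examples
#' metric_set(new_confusion_matrix(668, 60, 40, 410))$dor  # 114.12
metric_set <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0 || cm$tn + cm$fp == 0) {
    abort("metric_set needs at least one true positive-class and one true negative-class subject.")
  }
  vals <- metric_values(cm$tp, cm$fp, cm$fn, cm$tn)
  structure(c(as.list(vals), list(cm = cm)), class = "metric_set")
}

#' Construct a confusion matrix from its four cells
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts (BTT positive).
#' @return A `confusion_matrix`.
#' @export
new_confusion_matrix <- function(tp, fp, fn, tn) new_confusion(tp, fp, fn, tn)

#' @export
print.metric_set <- function(x, ...) {
  v <- unlist(x[MEASURES])
  cat("Diagnostic accuracy (positive class BTT):\n")
  print(round(v, 4))
  invisible(x)
}

#' @method tidy metric_set
#' @export
tidy.metric_set <- function(x, ...) {
  tibble::tibble(measure = MEASURES,
                 estimate = unname(unlist(x[MEASURES])))
}

#' @method glance metric_set
#' @export
glance.metric_set <- function(x, ...) {
  cm <- x$cm
  tibble::tibble(n = cm$tp + cm$fp + cm$fn + cm$tn,
                 n_pos = cm$tp + cm$fn, n_neg = cm$tn + cm$fp,
                 accuracy = x$accuracy, youden = x$youden, auc = x$auc)
}

clopper_pearson <- function(k, n, level) {
  alpha <- 1 - level
  lower <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower, upper)
}

log_ratio_ci <- function(est, se_log, level) {
  z <- qnorm(1 - (1 - level) / 2)
  exp(log(est) + c(-1, 1) * z * se_log)
}

#' Confidence intervals for all accuracy measures
#'
#' Proportion-type measures (sensitivity, specificity, FPR, FNR, PPV, NPV)
#' get exact Clopper-Pearson intervals on their own numerator/denominator;
#' PLR, NLR and DOR get standard log-method (delta) intervals; Youden's
#' index, accuracy, F-measure and the hard-classifier AUC get percentile
#' bootstrap intervals (per-class binomial resampling of the matrix,
#' default 2000 replicates under a fixed seed). Degenerate counts give
#' one-sided or `NA` bounds, flagged by a warning.
#'
#' @param cm A [confusion_matrix()].
#' @param level Confidence level, default 0.95.
#' @param boot Bootstrap replicates for the no-closed-form measures.
#' @param seed Seed for the bootstrap.
#' @return A tibble: `measure`, `estimate`, `lower`, `upper`.
#' @export
#' @examples
#' metric_cis(new_confusion_matrix(668, 60, 40, 410))
metric_cis <- function(cm, level = 0.95, boot = 2000, seed = 1L) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ms <- metric_set(cm)
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  n_pos <- tp + fn; n_neg <- tn + fp

  ci <- list(
    sensitivity = clopper_pearson(tp, n_pos, level),
    specificity = clopper_pearson(tn, n_neg, level),
    fpr = clopper_pearson(fp, n_neg, level),
    fnr = clopper_pearson(fn, n_pos, level),
    ppv = if (tp + fp > 0) clopper_pearson(tp, tp + fp, level) else c(NA, NA),
    npv = if (tn + fn > 0) clopper_pearson(tn, tn + fn, level) else c(NA, NA)
  )

  degenerate <- FALSE
  ci$plr <- if (tp > 0 && fp > 0) {
    log_ratio_ci(ms$plr, sqrt(1 / tp - 1 / n_pos + 1 / fp - 1 / n_neg), level)
  } else { degenerate <- TRUE; c(NA_real_, NA_real_) }
  ci$nlr <- if (fn > 0 && tn > 0) {
    log_ratio_ci(ms$nlr, sqrt(1 / fn - 1 / n_pos + 1 / tn - 1 / n_neg), level)
  } else { degenerate <- TRUE; c(NA_real_, NA_real_) }
  ci$dor <- if (all(c(tp, fp, fn, tn) > 0)) {
    log_ratio_ci(ms$dor, sqrt(1 / tp + 1 / fp + 1 / fn + 1 / tn), level)
  } else { degenerate <- TRUE; c(NA_real_, NA_real_) }
  if (degenerate) {
    warn("Zero cell(s): likelihood-ratio / DOR intervals are undefined and returned as NA.")
  }

  boot_stats <- withr::with_seed(seed, {
    tp_star <- stats::rbinom(boot, n_pos, tp / n_pos)
    tn_star <- stats::rbinom(boot, n_neg, tn / n_neg)
    sens <- tp_star / n_pos; spec <- tn_star / n_neg
    ppv <- ifelse(tp_star + (n_neg - tn_star) > 0,
                  tp_star / (tp_star + (n_neg - tn_star)), NA_real_)
    list(youden = sens + spec - 1,
         accuracy = (tp_star + tn_star) / (n_pos + n_neg),
         f_measure = ifelse(!is.na(ppv) & ppv + sens > 0,
                            2 * ppv * sens / (ppv + sens), NA_real_),
         auc = (sens + spec) / 2)
  })
  alpha <- 1 - level
  for (m in names(boot_stats)) {
    ci[[m]] <- unname(quantile(boot_stats[[m]], c(alpha / 2, 1 - alpha / 2),
                               na.rm = TRUE))
  }

  tibble::tibble(measure = MEASURES,
                 estimate = unname(unlist(ms[MEASURES])),
                 lower = vapply(MEASURES, function(m) ci[[m]][1], numeric(1)),
                 upper = vapply(MEASURES, function(m) ci[[m]][2], numeric(1)))
}

#' Accuracy report for several methods
#'
#' @param cms Named list of [confusion_matrix()] objects.
#' @param ci Compute confidence intervals too?
#' @param ... Passed to [metric_cis()].
#' @return A wide tibble, one row per method, measures in the conventional
#'   table order (with `<measure>_lower`/`_upper` columns when `ci = TRUE`).
#' @export
metric_report <- function(cms, ci = FALSE, ...) {
  stopifnot(is.list(cms), !is.null(names(cms)))
  rows <- purrr::imap(cms, function(cm, nm) {
    if (ci) {
      t1 <- metric_cis(cm, ...)
      wide <- as.list(t1$estimate)
      names(wide) <- t1$measure
      for (i in seq_len(nrow(t1))) {
        wide[[paste0(t1$measure[i], "_lower")]] <- t1$lower[i]
        wide[[paste0(t1$measure[i], "_upper")]] <- t1$upper[i]
      }
      dplyr::bind_cols(tibble::tibble(method = nm), tibble::as_tibble(wide))
    } else {
      ms <- metric_set(cm)
      dplyr::bind_cols(tibble::tibble(method = nm),
                       tibble::as_tibble(as.list(unlist(ms[MEASURES]))))
    }
  })
  dplyr::bind_rows(rows)
}

#' Empirical ROC curve and AUC
#'
#' Sweeps every observed score threshold and computes the (FPR, TPR)
#' curve; the AUC is the Mann-Whitney concordance probability (ties count
#' one half), with a DeLong standard error. For a binary 0/1 score this
#' reduces to (sensitivity + specificity) / 2.
#'
#' @param scores Numeric score per patient.
#' @param truth Labels (`"IDA"`/`"BTT"`); both classes must be present.
#' @param direction `"higher-is-BTT"` (default) or `"lower-is-BTT"`.
#' @return A `roc_curve` object: `points` (tibble `threshold, fpr, tpr`),
#'   `auc`, `se`, and the oriented scores/truth for paired comparison.
#' @seealso [compare_auc()]
#' @export
#' @examples
#' roc <- empirical_auc(c(1, 2, 3, 4), c("IDA", "IDA", "BTT", "BTT"))
#' roc$auc  # 1
empirical_auc <- function(scores, truth, direction = c("higher-is-BTT",
                                                       "lower-is-BTT")) {
  direction <- match.arg(direction)
  truth <- as.character(truth)
  if (length(scores) != length(truth)) abort("Lengths differ.")
  if (anyNA(scores) || anyNA(truth)) abort("Missing scores or labels.")
  if (!all(truth %in% CLASS_LEVELS)) abort("Labels must be IDA/BTT.")
  if (length(unique(truth)) < 2) {
    abort("Both classes must be present to compute a ROC curve.")
  }
  s <- if (direction == "lower-is-BTT") -scores else scores
  pos <- s[truth == "BTT"]; neg <- s[truth == "IDA"]
  m <- length(pos); n <- length(neg)

  # Mann-Whitney AUC via midranks (ties = 1/2)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)

  # DeLong placements
  v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n,
                numeric(1))
  v01 <- vapply(neg, function(y) (sum(pos > y) + 0.5 * sum(pos == y)) / m,
                numeric(1))
  se <- sqrt(var(v10) / m + var(v01) / n)

  thr <- sort(unique(s), decreasing = TRUE)
  pts <- tibble::tibble(
    threshold = c(Inf, thr),
    tpr = vapply(c(Inf, thr), function(t) mean(pos >= t), numeric(1)),
    fpr = vapply(c(Inf, thr), function(t) mean(neg >= t), numeric(1))
  )
  structure(list(points = pts, auc = auc, se = se,
                 scores = s, truth = truth, direction = direction),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC: AUC = %.4f (SE %.4f), %d thresholds\n",
              x$auc, x$se, nrow(x$points)))
  invisible(x)
}

#' @method tidy roc_curve
#' @export
tidy.roc_curve <- function(x, ...) x$points

#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, ...) {
  z <- qnorm(0.975)
  tibble::tibble(auc = x$auc, se = x$se,
                 conf_low = max(0, x$auc - z * x$se),
                 conf_high = min(1, x$auc + z * x$se),
                 n_pos = sum(x$truth == "BTT"),
                 n_neg = sum(x$truth == "IDA"))
}

#' Paired DeLong comparison of two AUCs
#'
#' Nonparametric test of equal AUC for two scores measured on the same
#' patients, using the DeLong placement-value covariance. Antisymmetric:
#' swapping the arguments negates `z`.
#'
#' @param curve_a,curve_b `roc_curve` objects from [empirical_auc()] on the
#'   same truth vector (same patients, same order).
#' @return A tibble: `auc_a`, `auc_b`, `delta`, `z`, `p_value`.
#' @export
compare_auc <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "roc_curve"), inherits(curve_b, "roc_curve"))
  if (length(curve_a$truth) != length(curve_b$truth) ||
      !all(curve_a$truth == curve_b$truth)) {
    abort("Curves must be paired: identical truth vectors on the same patients.")
  }
  truth <- curve_a$truth
  pos_i <- truth == "BTT"; neg_i <- truth == "IDA"
  m <- sum(pos_i); n <- sum(neg_i)
  placements <- function(curve) {
    pos <- curve$scores[pos_i]; neg <- curve$scores[neg_i]
    list(v10 = vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n,
                      numeric(1)),
         v01 = vapply(neg, function(y) (sum(pos > y) + 0.5 * sum(pos == y)) / m,
                      numeric(1)))
  }
  pa <- placements(curve_a); pb <- placements(curve_b)
  var_delta <- (var(pa$v10) + var(pb$v10) - 2 * stats::cov(pa$v10, pb$v10)) / m +
    (var(pa$v01) + var(pb$v01) - 2 * stats::cov(pa$v01, pb$v01)) / n
  delta <- curve_a$auc - curve_b$auc
  z <- if (var_delta <= 0) {
    if (abs(delta) < 1e-12) 0 else sign(delta) * Inf
  } else delta / sqrt(var_delta)
  tibble::tibble(auc_a = curve_a$auc, auc_b = curve_b$auc, delta = delta,
                 z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Recover the integer confusion matrix from printed summary accuracy
#'
#' With known class sizes, a method's Youden index and accuracy determine
#' its confusion matrix: solving `sens + spec = 1 + J` and
#' `p*sens + (1-p)*spec = A` (prevalence `p = n_pos/(n_pos+n_neg)`) gives
#' `sens = (A - (1-p)(1+J)) / (2p - 1)`; `tp` and `tn` are the nearest
#' integers to `n_pos*sens` and `n_neg*spec`. The recovered matrix is
#' verified by recomputing Youden and accuracy and matching the inputs to
#' two decimals; inconsistent inputs raise an error.
#'
#' @param youden,accuracy Printed values in percent (e.g. `81.58`).
#' @param n_pos,n_neg True class sizes (positive class BTT); must differ.
#' @param tolerance Extra slack (percentage points) allowed beyond the
#'   printed 2-dp precision. The default 0 demands exact agreement;
#'   a small positive value (e.g. `0.025`, one or two units in the last
#'   printed digit) accepts the nearest integer matrix when a published
#'   row is internally inconsistent from rounding, and marks the result
#'   with attribute `approx`.
#' @return A [confusion_matrix()].
#' @export
#' @examples
#' recover_confusion_from_summary(81.58, 91.51, 708, 470)
recover_confusion_from_summary <- function(youden, accuracy, n_pos, n_neg,
                                           tolerance = 0) {
  if (n_pos == n_neg) {
    abort("Recovery needs unequal class sizes (the system is singular at p = 1/2).")
  }
  J <- youden / 100; A <- accuracy / 100
  p <- n_pos / (n_pos + n_neg)
  sens <- (A - (1 - p) * (1 + J)) / (2 * p - 1)
  spec <- 1 + J - sens
  if (sens < -1e-9 || sens > 1 + 1e-9 || spec < -1e-9 || spec > 1 + 1e-9) {
    abort(sprintf("Inputs imply sensitivity %.4f / specificity %.4f outside [0, 1].",
                  sens, spec))
  }
  tp0 <- round(min(max(sens, 0), 1) * n_pos)
  tn0 <- round(min(max(spec, 0), 1) * n_neg)
  # printed 2-dp rounding of J and A can push the nearest-integer solution
  # off the closed-form solve; search all integer matrices for those that
  # reproduce both printed values exactly and take the one closest to the
  # solve
  grid <- expand.grid(tp = 0:n_pos, tn = 0:n_neg)
  J2 <- round(100 * (grid$tp / n_pos + grid$tn / n_neg - 1), 2)
  A2 <- round(100 * (grid$tp + grid$tn) / (n_pos + n_neg), 2)
  hit <- abs(J2 - youden) <= 0.005 + 1e-9 & abs(A2 - accuracy) <= 0.005 + 1e-9
  approx <- FALSE
  if (!any(hit) && tolerance > 0) {
    dev <- pmax(abs(J2 - youden), abs(A2 - accuracy))
    hit <- dev <= tolerance + 1e-9
    approx <- any(hit)
  }
  if (!any(hit)) {
    J0 <- 100 * (tp0 / n_pos + tn0 / n_neg - 1)
    A0 <- 100 * (tp0 + tn0) / (n_pos + n_neg)
    abort(sprintf(
      "No integer matrix reproduces Youden %.2f / accuracy %.2f (closest: %.2f / %.2f).",
      youden, accuracy, J0, A0))
  }
  cand <- grid[hit, , drop = FALSE]
  i <- which.min(abs(cand$tp - tp0) + abs(cand$tn - tn0) +
                   pmax(abs(J2[hit] - youden), abs(A2[hit] - accuracy)))
  tp <- cand$tp[i]; tn <- cand$tn[i]
  out <- new_confusion(tp = tp, fp = n_neg - tn, fn = n_pos - tp, tn = tn)
  attr(out, "approx") <- approx
  out
}
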