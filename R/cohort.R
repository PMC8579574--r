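#' Study eligibility criteria for a hypochromic-microcytic cohort
#'
#' Bundles the inclusion/exclusion thresholds used to assemble a two-class
#' cohort of iron deficiency anemia (IDA) and beta-thalassemia trait (BTT)
#' patients: hypochromic microcytosis (MCV below `mcv_max`, MCH below
#' `mch_max`), sex-specific anemia (Hb below `hb_max_female` /
#' `hb_max_male`), exclusion of severe anemia (Hb below `hb_min`), and the
#' gold-standard labeling rules (HbA2 above `hba2_btt_threshold` defines
#' BTT; serum ferritin below `ferritin_ida_threshold` defines IDA). All
#' comparisons are strict, as printed in the source criteria; records equal
#' to a threshold are rejected with an explicit reason.
#'
#' @param mcv_max Maximum mean corpuscular volume, fL. Default 80.
#' @param mch_max Maximum mean corpuscular hemoglobin, pg. Default 27.
#' @param hb_max_female,hb_max_male Sex-specific hemoglobin upper bounds,
#'   g/dL. Defaults 12 and 13.
#' @param hb_min Severe-anemia lower bound, g/dL. Default 8.
#' @param hba2_btt_threshold HbA2 percentage above which a patient is
#'   labeled BTT. Default 3.5.
#' @param ferritin_ida_threshold Serum ferritin (ng/mL) below which a
#'   patient is labeled IDA. Default 15.
#' @return An object of class `cohort_criteria` (a named list).
#' @export
#' @examples
#' cohort_criteria()
cohort_criteria <- function(mcv_max = 80, mch_max = 27,
                            hb_max_female = 12, hb_max_male = 13,
                            hb_min = 8,
                            hba2_btt_threshold = 3.5,
                            ferritin_ida_threshold = 15) {
  if (!(hb_min < hb_max_female && hb_max_female <= hb_max_male)) {
    abort("cohort_criteria requires hb_min < hb_max_female <= hb_max_male.")
  }
  structure(
    list(mcv_max = mcv_max, mch_max = mch_max,
         hb_max_female = hb_max_female, hb_max_male = hb_max_male,
         hb_min = hb_min,
         hba2_btt_threshold = hba2_btt_threshold,
         ferritin_ida_threshold = ferritin_ida_threshold),
    class = "cohort_criteria"
  )
}

#' @export
print.cohort_criteria <- function(x, ...) {
  cat("Cohort eligibility criteria (strict inequalities):\n")
  cat(sprintf("  MCV < %g fL, MCH < %g pg\n", x$mcv_max, x$mch_max))
  cat(sprintf("  Hb < %g g/dL (female) / < %g g/dL (male); Hb >= %g g/dL\n",
              x$hb_max_female, x$hb_max_male, x$hb_min))
  cat(sprintf("  BTT label: HbA2 > %g%%; IDA label: ferritin < %g ng/mL\n",
              x$hba2_btt_threshold, x$ferritin_ida_threshold))
  invisible(x)
}

required_cohort_fields <- c("hb", "mcv", "mch", "sex")

validate_patient_records <- function(records, mchc_tol = 0.15) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("`records` must be a non-empty data frame of patient CBC panels.")
  }
  records <- tibble::as_tibble(records)
  if (!"patient_id" %in% names(records)) {
    records <- dplyr::mutate(records,
                             patient_id = paste0("P", seq_len(nrow(records))),
                             .before = 1)
  }
  num_fields <- intersect(CBC_FIELDS, names(records))
  for (f in num_fields) {
    bad <- !is.na(records[[f]]) & records[[f]] <= 0
    if (any(bad)) {
      warn(sprintf("%d record(s) have non-positive %s; they will be rejected as invalid.",
                   sum(bad), f))
    }
  }
  # MCHC consistency: MCHC (g/dL) should be ~ 100 * MCH/MCV; warn only
  if (all(c("mchc", "mch", "mcv") %in% names(records))) {
    implied <- 100 * records$mch / records$mcv
    off <- !is.na(records$mchc) & !is.na(implied) &
      abs(records$mchc - implied) / implied > mchc_tol
    if (any(off)) {
      warn(sprintf("%d record(s) have MCHC inconsistent with 100*MCH/MCV beyond %.0f%% tolerance.",
                   sum(off), 100 * mchc_tol))
    }
  }
  records
}

#' Apply the study's inclusion/exclusion and labeling rules
#'
#' Filters a table of patient CBC records to the analyzable two-class
#' cohort and assigns the gold-standard label. A record is retained iff it
#' satisfies, with strict inequalities: MCV < `mcv_max`, MCH < `mch_max`,
#' sex-specific Hb bound, Hb >= `hb_min` (records with Hb < `hb_min` are
#' excluded as severe anemia), and exactly one of the two label rules
#' (HbA2 for BTT, ferritin for IDA). Records meeting both rules are
#' rejected as `"ambiguous"` (simultaneous presentation), records meeting
#' neither as `"unlabeled"`. Missing required fields reject the record with
#' the field named; nothing is dropped silently.
#'
#' @param records A data frame, one row per patient, with columns among
#'   `hb, hct, mcv, mch, mchc, rbc, rdw, hba2, ferritin, serum_iron, tibc,
#'   sex` (and optionally `patient_id`, `label`). `sex` must be
#'   `"male"`/`"female"`.
#' @param criteria A [cohort_criteria()] object.
#' @return A tibble of retained records with a `label` column
#'   (`"IDA"`/`"BTT"`), carrying the rejection report as attribute
#'   `"rejections"` (tibble: `patient_id`, `reason`), also retrievable via
#'   [rejection_report()].
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   hb = c(10, 10), mcv = c(70, 85), mch = c(22, 26), sex = "female",
#'   hba2 = c(4.2, 2.0), ferritin = c(60, 10)
#' )
#' cohort <- apply_inclusion_exclusion(recs)
#' rejection_report(cohort)
apply_inclusion_exclusion <- function(records, criteria = cohort_criteria()) {
  stopifnot(inherits(criteria, "cohort_criteria"))
  records <- validate_patient_records(records)

  n <- nrow(records)
  get <- function(f) if (f %in% names(records)) records[[f]] else rep(NA_real_, n)
  hb <- get("hb"); mcv <- get("mcv"); mch <- get("mch")
  hba2 <- get("hba2"); ferritin <- get("ferritin")
  sex <- if ("sex" %in% names(records)) as.character(records$sex) else rep(NA_character_, n)

  reason <- rep(NA_character_, n)
  note <- function(idx, why) {
    new <- is.na(reason) & idx
    reason[new] <<- why
  }

  # missing required fields first: explicit, never a silent drop
  for (f in required_cohort_fields) {
    v <- if (f == "sex") sex else get(f)
    note(is.na(v), paste0("missing ", f))
  }
  note(!is.na(sex) & !sex %in% c("male", "female"), "invalid sex")
  for (f in intersect(CBC_FIELDS, names(records))) {
    note(!is.na(records[[f]]) & records[[f]] <= 0, paste0("non-positive ", f))
  }

  note(!is.na(mcv) & !(mcv < criteria$mcv_max), "mcv")
  note(!is.na(mch) & !(mch < criteria$mch_max), "mch")
  hb_cap <- ifelse(sex == "male", criteria$hb_max_male, criteria$hb_max_female)
  note(!is.na(hb) & !(hb < hb_cap), "hb not anemic")
  note(!is.na(hb) & hb < criteria$hb_min, "severe anemia")

  is_btt <- !is.na(hba2) & hba2 > criteria$hba2_btt_threshold
  is_ida <- !is.na(ferritin) & ferritin < criteria$ferritin_ida_threshold
  note(is_btt & is_ida, "ambiguous")
  note(!is_btt & !is_ida, "unlabeled")

  keep <- is.na(reason)
  out <- records[keep, , drop = FALSE]
  out$label <- ifelse(is_btt[keep], "BTT", "IDA")
  rejections <- tibble::tibble(patient_id = records$patient_id[!keep],
                               reason = reason[!keep])
  attr(out, "rejections") <- rejections
  class(out) <- c("cbc_cohort", class(out))
  out
}

#' Rejection report of a filtered cohort
#'
#' @param cohort The tibble returned by [apply_inclusion_exclusion()].
#' @return A tibble with `patient_id` and `reason` for every rejected record.
#' @export
rejection_report <- function(cohort) {
  rej <- attr(cohort, "rejections")
  rej %||% tibble::tibble(patient_id = character(), reason = character())
}

#' Shannon-entropy class balance
#'
#' Normalized Shannon entropy of the label distribution, `H(p)/log(k)` with
#' `k` the number of distinct classes: 1 for perfectly balanced classes,
#' 0 for a single class (with the convention `0 * log 0 = 0`).
#'
#' @param labels Vector (or factor) of class labels; at least one.
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' class_balance_entropy(rep(c("IDA", "BTT"), c(470, 708)))  # 0.9704
class_balance_entropy <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) abort("`labels` must contain at least one label.")
  p <- as.numeric(table(labels)) / length(labels)
  k <- length(p)
  if (k == 1) return(0)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  h / log(k)
}

#' Read / write patient CBC tables
#'
#' CSV with one row per patient and canonical lower-case headers
#' (`hb,hct,mcv,mch,mchc,rbc,rdw,hba2,ferritin,serum_iron,tibc,sex,label`);
#' unknown columns are preserved on round-trip.
#'
#' @param path File path.
#' @return `read_cbc()`: a tibble. `write_cbc()`: `path`, invisibly.
#' @export
read_cbc <- function(path) {
  spec <- readr::cols(.default = readr::col_guess())
  out <- readr::read_csv(path, col_types = spec, progress = FALSE)
  for (f in intersect(CBC_FIELDS, names(out))) out[[f]] <- as.numeric(out[[f]])
  out
}

#' @rdname read_cbc
#' @param cohort A data frame of patient records.
#' @export
write_cbc <- function(cohort, path) {
  readr::write_csv(as.data.frame(cohort), path, progress = FALSE)
  invisible(path)
}
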