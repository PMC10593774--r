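#' Pubertal development and psychopathology scoring
#'
#' Scoring of the Pubertal Development Scale (PDS): sex-specific ordinal
#' items (1-4, plus a binary menarche item for females) are averaged into
#' `PDS_mean`, differenced across study visits into a maturation change
#' score, and summed into pubertal categories (prepubertal to postpubertal)
#' with the standard ABCD/Crockett conversion. Psychopathology severity is
#' proxied by the count of consensus diagnoses.
#'
#' @name phenotypes
NULL

#' Mean PDS score
#'
#' Arithmetic mean of the sex-specific item scores. The binary menarche
#' item is recoded onto the 4-point scale (`no = 1`, `yes = 4`) before
#' averaging. Any missing item invalidates the score (listwise policy).
#'
#' @param items numeric vector of ordinal item responses in 1-4 (menarche
#'   excluded).
#' @param menarche for females, `TRUE`/`FALSE`; `NULL` (default) for males.
#' @param menarche_recode values the binary item maps to on the 4-point
#'   scale.
#' @return the mean score in `[1, 4]`, or `NA` if any item is missing.
#' @export
pds_mean <- function(items, menarche = NULL, menarche_recode = c(no = 1, yes = 4)) {
  if (anyNA(items) || (!is.null(menarche) && is.na(menarche))) return(NA_real_)
  if (any(items < 1 | items > 4)) stop("PDS items must lie in 1-4")
  if (!is.null(menarche))
    items <- c(items, if (menarche) menarche_recode[["yes"]] else menarche_recode[["no"]])
  mean(items)
}

#' Pubertal maturation change score
#'
#' Follow-up minus baseline `PDS_mean` for one subject; both visits must be
#' scored by the same reporter.
#'
#' @param baseline,followup lists (or one-row data frames) with fields
#'   `pds_mean` and `reporter`.
#' @return the change score (followup - baseline).
#' @export
pds_delta <- function(baseline, followup) {
  if (!identical(as.character(baseline$reporter),
                 as.character(followup$reporter)))
    stop("reporter mismatch between visits")
  as.numeric(followup$pds_mean) - as.numeric(baseline$pds_mean)
}

#' Pubertal category from PDS items
#'
#' Males: sum of the three items on body hair, voice deepening and facial
#' hair (range 3-12). Females: sum of the body hair and breast development
#' items (range 2-8) combined with menarche. The sums are converted with
#' the standard ABCD/Crockett scheme, which is monotone in the item sum
#' within each menarche stratum.
#'
#' @param items the category items: 3 values for males, 2 for females,
#'   each in 1-4.
#' @param sex `"male"` or `"female"`.
#' @param menarche required for females.
#' @return one of `"prepubertal"`, `"early"`, `"mid"`, `"late"`, `"post"`.
#' @export
pubertal_category <- function(items, sex = c("male", "female"),
                              menarche = NULL) {
  sex <- match.arg(sex)
  if (anyNA(items)) return(NA_character_)
  if (any(items < 1 | items > 4)) stop("category items must lie in 1-4")
  s <- sum(items)
  if (sex == "male") {
    if (length(items) != 3L) stop("males need 3 category items")
    if (s == 3) "prepubertal"
    else if (s <= 5) { if (any(items >= 3)) "mid" else "early" }
    else if (s <= 8) { if (any(items == 4)) "late" else "mid" }
    else if (s <= 11) "late"
    else "post"
  } else {
    if (length(items) != 2L) stop("females need 2 category items")
    if (is.null(menarche) || is.na(menarche))
      stop("menarche status required for females")
    if (menarche) {
      if (s <= 7) "late" else "post"
    } else {
      if (s == 2) "prepubertal" else if (s == 3) "early" else "mid"
    }
  }
}

#' Sum of consensus diagnoses
#'
#' Count of clinician-consensus diagnoses, the proxy for psychopathology
#' severity in the clinical cohort.
#'
#' @param diagnoses character vector of diagnosis labels (possibly empty).
#' @return nonnegative integer count.
#' @export
diagnosis_sum <- function(diagnoses) length(diagnoses)

#' Score a phenotype table
#'
#' Adds `pds_mean` per row of a long phenotype table (one row per subject
#' and timepoint) using the sex-specific item sets: males use all ordinal
#' items (`pds_1..pds_5`); females use `pds_1..pds_4` plus the recoded
#' binary `menarche` item.
#'
#' @param phenotypes data frame with columns `subject_id`, `sex`,
#'   `timepoint`, item columns `pds_1..pds_5` and `menarche`.
#' @return the table with a `pds_mean` column appended.
#' @export
score_phenotypes <- function(phenotypes) {
  item_cols <- grep("^pds_[0-9]+$", names(phenotypes), value = TRUE)
  if (!length(item_cols)) stop("no PDS item columns (pds_1, ...)")
  female_items <- setdiff(item_cols, "pds_5")
  phenotypes$pds_mean <- vapply(seq_len(nrow(phenotypes)), function(i) {
    female <- identical(as.character(phenotypes$sex[i]), "female")
    cols <- if (female) female_items else item_cols
    items <- as.numeric(phenotypes[i, cols])
    men <- if (female && "menarche" %in% names(phenotypes))
      as.logical(phenotypes$menarche[i]) else NULL
    pds_mean(items, menarche = men)
  }, numeric(1L))
  phenotypes
}

#' Per-subject change scores between two visits
#'
#' @param phenotypes scored phenotype table with `timepoint` in
#'   `{"baseline", "followup"}` and columns `subject_id`, `age`,
#'   `pds_mean`.
#' @return data frame with one row per subject present at both visits:
#'   `subject_id`, `delta_age`, `delta_pds`.
#' @export
delta_scores <- function(phenotypes) {
  b <- phenotypes[phenotypes$timepoint == "baseline", ]
  f <- phenotypes[phenotypes$timepoint == "followup", ]
  common <- intersect(b$subject_id, f$subject_id)
  b <- b[match(common, b$subject_id), ]
  f <- f[match(common, f$subject_id), ]
  data.frame(subject_id = common,
             delta_age = f$age - b$age,
             delta_pds = f$pds_mean - b$pds_mean,
             stringsAsFactors = FALSE)
}
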