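# Aphasia Check List (ACL) score handling: subdomain merging, score
# inversion, impairment labelling and the diagnostic cut-off.
#
# The ACL total score runs 0-148, lower = worse language performance;
# aphasia is diagnosed strictly below 135. Each language subdomain is an
# ordinal 0-3 where 3 means no disorder.

ACL_MAX <- 148L
ACL_CUTOFF <- 135L

.check_ordinal <- function(x, what = "ordinal") {
  bad <- !is.na(x) & !(x %in% 0:3)
  if (any(bad)) stop(sprintf("%s values must be in {0,1,2,3}", what))
  as.integer(x)
}

.check_score <- function(x) {
  bad <- !is.na(x) & (x < 0 | x > ACL_MAX)
  if (any(bad)) stop(sprintf("aphasia score must be in [0, %d]", ACL_MAX))
  x
}

#' Lower median of ordinal items
#'
#' Median of the non-missing items; for an even number of items the lower
#' median is taken, which is conservative toward impairment. Missing if all
#' items are missing.
#'
#' @param x Integer vector of ordinals in {0,1,2,3} (NAs allowed).
#' @return A single ordinal, or NA if no item is available.
#' @export
ordinal_median <- function(x) {
  x <- .check_ordinal(x)
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_integer_)
  sort(x)[ceiling(length(x) / 2)]
}

#' Merge task items into the eight ACL subdomains
#'
#' The reading, writing and repeating subdomains each combine three task
#' items (words & sentences, pseudowords, numbers) by their median; the five
#' singleton subdomains pass through unchanged.
#'
#' @param items A data.frame (one row per patient) with columns
#'   \code{simple_comprehension}, \code{complex_comprehension},
#'   \code{semantic_fluency}, \code{phonemic_fluency}, \code{naming}, and
#'   item triplets \code{reading_1..3}, \code{writing_1..3},
#'   \code{repeating_1..3}, all ordinals in {0,1,2,3}.
#' @return A data.frame with the eight subdomain columns (ordinals 0-3,
#'   NA where no constituent item is available).
#' @export
merge_subdomains <- function(items) {
  singles <- c("simple_comprehension", "complex_comprehension",
               "semantic_fluency", "phonemic_fluency", "naming")
  triples <- c("reading", "writing", "repeating")
  need <- c(singles, paste0(rep(triples, each = 3), "_", 1:3))
  miss <- setdiff(need, names(items))
  if (length(miss)) stop("missing item columns: ", paste(miss, collapse = ", "))
  out <- items[, singles, drop = FALSE]
  for (col in singles) out[[col]] <- .check_ordinal(items[[col]], col)
  for (tri in triples) {
    m <- as.matrix(items[, paste0(tri, "_", 1:3), drop = FALSE])
    out[[tri]] <- vapply(seq_len(nrow(m)),
                         function(i) ordinal_median(m[i, ]), integer(1))
  }
  out
}

#' Invert an ACL aphasia score
#'
#' Returns \code{148 - score} so that higher values mean worse language
#' performance, the orientation used throughout lesion network mapping.
#'
#' @param score Aphasia score(s) in [0, 148]; NA propagates.
#' @return Inverted score(s).
#' @export
invert_score <- function(score) {
  ACL_MAX - .check_score(score)
}

#' Diagnose aphasia from the ACL total score
#'
#' Aphasia is present when the score is strictly below the cut-off
#' (default 135).
#'
#' @param score Aphasia score(s) in [0, 148]; NA propagates.
#' @param cutoff Diagnostic cut-off (default 135).
#' @return Logical vector, TRUE where aphasia is diagnosed.
#' @export
diagnose_aphasia <- function(score, cutoff = ACL_CUTOFF) {
  .check_score(score) < cutoff
}

#' Label a subdomain ordinal as impaired or unimpaired
#'
#' Scores 0-2 are impaired; only the maximal score 3 is unimpaired.
#'
#' @param ordinal Subdomain ordinal(s) in {0,1,2,3}; NA propagates.
#' @return Character vector, "impaired" or "unimpaired".
#' @export
flag_impaired <- function(ordinal) {
  x <- .check_ordinal(ordinal)
  ifelse(is.na(x), NA_character_, ifelse(x <= 2L, "impaired", "unimpaired"))
}

SUBDOMAIN_COLS <- c("simple_comprehension", "complex_comprehension",
                    "semantic_fluency", "phonemic_fluency", "naming",
                    "reading", "writing", "repeating")

#' Validate and complete a clinical record table
#'
#' Checks the schema and the internal consistency of a per-patient clinical
#' table: \code{inverted_score = 148 - aphasia_score} and
#' \code{aphasia_flag <=> aphasia_score < 135} whenever the score is
#' present. Missing derived columns are filled in from the score.
#'
#' @param df Data.frame with columns \code{patient_id}, \code{aphasia_score}
#'   (0-148 or NA), the eight subdomain ordinals, \code{age},
#'   \code{lesion_volume} (cm^3), \code{side}; optionally
#'   \code{inverted_score} and \code{aphasia_flag}.
#' @param cutoff Diagnostic cut-off passed to \code{\link{diagnose_aphasia}}.
#' @return The validated data.frame of class \code{aphasia_records}.
#' @export
aphasia_records <- function(df, cutoff = ACL_CUTOFF) {
  need <- c("patient_id", "aphasia_score", SUBDOMAIN_COLS,
            "age", "lesion_volume", "side")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing clinical columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id)) stop("duplicated patient_id")
  if (!all(df$side %in% c("left", "right"))) stop("side must be left/right")
  .check_score(df$aphasia_score)
  for (col in SUBDOMAIN_COLS) df[[col]] <- .check_ordinal(df[[col]], col)
  inv <- invert_score(df$aphasia_score)
  if (is.null(df$inverted_score)) df$inverted_score <- inv
  else if (!isTRUE(all.equal(df$inverted_score, inv)))
    stop("inverted_score inconsistent with 148 - aphasia_score")
  flag <- diagnose_aphasia(df$aphasia_score, cutoff)
  if (is.null(df$aphasia_flag)) df$aphasia_flag <- flag
  else if (!identical(as.logical(df$aphasia_flag), flag))
    stop("aphasia_flag inconsistent with the diagnostic cut-off")
  class(df) <- c("aphasia_records", "data.frame")
  df
}

#' Read a clinical table from TSV
#' @param path TSV path with the schema of \code{\link{aphasia_records}}.
#' @param cutoff Diagnostic cut-off.
#' @return An \code{aphasia_records} data.frame.
#' @export
read_clinical <- function(path, cutoff = ACL_CUTOFF) {
  if (!file.exists(path)) stop("clinical table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  aphasia_records(df, cutoff)
}

#' Write a clinical table to TSV
#' @param records An \code{aphasia_records} data.frame.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_clinical <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cohort summary of aphasia scores
#'
#' Median and interquartile range of the available scores and the fraction
#' of patients meeting the diagnostic cut-off. Patients with missing scores
#' are excluded (they remain in the table for subdomain analyses).
#'
#' @param records An \code{aphasia_records} data.frame.
#' @return List with \code{n_total}, \code{n_scored}, \code{median},
#'   \code{iqr} (lower, upper), \code{pct_aphasia}.
#' @export
clinical_summary <- function(records) {
  s <- records$aphasia_score
  ok <- !is.na(s)
  q <- stats::quantile(s[ok], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n_total = nrow(records), n_scored = sum(ok), median = q[2],
       iqr = c(lower = q[1], upper = q[3]),
       pct_aphasia = 100 * mean(records$aphasia_flag[ok]))
}
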