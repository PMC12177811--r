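## Subject metadata table (TSV, UTF-8, '.' decimal -- BIDS-adjacent).

.subject_required_cols <- c(
  "subject_id", "group", "contralesional_hemisphere", "etiology",
  "viq", "piq", "age_at_scan", "age_at_surgery", "age_at_onset",
  "skeleton_mean_fa")

#' Read the subject metadata table
#'
#' Tab-separated, one row per subject, with columns `subject_id`, `group`
#' (`patient`/`control`), `contralesional_hemisphere` (`left`/`right`/`n/a`),
#' `etiology` (`congenital`/`acquired`/`n/a`), `viq`, `piq`, `age_at_scan`,
#' `age_at_surgery`, `age_at_onset` and `skeleton_mean_fa`. Unknown columns
#' are preserved. Empty etiology on controls becomes `"n/a"`.
#'
#' @param path TSV file path.
#' @return a `data.frame` of typed subject records.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", "n/a", ""), check.names = FALSE,
                   fileEncoding = "UTF-8")
  missing_cols <- setdiff(.subject_required_cols, names(df))
  if (length(missing_cols) > 0L)
    stop("subject table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in subject table: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  if (!all(df$group %in% c("patient", "control")))
    stop("group must be 'patient' or 'control'")
  for (col in c("viq", "piq", "age_at_scan", "age_at_surgery", "age_at_onset",
                "skeleton_mean_fa")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (any(!is.na(v) & is.na(num)))
        stop("non-numeric values in column '", col, "'")
      v <- num
    }
    df[[col]] <- v
  }
  df$etiology[is.na(df$etiology)] <- "n/a"
  df$contralesional_hemisphere[is.na(df$contralesional_hemisphere)] <- "n/a"
  bad <- df$group == "control" & df$etiology != "n/a"
  if (any(bad)) stop("controls must have etiology n/a: ",
                     paste(df$subject_id[bad], collapse = ", "))
  if (any(!is.na(df$skeleton_mean_fa) & df$skeleton_mean_fa <= 0))
    stop("skeleton_mean_fa must be positive")
  df
}

#' Write a subject metadata table
#' @param subjects data.frame as returned by [read_subjects()].
#' @param path output TSV path.
#' @export
write_subjects <- function(subjects, path) {
  write.table(subjects, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "n/a", fileEncoding = "UTF-8")
  invisible(path)
}
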