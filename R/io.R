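#' Read a subject/battery CSV
#'
#' Expected columns: `id, group, sex, age, education, nct_a_s, nct_b_s,
#' sdt_s, ltt_time_s, ltt_errors, dst_points, child_pugh, ascites, jaundice,
#' gi_bleed` (comma-separated, UTF-8, "." decimal separator, header row
#' mandatory; lines starting with `#` are audit-header comments and are
#' skipped). Empty cells become missing values. Numeric columns are
#' validated: times must be positive, `ltt_errors` and `dst_points`
#' non-negative, `age` positive, `education` non-negative; violations raise a
#' parse error naming the row and column.
#'
#' @param path CSV file path.
#' @return Data frame in the subject/battery schema.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, comment.char = "#", colClasses = "character",
                  na.strings = "", check.names = TRUE)
  missing_cols <- setdiff(subject_columns, names(raw))
  if (length(missing_cols)) {
    stop("malformed header in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), subject_columns)
  if (length(extra)) {
    stop("unknown column(s) in ", path, ": ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  numeric_cols <- list(
    age = "positive", education = "non-negative",
    nct_a_s = "positive", nct_b_s = "positive", sdt_s = "positive",
    ltt_time_s = "positive", ltt_errors = "non-negative",
    dst_points = "non-negative"
  )
  out <- raw
  for (col in names(numeric_cols)) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(vals))
    if (length(bad)) {
      stop("row ", bad[1], ", column ", col, ": non-numeric value '",
           raw[[col]][bad[1]], "'", call. = FALSE)
    }
    limit <- if (numeric_cols[[col]] == "positive") {
      which(!is.na(vals) & vals <= 0)
    } else {
      which(!is.na(vals) & vals < 0)
    }
    if (length(limit)) {
      stop("row ", limit[1], ", column ", col, ": value ",
           raw[[col]][limit[1]], " must be ", numeric_cols[[col]],
           call. = FALSE)
    }
    out[[col]] <- vals
  }
  bad_group <- which(!is.na(out$group) &
                     !(out$group %in% c("volunteer", "cirrhotic")))
  if (length(bad_group)) {
    stop("row ", bad_group[1], ", column group: unknown group '",
         out$group[bad_group[1]], "'", call. = FALSE)
  }
  bad_cp <- which(!is.na(out$child_pugh) & !(out$child_pugh %in% c("A", "B", "C")))
  if (length(bad_cp)) {
    stop("row ", bad_cp[1], ", column child_pugh: must be A, B or C",
         call. = FALSE)
  }
  out
}

# Audit header written at the top of every output file.
audit_header <- function(norms_name = NA, seed = NA, mhe_rule = NA) {
  paste0("# phesnorm ", as.character(packageVersion("phesnorm")),
         "; norms=", norms_name, "; seed=", seed, "; mhe_rule=", mhe_rule)
}

#' Write a data frame as CSV with an audit header
#'
#' Output files carry a leading `#` comment recording the package version,
#' the normative model used, the seed and the MHE rule, so every artifact is
#' traceable. [read_subjects()] and [read_scored()] skip these lines.
#'
#' @param data Data frame to write.
#' @param path Destination path.
#' @param norms_name,seed,mhe_rule Metadata recorded in the header.
#' @return `path`, invisibly.
#' @export
write_phes_csv <- function(data, path, norms_name = NA, seed = NA,
                           mhe_rule = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(audit_header(norms_name, seed, mhe_rule), con)
  write.csv(data, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a scored-subject CSV
#'
#' @param path CSV written by [write_phes_csv()] from [score_phes()] output.
#' @return Data frame with numeric score columns and logical `mhe`.
#' @export
read_scored <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- read.csv(path, comment.char = "#", na.strings = "")
  if (!all(c("phes", "mhe") %in% names(out))) {
    stop("not a scored-subject file (missing phes/mhe): ", path,
         call. = FALSE)
  }
  out$mhe <- as.logical(out$mhe)
  out
}
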