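# Per-animal records: the unit of statistical analysis.

#' Assemble and validate the per-animal cohort table
#'
#' One row per animal with its group label, normalized MVE and the
#' two-observer mean CD31/VEGF microvessel counts. Validation enforces the
#' structural invariants: unique animal ids, group ids in 0..5, counts
#' >= 0, and -- because the occlusive-plaque group is histology-only --
#' a missing normalized MVE for every group-5 row (and only a warning-free
#' pass when all other rows have one).
#'
#' @param records A data.frame with columns `animal_id`, `group_id`,
#'   `nmve`, `cd31_mean`, `vegf_mean`.
#' @return The validated data.frame with class `cohort_table`.
#' @export
build_cohort_table <- function(records) {
  req <- c("animal_id", "group_id", "nmve", "cd31_mean", "vegf_mean")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    ceus_stop(paste("records must be a data.frame with columns",
                    paste(req, collapse = ", ")), "integrity_error")
  df <- records[, req]
  if (nrow(df) == 0L)
    ceus_stop("cohort table has no rows", "integrity_error")
  if (anyDuplicated(df$animal_id))
    ceus_stop("duplicate animal_id in cohort table", "integrity_error")
  if (any(!df$group_id %in% 0:5))
    ceus_stop("group_id must be an integer 0..5", "integrity_error")
  counts <- c(df$cd31_mean, df$vegf_mean)
  if (any(!is.finite(counts)) || any(counts < 0))
    ceus_stop("microvessel counts must be finite and >= 0", "integrity_error")
  g5 <- df$group_id == 5
  if (any(g5 & !is.na(df$nmve)))
    ceus_stop("group 5 is histology-only: its rows must not carry a normalized MVE",
              "integrity_error")
  if (any(!g5 & is.na(df$nmve)))
    warning(sprintf("%d non-group-5 rows have a missing normalized MVE",
                    sum(!g5 & is.na(df$nmve))), call. = FALSE)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read / write the cohort table as CSV
#'
#' Columns `animal_id`, `group_id`, `nmve`, `cd31_mean`, `vegf_mean`;
#' numeric fields carry 9 significant digits so a write/read round trip
#' reproduces the table exactly as validated.
#'
#' @param x A `cohort_table`.
#' @param path CSV path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a validated `cohort_table`.
#' @export
write_cohort_csv <- function(x, path) {
  stopifnot(inherits(x, "cohort_table"))
  out <- as.data.frame(x)
  for (col in c("nmve", "cd31_mean", "vegf_mean"))
    out[[col]] <- format_num(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$nmve <- as.numeric(df$nmve)
  build_cohort_table(df)
}
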