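#' Table readers for the pipeline's CSV formats
#'
#' All readers expect RFC-4180 CSV with a header row, a locale-independent
#' decimal point, and UTF-8 text; Unicode minus signs (U+2212), as printed
#' in some published tables, are normalised to ASCII on input. Validation
#' failures are signalled as conditions of class `digenic_validation_error`
#' naming the offending row and column.
#'
#' Formats (full schema documentation ships in `inst/docs/formats.md`):
#' * germination: `sample_id, rc_dosage, pb_dosage, n_total`, then one
#'   column per counting day named `d<day>` (e.g. `d2..d7`, or `d3,d5,d7`).
#' * imbibition (long): `sample_id, rc_dosage, pb_dosage, time_h`, and
#'   `wc` or (`weight` + `w0`).
#' * F2 phenotypes: `sample_id, rc_dosage, pb_dosage`, plus one or more
#'   numeric response columns (e.g. `gp`, `gi`).
#' * flavonoid cell summaries: `rc_dosage, pb_dosage, dpa, chemical, mean,
#'   se`, optional `line`, `detected`.
#'
#' @param path CSV file path.
#' @param counts `"incremental"` (counts are seeds newly germinated on each
#'   counting day; the stored representation) or `"cumulative"` (running
#'   totals, differenced at ingestion with a non-negativity check).
#' @return `read_germination()`: list of [germination_record()].
#' @name readers
NULL

validation_error <- function(msg, row = NULL, column = NULL) {
  loc <- c(if (!is.null(row)) sprintf("row %s", row),
           if (!is.null(column)) sprintf("column '%s'", column))
  if (length(loc)) msg <- sprintf("%s (%s)", msg, paste(loc, collapse = ", "))
  stop(structure(class = c("digenic_validation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.read_csv <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  # normalise Unicode minus in character columns before numeric coercion
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) df[[j]] <- gsub("−", "-", df[[j]])
  }
  df
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    validation_error(sprintf("%s table lacks required column(s): %s",
                             what, paste(miss, collapse = ", ")))
  }
}

.as_num <- function(df, col, what) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]))
  if (length(bad)) {
    validation_error(sprintf("%s: non-numeric value", what),
                     row = bad[1L], column = col)
  }
  v
}

.check_dosage_col <- function(df, col) {
  v <- .as_num(df, col, "dosage")
  bad <- which(!v %in% 0:2)
  if (length(bad)) {
    validation_error("dosage must be 0, 1, or 2", row = bad[1L], column = col)
  }
  as.integer(v)
}

#' @rdname readers
#' @export
read_germination <- function(path, counts = c("incremental", "cumulative")) {
  counts <- match.arg(counts)
  df <- .read_csv(path)
  .require_cols(df, c("sample_id", "rc_dosage", "pb_dosage", "n_total"),
                "germination")
  day_cols <- grep("^d[0-9]+$", names(df), value = TRUE)
  if (!length(day_cols)) {
    validation_error("germination table has no day columns (d<day>)")
  }
  days <- as.integer(sub("^d", "", day_cols))
  day_cols <- day_cols[order(days)]; days <- sort(days)
  rc <- .check_dosage_col(df, "rc_dosage")
  pb <- .check_dosage_col(df, "pb_dosage")
  n_total <- .as_num(df, "n_total", "n_total")
  cmat <- sapply(day_cols, function(cl) .as_num(df, cl, "count"))
  cmat <- matrix(cmat, nrow = nrow(df))
  lapply(seq_len(nrow(df)), function(i) {
    ci <- cmat[i, ]
    if (counts == "cumulative") {
      inc <- diff(c(0, ci))
      neg <- which(inc < 0)
      if (length(neg)) {
        validation_error("cumulative counts must be non-decreasing",
                         row = i, column = day_cols[neg[1L]])
      }
      ci <- inc
    }
    neg <- which(ci < 0)
    if (length(neg)) {
      validation_error("negative germination count",
                       row = i, column = day_cols[neg[1L]])
    }
    if (sum(ci) > n_total[i]) {
      validation_error("germinated seeds exceed n_total", row = i,
                       column = "n_total")
    }
    germination_record(as.character(df$sample_id[i]),
                       digenic_genotype(rc[i], pb[i]),
                       n_total[i], days, ci)
  })
}

#' Flatten germination records to the tabular format
#'
#' Inverse of [read_germination()] with `counts = "incremental"`.
#'
#' @param records list of [germination_record()] sharing one schedule.
#' @return data frame with `sample_id, rc_dosage, pb_dosage, n_total` and
#'   `d<day>` columns.
#' @export
germination_table <- function(records) {
  sched <- records[[1L]]$schedule
  same <- vapply(records, function(r) identical(r$schedule, sched), logical(1))
  if (!all(same)) stop("records have differing schedules", call. = FALSE)
  out <- data.frame(
    sample_id = vapply(records, `[[`, character(1), "sample_id"),
    rc_dosage = vapply(records, function(r) r$genotype$rc_dosage[1L],
                       integer(1)),
    pb_dosage = vapply(records, function(r) r$genotype$pb_dosage[1L],
                       integer(1)),
    n_total = vapply(records, `[[`, integer(1), "n_total"))
  cmat <- t(vapply(records, `[[`, numeric(length(sched)), "counts"))
  colnames(cmat) <- paste0("d", sched)
  cbind(out, as.data.frame(cmat))
}

#' @rdname readers
#' @param input_kind `"wc"` (water-content fractions supplied directly) or
#'   `"weight"` (gram weights plus a `w0` column; wc is derived).
#' @return `read_imbibition()`: long-format data frame with columns
#'   `sample_id, rc_dosage, pb_dosage, time_h, wc` for [fit_per_timepoint()].
#' @export
read_imbibition <- function(path, input_kind = c("wc", "weight")) {
  input_kind <- match.arg(input_kind)
  df <- .read_csv(path)
  .require_cols(df, c("sample_id", "rc_dosage", "pb_dosage", "time_h"),
                "imbibition")
  rc <- .check_dosage_col(df, "rc_dosage")
  pb <- .check_dosage_col(df, "pb_dosage")
  tt <- .as_num(df, "time_h", "time")
  if (input_kind == "wc") {
    .require_cols(df, "wc", "imbibition")
    wc <- .as_num(df, "wc", "water content")
  } else {
    .require_cols(df, c("weight", "w0"), "imbibition")
    w <- .as_num(df, "weight", "weight")
    w0 <- .as_num(df, "w0", "initial weight")
    bad <- which(w0 <= 0)
    if (length(bad)) {
      validation_error("w0 must be > 0", row = bad[1L], column = "w0")
    }
    wc <- (w - w0) / w0
  }
  data.frame(sample_id = as.character(df$sample_id), rc_dosage = rc,
             pb_dosage = pb, time_h = tt, wc = wc)
}

#' @rdname readers
#' @param response names of the response column(s) to validate as numeric;
#'   defaults to every column beyond the identifiers.
#' @return `read_f2_phenotypes()`: data frame with dosages validated.
#' @export
read_f2_phenotypes <- function(path, response = NULL) {
  df <- .read_csv(path)
  .require_cols(df, c("sample_id", "rc_dosage", "pb_dosage"), "phenotype")
  df$rc_dosage <- .check_dosage_col(df, "rc_dosage")
  df$pb_dosage <- .check_dosage_col(df, "pb_dosage")
  if (is.null(response)) {
    response <- setdiff(names(df), c("sample_id", "rc_dosage", "pb_dosage"))
  }
  for (cl in response) df[[cl]] <- .as_num(df, cl, "response")
  df
}

#' @rdname readers
#' @return `read_flavonoid()`: cell-summary data frame compatible with
#'   [flavonoid_records()].
#' @export
read_flavonoid <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, c("rc_dosage", "pb_dosage", "dpa", "chemical",
                      "mean", "se"), "flavonoid")
  df$rc_dosage <- .check_dosage_col(df, "rc_dosage")
  df$pb_dosage <- .check_dosage_col(df, "pb_dosage")
  df$dpa <- .as_num(df, "dpa", "dpa")
  df$mean <- .as_num(df, "mean", "mean")
  df$se <- .as_num(df, "se", "se")
  bad <- which(df$se < 0)
  if (length(bad)) {
    validation_error("se must be >= 0", row = bad[1L], column = "se")
  }
  if (is.null(df$detected)) df$detected <- df$mean > 0 | df$se > 0
  if (is.null(df$line)) df$line <- format(digenic_genotype(df$rc_dosage,
                                                           df$pb_dosage))
  df
}

# full-precision numeric formatting so written reports round-trip exactly
.fmt_num <- function(x) {
  ifelse(is.na(x), NA, sprintf("%.17g", x))
}

#' Write and read a model-fit report
#'
#' The report mirrors the published effect-table layout: one row for the
#' model mean, one per retained term (effect, standard error, p-value,
#' sequential R-squared increment as a percentage, entry order), and a
#' `Total` row carrying the model R-squared. Numbers are written at full
#' precision so a read-back reproduces them bit-exactly.
#'
#' @param fit a [fit_digenic()] result.
#' @param path output CSV path.
#' @return `write_fit_report()`: the report data frame, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "digenic_fit"))
  ct <- coef_table(fit)
  rep_df <- data.frame(
    term = c(ct$term, "Total"),
    effect = c(ct$coefficient, NA),
    standard_error = c(ct$standard_error, NA),
    p_value = c(ct$p_value, NA),
    r2_pct = c(ct$r2_increment * 100, fit$total_r2 * 100),
    entry_order = c(ct$entry_order, NA))
  out <- rep_df
  for (cl in c("effect", "standard_error", "p_value", "r2_pct")) {
    out[[cl]] <- .fmt_num(rep_df[[cl]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(rep_df)
}

#' @rdname write_fit_report
#' @return `read_fit_report()`: the report as a data frame with numeric
#'   columns restored.
#' @export
read_fit_report <- function(path) {
  df <- .read_csv(path)
  for (cl in c("effect", "standard_error", "p_value", "r2_pct")) {
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  }
  df$entry_order <- suppressWarnings(as.integer(df$entry_order))
  df
}
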