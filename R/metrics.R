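#' Germination count records
#'
#' A germination record holds the raw outcome of a germination test for one
#' seed sample: the total number of seeds plated (`n_total`), the counting
#' schedule (days of imbibition at which germinated seeds were scored,
#' e.g. daily from day 2 to 7 for isogenic lines, or days 3/5/7 for an F2
#' test), and the *incremental* number of seeds newly germinated at each
#' counting day. The test horizon `T` (last day, 7 by convention) sets the
#' weights used by the germination index.
#'
#' Counts are stored incrementally (germinated ON day d). Cumulative input
#' must be differenced at ingestion; [read_germination()] does this when
#' `counts = "cumulative"`.
#'
#' @param sample_id sample identifier (scalar).
#' @param genotype a one-row [digenic_genotype()], or `NULL` when the
#'   genotype is irrelevant (pure metric computations).
#' @param n_total total seeds in the sample (N > 0).
#' @param schedule strictly increasing integer counting days.
#' @param counts incremental germinated counts aligned to `schedule`;
#'   non-negative, summing to at most `n_total`.
#' @param horizon last day of the test `T` (default `max(schedule)`, the
#'   conventional value is 7).
#' @return An object of class `germination_record`.
#' @examples
#' r <- germination_record("s1", NULL, 60, 2:7, c(30, 15, 0, 0, 0, 0))
#' cumulative_gp(r, 3) # 75
#' germination_index(r)
#' @export
germination_record <- function(sample_id, genotype = NULL, n_total,
                               schedule, counts,
                               horizon = max(schedule)) {
  stopifnot(length(sample_id) == 1L)
  schedule <- as.integer(schedule)
  if (length(schedule) == 0L) stop("empty counting schedule", call. = FALSE)
  n_total <- as.integer(n_total)
  counts <- as.numeric(counts)
  horizon <- as.integer(horizon)
  if (is.na(n_total) || n_total <= 0L) stop("n_total must be > 0", call. = FALSE)
  if (length(counts) != length(schedule)) {
    stop("counts and schedule must align", call. = FALSE)
  }
  if (any(diff(schedule) <= 0L)) {
    stop("schedule must be strictly increasing", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(counts) > n_total + 1e-8) {
    stop("sum(counts) exceeds n_total", call. = FALSE)
  }
  if (max(schedule) > horizon) {
    stop("schedule extends beyond the test horizon", call. = FALSE)
  }
  if (!is.null(genotype) && !inherits(genotype, "digenic_genotype")) {
    genotype <- digenic_genotype(genotype[[1L]], genotype[[2L]])
  }
  structure(list(sample_id = sample_id, genotype = genotype,
                 n_total = n_total, schedule = schedule,
                 counts = counts, horizon = horizon),
            class = "germination_record")
}

#' Cumulative germination percentage
#'
#' `GP_i = 100 * sum(n_d / N)` over counting days `d <= i`: the percentage
#' of plated seeds that have germinated by day `i` of imbibition. Monotone
#' non-decreasing in the day; at the horizon it equals
#' `100 * total germinated / N` exactly.
#'
#' @param record a [germination_record()].
#' @param day day of imbibition; must not precede the first counting day
#'   (GP is undefined before the first count).
#' @return percentage in \[0, 100\].
#' @export
cumulative_gp <- function(record, day = record$horizon) {
  stopifnot(inherits(record, "germination_record"))
  if (day < min(record$schedule)) {
    stop(sprintf("GP undefined before the first counting day (%d)",
                 min(record$schedule)), call. = FALSE)
  }
  100 * sum(record$counts[record$schedule <= day]) / record$n_total
}

#' Weighted germination index
#'
#' The germination index (GI) is a weighted germination percentage that
#' rewards early germination:
#' \deqn{GI = 100 \sum_d n_d (T + 1 - d) / (N T)}
#' where the weight for counting day `d` is `T + 1 - d` and `T` is the test
#' horizon. With `T = 7` this yields weights 6..1 for daily counts on days
#' 2..7, and weights 5, 3, 1 for the three-day schedule \{3, 5, 7\} — the two
#' published schedules — without special-casing either. GI is 0 when nothing
#' germinates and at most `100 (T + 1 - d_min) / T` (all seeds on the first
#' counting day).
#'
#' @param record a [germination_record()].
#' @return percentage in \[0, 100\].
#' @export
germination_index <- function(record) {
  stopifnot(inherits(record, "germination_record"))
  w <- record$horizon + 1L - record$schedule
  100 * sum(record$counts * w) / (record$n_total * record$horizon)
}

#' Seed water content during imbibition
#'
#' An imbibition series records the weight trajectory of a seed sample
#' soaked in water; the water content at time `i` is the relative weight
#' gain `wc_i = (w_i - w_0) / w_0`, with `w_0` the pre-soak dry weight.
#'
#' @param sample_id sample identifier.
#' @param genotype a one-row [digenic_genotype()] or `NULL`.
#' @param w0 initial dry weight in grams (> 0).
#' @param times hours post-soaking, strictly increasing.
#' @param weights sample weights `w_i` in grams, aligned to `times`.
#' @return An object of class `imbibition_series`.
#' @export
imbibition_series <- function(sample_id, genotype = NULL, w0, times, weights) {
  stopifnot(length(sample_id) == 1L)
  if (!is.finite(w0) || w0 <= 0) stop("w0 must be > 0", call. = FALSE)
  if (length(times) != length(weights)) {
    stop("times and weights must align", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  structure(list(sample_id = sample_id, genotype = genotype, w0 = w0,
                 times = as.numeric(times), weights = as.numeric(weights)),
            class = "imbibition_series")
}

#' @rdname imbibition_series
#' @param series an [imbibition_series()].
#' @return `water_content()`: numeric vector of fractions `wc_i`, one per
#'   time point.
#' @export
water_content <- function(series) {
  stopifnot(inherits(series, "imbibition_series"))
  (series$weights - series$w0) / series$w0
}

#' Relative transcript abundance from qRT-PCR cycle thresholds
#'
#' Computes `2^-(Ct_target - Ct_control)`, the relative expression of a
#' target gene against an internal control (here *ACTIN*) from quantitative
#' real-time PCR cycle-threshold values. Equal thresholds give 1; each unit
#' of delta-Ct halves the estimate.
#'
#' @param ct_target cycle threshold of the target gene (finite, > 0).
#' @param ct_control cycle threshold of the internal control.
#' @return positive numeric vector of relative expression levels.
#' @export
relative_expression <- function(ct_target, ct_control) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_control)) ||
      any(ct_target <= 0) || any(ct_control <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  2^(-(ct_target - ct_control))
}

#' @export
print.germination_record <- function(x, ...) {
  cat(sprintf("germination_record '%s': N = %d, days %s, horizon %d\n",
              x$sample_id, x$n_total,
              paste(x$schedule, collapse = ","), x$horizon))
  cat(sprintf("  counts: %s | GP_T = %.1f%%, GI = %.1f%%\n",
              paste(x$counts, collapse = ","),
              cumulative_gp(x), germination_index(x)))
  invisible(x)
}
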