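#' Per-timepoint digenic effects along an imbibition time course
#'
#' At each measurement time, the seed water content of the four homozygous
#' genotype classes is analysed with the two-locus additive +
#' additive-by-additive model (no selection: all three genetic terms are
#' always estimated, and per-term significance is carried as a flag at the
#' raw 0.05 level). The background `mu(t)` — which on a balanced design
#' equals the unweighted mean of the four class means and is independent of
#' the genetic effects — traces the triphasic water-uptake curve and feeds
#' [segment_phases()].
#'
#' @param panel long-format data frame with columns `sample_id`,
#'   `rc_dosage`, `pb_dosage`, `time_h`, and `wc` (water-content fraction),
#'   or a list of [imbibition_series()] (converted with
#'   [imbibition_panel()]). All four homozygous classes must be present
#'   with at least 2 replicates at every time point.
#' @param alpha significance level for the per-time flags (default 0.05; no
#'   correction is applied across time points).
#' @return data frame of class `effect_trajectory`, one row per time:
#'   `time_h`, `mu`, `a1`, `a1_sig`, `a2`, `a2_sig`, `i_a1a2`,
#'   `i_a1a2_sig`, `r2_total`.
#' @export
fit_per_timepoint <- function(panel, alpha = 0.05) {
  panel <- as.data.frame(panel)
  need <- c("sample_id", "rc_dosage", "pb_dosage", "time_h", "wc")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop(sprintf("panel lacks columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  times <- sort(unique(panel$time_h))
  spec <- model_spec("hom", alpha = alpha)
  rows <- lapply(times, function(tt) {
    sub <- panel[panel$time_h == tt, , drop = FALSE]
    cls <- table(paste(sub$rc_dosage, sub$pb_dosage))
    if (length(cls) < 4L || any(cls < 2L)) {
      stop(sprintf(
        "time %g h: need >= 2 replicates of all 4 homozygous classes", tt),
        call. = FALSE)
    }
    d <- build_design(
      data.frame(rc_dosage = sub$rc_dosage, pb_dosage = sub$pb_dosage,
                 y = sub$wc, sample_id = sub$sample_id), spec)
    # constant response: all effects are exactly zero, nothing significant
    if (stats::sd(d$y) < 1e-10 * (1 + abs(mean(d$y)))) {
      return(data.frame(time_h = tt, mu = mean(d$y),
                        a1 = 0, a1_sig = FALSE, a2 = 0, a2_sig = FALSE,
                        i_a1a2 = 0, i_a1a2_sig = FALSE, r2_total = 0))
    }
    f <- fit_ols(d)
    sst <- sum((d$y - mean(d$y))^2)
    r2 <- if (sst > 0) 1 - f$rss / sst else 0
    co <- f$coefficients; pv <- f$p_value
    sig <- function(tm) isTRUE(pv[tm] < alpha)
    data.frame(time_h = tt, mu = unname(co["(Intercept)"]),
               a1 = unname(co["a1"]), a1_sig = sig("a1"),
               a2 = unname(co["a2"]), a2_sig = sig("a2"),
               i_a1a2 = unname(co["i_a1a2"]), i_a1a2_sig = sig("i_a1a2"),
               r2_total = r2)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("effect_trajectory", "data.frame")
  out
}

#' Assemble a long-format panel from imbibition series
#'
#' @param series_list list of [imbibition_series()] with genotypes; water
#'   content is derived from the weights via [water_content()].
#' @return long-format data frame suitable for [fit_per_timepoint()].
#' @export
imbibition_panel <- function(series_list) {
  do.call(rbind, lapply(series_list, function(s) {
    stopifnot(inherits(s, "imbibition_series"))
    if (is.null(s$genotype)) {
      stop(sprintf("series '%s' lacks a genotype", s$sample_id),
           call. = FALSE)
    }
    data.frame(sample_id = s$sample_id,
               rc_dosage = s$genotype$rc_dosage[1L],
               pb_dosage = s$genotype$pb_dosage[1L],
               time_h = s$times, wc = water_content(s))
  }))
}

#' Segment a water-uptake trajectory into the three germination phases
#'
#' Germinating seeds take up water in three phases: rapid imbibition (I), a
#' plateau (II), and post-germination resumption of uptake (III). The
#' published account identifies the phases visually; here a transparent,
#' deterministic substitute is used: a continuous three-segment
#' piecewise-linear least-squares fit, with the two breakpoints searched
#' exhaustively over all admissible pairs of observed time points (each
#' segment must contain at least two observations) and the pair minimising
#' the residual sum of squares retained. Ties go to the earliest pair.
#'
#' A trajectory that an ordinary straight line already fits exactly has no
#' identifiable phase structure and raises an error. A fit whose middle
#' segment is not the flattest (no plateau) is returned with
#' `valid_plateau = FALSE` and a warning.
#'
#' @param times measurement times in hours (>= 6 points).
#' @param mu_values background water-content values `mu(t)` from
#'   [fit_per_timepoint()] (or any uptake trajectory).
#' @return list of class `phase_segmentation`: `breakpoints` (end of phase
#'   I, end of phase II), `slopes` (per-phase rates, 1/h), `fit_sse`,
#'   `fitted`, `valid_plateau`.
#' @export
segment_phases <- function(times, mu_values) {
  stopifnot(length(times) == length(mu_values))
  if (length(times) < 6L) {
    stop("need at least 6 time points to segment three phases", call. = FALSE)
  }
  o <- order(times)
  times <- as.numeric(times[o]); mu_values <- as.numeric(mu_values[o])
  sst <- sum((mu_values - mean(mu_values))^2)
  # non-identifiability: a single line explains the trajectory exactly
  line_rss <- sum(stats::lm.fit(cbind(1, times), mu_values)$residuals^2)
  if (line_rss <= 1e-8 * (sst + .Machine$double.eps)) {
    stop("trajectory is a single straight line; phases are not identifiable",
         call. = FALSE)
  }
  n <- length(times)
  # candidate breakpoints: observed times with >= 2 points per segment
  best <- NULL
  for (i1 in 2:(n - 4L)) {
    for (i2 in (i1 + 2L):(n - 2L)) {
      b1 <- times[i1]; b2 <- times[i2]
      X <- cbind(1, times, pmax(times - b1, 0), pmax(times - b2, 0))
      f <- stats::lm.fit(X, mu_values)
      sse <- sum(f$residuals^2)
      if (is.null(best) || sse < best$sse - 1e-12) {
        best <- list(b1 = b1, b2 = b2, sse = sse, coef = f$coefficients,
                     fitted = drop(X %*% f$coefficients))
      }
    }
  }
  if (is.null(best)) stop("no admissible breakpoint pair", call. = FALSE)
  slopes <- cumsum(best$coef[2:4])
  valid <- which.min(abs(slopes)) == 2L
  if (!valid) {
    warning("middle segment is not the flattest: no valid plateau",
            call. = FALSE)
  }
  structure(list(breakpoints = c(best$b1, best$b2),
                 slopes = unname(slopes), fit_sse = best$sse,
                 fitted = best$fitted, valid_plateau = valid),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf(
    "Three-phase segmentation: phase I ends %.1f h, phase II ends %.1f h\n",
    x$breakpoints[1], x$breakpoints[2]))
  cat(sprintf("  slopes (1/h): I %.4g, II %.4g, III %.4g; SSE %.3g%s\n",
              x$slopes[1], x$slopes[2], x$slopes[3], x$fit_sse,
              if (x$valid_plateau) "" else " [no valid plateau]"))
  invisible(x)
}
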