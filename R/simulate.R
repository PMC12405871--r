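#' Default simulation configuration
#'
#' Bundles the default parameter sets for all synthetic-data generators.
#' Wherever a published value exists it is used directly: the F2 population
#' size (259 phenotyped plants), the F2 effect set for germination
#' percentage (a1 = -15.0, d1 = -3.9, a2 = -8.2, i_a1a2 = -6.2 about a
#' background of 78.6, with residual SD 14.1 chosen so the model R-squared
#' is ~0.45 as reported), the per-line 7-day germination targets (82, 50,
#' 69, 16 percent), the flavonoid cell means/SEs, the 0-96 h imbibition
#' sampling grid, and phase breakpoints at 30 and 50 h. Values the source
#' does not state (germination-day timing law and dispersion, imbibition
#' slopes and noise) are fixed plausible defaults, documented in the
#' package vignette.
#'
#' @param seed master RNG seed; sub-generator seeds are derived from it so
#'   that adding one generator to a run does not perturb the draws of the
#'   others.
#' @return nested list of class `sim_config` with components `f2`,
#'   `phenotype`, `germination`, `flavonoid`, `imbibition`, and per-block
#'   derived `seed`s.
#' @export
sim_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  child <- function(k) (seed * 67L + k * 10007L) %% 2147483629L
  classes <- data.frame(
    rc_dosage = c(0L, 2L, 0L, 2L), pb_dosage = c(0L, 0L, 2L, 2L),
    p_g = c(0.82, 0.50, 0.69, 0.16),       # published GP7 targets / 100
    mean_day = c(3.0, 4.0, 3.5, 5.0),      # plausible, not published
    day_scale = 0.8
  )
  structure(list(
    seed = seed,
    f2 = list(n = 259L, seed = child(1L)),
    phenotype = list(
      mu = 78.6,
      effects = c(a1 = -15.0, d1 = -3.9, a2 = -8.2, i_a1a2 = -6.2),
      residual_sd = 14.1, seed = child(2L)),
    germination = list(
      classes = classes, n_total = 60L, n_samples = 9L,
      schedule = 2:7, horizon = 7L, seed = child(3L)),
    flavonoid = list(
      table = flavonoid_reference(), n_rep = 3L, detect_floor = 0,
      seed = child(4L)),
    imbibition = list(
      breakpoints = c(30, 50), slopes = c(0.012, 0.001, 0.004),
      noise_sd = 0.005,
      times = c(0.5, seq(2, 12, 2), seq(16, 60, 4), seq(72, 96, 12)),
      w0 = 3.0, n_samples = 5L,
      effects = c(a1 = -0.03, a2 = -0.02, i_a1a2 = 0),
      onsets = c(a1 = 28, a2 = 6, i_a1a2 = 6),
      seed = child(5L))
  ), class = "sim_config")
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

#' Simulate F2 genotypes from selfing a double heterozygote
#'
#' Each locus segregates independently 1:2:1 (the loci sit on different
#' chromosomes, 4 and 7, and are treated as unlinked), so the nine digenic
#' classes occur with the product frequencies — 1/16 for each double
#' homozygote up to 1/4 for the double heterozygote.
#'
#' @param n number of F2 individuals.
#' @param seed RNG seed (optional).
#' @return a [digenic_genotype()] data frame with `n` rows.
#' @export
simulate_f2_genotypes <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  .with_seed(seed, {
    digenic_genotype(
      sample(0:2, n, replace = TRUE, prob = c(1, 2, 1) / 4),
      sample(0:2, n, replace = TRUE, prob = c(1, 2, 1) / 4))
  })
}

#' Simulate quantitative phenotypes from a digenic linear model
#'
#' Generates `y = mu + sum(effect * code) + N(0, residual_sd^2)` with the
#' contrast codes of [code_additive()] and [code_dominance()] — the
#' additive-dominance-epistasis model read as a generative process.
#'
#' @param genotypes a [digenic_genotype()] data frame.
#' @param effects named numeric vector over the model's term labels (any
#'   subset of `a1, d1, a2, d2, i_a1a2, i_a1d2, i_d1a2, i_d1d2`).
#' @param mu background mean.
#' @param residual_sd residual standard deviation (>= 0).
#' @param seed RNG seed (optional).
#' @return numeric response vector.
#' @export
simulate_phenotypes <- function(genotypes, effects, mu = 0,
                                residual_sd = 0, seed = NULL) {
  stopifnot(inherits(genotypes, "digenic_genotype"), residual_sd >= 0)
  bad <- setdiff(names(effects), .MODEL_TERMS$f2)
  if (length(bad)) {
    stop(sprintf("unknown effect term(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  spec <- model_spec("f2", terms = .MODEL_TERMS$f2)
  rec <- data.frame(rc_dosage = genotypes$rc_dosage,
                    pb_dosage = genotypes$pb_dosage, y = 0)
  X <- build_design(rec, spec)$X
  eta <- mu + drop(X[, names(effects), drop = FALSE] %*% unname(effects))
  .with_seed(seed, eta + stats::rnorm(length(eta), 0, residual_sd))
}

# Discretized logistic law over days 1..horizon: P(day = d) proportional to
# F(d + 1/2) - F(d - 1/2), renormalized within the observation window.
.day_probs <- function(mean_day, day_scale, horizon) {
  d <- seq_len(horizon)
  if (day_scale <= 0) {
    p <- as.numeric(d == min(max(round(mean_day), 1L), horizon))
  } else {
    p <- stats::plogis(d + 0.5, mean_day, day_scale) -
         stats::plogis(d - 0.5, mean_day, day_scale)
  }
  p / sum(p)
}

#' Simulate germination count series
#'
#' Emulates a Petri-dish germination test. Each seed germinates within the
#' test window with its genotype's probability `p_g`; germinating seeds
#' draw a germination day from a discretized logistic law (location
#' `mean_day`, scale `day_scale`) truncated to the test horizon, and a seed
#' is scored at the first counting day on or after its germination day.
#' The expected horizon germination percentage is `100 * p_g` exactly, so
#' class configurations calibrated to target GP values are unbiased by
#' construction.
#'
#' @param genotypes a [digenic_genotype()] data frame, one row per sample.
#' @param p_g per-sample (or scalar) germination probability.
#' @param mean_day per-sample (or scalar) mean germination day.
#' @param day_scale logistic scale of the timing law (0 = all seeds on
#'   `round(mean_day)`).
#' @param n_total seeds per sample.
#' @param schedule counting days; `horizon` the last test day.
#' @param horizon see `schedule`.
#' @param seed RNG seed (optional).
#' @return list of [germination_record()].
#' @export
simulate_germination_counts <- function(genotypes, p_g, mean_day,
                                        day_scale = 0.8, n_total = 60L,
                                        schedule = 2:7,
                                        horizon = max(schedule),
                                        seed = NULL) {
  stopifnot(inherits(genotypes, "digenic_genotype"),
            all(p_g >= 0 & p_g <= 1))
  n <- nrow(genotypes)
  p_g <- rep_len(p_g, n); mean_day <- rep_len(mean_day, n)
  day_scale <- rep_len(day_scale, n)
  .with_seed(seed, lapply(seq_len(n), function(s) {
    germ <- stats::rbinom(1L, n_total, p_g[s])
    counts <- numeric(length(schedule))
    if (germ > 0) {
      days <- sample(seq_len(horizon), germ, replace = TRUE,
                     prob = .day_probs(mean_day[s], day_scale[s], horizon))
      # score at the first counting day on/after germination
      bin <- findInterval(days, schedule, left.open = TRUE) + 1L
      tab <- tabulate(bin, nbins = length(schedule))
      counts <- as.numeric(tab)
    }
    germination_record(sprintf("sim%03d", s), genotypes[s, ], n_total,
                       schedule, counts, horizon)
  }))
}

#' Simulate a flavonoid content panel
#'
#' Draws `n_rep` Gaussian replicates per genotype-by-time-by-chemical cell
#' around the configured cell mean with SD = SE * sqrt(n_rep) (so the
#' sampling SE of the cell mean matches the configured SE). Cells marked
#' not-detectable yield exact zeros flagged `detected = FALSE`; simulated
#' values falling below `detect_floor` are likewise recorded as 0 and
#' flagged.
#'
#' @param table cell-summary data frame as from [flavonoid_reference()]
#'   (the default).
#' @param n_rep replicates per cell (default 3).
#' @param detect_floor detection limit; values below it become 0 (default 0).
#' @param seed RNG seed (optional).
#' @return data frame with columns `line`, `rc_dosage`, `pb_dosage`,
#'   `dpa`, `chemical`, `replicate`, `value`, `detected`.
#' @export
simulate_flavonoid_panel <- function(table = flavonoid_reference(),
                                     n_rep = 3L, detect_floor = 0,
                                     seed = NULL) {
  if (any(table$mean < 0)) stop("negative cell means", call. = FALSE)
  .with_seed(seed, do.call(rbind, lapply(seq_len(nrow(table)), function(i) {
    row <- table[i, ]
    if (row$detected) {
      v <- stats::rnorm(n_rep, row$mean, row$se * sqrt(n_rep))
    } else {
      v <- rep(0, n_rep)
    }
    det <- row$detected & v > detect_floor
    v[!det] <- 0
    data.frame(line = row$line, rc_dosage = row$rc_dosage,
               pb_dosage = row$pb_dosage, dpa = row$dpa,
               chemical = row$chemical, replicate = seq_len(n_rep),
               value = v, detected = det)
  })))
}

# Continuous three-phase piecewise-linear base curve through the origin.
.triphasic <- function(t, breakpoints, slopes) {
  b1 <- breakpoints[1]; b2 <- breakpoints[2]
  slopes[1] * pmin(t, b1) +
    slopes[2] * pmin(pmax(t - b1, 0), b2 - b1) +
    slopes[3] * pmax(t - b2, 0)
}

#' Simulate triphasic seed water-uptake series
#'
#' Water content follows a continuous three-segment piecewise-linear base
#' curve (imbibition / plateau / post-germination) plus genotype-specific
#' additive and epistatic offsets that switch on at configurable onset
#' times and grow linearly to their terminal magnitude at the last time
#' point, plus Gaussian measurement noise. Weights are derived as
#' `w0 * (1 + wc)`; at time 0 the water content is exactly 0.
#'
#' @param genotypes a [digenic_genotype()] data frame (homozygous), one row
#'   per sample.
#' @param breakpoints phase boundaries (end of phase I, end of phase II),
#'   both inside the time grid.
#' @param slopes per-phase uptake rates (1/h).
#' @param times measurement grid in hours.
#' @param effects named terminal magnitudes for `a1`, `a2`, `i_a1a2`.
#' @param onsets named onset times (h) for the same terms.
#' @param noise_sd measurement noise SD on the wc scale.
#' @param w0 initial sample dry weight (g).
#' @param seed RNG seed (optional).
#' @return list of [imbibition_series()].
#' @export
simulate_imbibition <- function(genotypes,
                                breakpoints = c(30, 50),
                                slopes = c(0.012, 0.001, 0.004),
                                times = c(0.5, seq(2, 12, 2),
                                          seq(16, 60, 4), seq(72, 96, 12)),
                                effects = c(a1 = -0.03, a2 = -0.02,
                                            i_a1a2 = 0),
                                onsets = c(a1 = 28, a2 = 6, i_a1a2 = 6),
                                noise_sd = 0.005, w0 = 3.0, seed = NULL) {
  stopifnot(inherits(genotypes, "digenic_genotype"))
  if (breakpoints[1] <= 0 ||
      breakpoints[1] >= breakpoints[2] || breakpoints[2] >= max(times)) {
    stop("breakpoints must satisfy 0 < b1 < b2 < max(times)", call. = FALSE)
  }
  tmax <- max(times)
  ramp <- function(term) {
    on <- onsets[[term]]
    if (tmax <= on) return(rep(0, length(times)))
    effects[[term]] * pmax(times - on, 0) / (tmax - on)
  }
  base <- .triphasic(times, breakpoints, slopes)
  .with_seed(seed, lapply(seq_len(nrow(genotypes)), function(s) {
    xi <- code_additive(genotypes$rc_dosage[s])
    xj <- code_additive(genotypes$pb_dosage[s])
    wc <- base + ramp("a1") * xi + ramp("a2") * xj +
      ramp("i_a1a2") * xi * xj +
      stats::rnorm(length(times), 0, noise_sd)
    wc[times == 0] <- 0
    imbibition_series(sprintf("imb%03d", s), genotypes[s, ], w0,
                      times, w0 * (1 + wc))
  }))
}

#' Balanced homozygous genotype layout
#'
#' Convenience constructor: the four homozygous digenic classes, each
#' repeated `n_samples` times, in the fixed order `rcpb, Rcpb, rcPb, RcPb`.
#'
#' @param n_samples replicates per class.
#' @return a [digenic_genotype()] data frame.
#' @export
il_genotypes <- function(n_samples = 1L) {
  digenic_genotype(rep(c(0L, 2L, 0L, 2L), each = n_samples),
                   rep(c(0L, 0L, 2L, 2L), each = n_samples))
}
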