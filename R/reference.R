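#' Published reference values for the rice Rc/Pb isogenic-line system
#'
#' Small tables of published summary statistics for the digenic
#' red/purple-pericarp system, shipped as defaults for the synthetic-data
#' generators and as inputs for reanalysis. These are printed summary
#' values (means, standard errors, effect estimates), not raw data.
#'
#' `flavonoid_reference()` gives the per-cell means and standard errors
#' (3 replicates, micrograms per gram) of five flavonoid chemicals —
#' catechin (CA), procyanidin B3 (PB3), epicatechin (EC), procyanidin B2
#' (PB2), and anthocyanins (AC) — in caryopses of the four homozygous
#' isogenic lines sampled at 5 and 40 days post-anthesis. Cells in which a
#' chemical was not detectable are recorded as mean 0, SE 0, with
#' `detected = FALSE`; the genotype-by-time model treats them as exact
#' zeros, which is what makes the model estimable over all 8 cells.
#'
#' @return `flavonoid_reference()`: data frame with columns `line`,
#'   `rc_dosage`, `pb_dosage`, `dpa`, `chemical`, `mean`, `se`, `detected`.
#' @examples
#' head(flavonoid_reference())
#' il_gp7_reference()
#' @export
flavonoid_reference <- function() {
  lines <- data.frame(
    line = c("IL_rcpb", "IL_Rcpb", "IL_rcPb", "IL_RcPb"),
    rc_dosage = c(0L, 2L, 0L, 2L),
    pb_dosage = c(0L, 0L, 2L, 2L)
  )
  # mean (se) per line x DPA x chemical; NA marks a non-detectable cell
  cells <- rbind(
    c("IL_rcpb",  5, "CA",     1.0,  0.3), c("IL_rcpb", 40, "CA",   248,  53),
    c("IL_Rcpb",  5, "CA",  5627, 262),    c("IL_Rcpb", 40, "CA", 10167, 637),
    c("IL_rcPb",  5, "CA",    17.9,  4.3), c("IL_rcPb", 40, "CA",   9.7, 3.3),
    c("IL_RcPb",  5, "CA",  6306, 239),    c("IL_RcPb", 40, "CA", 10149, 768),
    c("IL_Rcpb",  5, "PB3", 1673,  84),    c("IL_Rcpb", 40, "PB3", 3072, 168),
    c("IL_RcPb",  5, "PB3", 2154, 107),    c("IL_RcPb", 40, "PB3", 3062, 215),
    c("IL_Rcpb",  5, "EC",   106,  18),    c("IL_Rcpb", 40, "EC",   202,  11),
    c("IL_RcPb",  5, "EC",   125,  16),    c("IL_RcPb", 40, "EC",   234,   9),
    c("IL_Rcpb",  5, "PB2",  209,  26),    c("IL_Rcpb", 40, "PB2",  510,  36),
    c("IL_RcPb",  5, "PB2",  297,  30),    c("IL_RcPb", 40, "PB2",  555,  26),
    c("IL_rcPb",  5, "AC",  2331, 128),    c("IL_rcPb", 40, "AC",  3271, 231),
    c("IL_RcPb",  5, "AC",   125,  13),    c("IL_RcPb", 40, "AC",  3326, 168)
  )
  obs <- data.frame(line = cells[, 1], dpa = as.numeric(cells[, 2]),
                    chemical = cells[, 3], mean = as.numeric(cells[, 4]),
                    se = as.numeric(cells[, 5]), detected = TRUE,
                    stringsAsFactors = FALSE)
  full <- merge(expand.grid(line = lines$line, dpa = c(5, 40),
                            chemical = c("CA", "PB3", "EC", "PB2", "AC"),
                            stringsAsFactors = FALSE),
                obs, all.x = TRUE)
  full$detected[is.na(full$detected)] <- FALSE
  full$mean[!full$detected] <- 0
  full$se[!full$detected] <- 0
  full <- merge(lines, full, by = "line")
  full[order(full$chemical, full$dpa, full$rc_dosage, full$pb_dosage),
       c("line", "rc_dosage", "pb_dosage", "dpa", "chemical",
         "mean", "se", "detected")]
}

#' @rdname flavonoid_reference
#' @return `il_gp7_reference()`: named vector of published mean 7-day
#'   germination percentages for the four isogenic lines (9 samples each,
#'   no after-ripening), named by line.
#' @export
il_gp7_reference <- function() {
  c(IL_rcpb = 82, IL_Rcpb = 50, IL_rcPb = 69, IL_RcPb = 16)
}

#' @rdname flavonoid_reference
#' @return `dormancy_effect_reference()`: data frame of published effect
#'   estimates (percent trait units) for germination percentage (GP) and
#'   germination index (GI) in the isogenic-line (`IL`) and F2 systems:
#'   columns `system`, `trait`, `term`, `effect`, `r2_pct` (per-term
#'   variance share, percent; NA where not reported). A term absent for a
#'   system/trait was not significant at the 0.05 level.
#' @export
dormancy_effect_reference <- function() {
  data.frame(
    system = c(rep("IL", 8), rep("F2", 9)),
    trait  = c(rep("GP", 4), rep("GI", 4),
               rep("GP", 5), rep("GI", 4)),
    term   = c("mu", "a1", "a2", "i_a1a2",
               "mu", "a1", "a2", "i_a1a2",
               "mu", "a1", "d1", "a2", "i_a1a2",
               "mu", "a1", "d1", "a2"),
    effect = c(54.4, -21.3, -11.7, -5.2,
               32.7, -13.4, -9.0, -2.6,
               78.6, -15.0, -3.9, -8.2, -6.2,
               43.1, -12.3, -5.7, -9.7),
    r2_pct = c(NA, 66.7, 20.1, 4.0,
               NA, 63.2, 28.2, 2.5,
               NA, 31.7, 2.5, 9.1, 1.3,
               NA, 31.5, 3.8, 19.2),
    stringsAsFactors = FALSE
  )
}

#' Reconstruct a model-ready flavonoid table from published cell summaries
#'
#' Expands a cell-summary table (mean/SE per genotype-by-time cell, as from
#' [flavonoid_reference()]) into exact moment-matched replicates via
#' [reconstruct_replicates()], giving a record table ready for
#' [fit_digenic()] with the genotype-by-time model. Because all model
#' predictors are constant within cells, every sum of squares — and hence
#' every R-squared — computed from the reconstruction equals the value the
#' raw replicates would give.
#'
#' @param chemical which chemical to extract (e.g. `"CA"`).
#' @param table a cell-summary data frame (default [flavonoid_reference()]).
#' @param n_rep replicates per cell (default 3, the published design).
#' @return data frame with columns `rc_dosage`, `pb_dosage`, `dpa`, `y`.
#' @export
flavonoid_records <- function(chemical, table = flavonoid_reference(),
                              n_rep = 3L) {
  sub <- table[table$chemical == chemical, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("unknown chemical '%s'", chemical),
                       call. = FALSE)
  if (any(sub$mean < 0)) stop("negative cell means", call. = FALSE)
  do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
    data.frame(rc_dosage = sub$rc_dosage[i], pb_dosage = sub$pb_dosage[i],
               dpa = sub$dpa[i],
               y = reconstruct_replicates(sub$mean[i], sub$se[i], n_rep))
  }))
}
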