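test_that("generators are deterministic under a fixed seed", {
  g1 <- simulate_f2_genotypes(50, seed = 42)
  g2 <- simulate_f2_genotypes(50, seed = 42)
  expect_identical(g1, g2)
  y1 <- simulate_phenotypes(g1, c(a1 = -2), mu = 10, residual_sd = 1,
                            seed = 7)
  y2 <- simulate_phenotypes(g2, c(a1 = -2), mu = 10, residual_sd = 1,
                            seed = 7)
  expect_identical(y1, y2)
  r1 <- simulate_germination_counts(il_genotypes(2), 0.6, 3, seed = 5)
  r2 <- simulate_germination_counts(il_genotypes(2), 0.6, 3, seed = 5)
  expect_identical(lapply(r1, `[[`, "counts"), lapply(r2, `[[`, "counts"))
  s1 <- simulate_imbibition(il_genotypes(1), seed = 3)
  s2 <- simulate_imbibition(il_genotypes(1), seed = 3)
  expect_identical(lapply(s1, `[[`, "weights"), lapply(s2, `[[`, "weights"))
})

test_that("F2 segregation matches independent 1:2:1 at each locus", {
  g <- simulate_f2_genotypes(20000, seed = 8)
  # marginal 1:2:1 and 1/16 expectation for each double homozygote
  exp9 <- outer(c(1, 2, 1) / 4, c(1, 2, 1) / 4)
  obs <- table(factor(g$rc_dosage, 0:2), factor(g$pb_dosage, 0:2))
  p <- stats::chisq.test(as.vector(obs), p = as.vector(exp9))$p.value
  expect_gt(p, 0.001)
  expect_equal(mean(g$rc_dosage == 1), 0.5, tolerance = 0.02)
  expect_equal(obs["0", "0"] / 20000, 1 / 16, tolerance = 0.01)
})

test_that("phenotype simulation is the coded linear predictor plus noise", {
  g <- digenic_genotype(c(2, 0, 1), c(2, 0, 1))
  eff <- c(a1 = -15.0, d1 = -3.9, a2 = -8.2, i_a1a2 = -6.2)
  y <- simulate_phenotypes(g, eff, mu = 78.6, residual_sd = 0)
  # RcRcPbPb: mu + a1 - d1/2 + a2 + i
  expect_equal(y[1], 78.6 - 15.0 - (-3.9) * 0.5 - 8.2 - 6.2)
  # rcrcpbpb: mu - a1 - d1/2 - a2 + i
  expect_equal(y[2], 78.6 + 15.0 + 3.9 * 0.5 + 8.2 - 6.2)
  # double heterozygote: mu + d1/2 (+ d2 terms absent)
  expect_equal(y[3], 78.6 - 3.9 * 0.5)
  expect_equal(simulate_phenotypes(g, c(a1 = 0), mu = 5), rep(5, 3))
  expect_error(simulate_phenotypes(g, c(tau = 1)), "unknown effect")
})

test_that("germination counts honour the timing law limits", {
  g <- il_genotypes(3)
  recs <- simulate_germination_counts(g, p_g = 1, mean_day = 2,
                                      day_scale = 0, n_total = 60,
                                      seed = 1)
  for (r in recs) {
    expect_equal(r$counts[1], 60)
    expect_equal(sum(r$counts[-1]), 0)
    expect_equal(germination_index(r), 100 * 6 / 7)
  }
  none <- simulate_germination_counts(g, p_g = 0, mean_day = 3, seed = 1)
  for (r in none) {
    expect_equal(sum(r$counts), 0)
    expect_equal(cumulative_gp(r), 0)
  }
  # three-day F2 schedule: early germination binned at the first count
  f2r <- simulate_germination_counts(il_genotypes(1), p_g = 1, mean_day = 2,
                                     day_scale = 0, schedule = c(3, 5, 7),
                                     seed = 1)
  expect_equal(f2r[[1]]$counts, c(60, 0, 0))
})

test_that("germination GP expectation tracks the configured targets", {
  cfg <- sim_config(1)$germination
  g <- il_genotypes(60)
  key <- match(paste(g$rc_dosage, g$pb_dosage),
               paste(cfg$classes$rc_dosage, cfg$classes$pb_dosage))
  recs <- simulate_germination_counts(g, cfg$classes$p_g[key],
                                      cfg$classes$mean_day[key],
                                      seed = 13)
  gp <- vapply(recs, cumulative_gp, numeric(1))
  cls_mean <- as.vector(tapply(gp, key, mean))
  # 60 samples x 60 seeds per class: SE of the class mean GP ~ 0.8 points
  expect_equal(cls_mean, 100 * cfg$classes$p_g, tolerance = 0.05)
})

test_that("flavonoid panel respects detection and moment structure", {
  tab <- flavonoid_reference()
  pan <- simulate_flavonoid_panel(tab, seed = 4)
  nd <- merge(pan, tab[!tab$detected, c("line", "dpa", "chemical")])
  expect_true(all(nd$value == 0) && !any(nd$detected))
  zero_se <- tab[tab$detected & tab$se == 0, ]
  if (nrow(zero_se)) {
    zv <- merge(pan, zero_se[, c("line", "dpa", "chemical")])
    expect_true(all(tapply(zv$value, zv$line, function(v) length(unique(v))) == 1))
  }
  # moments: repeated cells converge to configured mean and SD = SE*sqrt(3)
  cell <- tab[tab$line == "IL_Rcpb" & tab$dpa == 5 & tab$chemical == "CA", ]
  many <- simulate_flavonoid_panel(cell[rep(1, 2000), ], seed = 6)
  expect_equal(mean(many$value), cell$mean, tolerance = 0.01 * cell$mean)
  expect_equal(sd(many$value), cell$se * sqrt(3),
               tolerance = 0.03 * cell$se * sqrt(3))
  expect_error(simulate_flavonoid_panel(transform(cell, mean = -1)),
               "negative")
})

test_that("imbibition simulation round-trips through the segmenter", {
  g <- il_genotypes(2)
  # the default (published) grid has no point at 30 or 50 h, so exact
  # breakpoint recovery needs a grid aligned with the true breakpoints
  aligned <- c(0.5, seq(2, 12, 2), seq(14, 62, 4), seq(74, 96, 12))
  ser <- simulate_imbibition(g, times = aligned, noise_sd = 0,
                             effects = c(a1 = 0, a2 = 0, i_a1a2 = 0),
                             seed = 1)
  traj <- fit_per_timepoint(imbibition_panel(ser))
  seg <- segment_phases(traj$time_h, traj$mu)
  expect_equal(seg$breakpoints, c(30, 50))
  # time 0 gives zero water content by definition
  ser0 <- simulate_imbibition(g, times = c(0, 2, 10, 20, 30, 40, 60, 96),
                              noise_sd = 0.01, seed = 2)
  expect_equal(vapply(ser0, function(s) water_content(s)[1], numeric(1)),
               rep(0, 8))
  expect_error(simulate_imbibition(g, breakpoints = c(50, 30)),
               "breakpoints")
  expect_error(simulate_imbibition(g, breakpoints = c(30, 120)),
               "breakpoints")
})

test_that("end-to-end simulate-then-fit recovers parameters at large n", {
  # bias check at 10x the published population size, averaged over
  # replicates so sampling noise does not mask (or mimic) bias
  cfg <- sim_config(5)
  eff <- cfg$phenotype$effects
  n_rep <- 30L
  est_sum <- setNames(numeric(length(eff)), names(eff))
  r2s <- numeric(n_rep)
  set.seed(cfg$f2$seed)
  for (r in seq_len(n_rep)) {
    g <- simulate_f2_genotypes(2590)
    y <- simulate_phenotypes(g, eff, cfg$phenotype$mu,
                             cfg$phenotype$residual_sd)
    fit <- fit_digenic(data.frame(rc_dosage = g$rc_dosage,
                                  pb_dosage = g$pb_dosage, y = y),
                       model_spec("f2"), select = FALSE)
    est <- fit$estimates
    r2s[r] <- fit$total_r2
    for (tm in names(eff)) {
      est_sum[tm] <- est_sum[tm] + est$coefficient[match(tm, est$term)]
    }
  }
  for (tm in names(eff)) {
    expect_lt(abs(est_sum[[tm]] / n_rep - eff[[tm]]), 0.05 * abs(eff[[tm]]))
  }
  # residual SD 14.1 was derived to put the model R2 near the reported 0.45
  expect_lt(abs(mean(r2s) - 0.45), 0.03)
})
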