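test_that("fit_ols handles degenerate exact cases", {
  d <- build_design(hom_records(c(1, 2, 3, 4), n_rep = 2L), model_spec("hom"))
  # response identical to a single +-1 column
  d$y <- d$X[, "a1"]
  f <- fit_ols(d, "a1")
  expect_equal(unname(f$coefficients["a1"]), 1)
  expect_equal(f$residuals, rep(0, 8))
  # constant response
  d$y <- rep(7, 8)
  f2 <- fit_ols(d)
  expect_equal(unname(f2$coefficients), c(7, 0, 0, 0))
})

test_that("fit_ols agrees with the normal-equations oracle", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(10:30, 1); k <- sample(1:5, 1)
    X <- random_design(n, k)
    y <- rnorm(n, sd = 2)
    f <- fit_ols(as_design(X, y))
    o <- ols_oracle(X, y)
    expect_equal(unname(f$coefficients), unname(o$coef), tolerance = 1e-8)
    expect_equal(unname(f$se), unname(o$se), tolerance = 1e-8)
    expect_equal(unname(f$p_value), unname(o$p), tolerance = 1e-8)
  }
})

test_that("balanced cell-mean coefficients equal half-difference contrasts", {
  m <- c(82, 50, 69, 16) # rcpb, Rcpb, rcPb, RcPb
  d <- build_design(hom_records(m, n_rep = 2L), model_spec("hom"))
  f <- fit_ols(d)
  # oracle from the 4x4 normal equations on the class means
  a1 <- ((m[2] + m[4]) - (m[1] + m[3])) / 4
  a2 <- ((m[3] + m[4]) - (m[1] + m[2])) / 4
  ii <- ((m[1] + m[4]) - (m[2] + m[3])) / 4
  expect_equal(unname(f$coefficients),
               c(mean(m), a1, a2, ii), tolerance = 1e-12)
})

test_that("rank deficiency is reported with the collinear column", {
  rec <- data.frame(rc_dosage = c(0, 2, 0, 2), pb_dosage = 0,
                    y = c(1, 2, 3, 4))
  d <- build_design(rec, model_spec("hom"))
  expect_error(fit_ols(d), "collinear.*(a2|i_a1a2)")
  expect_error(fit_ols(as_design(matrix(1, 2, 1,
                                        dimnames = list(NULL, "(Intercept)")),
                                 1:2), "a1"), "not in design")
})

test_that("forward selection retains exactly the generating term", {
  d <- build_design(hom_records(c(0, 0, 0, 0), n_rep = 5L), model_spec("hom"))
  d$y <- 3 * d$X[, "a1"]
  sel <- forward_select(d)
  expect_identical(sel$term, "a1")
  expect_identical(sel$entry_order, 1L)
  expect_equal(sel$p_entry, 0)
})

test_that("forward selection has bounded type-I retention on pure noise", {
  set.seed(303)
  hits <- 0L
  for (i in 1:200) {
    rec <- hom_records(rep(0, 4), n_rep = 9L, noise_sd = 1)
    sel <- forward_select(build_design(rec, model_spec("hom")))
    if (nrow(sel) > 0L) hits <- hits + 1L
  }
  # familywise entry probability over 3 orthogonal candidates is
  # 1 - 0.95^3 ~ 0.14; 0.25 is a conservative binomial upper bound at n=200
  expect_lte(hits / 200, 0.25)
  expect_gte(hits / 200, 0.03) # and the test is not vacuously silent
})

test_that("catechin panel retains the additive, time, and interaction terms", {
  fit <- fit_digenic(flavonoid_records("CA"), model_spec("gxt"))
  expect_setequal(fit$estimates$term, c("a1", "tau", "I_a1tau"))
  expect_identical(fit$estimates$term[fit$estimates$entry_order == 1L], "a1")
})

test_that("sequential R2 is order-invariant on orthogonal designs", {
  rec <- hom_records(c(82, 50, 69, 16), n_rep = 3L, noise_sd = 4, seed = 7)
  base <- fit_digenic(rec, model_spec("hom"), select = FALSE)
  ref <- base$estimates[order(base$estimates$term),
                        c("term", "r2_increment")]
  perms <- list(c("a1", "a2", "i_a1a2"), c("a2", "i_a1a2", "a1"),
                c("i_a1a2", "a1", "a2"), c("a2", "a1", "i_a1a2"),
                c("a1", "i_a1a2", "a2"), c("i_a1a2", "a2", "a1"))
  for (p in perms) {
    f <- fit_digenic(rec, model_spec("hom", terms = p), select = FALSE)
    got <- f$estimates[order(f$estimates$term), c("term", "r2_increment")]
    expect_equal(got$r2_increment, ref$r2_increment, tolerance = 1e-10)
    # and each increment equals SS_term / SS_total
    d <- build_design(rec, model_spec("hom"))
    for (tm in got$term) {
      x <- d$X[, tm]
      ss <- sum(x * d$y)^2 / sum(x * x) # orthogonal contrast SS
      expect_equal(got$r2_increment[got$term == tm],
                   ss / sum((d$y - mean(d$y))^2), tolerance = 1e-10)
    }
  }
})

test_that("increments sum to the model R2 and live in [0,1]", {
  set.seed(17)
  g <- simulate_f2_genotypes(120)
  rec <- data.frame(rc_dosage = g$rc_dosage, pb_dosage = g$pb_dosage,
                    y = simulate_phenotypes(g, c(a1 = -10, a2 = -5),
                                            mu = 60, residual_sd = 8))
  fit <- fit_digenic(rec, model_spec("f2"))
  expect_true(all(fit$estimates$r2_increment >= 0 &
                  fit$estimates$r2_increment <= 1))
  d <- fit$design
  r2_direct <- 1 - fit$ols$rss / sum((d$y - mean(d$y))^2)
  expect_equal(fit$total_r2, r2_direct, tolerance = 1e-10)
})

test_that("the four-line class means yield the printed contrast estimates", {
  il <- hom_records(c(82, 50, 69, 16))
  # saturated noise-free fit: no residual df, so selection is bypassed
  fit <- fit_digenic(il, model_spec("hom"), select = FALSE)
  expect_equal(fit$mu, 54.25)
  est <- setNames(fit$estimates$coefficient, fit$estimates$term)
  expect_equal(unname(est[c("a1", "a2", "i_a1a2")]),
               c(-21.25, -11.75, -5.25))
  # equal class means leave nothing to retain
  flat <- fit_digenic(hom_records(rep(50, 4), n_rep = 3L), model_spec("hom"))
  expect_identical(nrow(flat$estimates), 0L)
  expect_equal(flat$mu, 50)
})

test_that("synthetic F2 fits recover the generating effects within 2 SE", {
  set.seed(404)
  eff <- c(a1 = -15.0, d1 = -3.9, a2 = -8.2, i_a1a2 = -6.2)
  g <- simulate_f2_genotypes(259)
  y <- simulate_phenotypes(g, eff, mu = 78.6, residual_sd = 5)
  rec <- data.frame(rc_dosage = g$rc_dosage, pb_dosage = g$pb_dosage, y = y)
  fit <- fit_digenic(rec, model_spec("f2"), select = FALSE)
  est <- fit$estimates
  for (tm in names(eff)) {
    i <- match(tm, est$term)
    expect_lt(abs(est$coefficient[i] - eff[[tm]]), 2 * est$standard_error[i])
  }
})

test_that("dominance ratio follows |d/a| with absent dominance as zero", {
  g <- digenic_genotype(rep(0:2, each = 3 * 9), rep(rep(0:2, each = 9), 3))
  eff <- c(a1 = -15.0, d1 = -3.9, a2 = -8.2, i_a1a2 = -6.2)
  rec <- data.frame(rc_dosage = g$rc_dosage, pb_dosage = g$pb_dosage,
                    y = simulate_phenotypes(g, eff, mu = 78.6))
  fit <- fit_digenic(rec, model_spec("f2"), select = FALSE)
  expect_equal(dominance_ratio(fit, "rc"), 3.9 / 15.0, tolerance = 1e-10)

  rec$y <- simulate_phenotypes(g, c(a1 = -15), mu = 78.6, residual_sd = 0.01,
                               seed = 2)
  fit2 <- fit_digenic(rec, model_spec("f2"))
  expect_true("a1" %in% fit2$estimates$term)
  expect_equal(dominance_ratio(fit2, "rc"), 0,
               tolerance = 0.01) # d1 not retained or negligible
  expect_error(dominance_ratio(fit2, "pb"), "additive term")
})

test_that("reconstruct_replicates matches mean and SE exactly", {
  x <- reconstruct_replicates(5627, 262, 3)
  expect_equal(sort(x), c(5627 - 262 * sqrt(3), 5627, 5627 + 262 * sqrt(3)))
  expect_equal(mean(x), 5627)
  expect_equal(sd(x) / sqrt(3), 262)
  expect_equal(reconstruct_replicates(10, 0, 3), rep(10, 3))
  p <- reconstruct_replicates(10, 1, 2)
  expect_equal(mean(p), 10)
  expect_equal(sd(p) / sqrt(2), 1)
  expect_equal(sort(p), c(9, 11))
  expect_error(reconstruct_replicates(1, 0.5, 1), "fewer than 2")
})

test_that("moment-matched reconstruction preserves every R2", {
  set.seed(55)
  for (i in 1:5) {
    cells <- expand.grid(rc_dosage = c(0L, 2L), pb_dosage = c(0L, 2L),
                         dpa = c(5, 40))
    raw <- do.call(rbind, lapply(seq_len(nrow(cells)), function(j) {
      data.frame(rc_dosage = cells$rc_dosage[j],
                 pb_dosage = cells$pb_dosage[j], dpa = cells$dpa[j],
                 y = rnorm(3, mean = runif(1, 0, 100),
                           sd = runif(1, 0.1, 10)))
    }))
    summ <- cbind(cells, t(vapply(seq_len(nrow(cells)), function(j) {
      yy <- raw$y[(j - 1) * 3 + 1:3]
      c(m = mean(yy), se = sd(yy) / sqrt(3))
    }, numeric(2))))
    recon <- do.call(rbind, lapply(seq_len(nrow(summ)), function(j) {
      data.frame(rc_dosage = summ$rc_dosage[j],
                 pb_dosage = summ$pb_dosage[j], dpa = summ$dpa[j],
                 y = reconstruct_replicates(summ$m[j], summ$se[j], 3))
    }))
    f_raw <- fit_digenic(raw, model_spec("gxt"), select = FALSE)
    f_rec <- fit_digenic(recon, model_spec("gxt"), select = FALSE)
    expect_equal(f_rec$total_r2, f_raw$total_r2, tolerance = 1e-10)
    expect_equal(f_rec$estimates$r2_increment, f_raw$estimates$r2_increment,
                 tolerance = 1e-10)
  }
})

test_that("degenerate columns are dropped with a warning", {
  rec <- data.frame(rc_dosage = c(0, 2, 0, 2), pb_dosage = 0,
                    y = c(10, 2, 11, 1))
  expect_warning(fit <- fit_digenic(rec, model_spec("hom")), "degenerate")
  expect_false(any(c("a2", "i_a1a2") %in% fit$estimates$term))
})

test_that("fit reports round-trip through the report writer", {
  rec <- hom_records(c(82, 50, 69, 16), n_rep = 3L, noise_sd = 5, seed = 31)
  fit <- fit_digenic(rec, model_spec("hom"))
  path <- withr::local_tempfile(fileext = ".csv")
  rep_df <- write_fit_report(fit, path)
  back <- read_fit_report(path)
  expect_identical(back$term, rep_df$term)
  expect_identical(back$effect, rep_df$effect) # bit-exact numerics
  expect_identical(back$r2_pct, rep_df$r2_pct)
  expect_equal(back$term[1], "mu")
  expect_equal(back$term[nrow(back)], "Total")
})
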