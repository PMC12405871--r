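#' Ordinary least squares on a coded digenic design
#'
#' Fits the response on the intercept plus the requested term columns by QR
#' decomposition, returning coefficients, standard errors, two-sided
#' p-values (partial t, equivalent to the partial F with 1 numerator df),
#' and residual diagnostics. A rank-deficient design is an error naming the
#' collinear columns.
#'
#' @param design a [build_design()] result.
#' @param terms term labels to include (default: all in the design).
#' @return list of class `digenic_ols` with elements `coefficients`, `se`,
#'   `p_value`, `fitted`, `residuals`, `df_residual`, `sigma2` (residual
#'   variance), `rss`, and `terms`.
#' @export
fit_ols <- function(design, terms = design$terms) {
  stopifnot(inherits(design, "digenic_design"))
  bad <- setdiff(terms, design$terms)
  if (length(bad)) {
    stop(sprintf("terms not in design: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  X <- design$X[, c("(Intercept)", terms), drop = FALSE]
  y <- design$y
  n <- nrow(X); p <- ncol(X)
  if (n < p) {
    stop(sprintf("need more observations (%d) than coefficients (%d)", n, p),
         call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < p) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop(sprintf("design is rank-deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  coefs <- qr.coef(qx, y)
  fitted <- drop(X %*% coefs)
  res <- y - fitted
  rss <- sum(res^2)
  df <- n - p
  sigma2 <- if (df > 0) rss / df else NA_real_
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  se <- sqrt(diag(xtx_inv) * sigma2)
  names(se) <- colnames(X)
  tval <- coefs / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  structure(list(coefficients = coefs, se = se, p_value = pval,
                 fitted = fitted, residuals = res, df_residual = df,
                 sigma2 = sigma2, rss = rss, terms = terms, n_obs = n),
            class = "digenic_ols")
}

# RSS of y on the intercept plus the given columns of X; NULL terms = mean-only
.rss_of <- function(X, y, terms) {
  Xi <- X[, c("(Intercept)", terms), drop = FALSE]
  f <- stats::lm.fit(Xi, y)
  sum(f$residuals^2)
}

#' Forward stepwise selection of model terms
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' term with the largest sum-of-squares increment whose partial F-test
#' p-value is below `alpha`, and stops when no candidate qualifies. Ties in
#' the SS increment are broken by candidate order in the model
#' specification, making the procedure deterministic. An empty retained set
#' is a valid outcome.
#'
#' A candidate that drives the residual sum of squares to (numerically)
#' exact zero is treated as significant even when no residual degrees of
#' freedom remain — this is what makes a saturated fit to noise-free class
#' means (e.g. four homozygous-line means under the three-term model)
#' retain all terms.
#'
#' @param design a [build_design()] result.
#' @param alpha entry significance level (default: from the design's spec).
#' @return data frame of class `forward_selection` with one row per
#'   retained term: `term`, `entry_order`, `ss_increment`, `p_entry`;
#'   attributes `sst` (total SS about the mean), `rss_final`, and
#'   `candidates`.
#' @export
forward_select <- function(design, alpha = design$spec$alpha) {
  stopifnot(inherits(design, "digenic_design"))
  X <- design$X; y <- design$y; n <- length(y)
  sst <- sum((y - mean(y))^2)
  exact_tol <- 1e-10 * (sst + .Machine$double.eps)
  kept <- character(0)
  rows <- list()
  rss <- sst
  repeat {
    cands <- setdiff(design$terms, kept)
    if (!length(cands) || rss <= exact_tol) break
    best <- NULL
    for (tm in cands) {
      rss_c <- .rss_of(X, y, c(kept, tm))
      dss <- rss - rss_c
      if (is.null(best) || dss > best$dss) {
        best <- list(term = tm, dss = dss, rss = rss_c)
      }
    }
    df_res <- n - (length(kept) + 2L)
    if (best$rss <= exact_tol) {
      p <- 0
    } else if (df_res <= 0L || best$dss <= 0) {
      p <- NA_real_
    } else {
      Fv <- best$dss / (best$rss / df_res)
      p <- stats::pf(Fv, 1, df_res, lower.tail = FALSE)
    }
    if (is.na(p) || p >= alpha) break
    kept <- c(kept, best$term)
    rows[[length(rows) + 1L]] <-
      data.frame(term = best$term, entry_order = length(kept),
                 ss_increment = best$dss, p_entry = p,
                 stringsAsFactors = FALSE)
    rss <- best$rss
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(0), entry_order = integer(0),
               ss_increment = numeric(0), p_entry = numeric(0))
  attr(out, "sst") <- sst
  attr(out, "rss_final") <- rss
  attr(out, "candidates") <- design$terms
  class(out) <- c("forward_selection", "data.frame")
  out
}

#' Sequential per-term variance partition
#'
#' Each retained term's share of variance is the reduction in residual sum
#' of squares at the step where the term entered the forward-selection
#' path, divided by the total sum of squares about the mean. The increments
#' sum to the final model's coefficient of determination. On a fully
#' orthogonal balanced design the increments are independent of entry
#' order and equal `SS_term / SS_total`; with the 0/1 time coding (or an
#' unbalanced F2) they are order-dependent, and entry order — the order the
#' stepwise procedure itself chose — is the documented convention.
#'
#' @param selection a [forward_select()] result.
#' @return named numeric vector of R-squared increments (fractions of total
#'   SS), in entry order.
#' @export
partition_r2 <- function(selection) {
  stopifnot(inherits(selection, "forward_selection"))
  sst <- attr(selection, "sst")
  if (sst <= 0) {
    return(stats::setNames(rep(0, nrow(selection)), selection$term))
  }
  stats::setNames(selection$ss_increment / sst, selection$term)
}

#' Fit a digenic model with forward selection and variance partition
#'
#' The full pipeline for one trait: build the coded design, run forward
#' selection at the spec's `alpha`, refit the retained terms by OLS for
#' coefficients/SEs/p-values, and attach the entry-order sequential
#' R-squared partition. Zero-variance and duplicated predictor columns are
#' dropped with a warning before fitting.
#'
#' @param records data frame with `rc_dosage`, `pb_dosage`, `y`, and `dpa`
#'   for the genotype-by-time model (see [build_design()]).
#' @param spec a [model_spec()].
#' @param select run forward selection (`TRUE`, default) or fit all
#'   candidate terms with sequential SS in specification order (`FALSE`).
#' @return object of class `digenic_fit`: `mu` (model mean / background
#'   effect), `estimates` (data frame: term, coefficient, standard_error,
#'   p_value, r2_increment, entry_order), `total_r2`, `residual_variance`,
#'   `n_obs`, `model_kind`, plus the underlying `design`, `selection`, and
#'   final `ols` fit.
#' @examples
#' il <- data.frame(rc_dosage = c(0, 2, 0, 2), pb_dosage = c(0, 0, 2, 2),
#'                  y = c(82, 50, 69, 16))
#' fit <- fit_digenic(il, model_spec("hom"))
#' coef_table(fit)
#' @export
fit_digenic <- function(records, spec, select = TRUE) {
  design <- build_design(records, spec)
  # drop degenerate columns up front
  Xt <- design$X[, -1L, drop = FALSE]
  sds <- apply(Xt, 2, stats::sd)
  dup <- duplicated(t(Xt))
  drop <- colnames(Xt)[sds == 0 | dup]
  if (length(drop)) {
    warning(sprintf("dropping degenerate column(s): %s",
                    paste(drop, collapse = ", ")), call. = FALSE)
    spec <- model_spec(spec$kind, setdiff(spec$terms, drop), spec$alpha)
    design <- build_design(records, spec)
  }
  if (select) {
    sel <- forward_select(design)
    retained <- sel$term
  } else {
    # sequential SS in specification order, all terms kept
    X <- design$X; y <- design$y
    rss <- sum((y - mean(y))^2)
    rows <- lapply(seq_along(design$terms), function(k) {
      rss_k <- .rss_of(X, y, design$terms[seq_len(k)])
      r <- data.frame(term = design$terms[k], entry_order = k,
                      ss_increment = rss - rss_k, p_entry = NA_real_)
      rss <<- rss_k
      r
    })
    sel <- do.call(rbind, rows)
    attr(sel, "sst") <- sum((y - mean(y))^2)
    attr(sel, "rss_final") <- rss
    attr(sel, "candidates") <- design$terms
    class(sel) <- c("forward_selection", "data.frame")
    retained <- design$terms
  }
  ols <- fit_ols(design, retained)
  inc <- partition_r2(sel)
  est <- data.frame(
    term = retained,
    coefficient = unname(ols$coefficients[retained]),
    standard_error = unname(ols$se[retained]),
    p_value = unname(ols$p_value[retained]),
    r2_increment = unname(inc[retained]),
    entry_order = sel$entry_order[match(retained, sel$term)],
    stringsAsFactors = FALSE
  )
  structure(list(
    mu = unname(ols$coefficients["(Intercept)"]),
    estimates = est,
    total_r2 = sum(est$r2_increment),
    residual_variance = ols$sigma2,
    n_obs = ols$n_obs,
    model_kind = spec$kind,
    design = design, selection = sel, ols = ols
  ), class = "digenic_fit")
}

#' @rdname fit_digenic
#' @param fit a `digenic_fit`.
#' @return `coef_table()`: the per-term estimates data frame with the model
#'   mean prepended.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "digenic_fit"))
  rbind(data.frame(term = "mu", coefficient = fit$mu,
                   standard_error = unname(fit$ols$se["(Intercept)"]),
                   p_value = unname(fit$ols$p_value["(Intercept)"]),
                   r2_increment = NA_real_, entry_order = NA_integer_),
        fit$estimates)
}

#' Degree-of-dominance ratio at one locus
#'
#' `|d / a|`: the absolute ratio of the dominance to the additive effect of
#' a locus. Values near 0 indicate additivity, near 1 complete dominance.
#' When the dominance term was not retained by selection the ratio is 0;
#' an additive coefficient of exactly 0 leaves the ratio undefined.
#'
#' @param fit a [fit_digenic()] result containing the locus's additive term.
#' @param locus `"rc"` or `"pb"`.
#' @return non-negative scalar.
#' @export
dominance_ratio <- function(fit, locus = c("rc", "pb")) {
  stopifnot(inherits(fit, "digenic_fit"))
  locus <- match.arg(locus)
  a_term <- if (locus == "rc") "a1" else "a2"
  d_term <- if (locus == "rc") "d1" else "d2"
  est <- fit$estimates
  if (!a_term %in% est$term) {
    stop(sprintf("fit does not contain the additive term %s", a_term),
         call. = FALSE)
  }
  a <- est$coefficient[est$term == a_term]
  if (a == 0) stop("additive coefficient is 0; ratio undefined", call. = FALSE)
  d <- if (d_term %in% est$term) est$coefficient[est$term == d_term] else 0
  abs(d / a)
}

#' Moment-matched replicate reconstruction from a mean and standard error
#'
#' Published tables often report only per-cell means and standard errors of
#' n replicates. This returns n values whose sample mean equals `mean` and
#' whose sample standard error equals `se` *exactly*, so any linear-model
#' sum of squares computed from the reconstruction equals the value the raw
#' data would give whenever predictors are constant within cells. The
#' values follow the symmetric pattern `mean + se * sqrt(n) * e` with `e` a
#' centred unit-variance ramp; for n = 3 this is `{m - se*sqrt(3), m,
#' m + se*sqrt(3)}`, for n = 2 the pair `m +/- se`.
#'
#' @param mean cell mean.
#' @param se cell standard error (>= 0).
#' @param n number of replicates (>= 2 when `se > 0`).
#' @return numeric vector of length `n`.
#' @examples
#' x <- reconstruct_replicates(5627, 262, 3)
#' c(mean(x), sd(x) / sqrt(3)) # 5627, 262
#' @export
reconstruct_replicates <- function(mean, se, n = 3L) {
  stopifnot(length(mean) == 1L, length(se) == 1L, is.finite(mean))
  if (!is.finite(se) || se < 0) stop("se must be >= 0", call. = FALSE)
  n <- as.integer(n)
  if (se > 0 && n < 2L) {
    stop("cannot reconstruct a positive SE from fewer than 2 replicates",
         call. = FALSE)
  }
  if (se == 0) return(rep(mean, n))
  e <- seq_len(n)
  e <- (e - base::mean(e)) / stats::sd(e)
  mean + se * sqrt(n) * e
}

#' @export
print.digenic_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Digenic %s-model fit: n = %d, mu = %s, total R2 = %s\n",
              x$model_kind, x$n_obs, format(x$mu, digits = digits),
              format(x$total_r2, digits = digits)))
  if (nrow(x$estimates)) {
    print(format(x$estimates, digits = digits), row.names = FALSE)
  } else {
    cat("  no terms retained\n")
  }
  invisible(x)
}
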