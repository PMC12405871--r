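# Independent OLS oracle: explicit normal equations, no shared code with
# fit_ols (which uses QR).
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tv <- drop(beta) / se
  list(coef = drop(beta), se = se,
       p = 2 * stats::pt(abs(tv), df, lower.tail = FALSE))
}

# random well-conditioned small design (intercept + k continuous columns)
random_design <- function(n, k) {
  X <- cbind(1, matrix(stats::rnorm(n * k), n, k))
  colnames(X) <- c("(Intercept)", paste0("t", seq_len(k)))
  X
}

# wrap an arbitrary numeric design as a digenic_design so fit_ols accepts it
as_design <- function(X, y) {
  structure(list(X = X, terms = colnames(X)[-1], y = y,
                 ids = as.character(seq_along(y)),
                 spec = digenic::model_spec("f2")),
            class = "digenic_design")
}

# balanced homozygous 2x2 layout with n_rep observations per class
hom_records <- function(cell_means, n_rep = 1L, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- digenic::il_genotypes(n_rep)
  mu <- rep(cell_means, each = n_rep)
  data.frame(rc_dosage = g$rc_dosage, pb_dosage = g$pb_dosage,
             y = mu + stats::rnorm(length(mu), 0, noise_sd))
}
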