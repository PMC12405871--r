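#' Orthogonal contrast codes for digenic genotypes
#'
#' The digenic linear models use contrast codes chosen so that, under
#' balanced (equal-replication) or exact 1:2:1 segregation frequencies, the
#' additive, dominance, and epistatic columns are mutually orthogonal and
#' their coefficients estimate the classical genetic effects directly:
#'
#' * `code_additive()`: dosage 0 (e.g. `rcrc`) -> -1, 1 (`Rcrc`) -> 0,
#'   2 (`RcRc`) -> +1. The additive effect is then half the difference
#'   between the homozygote means.
#' * `code_dominance()`: heterozygote -> +0.5, either homozygote -> -0.5,
#'   so the dominance effect is the heterozygote's deviation from the
#'   homozygote midpoint.
#' * `code_time()`: a two-level development-time factor coded 0 for the
#'   earlier level (5 DPA) and 1 for the later (40 DPA). This 0/1 coding is
#'   kept as published even though it leaves the genotype-by-time product
#'   columns non-orthogonal to the main effects; the forward-entry
#'   sequential sum-of-squares partition in [fit_digenic()] resolves the
#'   resulting order dependence.
#'
#' @param dosage integer functional-allele dosages in \{0, 1, 2\}.
#' @return numeric contrast codes.
#' @examples
#' code_additive(0:2)   # -1  0  1
#' code_dominance(0:2)  # -0.5 0.5 -0.5
#' code_time(c(5, 40))  # 0 1
#' @export
code_additive <- function(dosage) {
  c(-1, 0, 1)[check_dosage(dosage, "dosage") + 1L]
}

#' @rdname code_additive
#' @export
code_dominance <- function(dosage) {
  c(-0.5, 0.5, -0.5)[check_dosage(dosage, "dosage") + 1L]
}

#' @rdname code_additive
#' @param dpa development-time labels (days post-anthesis, or any two-level
#'   factor); exactly two distinct levels are required, and the
#'   lower/earlier level is coded 0.
#' @export
code_time <- function(dpa) {
  lev <- sort(unique(dpa))
  if (length(lev) != 2L) {
    stop(sprintf(
      "development time must have exactly two levels (got %d: %s)",
      length(lev), paste(lev, collapse = ", ")), call. = FALSE)
  }
  as.numeric(dpa == lev[2L])
}

.DIGENIC_TERMS <- c("a1", "d1", "a2", "d2",
                    "i_a1a2", "i_a1d2", "i_d1a2", "i_d1d2",
                    "tau", "I_a1tau", "I_a2tau")

.MODEL_TERMS <- list(
  # homozygous-line model: additive + additive-by-additive epistasis
  hom = c("a1", "a2", "i_a1a2"),
  # F2 additive-dominance-epistasis model
  f2  = c("a1", "d1", "a2", "d2", "i_a1a2", "i_a1d2", "i_d1a2", "i_d1d2"),
  # genotype x development-time model for homozygous lines at two times
  gxt = c("a1", "a2", "i_a1a2", "tau", "I_a1tau", "I_a2tau")
)

#' Specify a digenic linear model
#'
#' Three model kinds cover the published designs:
#'
#' * `"hom"` — two-locus additive + additive-by-additive model for
#'   homozygous material (isogenic lines); terms `a1, a2, i_a1a2`. Used for
#'   IL germination statistics and per-timepoint water content.
#' * `"f2"` — full additive-dominance-epistasis model for an F2 population,
#'   adding `d1, d2` and the four epistatic products
#'   `i_a1a2, i_a1d2, i_d1a2, i_d1d2`.
#' * `"gxt"` — homozygous-line model with a two-level development-time
#'   covariate and its interactions with the additive terms
#'   (`tau, I_a1tau, I_a2tau`); used for flavonoid contents at 5 vs 40 DPA.
#'
#' @param kind one of `"hom"`, `"f2"`, `"gxt"`.
#' @param terms ordered candidate terms; defaults to the kind's full set.
#'   Order matters: it is the tie-break order during forward selection.
#' @param alpha significance level for forward selection (default 0.05).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("hom", "f2", "gxt"),
                       terms = NULL, alpha = 0.05) {
  kind <- match.arg(kind)
  allowed <- .MODEL_TERMS[[kind]]
  if (is.null(terms)) terms <- allowed
  bad <- setdiff(terms, allowed)
  if (length(bad)) {
    stop(sprintf("terms not valid for model kind '%s': %s",
                 kind, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(terms)) stop("duplicated terms", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  structure(list(kind = kind, terms = terms, alpha = alpha),
            class = "model_spec")
}

#' Build a coded design matrix for a digenic model
#'
#' Translates genotype (and, for the genotype-by-time model, development
#' time) records into the coded predictor columns of the requested model.
#' Product terms are computed element-wise from their parent columns; an
#' intercept column of ones is always first. Row order is preserved, and
#' the build is deterministic.
#'
#' @param records a data frame with columns `rc_dosage`, `pb_dosage`, a
#'   response column `y`, and (for `kind = "gxt"`) a `dpa` column.
#' @param spec a [model_spec()].
#' @return An object of class `digenic_design`: list with the model matrix
#'   `X` (intercept first, then coded term columns), `terms` (column
#'   labels excluding the intercept), response `y`, `ids`, and the `spec`.
#' @examples
#' recs <- data.frame(rc_dosage = c(0, 2, 0, 2), pb_dosage = c(0, 0, 2, 2),
#'                    y = c(82, 50, 69, 16))
#' build_design(recs, model_spec("hom"))
#' @export
build_design <- function(records, spec) {
  stopifnot(inherits(spec, "model_spec"))
  records <- as.data.frame(records)
  need <- c("rc_dosage", "pb_dosage", "y")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop(sprintf("records lack columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  g <- digenic_genotype(records$rc_dosage, records$pb_dosage)
  if (spec$kind %in% c("hom", "gxt") && !all(is_homozygous(g))) {
    stop(sprintf("model kind '%s' requires homozygous genotypes (dosage 0 or 2)",
                 spec$kind), call. = FALSE)
  }
  base <- list(
    a1 = code_additive(g$rc_dosage),
    d1 = code_dominance(g$rc_dosage),
    a2 = code_additive(g$pb_dosage),
    d2 = code_dominance(g$pb_dosage)
  )
  if (spec$kind == "gxt") {
    if (is.null(records$dpa)) {
      stop("the genotype-by-time model requires a 'dpa' column", call. = FALSE)
    }
    base$tau <- code_time(records$dpa)
  }
  col_for <- function(term) {
    switch(term,
      a1 = base$a1, d1 = base$d1, a2 = base$a2, d2 = base$d2,
      tau = base$tau,
      i_a1a2 = base$a1 * base$a2,
      i_a1d2 = base$a1 * base$d2,
      i_d1a2 = base$d1 * base$a2,
      i_d1d2 = base$d1 * base$d2,
      I_a1tau = base$a1 * base$tau,
      I_a2tau = base$a2 * base$tau,
      stop(sprintf("unknown term '%s'", term), call. = FALSE))
  }
  X <- vapply(spec$terms, col_for, numeric(nrow(records)))
  if (nrow(records) == 1L) X <- matrix(X, nrow = 1L,
                                       dimnames = list(NULL, spec$terms))
  X <- cbind(`(Intercept)` = 1, X)
  ids <- if (!is.null(records$sample_id)) as.character(records$sample_id)
         else as.character(seq_len(nrow(records)))
  structure(list(X = X, terms = spec$terms, y = as.numeric(records$y),
                 ids = ids, spec = spec),
            class = "digenic_design")
}

#' Check pairwise orthogonality of design columns
#'
#' The genetic contrast codes are chosen "to comply with the orthogonal
#' property" under balanced replication; unbalanced data (an F2 with
#' unequal class counts) or the 0/1 time coding break it. This report makes
#' the actual orthogonality structure of a realised design explicit: it
#' returns the matrix of centred inner products between non-intercept
#' columns and flags each pair whose absolute centred inner product is
#' below `tol`.
#'
#' @param design a [digenic_design()].
#' @param tol absolute tolerance; default `1e-9 * n` observations.
#' @return list with `inner` (centred inner-product matrix) and
#'   `orthogonal` (logical matrix; diagonal `NA`).
#' @export
check_orthogonality <- function(design, tol = NULL) {
  stopifnot(inherits(design, "digenic_design"))
  Xc <- design$X[, -1L, drop = FALSE]
  if (ncol(Xc) < 2L) {
    stop("need at least two non-intercept columns", call. = FALSE)
  }
  n <- nrow(Xc)
  if (is.null(tol)) tol <- 1e-9 * n
  Xc <- scale(Xc, center = TRUE, scale = FALSE)
  ip <- crossprod(Xc)
  ortho <- abs(ip) < tol
  diag(ortho) <- NA
  list(inner = ip, orthogonal = ortho)
}
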