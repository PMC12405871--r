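#' Digenic genotypes as functional-allele dosages
#'
#' A digenic genotype records the number of functional alleles (0, 1, or 2)
#' at each of two unlinked biallelic loci: the red-pericarp locus *Rc/rc*
#' (chromosome 7) and the purple-pericarp locus *Pb/pb* (chromosome 4).
#' Dosage 0 is the homozygous loss-of-function class (`rcrc`/`pbpb`),
#' 1 the heterozygote, and 2 the homozygous functional class.
#'
#' @param rc_dosage integer vector of functional *Rc* allele counts in
#'   \{0, 1, 2\}.
#' @param pb_dosage integer vector of functional *Pb* allele counts in
#'   \{0, 1, 2\}; recycled against `rc_dosage` if of length 1.
#' @return A data frame of class `digenic_genotype` with columns
#'   `rc_dosage` and `pb_dosage`.
#' @examples
#' digenic_genotype(c(0, 2), c(2, 2))
#' parse_genotype(c("RcrcPbpb", "rcrc/pbpb"))
#' @export
digenic_genotype <- function(rc_dosage, pb_dosage) {
  rc <- check_dosage(rc_dosage, "rc_dosage")
  pb <- check_dosage(pb_dosage, "pb_dosage")
  if (length(rc) == 1L && length(pb) > 1L) rc <- rep(rc, length(pb))
  if (length(pb) == 1L && length(rc) > 1L) pb <- rep(pb, length(rc))
  if (length(rc) != length(pb)) {
    stop("rc_dosage and pb_dosage must have equal length", call. = FALSE)
  }
  structure(data.frame(rc_dosage = rc, pb_dosage = pb),
            class = c("digenic_genotype", "data.frame"))
}

check_dosage <- function(x, what) {
  x <- as.integer(x)
  bad <- which(is.na(x) | !(x %in% 0:2))
  if (length(bad)) {
    stop(sprintf("%s must be 0, 1, or 2 (offending entries: %s)",
                 what, paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  x
}

#' Parse allele-string genotype labels into dosages
#'
#' Maps labels such as `"RcRc"`, `"Rcrc"`, `"rcrc"`, `"PbPb"`, `"Pbpb"`,
#' `"pbpb"` — or combined labels like `"RcrcPbpb"` or `"rcrc/PbPb"` — to
#' functional-allele dosages. A capital initial marks the functional allele.
#'
#' @param labels character vector of genotype labels. Each label must
#'   contain an *Rc*-locus part and a *Pb*-locus part (separator optional).
#' @return A `digenic_genotype` data frame.
#' @export
parse_genotype <- function(labels) {
  one_locus <- function(txt, up, lo) {
    count <- function(pat) {
      vapply(gregexpr(pat, txt, fixed = TRUE),
             function(m) sum(m > 0L), integer(1))
    }
    n <- count(up)
    m <- count(lo)
    if (any(n + m != 2L)) {
      stop(sprintf("cannot parse %s-locus genotype in: %s", up,
                   paste(txt[n + m != 2L], collapse = ", ")), call. = FALSE)
    }
    as.integer(n)
  }
  labels <- gsub("[ /_:+-]", "", labels)
  digenic_genotype(one_locus(labels, "Rc", "rc"),
                   one_locus(labels, "Pb", "pb"))
}

#' @export
format.digenic_genotype <- function(x, ...) {
  rc <- c("rcrc", "Rcrc", "RcRc")[x$rc_dosage + 1L]
  pb <- c("pbpb", "Pbpb", "PbPb")[x$pb_dosage + 1L]
  paste0(rc, pb)
}

is_homozygous <- function(g) {
  g$rc_dosage != 1L & g$pb_dosage != 1L
}
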