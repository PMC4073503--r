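## Pooled, df-weighted variance of two replicate sets.
.pooledVar <- function(a, b) {
  na <- length(a); nb <- length(b)
  ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
}

.checkGroups <- function(segregants, parentA, parentB) {
  if (length(segregants) < 2L) stop("need >= 2 segregant values")
  if (length(parentA) < 2L || length(parentB) < 2L)
    stop("need >= 2 replicate measurements per parent")
}

#' Broad-sense heritability
#'
#' Estimates broad-sense heritability as
#' \eqn{H^2 = 100\,(Var_{seg} - Var_{env}) / Var_{seg}}, where
#' \eqn{Var_{seg}} is the sample variance of the segregant phenotypes and
#' \eqn{Var_{env}} the pooled (df-weighted) variance of the two parental
#' replicate sets. The estimate is reported unclipped; when
#' \eqn{Var_{env} > Var_{seg}} (negative estimate) the result is flagged
#' rather than truncated.
#'
#' @param segregants Numeric phenotype values of the segregant population
#'   (>= 2).
#' @param parentA,parentB Replicate phenotype measurements of each parent
#'   (>= 2 each).
#'
#' @return A [HeritabilityResult-class].
#' @examples
#' heritability(rnorm(100, sd = 2), c(9, 10, 11), c(19, 20, 21))
#' @export
heritability <- function(segregants, parentA, parentB) {
  .checkGroups(segregants, parentA, parentB)
  varSeg <- stats::var(segregants)
  if (varSeg == 0) stop("segregant variance is zero: H2 is undefined")
  varEnv <- .pooledVar(parentA, parentB)
  methods::new("HeritabilityResult",
               H2Percent = 100 * (varSeg - varEnv) / varSeg,
               varSeg = varSeg, varEnv = varEnv,
               flagged = varEnv > varSeg)
}

#' @describeIn HeritabilityResult-class Heritability in percent.
#' @param x,object A \code{HeritabilityResult}.
#' @export
H2Percent <- function(x) x@H2Percent

setMethod("show", "HeritabilityResult", function(object) {
  cat(sprintf("H2 = %.1f%%  (Var_seg = %.4g, Var_env = %.4g)%s\n",
              object@H2Percent, object@varSeg, object@varEnv,
              if (object@flagged) "  [flagged: Var_env > Var_seg]" else ""))
})

#' Transgressive segregation
#'
#' Counts segregants whose phenotype lies at least 2 pooled parental standard
#' deviations above the higher parental mean or below the lower parental mean
#' (boundaries inclusive).
#'
#' @inheritParams heritability
#'
#' @return A [TransgressionResult-class].
#' @examples
#' transgression(c(7, 9, 23), c(9, 10, 11), c(19, 20, 21))
#' @export
transgression <- function(segregants, parentA, parentB) {
  .checkGroups(segregants, parentA, parentB)
  sigma <- sqrt(.pooledVar(parentA, parentB))
  mA <- mean(parentA); mB <- mean(parentB)
  highCut <- max(mA, mB) + 2 * sigma
  lowCut <- min(mA, mB) - 2 * sigma
  nHigh <- sum(segregants >= highCut)
  nLow <- sum(segregants <= lowCut)
  methods::new("TransgressionResult",
               nHigh = as.integer(nHigh), nLow = as.integer(nLow),
               percent = 100 * (nHigh + nLow) / length(segregants),
               sigma = sigma,
               thresholds = c(low_cut = lowCut, high_cut = highCut))
}

#' @describeIn TransgressionResult-class Percentage of transgressive
#'   segregants.
#' @param x,object A \code{TransgressionResult}.
#' @export
transgressionPercent <- function(x) x@percent

setMethod("show", "TransgressionResult", function(object) {
  cat(sprintf(
    "Transgression: %d high + %d low (%.1f%%); cuts [%.3g, %.3g], sigma %.3g\n",
    object@nHigh, object@nLow, object@percent,
    object@thresholds["low_cut"], object@thresholds["high_cut"],
    object@sigma))
})

#' Select phenotypic bulks
#'
#' Picks the \code{k} segregants with the highest and the \code{k} with the
#' lowest checkpoint phenotype. Ties are broken by strain id: the low bulk
#' prefers lexicographically smaller ids, the high bulk larger ids, so the
#' two bulks are deterministic and disjoint whenever \code{2k <= n}.
#'
#' @param phenotypes data.frame with columns \code{strain},
#'   \code{co2_at_checkpoint} and optionally \code{group} (only rows with
#'   \code{group == "segregant"} are used when present).
#' @param k Bulk size (default 15).
#'
#' @return list with character vectors \code{low} and \code{high} of strain
#'   ids, each of length \code{k}.
#' @export
selectBulks <- function(phenotypes, k = 15L) {
  k <- as.integer(k)
  seg <- phenotypes
  if ("group" %in% names(seg)) seg <- seg[seg$group == "segregant", ]
  n <- nrow(seg)
  if (2L * k > n)
    stop("cannot form two disjoint bulks of ", k, " from ", n, " segregants")
  v <- seg$co2_at_checkpoint
  id <- as.character(seg$strain)
  lowOrd <- order(v, id)             # ascending value, then id ascending
  highOrd <- order(-v, -xtfrm(id))   # descending value, then id descending
  list(low = id[lowOrd[seq_len(k)]],
       high = id[highOrd[seq_len(k)]])
}
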