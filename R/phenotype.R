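#' Plate-level embryo counts
#'
#' Constructor for the raw observation of the feeding-RNAi assay: the number of
#' dead fertilized embryos and hatched larvae counted on one plate.
#'
#' @param dead_embryos Count of dead fertilized embryos (DE).
#' @param hatched_larvae Count of hatched larvae (HL).
#' @return An object of class \code{"plate_counts"}.
#' @examples
#' plate_counts(25, 75)
#' @export
plate_counts <- function(dead_embryos, hatched_larvae) {
  if (length(dead_embryos) != 1L || length(hatched_larvae) != 1L)
    stop("plate_counts takes scalar counts")
  if (is.na(dead_embryos) || is.na(hatched_larvae))
    stop("counts must not be NA")
  if (dead_embryos < 0 || hatched_larvae < 0)
    stop("counts must be non-negative")
  structure(list(dead_embryos = as.numeric(dead_embryos),
                 hatched_larvae = as.numeric(hatched_larvae)),
            class = "plate_counts")
}

#' @export
print.plate_counts <- function(x, ...) {
  cat(sprintf("plate: %g dead embryos, %g hatched larvae\n",
              x$dead_embryos, x$hatched_larvae))
  invisible(x)
}

#' Embryonic lethality of one plate
#'
#' The fraction of laid embryos that arrest: DE / (DE + HL), where DE is the
#' count of dead fertilized embryos and HL the count of hatched larvae.
#'
#' @param counts A \code{plate_counts} object, or a list/data.frame row with
#'   fields \code{dead_embryos} and \code{hatched_larvae}.
#' @return Lethality in [0, 1].
#' @examples
#' embryonic_lethality(plate_counts(25, 75))  # 0.25
#' @export
embryonic_lethality <- function(counts) {
  de <- counts$dead_embryos
  hl <- counts$hatched_larvae
  if (any(de < 0) || any(hl < 0)) stop("counts must be non-negative")
  tot <- de + hl
  if (any(tot <= 0)) stop("empty plate: dead_embryos + hatched_larvae must be > 0")
  de / tot
}

#' A treated/control plate pair
#'
#' Pairs the RNAi-treatment plate with its empty-vector control plate for one
#' strain (or individual) and replicate.
#'
#' @param treated \code{plate_counts} from the dsRNA-feeding plate.
#' @param control \code{plate_counts} from the empty-vector plate.
#' @return An object of class \code{"assay_pair"}.
#' @export
assay_pair <- function(treated, control) {
  structure(list(treated = treated, control = control), class = "assay_pair")
}

#' Background-corrected induced embryonic lethality
#'
#' Isolates the lethality attributable to the RNAi treatment from background
#' embryonic lethality measured on the matched empty-vector control plate:
#' \deqn{(L_T - L_C) / (1 - L_C)}
#' where \eqn{L_T} and \eqn{L_C} are the embryonic lethalities of the treated
#' and control plates. The statistic is 1 exactly when the treated plate is
#' fully lethal, and may be negative when the treated plate shows less
#' lethality than the control.
#'
#' @param pair An \code{assay_pair}, or anything with \code{$treated} and
#'   \code{$control} plate counts.
#' @return Induced lethality (unitless, at most 1; can be negative).
#' @examples
#' induced_lethality(assay_pair(plate_counts(50, 50), plate_counts(10, 90)))
#' @export
induced_lethality <- function(pair) {
  lt <- embryonic_lethality(pair$treated)
  lc <- embryonic_lethality(pair$control)
  if (any(lc >= 1))
    stop("control plate fully lethal: induced lethality undefined (denominator 0)")
  (lt - lc) / (1 - lc)
}

#' Dominance of one parental phenotype over the other
#'
#' Scaled deviation of the hybrid (F1) phenotype from the midparent value:
#' \deqn{d = (Hybrid - MidParent) / |ParentA - MidParent|}
#' with MidParent = (ParentA + ParentB) / 2. d = 0 is additivity, d = 1 full
#' dominance of parent A's phenotype, d = -1 full dominance of parent B's.
#'
#' @param hybrid_mean Mean phenotype of the F1 hybrid.
#' @param parentA_mean,parentB_mean Mean phenotypes of the two parents; must
#'   differ.
#' @return The dominance coefficient d.
#' @examples
#' dominance(0.75, 1, 0)  # 0.5
#' @export
dominance <- function(hybrid_mean, parentA_mean, parentB_mean) {
  if (isTRUE(all.equal(parentA_mean, parentB_mean)))
    stop("parent means are equal: midparent distance is zero")
  mid <- (parentA_mean + parentB_mean) / 2
  (hybrid_mean - mid) / abs(parentA_mean - mid)
}

#' Classify an F2 lethality into sensitivity classes
#'
#' The four-class scheme used for F2 segregation analysis: full sensitivity
#' (100\% lethality), high (75--99\%), intermediate (25--75\%) and low (<25\%).
#' The printed ranges overlap at the boundaries; the package resolves them as
#' half-open intervals [0.75, 1), [0.25, 0.75) and [0, 0.25), with "full"
#' reserved for lethality exactly 1. Negative values (possible for
#' background-corrected lethality on noisy plates) are clamped to 0 before
#' classification.
#'
#' @param lethality Numeric vector of lethalities.
#' @return Factor with levels \code{full}, \code{high}, \code{intermediate},
#'   \code{low}.
#' @examples
#' classify_f2(c(1, 0.8, 0.5, 0.1))
#' @export
classify_f2 <- function(lethality) {
  x <- pmax(lethality, 0)
  if (any(x > 1 + 1e-9)) stop("lethality must be at most 1")
  lab <- ifelse(x >= 1 - 1e-12, "full",
         ifelse(x >= 0.75, "high",
         ifelse(x >= 0.25, "intermediate", "low")))
  factor(lab, levels = c("full", "high", "intermediate", "low"))
}

#' Classify an inbred-line induced lethality
#'
#' The three-class scheme used for RIAIL panels: \code{full} for induced
#' lethality exactly 1, \code{zero} for values at or below 0 (negative
#' corrected values are treated as zero), and \code{intermediate} otherwise.
#'
#' @param value Numeric vector of induced lethalities.
#' @return Factor with levels \code{full}, \code{zero}, \code{intermediate}.
#' @examples
#' classify_riail(c(1, 0, 0.97357))
#' @export
classify_riail <- function(value) {
  lab <- ifelse(value >= 1 - 1e-12, "full",
         ifelse(value <= 0, "zero", "intermediate"))
  factor(lab, levels = c("full", "zero", "intermediate"))
}
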