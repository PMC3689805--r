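#' Genetic map distance to recombination fraction (linear)
#'
#' Converts a cM distance to a recombination fraction as r = cM/100, capped at
#' 0.5 (free recombination). The linear conversion, rather than a mapping
#' function such as Haldane's, is the convention used for the two-locus F2
#' expectation model in this package: at short distances the two agree closely,
#' and the linear form reproduces the published class expectations at 7.47 cM
#' exactly.
#'
#' @param distance_cM Genetic distance in centimorgans, >= 0.
#' @return Recombination fraction in [0, 0.5].
#' @examples
#' cM_to_r(7.47)  # 0.0747
#' @export
cM_to_r <- function(distance_cM) {
  if (any(distance_cM < 0)) stop("genetic distance must be non-negative")
  pmin(distance_cM / 100, 0.5)
}

#' Haldane map function
#'
#' Recombination fraction under Haldane's no-interference model,
#' r = (1 - exp(-2d/100))/2 for d in cM. Used by the meiosis simulator and by
#' the genotype posteriors of the mapping module.
#'
#' @param distance_cM Genetic distance in centimorgans, >= 0.
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane_r <- function(distance_cM) {
  if (any(distance_cM < 0)) stop("genetic distance must be non-negative")
  (1 - exp(-2 * distance_cM / 100)) / 2
}

#' Two-locus gamete haplotype distribution from a heterozygous F1
#'
#' For an F1 heterozygous at two linked loci in coupling (parental haplotypes
#' N2-N2 and CB-CB), each parental haplotype is produced with frequency
#' (1-r)/2 and each recombinant with frequency r/2.
#'
#' @param r Recombination fraction between the two loci, in [0, 0.5].
#' @return Named numeric vector over haplotypes \code{NN}, \code{CC},
#'   \code{NC}, \code{CN} (first letter: toxin/rescue locus; second:
#'   sensitivity locus), summing to 1.
#' @examples
#' gamete_distribution(0.0747)
#' @export
gamete_distribution <- function(r) {
  if (length(r) != 1L || is.na(r) || r < 0 || r > 0.5)
    stop("recombination fraction must be a single value in [0, 0.5]")
  c(NN = (1 - r) / 2, CC = (1 - r) / 2, NC = r / 2, CN = r / 2)
}

#' Linked incompatibility cross model
#'
#' Specifies the two-locus model for an N2 x CB4856 F2: a recessive
#' insensitivity locus (ppw-1, CB allele confers recessive loss of germline
#' RNAi sensitivity) linked to a paternal-effect toxin/rescue incompatibility
#' locus (zeel-1/peel-1; CB4856 carries a deletion, so zygotes homozygous for
#' the CB allele lacking zygotic rescue die with some penetrance when sperm
#' delivered the toxin). Every F1 gamete deposits the toxin, because the F1 is
#' heterozygous for the toxin allele and deposition is sperm-autonomous.
#'
#' @param distance_cM Distance between the rescue locus and the sensitivity
#'   locus in cM (default 7.47).
#' @param penetrance Probability that a susceptible (rescue-null homozygous)
#'   zygote dies, in [0, 1] (default 0.26).
#' @param map_function Either \code{"linear"} (default; r = cM/100) or
#'   \code{"haldane"}.
#' @return An object of class \code{"cross_model"} with fields \code{r},
#'   \code{penetrance}, \code{distance_cM}.
#' @examples
#' m <- incompatibility_model(7.47, 0.26)
#' expected_f2_classes(m)
#' @export
incompatibility_model <- function(distance_cM = 7.47, penetrance = 0.26,
                                  map_function = c("linear", "haldane")) {
  map_function <- match.arg(map_function)
  if (penetrance < 0 || penetrance > 1) stop("penetrance must be in [0, 1]")
  r <- switch(map_function, linear = cM_to_r(distance_cM),
              haldane = haldane_r(distance_cM))
  structure(list(distance_cM = distance_cM, r = r, penetrance = penetrance,
                 map_function = map_function),
            class = "cross_model")
}

#' @export
print.cross_model <- function(x, ...) {
  cat(sprintf(paste0("linked incompatibility cross model: %.4g cM (r = %.4g, %s),",
                     " toxin penetrance %.3g\n"),
              x$distance_cM, x$r, x$map_function, x$penetrance))
  invisible(x)
}

#' Expected F2 phenotype-class frequencies under the linked incompatibility
#'
#' Exact expectation for the selfed F2 of an N2 x CB4856 F1 heterozygous at a
#' recessive-insensitivity locus linked to the toxin/rescue incompatibility.
#' The F2 zygote distribution is the product of two independent F1 gametes;
#' zygotes homozygous for the non-rescue (CB) allele die with probability
#' \code{penetrance} (all F1 gametes deposit the toxin); the distribution is
#' renormalized over survivors. Surviving F2 are classed by the lethality of
#' their own RNAi-treated broods:
#' \describe{
#'   \item{total_lethality}{any survivor carrying at least one sensitive (N2)
#'     allele at the sensitivity locus: its brood arrests completely.}
#'   \item{no_lethality}{insensitivity-locus CB homozygotes that are rescue
#'     homozygous (either allele): their self-broods see no toxin deaths
#'     (CB/CB mothers produce no toxin; N2/N2 broods are all rescued).}
#'   \item{low_lethality}{insensitivity-locus CB homozygotes heterozygous at
#'     the rescue locus: their self-broods lose rescue-null zygotes at rate
#'     penetrance/4, a low background lethality.}
#' }
#'
#' @param model A \code{cross_model} from \code{\link{incompatibility_model}}.
#' @return A named numeric vector of class proportions
#'   (\code{total_lethality}, \code{no_lethality}, \code{low_lethality})
#'   summing to 1, with attribute \code{"low_level"} giving the expected brood
#'   lethality (penetrance/4) of the low class.
#' @examples
#' expected_f2_classes(incompatibility_model(7.47, 0.26))
#' @export
expected_f2_classes <- function(model) {
  stopifnot(inherits(model, "cross_model"))
  g <- gamete_distribution(model$r)
  p <- model$penetrance
  a <- g[["CC"]]  # rescue-null, insensitive haplotype
  b <- g[["NC"]]  # recombinant: rescued, insensitive
  # insensitive homozygotes (sensitivity locus CB/CB), by rescue genotype
  ins_rescueNN  <- b * b          # survives always, no toxin in own brood
  ins_rescueHet <- 2 * a * b      # survives; own brood loses p/4
  ins_rescueCC  <- a * a * (1 - p)  # survives toxin with prob 1-p; no toxin in brood
  # all rescue-null homozygotes die with probability p
  p_rescue_null <- (a + b)^2      # = 1/4 regardless of r
  surv <- 1 - p * p_rescue_null
  none <- (ins_rescueNN + ins_rescueCC) / surv
  low <- ins_rescueHet / surv
  total <- 1 - none - low
  out <- c(total_lethality = total, no_lethality = none, low_lethality = low)
  attr(out, "low_level") <- p / 4
  out
}

#' Extend the incompatibility model with an unlinked recessive modifier
#'
#' Composes the surviving-F2 class distribution of
#' \code{\link{expected_f2_classes}} with one additional unlinked locus whose
#' recessive (CB) homozygote confers an intermediate (partial) loss of
#' sensitivity. The modifier segregates independently, so a quarter of the
#' otherwise fully-sensitive class drops to intermediate sensitivity; the base
#' model's no/low-lethality classes merge into the low-sensitivity class.
#'
#' @param model A \code{cross_model}; its \code{expected_f2_classes} output is
#'   the base distribution.
#' @param modifier Logical; if \code{FALSE} the base three-class distribution
#'   is returned relabeled with the modifier absent (high = total lethality,
#'   intermediate = 0 from the modifier, low = none + low).
#' @return Named numeric vector over \code{high}, \code{intermediate},
#'   \code{low} sensitivity classes, summing to 1.
#' @examples
#' expected_classes_additive(incompatibility_model(7.47, 0.26))
#' @export
expected_classes_additive <- function(model, modifier = TRUE) {
  base <- expected_f2_classes(model)
  tot <- base[["total_lethality"]]
  lowpool <- base[["no_lethality"]] + base[["low_lethality"]]
  if (!modifier)
    return(c(high = tot, intermediate = 0, low = lowpool))
  c(high = tot * 3 / 4, intermediate = tot * 1 / 4, low = lowpool)
}

#' Single-locus Mendelian expectations for full sensitivity
#'
#' Expected proportion of fully sensitive F2 from a selfed heterozygote under a
#' single unlinked insensitivity locus with no viability selection: a dominant
#' insensitivity allele leaves 1/4 of F2 sensitive; a recessive one leaves 3/4.
#'
#' @param mode \code{"dominant"} or \code{"recessive"} insensitivity, or
#'   \code{"none"} for a null allele with no effect.
#' @return Proportion of F2 expected to be fully sensitive.
#' @examples
#' expected_single_locus("dominant")   # 0.25
#' expected_single_locus("recessive")  # 0.75
#' @export
expected_single_locus <- function(mode = c("dominant", "recessive", "none")) {
  mode <- match.arg(mode)
  switch(mode, dominant = 0.25, recessive = 0.75, none = 1)
}

#' Chi-square goodness of fit of observed class counts to a model
#'
#' Pearson chi-square test of observed phenotype-class counts against expected
#' class proportions, with an optional merge map collapsing observed classes
#' onto the model's classes (segregation models often predict coarser classes
#' than the assay records). No continuity correction; degrees of freedom are
#' (number of merged classes - 1), as no parameter is estimated from the tested
#' data.
#'
#' @param observed Named integer vector of observed counts per class.
#' @param expected Named numeric vector of expected proportions per model
#'   class (must sum to 1).
#' @param merge_map Optional named character vector mapping names of
#'   \code{observed} to names of \code{expected}; observed classes mapping to
#'   the same model class are summed. If \code{NULL}, names must already
#'   match.
#' @return A list of class \code{"gof_result"}: \code{chi2}, \code{df},
#'   \code{p_value}, plus the merged \code{observed} and \code{expected}
#'   counts.
#' @examples
#' obs <- c(full = 109, high = 22, intermediate = 12, low = 38)
#' exp <- expected_classes_additive(incompatibility_model(7.47, 0.26))
#' chisq_gof(obs, exp, merge_map = c(full = "high", high = "intermediate",
#'                                   intermediate = "intermediate", low = "low"))
#' @export
chisq_gof <- function(observed, expected, merge_map = NULL) {
  if (is.null(names(observed)) || is.null(names(expected)))
    stop("observed and expected must be named")
  if (abs(sum(expected) - 1) > 1e-8)
    stop("expected proportions must sum to 1")
  if (!is.null(merge_map)) {
    if (!all(names(observed) %in% names(merge_map)))
      stop("merge_map must cover every observed class")
    tgt <- merge_map[names(observed)]
    if (!all(tgt %in% names(expected)))
      stop("merge_map targets must be names of expected classes")
    merged <- tapply(observed, factor(tgt, levels = names(expected)), sum)
    merged[is.na(merged)] <- 0
    observed <- stats::setNames(as.numeric(merged), names(expected))
  }
  if (!setequal(names(observed), names(expected)))
    stop("observed classes do not align with expected classes")
  observed <- observed[names(expected)]
  n <- sum(observed)
  if (n <= 0) stop("total observed count must be positive")
  if (any(expected <= 0 & observed > 0))
    stop("nonzero observed count in a class with expected proportion 0")
  keep <- expected > 0
  e <- n * expected[keep]
  chi2 <- sum((observed[keep] - e)^2 / e)
  df <- sum(keep) - 1L
  structure(list(chi2 = unname(chi2), df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 observed = observed, expected = n * expected),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("chi-square goodness of fit: chi2 = %.4g, df = %d, p = %.3g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}
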