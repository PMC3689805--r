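#' Build a genetic map
#'
#' A genetic map is a data.frame with columns \code{marker}, \code{chr} and
#' \code{pos} (cM), positions strictly increasing within each chromosome.
#' \code{make_genetic_map} lays markers at regular spacing along chromosomes of
#' given lengths; \code{as_genetic_map} validates an existing data.frame.
#'
#' @param lengths_cM Named numeric vector of chromosome lengths in cM. The
#'   default is a compact six-chromosome caricature of the worm genome.
#' @param spacing_cM Marker spacing in cM.
#' @return A data.frame of class \code{"genetic_map"}.
#' @examples
#' map <- make_genetic_map(c(I = 50, II = 50), spacing_cM = 5)
#' @export
make_genetic_map <- function(lengths_cM = c(I = 50, II = 50, III = 50,
                                            IV = 50, V = 50, X = 50),
                             spacing_cM = 2) {
  if (is.null(names(lengths_cM)) || any(!nzchar(names(lengths_cM))))
    stop("chromosome lengths must be named")
  if (spacing_cM <= 0) stop("spacing must be positive")
  rows <- lapply(names(lengths_cM), function(ch) {
    pos <- seq(0, lengths_cM[[ch]], by = spacing_cM)
    data.frame(marker = sprintf("c%sm%02d", ch, seq_along(pos)),
               chr = ch, pos = pos, stringsAsFactors = FALSE)
  })
  as_genetic_map(do.call(rbind, rows))
}

#' @rdname make_genetic_map
#' @param x A data.frame with columns \code{marker}, \code{chr}, \code{pos}.
#' @export
as_genetic_map <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(c("marker", "chr", "pos") %in% names(x)))
    stop("map needs columns marker, chr, pos")
  if (nrow(x) == 0) stop("empty map")
  if (anyDuplicated(x$marker)) stop("duplicate marker names")
  for (ch in unique(x$chr)) {
    p <- x$pos[x$chr == ch]
    if (any(diff(p) <= 0))
      stop(sprintf("positions not strictly increasing on chromosome %s", ch))
  }
  rownames(x) <- NULL
  class(x) <- c("genetic_map", "data.frame")
  x
}

# cumulative-XOR mosaic: gamete rows from per-row parental haplotype matrices.
# hap1, hap2: n x m 0/1 matrices (columns in map order). Crossovers fall in
# each inter-marker interval independently with its Haldane recombination
# fraction (no interference); the starting strand is fair.
.sim_gametes <- function(hap1, hap2, map, n) {
  m <- nrow(map)
  out <- matrix(0L, n, m)
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    state <- matrix(0L, n, length(idx))
    state[, 1] <- stats::rbinom(n, 1L, 0.5)
    if (length(idx) > 1) {
      r <- haldane_r(diff(map$pos[idx]))
      for (j in 2:length(idx)) {
        xo <- stats::rbinom(n, 1L, r[j - 1])
        state[, j] <- (state[, j - 1] + xo) %% 2L
      }
    }
    out[, idx] <- ifelse(state == 0L, hap1[, idx, drop = FALSE],
                         hap2[, idx, drop = FALSE])
  }
  out
}

#' Simulate one meiosis
#'
#' Draws gamete haplotypes from a diploid parent by no-interference meiosis:
#' the returned haplotype is a mosaic of the parent's two haplotypes, with a
#' crossover in each inter-marker interval independently with its Haldane
#' recombination fraction.
#'
#' @param parent List with elements \code{hap1} and \code{hap2}: integer
#'   vectors (0 = N2 allele, 1 = CB allele), one entry per map marker.
#' @param map A \code{genetic_map}.
#' @param n Number of independent gametes to draw.
#' @param seed Optional integer seed.
#' @return If \code{n = 1} an integer vector; otherwise an \code{n} x markers
#'   integer matrix, one gamete per row.
#' @examples
#' map <- make_genetic_map(c(I = 10), spacing_cM = 10)
#' f1 <- list(hap1 = rep(0L, 2), hap2 = rep(1L, 2))
#' simulate_meiosis(f1, map, n = 5, seed = 1)
#' @export
simulate_meiosis <- function(parent, map, n = 1, seed = NULL) {
  if (nrow(map) == 0) stop("empty map")
  if (length(parent$hap1) != nrow(map) || length(parent$hap2) != nrow(map))
    stop("parent haplotypes must have one allele per map marker")
  if (!is.null(seed)) set.seed(seed)
  h1 <- matrix(as.integer(parent$hap1), n, nrow(map), byrow = TRUE)
  h2 <- matrix(as.integer(parent$hap2), n, nrow(map), byrow = TRUE)
  g <- .sim_gametes(h1, h2, map, n)
  if (n == 1) drop(g) else g
}

#' Simulate an F2 panel under the linked incompatibility
#'
#' Draws F2 zygotes of a selfed N2 x CB4856 F1 as products of two independent
#' two-locus gametes, then applies viability selection: zygotes homozygous for
#' the non-rescue (CB) allele at the toxin/rescue locus die with probability
#' \code{model$penetrance} (every F1 gamete deposits the toxin).
#'
#' @param model A \code{cross_model} from \code{\link{incompatibility_model}}.
#' @param n Number of F2 zygotes to draw.
#' @param seed Optional integer seed.
#' @return data.frame with one row per zygote: \code{rescue_cb} and
#'   \code{sens_cb} (count of CB alleles, 0/1/2, at the rescue and sensitivity
#'   locus), \code{survived} (logical), and \code{class} — the expected-brood
#'   phenotype class of survivors (\code{total_lethality}, \code{no_lethality},
#'   \code{low_lethality}; \code{NA} for dead zygotes).
#' @examples
#' f2 <- simulate_f2_panel(incompatibility_model(7.47, 0.26), 1000, seed = 1)
#' table(f2$class[f2$survived])
#' @export
simulate_f2_panel <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "cross_model"), n > 0)
  if (!is.null(seed)) set.seed(seed)
  g <- gamete_distribution(model$r)
  # haplotypes: 1=NN 2=CC 3=NC 4=CN (rescue allele first; 0=N2, 1=CB)
  hap_rescue <- c(0L, 1L, 0L, 1L)
  hap_sens <- c(0L, 1L, 1L, 0L)
  g1 <- sample.int(4L, n, replace = TRUE, prob = g)
  g2 <- sample.int(4L, n, replace = TRUE, prob = g)
  rescue_cb <- hap_rescue[g1] + hap_rescue[g2]
  sens_cb <- hap_sens[g1] + hap_sens[g2]
  susceptible <- rescue_cb == 2L
  survived <- !(susceptible & stats::runif(n) < model$penetrance)
  cls <- ifelse(sens_cb < 2L, "total_lethality",
         ifelse(rescue_cb == 1L, "low_lethality", "no_lethality"))
  cls[!survived] <- NA
  data.frame(rescue_cb = rescue_cb, sens_cb = sens_cb, survived = survived,
             class = factor(cls, levels = c("total_lethality", "no_lethality",
                                            "low_lethality")))
}

#' Simulate a panel of recombinant inbred advanced intercross lines
#'
#' Starts from an F1 base population (every individual heterozygous N2/CB at
#' all markers), intercrosses by random pairing for \code{g_intercross}
#' generations at constant population size, then derives each line by inbreeding
#' to fixation, shortcut as doubling one final gamete — every line is
#' homozygous at every marker. No viability selection or incompatibility acts
#' during panel construction.
#'
#' @param map A \code{genetic_map}.
#' @param n_lines Number of inbred lines to derive.
#' @param g_intercross Number of random-pairing intercross generations
#'   (default 10, the advanced-intercross design).
#' @param seed Optional integer seed.
#' @param pop_size Intercross population size (default \code{2 * n_lines},
#'   at least 50).
#' @return An object of class \code{"genotype_panel"}: list with \code{geno}
#'   (integer matrix lines x markers, 0 = N2, 1 = CB, \code{NA} missing) and
#'   \code{map}.
#' @examples
#' map <- make_genetic_map(c(I = 20), spacing_cM = 5)
#' panel <- simulate_riail_panel(map, 20, seed = 1)
#' @export
simulate_riail_panel <- function(map, n_lines, g_intercross = 10, seed = NULL,
                                 pop_size = max(2 * n_lines, 50)) {
  stopifnot(n_lines > 0, g_intercross >= 0)
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(map)
  hap1 <- matrix(0L, pop_size, m)  # F1 base: N2 / CB at every marker
  hap2 <- matrix(1L, pop_size, m)
  if (g_intercross > 0) {
    for (g in seq_len(g_intercross)) {
      mothers <- sample.int(pop_size, pop_size, replace = TRUE)
      fathers <- sample.int(pop_size, pop_size, replace = TRUE)
      new1 <- .sim_gametes(hap1[mothers, , drop = FALSE],
                           hap2[mothers, , drop = FALSE], map, pop_size)
      new2 <- .sim_gametes(hap1[fathers, , drop = FALSE],
                           hap2[fathers, , drop = FALSE], map, pop_size)
      hap1 <- new1
      hap2 <- new2
    }
  }
  founders <- sample.int(pop_size, n_lines, replace = n_lines > pop_size)
  geno <- .sim_gametes(hap1[founders, , drop = FALSE],
                       hap2[founders, , drop = FALSE], map, n_lines)
  dimnames(geno) <- list(sprintf("L%03d", seq_len(n_lines)), map$marker)
  genotype_panel(geno, map)
}

#' Genotype panel container
#'
#' @param geno Integer matrix (lines x markers) of homozygous genotypes coded
#'   0 = N2, 1 = CB, \code{NA} = missing; column names must match the map's
#'   markers.
#' @param map A \code{genetic_map}.
#' @return Object of class \code{"genotype_panel"}.
#' @export
genotype_panel <- function(geno, map) {
  map <- as_genetic_map(map)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (ncol(geno) != nrow(map)) stop("genotype columns must match map markers")
  if (is.null(colnames(geno))) colnames(geno) <- map$marker
  if (!identical(colnames(geno), map$marker))
    stop("genotype column names must match map marker names (in order)")
  if (is.null(rownames(geno))) rownames(geno) <- sprintf("L%03d", seq_len(nrow(geno)))
  bad <- !(geno %in% c(0L, 1L) | is.na(geno))
  if (any(bad)) stop("genotypes must be 0, 1 or NA")
  structure(list(geno = geno, map = map), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype panel: %d lines, %d markers on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chr))))
  invisible(x)
}

# index of the map marker nearest to (chr, pos)
.nearest_marker <- function(map, chr, pos) {
  idx <- which(map$chr == chr)
  if (length(idx) == 0) stop(sprintf("no markers on chromosome %s", chr))
  idx[which.min(abs(map$pos[idx] - pos))]
}

#' Preset genetic architectures for the assay forward model
#'
#' An architecture maps a line's genotype at a few named loci to its expected
#' induced embryonic lethality, plus the assay nuisance parameters (background
#' control-plate lethality and embryos per plate). All presets place the major
#' insensitivity locus (the argonaute ppw-1 analog) mid-chromosome I; the CB
#' homozygote there is insensitive (expected induced lethality 0) and any other
#' genotype fully sensitive, except as modified:
#' \describe{
#'   \item{ppw1_only}{the major locus alone — a bimodal 0/1 trait.}
#'   \item{ppw1_additive_modifier}{an unlinked recessive modifier (chromosome
#'     IV) drops otherwise fully sensitive lines to intermediate lethality 0.5.}
#'   \item{epistatic_suppressor}{two unlinked loci (chromosomes II and V) in a
#'     specific trans combination (CB at one, N2 at the other) suppress the
#'     insensitivity of CB-ppw lines, restoring lethality 0.97 — lines with CB
#'     alleles flanking the major locus yet high lethality.}
#'   \item{dominant_insensitivity}{two unlinked loci (chromosomes III and X) in
#'     a specific trans combination confer insensitivity (lethality 0.16)
#'     despite an N2 major locus.}
#' }
#'
#' @param name Preset name.
#' @param map The \code{genetic_map} the panel is defined on; loci are attached
#'   to their nearest markers.
#' @param background Control-plate (background) embryonic lethality.
#' @param n_embryos Embryos laid per plate.
#' @return Object of class \code{"architecture"}: \code{loci} data.frame
#'   (name, chr, pos, marker), \code{rule} (function from the lines x loci
#'   allele matrix to expected induced lethality), \code{background},
#'   \code{n_embryos}.
#' @examples
#' map <- make_genetic_map()
#' arch <- arch_preset("ppw1_only", map)
#' @export
arch_preset <- function(name = c("ppw1_only", "ppw1_additive_modifier",
                                 "epistatic_suppressor", "dominant_insensitivity"),
                        map, background = 0.05, n_embryos = 200) {
  name <- match.arg(name)
  map <- as_genetic_map(map)
  chrs <- unique(map$chr)
  mid <- function(ch) mean(range(map$pos[map$chr == ch]))
  pick <- function(i) chrs[min(i, length(chrs))]
  loci <- switch(name,
    ppw1_only = data.frame(name = "ppw1", chr = pick(1), pos = mid(pick(1))),
    ppw1_additive_modifier = data.frame(
      name = c("ppw1", "modifier"),
      chr = c(pick(1), pick(4)),
      pos = c(mid(pick(1)), mid(pick(4)))),
    epistatic_suppressor = data.frame(
      name = c("ppw1", "sup_cb", "sup_n2"),
      chr = c(pick(1), pick(2), pick(5)),
      pos = c(mid(pick(1)), mid(pick(2)), mid(pick(5)))),
    dominant_insensitivity = data.frame(
      name = c("ppw1", "ins_cb", "ins_n2"),
      chr = c(pick(1), pick(3), pick(6)),
      pos = c(mid(pick(1)), mid(pick(3)), mid(pick(6)))))
  if (anyDuplicated(paste(loci$chr, loci$pos)))
    stop("architecture needs distinct loci; supply a map with enough chromosomes")
  loci$marker <- map$marker[mapply(.nearest_marker, loci$chr, loci$pos,
                                   MoreArgs = list(map = map))]
  rule <- switch(name,
    ppw1_only = function(A) ifelse(A[, "ppw1"] == 1L, 0, 1),
    ppw1_additive_modifier = function(A)
      ifelse(A[, "ppw1"] == 1L, 0, ifelse(A[, "modifier"] == 1L, 0.5, 1)),
    epistatic_suppressor = function(A)
      ifelse(A[, "ppw1"] == 1L,
             ifelse(A[, "sup_cb"] == 1L & A[, "sup_n2"] == 0L, 0.97, 0), 1),
    dominant_insensitivity = function(A)
      ifelse(A[, "ppw1"] == 1L, 0,
             ifelse(A[, "ins_cb"] == 1L & A[, "ins_n2"] == 0L, 0.16, 1)))
  structure(list(name = name, loci = loci, rule = rule,
                 background = background, n_embryos = n_embryos),
            class = "architecture")
}

#' Simulate plate-level assay counts for a genotype panel
#'
#' The forward model of the feeding-RNAi assay: each line's expected induced
#' lethality comes from the architecture's genotype rule; the treated plate's
#' dead-embryo count is Binomial(n_embryos, combined) with
#' combined = background + (1 - background) * induced, and the control plate's
#' is Binomial(n_embryos, background). The background-corrected induced
#' lethality recovers the rule value in expectation.
#'
#' @param panel A \code{genotype_panel}.
#' @param arch An \code{architecture} (or compatible list) whose loci markers
#'   exist in the panel.
#' @param seed Optional integer seed.
#' @param replicates Plate pairs per line (default 1).
#' @return data.frame in the plate-count schema: \code{strain},
#'   \code{condition} (\code{treated}/\code{control}), \code{dead_embryos},
#'   \code{hatched_larvae}, \code{replicate}.
#' @examples
#' map <- make_genetic_map(c(I = 20), spacing_cM = 10)
#' panel <- simulate_riail_panel(map, 10, seed = 1)
#' counts <- simulate_phenotypes(panel, arch_preset("ppw1_only", map), seed = 2)
#' @export
simulate_phenotypes <- function(panel, arch, seed = NULL, replicates = 1) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!all(arch$loci$marker %in% colnames(panel$geno)))
    stop("architecture loci markers not present in panel")
  if (!is.null(seed)) set.seed(seed)
  A <- panel$geno[, arch$loci$marker, drop = FALSE]
  colnames(A) <- arch$loci$name
  if (anyNA(A)) stop("genotype rule undefined: missing genotype at an architecture locus")
  induced <- arch$rule(A)
  if (any(is.na(induced)) || any(induced < 0) || any(induced > 1))
    stop("architecture rule must map every genotype to a lethality in [0, 1]")
  bg <- arch$background
  combined <- bg + (1 - bg) * induced
  n <- nrow(panel$geno)
  ne <- arch$n_embryos
  out <- vector("list", replicates)
  for (rep_i in seq_len(replicates)) {
    de_t <- stats::rbinom(n, ne, combined)
    de_c <- stats::rbinom(n, ne, bg)
    out[[rep_i]] <- data.frame(
      strain = rep(rownames(panel$geno), 2L),
      condition = rep(c("treated", "control"), each = n),
      dead_embryos = c(de_t, de_c),
      hatched_larvae = c(ne - de_t, ne - de_c),
      replicate = rep_i,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$strain, df$replicate, df$condition, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}
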