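#' Genotype posteriors on a cM grid for an inbred panel
#'
#' Computes, at every grid position, each line's posterior probability of
#' carrying the CB genotype, conditional on its typed flanking markers, under a
#' two-genotype (inbred-line) model with Haldane no-interference transitions.
#' The allele process along a chromosome is a two-state Markov chain, so the
#' posterior at a position depends only on the nearest typed marker on each
#' side; missing genotypes are marginalized by skipping to the nearest typed
#' marker. At a typed marker the posterior is 0 or 1 as observed; off the ends
#' of the typed markers a single flanking marker is used; lines untyped on a
#' whole chromosome get probability 0.5 everywhere on it.
#'
#' The grid is the union of a regular \code{step_cM} lattice spanning each
#' chromosome and the marker positions themselves.
#'
#' @param panel A \code{genotype_panel} (homozygous genotypes 0/1, NA missing).
#' @param step_cM Grid spacing in cM (default 1).
#' @return Object of class \code{"genotype_prob_grid"}: \code{positions}
#'   (data.frame chr, pos, marker), \code{prob_cb} (lines x positions matrix of
#'   P(CB genotype)), \code{lines}.
#' @examples
#' map <- make_genetic_map(c(I = 10), spacing_cM = 5)
#' panel <- simulate_riail_panel(map, 10, seed = 1)
#' grid <- genotype_probs(panel)
#' @export
genotype_probs <- function(panel, step_cM = 1) {
  stopifnot(inherits(panel, "genotype_panel"), step_cM > 0)
  map <- panel$map
  geno <- panel$geno
  n <- nrow(geno)
  pos_list <- list()
  prob_list <- list()
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    mp <- map$pos[idx]
    grid <- sort(unique(c(seq(mp[1], mp[length(mp)], by = step_cM), mp)))
    G <- length(grid)
    # immediate flanking markers per grid point (left = right at a marker)
    L <- findInterval(grid, mp)
    at_marker <- grid %in% mp
    R <- ifelse(at_marker, L, pmin(L + 1L, length(mp)))
    rL <- haldane_r(grid - mp[L])
    rR <- haldane_r(mp[R] - grid)
    gL <- geno[, idx[L], drop = FALSE]
    gR <- geno[, idx[R], drop = FALSE]
    # P(state = CB | flank): product of the two transition likelihoods
    w1 <- gL * rep(1 - 2 * rL, each = n) + rep(rL, each = n)
    w2 <- gR * rep(1 - 2 * rR, each = n) + rep(rR, each = n)
    pr <- (w1 * w2) / (w1 * w2 + (1 - w1) * (1 - w2))
    # lines with missing genotypes on this chromosome: use nearest typed flanks
    for (i in which(rowSums(is.na(geno[, idx, drop = FALSE])) > 0)) {
      typed <- which(!is.na(geno[i, idx]))
      if (length(typed) == 0) { pr[i, ] <- 0.5; next }
      tp <- mp[typed]
      tg <- geno[i, idx[typed]]
      tl <- findInterval(grid, tp)
      wl <- ifelse(tl >= 1,
                   { r <- haldane_r(abs(grid - tp[pmax(tl, 1L)]))
                     tg[pmax(tl, 1L)] * (1 - 2 * r) + r }, 0.5)
      tr <- tl + ifelse(grid %in% tp, 0L, 1L)
      wr <- ifelse(tr <= length(typed),
                   { j <- pmin(tr, length(typed))
                     r <- haldane_r(abs(tp[j] - grid))
                     tg[j] * (1 - 2 * r) + r }, 0.5)
      pr[i, ] <- (wl * wr) / (wl * wr + (1 - wl) * (1 - wr))
    }
    pos_list[[ch]] <- data.frame(chr = ch, pos = grid,
                                 marker = ifelse(at_marker,
                                                 map$marker[idx][match(grid, mp)],
                                                 NA_character_),
                                 stringsAsFactors = FALSE)
    prob_list[[ch]] <- pr
  }
  positions <- do.call(rbind, pos_list)
  rownames(positions) <- NULL
  structure(list(positions = positions,
                 prob_cb = do.call(cbind, prob_list),
                 lines = rownames(geno)),
            class = "genotype_prob_grid")
}

#' @export
print.genotype_prob_grid <- function(x, ...) {
  cat(sprintf("genotype probability grid: %d lines x %d positions (%d chromosome(s))\n",
              length(x$lines), nrow(x$positions), length(unique(x$positions$chr))))
  invisible(x)
}

# midrank deviations and Kruskal-Wallis tie/scale constants for a phenotype
.np_rank_parts <- function(y) {
  n <- length(y)
  rk <- rank(y)  # midranks
  z <- rk - (n + 1) / 2
  tab <- table(rk)
  tie <- 1 - sum(tab^3 - tab) / (n^3 - n)
  list(z = z, n = n, tie = tie, scale = 12 / (n * (n + 1)))
}

# H statistics for (possibly many) centered rank vectors Z (n x k) against the
# soft two-group weights W (n x G); returns G x k matrix
.np_H <- function(W, Z, parts) {
  n <- parts$n
  n1 <- colSums(W)
  n0 <- n - n1
  S <- crossprod(W, Z)                    # G x k group-1 weighted rank sums
  inv <- ifelse(n1 > 1e-9 & n0 > 1e-9, 1 / n1 + 1 / n0, 0)
  H <- parts$scale * (S^2) * inv
  if (parts$tie <= 0) H[] <- 0 else H <- H / parts$tie
  H
}

.new_scan_result <- function(positions, lod, method) {
  out <- positions
  out$lod <- as.numeric(lod)
  attr(out, "method") <- method
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Nonparametric (extended Kruskal-Wallis) genome scan
#'
#' At each grid position, computes the Kruskal-Wallis rank statistic extended
#' to soft genotype assignments: group membership is weighted by the genotype
#' posterior, ties are midranked with the standard tie correction, and the
#' statistic reduces exactly to the classical two-group Kruskal-Wallis H at
#' fully informative positions. The reported score is lod = H / (2 ln 10), so
#' 2 ln(10) lod is asymptotically chi-square with 1 df under the null.
#'
#' @param grid A \code{genotype_prob_grid}.
#' @param phenotype Numeric vector, one value per line (no NAs).
#' @return A \code{scan_result} data.frame: chr, pos, marker, lod.
#' @examples
#' map <- make_genetic_map(c(I = 20), spacing_cM = 5)
#' panel <- simulate_riail_panel(map, 30, seed = 1)
#' y <- as.numeric(panel$geno[, 3])
#' scan_np(genotype_probs(panel), y)
#' @export
scan_np <- function(grid, phenotype) {
  stopifnot(inherits(grid, "genotype_prob_grid"))
  y <- as.numeric(phenotype)
  if (length(y) != length(grid$lines)) stop("phenotype length must match panel lines")
  if (anyNA(y)) stop("phenotype must not contain NAs")
  parts <- .np_rank_parts(y)
  H <- .np_H(grid$prob_cb, matrix(parts$z, ncol = 1), parts)
  .new_scan_result(grid$positions, H / (2 * log(10)), "np")
}

#' Normal-model (Haley-Knott) genome scan with an optional covariate
#'
#' At each position, regresses the phenotype on the expected genotype dosage
#' (the posterior probability of the CB genotype) plus any covariates, and
#' reports lod = (n/2) log10(RSS_null / RSS_full), where the null model retains
#' the covariates. Positions whose dosage is collinear with the null design
#' (e.g. the covariate is the dosage itself) get lod 0 with a warning.
#'
#' @param grid A \code{genotype_prob_grid}.
#' @param phenotype Numeric vector, one value per line (no NAs).
#' @param covariate Optional numeric vector or matrix of per-line covariates.
#' @return A \code{scan_result} data.frame: chr, pos, marker, lod.
#' @export
scan_normal <- function(grid, phenotype, covariate = NULL) {
  stopifnot(inherits(grid, "genotype_prob_grid"))
  y <- as.numeric(phenotype)
  n <- length(grid$lines)
  if (length(y) != n) stop("phenotype length must match panel lines")
  if (anyNA(y)) stop("phenotype must not contain NAs")
  X0 <- cbind(rep(1, n), covariate)
  if (anyNA(X0) || any(!is.finite(X0))) stop("covariate must be finite")
  Q <- qr(X0)
  ry <- qr.resid(Q, y)
  RX <- qr.resid(Q, grid$prob_cb)
  ssx <- colSums(RX^2)
  rss0 <- sum(ry^2)
  collinear <- ssx < 1e-10 * n
  if (any(collinear) && !is.null(covariate))
    warning(sprintf("%d position(s) collinear with the covariate design; lod set to 0",
                    sum(collinear)))
  if (rss0 < 1e-12) {
    lod <- rep(0, ncol(RX))
  } else {
    sxy <- drop(crossprod(RX, ry))
    rho2 <- ifelse(collinear, 0, sxy^2 / (ssx * rss0))
    rho2 <- pmin(pmax(rho2, 0), 1 - 1e-15)
    lod <- -(n / 2) * log10(1 - rho2)
  }
  .new_scan_result(grid$positions, lod, "normal")
}

#' @export
print.scan_result <- function(x, ...) {
  peak <- x[which.max(x$lod), ]
  cat(sprintf("%s interval-mapping scan: %d positions on %d chromosome(s); peak lod %.3f at %s:%.1f cM\n",
              attr(x, "method"), nrow(x), length(unique(x$chr)),
              peak$lod, peak$chr, peak$pos))
  invisible(x)
}

#' Plot a genome scan
#'
#' Lod score against genomic position, chromosomes laid side by side, with an
#' optional horizontal significance threshold.
#'
#' @param x A \code{scan_result}.
#' @param threshold Optional lod threshold drawn as a dashed line.
#' @param ... Passed to \code{plot}.
#' @export
plot.scan_result <- function(x, threshold = NULL, ...) {
  chrs <- unique(x$chr)
  offs <- c(0, cumsum(vapply(chrs, function(ch) max(x$pos[x$chr == ch]) + 5, 0)))
  names(offs) <- c(chrs, "end")
  xx <- x$pos + offs[x$chr]
  graphics::plot(xx, x$lod, type = "n", xlab = "position (cM)", ylab = "lod",
                 xaxt = "n", ...)
  for (ch in chrs) {
    sel <- x$chr == ch
    graphics::lines(xx[sel], x$lod[sel])
  }
  mids <- vapply(chrs, function(ch) mean(range(xx[x$chr == ch])), 0)
  graphics::axis(1, at = mids, labels = chrs)
  if (!is.null(threshold))
    graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Genome-wide significance threshold by phenotype permutation
#'
#' Permutes phenotype values across lines (keeping the genotype grid intact,
#' so genome structure and marker correlation are preserved), records the
#' genome-wide maximum lod of each permuted scan, and returns the empirical
#' (1 - alpha) quantile as the genome-wide threshold.
#'
#' @param grid A \code{genotype_prob_grid}.
#' @param phenotype Numeric vector, one value per line.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Genome-wide type-I error rate (default 0.05).
#' @param seed Optional integer seed.
#' @param method \code{"np"} (default) or \code{"normal"} — must match the scan
#'   the threshold will be compared against.
#' @param covariate Covariate(s) for the normal-model scan.
#' @return Object of class \code{"permutation_result"}: \code{max_lod}
#'   (per-permutation genome-wide maxima), \code{threshold}, \code{alpha},
#'   \code{n_perm}, \code{method}.
#' @examples
#' map <- make_genetic_map(c(I = 20), spacing_cM = 5)
#' panel <- simulate_riail_panel(map, 30, seed = 1)
#' grid <- genotype_probs(panel)
#' perm <- permutation_threshold(grid, rnorm(30), n_perm = 50, seed = 2)
#' @export
permutation_threshold <- function(grid, phenotype, n_perm = 1000, alpha = 0.05,
                                  seed = NULL, method = c("np", "normal"),
                                  covariate = NULL) {
  stopifnot(inherits(grid, "genotype_prob_grid"), n_perm >= 20)
  method <- match.arg(method)
  y <- as.numeric(phenotype)
  n <- length(y)
  if (n != length(grid$lines)) stop("phenotype length must match panel lines")
  if (!is.null(seed)) set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  if (method == "np") {
    parts <- .np_rank_parts(y)
    Z <- matrix(parts$z[perms], n, n_perm)
    H <- .np_H(grid$prob_cb, Z, parts)
    max_lod <- apply(H, 2, max) / (2 * log(10))
  } else {
    X0 <- cbind(rep(1, n), covariate)
    Q <- qr(X0)
    RX <- qr.resid(Q, grid$prob_cb)
    ssx <- colSums(RX^2)
    ok <- ssx >= 1e-10 * n
    RY <- qr.resid(Q, matrix(y[perms], n, n_perm))
    rssp <- colSums(RY^2)
    sxy <- crossprod(RX, RY)                       # positions x perms
    rho2 <- sxy^2 / outer(ssx, rssp)
    rho2[!ok, ] <- 0
    rho2[, rssp < 1e-12] <- 0
    rho2 <- pmin(pmax(rho2, 0), 1 - 1e-15)
    max_lod <- apply(-(n / 2) * log10(1 - rho2), 2, max)
  }
  structure(list(max_lod = max_lod,
                 threshold = stats::quantile(max_lod, 1 - alpha, names = FALSE),
                 alpha = alpha, n_perm = n_perm, method = method),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("%d %s-scan permutations: %g%% genome-wide threshold lod = %.3f\n",
              x$n_perm, x$method, 100 * (1 - x$alpha), x$threshold))
  invisible(x)
}

#' Threshold at another significance level
#'
#' @param perm A \code{permutation_result}.
#' @param alpha Genome-wide type-I error rate.
#' @return The empirical (1 - alpha) quantile of the permutation maxima.
#' @export
threshold_at <- function(perm, alpha) {
  stopifnot(inherits(perm, "permutation_result"))
  stats::quantile(perm$max_lod, 1 - alpha, names = FALSE)
}

#' Lod-drop support interval around the scan peak
#'
#' Finds the global peak of a scan and returns the smallest contiguous grid
#' interval on the peak chromosome over which the lod stays within \code{drop}
#' units of the peak, extended by one flanking grid point on each side (the
#' conventional 1.5-lod support interval with \code{drop = 1.5}).
#'
#' @param scan A \code{scan_result}.
#' @param drop Lod units below the peak delimiting the interval (default 1.5).
#' @return List with \code{chr}, \code{lo}, \code{hi} (cM), \code{peak_pos},
#'   \code{peak_lod}.
#' @export
lod_support_interval <- function(scan, drop = 1.5) {
  stopifnot(inherits(scan, "scan_result"), drop >= 0)
  if (max(scan$lod) - min(scan$lod) < 1e-12) {
    warning("flat scan: support interval spans the whole peak chromosome")
    ch <- scan$chr[1]
    p <- scan$pos[scan$chr == ch]
    return(list(chr = ch, lo = min(p), hi = max(p),
                peak_pos = p[1], peak_lod = scan$lod[1]))
  }
  peak <- which.max(scan$lod)
  ch <- scan$chr[peak]
  sel <- which(scan$chr == ch)
  lod <- scan$lod[sel]
  pos <- scan$pos[sel]
  k <- match(peak, sel)
  keep <- lod >= scan$lod[peak] - drop
  lo <- k
  while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  hi <- k
  while (hi < length(keep) && keep[hi + 1]) hi <- hi + 1
  lo <- max(lo - 1, 1)          # extend to flanking grid points
  hi <- min(hi + 1, length(keep))
  list(chr = ch, lo = pos[lo], hi = pos[hi],
       peak_pos = pos[k], peak_lod = scan$lod[peak])
}
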