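test_that("genotype posteriors are exact at typed markers and symmetric between", {
  # two lines, concordant N2/N2 and CB/CB; one discordant
  geno <- rbind(c(0L, 0L), c(1L, 1L), c(0L, 1L))
  panel <- toy_panel(geno, data.frame(chr = "I", pos = c(0, 2)))
  grid <- genotype_probs(panel, step_cM = 1)
  expect_equal(grid$positions$pos, c(0, 1, 2))
  # typed markers: posterior 1 for the observed genotype
  expect_equal(unname(grid$prob_cb[, 1]), c(0, 1, 0))
  expect_equal(unname(grid$prob_cb[, 3]), c(0, 1, 1))
  # midpoint: concordant flanks nearly certain, discordant exactly 1/2
  expect_lt(grid$prob_cb[1, 2], 0.01)
  expect_gt(grid$prob_cb[2, 2], 0.99)
  expect_equal(grid$prob_cb[3, 2], 0.5)
})

test_that("grid covers every chromosome at the requested step plus markers", {
  map <- make_genetic_map(c(I = 10, II = 7), spacing_cM = 2.5)
  panel <- simulate_riail_panel(map, 5, seed = 1)
  grid <- genotype_probs(panel, step_cM = 1)
  pos1 <- grid$positions$pos[grid$positions$chr == "I"]
  expect_true(all(seq(0, 10, by = 1) %in% pos1))
  expect_true(all(map$pos[map$chr == "I"] %in% pos1))
  expect_true(all(grid$prob_cb >= 0 & grid$prob_cb <= 1))
})

test_that("missing genotypes are marginalized via the nearest typed flanks", {
  geno <- rbind(c(0L, NA, 0L), c(1L, NA, 0L), c(NA, NA, NA))
  panel <- toy_panel(geno, data.frame(chr = "I", pos = c(0, 5, 10)))
  grid <- genotype_probs(panel, step_cM = 5)
  mid <- which(grid$positions$pos == 5)
  # line 1: concordant distant flanks -> strongly N2 but uncertain
  expect_lt(grid$prob_cb[1, mid], 0.05)
  expect_gt(grid$prob_cb[1, mid], 0)
  # line 2: discordant flanks equidistant -> exactly 1/2
  expect_equal(grid$prob_cb[2, mid], 0.5)
  # line 3: untyped everywhere -> 1/2 everywhere
  expect_true(all(grid$prob_cb[3, ] == 0.5))
  # posteriors at typed markers unaffected by the missing neighbor
  expect_equal(unname(grid$prob_cb[1:2, 1]), c(0, 1))
})

test_that("np scan equals the classical Kruskal-Wallis test at informative markers", {
  # textbook case: two clean groups of three
  panel <- toy_panel(cbind(c(0L, 0L, 0L, 1L, 1L, 1L)),
                     data.frame(chr = "I", pos = 0))
  y <- c(1, 2, 3, 4, 5, 6)
  s <- scan_np(genotype_probs(panel), y)
  expect_equal(2 * log(10) * s$lod[1], 3.857143, tolerance = 1e-6)
  expect_equal(s$lod[1], kw_lod_oracle(y, panel$geno[, 1]))
  # randomized small panels, with ties, against the base-R oracle
  set.seed(99)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    g <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))  # both groups present
    y <- sample(round(rnorm(n), 1))                      # duplicates create ties
    if (length(unique(y)) < 2) next
    panel <- toy_panel(cbind(g), data.frame(chr = "I", pos = 0))
    s <- scan_np(genotype_probs(panel), y)
    expect_equal(s$lod[1], kw_lod_oracle(y, g), tolerance = 1e-10)
  }
})

test_that("np scan is rank-based and handles degenerate phenotypes", {
  map <- make_genetic_map(c(I = 20), spacing_cM = 5)
  panel <- simulate_riail_panel(map, 40, seed = 2)
  y <- rnorm(40)
  grid <- genotype_probs(panel)
  s1 <- scan_np(grid, y)
  s2 <- scan_np(grid, exp(3 * y))   # strictly monotone transform
  expect_equal(s1$lod, s2$lod, tolerance = 1e-12)
  s3 <- scan_np(grid, rep(1, 40))   # constant phenotype: lod 0, not an error
  expect_true(all(s3$lod == 0))
  expect_true(all(s1$lod >= 0) && all(is.finite(s1$lod)))
})

test_that("normal-model scan matches a least-squares oracle at markers", {
  map <- make_genetic_map(c(I = 20), spacing_cM = 5)
  panel <- simulate_riail_panel(map, 60, seed = 3)
  grid <- genotype_probs(panel)
  x <- as.numeric(panel$geno[, 3])
  y <- 2 + 1.5 * x + rnorm(60, sd = 0.3)
  s <- scan_normal(grid, y)
  at <- which(grid$positions$marker %in% map$marker[3])
  rss0 <- sum(resid(lm(y ~ 1))^2)
  rss1 <- sum(resid(lm(y ~ x))^2)
  expect_equal(s$lod[at], (60 / 2) * log10(rss0 / rss1), tolerance = 1e-8)
  # noise-free trait: peak is at the causal marker
  y0 <- 1 + x
  s0 <- scan_normal(grid, y0)
  expect_equal(grid$positions$pos[which.max(s0$lod)], map$pos[3])
})

test_that("covariates are retained under the null and absorb their own signal", {
  map <- make_genetic_map(c(I = 30), spacing_cM = 5)
  panel <- simulate_riail_panel(map, 80, seed = 4)
  grid <- genotype_probs(panel)
  x <- as.numeric(panel$geno[, 4])
  y <- x + rnorm(80, sd = 0.2)
  # constant covariate: identical to the covariate-free scan
  plain <- scan_normal(grid, y)
  const <- scan_normal(grid, y, covariate = rep(2, 80))
  expect_equal(plain$lod, const$lod, tolerance = 1e-9)
  # covariate = causal dosage: signal absorbed, lod ~ 0 at the locus
  expect_warning(adj <- scan_normal(grid, y, covariate = x), "collinear")
  at <- which(grid$positions$marker %in% map$marker[4])
  expect_equal(adj$lod[at], 0)
  expect_lt(max(adj$lod), max(plain$lod) / 5)
})

test_that("permutation thresholds are deterministic and honor alpha extremes", {
  map <- make_genetic_map(c(I = 20, II = 20), spacing_cM = 5)
  panel <- simulate_riail_panel(map, 40, seed = 5)
  grid <- genotype_probs(panel)
  y <- rnorm(40)
  p1 <- permutation_threshold(grid, y, n_perm = 50, seed = 10)
  p2 <- permutation_threshold(grid, y, n_perm = 50, seed = 10)
  expect_identical(p1$max_lod, p2$max_lod)
  expect_equal(p1$threshold, stats::quantile(p1$max_lod, 0.95, names = FALSE))
  expect_equal(threshold_at(p1, 1), min(p1$max_lod))
  # constant phenotype: every permuted scan is flat
  p0 <- permutation_threshold(grid, rep(3, 40), n_perm = 20, seed = 11)
  expect_true(all(p0$max_lod == 0))
  # normal-model permutations run through the same machinery
  pn <- permutation_threshold(grid, y, n_perm = 30, seed = 12, method = "normal")
  expect_true(all(pn$max_lod >= 0))
})

test_that("lod support intervals cover the drop region plus flanking points", {
  # steep single-point peak: the three grid points around the peak
  s <- toy_scan("I", 0:10, c(0, 0, 0, 0, 0.2, 5, 0.2, 0, 0, 0, 0))
  si <- lod_support_interval(s, drop = 1.5)
  expect_equal(c(si$lo, si$hi), c(4, 6))
  expect_equal(si$peak_pos, 5)
  # plateau at peak level is covered
  s2 <- toy_scan("I", 0:10, c(0, 0, 4.9, 5, 5, 5, 4.9, 0, 0, 0, 0))
  si2 <- lod_support_interval(s2, drop = 1.5)
  expect_lte(si2$lo, 2)
  expect_gte(si2$hi, 6)
  # flat scan: whole chromosome with a warning
  s3 <- toy_scan("I", 0:10, rep(1, 11))
  expect_warning(si3 <- lod_support_interval(s3), "flat scan")
  expect_equal(c(si3$lo, si3$hi), c(0, 10))
  # peak chromosome is selected among several
  s4 <- toy_scan(rep(c("I", "II"), each = 5), rep(0:4, 2),
                 c(1, 1, 1, 1, 1, 0, 1, 6, 1, 0))
  si4 <- lod_support_interval(s4)
  expect_equal(si4$chr, "II")
})

test_that("scan recovers a simulated major-effect locus", {
  map <- make_genetic_map()
  panel <- simulate_riail_panel(map, 200, seed = 21)
  arch <- arch_preset("ppw1_only", map)
  plates <- simulate_phenotypes(panel, arch, seed = 22, replicates = 2)
  tab <- induced_lethality_table(plates)
  y <- tab$mean_induced_lethality[match(rownames(panel$geno), tab$strain)]
  grid <- genotype_probs(panel)
  s <- scan_np(grid, y)
  peak <- s[which.max(s$lod), ]
  causal <- arch$loci[arch$loci$name == "ppw1", ]
  expect_equal(peak$chr, causal$chr)
  expect_lt(abs(peak$pos - causal$pos), 5)
  si <- lod_support_interval(s)
  expect_equal(si$chr, causal$chr)
  expect_true(si$lo <= causal$pos && causal$pos <= si$hi)
})
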