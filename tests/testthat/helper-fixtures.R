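# shared fixtures built in code

# a fully informative toy panel: genotypes given explicitly at typed markers
toy_panel <- function(geno, chr_pos = NULL) {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  if (is.null(chr_pos))
    chr_pos <- data.frame(chr = "I", pos = seq(0, by = 10, length.out = m))
  map <- as_genetic_map(data.frame(marker = sprintf("m%d", seq_len(m)),
                                   chr = chr_pos$chr, pos = chr_pos$pos))
  colnames(geno) <- map$marker
  genotype_panel(geno, map)
}

# hand-built scan result for interval tests
toy_scan <- function(chr, pos, lod) {
  out <- data.frame(chr = chr, pos = pos, marker = NA_character_, lod = lod,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "np"
  class(out) <- c("scan_result", "data.frame")
  out
}

# plate-count data.frame for one strain/replicate pair
toy_plates <- function(strain, de_t, hl_t, de_c, hl_c, replicate = 1) {
  data.frame(strain = strain, condition = c("treated", "control"),
             dead_embryos = c(de_t, de_c), hatched_larvae = c(hl_t, hl_c),
             replicate = replicate, stringsAsFactors = FALSE)
}

# classical two-group Kruskal-Wallis lod at a fully informative marker,
# via the independent base-R implementation
kw_lod_oracle <- function(y, grp) {
  H <- unname(stats::kruskal.test(y, factor(grp))$statistic)
  H / (2 * log(10))
}
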