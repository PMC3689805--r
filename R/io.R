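#' Write a genotype panel in the cross CSV dialect
#'
#' The cross CSV dialect is three header rows followed by one row per line:
#' row 1 holds the phenotype column name then the marker names, row 2 a blank
#' then each marker's chromosome, row 3 a blank then each marker's cM position;
#' data rows hold the phenotype value then allele codes. Alleles are coded
#' \code{A} = N2, \code{B} = CB, \code{-} = missing.
#'
#' @param panel A \code{genotype_panel}.
#' @param path Output file path.
#' @param phenotype Optional numeric vector (one value per line); blank if
#'   omitted.
#' @param pheno_name Phenotype column name (default \code{"pheno"}).
#' @return \code{path}, invisibly.
#' @export
write_cross_csv <- function(panel, path, phenotype = NULL, pheno_name = "pheno") {
  stopifnot(inherits(panel, "genotype_panel"))
  map <- panel$map
  n <- nrow(panel$geno)
  if (!is.null(phenotype) && length(phenotype) != n)
    stop("phenotype length must match panel lines")
  ph <- if (is.null(phenotype)) rep("", n) else
    ifelse(is.na(phenotype), "", format(phenotype, digits = 17, trim = TRUE,
                                        scientific = FALSE))
  code <- matrix("-", n, ncol(panel$geno))
  code[panel$geno == 0L] <- "A"
  code[panel$geno == 1L] <- "B"
  lines <- c(paste(c(pheno_name, map$marker), collapse = ","),
             paste(c("", map$chr), collapse = ","),
             paste(c("", format(map$pos, digits = 15, trim = TRUE,
                                scientific = FALSE)), collapse = ","),
             apply(cbind(ph, code), 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cross CSV file
#'
#' Parses the dialect written by \code{\link{write_cross_csv}} and validates it:
#' consistent row widths, numeric strictly increasing positions within each
#' chromosome, and allele codes in \code{A}/\code{B}/\code{-}. Parse failures
#' report the offending line number.
#'
#' @param path Input file path.
#' @return List with \code{panel} (a \code{genotype_panel}), \code{map} (its
#'   \code{genetic_map}), \code{phenotype} (numeric, NA where blank) and
#'   \code{pheno_name}.
#' @export
read_cross_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) < 4)
    stop("cross CSV needs three header rows and at least one individual")
  cells <- strsplit(raw, ",", fixed = TRUE)
  width <- length(cells[[1]])
  ragged <- which(vapply(cells, length, 0L) != width)
  if (length(ragged))
    stop(sprintf("ragged row: line %d has %d fields, expected %d",
                 ragged[1], length(cells[[ragged[1]]]), width))
  if (width < 2) stop("line 1: no marker columns")
  markers <- cells[[1]][-1]
  chr <- cells[[2]][-1]
  pos <- suppressWarnings(as.numeric(cells[[3]][-1]))
  if (anyNA(pos)) stop("line 3: non-numeric cM position")
  map <- tryCatch(as_genetic_map(data.frame(marker = markers, chr = chr, pos = pos,
                                            stringsAsFactors = FALSE)),
                  error = function(e) stop(sprintf("line 3: %s", conditionMessage(e))))
  body <- cells[-(1:3)]
  ph_raw <- vapply(body, `[[`, "", 1L)
  phenotype <- suppressWarnings(as.numeric(ph_raw))
  bad_ph <- which(!is.na(ph_raw) & nzchar(ph_raw) & is.na(phenotype))
  if (length(bad_ph))
    stop(sprintf("line %d: non-numeric phenotype value '%s'",
                 bad_ph[1] + 3L, ph_raw[bad_ph[1]]))
  code <- matrix(unlist(lapply(body, function(x) x[-1])),
                 nrow = length(body), byrow = TRUE)
  bad <- which(matrix(!(code %in% c("A", "B", "-")), nrow(code)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("line %d: unknown allele code '%s' (expected A, B or -)",
                 bad[1, 1] + 3L, code[bad[1, 1], bad[1, 2]]))
  geno <- matrix(NA_integer_, nrow(code), ncol(code),
                 dimnames = list(sprintf("L%03d", seq_len(nrow(code))), markers))
  geno[code == "A"] <- 0L
  geno[code == "B"] <- 1L
  panel <- genotype_panel(geno, map)
  list(panel = panel, map = map, phenotype = phenotype,
       pheno_name = cells[[1]][1])
}

#' Read a plate-count CSV
#'
#' Expects columns \code{strain}, \code{condition} (\code{treated} or
#' \code{control}), \code{dead_embryos}, \code{hatched_larvae},
#' \code{replicate}.
#'
#' @param path Input file path.
#' @return data.frame of plate counts.
#' @export
read_plate_counts <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "condition", "dead_embryos", "hatched_larvae", "replicate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("plate-count CSV missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  bad <- setdiff(unique(df$condition), c("treated", "control"))
  if (length(bad))
    stop(sprintf("unknown condition '%s' (expected treated/control)", bad[1]))
  if (any(df$dead_embryos < 0) || any(df$hatched_larvae < 0))
    stop("counts must be non-negative")
  df
}

#' Induced lethality per strain from plate counts
#'
#' Pairs each strain/replicate's treated plate with its empty-vector control
#' plate, computes the background-corrected induced lethality per pair, and
#' averages pairs within a strain (replicate plate pairs are averaged, not
#' pooled as counts).
#'
#' @param plates A plate-count data.frame (see \code{\link{read_plate_counts}}).
#' @param per \code{"strain"} (default) for per-strain means or \code{"pair"}
#'   for one row per replicate pair.
#' @return data.frame: for \code{per = "strain"}, columns \code{strain},
#'   \code{mean_induced_lethality}, \code{n}; for \code{per = "pair"}, columns
#'   \code{strain}, \code{replicate}, \code{induced_lethality}.
#' @export
induced_lethality_table <- function(plates, per = c("strain", "pair")) {
  per <- match.arg(per)
  key <- interaction(plates$strain, plates$replicate, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(plates)), key), function(ix) {
    sub <- plates[ix, ]
    tr <- sub[sub$condition == "treated", ]
    ct <- sub[sub$condition == "control", ]
    if (nrow(tr) != 1L || nrow(ct) != 1L)
      stop(sprintf("strain %s replicate %s: need exactly one treated and one control plate",
                   sub$strain[1], sub$replicate[1]))
    il <- induced_lethality(assay_pair(
      plate_counts(tr$dead_embryos, tr$hatched_larvae),
      plate_counts(ct$dead_embryos, ct$hatched_larvae)))
    data.frame(strain = sub$strain[1], replicate = sub$replicate[1],
               induced_lethality = il, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  if (per == "pair") return(pairs[order(pairs$strain, pairs$replicate), ])
  agg <- stats::aggregate(induced_lethality ~ strain, pairs, mean)
  cnt <- stats::aggregate(induced_lethality ~ strain, pairs, length)
  out <- data.frame(strain = agg$strain,
                    mean_induced_lethality = agg$induced_lethality,
                    n = cnt$induced_lethality, stringsAsFactors = FALSE)
  out[order(out$strain), ]
}

#' Write a scan result as CSV
#'
#' @param scan A \code{scan_result}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "scan_result"))
  utils::write.csv(data.frame(chr = scan$chr, pos_cM = scan$pos, lod = scan$lod),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled table of intermediate-lethality inbred lines
#'
#' Loads the packaged table of the 18 recombinant inbred lines with induced
#' lethality strictly between 0 and 1: strain, mean induced lethality over two
#' replicate assays, and the genotypes of the markers flanking the major
#' insensitivity locus.
#'
#' @return data.frame with columns \code{strain},
#'   \code{mean_induced_lethality}, \code{marker_5prime}, \code{marker_3prime}.
#' @export
riail_intermediate_table <- function() {
  path <- system.file("extdata", "riail_intermediate_lethality.csv",
                      package = "rnaimap", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
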