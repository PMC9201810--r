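#' Packaged chromosome reference table
#'
#' Autosome lengths and centromere intervals (hg19-derived; centromere
#' intervals are approximate acen bounds). Coordinates are 0-based half-open.
#' An alternate assembly can be supplied as a TSV with columns
#' `chrom, length, cen_start, cen_end` (and optionally `is_acrocentric`;
#' when absent, chromosomes 13, 14, 15, 21, 22 are flagged).
#'
#' @param path optional TSV path overriding the packaged table.
#' @return data.frame with columns `chrom`, `length`, `cen_start`, `cen_end`,
#'   `is_acrocentric`, one row per autosome.
#' @export
#' @examples
#' chrom_table()[1:3, ]
chrom_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chromosomes_hg19.tsv", package = "quadseg")
  }
  tab <- read.delim(path, colClasses = c(chrom = "character"))
  need <- c("chrom", "length", "cen_start", "cen_end")
  if (!all(need %in% names(tab))) {
    stop("chromosome table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(tab$is_acrocentric)) {
    tab$is_acrocentric <- tab$chrom %in% ACROCENTRIC
  }
  bad <- !(tab$cen_start > 0 & tab$cen_start < tab$cen_end &
             tab$cen_end < tab$length)
  if (any(bad)) {
    stop("invalid centromere interval for chromosome(s): ",
         paste(tab$chrom[bad], collapse = ", "))
  }
  tab
}

#' Packaged cytoband map (synthetic)
#'
#' An ISCN-like band map used to turn band labels (e.g. "q21") into genomic
#' coordinates. The packaged map is synthetic: arms are divided into
#' centromere-outward regions and bands at a plausible genomic scale with
#' ISCN-style labels, because the pipeline only needs band-level coordinates
#' as a starting point — segment lengths are subsequently refined from the
#' CNV boundaries of unbalanced embryos (see [estimate_breakpoints()]). A
#' real assembly-specific cytoband TSV (`chrom, start, end, band`, 0-based
#' half-open) can be supplied instead.
#'
#' @param path optional TSV path overriding the packaged map.
#' @return data.frame with columns `chrom`, `start`, `end`, `band`.
#' @export
band_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cytobands_synthetic.tsv", package = "quadseg")
  }
  tab <- read.delim(path, colClasses = c(chrom = "character"))
  need <- c("chrom", "start", "end", "band")
  if (!all(need %in% names(tab))) {
    stop("band table must have columns: ", paste(need, collapse = ", "))
  }
  tab
}

chrom_record <- function(chrom, chrom_tab) {
  i <- match(as.character(chrom), chrom_tab$chrom)
  if (is.na(i)) {
    stop("chromosome '", chrom, "' not in reference table", call. = FALSE)
  }
  chrom_tab[i, ]
}

# arm span as 0-based half-open [start, end)
arm_interval <- function(rec, arm) {
  if (arm == "p") c(0, rec$cen_start) else c(rec$cen_end, rec$length)
}
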