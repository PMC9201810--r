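#' Construct a breakpoint
#'
#' A breakpoint is a position on one arm of an autosome, strictly inside the
#' arm: not at the telomere or chromosome end and not within the centromere
#' interval. Acrocentric p-arm breakpoints are accepted but flagged with a
#' warning, since near-Robertsonian events sit outside the usual reciprocal
#' translocation study population.
#'
#' @param chrom autosome label ("1".."22").
#' @param arm "p" or "q".
#' @param position_bp 0-based position in bp.
#' @param chrom_tab reference table from [chrom_table()].
#' @param band_label optional ISCN band text the position was resolved from.
#' @return object of class `breakpoint`.
#' @export
breakpoint <- function(chrom, arm, position_bp, chrom_tab = chrom_table(),
                       band_label = NULL) {
  chrom <- as.character(chrom)
  if (!chrom %in% as.character(1:22)) {
    stop("breakpoint chromosome must be an autosome (1-22), got '", chrom, "'")
  }
  if (!arm %in% c("p", "q")) stop("arm must be 'p' or 'q', got '", arm, "'")
  rec <- chrom_record(chrom, chrom_tab)
  iv <- arm_interval(rec, arm)
  if (!(position_bp > iv[1] && position_bp < iv[2])) {
    stop(sprintf(
      "breakpoint %s%s:%d lies outside the %s arm (%d-%d exclusive)",
      chrom, arm, position_bp, arm, iv[1], iv[2]))
  }
  if (arm == "p" && rec$is_acrocentric) {
    warning("breakpoint on the p arm of acrocentric chromosome ", chrom,
            "; near-Robertsonian events are atypical for reciprocal ",
            "translocation cohorts", call. = FALSE)
  }
  structure(list(chromosome = chrom, arm = arm,
                 position_bp = as.numeric(position_bp),
                 band_label = band_label),
            class = "breakpoint")
}

#' Construct a reciprocal translocation
#'
#' The study unit: a carrier with one breakpoint on each of two distinct
#' autosomes.
#'
#' @param bp1,bp2 [breakpoint()] objects on distinct autosomes.
#' @param carrier_id carrier identifier.
#' @param carrier_sex "female" or "male" (or NA).
#' @param carrier_age optional age in years.
#' @return object of class `reciprocal_translocation`.
#' @export
reciprocal_translocation <- function(bp1, bp2, carrier_id = NA_character_,
                                     carrier_sex = NA_character_,
                                     carrier_age = NA_real_) {
  stopifnot(inherits(bp1, "breakpoint"), inherits(bp2, "breakpoint"))
  if (bp1$chromosome == bp2$chromosome) {
    stop("the two breakpoints must lie on distinct autosomes (both on chr",
         bp1$chromosome, ")")
  }
  if (!is.na(carrier_sex) && !carrier_sex %in% c("female", "male")) {
    stop("carrier_sex must be 'female' or 'male'")
  }
  structure(list(carrier_id = carrier_id, carrier_sex = carrier_sex,
                 carrier_age = carrier_age, bp1 = bp1, bp2 = bp2),
            class = "reciprocal_translocation")
}

#' @export
print.reciprocal_translocation <- function(x, ...) {
  lab <- function(bp) bp$band_label %||%
    paste0(bp$arm, ":", format(bp$position_bp, big.mark = ","))
  cat(sprintf("t(%s;%s)(%s;%s) carrier=%s sex=%s\n",
              x$bp1$chromosome, x$bp2$chromosome, lab(x$bp1), lab(x$bp2),
              x$carrier_id, x$carrier_sex))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve an ISCN band label to a genomic position
#'
#' Returns the midpoint of the band's interval. Sub-band queries (e.g.
#' "q21.3") fall back to their parent band ("q21") with a warning when the
#' sub-band is not mapped; the fallback is tried progressively ("q21.31" ->
#' "q21.3" -> "q21"). A midpoint is the unbiased choice absent sub-band
#' precision; `at` selects the band start or end instead.
#'
#' @param chrom autosome label.
#' @param band_label ISCN band text including the arm letter, e.g. "q21".
#' @param band_tab band map from [band_table()].
#' @param at "midpoint" (default), "start" or "end".
#' @return position in bp (0-based).
#' @export
resolve_band_position <- function(chrom, band_label, band_tab = band_table(),
                                  at = c("midpoint", "start", "end")) {
  at <- match.arg(at)
  chrom <- as.character(chrom)
  have <- band_tab[band_tab$chrom == chrom, ]
  if (nrow(have) == 0) stop("no bands mapped for chromosome '", chrom, "'")
  query <- band_label
  repeat {
    i <- match(query, have$band)
    if (!is.na(i)) {
      if (query != band_label) {
        warning(sprintf("band %s%s not mapped; using parent band %s%s",
                        chrom, band_label, chrom, query), call. = FALSE)
      }
      return(switch(at,
                    midpoint = floor((have$start[i] + have$end[i]) / 2),
                    start = have$start[i],
                    end = have$end[i]))
    }
    # strip one trailing sub-band character (digits after, then the dot)
    parent <- sub("\\.?[0-9]$", "", query)
    if (parent == query || !grepl("[0-9]", parent)) break
    query <- sub("\\.$", "", parent)
  }
  arm <- substr(band_label, 1, 1)
  near <- have$band[substr(have$band, 1, 1) == arm]
  stop(sprintf("band %s%s not found in band table; known %s-arm bands: %s",
               chrom, band_label, arm, paste(near, collapse = ", ")),
       call. = FALSE)
}

# grammar: 46,XX|XY (optional), one t(a;b)(armband;armband) token
ISCN_RE <- paste0(
  "^\\s*(?:(4[5-7]),)?\\s*(?:(X[XY]),)?\\s*",
  "t\\(([0-9XY]{1,2});([0-9XY]{1,2})\\)",
  "\\(([pq][0-9.]+);([pq][0-9.]+)\\)\\s*$")

#' Parse an ISCN reciprocal-translocation karyotype
#'
#' Accepts karyotype strings such as `"46,XX,t(2;5)(q21;q13)"` containing
#' exactly one two-autosome translocation token, resolves each band label to
#' the midpoint of its interval in `band_tab`, and extracts carrier sex from
#' the `46,XX` / `46,XY` prefix when present.
#'
#' @param text ISCN karyotype string.
#' @param band_tab band map from [band_table()].
#' @param chrom_tab reference table from [chrom_table()].
#' @param carrier_id,carrier_age carried through to the result.
#' @param carrier_sex used when the karyotype has no sex-chromosome prefix.
#' @return a [reciprocal_translocation()].
#' @export
#' @examples
#' tr <- parse_iscn_karyotype("46,XY,t(4;20)(q31;p12)")
#' tr$bp1$chromosome; tr$bp2$arm
parse_iscn_karyotype <- function(text, band_tab = band_table(),
                                 chrom_tab = chrom_table(),
                                 carrier_id = NA_character_,
                                 carrier_sex = NA_character_,
                                 carrier_age = NA_real_) {
  m <- regmatches(text, regexec(ISCN_RE, text))[[1]]
  if (length(m) == 0) {
    # name the offending fragment: the part that first fails the grammar
    frag <- regmatches(text, regexpr("t\\([^)]*\\)(\\([^)]*\\))?", text))
    stop("cannot parse karyotype '", text, "'",
         if (length(frag)) paste0(": malformed translocation token '", frag, "'")
         else ": no t(a;b)(band;band) token found",
         call. = FALSE)
  }
  chr_a <- m[4]; chr_b <- m[5]
  if (chr_a %in% c("X", "Y") || chr_b %in% c("X", "Y")) {
    stop("unsupported karyotype '", text,
         "': sex-chromosome translocations are out of scope", call. = FALSE)
  }
  if (chr_a == chr_b) {
    stop("unsupported karyotype '", text,
         "': both breakpoints on one chromosome", call. = FALSE)
  }
  sex <- if (nzchar(m[3]) && !is.na(m[3]) && m[3] %in% c("XX", "XY")) {
    if (m[3] == "XX") "female" else "male"
  } else carrier_sex
  mk_bp <- function(chrom, band) {
    arm <- substr(band, 1, 1)
    pos <- resolve_band_position(chrom, band, band_tab)
    breakpoint(chrom, arm, pos, chrom_tab, band_label = band)
  }
  reciprocal_translocation(mk_bp(chr_a, m[6]), mk_bp(chr_b, m[7]),
                           carrier_id = carrier_id, carrier_sex = sex,
                           carrier_age = carrier_age)
}

#' Format a translocation back to ISCN
#'
#' Inverse of [parse_iscn_karyotype()] on the supported grammar (band labels
#' must be attached to the breakpoints).
#'
#' @param tr a [reciprocal_translocation()].
#' @return ISCN karyotype string.
#' @export
format_iscn <- function(tr) {
  stopifnot(inherits(tr, "reciprocal_translocation"))
  if (is.null(tr$bp1$band_label) || is.null(tr$bp2$band_label)) {
    stop("breakpoints carry no band labels; cannot format to ISCN")
  }
  prefix <- if (is.na(tr$carrier_sex)) "46," else
    if (tr$carrier_sex == "female") "46,XX," else "46,XY,"
  sprintf("%st(%s;%s)(%s;%s)", prefix, tr$bp1$chromosome, tr$bp2$chromosome,
          tr$bp1$band_label, tr$bp2$band_label)
}

#' Quadrivalent geometry covariates
#'
#' For each involved chromosome the breakpoint splits it into the
#' translocated segment (TS, breakpoint to the telomere of the breakpoint
#' arm) and the centric segment (CS, the remainder, containing the
#' centromere), so TS + CS equals the chromosome length. Derived ratios:
#' TSR = longest/shortest TS, CSR = longest/shortest CS, and TAR = TS over
#' the length of its chromosome arm. Index 1 refers to the longer of the two
#' chromosomes (so TAR1 is the translocated-segment/arm ratio on the longer
#' chromosome); the per-chromosome breakdown is also returned so either
#' ordering can be read off.
#'
#' @param tr a [reciprocal_translocation()].
#' @param chrom_tab reference table from [chrom_table()].
#' @return object of class `quadrivalent_metrics`: a list with `size1`,
#'   `size2`, `ts1`, `ts2`, `cs1`, `cs2`, `tsr`, `csr`, `tar1`, `tar2`,
#'   `acr_involved`, and `per_chromosome` (data.frame keyed by physical
#'   chromosome, independent of input order).
#' @export
#' @examples
#' tr <- parse_iscn_karyotype("46,XX,t(2;5)(q21;q13)")
#' m <- compute_metrics(tr)
#' c(m$tar1, m$tsr, m$acr_involved)
compute_metrics <- function(tr, chrom_tab = chrom_table()) {
  stopifnot(inherits(tr, "reciprocal_translocation"))
  one <- function(bp) {
    rec <- chrom_record(bp$chromosome, chrom_tab)
    iv <- arm_interval(rec, bp$arm)
    if (!(bp$position_bp > iv[1] && bp$position_bp < iv[2])) {
      stop(sprintf("breakpoint %s%s:%s outside its arm", bp$chromosome,
                   bp$arm, format(bp$position_bp)))
    }
    ts <- if (bp$arm == "q") rec$length - bp$position_bp else bp$position_bp
    data.frame(chrom = bp$chromosome, arm = bp$arm,
               position_bp = bp$position_bp, size = rec$length,
               ts = ts, cs = rec$length - ts, arm_length = iv[2] - iv[1],
               tar = ts / (iv[2] - iv[1]),
               is_acrocentric = rec$is_acrocentric)
  }
  per <- rbind(one(tr$bp1), one(tr$bp2))
  # canonical: index 1 = the longer chromosome; ties broken by label
  ord <- order(-per$size, as.integer(per$chrom))
  per <- per[ord, ]
  structure(list(
    size1 = per$size[1], size2 = per$size[2],
    ts1 = per$ts[1], ts2 = per$ts[2],
    cs1 = per$cs[1], cs2 = per$cs[2],
    tsr = max(per$ts) / min(per$ts),
    csr = max(per$cs) / min(per$cs),
    tar1 = per$tar[1], tar2 = per$tar[2],
    acr_involved = any(per$is_acrocentric),
    per_chromosome = per), class = "quadrivalent_metrics")
}

#' @export
print.quadrivalent_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "quadrivalent metrics (index 1 = longer chromosome)\n",
    "  size1/size2: %.1f / %.1f Mb  ts1/ts2: %.1f / %.1f Mb\n",
    "  cs1/cs2: %.1f / %.1f Mb  tsr %.3f  csr %.3f\n",
    "  tar1 %.3f  tar2 %.3f  Acr-ch involved: %s\n"),
    x$size1 / 1e6, x$size2 / 1e6, x$ts1 / 1e6, x$ts2 / 1e6,
    x$cs1 / 1e6, x$cs2 / 1e6, x$tsr, x$csr, x$tar1, x$tar2, x$acr_involved))
  invisible(x)
}
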