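#' Construct a per-embryo CNV profile
#'
#' Wraps an embryo's copy-number segment calls. Calls use 0-based half-open
#' intervals and integer copy numbers; an empty call set is the
#' euploid/balanced profile. Calls with copy number outside 0..4 or shorter
#' than the platform detection floor (1 Mb) are dropped with a warning.
#' Overlapping calls on one chromosome are an input error.
#'
#' @param embryo_id,carrier_id identifiers.
#' @param calls data.frame with columns `chrom`, `start`, `end`,
#'   `copy_number` (may have zero rows).
#' @param min_size_bp platform detection floor; smaller calls are dropped.
#' @return object of class `embryo_cnv_profile`.
#' @export
embryo_profile <- function(embryo_id, carrier_id = NA_character_,
                           calls = NULL, min_size_bp = 1e6) {
  if (is.null(calls)) {
    calls <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), copy_number = integer())
  }
  calls$chrom <- as.character(calls$chrom)
  if (nrow(calls)) {
    if (any(calls$end <= calls$start)) {
      stop("embryo ", embryo_id, ": CNV call with end <= start")
    }
    drop <- calls$copy_number < 0 | calls$copy_number > 4 |
      (calls$end - calls$start) < min_size_bp
    if (any(drop)) {
      warning(sprintf(
        "embryo %s: dropped %d call(s) below the %.0f Mb floor or with copy number outside 0..4",
        embryo_id, sum(drop), min_size_bp / 1e6), call. = FALSE)
      calls <- calls[!drop, , drop = FALSE]
    }
    o <- order(calls$chrom, calls$start)
    calls <- calls[o, , drop = FALSE]
    same <- calls$chrom[-1] == calls$chrom[-nrow(calls)]
    if (nrow(calls) > 1 &&
        any(same & calls$start[-1] < calls$end[-nrow(calls)])) {
      stop("embryo ", embryo_id, ": overlapping CNV calls on chromosome ",
           calls$chrom[c(same & calls$start[-1] < calls$end[-nrow(calls)],
                         FALSE)][1])
    }
  }
  structure(list(embryo_id = embryo_id, carrier_id = carrier_id,
                 calls = calls), class = "embryo_cnv_profile")
}

near <- function(x, y, tol) abs(x - y) <= tol

# the dosage-vector -> (mode, balanced) lookup is the same for every
# translocation; built once per session
.sig_lookup_cache <- new.env(parent = emptyenv())
signature_lookup <- function() {
  hit <- .sig_lookup_cache$lookup
  if (!is.null(hit)) return(hit)
  classes <- enumerate_gamete_classes(include_recombinants = FALSE)
  lookup <- list()
  for (i in seq_len(nrow(classes))) {
    sig <- embryo_signature(classes[i, ])
    key <- paste(sig$dosage, collapse = ",")
    if (is.null(lookup[[key]])) {
      lookup[[key]] <- list(mode = sig$mode, balanced = sig$balanced)
    }
  }
  .sig_lookup_cache$lookup <- lookup
  lookup
}

# precomputed per-carrier matching context: segment intervals, involved
# chromosome lengths and breakpoint positions, and the signature lookup
carrier_context <- function(tr, chrom_tab = chrom_table(), tol_bp = 5e6) {
  segs <- segment_intervals(tr, chrom_tab)
  list(segs = segs, lookup = signature_lookup(), tol_bp = tol_bp,
       involved = c(a = tr$bp1$chromosome, b = tr$bp2$chromosome),
       bp_pos = c(a = tr$bp1$position_bp, b = tr$bp2$position_bp),
       len = c(a = chrom_record(tr$bp1$chromosome, chrom_tab)$length,
               b = chrom_record(tr$bp2$chromosome, chrom_tab)$length),
       all_len = setNames(chrom_tab$length, chrom_tab$chrom))
}

# core matcher on plain vectors; returns dosage, residual flags and matched
# boundary observations
dosage_impl <- function(chrom, start, end, cn, ctx) {
  tol <- ctx$tol_bp
  dosage <- c(cs_a = 2, ts_a = 2, cs_b = 2, ts_b = 2)
  n <- length(chrom)
  res_idx <- integer(); res_whole <- logical()
  m_seg <- character(); m_bound <- numeric(); m_dev <- numeric()
  for (i in seq_len(n)) {
    len_i <- ctx$all_len[[chrom[i]]] %||% NA_real_
    whole <- !is.na(len_i) && near(start[i], 0, tol) && near(end[i], len_i, tol)
    side <- if (chrom[i] == ctx$involved[["a"]]) "a"
            else if (chrom[i] == ctx$involved[["b"]]) "b" else NA
    if (is.na(side)) {
      res_idx <- c(res_idx, i); res_whole <- c(res_whole, whole)
      next
    }
    cs <- ctx$segs[[paste0("cs_", side)]]
    ts <- ctx$segs[[paste0("ts_", side)]]
    delta <- cn[i] - 2
    # candidate interpretations within tolerance; when the translocated
    # segment is shorter than tol a cs call also passes the whole-chromosome
    # test, so pick the smallest total boundary deviation
    cand_name <- character(); cand_dev <- numeric()
    if (whole) {
      cand_name <- "whole"; cand_dev <- start[i] + abs(end[i] - len_i)
    }
    for (seg_name in c("cs", "ts")) {
      seg <- if (seg_name == "cs") cs else ts
      if (near(start[i], seg$start, tol) && near(end[i], seg$end, tol)) {
        cand_name <- c(cand_name, seg_name)
        cand_dev <- c(cand_dev,
                      abs(start[i] - seg$start) + abs(end[i] - seg$end))
      }
    }
    if (!length(cand_name)) {
      res_idx <- c(res_idx, i); res_whole <- c(res_whole, FALSE)
      next
    }
    best <- cand_name[which.min(cand_dev)]
    if (best == "whole") {
      k <- paste0(c("cs_", "ts_"), side)
      dosage[k] <- dosage[k] + delta
      m_seg <- c(m_seg, paste0("whole_", side))
      m_bound <- c(m_bound, NA_real_); m_dev <- c(m_dev, NA_real_)
    } else {
      seg <- if (best == "cs") cs else ts
      # the breakpoint-side boundary is the one at the breakpoint; the
      # other sits at the chromosome end / telomere
      boundary <- if (near(seg$start, ctx$bp_pos[[side]], tol))
        start[i] else end[i]
      k <- paste0(best, "_", side)
      dosage[k] <- dosage[k] + delta
      m_seg <- c(m_seg, k)
      m_bound <- c(m_bound, boundary)
      m_dev <- c(m_dev, abs(boundary - ctx$bp_pos[[side]]))
    }
  }
  list(dosage = dosage, res_idx = res_idx, res_whole = res_whole,
       m_seg = m_seg, m_bound = m_bound, m_dev = m_dev)
}

#' Convert a CNV profile to a quadrivalent segment-dosage vector
#'
#' Each call whose boundaries match one quadrivalent segment (or a whole
#' involved chromosome, i.e. both segments) within `tol_bp` contributes its
#' copy-number deviation from 2 to the matching segment dosage(s); segments
#' with no call keep dosage 2. Calls matching nothing are returned as
#' residuals, split into whole-chromosome and partial events.
#'
#' @param p an [embryo_profile()].
#' @param tr a [reciprocal_translocation()].
#' @param chrom_tab reference table from [chrom_table()].
#' @param tol_bp boundary-matching tolerance in bp (default 5 Mb: the
#'   platform's 1-4 Mb resolution plus band-midpoint uncertainty).
#' @return list with `dosage` (named vector over cs_a, ts_a, cs_b, ts_b),
#'   `residuals` (data.frame of unmatched calls with a `whole_chromosome`
#'   flag), and `matched` (data.frame of matched calls with the observed
#'   breakpoint-side boundary and its deviation in bp).
#' @export
profile_to_dosage <- function(p, tr, chrom_tab = chrom_table(),
                              tol_bp = 5e6) {
  stopifnot(inherits(p, "embryo_cnv_profile"),
            inherits(tr, "reciprocal_translocation"))
  ctx <- carrier_context(tr, chrom_tab, tol_bp)
  d <- dosage_impl(p$calls$chrom, p$calls$start, p$calls$end,
                   p$calls$copy_number, ctx)
  list(dosage = d$dosage,
       residuals = cbind(p$calls[d$res_idx, , drop = FALSE],
                         whole_chromosome = d$res_whole),
       matched = data.frame(segment = d$m_seg, boundary_bp = d$m_bound,
                            deviation_bp = d$m_dev))
}

classify_impl <- function(embryo_id, calls, ctx) {
  d <- dosage_impl(calls$chrom, calls$start, calls$end, calls$copy_number,
                   ctx)
  key <- paste(d$dosage, collapse = ",")
  entry <- ctx$lookup[[key]]
  res_chrom <- calls$chrom[d$res_idx]
  partial_involved <- any(!d$res_whole & res_chrom %in% ctx$involved)
  incidental <- any(d$res_whole | !(res_chrom %in% ctx$involved))
  max_dev <- if (length(d$m_dev) && any(!is.na(d$m_dev)))
    max(d$m_dev, na.rm = TRUE) else 0
  if (is.null(entry) || partial_involved) {
    call <- list(embryo_id = embryo_id, mode = "ND", balanced = FALSE,
                 incidental_aneuploidy = incidental, matched_dosage = NULL,
                 max_breakpoint_deviation_bp = max_dev)
  } else {
    call <- list(embryo_id = embryo_id, mode = entry$mode,
                 balanced = entry$balanced,
                 incidental_aneuploidy = incidental,
                 matched_dosage = d$dosage,
                 max_breakpoint_deviation_bp = max_dev)
  }
  call$boundary_obs <- data.frame(segment = d$m_seg,
                                  boundary_bp = d$m_bound)
  structure(call, class = "segregation_call")
}

#' Classify an embryo's segregation mode from its CNV profile
#'
#' Matches the embryo's segment-dosage vector against the 15-entry
#' signature table of its carrier's translocation. A balanced dosage with no
#' involved-chromosome residuals is alternate segregation (CCS cannot
#' separate a normal from a balanced-carrier embryo, nor detect copy-neutral
#' recombinants, so no "recombinant" calls are emitted). Whole-chromosome
#' residual events — and segmental residuals on uninvolved chromosomes —
#' are incidental aneuploidies and do not veto the quadrivalent mode call;
#' partial residual events on an involved chromosome are inconsistent with
#' every segregation product and force ND, as does a dosage matching no
#' table entry.
#'
#' @inheritParams profile_to_dosage
#' @param ctx optional precomputed [carrier context][profile_to_dosage]
#'   (internal; built from `tr` when NULL).
#' @return object of class `segregation_call`: list with `embryo_id`,
#'   `mode` (alternate / adjacent-1 / adjacent-2 / 3:1 / 4:0 / ND),
#'   `balanced`, `incidental_aneuploidy`, `matched_dosage` (NULL for ND) and
#'   `max_breakpoint_deviation_bp`.
#' @export
#' @examples
#' tr <- parse_iscn_karyotype("46,XX,t(2;5)(q21;q13)", carrier_id = "C1")
#' classify_embryo(embryo_profile("E1", "C1"), tr)$mode  # "alternate"
classify_embryo <- function(p, tr, chrom_tab = chrom_table(), tol_bp = 5e6,
                            ctx = NULL) {
  stopifnot(inherits(p, "embryo_cnv_profile"))
  if (is.null(ctx)) ctx <- carrier_context(tr, chrom_tab, tol_bp)
  classify_impl(p$embryo_id, p$calls, ctx)
}

#' @export
print.segregation_call <- function(x, ...) {
  cat(sprintf("embryo %s: %s%s%s\n", x$embryo_id, x$mode,
              if (x$balanced) " (balanced)" else "",
              if (x$incidental_aneuploidy) " + incidental aneuploidy" else ""))
  invisible(x)
}

#' Refine breakpoint positions from unbalanced embryos
#'
#' Band midpoints locate a breakpoint only to band resolution; the CNV
#' boundaries of a carrier's unbalanced embryos pinpoint it. For each
#' involved chromosome the estimate is the median, across unbalanced embryos
#' of the carrier, of the breakpoint-side boundaries of CNV calls matching a
#' quadrivalent segment; dispersion is the raw median absolute deviation.
#'
#' @param profiles list of [embryo_profile()] for one carrier.
#' @param tr the carrier's [reciprocal_translocation()].
#' @param chrom_tab reference table from [chrom_table()].
#' @param tol_bp matching tolerance passed to the classifier.
#' @return list with one `breakpoint_estimate` per involved chromosome
#'   (fields `chromosome`, `arm`, `position_bp`, `n_supporting_embryos`,
#'   `dispersion_bp`) or `NULL` where no unbalanced embryo contributed a
#'   boundary on that chromosome (metrics then fall back to the band
#'   midpoint).
#' @export
estimate_breakpoints <- function(profiles, tr, chrom_tab = chrom_table(),
                                 tol_bp = 5e6) {
  stopifnot(inherits(tr, "reciprocal_translocation"))
  ctx <- carrier_context(tr, chrom_tab, tol_bp)
  cls <- lapply(profiles, function(p) classify_impl(p$embryo_id, p$calls, ctx))
  obs <- boundary_observations(cls)
  mk <- function(side, bp_obj) {
    x <- obs[[side]]$pos
    if (!length(x)) {
      warning("no unbalanced-embryo boundary available for chromosome ",
              bp_obj$chromosome, "; falling back to band midpoint",
              call. = FALSE)
      return(NULL)
    }
    structure(list(chromosome = bp_obj$chromosome, arm = bp_obj$arm,
                   position_bp = median(x),
                   n_supporting_embryos = obs[[side]]$n_embryos,
                   dispersion_bp = mad(x, constant = 1)),
              class = "breakpoint_estimate")
  }
  list(bp1 = mk("a", tr$bp1), bp2 = mk("b", tr$bp2))
}

# collect breakpoint-side boundary observations from unbalanced calls
boundary_observations <- function(cls) {
  out <- list(a = list(pos = numeric(), n_embryos = 0L),
              b = list(pos = numeric(), n_embryos = 0L))
  for (cl in cls) {
    if (cl$mode %in% c("alternate", "ND")) next
    b <- cl$boundary_obs
    for (side in c("a", "b")) {
      x <- b$boundary_bp[grepl(paste0("^(cs|ts)_", side, "$"), b$segment) &
                           !is.na(b$boundary_bp)]
      if (length(x)) {
        out[[side]]$pos <- c(out[[side]]$pos, x)
        out[[side]]$n_embryos <- out[[side]]$n_embryos + 1L
      }
    }
  }
  out
}

#' Apply refined breakpoint estimates to a translocation
#'
#' Returns the translocation with each breakpoint moved to its
#' [estimate_breakpoints()] position (where available and still inside the
#' arm), ready for [compute_metrics()].
#'
#' @param tr a [reciprocal_translocation()].
#' @param est result of [estimate_breakpoints()].
#' @param chrom_tab reference table from [chrom_table()].
#' @return a [reciprocal_translocation()] with updated positions.
#' @export
refine_translocation <- function(tr, est, chrom_tab = chrom_table()) {
  upd <- function(bp, e) {
    if (is.null(e)) return(bp)
    rec <- chrom_record(bp$chromosome, chrom_tab)
    iv <- arm_interval(rec, bp$arm)
    pos <- min(max(e$position_bp, iv[1] + 1), iv[2] - 1)
    breakpoint(bp$chromosome, bp$arm, pos, chrom_tab,
               band_label = bp$band_label)
  }
  reciprocal_translocation(upd(tr$bp1, est$bp1), upd(tr$bp2, est$bp2),
                           carrier_id = tr$carrier_id,
                           carrier_sex = tr$carrier_sex,
                           carrier_age = tr$carrier_age)
}
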