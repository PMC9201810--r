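# The quadrivalent holds four elements: the normal chromosomes A and B and
# the derivatives der(A) = CS(A)+TS(B), der(B) = CS(B)+TS(A). Each element's
# content over the four segments (cs_a, ts_a, cs_b, ts_b):
ELEMENT_DOSAGE <- rbind(
  "A"      = c(cs_a = 1, ts_a = 1, cs_b = 0, ts_b = 0),
  "der(A)" = c(cs_a = 1, ts_a = 0, cs_b = 0, ts_b = 1),
  "B"      = c(cs_a = 0, ts_a = 0, cs_b = 1, ts_b = 1),
  "der(B)" = c(cs_a = 0, ts_a = 1, cs_b = 1, ts_b = 0))

# an interstitial crossover exchanges the translocated segments between a
# chromosome and its derivative, so dosage-wise A <-> der(A), B <-> der(B)
CROSSOVER_PARTNER <- c("A" = "der(A)", "der(A)" = "A",
                       "B" = "der(B)", "der(B)" = "B")

composition_dosage <- function(members) {
  if (length(members) == 0) {
    return(c(cs_a = 0, ts_a = 0, cs_b = 0, ts_b = 0))
  }
  colSums(ELEMENT_DOSAGE[members, , drop = FALSE])
}

#' Enumerate the quadrivalent's gamete classes
#'
#' Lists every segregation product of a two-autosome reciprocal
#' translocation quadrivalent, grouped by disjunction mode: alternate
#' (\{A,B\} and \{der(A),der(B)\}), adjacent-1 (homologous centromeres to
#' opposite poles: \{A,der(B)\}, \{der(A),B\}), adjacent-2 (homologous
#' centromeres together: \{A,der(A)\}, \{B,der(B)\}), 3:1 (the four
#' three-chromosome and four one-chromosome products) and 4:0 (all four or
#' none). That is 16 composition classes; counting each in both
#' interstitial-crossover states (non-recombinant / recombinant) gives the
#' classical 32 gamete karyotypes. A recombinant class carries one crossover
#' chromatid, whose segment content equals its pairing partner's, so
#' recombination introduces no new segment-dosage vectors.
#'
#' @param include_recombinants if `TRUE`, each composition is returned in
#'   both recombinant states (32 classes); otherwise only the 16
#'   non-recombinant classes.
#' @return data.frame with one row per class: `mode`, `composition`
#'   (comma-separated members), `n_chromosomes`, `recombinant`, dosage
#'   columns `cs_a`, `ts_a`, `cs_b`, `ts_b`, and `balanced` (gamete dosage
#'   equal to (1,1,1,1)). Ordering is deterministic: by mode, then
#'   composition, non-recombinant first.
#' @export
#' @examples
#' nrow(enumerate_gamete_classes())            # 16
#' nrow(enumerate_gamete_classes(TRUE))        # 32
enumerate_gamete_classes <- function(include_recombinants = FALSE) {
  els <- rownames(ELEMENT_DOSAGE)
  comp <- list(
    "alternate"  = list(c("A", "B"), c("der(A)", "der(B)")),
    "adjacent-1" = list(c("A", "der(B)"), c("der(A)", "B")),
    "adjacent-2" = list(c("A", "der(A)"), c("B", "der(B)")),
    "3:1" = c(lapply(seq_along(els), function(i) els[-i]),
              lapply(els, function(e) e)),
    "4:0" = list(els, character(0)))
  rows <- list()
  for (mode in names(comp)) {
    for (members in comp[[mode]]) {
      for (rec in if (include_recombinants) c(FALSE, TRUE) else FALSE) {
        d <- if (rec && length(members) > 0) {
          # the crossover chromatid has the segment content of its pairing
          # partner. When the partner centromere segregates to the same
          # pole the reciprocal chromatid travels with it and the exchange
          # is copy-neutral; when it does not, the recombinant chromatid
          # replaces its element's content by the partner's. Canonical
          # choice: the first member (element order) without its partner.
          lone <- members[!CROSSOVER_PARTNER[members] %in% members]
          if (length(lone)) {
            first <- els[min(match(lone, els))]
            composition_dosage(c(setdiff(members, first),
                                 CROSSOVER_PARTNER[[first]]))
          } else {
            composition_dosage(members)
          }
        } else {
          composition_dosage(members)
        }
        rows[[length(rows) + 1]] <- data.frame(
          mode = mode,
          composition = paste(members, collapse = ","),
          n_chromosomes = length(members),
          recombinant = rec,
          t(d),
          balanced = all(d == 1))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expected embryo copy-number signature of a gamete class
#'
#' The embryo combines the carrier gamete with a balanced partner gamete
#' contributing one copy of every segment, so the embryo's segment dosage is
#' the gamete dosage plus (1,1,1,1). A balanced embryo has dosage (2,2,2,2);
#' 2:2 and 3:1 products stay within copy numbers 1..3, 4:0 products reach 0
#' or 4 on no segment but 3 (double-trisomy) or 1 (double-monosomy) on all.
#'
#' @param g one row of [enumerate_gamete_classes()] (data.frame row or list
#'   with the dosage fields).
#' @return list with `mode`, `dosage` (named embryo segment copy numbers)
#'   and `balanced`.
#' @export
embryo_signature <- function(g) {
  d <- unlist(g[SEGMENTS]) + 1
  list(mode = as.character(g$mode), dosage = d, balanced = all(d == 2))
}

segment_intervals <- function(tr, chrom_tab = chrom_table()) {
  # genomic interval of each quadrivalent segment, 0-based half-open
  one <- function(bp) {
    rec <- chrom_record(bp$chromosome, chrom_tab)
    if (bp$arm == "q") {
      list(ts = c(bp$position_bp, rec$length), cs = c(0, bp$position_bp),
           len = rec$length)
    } else {
      list(ts = c(0, bp$position_bp), cs = c(bp$position_bp, rec$length),
           len = rec$length)
    }
  }
  a <- one(tr$bp1); b <- one(tr$bp2)
  list(
    cs_a = list(chrom = tr$bp1$chromosome, start = a$cs[1], end = a$cs[2]),
    ts_a = list(chrom = tr$bp1$chromosome, start = a$ts[1], end = a$ts[2]),
    cs_b = list(chrom = tr$bp2$chromosome, start = b$cs[1], end = b$cs[2]),
    ts_b = list(chrom = tr$bp2$chromosome, start = b$ts[1], end = b$ts[2]))
}

#' Embryo signature table for a concrete translocation
#'
#' Binds the abstract segment-dosage signatures of the 16 non-recombinant
#' gamete classes to genomic coordinates. The two alternate classes share
#' the balanced signature (2,2,2,2) and collapse to one entry, leaving 15
#' distinct embryo dosage vectors: 1 balanced + 14 unbalanced, each carrying
#' the expected gain/loss intervals (e.g. the ts_a entry runs from the
#' breakpoint to the telomere of the breakpoint arm of chromosome A).
#' Recombinant classes add no further dosages, so this table is complete for
#' CNV-level classification.
#'
#' @param tr a [reciprocal_translocation()].
#' @param chrom_tab reference table from [chrom_table()].
#' @return object of class `signature_table`: list with `entries` (one per
#'   distinct embryo dosage: `mode`, `dosage`, `balanced`, `intervals` — a
#'   data.frame of segment, chrom, start, end, expected copy number) and
#'   `segments` (the four segment intervals).
#' @export
signature_table <- function(tr, chrom_tab = chrom_table()) {
  segs <- segment_intervals(tr, chrom_tab)
  classes <- enumerate_gamete_classes(include_recombinants = FALSE)
  entries <- list()
  for (i in seq_len(nrow(classes))) {
    sig <- embryo_signature(classes[i, ])
    key <- paste(sig$dosage, collapse = ",")
    if (!is.null(entries[[key]])) next   # alternate's two classes collapse
    iv <- do.call(rbind, lapply(SEGMENTS, function(s) {
      data.frame(segment = s, chrom = segs[[s]]$chrom,
                 start = segs[[s]]$start, end = segs[[s]]$end,
                 copy_number = unname(sig$dosage[s]))
    }))
    entries[[key]] <- list(mode = sig$mode, dosage = sig$dosage,
                           balanced = sig$balanced,
                           intervals = iv[iv$copy_number != 2, , drop = FALSE])
  }
  structure(list(entries = entries, segments = segs, translocation = tr),
            class = "signature_table")
}

#' @export
print.signature_table <- function(x, ...) {
  cat(sprintf("signature table for t(%s;%s): %d distinct embryo dosages\n",
              x$translocation$bp1$chromosome, x$translocation$bp2$chromosome,
              length(x$entries)))
  for (key in names(x$entries)) {
    e <- x$entries[[key]]
    cat(sprintf("  (%s) %-10s%s\n", key, e$mode,
                if (e$balanced) " [balanced]" else ""))
  }
  invisible(x)
}
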