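# Tabular IO. TSV is the canonical dialect (karyotype strings contain
# commas), UTF-8, "." decimal, header required. Coordinates in files are
# 0-based half-open; `one_based = TRUE` converts on read.

#' Read a carrier table
#'
#' TSV with columns `carrier_id`, `sex` (female/male), optional `age`, and
#' either `karyotype` (ISCN, e.g. `46,XX,t(2;5)(q21;q13)`) or explicit
#' coordinates `chrom1, pos1, chrom2, pos2` (0-based; arms inferred from the
#' position relative to the centromere). Malformed rows are collected as
#' rejects with their line numbers rather than aborting the read; missing
#' required columns or duplicate carrier ids are errors.
#'
#' @param path TSV path.
#' @param band_tab,chrom_tab reference tables.
#' @return list with `carriers` (named list of
#'   [reciprocal_translocation()]) and `rejects` (data.frame: line,
#'   carrier_id, reason).
#' @export
read_carrier_table <- function(path, band_tab = band_table(),
                               chrom_tab = chrom_table()) {
  tab <- read.delim(path, colClasses = "character")
  has_kar <- "karyotype" %in% names(tab)
  has_pos <- all(c("chrom1", "pos1", "chrom2", "pos2") %in% names(tab))
  if (!"carrier_id" %in% names(tab) || !(has_kar || has_pos)) {
    stop("carrier table needs columns carrier_id and karyotype (or ",
         "chrom1, pos1, chrom2, pos2)")
  }
  dup <- unique(tab$carrier_id[duplicated(tab$carrier_id)])
  if (length(dup)) {
    stop("duplicate carrier_id: ", paste(dup, collapse = ", "))
  }
  carriers <- list()
  rejects <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    res <- tryCatch({
      sex <- if (!is.null(row$sex) && row$sex %in% c("female", "male"))
        row$sex else NA_character_
      age <- if (!is.null(row$age)) suppressWarnings(as.numeric(row$age))
             else NA_real_
      if (has_kar && nzchar(row$karyotype %||% "") &&
          !is.na(row$karyotype)) {
        parse_iscn_karyotype(row$karyotype, band_tab, chrom_tab,
                             carrier_id = row$carrier_id,
                             carrier_sex = sex, carrier_age = age)
      } else if (has_pos) {
        mk <- function(ch, pos) {
          pos <- as.numeric(pos)
          rec <- chrom_record(ch, chrom_tab)
          arm <- if (pos < rec$cen_start) "p" else "q"
          breakpoint(ch, arm, pos, chrom_tab)
        }
        reciprocal_translocation(mk(row$chrom1, row$pos1),
                                 mk(row$chrom2, row$pos2),
                                 carrier_id = row$carrier_id,
                                 carrier_sex = sex, carrier_age = age)
      } else {
        stop("no karyotype and no coordinates")
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rejects[[length(rejects) + 1]] <- data.frame(
        line = i + 1L, carrier_id = row$carrier_id,
        reason = conditionMessage(res))
    } else {
      carriers[[row$carrier_id]] <- res
    }
  }
  list(carriers = carriers,
       rejects = if (length(rejects))
         do.call(rbind, c(rejects, make.row.names = FALSE))
       else data.frame(line = integer(), carrier_id = character(),
                       reason = character()))
}

#' Read a CNV segment-call table
#'
#' BED-like TSV with columns `embryo_id`, `carrier_id`, `chrom`, `start`,
#' `end`, `copy_number` (0-based half-open; header required). Rows with
#' `copy_number = 2` act as explicit euploid markers: they register the
#' embryo without contributing a call, so an embryo with no imbalance can
#' still appear. Bad rows (end <= start, unknown chromosome, non-integer
#' copy number) are collected as rejects with line numbers; overlapping
#' calls within one embryo/chromosome are an error at profile construction.
#'
#' @param path TSV path.
#' @param chrom_tab reference table from [chrom_table()].
#' @param one_based input coordinates are 1-based inclusive; convert.
#' @return list with `profiles` (named list of [embryo_profile()]) and
#'   `rejects` (data.frame: line, embryo_id, reason).
#' @export
read_cnv_table <- function(path, chrom_tab = chrom_table(),
                           one_based = FALSE) {
  tab <- read.delim(path, colClasses = c(chrom = "character",
                                         embryo_id = "character",
                                         carrier_id = "character"))
  need <- c("embryo_id", "carrier_id", "chrom", "start", "end",
            "copy_number")
  if (!all(need %in% names(tab))) {
    stop("CNV table needs columns: ", paste(need, collapse = ", "))
  }
  if (one_based) tab$start <- tab$start - 1
  bad <- rep(NA_character_, nrow(tab))
  bad[tab$end <= tab$start] <- "end <= start"
  bad[!tab$chrom %in% chrom_tab$chrom] <- "unknown chromosome"
  bad[tab$copy_number %% 1 != 0] <- "non-integer copy number"
  rejects <- data.frame(line = which(!is.na(bad)) + 1L,
                        embryo_id = tab$embryo_id[!is.na(bad)],
                        reason = bad[!is.na(bad)])
  ok <- tab[is.na(bad), , drop = FALSE]
  profiles <- lapply(split(ok, ok$embryo_id), function(g) {
    calls <- g[g$copy_number != 2,
               c("chrom", "start", "end", "copy_number"), drop = FALSE]
    embryo_profile(g$embryo_id[1], g$carrier_id[1], calls)
  })
  list(profiles = profiles, rejects = rejects)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write analysis reports
#'
#' Writes the pipeline outputs as TSV + JSON with deterministic column
#' order; the run manifest is written last and acts as the success marker.
#' All outputs except the manifest (which carries a timestamp) are
#' byte-identical across re-runs on identical inputs.
#'
#' @param results named list; recognised elements: `cohort` (embryo-level
#'   table), `mode_table` ([tabulate_modes()] output), `fits` (named list of
#'   `glmm_fit`), `roc` (`roc_result`), `cmh` (`cmh_result`), `rejects`
#'   (data.frame), `config` (echoed into the manifest).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_reports <- function(results, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory ", out_dir)
  }
  if (file.access(out_dir, 2) != 0) {
    stop("output directory ", out_dir, " is not writable")
  }
  counts <- list()
  if (!is.null(results$cohort)) {
    write_tsv(results$cohort[order(results$cohort$embryo_id), ],
              file.path(out_dir, "cohort.tsv"))
    counts$classified <- nrow(results$cohort)
    counts$nd <- sum(results$cohort$mode == "ND")
  }
  if (!is.null(results$mode_table)) {
    write_tsv(results$mode_table$table, file.path(out_dir, "mode_table.tsv"))
  }
  summary <- list()
  for (nm in names(results$fits %||% list())) {
    f <- results$fits[[nm]]
    summary[[paste0("fit_", nm)]] <- list(
      coefficients = f$coefficients,
      random_intercept_sd = f$random_intercept_sd,
      converged = f$converged, n_obs = f$n_obs, n_groups = f$n_groups)
    write_tsv(f$coefficients,
              file.path(out_dir, paste0("fit_", gsub("[^A-Za-z0-9]", "_", nm),
                                        ".tsv")))
  }
  if (!is.null(results$roc)) summary$roc <- unclass(results$roc)
  if (!is.null(results$cmh)) {
    summary$cmh <- unclass(results$cmh)
  }
  if (!is.null(results$mode_table)) {
    summary$modes <- results$mode_table$table
    summary$two_two_pct <- results$mode_table$two_two_pct
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(results$rejects)) {
    write_tsv(results$rejects, file.path(out_dir, "rejects.tsv"))
    counts$rejected <- nrow(results$rejects)
  }
  counts$read <- (counts$classified %||% 0) + (counts$rejected %||% 0)
  manifest <- list(
    tool = "quadseg",
    version = as.character(utils::packageVersion("quadseg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = results$config,
    row_counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a simulated cohort to disk
#'
#' Emits `carriers.tsv`, `cnv.tsv`, `truth.tsv` and `config.json` (the
#' config echo, from which the cohort is exactly reproducible).
#'
#' @param sim a [simulate_cohort()] result.
#' @param out_dir output directory.
#' @return invisibly, the output paths.
#' @export
write_simulated_cohort <- function(sim, out_dir) {
  stopifnot(inherits(sim, "simulated_cohort"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory ", out_dir)
  }
  carr <- sim$carrier_table
  # chrom1/pos1, chrom2/pos2 are the explicit breakpoint coordinates (in
  # the carrier's bp1/bp2 order) so the file feeds read_carrier_table
  # directly; the size-ordered labels keep their own columns
  names(carr)[names(carr) == "chrom1"] <- "chrom_longer"
  names(carr)[names(carr) == "chrom2"] <- "chrom_shorter"
  trs <- sim$carriers[carr$carrier_id]
  carr$chrom1 <- vapply(trs, function(tr) tr$bp1$chromosome, "")
  carr$pos1 <- vapply(trs, function(tr) tr$bp1$position_bp, 0)
  carr$chrom2 <- vapply(trs, function(tr) tr$bp2$chromosome, "")
  carr$pos2 <- vapply(trs, function(tr) tr$bp2$position_bp, 0)
  write_tsv(carr, file.path(out_dir, "carriers.tsv"))
  cnv <- do.call(rbind, lapply(sim$profiles, function(p) {
    if (!nrow(p$calls)) {
      # explicit euploid marker row so the embryo stays listed
      return(data.frame(embryo_id = p$embryo_id, carrier_id = p$carrier_id,
                        chrom = "1", start = 0, end = 1e6, copy_number = 2))
    }
    cbind(embryo_id = p$embryo_id, carrier_id = p$carrier_id, p$calls)
  }))
  write_tsv(cnv, file.path(out_dir, "cnv.tsv"))
  write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
  sim_config_write(sim$config, file.path(out_dir, "config.json"))
  invisible(file.path(out_dir, c("carriers.tsv", "cnv.tsv", "truth.tsv",
                                 "config.json")))
}
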