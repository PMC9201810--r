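# Calibration constants for the default simulated study conditions: a large
# clinical PGT-SR cohort of autosomal reciprocal translocation carriers
# (2,253 carriers, 10,846 diagnosed blastocysts, ~4.8 per carrier; mode
# frequencies alternate 46.1%, adjacent-1 31.3%, adjacent-2 12.4%, 3:1 5.4%,
# other/undetermined 4.7% with only 4 true 4:0 products; 1,028 female /
# 1,225 male carriers).
MODE_FREQ <- c("alternate" = 46.1, "adjacent-1" = 31.3, "adjacent-2" = 12.4,
               "3:1" = 5.4)
FOUR_ZERO_RATE <- 4 / 10846
SIM_COVARIATES <- c("female", "acr_involved", "tar1", "ts1_mb")

#' Default covariate effects on non-alternate segregation
#'
#' The multivariable adjusted odds ratios for the pooled
#' unbalanced-vs-alternate outcome reported for the calibration cohort:
#' female carrier sex 1.293, acrocentric-chromosome involvement 1.208, TAR1
#' 0.806 (per unit ratio). Applied identically to every non-alternate
#' contrast of the simulator's multinomial logit, so the pooled
#' unbalanced-vs-alternate odds ratio conditional on the carrier's random
#' intercept equals these values exactly.
#'
#' @return named list of per-contrast coefficient vectors (log odds ratios)
#'   over the covariates `female`, `acr_involved`, `tar1`, `ts1_mb`.
#' @export
default_mode_effects <- function() {
  shared <- c(female = log(1.293), acr_involved = log(1.208),
              tar1 = log(0.806), ts1_mb = 0)
  list("adjacent-1" = shared, "adjacent-2" = shared,
       "3:1" = shared, "4:0" = shared)
}

#' Mode-specific covariate effects
#'
#' Contrast-specific multivariable odds ratios reported for the calibration
#' cohort: adjacent-1 is reduced by higher TAR1 (OR 0.316 per unit), adjacent-2
#' is increased by longer TS1 (OR 1.014 per Mb) and female sex (OR 1.66), and
#' 3:1 is increased by female sex (OR 2.643) and acrocentric involvement
#' (OR 1.387).
#'
#' @return named list of per-contrast coefficient vectors, as in
#'   [default_mode_effects()].
#' @export
mode_specific_effects <- function() {
  zero <- c(female = 0, acr_involved = 0, tar1 = 0, ts1_mb = 0)
  list(
    "adjacent-1" = replace(zero, "tar1", log(0.316)),
    "adjacent-2" = replace(zero, c("female", "ts1_mb"),
                           c(log(1.66), log(1.014))),
    "3:1" = replace(zero, c("female", "acr_involved"),
                    c(log(2.643), log(1.387))),
    "4:0" = zero)
}

# mean acrocentric-involvement, TAR1 and TS1 under the karyotype sampler,
# estimated once per (table, min segment) from a fixed internal stream so
# configs are deterministic and cheap; cached in the package environment
.sampler_means_cache <- new.env(parent = emptyenv())
sampler_covariate_means <- function(chrom_tab, min_segment_bp,
                                    n_draws = 4000L) {
  key <- paste(nrow(chrom_tab), sum(chrom_tab$length), min_segment_bp,
               n_draws, sep = "|")
  hit <- .sampler_means_cache[[key]]
  if (!is.null(hit)) return(hit)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(602L)
  xs <- vapply(seq_len(n_draws), function(i) {
    k <- sample_karyotype(chrom_tab, min_segment_bp)
    recs <- lapply(list(k$bp1, k$bp2), function(bp)
      chrom_record(bp$chromosome, chrom_tab))
    lens <- vapply(recs, `[[`, 0, "length")
    long <- which.max(lens)
    bp <- list(k$bp1, k$bp2)[[long]]
    iv <- arm_interval(recs[[long]], bp$arm)
    ts1 <- if (bp$arm == "q") lens[long] - bp$position_bp else bp$position_bp
    c(acr_involved = as.numeric(any(vapply(recs, `[[`, TRUE,
                                           "is_acrocentric"))),
      tar1 = ts1 / (iv[2] - iv[1]), ts1_mb = ts1 / 1e6)
  }, c(acr_involved = 0, tar1 = 0, ts1_mb = 0))
  out <- rowMeans(xs)
  .sampler_means_cache[[key]] <- out
  out
}

sample_karyotype <- function(chrom_tab, min_segment_bp) {
  chroms <- sample(chrom_tab$chrom, 2)
  mk <- function(ch) {
    rec <- chrom_record(ch, chrom_tab)
    usable <- function(arm) {
      iv <- arm_interval(rec, arm)
      max(0, (iv[2] - min_segment_bp) - (iv[1] + min_segment_bp))
    }
    # acrocentric p arms carry no euchromatic breakpoints in this population
    w <- c(p = if (rec$is_acrocentric) 0 else usable("p"), q = usable("q"))
    arm <- sample(c("p", "q"), 1, prob = w)
    iv <- arm_interval(rec, arm)
    pos <- runif(1, iv[1] + min_segment_bp, iv[2] - min_segment_bp)
    breakpoint(ch, arm, round(pos), chrom_tab)
  }
  list(bp1 = mk(chroms[1]), bp2 = mk(chroms[2]))
}

sim_covariates <- function(tr, metrics) {
  c(female = as.numeric(tr$carrier_sex == "female"),
    acr_involved = as.numeric(metrics$acr_involved),
    tar1 = metrics$tar1, ts1_mb = metrics$ts1 / 1e6)
}

#' Simulation configuration
#'
#' Defaults emulate the calibration cohort's study conditions: 2,253
#' carriers (45.6\% female), a zero-truncated Poisson(4.8) number of
#' diagnosed blastocysts per carrier, autosome pairs drawn uniformly with
#' breakpoints uniform within arms (minimum segment 5 Mb; acrocentric p arms
#' excluded), per-carrier random intercepts (SD 0.5 log-odds) shared across
#' all non-alternate contrasts, baseline contrast logits reproducing the
#' published mode frequencies at covariate means, contrast coefficients from
#' [default_mode_effects()], 1 Mb CNV boundary jitter (the platform's
#' resolution scale), an 8\% incidental whole-chromosome aneuploidy rate,
#' and a 4.7\% rate of uninterpretable (ND) profiles simulated as profile
#' corruption.
#'
#' Baseline contrast logits are `log(p_k / p_alternate)` of the published
#' frequencies, shifted by `-beta_k' xbar` so the stated frequencies hold at
#' the covariate means `xbar` (estimated once from the karyotype sampler
#' with a fixed internal stream and stored in the config).
#'
#' @param n_carriers,p_female,embryos_per_carrier cohort shape.
#' @param mode_effects per-contrast coefficient list; see
#'   [default_mode_effects()] and [mode_specific_effects()].
#' @param random_intercept_sd SD of the shared per-carrier intercept
#'   (log-odds).
#' @param cnv_noise_sd_bp Gaussian jitter SD on breakpoint-side CNV
#'   boundaries, bp.
#' @param incidental_aneuploidy_rate per-embryo probability of one extra
#'   whole-chromosome aneuploidy on an uninvolved autosome.
#' @param nd_rate per-embryo probability of profile corruption (a spurious
#'   segmental call on an involved chromosome).
#' @param min_segment_bp minimum translocated / centromere-side segment, bp.
#' @param seed integer master seed; the cohort is a pure function of the
#'   config including the seed.
#' @param chrom_tab reference table from [chrom_table()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_carriers = 2253,
                       p_female = 1028 / 2253,
                       embryos_per_carrier = 4.8,
                       mode_effects = default_mode_effects(),
                       random_intercept_sd = 0.5,
                       cnv_noise_sd_bp = 1e6,
                       incidental_aneuploidy_rate = 0.08,
                       nd_rate = 0.047,
                       min_segment_bp = 5e6,
                       seed = 1L,
                       chrom_tab = chrom_table()) {
  stopifnot(n_carriers >= 1, p_female >= 0, p_female <= 1,
            embryos_per_carrier > 0, random_intercept_sd >= 0,
            cnv_noise_sd_bp >= 0,
            incidental_aneuploidy_rate >= 0, incidental_aneuploidy_rate <= 1,
            nd_rate >= 0, nd_rate <= 1)
  contrasts <- c("adjacent-1", "adjacent-2", "3:1", "4:0")
  stopifnot(identical(names(mode_effects), contrasts),
            all(vapply(mode_effects, function(b)
              identical(names(b), SIM_COVARIATES), TRUE)))
  if (min_segment_bp * 2 >= max(chrom_tab$length - chrom_tab$cen_end)) {
    stop("min_segment_bp too large for the reference chromosome arms")
  }
  p <- c(MODE_FREQ / sum(c(MODE_FREQ, 100 * FOUR_ZERO_RATE)),
         "4:0" = 100 * FOUR_ZERO_RATE /
           sum(c(MODE_FREQ, 100 * FOUR_ZERO_RATE)))
  raw_logits <- log(p[contrasts] / p[["alternate"]])
  xbar <- c(female = p_female,
            sampler_covariate_means(chrom_tab, min_segment_bp))
  baseline_logits <- vapply(contrasts, function(k)
    unname(raw_logits[k] - sum(mode_effects[[k]] * xbar)), 0)
  structure(list(
    n_carriers = as.integer(n_carriers), p_female = p_female,
    embryos_per_carrier = embryos_per_carrier,
    mode_effects = mode_effects, baseline_logits = baseline_logits,
    covariate_means = xbar,
    random_intercept_sd = random_intercept_sd,
    cnv_noise_sd_bp = cnv_noise_sd_bp,
    incidental_aneuploidy_rate = incidental_aneuploidy_rate,
    nd_rate = nd_rate, min_segment_bp = min_segment_bp,
    seed = as.integer(seed)), class = "sim_config")
}

#' Write / read a simulation config as JSON
#'
#' The JSON echo preserves names of every coefficient vector, so a config
#' round-trips losslessly and a cohort can be reproduced exactly from the
#' file.
#'
#' @param cfg a [sim_config()].
#' @param path JSON file path.
#' @return `sim_config_write` returns `path` invisibly; `sim_config_read`
#'   returns the reconstructed `sim_config`.
#' @export
sim_config_write <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  x <- unclass(cfg)
  x$mode_effects <- lapply(x$mode_effects, as.list)
  x$baseline_logits <- as.list(x$baseline_logits)
  x$covariate_means <- as.list(x$covariate_means)
  # 17 significant digits: lossless binary64 round-trip
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname sim_config_write
#' @export
sim_config_read <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(l) vapply(l, as.numeric, 0)
  structure(list(
    n_carriers = as.integer(x$n_carriers),
    p_female = as.numeric(x$p_female),
    embryos_per_carrier = as.numeric(x$embryos_per_carrier),
    mode_effects = lapply(x$mode_effects, num),
    baseline_logits = num(x$baseline_logits),
    covariate_means = num(x$covariate_means),
    random_intercept_sd = as.numeric(x$random_intercept_sd),
    cnv_noise_sd_bp = as.numeric(x$cnv_noise_sd_bp),
    incidental_aneuploidy_rate = as.numeric(x$incidental_aneuploidy_rate),
    nd_rate = as.numeric(x$nd_rate),
    min_segment_bp = as.numeric(x$min_segment_bp),
    seed = as.integer(x$seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "simulation config: %d carriers (%.1f%% female), %.1f embryos/carrier\n",
    "  random intercept SD %.2f, CNV jitter %.1f Mb, incidental %.1f%%, ND %.1f%%, seed %d\n"),
    x$n_carriers, 100 * x$p_female, x$embryos_per_carrier,
    x$random_intercept_sd, x$cnv_noise_sd_bp / 1e6,
    100 * x$incidental_aneuploidy_rate, 100 * x$nd_rate, x$seed))
  invisible(x)
}

# expected embryo CNV calls for one gamete class bound to a translocation,
# as parallel vectors (chrom, start, end, copy_number). Segments with
# identical non-disomic copy number on one chromosome merge into a
# whole-chromosome call; the breakpoint-side boundary is jittered once per
# chromosome (a segmentation algorithm places a single changepoint), so
# adjacent cs/ts calls stay exactly adjacent; chromosome ends are fixed.
signature_calls <- function(dosage, segs, lens, noise_sd, min_size_bp) {
  chrom <- character(); start <- numeric(); end <- numeric(); cn <- integer()
  for (side in c("a", "b")) {
    cs <- segs[[paste0("cs_", side)]]; ts <- segs[[paste0("ts_", side)]]
    cn_cs <- dosage[[paste0("cs_", side)]]
    cn_ts <- dosage[[paste0("ts_", side)]]
    len <- lens[[side]]
    if (cn_cs != 2 && cn_cs == cn_ts) {
      chrom <- c(chrom, cs$chrom); start <- c(start, 0)
      end <- c(end, len); cn <- c(cn, cn_cs)
      next
    }
    jit <- round(rnorm(1, 0, noise_sd))
    for (seg in list(c(list(cn = cn_cs), cs), c(list(cn = cn_ts), ts))) {
      if (seg$cn == 2) next
      s <- seg$start; e <- seg$end
      if (s > 0) s <- min(max(0, s + jit), len - 1)
      if (e < len) e <- min(max(1, e + jit), len)
      if (e - s >= min_size_bp) {   # platform floor
        chrom <- c(chrom, seg$chrom); start <- c(start, s)
        end <- c(end, e); cn <- c(cn, seg$cn)
      }
    }
  }
  list(chrom = chrom, start = start, end = end, copy_number = cn)
}

# spurious segmental call on an involved chromosome, placed in a gap so it
# overlaps nothing and matches no quadrivalent segment; returns the call
# vectors with the spurious segment appended, or NULL when no gap is wide
# enough
corrupt_calls <- function(calls, involved, lens, margin_bp = 6e6,
                          min_len_bp = 5e6) {
  sides <- sample(c("a", "b"))
  for (side in sides) {
    ch <- involved[[side]]
    len <- lens[[side]]
    on_ch <- calls$chrom == ch
    ss <- sort(calls$start[on_ch]); ee <- sort(calls$end[on_ch])
    g_start <- c(0, ee); g_end <- c(ss, len)
    ok <- which(g_end - g_start >= 2 * margin_bp + min_len_bp)
    if (!length(ok)) next
    gi <- ok[sample.int(length(ok), 1)]
    lo <- g_start[gi] + margin_bp; hi <- g_end[gi] - margin_bp
    s <- runif(1, lo, hi - min_len_bp)
    e <- runif(1, s + min_len_bp, min(hi, s + 20e6))
    return(list(chrom = c(calls$chrom, ch),
                start = c(calls$start, round(s)),
                end = c(calls$end, round(e)),
                copy_number = c(calls$copy_number, sample(c(1, 3), 1))))
  }
  NULL
}

#' Simulate a PGT-SR cohort
#'
#' Draws carriers (sex, age, karyotype), per-carrier random intercepts, a
#' zero-truncated Poisson number of embryos each, per-embryo true
#' segregation modes from the multinomial logit, a concrete gamete class
#' uniformly within the mode, and the embryo's CNV profile from the class's
#' signature intervals with boundary jitter, incidental whole-chromosome
#' aneuploidies, and ND corruption at the configured rates. Output is a pure
#' function of the config (seed included): per-carrier substreams are
#' derived from the master seed so adding draw sites for one carrier never
#' shifts another carrier's draws.
#'
#' @param cfg a [sim_config()].
#' @param chrom_tab reference table from [chrom_table()].
#' @return list of class `simulated_cohort`: `carriers` (named list of
#'   [reciprocal_translocation()]), `carrier_table` (data.frame of carrier
#'   covariates incl. quadrivalent metrics in Mb), `truth` (embryo-level
#'   data.frame: embryo_id, carrier_id, true_mode, composition, incidental,
#'   corrupted), `profiles` (named list of [embryo_profile()]), `config`.
#' @export
simulate_cohort <- function(cfg, chrom_tab = chrom_table()) {
  stopifnot(inherits(cfg, "sim_config"))
  classes <- enumerate_gamete_classes(include_recombinants = FALSE)
  class_dosages <- as.matrix(classes[SEGMENTS]) + 1L
  class_idx <- split(seq_len(nrow(classes)), classes$mode)
  contrasts <- names(cfg$baseline_logits)
  all_len <- setNames(chrom_tab$length, chrom_tab$chrom)
  set.seed(cfg$seed)
  carrier_seeds <- sample.int(.Machine$integer.max - 1, cfg$n_carriers)
  carriers <- vector("list", cfg$n_carriers)
  carrier_rows <- vector("list", cfg$n_carriers)
  profiles <- list()
  t_eid <- character(); t_cid <- character(); t_mode <- character()
  t_comp <- character(); t_bal <- logical(); t_inc <- logical()
  t_cor <- logical()
  for (i in seq_len(cfg$n_carriers)) {
    set.seed(carrier_seeds[i])
    cid <- sprintf("C%04d", i)
    sex <- if (runif(1) < cfg$p_female) "female" else "male"
    age <- round(min(max(rnorm(1, 30, 4), 20), 45), 1)
    k <- sample_karyotype(chrom_tab, cfg$min_segment_bp)
    tr <- reciprocal_translocation(k$bp1, k$bp2, carrier_id = cid,
                                   carrier_sex = sex, carrier_age = age)
    met <- compute_metrics(tr, chrom_tab)
    x <- sim_covariates(tr, met)
    u <- rnorm(1, 0, cfg$random_intercept_sd)
    eta <- vapply(contrasts, function(kk)
      cfg$baseline_logits[[kk]] +
        sum(cfg$mode_effects[[kk]] * (x - cfg$covariate_means)) + u, 0)
    pmode <- exp(c(alternate = 0, eta))
    pmode <- pmode / sum(pmode)
    n_emb <- 0
    while (n_emb < 1) n_emb <- rpois(1, cfg$embryos_per_carrier)
    segs <- segment_intervals(tr, chrom_tab)
    involved <- c(a = tr$bp1$chromosome, b = tr$bp2$chromosome)
    lens <- list(a = all_len[[involved[["a"]]]],
                 b = all_len[[involved[["b"]]]])
    uninvolved <- setdiff(chrom_tab$chrom, involved)
    carriers[[i]] <- tr
    carrier_rows[[i]] <- data.frame(
      carrier_id = cid, sex = sex, age = age,
      chrom1 = met$per_chromosome$chrom[1],
      chrom2 = met$per_chromosome$chrom[2],
      acr_involved = met$acr_involved,
      size1 = met$size1 / 1e6, size2 = met$size2 / 1e6,
      ts1 = met$ts1 / 1e6, ts2 = met$ts2 / 1e6,
      cs1 = met$cs1 / 1e6, cs2 = met$cs2 / 1e6,
      tsr = met$tsr, csr = met$csr, tar1 = met$tar1, tar2 = met$tar2,
      random_intercept = u, n_embryos = n_emb)
    for (j in seq_len(n_emb)) {
      eid <- sprintf("%s_E%02d", cid, j)
      mode <- sample(names(pmode), 1, prob = pmode)
      ci_ <- class_idx[[mode]]
      cls_i <- ci_[sample.int(length(ci_), 1)]
      dosage <- as.list(class_dosages[cls_i, ])
      calls <- signature_calls(dosage, segs, lens, cfg$cnv_noise_sd_bp, 1e6)
      incidental <- runif(1) < cfg$incidental_aneuploidy_rate
      if (incidental) {
        ch <- uninvolved[sample.int(length(uninvolved), 1)]
        calls$chrom <- c(calls$chrom, ch)
        calls$start <- c(calls$start, 0)
        calls$end <- c(calls$end, all_len[[ch]])
        calls$copy_number <- c(calls$copy_number, sample(c(1, 3), 1))
      }
      corrupted <- runif(1) < cfg$nd_rate
      if (corrupted) {
        cc <- corrupt_calls(calls, involved, lens)
        corrupted <- !is.null(cc)
        if (corrupted) calls <- cc
      }
      t_eid <- c(t_eid, eid); t_cid <- c(t_cid, cid)
      t_mode <- c(t_mode, mode); t_comp <- c(t_comp, classes$composition[cls_i])
      t_bal <- c(t_bal, classes$balanced[cls_i])
      t_inc <- c(t_inc, incidental); t_cor <- c(t_cor, corrupted)
      profiles[[eid]] <- embryo_profile(eid, cid, as.data.frame(calls))
    }
  }
  names(carriers) <- sprintf("C%04d", seq_len(cfg$n_carriers))
  structure(list(carriers = carriers,
                 carrier_table = do.call(rbind, c(carrier_rows,
                                                  make.row.names = FALSE)),
                 truth = data.frame(embryo_id = t_eid, carrier_id = t_cid,
                                    true_mode = t_mode, composition = t_comp,
                                    balanced_true = t_bal,
                                    incidental = t_inc, corrupted = t_cor),
                 profiles = profiles, config = cfg),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("simulated cohort: %d carriers, %d embryos (seed %d)\n",
              length(x$carriers), nrow(x$truth), x$config$seed))
  print(round(100 * table(x$truth$true_mode) / nrow(x$truth), 1))
  invisible(x)
}
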