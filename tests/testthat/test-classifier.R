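test_that("an empty profile is alternate/balanced with dosage (2,2,2,2)", {
  tr <- toy_translocation()
  ct <- toy_chrom_tab()
  pd <- profile_to_dosage(embryo_profile("E0", "T1"), tr, ct)
  expect_equal(unname(pd$dosage), c(2, 2, 2, 2))
  expect_equal(nrow(pd$residuals), 0)
  cl <- classify_embryo(embryo_profile("E0", "T1"), tr, ct)
  expect_equal(cl$mode, "alternate")
  expect_true(cl$balanced)
  expect_false(cl$incidental_aneuploidy)
})

test_that("every signature entry round-trips through classification", {
  ct <- toy_chrom_tab()
  for (tr in list(toy_translocation(),
                  toy_translocation(pos1 = 20e6, arm1 = "p"),
                  toy_translocation(pos1 = 50e6, pos2 = 10e6, arm2 = "p"))) {
    st <- signature_table(tr, ct)
    for (key in names(st$entries)) {
      e <- st$entries[[key]]
      p <- embryo_profile(paste0("E", key), "T1", calls_for_entry(e))
      cl <- classify_embryo(p, tr, ct)
      expect_equal(cl$mode, e$mode, info = key)
      expect_equal(cl$balanced, e$balanced, info = key)
      expect_false(cl$incidental_aneuploidy)
      # and is stable under tolerance-bounded boundary perturbation
      p2 <- embryo_profile(paste0("E", key, "j"), "T1",
                           calls_for_entry(e, shift = 2e6))
      expect_equal(classify_embryo(p2, tr, ct)$mode, e$mode, info = key)
    }
  }
})

test_that("specific dosages map to the published mode taxonomy", {
  tr <- toy_translocation()
  ct <- toy_chrom_tab()
  st <- signature_table(tr, ct)
  cases <- list(c("2,3,2,1", "adjacent-1"), c("2,1,2,3", "adjacent-1"),
                c("3,2,1,2", "adjacent-2"), c("3,3,3,3", "4:0"),
                c("3,2,2,3", "3:1"), c("1,1,2,2", "3:1"))
  for (cs in cases) expect_equal(st$entries[[cs[1]]]$mode, cs[2])
})

test_that("incidental whole-chromosome aneuploidy does not veto the mode", {
  tr <- toy_translocation()
  ct <- toy_chrom_tab()
  # balanced quadrivalent + whole-chromosome trisomy on the uninvolved
  # chromosome would need a 3rd chromosome; use the packaged reference
  tr2 <- parse_iscn_karyotype("46,XX,t(2;5)(q21;q13)", carrier_id = "C1")
  len16 <- chrom_table()$length[chrom_table()$chrom == "16"]
  p <- embryo_profile("E1", "C1", data.frame(
    chrom = "16", start = 0, end = len16, copy_number = 3))
  cl <- classify_embryo(p, tr2)
  expect_equal(cl$mode, "alternate")
  expect_true(cl$balanced)
  expect_true(cl$incidental_aneuploidy)
  # unbalanced mode + incidental aneuploidy keeps the mode call
  st <- signature_table(tr2)
  adj1 <- st$entries[["2,3,2,1"]]
  calls <- rbind(calls_for_entry(adj1),
                 data.frame(chrom = "16", start = 0, end = len16,
                            copy_number = 3))
  cl2 <- classify_embryo(embryo_profile("E2", "C1", calls), tr2)
  expect_equal(cl2$mode, "adjacent-1")
  expect_true(cl2$incidental_aneuploidy)
})

test_that("partial residuals on involved chromosomes force ND", {
  tr <- toy_translocation()
  ct <- toy_chrom_tab()
  # a mid-arm segmental event on chr1 matching no segment
  p <- embryo_profile("E1", "T1", data.frame(
    chrom = "1", start = 50e6, end = 62e6, copy_number = 3))
  cl <- classify_embryo(p, tr, ct)
  expect_equal(cl$mode, "ND")
  expect_null(cl$matched_dosage)
  # never balanced together with such a residual
  expect_false(cl$balanced)
})

test_that("unmatchable dosages classify as ND", {
  tr <- toy_translocation()
  ct <- toy_chrom_tab()
  # ts gains on both chromosomes: dosage (2,3,2,3) matches no product
  p <- embryo_profile("E1", "T1", data.frame(
    chrom = c("1", "2"), start = c(80e6, 60e6), end = c(100e6, 80e6),
    copy_number = c(3, 3)))
  expect_equal(classify_embryo(p, tr, ct)$mode, "ND")
})

test_that("input hygiene: overlaps error, floor and cn>4 drop with warning", {
  expect_error(embryo_profile("E1", "T1", data.frame(
    chrom = "1", start = c(0, 5e6), end = c(10e6, 20e6),
    copy_number = c(3, 3))), "overlapping")
  expect_error(embryo_profile("E1", "T1", data.frame(
    chrom = "1", start = 10e6, end = 10e6, copy_number = 3)), "end <= start")
  expect_warning(p <- embryo_profile("E1", "T1", data.frame(
    chrom = "1", start = c(0, 20e6), end = c(0.5e6, 40e6),
    copy_number = c(3, 5))), "dropped 2")
  expect_equal(nrow(p$calls), 0)
})

test_that("breakpoint estimates are the median with raw-MAD dispersion", {
  tr <- toy_translocation()
  ct <- toy_chrom_tab()
  st <- signature_table(tr, ct)
  adj1 <- st$entries[["2,3,2,1"]]
  mk <- function(i, shift) {
    embryo_profile(paste0("E", i), "T1", calls_for_entry(adj1, shift))
  }
  # five embryos with the chr1 boundary at exactly 80 Mb
  est <- estimate_breakpoints(lapply(1:5, mk, shift = 0), tr, ct)
  expect_equal(est$bp1$position_bp, 80e6)
  expect_equal(est$bp1$dispersion_bp, 0)
  expect_equal(est$bp1$n_supporting_embryos, 5)
  # boundaries 79, 80, 81 Mb -> median 80 Mb, MAD 1 Mb
  ps <- mapply(mk, 1:3, shift = c(-1e6, 0, 1e6), SIMPLIFY = FALSE)
  est2 <- estimate_breakpoints(ps, tr, ct)
  expect_equal(est2$bp1$position_bp, 80e6)
  expect_equal(est2$bp1$dispersion_bp, 1e6)
  # no unbalanced embryos: estimation unavailable, fall back signalled for
  # both chromosomes
  expect_warning(expect_warning(
    est3 <- estimate_breakpoints(list(embryo_profile("E0", "T1")), tr, ct),
    "falling back"), "falling back")
  expect_null(est3$bp1)
})

test_that("median breakpoint estimation concentrates around truth", {
  # 20 unbalanced embryos per replicate, 1 Mb boundary jitter; the median
  # of ~20 jittered boundaries has SE ~ 1.25/sqrt(20) ~ 0.28 Mb, so the
  # estimate lands within 0.5 Mb of the true 80 Mb in the large majority of
  # replicates
  tr <- toy_translocation()
  ct <- toy_chrom_tab()
  st <- signature_table(tr, ct)
  adj1 <- st$entries[["2,3,2,1"]]
  set.seed(77)
  hits <- vapply(1:200, function(r) {
    ps <- lapply(1:20, function(i)
      embryo_profile(paste0("E", i), "T1",
                     calls_for_entry(adj1, shift = rnorm(1, 0, 1e6))))
    est <- estimate_breakpoints(ps, tr, ct)
    abs(est$bp1$position_bp - 80e6) < 0.5e6
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})

test_that("refined breakpoints feed the metrics", {
  tr <- toy_translocation()
  ct <- toy_chrom_tab()
  st <- signature_table(tr, ct)
  adj1 <- st$entries[["2,3,2,1"]]
  ps <- lapply(1:4, function(i)
    embryo_profile(paste0("E", i), "T1", calls_for_entry(adj1, shift = 2e6)))
  est <- estimate_breakpoints(ps, tr, ct)
  tr2 <- refine_translocation(tr, est, ct)
  expect_equal(tr2$bp1$position_bp, 82e6)
  m <- compute_metrics(tr2, ct)
  expect_equal(m$ts1, 18e6)
})
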