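test_that("ISCN parsing extracts chromosomes, arms and carrier sex", {
  tr <- parse_iscn_karyotype("46,XY,t(4;20)(q31;p12)")
  expect_s3_class(tr, "reciprocal_translocation")
  expect_equal(tr$bp1$chromosome, "4")
  expect_equal(tr$bp1$arm, "q")
  expect_equal(tr$bp2$chromosome, "20")
  expect_equal(tr$bp2$arm, "p")
  expect_equal(tr$carrier_sex, "male")
  expect_equal(parse_iscn_karyotype("46,XX,t(2;5)(q21;q13)")$carrier_sex,
               "female")
  # no sex prefix: fall back to the explicit field
  expect_equal(parse_iscn_karyotype("t(2;5)(q21;q13)",
                                    carrier_sex = "male")$carrier_sex,
               "male")
})

test_that("band labels resolve to packaged band-interval midpoints", {
  bt <- band_table()
  for (q in list(c("2", "q21"), c("5", "q13"))) {
    row <- bt[bt$chrom == q[1] & bt$band == q[2], ]
    expect_equal(resolve_band_position(q[1], q[2]),
                 floor((row$start + row$end) / 2))
  }
  tr <- parse_iscn_karyotype("46,XX,t(2;5)(q21;q13)")
  b2 <- bt[bt$chrom == "2" & bt$band == "q21", ]
  expect_equal(tr$bp1$position_bp, floor((b2$start + b2$end) / 2))
})

test_that("unsupported and malformed karyotypes raise the right errors", {
  expect_error(parse_iscn_karyotype("46,XY,t(X;1)(q22;p13)"),
               "sex-chromosome")
  expect_error(parse_iscn_karyotype("46,XY,t(4;4)(q31;p12)"),
               "one chromosome")
  expect_error(parse_iscn_karyotype("46,XY,inv(2)(p11q13)"), "cannot parse")
  expect_error(parse_iscn_karyotype("46,XY,t(4;20)(q31)"),
               "malformed translocation token")
  expect_error(parse_iscn_karyotype("46,XX,t(2;5)(q99;q13)"), "q99")
})

test_that("sub-band queries fall back to the parent band with a warning", {
  bt <- data.frame(chrom = "1", start = 50e6, end = 60e6, band = "q11")
  expect_equal(resolve_band_position("1", "q11", bt), 55e6)
  expect_warning(pos <- resolve_band_position("1", "q11.3", bt),
                 "parent band")
  expect_equal(pos, 55e6)
  err <- tryCatch(resolve_band_position("1", "q99", bt),
                  error = conditionMessage)
  expect_match(err, "q11")   # lists nearest known bands
})

test_that("segment arithmetic follows from the breakpoint definitions", {
  ct <- toy_chrom_tab()
  # chr1: 100 Mb, centromere 40-45 Mb, q-breakpoint at 80 Mb
  m <- compute_metrics(toy_translocation(), ct)
  expect_equal(m$size1, 100e6)
  expect_equal(m$ts1, 20e6)
  expect_equal(m$cs1, 80e6)
  expect_equal(m$tar1, 20 / 55)
  # chr2: 80 Mb, cen 30-35, q-breakpoint at 60 Mb
  expect_equal(m$ts2, 20e6)
  expect_equal(m$tar2, 20 / 45)
  expect_equal(m$tsr, 1)
  expect_equal(m$csr, 80 / 60)
  expect_false(m$acr_involved)
})

test_that("breakpoint 1 bp distal to the centromere gives tar ~ 1", {
  ct <- toy_chrom_tab()
  m <- compute_metrics(toy_translocation(pos1 = 45e6 + 1), ct)
  expect_equal(m$ts1, 55e6 - 1)
  expect_equal(m$tar1, (55e6 - 1) / 55e6, tolerance = 1e-9)
})

test_that("ts + cs conserves chromosome size and ratios stay in range", {
  ct <- toy_chrom_tab()
  set.seed(11)
  for (i in 1:50) {
    arm1 <- sample(c("p", "q"), 1)
    arm2 <- sample(c("p", "q"), 1)
    iv1 <- if (arm1 == "p") c(1e6, 39e6) else c(46e6, 99e6)
    iv2 <- if (arm2 == "p") c(1e6, 29e6) else c(36e6, 79e6)
    tr <- toy_translocation(pos1 = round(runif(1, iv1[1], iv1[2])),
                            pos2 = round(runif(1, iv2[1], iv2[2])),
                            arm1 = arm1, arm2 = arm2)
    m <- compute_metrics(tr, ct)
    expect_identical(m$ts1 + m$cs1, m$size1)
    expect_identical(m$ts2 + m$cs2, m$size2)
    expect_gte(m$tsr, 1); expect_gte(m$csr, 1)
    expect_true(m$tar1 > 0 && m$tar1 <= 1)
    expect_true(m$tar2 > 0 && m$tar2 <= 1)
  }
})

test_that("metric labels attach to physical chromosomes, not input order", {
  ct <- toy_chrom_tab()
  tr <- toy_translocation()
  swapped <- reciprocal_translocation(tr$bp2, tr$bp1, carrier_id = "T1",
                                      carrier_sex = "female")
  m1 <- compute_metrics(tr, ct)
  m2 <- compute_metrics(swapped, ct)
  for (f in c("size1", "size2", "ts1", "ts2", "cs1", "cs2",
              "tar1", "tar2", "tsr", "csr")) {
    expect_identical(m1[[f]], m2[[f]])
  }
  # index 1 is the longer chromosome
  expect_equal(m1$per_chromosome$chrom[1], "1")
  expect_gte(m1$size1, m1$size2)
})

test_that("acrocentric involvement is flagged from either chromosome", {
  tr <- parse_iscn_karyotype("46,XY,t(13;4)(q21;q31)")
  expect_true(compute_metrics(tr)$acr_involved)
  expect_false(compute_metrics(
    parse_iscn_karyotype("46,XY,t(4;20)(q31;p12)"))$acr_involved)
})

test_that("acrocentric p-arm breakpoints are accepted with a warning", {
  expect_warning(breakpoint("13", "p", 8e6), "acrocentric")
})

test_that("parse then format is the identity on the supported grammar", {
  for (k in c("46,XY,t(4;20)(q31;p12)", "46,XX,t(2;5)(q21;q13)",
              "46,XX,t(11;18)(q21;q12)")) {
    expect_identical(format_iscn(parse_iscn_karyotype(k)), k)
  }
})

test_that("breakpoints outside the stated arm are rejected", {
  ct <- toy_chrom_tab()
  expect_error(breakpoint("1", "q", 42e6, ct), "outside")  # in centromere
  expect_error(breakpoint("1", "q", 100e6, ct), "outside") # at chrom end
  expect_error(breakpoint("1", "p", 50e6, ct), "outside")  # wrong arm
  expect_error(breakpoint("1", "q", 0, ct), "outside")
})
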