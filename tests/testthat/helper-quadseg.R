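# Shared fixtures, built in code.

# two synthetic metacentric chromosomes with round numbers so segment
# arithmetic is checkable by hand (labels reuse autosome names because the
# parsers only accept autosomes)
toy_chrom_tab <- function() {
  data.frame(chrom = c("1", "2"),
             length = c(100e6, 80e6),
             cen_start = c(40e6, 30e6),
             cen_end = c(45e6, 35e6),
             is_acrocentric = c(FALSE, FALSE))
}

# q-breakpoints at 80 Mb (chr1) and 60 Mb (chr2)
toy_translocation <- function(pos1 = 80e6, pos2 = 60e6, arm1 = "q",
                              arm2 = "q", sex = "female", id = "T1") {
  ct <- toy_chrom_tab()
  reciprocal_translocation(breakpoint("1", arm1, pos1, ct),
                           breakpoint("2", arm2, pos2, ct),
                           carrier_id = id, carrier_sex = sex)
}

# emit CNV calls realising one signature-table entry, optionally perturbed
calls_for_entry <- function(entry, shift = 0) {
  iv <- entry$intervals
  if (!nrow(iv)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), copy_number = integer()))
  }
  data.frame(chrom = iv$chrom, start = pmax(0, iv$start + shift),
             end = iv$end + shift, copy_number = iv$copy_number)
}

# a moderate simulated cohort shared (read-only) across tests
.shared <- new.env()
shared_sim <- function() {
  if (is.null(.shared$sim)) {
    .shared$sim <- simulate_cohort(sim_config(n_carriers = 600, seed = 42))
  }
  .shared$sim
}
shared_cohort <- function() {
  if (is.null(.shared$cohort)) {
    .shared$cohort <- build_cohort_table(shared_sim())
  }
  .shared$cohort
}
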