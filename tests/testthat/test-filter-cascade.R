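base_call <- function(...) {
  # one fully-specified passing paired call, overridable field by field
  defaults <- list(
    chrom = "chr1", pos = 100L, ref = "A", alt = "C",
    sample_case = "lens", sample_control = "cornea",
    sample_control2 = NA_character_,
    depth_case = 1000L, depth_control = 1000L, depth_control2 = NA_integer_,
    alt_case = 30L, alt_fwd_case = 15L, alt_rev_case = 15L,
    alt_control = 0L, alt_control2 = NA_integer_,
    vaf_case = 0.03, vaf_control = 0, p_somatic = 1e-6,
    status = "SOMATIC", filters_failed = ""
  )
  over <- list(...)
  defaults[names(over)] <- over
  as.data.frame(defaults, stringsAsFactors = FALSE)
}

test_that("depth thresholds are inclusive for paired, strict for unpaired", {
  cfg <- filter_config()
  expect_true(depth_filter(base_call(depth_case = 300L, depth_control = 300L),
                           cfg, 1L, "paired")$pass)
  res <- depth_filter(base_call(depth_case = 299L), cfg, 1L, "paired")
  expect_false(res$pass)
  row <- res$audit[res$audit$filter == "depth_case", ]
  expect_false(row$pass)
  expect_identical(row$observed, 299)
  expect_identical(row$threshold, 300)
  # three-way: 250 for the case, 300 for each control
  c3 <- base_call(depth_case = 250L, depth_control = 300L,
                  depth_control2 = 300L, sample_control2 = "retina")
  expect_true(depth_filter(c3, cfg, 2L, "paired")$pass)
  expect_false(depth_filter(base_call(depth_case = 250L), cfg, 1L,
                            "paired")$pass)
  # unpaired is strictly greater than
  expect_false(depth_filter(base_call(depth_case = 300L), cfg,
                            mode = "unpaired")$pass)
  expect_true(depth_filter(base_call(depth_case = 301L), cfg,
                           mode = "unpaired")$pass)
})

test_that("strand support requires four reads on each strand, inclusive", {
  cfg <- filter_config()
  expect_true(strand_filter(base_call(alt_fwd_case = 4L, alt_rev_case = 4L),
                            cfg)$pass)
  expect_false(strand_filter(base_call(alt_fwd_case = 10L, alt_rev_case = 3L),
                             cfg)$pass)
  expect_false(strand_filter(base_call(alt_fwd_case = 0L, alt_rev_case = 0L),
                             cfg)$pass)
})

test_that("control absence is strict by default and configurable", {
  expect_true(control_absence_filter(base_call(alt_control = 0L),
                                     filter_config())$pass)
  expect_false(control_absence_filter(base_call(alt_control = 1L),
                                      filter_config())$pass)
  expect_true(control_absence_filter(
    base_call(alt_control = 1L),
    filter_config(control_absence_max_alt_reads = 2L))$pass)
  # two controls: both must be absent
  c2 <- base_call(sample_control2 = "retina", alt_control2 = 1L)
  expect_false(control_absence_filter(c2, filter_config())$pass)
  # missing control counts fail with a note
  res <- control_absence_filter(base_call(alt_control = NA_integer_),
                                filter_config())
  expect_false(res$pass)
  expect_identical(res$audit$note, "MISSING_CONTROL")
})

test_that("the unpaired frequency window is strict and reconfigurable", {
  cfg <- filter_config()
  expect_true(frequency_window_filter(base_call(vaf_case = 0.39), cfg)$pass)
  expect_false(frequency_window_filter(base_call(vaf_case = 0.40), cfg)$pass)
  expect_true(frequency_window_filter(base_call(vaf_case = 0.03), cfg)$pass)
  expect_false(frequency_window_filter(
    base_call(vaf_case = 0.30), cfg,
    max_freq = cfg$max_unpaired_freq_report)$pass)
})

test_that("recurrent low-VAF variants across samples are flagged everywhere", {
  cfg <- filter_config()
  # the same low-fraction variant in 35 of 39 samples
  rec <- do.call(rbind, lapply(1:35, function(i) {
    base_call(sample_case = paste0("S", i), vaf_case = 0.04)
  }))
  solo <- base_call(pos = 900L, sample_case = "S1")
  calls <- rbind(rec, solo)
  res <- recurrence_artifact_filter(calls, cfg)
  expect_identical(sum(!res$pass), 35L)
  expect_true(all(res$audit$note[!res$pass] == "RECURRENT_ARTIFACT"))
  expect_true(res$pass[nrow(calls)])
  # exactly one below the sample threshold is not flagged
  two <- do.call(rbind, lapply(1:2, function(i) {
    base_call(sample_case = paste0("S", i))
  }))
  expect_true(all(recurrence_artifact_filter(two, cfg)$pass))
  three <- do.call(rbind, lapply(1:3, function(i) {
    base_call(sample_case = paste0("S", i))
  }))
  expect_true(all(!recurrence_artifact_filter(three, cfg)$pass))
  # high-fraction occurrences do not count toward recurrence
  hi <- do.call(rbind, lapply(1:5, function(i) {
    base_call(sample_case = paste0("S", i), vaf_case = 0.5)
  }))
  expect_true(all(recurrence_artifact_filter(hi, cfg)$pass))
})

test_that("read evidence filtering discards questionable support", {
  cfg <- filter_config()
  call <- base_call(sample_case = "case", alt_case = 11L,
                    alt_fwd_case = 6L, alt_rev_case = 5L)
  make_mp <- function(ev) {
    multi_pileup(rbind(
      pileup_row("case", pos = 100L, ref = "A",
                 counts = list(A = c(495, 494), C = c(6, 5)),
                 evidence = list(C = ev)),
      pileup_row("cornea", pos = 100L, ref = "A",
                 counts = list(A = c(500, 500)))
    ))
  }
  # all supporting reads clean: pass
  clean <- evidence_table(11)
  expect_true(read_evidence_filter(call, cfg, make_mp(clean))$pass)
  # every read carries 4 mismatches: all removed, fail
  dirty <- evidence_table(11, mismatches = 4L)
  expect_false(read_evidence_filter(call, cfg, make_mp(dirty))$pass)
  # 8 clean (4 per strand) + 3 dirty: passes after removal
  mixed <- rbind(evidence_table(8, strand = rep(c("+", "-"), 4)),
                 evidence_table(3, dist_to_read_end = 2L))
  expect_true(read_evidence_filter(call, cfg, make_mp(mixed))$pass)
  # reads close to an indel are discarded
  near_indel <- evidence_table(11, dist_to_indel = 10)
  expect_false(read_evidence_filter(call, cfg, make_mp(near_indel))$pass)
  # no evidence: pass with a NO_EVIDENCE note
  res <- read_evidence_filter(call, cfg, NULL)
  expect_true(res$pass)
  expect_identical(res$audit$note, "NO_EVIDENCE")
})

test_that("the cascade keeps a clean planted somatic call end to end", {
  calls <- base_call()
  res <- run_cascade(calls, cfg = filter_config(), mode = "paired")
  expect_identical(nrow(res$passed), 1L)
  expect_identical(res$passed$filters_failed, "")
  expect_true(all(diff(res$stage_counts) <= 0))
  # audit covers every filter for the call
  expect_setequal(unique(res$audit$filter),
                  c("status_gate", "depth_case", "depth_control", "strand",
                    "control_absence", "recurrent_artifact", "read_evidence"))
})

test_that("empty input yields empty output and audit", {
  res <- run_cascade(random_calls(0L, 1), mode = "paired")
  expect_identical(nrow(res$passed), 0L)
  expect_identical(nrow(res$audit), 0L)
})

test_that("non-somatic statuses are gated out in paired mode", {
  calls <- rbind(base_call(status = "GERMLINE"),
                 base_call(pos = 200L, status = "UNKNOWN"),
                 base_call(pos = 300L, status = "LOH"))
  res <- run_cascade(calls, mode = "paired")
  expect_identical(res$passed$pos, 300L)
  expect_match(res$calls$filters_failed[res$calls$pos == 100L], "status_gate")
})

test_that("cascade is monotone and idempotent on randomized call sets", {
  for (i in 1:200) {
    n <- sample(0:20, 1)
    calls <- random_calls(n, seed = 3000 + i)
    mode <- if (i %% 2 == 0) "paired" else "unpaired"
    res <- run_cascade(calls, cfg = filter_config(), mode = mode)
    # monotone: survivors are a subset of the input
    in_ids <- with(calls, paste(chrom, pos, ref, alt, sample_case))
    out_ids <- with(res$passed, paste(chrom, pos, ref, alt, sample_case))
    expect_true(all(out_ids %in% in_ids))
    expect_true(all(diff(res$stage_counts) <= 0))
    # audit complete: every input call appears at the status gate
    expect_identical(sum(res$audit$filter == "status_gate"), nrow(calls))
    # idempotent: rerunning on the survivors changes nothing
    res2 <- run_cascade(res$passed, cfg = filter_config(), mode = mode)
    expect_identical(as.data.frame(res2$passed), as.data.frame(res$passed))
  }
})

test_that("per-call filters give the same PASS set in any order", {
  calls <- random_calls(40L, seed = 777)
  cfg <- filter_config()
  f_depth <- depth_filter(calls, cfg, 1L, "paired")$pass
  f_strand <- strand_filter(calls, cfg)$pass
  f_abs <- control_absence_filter(calls, cfg)$pass
  f_freq <- frequency_window_filter(calls, cfg)$pass
  orders <- list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3))
  sets <- lapply(orders, function(o) {
    Reduce(`&`, list(f_depth, f_strand, f_abs, f_freq)[o])
  })
  expect_identical(sets[[1]], sets[[2]])
  expect_identical(sets[[1]], sets[[3]])
})
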