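test_that("counts TSV round trip is lossless, including indels and evidence", {
  ev <- list(C = evidence_table(3, mismatches = c(0L, 1L, 4L),
                                dist_to_indel = c(Inf, 8, Inf)))
  mp <- multi_pileup(rbind(
    pileup_row("s1", pos = 1, ref = "A",
               counts = list(A = c(400, 380), C = c(2, 1), "+AG" = c(1, 2)),
               evidence = ev),
    pileup_row("s1", pos = 2, ref = "G", counts = list(G = c(250, 260))),
    pileup_row("s2", pos = 1, ref = "A", counts = list(A = c(300, 310))),
    pileup_row("s2", pos = 2, ref = "G", counts = list(G = c(100, 90)))
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(mp, path)
  back <- read_counts_tsv(path)
  expect_identical(as.data.frame(back)[names(back) != "evidence"],
                   as.data.frame(mp)[names(mp) != "evidence"])
  expect_equal(back$evidence[[1]]$C, ev$C)
  expect_true(is.infinite(back$evidence[[1]]$C$dist_to_indel[1]))
})

test_that("a header-only counts file yields an empty pileup", {
  path <- withr::local_tempfile(fileext = ".tsv")
  mp0 <- multi_pileup(pileup_row()[0, ])
  write_counts_tsv(mp0, path)
  expect_identical(length(readLines(path)), 1L)
  back <- read_counts_tsv(path)
  expect_s3_class(back, "multi_pileup")
  expect_identical(nrow(back), 0L)
})

test_that("malformed counts rows are rejected with their line number", {
  mp <- multi_pileup(rbind(
    pileup_row("s1", pos = 1, counts = list(A = c(10, 10))),
    pileup_row("s1", pos = 2, counts = list(A = c(5, 5)))
  ))
  path <- withr::local_tempfile(fileext = ".tsv")

  write_counts_tsv(mp, path)
  lines <- readLines(path)
  bad <- strsplit(lines[3], "\t")[[1]]
  bad[5] <- "999"  # depth no longer equals the count sum
  writeLines(c(lines[1:2], paste(bad, collapse = "\t")), path)
  expect_error(read_counts_tsv(path), "line 3")

  write_counts_tsv(mp, path)
  lines <- readLines(path)
  bad <- strsplit(lines[2], "\t")[[1]]
  bad[6] <- "-1"
  writeLines(c(lines[1], paste(bad, collapse = "\t"), lines[3]), path)
  expect_error(read_counts_tsv(path), "negative count at line 2")

  write_counts_tsv(mp, path)
  lines <- readLines(path)
  writeLines(c(lines, lines[2]), path)
  expect_error(read_counts_tsv(path), "duplicated.*line 4")
})

test_that("quality mask removes low-quality support and is idempotent", {
  ev <- list(C = evidence_table(3, base_quality = c(19L, 30L, 30L),
                                strand = c("+", "+", "-")))
  mp <- multi_pileup(pileup_row(
    counts = list(A = c(500, 497), C = c(2, 1)), evidence = ev))
  masked <- apply_quality_mask(mp, min_base_q = 20, min_map_q = 30)
  expect_identical(masked$C_fwd, 1L)  # the base_q-19 forward read removed
  expect_identical(masked$C_rev, 1L)
  expect_identical(masked$depth, mp$depth - 1L)
  again <- apply_quality_mask(masked, 20, 30)
  expect_identical(as.data.frame(again), as.data.frame(masked))
  # thresholds 0/0 are the identity
  expect_equal(as.data.frame(apply_quality_mask(mp, 0, 0)),
               as.data.frame(mp), ignore_attr = TRUE)
  # monotone: no count ever increases
  cols <- paste(rep(c("A", "C", "G", "T"), each = 2), c("fwd", "rev"),
                sep = "_")
  expect_true(all(as.matrix(as.data.frame(masked)[cols]) <=
                    as.matrix(as.data.frame(mp)[cols])))
})

test_that("counts without evidence pass the mask unchanged but are flagged", {
  mp <- multi_pileup(pileup_row(counts = list(A = c(500, 497), C = c(2, 1))))
  masked <- apply_quality_mask(mp)
  expect_equal(as.data.frame(masked), as.data.frame(mp), ignore_attr = TRUE)
  expect_identical(attr(masked, "no_evidence_rows"), 1L)
})

test_that("VCF output is valid and round-trips through a standard parser", {
  skip_if_not_installed("vcfR")
  calls <- call_sample_set(
    paired_pileup(case_counts = list(T = c(495, 494), C = c(6, 5)),
                  ctrl_counts = list(T = c(500, 500)),
                  pos = 32907082, ref = "T"),
    case = "case", controls = "control")
  calls$chrom <- "chr13"
  calls$filters_failed <- ""
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  expect_identical(fix$CHROM, "chr13")
  expect_identical(fix$POS, "32907082")
  expect_identical(fix$REF, "T")
  expect_identical(fix$ALT, "C")
  expect_identical(fix$FILTER, "PASS")
  info <- function(key) unname(vcfR::extract.info(v, key))
  expect_identical(info("SS"), "SOMATIC")
  expect_equal(as.numeric(info("VAFC")), calls$vaf_case, tolerance = 1e-5)
  expect_equal(as.numeric(info("VAFN")), calls$vaf_control, tolerance = 1e-5)
  expect_equal(as.numeric(info("SPV")), calls$p_somatic, tolerance = 1e-5)
  expect_identical(as.integer(info("DPC")), calls$depth_case)
  expect_identical(as.integer(info("DPN")), calls$depth_control)
  expect_identical(as.integer(info("ADF")), calls$alt_fwd_case)
  expect_identical(as.integer(info("ADR")), calls$alt_rev_case)
  expect_identical(info("SMPL"), "case")
})

test_that("an empty call list produces a header-only VCF", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(call_sample_set(paired_pileup(list(A = c(500, 500)),
                                          list(A = c(500, 500))),
                            "case", "control"), path)
  lines <- readLines(path)
  expect_true(all(startsWith(lines, "#")))
  expect_identical(sum(!startsWith(lines, "##")), 1L)
})

test_that("failed filters appear in FILTER and conflicts are rejected", {
  calls <- call_sample_set(
    paired_pileup(case_counts = list(A = c(480, 490), C = c(16, 14)),
                  ctrl_counts = list(A = c(500, 500))),
    "case", "control")
  calls$filters_failed <- "depth_case;strand"
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  body <- readLines(path)
  body <- body[!startsWith(body, "#")]
  expect_match(body, "\tdepth_case;strand\t")
  conflicting <- rbind(calls, transform(calls, vaf_case = 0.5))
  expect_error(write_vcf(conflicting, path), "conflicting duplicate")
})

test_that("samtools-mpileup text converts to stranded counts", {
  path <- withr::local_tempfile(fileext = ".pileup")
  writeLines(c(
    # . . , , C c ^I. ,+2ag T $  ->  A 3+/2-, C 1+/1-, +AG 1-, T 1+
    "chr1\t10\tA\t9\t..,,Cc^I.,+2agT$\tIIIIIIIII",
    # deletion placeholder and skipped N
    "chr1\t11\tG\t4\t.,*N\tIIII"
  ), path)
  mp <- read_mpileup(path, sample = "s1")
  r1 <- as.data.frame(mp)[mp$pos == 10, ]
  expect_identical(c(r1$A_fwd, r1$A_rev), c(3L, 2L))
  expect_identical(c(r1$C_fwd, r1$C_rev), c(1L, 1L))
  expect_identical(c(r1$T_fwd, r1$T_rev), c(1L, 0L))
  expect_identical(r1$indels[[1]][["+AG"]], c(0L, 1L))
  expect_identical(r1$depth, 9L)
  r2 <- as.data.frame(mp)[mp$pos == 11, ]
  expect_identical(c(r2$G_fwd, r2$G_rev), c(1L, 1L))
  expect_identical(r2$indels[[1]][["*"]], c(1L, 0L))
  expect_identical(r2$depth, 3L)  # N does not count toward depth
  # the converted pileup flows into the caller unchanged
  calls <- call_unpaired(multi_pileup(as.data.frame(mp)[mp$pos == 10, ]),
                         caller_params(min_coverage_case = 5L))
  expect_s3_class(calls, "variant_calls")
})

test_that("simulation truth round-trips through the truth TSV", {
  out <- plant_sim(vaf = 0.05, seed = 19, error_rate = 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(out$truth, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_identical(nrow(back), nrow(out$truth))
  expect_identical(names(back),
                   c("sample", "chrom", "pos", "ref", "alt", "class",
                     "true_vaf"))
  expect_true(any(back$class == "somatic"))
})

test_that("BED regions restrict a pileup with 0-based to 1-based conversion", {
  cfg <- sim_config(n_sites = 10, error_rate = 0, germline_het_rate = 0,
                    germline_hom_rate = 0, seed = 2)
  mp <- simulate_pileups(cfg)$pileup
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t5", bed)  # half-open [0, 5) -> 1-based positions 1..5
  sub <- restrict_to_regions(mp, bed)
  expect_identical(sort(unique(sub$pos)), 1:5)
  expect_identical(length(mp_samples(sub)), 2L)
})
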