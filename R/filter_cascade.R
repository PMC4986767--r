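#' Filter cascade configuration
#'
#' Every threshold of the post-call quality cascade. Defaults: minimum site
#' depth 300/300 (case/control) for two-way comparisons and 250/300 for
#' three-way comparisons (inclusive); unpaired candidates require depth
#' strictly greater than 300; at least 4 variant-supporting reads on each
#' strand; unpaired screening keeps allele fractions below 40% (a stricter
#' 25% reporting window is available as `max_unpaired_freq_report`); strict
#' absence of the variant allele from every control (0 alt reads); a
#' variant observed at fraction <= 10% in 3 or more distinct samples is a
#' recurrent artifact; supporting reads with more than 3 other mismatches,
#' within 10 bp of an indel, or within 5 bp of a read end are discarded by
#' the read-evidence filter.
#'
#' @param min_depth_case_2way,min_depth_control_2way Inclusive minimum
#'   depths for two-way (one control) comparisons.
#' @param min_depth_case_3way,min_depth_control_3way Inclusive minimum
#'   depths for three-way (two control) comparisons.
#' @param min_depth_unpaired Unpaired candidates must exceed this depth
#'   (strict `>`).
#' @param min_alt_per_strand Minimum variant-supporting reads required on
#'   each of the forward and reverse strands (inclusive).
#' @param max_unpaired_freq Unpaired screening window: case allele fraction
#'   must be strictly below this value.
#' @param max_unpaired_freq_report Stricter reporting window available for
#'   unpaired summaries.
#' @param max_p_unpaired Significance threshold of the unpaired screen.
#' @param control_absence_max_alt_reads Maximum variant-supporting reads
#'   tolerated in any control (0 = strict absence).
#' @param recurrence_min_samples,recurrence_max_vaf A variant seen at
#'   fraction <= `recurrence_max_vaf` in >= `recurrence_min_samples`
#'   distinct samples is flagged as a recurrent artifact everywhere.
#' @param max_read_mismatches Supporting reads with more than this many
#'   non-variant discrepancies are discarded.
#' @param read_end_margin_bp,indel_margin_bp Supporting reads whose variant
#'   base lies within these margins of a read end / an indel are discarded.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth_case_2way = 300L,
                          min_depth_control_2way = 300L,
                          min_depth_case_3way = 250L,
                          min_depth_control_3way = 300L,
                          min_depth_unpaired = 300L,
                          min_alt_per_strand = 4L,
                          max_unpaired_freq = 0.40,
                          max_unpaired_freq_report = 0.25,
                          max_p_unpaired = 0.05,
                          control_absence_max_alt_reads = 0L,
                          recurrence_min_samples = 3L,
                          recurrence_max_vaf = 0.10,
                          max_read_mismatches = 3L,
                          read_end_margin_bp = 5L,
                          indel_margin_bp = 10L) {
  stopifnot(min_depth_case_2way > 0L, min_depth_control_2way > 0L,
            min_depth_case_3way > 0L, min_depth_control_3way > 0L,
            min_depth_unpaired > 0L, min_alt_per_strand >= 0L,
            max_unpaired_freq > 0, max_unpaired_freq <= 1,
            max_unpaired_freq_report > 0, max_unpaired_freq_report <= 1,
            max_p_unpaired > 0, max_p_unpaired <= 1,
            control_absence_max_alt_reads >= 0L,
            recurrence_min_samples >= 1L,
            recurrence_max_vaf > 0, recurrence_max_vaf <= 1,
            max_read_mismatches >= 0L, read_end_margin_bp >= 0L,
            indel_margin_bp >= 0L)
  structure(as.list(environment()), class = "filter_config")
}

call_ids <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, calls$sample_case,
        sep = ":")
}

audit_rows <- function(calls, filter, pass, observed, threshold, note = "") {
  data.frame(call_id = call_ids(calls), filter = filter,
             pass = pass, observed = as.numeric(observed),
             threshold = as.numeric(threshold), note = note,
             stringsAsFactors = FALSE)
}

empty_audit <- function() {
  data.frame(call_id = character(), filter = character(), pass = logical(),
             observed = numeric(), threshold = numeric(), note = character(),
             stringsAsFactors = FALSE)
}

#' Site depth filter
#'
#' Two-way comparisons require at least `min_depth_case_2way` /
#' `min_depth_control_2way` reads at the variant position in the case and
#' control; three-way comparisons require `min_depth_case_3way` in the case
#' and `min_depth_control_3way` in each of the two controls (all
#' inclusive). Unpaired calls must exceed `min_depth_unpaired` (strict).
#'
#' @param calls A `variant_calls` data.frame.
#' @param cfg A [filter_config()].
#' @param n_controls 1 or 2 (ignored for unpaired mode).
#' @param mode `"paired"` or `"unpaired"`.
#' @return A list with `pass` (logical per call) and `audit` (one audit row
#'   per depth component per call).
#' @export
depth_filter <- function(calls, cfg = filter_config(), n_controls = 1L,
                         mode = "paired") {
  if (nrow(calls) == 0L) return(list(pass = logical(0L), audit = empty_audit()))
  if (mode == "unpaired") {
    pass <- calls$depth_case > cfg$min_depth_unpaired
    audit <- audit_rows(calls, "depth_case", pass, calls$depth_case,
                        cfg$min_depth_unpaired)
    return(list(pass = pass, audit = audit))
  }
  if (n_controls == 2L) {
    p1 <- calls$depth_case >= cfg$min_depth_case_3way
    p2 <- !is.na(calls$depth_control) &
      calls$depth_control >= cfg$min_depth_control_3way
    p3 <- !is.na(calls$depth_control2) &
      calls$depth_control2 >= cfg$min_depth_control_3way
    audit <- rbind(
      audit_rows(calls, "depth_case", p1, calls$depth_case,
                 cfg$min_depth_case_3way),
      audit_rows(calls, "depth_control", p2, calls$depth_control,
                 cfg$min_depth_control_3way),
      audit_rows(calls, "depth_control2", p3, calls$depth_control2,
                 cfg$min_depth_control_3way)
    )
    return(list(pass = p1 & p2 & p3, audit = audit))
  }
  p1 <- calls$depth_case >= cfg$min_depth_case_2way
  p2 <- !is.na(calls$depth_control) &
    calls$depth_control >= cfg$min_depth_control_2way
  audit <- rbind(
    audit_rows(calls, "depth_case", p1, calls$depth_case,
               cfg$min_depth_case_2way),
    audit_rows(calls, "depth_control", p2, calls$depth_control,
               cfg$min_depth_control_2way)
  )
  list(pass = p1 & p2, audit = audit)
}

#' Per-strand variant support filter
#'
#' Requires at least `min_alt_per_strand` variant-supporting reads on the
#' forward strand and at least as many on the reverse strand (inclusive).
#'
#' @inheritParams depth_filter
#' @return A list with `pass` and `audit`; the observed value is the weaker
#'   strand's supporting-read count.
#' @export
strand_filter <- function(calls, cfg = filter_config()) {
  if (nrow(calls) == 0L) return(list(pass = logical(0L), audit = empty_audit()))
  observed <- pmin(calls$alt_fwd_case, calls$alt_rev_case)
  pass <- calls$alt_fwd_case >= cfg$min_alt_per_strand &
    calls$alt_rev_case >= cfg$min_alt_per_strand
  list(pass = pass,
       audit = audit_rows(calls, "strand", pass, observed,
                          cfg$min_alt_per_strand))
}

#' Control absence filter
#'
#' Requires the variant allele to be (essentially) absent from every
#' control: each control's variant-supporting read count must not exceed
#' `control_absence_max_alt_reads` (default 0, i.e. strict absence). A call
#' whose control counts are unavailable fails with a `MISSING_CONTROL`
#' note.
#'
#' @inheritParams depth_filter
#' @return A list with `pass` and `audit`; the observed value is the
#'   largest control alt-read count.
#' @export
control_absence_filter <- function(calls, cfg = filter_config()) {
  if (nrow(calls) == 0L) return(list(pass = logical(0L), audit = empty_audit()))
  has2 <- !is.na(calls$sample_control2)
  alt2 <- ifelse(has2, calls$alt_control2, 0L)
  missing <- is.na(calls$alt_control) | (has2 & is.na(calls$alt_control2))
  observed <- pmax(calls$alt_control, alt2)
  pass <- !missing & observed <= cfg$control_absence_max_alt_reads
  note <- ifelse(missing, "MISSING_CONTROL", "")
  list(pass = pass,
       audit = audit_rows(calls, "control_absence", pass, observed,
                          cfg$control_absence_max_alt_reads, note))
}

#' Unpaired frequency window filter
#'
#' Keeps candidate variants whose case allele fraction is strictly below
#' the screening window (default 40%). Pass `max_freq =
#' cfg$max_unpaired_freq_report` to apply the stricter reporting window.
#'
#' @inheritParams depth_filter
#' @param max_freq Upper bound (exclusive) on the case allele fraction.
#' @return A list with `pass` and `audit`.
#' @export
frequency_window_filter <- function(calls, cfg = filter_config(),
                                    max_freq = cfg$max_unpaired_freq) {
  if (nrow(calls) == 0L) return(list(pass = logical(0L), audit = empty_audit()))
  pass <- calls$vaf_case < max_freq
  list(pass = pass,
       audit = audit_rows(calls, "frequency_window", pass, calls$vaf_case,
                          max_freq))
}

#' Cross-sample recurrence artifact filter
#'
#' The same low-fraction substitution arising independently in many samples
#' is overwhelmingly more likely to be a recurrent sequencing/alignment
#' artifact (e.g. cross-mapping between near-identical paralogues) than a
#' shared somatic event. Any (site, allele) observed at fraction
#' `<= recurrence_max_vaf` in `>= recurrence_min_samples` distinct samples
#' is flagged `RECURRENT_ARTIFACT` in every sample where it occurs.
#'
#' @param calls A `variant_calls` collection spanning multiple samples.
#' @param cfg A [filter_config()].
#' @return A list with `pass` (FALSE for flagged calls) and `audit`; the
#'   observed value is the number of distinct samples carrying the variant
#'   at low fraction.
#' @export
recurrence_artifact_filter <- function(calls, cfg = filter_config()) {
  if (nrow(calls) == 0L) return(list(pass = logical(0L), audit = empty_audit()))
  key <- paste(calls$chrom, calls$pos, calls$alt, sep = ":")
  low <- calls$vaf_case <= cfg$recurrence_max_vaf
  n_low <- vapply(
    split(ifelse(low, calls$sample_case, NA_character_), key),
    function(s) length(unique(s[!is.na(s)])), integer(1L)
  )
  observed <- as.integer(n_low[key])
  flagged <- observed >= cfg$recurrence_min_samples
  list(pass = !flagged,
       audit = audit_rows(calls, "recurrent_artifact", !flagged, observed,
                          cfg$recurrence_min_samples,
                          ifelse(flagged, "RECURRENT_ARTIFACT", "")))
}

#' Read-evidence filter
#'
#' The automated stand-in for manual inspection of the supporting reads:
#' variant-supporting reads with more than `max_read_mismatches` other
#' discrepancies, lying within `indel_margin_bp` of an indel, or within
#' `read_end_margin_bp` of a read end are discarded; the call then fails if
#' the surviving support no longer meets the per-strand minimum. Calls with
#' no attached evidence pass with a `NO_EVIDENCE` note.
#'
#' @inheritParams depth_filter
#' @param pileup Optional [multi_pileup()] holding the per-read evidence for
#'   the case samples.
#' @return A list with `pass` and `audit`; the observed value is the weaker
#'   strand's surviving supporting-read count.
#' @export
read_evidence_filter <- function(calls, cfg = filter_config(),
                                 pileup = NULL) {
  if (nrow(calls) == 0L) return(list(pass = logical(0L), audit = empty_audit()))
  n <- nrow(calls)
  pass <- rep(TRUE, n)
  observed <- rep(NA_real_, n)
  note <- rep("NO_EVIDENCE", n)
  if (!is.null(pileup) && nrow(pileup) > 0L) {
    pkey <- paste(pileup$sample, pileup$chrom, pileup$pos, sep = "\r")
    ckey <- paste(calls$sample_case, calls$chrom, calls$pos, sep = "\r")
    row_of <- match(ckey, pkey)
    for (i in seq_len(n)) {
      r <- row_of[i]
      if (is.na(r)) next
      ev <- pileup$evidence[[r]]
      tab <- if (is.null(ev)) NULL else ev[[calls$alt[i]]]
      if (is.null(tab) || nrow(tab) == 0L) next
      keep <- tab$mismatches <= cfg$max_read_mismatches &
        tab$dist_to_indel > cfg$indel_margin_bp &
        tab$dist_to_read_end > cfg$read_end_margin_bp
      if ("strand" %in% names(tab)) {
        surv_f <- sum(keep & tab$strand == "+")
        surv_r <- sum(keep & tab$strand == "-")
        observed[i] <- min(surv_f, surv_r)
        pass[i] <- surv_f >= cfg$min_alt_per_strand &
          surv_r >= cfg$min_alt_per_strand
      } else {
        # unstranded evidence: compare total survivors to the combined bound
        observed[i] <- sum(keep)
        pass[i] <- sum(keep) >= 2L * cfg$min_alt_per_strand
      }
      note[i] <- ""
    }
  }
  list(pass = pass,
       audit = audit_rows(calls, "read_evidence", pass, observed,
                          cfg$min_alt_per_strand, note))
}

#' Run the full post-call filter cascade
#'
#' Applies, in a fixed order, the status gate (paired mode keeps SOMATIC
#' and LOH calls; unpaired mode keeps calls significant at
#' `max_p_unpaired`), the depth filter, the per-strand support filter, the
#' control-absence filter (paired only), the frequency window (unpaired
#' only), the cross-sample recurrence filter and the read-evidence filter.
#' Every filter is evaluated for every input call, so the audit table is
#' complete regardless of earlier failures; a call survives iff it passes
#' everything. The cascade is monotone (output is a subset of input) and
#' idempotent on its own output.
#'
#' @param calls A `variant_calls` data.frame (typically from
#'   [call_sample_set()]).
#' @param pileup Optional [multi_pileup()] supplying read evidence.
#' @param cfg A [filter_config()].
#' @param mode `"paired"` or `"unpaired"`.
#' @param n_controls Number of controls in the design (1 or 2).
#' @return A list with `passed` (surviving calls, `filters_failed` empty),
#'   `audit` (the complete audit table), and `stage_counts` (named vector
#'   of surviving calls after each successive stage). The input calls are
#'   returned in `calls` with `filters_failed` annotated.
#' @export
run_cascade <- function(calls, pileup = NULL, cfg = filter_config(),
                        mode = c("paired", "unpaired"), n_controls = 1L) {
  mode <- match.arg(mode)
  if (is.null(calls) || nrow(calls) == 0L) {
    return(list(passed = empty_calls(), calls = empty_calls(),
                audit = empty_audit(),
                stage_counts = c(input = 0L)))
  }
  calls <- as_variant_calls(as.data.frame(calls))
  if (mode == "paired") {
    gate_pass <- calls$status %in% c("SOMATIC", "LOH")
    gate_audit <- audit_rows(calls, "status_gate", gate_pass, NA_real_,
                             NA_real_, calls$status)
  } else {
    gate_pass <- !is.na(calls$p_somatic) & calls$p_somatic <= cfg$max_p_unpaired
    gate_audit <- audit_rows(calls, "status_gate", gate_pass,
                             calls$p_somatic, cfg$max_p_unpaired)
  }
  stages <- list(status_gate = list(pass = gate_pass, audit = gate_audit),
                 depth = depth_filter(calls, cfg, n_controls, mode))
  stages$strand <- strand_filter(calls, cfg)
  if (mode == "paired") {
    stages$control_absence <- control_absence_filter(calls, cfg)
  } else {
    stages$frequency_window <- frequency_window_filter(calls, cfg)
  }
  stages$recurrent_artifact <- recurrence_artifact_filter(calls, cfg)
  stages$read_evidence <- read_evidence_filter(calls, cfg, pileup)

  audit <- do.call(rbind, lapply(stages, `[[`, "audit"))
  rownames(audit) <- NULL
  pass <- rep(TRUE, nrow(calls))
  stage_counts <- c(input = nrow(calls))
  for (nm in names(stages)) {
    pass <- pass & stages[[nm]]$pass
    stage_counts[nm] <- sum(pass)
  }
  failed <- audit[!audit$pass, , drop = FALSE]
  failed_by_call <- split(failed$filter, failed$call_id)
  ids <- call_ids(calls)
  calls$filters_failed <- vapply(ids, function(id) {
    f <- failed_by_call[[id]]
    if (is.null(f)) "" else paste(unique(f), collapse = ";")
  }, character(1L), USE.NAMES = FALSE)
  passed <- calls[pass, , drop = FALSE]
  rownames(passed) <- NULL
  class(passed) <- c("variant_calls", "data.frame")
  list(passed = passed, calls = calls, audit = audit,
       stage_counts = stage_counts)
}
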