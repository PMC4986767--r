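#' Caller parameters
#'
#' Thresholds governing genotyping and the paired/unpaired somatic tests.
#' The defaults are the standard settings for deep targeted somatic calling
#' on matched tissue pairs: minimum coverage 50x in both samples, at least 2
#' variant-supporting reads seen on 2 strands in the control and 1 in the
#' case, a minimum variant allele fraction of 0.01, homozygous calls at
#' fraction >= 0.75, purities fixed at 1.0, minimum average base quality 15
#' of the supporting reads, a genotype p-value threshold of 0.99 and a
#' somatic p-value threshold of 0.05. `error_rate` parameterises the
#' expected-error contingency table used by the unpaired screening test.
#'
#' @param min_coverage_normal,min_coverage_case Minimum read depth to call a
#'   genotype in the control / case sample.
#' @param min_reads2 Minimum variant-supporting reads.
#' @param min_strands_normal,min_strands_case Minimum number of strands
#'   carrying the variant.
#' @param min_var_freq Minimum variant allele fraction for a non-reference
#'   genotype.
#' @param min_freq_for_hom Allele fraction at or above which a genotype is
#'   called homozygous.
#' @param normal_purity,tumor_purity Sample purities; fixed at 1.0, at which
#'   the purity correction is the identity (no correction is applied).
#' @param min_avg_qual Minimum mean Phred base quality of the
#'   variant-supporting reads, applied only when per-read evidence is
#'   available.
#' @param p_value_thresh Genotype-call p-value threshold (accepted for
#'   interface completeness).
#' @param somatic_p_value Fisher exact p-value at or below which a
#'   case-only (or control-only) variant is classified SOMATIC (or LOH).
#' @param error_rate Assumed per-base error rate for the unpaired test.
#' @return A `caller_params` list.
#' @export
caller_params <- function(min_coverage_normal = 50L,
                          min_coverage_case = 50L,
                          min_reads2 = 2L,
                          min_strands_normal = 2L,
                          min_strands_case = 1L,
                          min_var_freq = 0.01,
                          min_freq_for_hom = 0.75,
                          normal_purity = 1.0,
                          tumor_purity = 1.0,
                          min_avg_qual = 15,
                          p_value_thresh = 0.99,
                          somatic_p_value = 0.05,
                          error_rate = 0.01) {
  stopifnot(min_var_freq > 0, min_var_freq < min_freq_for_hom,
            min_freq_for_hom <= 1,
            p_value_thresh > 0, p_value_thresh <= 1,
            somatic_p_value > 0, somatic_p_value <= 1,
            min_coverage_normal >= 0, min_coverage_case >= 0,
            min_reads2 >= 0, error_rate >= 0, error_rate < 1)
  structure(list(min_coverage_normal = min_coverage_normal,
                 min_coverage_case = min_coverage_case,
                 min_reads2 = min_reads2,
                 min_strands_normal = min_strands_normal,
                 min_strands_case = min_strands_case,
                 min_var_freq = min_var_freq,
                 min_freq_for_hom = min_freq_for_hom,
                 normal_purity = normal_purity,
                 tumor_purity = tumor_purity,
                 min_avg_qual = min_avg_qual,
                 p_value_thresh = p_value_thresh,
                 somatic_p_value = somatic_p_value,
                 error_rate = error_rate),
            class = "caller_params")
}

# vectorised genotype rule shared by all entry points
genotype_vec <- function(depth, alt, strands, params, role = "case") {
  min_cov <- if (role == "case") params$min_coverage_case else params$min_coverage_normal
  min_str <- if (role == "case") params$min_strands_case else params$min_strands_normal
  vaf <- ifelse(depth > 0L, alt / depth, 0)
  is_ref <- alt < params$min_reads2 | vaf < params$min_var_freq |
    strands < min_str
  gt <- ifelse(is_ref, "REF",
               ifelse(vaf >= params$min_freq_for_hom, "HOM", "HET"))
  gt[depth < min_cov] <- "LOW_COVERAGE"
  list(genotype = gt, vaf = vaf)
}

#' Call the genotype of one sample at one site
#'
#' Applies the coverage, read-support, strand-support and allele-fraction
#' thresholds: `LOW_COVERAGE` below the minimum depth; `REF` when the
#' variant has fewer than `min_reads2` supporting reads, an allele fraction
#' below `min_var_freq`, or support on fewer than the required number of
#' strands; `HOM` at fraction >= `min_freq_for_hom`; `HET` otherwise. When
#' per-read evidence for the allele is attached and its mean base quality
#' falls below `min_avg_qual`, the variant support is disregarded (genotype
#' `REF`, flagged via the `low_avg_qual` attribute).
#'
#' @param pileup_row A single-row [multi_pileup()] slice (one sample, one
#'   site).
#' @param alt The alternate allele (A/C/G/T or an indel symbol).
#' @param params A [caller_params()].
#' @param role `"case"` or `"normal"`; selects the per-sample thresholds.
#' @return A `genotype` list with elements `genotype` (one of REF, HET, HOM,
#'   LOW_COVERAGE) and `vaf`.
#' @export
call_genotype <- function(pileup_row, alt, params = caller_params(),
                          role = "case") {
  stopifnot(nrow(pileup_row) == 1L)
  if (alt == pileup_row$ref) stop("alt equals the reference allele", call. = FALSE)
  cnt <- allele_strand_counts(pileup_row, alt)
  low_qual <- FALSE
  ev <- pileup_row$evidence[[1L]]
  if (!is.null(ev) && !is.null(ev[[alt]]) && nrow(ev[[alt]]) > 0L) {
    if (mean(ev[[alt]]$base_quality) < params$min_avg_qual) {
      low_qual <- TRUE
      cnt <- c(0L, 0L)
    }
  }
  g <- genotype_vec(pileup_row$depth, sum(cnt), sum(cnt > 0L), params, role)
  out <- list(genotype = g$genotype, vaf = g$vaf)
  class(out) <- "genotype"
  attr(out, "low_avg_qual") <- low_qual
  out
}

# stranded counts c(fwd, rev) of one allele in a single pileup row
allele_strand_counts <- function(row, allele) {
  if (allele %in% BASES) {
    c(row[[paste0(allele, "_fwd")]], row[[paste0(allele, "_rev")]])
  } else {
    x <- row$indels[[1L]][[allele]]
    if (is.null(x)) c(0L, 0L) else x
  }
}

#' One-sided Fisher exact somatic p-value
#'
#' Tests whether the case sample's variant allele fraction exceeds the
#' control's, on the 2x2 table `[[ctrl_ref, ctrl_alt], [case_ref,
#' case_alt]]`. The p-value is the upper hypergeometric tail: the
#' probability, with all margins fixed, of the case carrying at least the
#' observed number of variant reads. Vectorised over its arguments.
#'
#' @param case_ref,case_alt Reference / variant-supporting read counts in
#'   the case sample.
#' @param ctrl_ref,ctrl_alt The same for the control sample.
#' @return p-values in (0, 1] (clamped away from exact 0 at the smallest
#'   representable double). An all-zero table yields p = 1 and is recorded
#'   in the `degenerate` attribute.
#' @examples
#' fisher_somatic_p(case_ref = 980, case_alt = 20,
#'                  ctrl_ref = 995, ctrl_alt = 5)
#' @export
fisher_somatic_p <- function(case_ref, case_alt, ctrl_ref, ctrl_alt) {
  n <- max(length(case_ref), length(case_alt), length(ctrl_ref),
           length(ctrl_alt))
  case_ref <- rep_len(as.numeric(case_ref), n)
  case_alt <- rep_len(as.numeric(case_alt), n)
  ctrl_ref <- rep_len(as.numeric(ctrl_ref), n)
  ctrl_alt <- rep_len(as.numeric(ctrl_alt), n)
  if (any(c(case_ref, case_alt, ctrl_ref, ctrl_alt) < 0)) {
    stop("negative counts in contingency table", call. = FALSE)
  }
  m <- ctrl_alt + case_alt            # total variant reads
  nn <- ctrl_ref + case_ref           # total reference reads
  k <- case_ref + case_alt            # case margin
  p <- stats::phyper(case_alt - 1, m, nn, k, lower.tail = FALSE)
  p <- pmin(1, pmax(p, .Machine$double.xmin))
  degenerate <- which(m + nn == 0)
  p[degenerate] <- 1
  if (length(degenerate) > 0L) attr(p, "degenerate") <- degenerate
  p
}

#' Classify a paired observation as germline, somatic or LOH
#'
#' A variant present (HET or HOM) in both case and control is germline;
#' present in the case only and significant at `somatic_p_value` it is
#' somatic; present in the control only and significant it is loss of
#' heterozygosity (LOH) — which downstream reporting counts under the
#' somatic umbrella. Anything else is UNKNOWN. Sites where either genotype
#' is LOW_COVERAGE cannot be classified and return `NA`.
#'
#' @param case_gt,ctrl_gt Genotypes (a [call_genotype()] result or one of
#'   the strings REF/HET/HOM/LOW_COVERAGE). Vectors are accepted.
#' @param p The one-sided Fisher p-value in the direction of the observed
#'   contrast (case over control for a putative somatic variant, control
#'   over case for putative LOH).
#' @param params A [caller_params()].
#' @return Status string(s): GERMLINE, SOMATIC, LOH, UNKNOWN, or `NA` for
#'   unclassifiable (low-coverage) input.
#' @export
classify_paired <- function(case_gt, ctrl_gt, p, params = caller_params()) {
  as_gt <- function(g) if (inherits(g, "genotype")) g$genotype else g
  case_gt <- as_gt(case_gt)
  ctrl_gt <- as_gt(ctrl_gt)
  n <- max(length(case_gt), length(ctrl_gt), length(p))
  case_gt <- rep_len(case_gt, n)
  ctrl_gt <- rep_len(ctrl_gt, n)
  p <- rep_len(p, n)
  pres_c <- case_gt %in% c("HET", "HOM")
  pres_n <- ctrl_gt %in% c("HET", "HOM")
  sig <- p <= params$somatic_p_value
  status <- rep("UNKNOWN", n)
  status[pres_c & pres_n] <- "GERMLINE"
  status[pres_c & !pres_n & sig] <- "SOMATIC"
  status[!pres_c & pres_n & sig] <- "LOH"
  low <- case_gt == "LOW_COVERAGE" | ctrl_gt == "LOW_COVERAGE"
  status[low] <- NA_character_
  status
}

# canonical empty variant_calls table
empty_calls <- function() {
  df <- data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), sample_case = character(),
    sample_control = character(), sample_control2 = character(),
    depth_case = integer(), depth_control = integer(),
    depth_control2 = integer(), alt_case = integer(),
    alt_fwd_case = integer(), alt_rev_case = integer(),
    alt_control = integer(), alt_control2 = integer(),
    vaf_case = numeric(), vaf_control = numeric(),
    p_somatic = numeric(), status = character(),
    filters_failed = character(), stringsAsFactors = FALSE
  )
  class(df) <- c("variant_calls", "data.frame")
  df
}

as_variant_calls <- function(df) {
  out <- empty_calls()
  if (is.null(df) || nrow(df) == 0L) return(out)
  for (nm in names(out)) if (!nm %in% names(df)) df[[nm]] <- out[[nm]][NA_integer_]
  df <- df[names(out)]
  df <- df[order(df$chrom, df$pos, df$alt, df$sample_case), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("variant_calls", "data.frame")
  df
}

#' Screen one unpaired site for a low-fraction variant
#'
#' Without a matched control, each candidate allele that clears the
#' read-support thresholds is tested against the expectation under the
#' assumed sequencing error rate: the observed `[ref, alt]` counts are
#' compared by a one-sided Fisher exact test with an expected row of
#' `[depth * (1 - e), round(depth * e)]`. The resulting calls carry status
#' `UNKNOWN` (no control evidence) and the screening p-value.
#'
#' @param pileup_row A single-row [multi_pileup()] slice.
#' @param params A [caller_params()]; `params$error_rate` is the assumed
#'   error rate `e`.
#' @return A `variant_calls` data.frame with 0 or more rows.
#' @export
call_unpaired <- function(pileup_row, params = caller_params()) {
  stopifnot(nrow(pileup_row) == 1L)
  mp <- multi_pileup(as.data.frame(pileup_row), validate = FALSE)
  call_sample_set(mp, case = mp$sample[1L], controls = character(0L),
                  params = params)
}

# mean base quality below threshold => variant support disregarded; returns
# indices (into the candidate vectors) whose support must be zeroed
low_qual_candidates <- function(view, sites, alleles, params) {
  out <- integer(0L)
  for (j in seq_along(sites)) {
    ev <- view$evidence[[sites[j]]]
    if (is.null(ev)) next
    tab <- ev[[alleles[j]]]
    if (is.null(tab) || nrow(tab) == 0L) next
    if (mean(tab$base_quality) < params$min_avg_qual) out <- c(out, j)
  }
  out
}

#' Call variants across a case/control sample design
#'
#' The main calling entry point. For every site and candidate alternate
#' allele (any allele with at least `min_reads2` supporting reads in the
#' case or a control), the case and control samples are genotyped and the
#' observation is classified:
#'
#' * with one control: GERMLINE / SOMATIC / LOH / UNKNOWN per
#'   [classify_paired()], with the one-sided Fisher p computed in the
#'   direction of the observed contrast;
#' * with two controls: SOMATIC requires the variant absent from both
#'   controls and significance against each (the reported `p_somatic` is
#'   the less significant of the two); presence in any control makes the
#'   variant GERMLINE; LOH requires presence in both controls;
#' * with no controls: the unpaired error-model screen (see
#'   [call_unpaired()]).
#'
#' Sites where any involved sample is below its minimum coverage are
#' skipped; their number is recorded in the `n_skipped_low_coverage`
#' attribute. Calls are returned in coordinate order.
#'
#' @param pileup A [multi_pileup()].
#' @param case Case sample label.
#' @param controls Zero, one or two control sample labels.
#' @param params A [caller_params()].
#' @return A `variant_calls` data.frame.
#' @export
call_sample_set <- function(pileup, case, controls = character(0L),
                            params = caller_params()) {
  stopifnot(inherits(pileup, "multi_pileup"), length(controls) <= 2L)
  missing <- setdiff(c(case, controls), mp_samples(pileup))
  if (length(missing) > 0L) {
    stop("design references missing sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vc <- mp_sample_view(pileup, case)
  vn <- lapply(controls, function(s) mp_sample_view(pileup, s))
  n <- length(vc$pos)
  if (n == 0L) return(empty_calls())
  tot_c <- vc$fwd + vc$rev
  tot_n <- lapply(vn, function(v) v$fwd + v$rev)
  ri <- match(vc$ref, BASES)

  # candidate (site, base) pairs
  support <- tot_c >= params$min_reads2
  for (tn in tot_n) support <- support | tn >= params$min_reads2
  support[cbind(seq_len(n), ri)] <- FALSE
  cand <- which(support, arr.ind = TRUE)
  sites <- cand[, 1L]
  b <- cand[, 2L]
  alleles <- BASES[b]

  build <- function(sites, alleles, a_fwd_c, a_rev_c, a_n, a_n2) {
    # genotype + classify the flattened candidates; returns calls df
    alt_c <- a_fwd_c + a_rev_c
    str_c <- (a_fwd_c > 0L) + (a_rev_c > 0L)
    depth_c <- vc$depth[sites]
    gc <- genotype_vec(depth_c, alt_c, str_c, params, "case")
    lowq <- low_qual_candidates(vc, sites, alleles, params)
    if (length(lowq) > 0L) {
      gc2 <- genotype_vec(depth_c[lowq], 0L, 0L, params, "case")
      gc$genotype[lowq] <- gc2$genotype
    }
    if (length(vn) == 0L) {
      keep <- gc$genotype %in% c("HET", "HOM")
      if (!any(keep)) return(empty_calls())
      s <- sites[keep]
      e_alt <- round(vc$depth[s] * params$error_rate)
      p <- fisher_somatic_p(case_ref = vc$depth[s] - alt_c[keep],
                            case_alt = alt_c[keep],
                            ctrl_ref = vc$depth[s] - e_alt,
                            ctrl_alt = e_alt)
      return(as_variant_calls(data.frame(
        chrom = vc$chrom[s], pos = vc$pos[s], ref = vc$ref[s],
        alt = alleles[keep], sample_case = case,
        sample_control = NA_character_, sample_control2 = NA_character_,
        depth_case = vc$depth[s], depth_control = NA_integer_,
        depth_control2 = NA_integer_, alt_case = alt_c[keep],
        alt_fwd_case = a_fwd_c[keep], alt_rev_case = a_rev_c[keep],
        alt_control = NA_integer_, alt_control2 = NA_integer_,
        vaf_case = gc$vaf[keep], vaf_control = NA_real_,
        p_somatic = as.numeric(p), status = "UNKNOWN",
        filters_failed = "", stringsAsFactors = FALSE
      )))
    }
    gn <- vector("list", length(vn))
    for (j in seq_along(vn)) {
      alt_n <- a_n[[j]]$alt
      gn[[j]] <- genotype_vec(vn[[j]]$depth[sites], alt_n,
                              a_n[[j]]$strands, params, "normal")
      lowq <- low_qual_candidates(vn[[j]], sites, alleles, params)
      if (length(lowq) > 0L) {
        g2 <- genotype_vec(vn[[j]]$depth[sites][lowq], 0L, 0L, params,
                           "normal")
        gn[[j]]$genotype[lowq] <- g2$genotype
      }
    }
    pres_c <- gc$genotype %in% c("HET", "HOM")
    low <- gc$genotype == "LOW_COVERAGE"
    pres_n <- lapply(gn, function(g) g$genotype %in% c("HET", "HOM"))
    for (g in gn) low <- low | g$genotype == "LOW_COVERAGE"

    # directional p per control, then combined per the design
    p_dir <- vector("list", length(vn))
    for (j in seq_along(vn)) {
      dn <- vn[[j]]$depth[sites]
      an <- a_n[[j]]$alt
      p_fwdir <- fisher_somatic_p(vc$depth[sites] - alt_c, alt_c,
                                  dn - an, an)
      p_revdir <- fisher_somatic_p(dn - an, an,
                                   vc$depth[sites] - alt_c, alt_c)
      p_dir[[j]] <- ifelse(pres_c & !pres_n[[j]], p_fwdir,
                           ifelse(!pres_c & pres_n[[j]], p_revdir, p_fwdir))
    }
    p <- do.call(pmax, p_dir)

    pres_any_n <- Reduce(`|`, pres_n)
    pres_all_n <- Reduce(`&`, pres_n)
    sig <- p <= params$somatic_p_value
    status <- rep("UNKNOWN", length(sites))
    status[pres_c & pres_any_n] <- "GERMLINE"
    status[pres_c & !pres_any_n & sig] <- "SOMATIC"
    status[!pres_c & pres_all_n & sig] <- "LOH"
    keep <- (pres_c | pres_any_n) & !low
    n_low <- sum((pres_c | pres_any_n) & low)
    if (!any(keep)) {
      out <- empty_calls()
      attr(out, "n_skipped_low_coverage") <- n_low
      return(out)
    }
    s <- sites[keep]
    two <- length(vn) == 2L
    out <- as_variant_calls(data.frame(
      chrom = vc$chrom[s], pos = vc$pos[s], ref = vc$ref[s],
      alt = alleles[keep], sample_case = case,
      sample_control = controls[1L],
      sample_control2 = if (two) controls[2L] else NA_character_,
      depth_case = vc$depth[s],
      depth_control = vn[[1L]]$depth[s],
      depth_control2 = if (two) vn[[2L]]$depth[s] else NA_integer_,
      alt_case = alt_c[keep],
      alt_fwd_case = a_fwd_c[keep], alt_rev_case = a_rev_c[keep],
      alt_control = a_n[[1L]]$alt[keep],
      alt_control2 = if (two) a_n[[2L]]$alt[keep] else NA_integer_,
      vaf_case = gc$vaf[keep], vaf_control = gn[[1L]]$vaf[keep],
      p_somatic = as.numeric(p[keep]), status = status[keep],
      filters_failed = "", stringsAsFactors = FALSE
    ))
    attr(out, "n_skipped_low_coverage") <- n_low
    out
  }

  a_n <- lapply(seq_along(vn), function(j) {
    f <- vn[[j]]$fwd[cbind(sites, b)]
    r <- vn[[j]]$rev[cbind(sites, b)]
    list(alt = f + r, strands = (f > 0L) + (r > 0L))
  })
  calls <- build(sites, alleles,
                 vc$fwd[cbind(sites, b)], vc$rev[cbind(sites, b)], a_n, NULL)

  # indel candidates (alleles outside A/C/G/T), handled site by site
  views <- c(list(vc), vn)
  has_indel <- Reduce(`|`, lapply(views, function(v) {
    vapply(v$indels, function(x) !is.null(x) && length(x) > 0L, logical(1L))
  }))
  idx <- which(has_indel)
  if (length(idx) > 0L) {
    isite <- integer(0L); iallele <- character(0L)
    ifc <- integer(0L); irc <- integer(0L)
    ian <- rep(list(list(alt = integer(0L), strands = integer(0L))),
               length(vn))
    for (site in idx) {
      alleles_here <- unique(unlist(lapply(views, function(v)
        names(v$indels[[site]]))))
      for (al in alleles_here) {
        get2 <- function(v) {
          x <- v$indels[[site]][[al]]
          if (is.null(x)) c(0L, 0L) else x
        }
        cc <- get2(vc)
        nn <- lapply(vn, get2)
        sup <- sum(cc) >= params$min_reads2 ||
          any(vapply(nn, sum, numeric(1L)) >= params$min_reads2)
        if (!sup) next
        isite <- c(isite, site); iallele <- c(iallele, al)
        ifc <- c(ifc, cc[1L]); irc <- c(irc, cc[2L])
        for (j in seq_along(vn)) {
          ian[[j]]$alt <- c(ian[[j]]$alt, sum(nn[[j]]))
          ian[[j]]$strands <- c(ian[[j]]$strands, sum(nn[[j]] > 0L))
        }
      }
    }
    if (length(isite) > 0L) {
      icalls <- build(isite, iallele, ifc, irc, ian, NULL)
      n_low <- sum(attr(calls, "n_skipped_low_coverage") %||% 0L,
                   attr(icalls, "n_skipped_low_coverage") %||% 0L)
      calls <- as_variant_calls(rbind(as.data.frame(calls),
                                      as.data.frame(icalls)))
      attr(calls, "n_skipped_low_coverage") <- n_low
    }
  }
  calls
}

#' @export
print.variant_calls <- function(x, ...) {
  cat(sprintf("<variant_calls> %d call(s)\n", nrow(x)))
  if (nrow(x) > 0L) {
    show <- c("chrom", "pos", "ref", "alt", "sample_case", "depth_case",
              "alt_case", "vaf_case", "p_somatic", "status",
              "filters_failed")
    print(utils::head(as.data.frame(x)[show], 10L))
    if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more calls\n")
  }
  invisible(x)
}
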