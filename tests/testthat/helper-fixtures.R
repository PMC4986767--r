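# build one pileup row from a named list of allele -> c(fwd, rev);
# alleles outside A/C/G/T go into the indels list-column
pileup_row <- function(sample = "S1", chrom = "chr1", pos = 1L, ref = "A",
                       counts = list(A = c(500L, 500L)),
                       evidence = NULL) {
  df <- data.frame(sample = sample, chrom = chrom, pos = as.integer(pos),
                   ref = ref, depth = 0L, stringsAsFactors = FALSE)
  for (b in c("A", "C", "G", "T")) {
    df[[paste0(b, "_fwd")]] <- 0L
    df[[paste0(b, "_rev")]] <- 0L
  }
  indels <- list()
  depth <- 0L
  for (al in names(counts)) {
    cc <- as.integer(counts[[al]])
    depth <- depth + sum(cc)
    if (al %in% c("A", "C", "G", "T")) {
      df[[paste0(al, "_fwd")]] <- cc[1L]
      df[[paste0(al, "_rev")]] <- cc[2L]
    } else {
      indels[[al]] <- cc
    }
  }
  df$depth <- depth
  df$indels <- list(if (length(indels) > 0L) indels else NULL)
  df$evidence <- list(evidence)
  df
}

# a one-site case/control pileup
paired_pileup <- function(case_counts, ctrl_counts, pos = 1L, ref = "A",
                          case_evidence = NULL,
                          samples = c("case", "control")) {
  multi_pileup(rbind(
    pileup_row(samples[1L], pos = pos, ref = ref, counts = case_counts,
               evidence = case_evidence),
    pileup_row(samples[2L], pos = pos, ref = ref, counts = ctrl_counts)
  ))
}

# uniform per-read evidence table for n supporting reads
evidence_table <- function(n, mismatches = 0L, dist_to_read_end = 25L,
                           dist_to_indel = Inf, base_quality = 35L,
                           mapping_quality = 60L,
                           strand = rep(c("+", "-"), length.out = n)) {
  data.frame(mismatches = rep_len(mismatches, n),
             dist_to_read_end = rep_len(dist_to_read_end, n),
             dist_to_indel = rep_len(dist_to_indel, n),
             base_quality = rep_len(base_quality, n),
             mapping_quality = rep_len(mapping_quality, n),
             strand = rep_len(strand, n),
             stringsAsFactors = FALSE)
}

# a randomised variant_calls table for cascade property tests
random_calls <- function(n, seed) {
  set.seed(seed)
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      sample_case = character(), stringsAsFactors = FALSE))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1L))
  depth_case <- sample(50:1500, n, replace = TRUE)
  alt_case <- pmin(depth_case, stats::rpois(n, 15))
  alt_fwd <- stats::rbinom(n, alt_case, 0.5)
  data.frame(
    chrom = "chr1", pos = sample.int(5000L, n),
    ref = ref, alt = alt,
    sample_case = sample(paste0("S", 1:6), n, replace = TRUE),
    sample_control = "ctrlA", sample_control2 = NA_character_,
    depth_case = depth_case,
    depth_control = sample(50:1500, n, replace = TRUE),
    depth_control2 = NA_integer_,
    alt_case = alt_case, alt_fwd_case = alt_fwd,
    alt_rev_case = alt_case - alt_fwd,
    alt_control = stats::rpois(n, 0.5), alt_control2 = NA_integer_,
    vaf_case = alt_case / depth_case,
    vaf_control = 0,
    p_somatic = stats::runif(n)^3,
    status = sample(c("SOMATIC", "LOH", "GERMLINE", "UNKNOWN"), n,
                    replace = TRUE, prob = c(0.4, 0.1, 0.3, 0.2)),
    filters_failed = "",
    stringsAsFactors = FALSE
  )
}

# simulate a case/control pair with one planted somatic variant; the plant
# allele is re-chosen if the seed happens to draw it as the reference base
plant_sim <- function(vaf, seed, n_sites = 40L, mean_depth = 1000,
                      error_rate = 0, site = 17L, depth_dispersion = 0.05) {
  for (al in c("A", "C", "G", "T")) {
    cfg <- sim_config(
      n_sites = n_sites, mean_depth = mean_depth,
      depth_dispersion = depth_dispersion, error_rate = error_rate,
      germline_het_rate = 0.01, germline_hom_rate = 0.005,
      somatic_plants = list(planted_variant(site, al, vaf,
                                            samples = "case")),
      seed = seed
    )
    out <- tryCatch(simulate_pileups(cfg), error = function(e) NULL)
    if (!is.null(out)) {
      attr(out, "plant") <- list(site = site, alt = al, vaf = vaf)
      return(out)
    }
  }
  stop("could not place plant")
}
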