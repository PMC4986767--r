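# index of the three non-ref bases for each ref base (rows in BASES order)
OTHERS <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))

#' Describe a planted somatic variant
#'
#' @param site Site index (1..`n_sites` of the simulation).
#' @param alt Alternate allele: one of A/C/G/T, or an indel symbol (any
#'   other string), which is carried through the pipeline as an opaque
#'   allele.
#' @param vaf True variant allele fraction, in (0, 0.5].
#' @param samples Sample labels carrying the clone; `NULL` (default) means
#'   the first (case) sample of the simulation.
#' @return A `planted_variant` list.
#' @export
planted_variant <- function(site, alt, vaf, samples = NULL) {
  stopifnot(length(site) == 1L, site >= 1L, is.character(alt),
            vaf > 0, vaf <= 0.5)
  structure(list(site = as.integer(site), alt = alt, vaf = vaf,
                 samples = samples),
            class = "planted_variant")
}

#' Describe a recurrent cross-sample artifact site
#'
#' Models the signature of cross-mapping errors between homologous loci: the
#' same low-fraction apparent variant shows up in a large share of otherwise
#' unrelated samples.
#'
#' @param site Site index.
#' @param alt Artifact allele (A/C/G/T, distinct from the reference base).
#' @param vaf Apparent allele fraction of the artifact, in (0, 0.25].
#' @param sample_fraction Fraction of all simulated samples affected,
#'   in (0, 1].
#' @return An `artifact_site` list.
#' @export
artifact_site <- function(site, alt, vaf, sample_fraction = 1) {
  stopifnot(length(site) == 1L, site >= 1L, is.character(alt),
            vaf > 0, vaf <= 0.25,
            sample_fraction > 0, sample_fraction <= 1)
  structure(list(site = as.integer(site), alt = alt, vaf = vaf,
                 sample_fraction = sample_fraction),
            class = "artifact_site")
}

#' Simulation configuration
#'
#' Defines the sequencing conditions the generator emulates: targeted
#' capture at roughly 1000x mean depth with overdispersed per-site coverage,
#' germline heterozygous/homozygous variants at 50%/100% allele fraction,
#' per-base substitution error, optional strand imbalance, planted somatic
#' clones and recurrent cross-sample artifact sites.
#'
#' @param n_sites Number of targeted sites.
#' @param samples Character vector of sample labels (all samples are drawn
#'   from one underlying genome, i.e. one individual).
#' @param mean_depth Mean reads per site (default 1000).
#' @param depth_dispersion Negative-binomial overdispersion of per-site
#'   depth; variance is `mu + dispersion * mu^2`. 0 gives Poisson depths.
#' @param error_rate Per-base substitution probability, in \[0, 0.05\].
#'   Errors are substitution-only; an erroneous read reports one of the
#'   three other bases uniformly.
#' @param germline_het_rate,germline_hom_rate Per-site probabilities of a
#'   germline heterozygous / homozygous variant (drawn only at sites without
#'   a plant or artifact).
#' @param somatic_plants List of [planted_variant()].
#' @param artifact_sites List of [artifact_site()].
#' @param strand_bias Probability that a read is forward-strand.
#' @param error_strand_bias Optional separate forward-strand probability for
#'   error-derived reads; `NULL` (default) uses `strand_bias`. Setting this
#'   near 0 or 1 produces strand-imbalanced artifacts that exercise the
#'   strand-support filter.
#' @param simulate_evidence Attach per-read evidence (mismatch count,
#'   distance to read end, distance to indel, base and mapping quality,
#'   strand) for variant-supporting reads.
#' @param seed Integer seed stored with the configuration.
#' @param chrom Chromosome label used for all sites.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites,
                       samples = c("case", "control"),
                       mean_depth = 1000,
                       depth_dispersion = 0.05,
                       error_rate = 0.001,
                       germline_het_rate = 3e-4,
                       germline_hom_rate = 1.5e-4,
                       somatic_plants = list(),
                       artifact_sites = list(),
                       strand_bias = 0.5,
                       error_strand_bias = NULL,
                       simulate_evidence = FALSE,
                       seed = 1L,
                       chrom = "chr1") {
  stopifnot(n_sites >= 1L, mean_depth > 0, depth_dispersion >= 0,
            error_rate >= 0, error_rate <= 0.05,
            germline_het_rate >= 0, germline_het_rate <= 1,
            germline_hom_rate >= 0, germline_hom_rate <= 1,
            germline_het_rate + germline_hom_rate <= 1,
            strand_bias >= 0, strand_bias <= 1,
            length(samples) >= 1L, !anyDuplicated(samples))
  if (!is.null(error_strand_bias)) {
    stopifnot(error_strand_bias >= 0, error_strand_bias <= 1)
  }
  for (p in somatic_plants) {
    stopifnot(inherits(p, "planted_variant"), p$site <= n_sites)
  }
  for (a in artifact_sites) {
    stopifnot(inherits(a, "artifact_site"), a$site <= n_sites)
  }
  pk <- vapply(somatic_plants, function(p) paste0(p$site, ":", p$alt),
               character(1L))
  if (anyDuplicated(pk) > 0L) {
    vafs <- split(vapply(somatic_plants, `[[`, numeric(1L), "vaf"), pk)
    if (any(vapply(vafs, function(v) length(unique(v)) > 1L, logical(1L)))) {
      stop("overlapping plants at the same (site, allele) with conflicting VAFs",
           call. = FALSE)
    }
  }
  structure(list(n_sites = as.integer(n_sites), samples = samples,
                 mean_depth = mean_depth, depth_dispersion = depth_dispersion,
                 error_rate = error_rate,
                 germline_het_rate = germline_het_rate,
                 germline_hom_rate = germline_hom_rate,
                 somatic_plants = somatic_plants,
                 artifact_sites = artifact_sites,
                 strand_bias = strand_bias,
                 error_strand_bias = error_strand_bias,
                 simulate_evidence = simulate_evidence,
                 seed = as.integer(seed), chrom = chrom),
            class = "sim_config")
}

# draw a random non-ref base for each element of ref (character vector)
pick_alt <- function(ref) {
  ri <- match(ref, BASES)
  BASES[OTHERS[cbind(ri, sample.int(3L, length(ref), replace = TRUE))]]
}

# Split a vector of error-read totals uniformly over the 3 non-ref bases.
# Returns an n x 3 integer matrix (columns align with OTHERS[ref_idx, ]).
split_errors <- function(err) {
  e1 <- stats::rbinom(length(err), err, 1 / 3)
  e2 <- stats::rbinom(length(err), err - e1, 1 / 2)
  cbind(e1, e2, err - e1 - e2)
}

clean_evidence_draw <- function(n, strand) {
  data.frame(
    mismatches = stats::rpois(n, 0.3),
    dist_to_read_end = sample(0:50, n, replace = TRUE),
    dist_to_indel = rep(Inf, n),
    base_quality = pmin(41L, pmax(2L, as.integer(round(stats::rnorm(n, 35, 3))))),
    mapping_quality = rep(60L, n),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Simulate multi-sample pileup count tables with known ground truth
#'
#' Draws, for every sample and site, a sequencing depth (negative binomial,
#' or Poisson when `depth_dispersion = 0`), allocates reads to the germline,
#' planted-somatic and artifact alleles binomially at their true allele
#' fractions, applies the substitution error process to every read
#' (including reads of homozygous alt sites, so those observe allele
#' fractions of 1 minus the error rate), and splits each allele's reads
#' across strands. All samples share one germline and artifact truth (one
#' individual); planted clones appear only in their target samples.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list with elements `pileup` (a [multi_pileup()]) and `truth`
#'   (a data.frame: sample, chrom, pos, ref, alt, class, true_vaf; class is
#'   one of `germline_het`, `germline_hom`, `somatic`, `artifact`).
#' @export
simulate_pileups <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  n <- config$n_sites
  smp <- config$samples
  chrom <- config$chrom
  pos <- seq_len(n)
  ref <- sample(BASES, n, replace = TRUE)
  ri <- match(ref, BASES)

  planted_sites <- unique(c(
    vapply(config$somatic_plants, `[[`, integer(1L), "site"),
    vapply(config$artifact_sites, `[[`, integer(1L), "site")
  ))

  # germline genotype of the shared genome (skips planted/artifact sites so
  # every planted signal has an unambiguous truth class)
  u <- stats::runif(n)
  g_class <- rep("none", n)
  g_class[u < config$germline_het_rate] <- "het"
  g_class[u >= config$germline_het_rate &
            u < config$germline_het_rate + config$germline_hom_rate] <- "hom"
  g_class[planted_sites] <- "none"
  g_idx <- which(g_class != "none")
  g_alt <- if (length(g_idx) > 0L) pick_alt(ref[g_idx]) else character(0L)

  # per-sample signal tables: site, allele, vaf, class
  base_signals <- data.frame(
    site = g_idx, allele = g_alt,
    vaf = ifelse(g_class[g_idx] == "hom", 1, 0.5),
    class = if (length(g_idx) > 0L) paste0("germline_", g_class[g_idx])
            else character(0L),
    stringsAsFactors = FALSE
  )
  signals <- stats::setNames(rep(list(base_signals), length(smp)), smp)
  add_signal <- function(sample, site, allele, vaf, class) {
    signals[[sample]] <<- rbind(
      signals[[sample]],
      data.frame(site = site, allele = allele, vaf = vaf, class = class,
                 stringsAsFactors = FALSE)
    )
  }
  for (p in config$somatic_plants) {
    targets <- if (is.null(p$samples)) smp[1L] else p$samples
    stopifnot(all(targets %in% smp))
    if (p$alt == ref[p$site]) {
      stop("planted alt equals the reference base at site ", p$site,
           call. = FALSE)
    }
    for (s in targets) add_signal(s, p$site, p$alt, p$vaf, "somatic")
  }
  for (a in config$artifact_sites) {
    if (a$alt == ref[a$site]) {
      stop("artifact alt equals the reference base at site ", a$site,
           call. = FALSE)
    }
    n_aff <- max(1L, round(a$sample_fraction * length(smp)))
    affected <- if (n_aff >= length(smp)) smp else sample(smp, n_aff)
    for (s in affected) add_signal(s, a$site, a$alt, a$vaf, "artifact")
  }

  sb <- config$strand_bias
  esb <- if (is.null(config$error_strand_bias)) sb else config$error_strand_bias
  e <- config$error_rate

  rows <- vector("list", length(smp))
  truth <- vector("list", length(smp))
  for (k in seq_along(smp)) {
    s <- smp[k]
    sig <- signals[[s]]
    sig <- sig[!duplicated(sig[c("site", "allele")]), , drop = FALSE]
    depth <- if (config$depth_dispersion == 0) {
      stats::rpois(n, config$mean_depth)
    } else {
      stats::rnbinom(n, mu = config$mean_depth,
                     size = 1 / config$depth_dispersion)
    }
    intend <- matrix(0L, n, 4L)        # signal-intended reads per base
    indel_intend <- vector("list", n)  # indel allele -> intended read count
    is_base <- sig$allele %in% BASES
    nsig_per_site <- table(factor(sig$site, levels = seq_len(n)))
    single <- sig$site %in% which(nsig_per_site == 1L)
    # common case: one signal allele at a site
    s1 <- sig[single & is_base, , drop = FALSE]
    if (nrow(s1) > 0L) {
      intend[cbind(s1$site, match(s1$allele, BASES))] <-
        stats::rbinom(nrow(s1), depth[s1$site], s1$vaf)
    }
    s1i <- sig[single & !is_base, , drop = FALSE]
    for (j in seq_len(nrow(s1i))) {
      cnt <- stats::rbinom(1L, depth[s1i$site[j]], s1i$vaf[j])
      indel_intend[[s1i$site[j]]] <- stats::setNames(cnt, s1i$allele[j])
    }
    # rare case: several signal alleles at one site -> sequential peel
    multi_sites <- as.integer(names(nsig_per_site)[nsig_per_site > 1L])
    for (site in multi_sites) {
      rows_here <- sig[sig$site == site, , drop = FALSE]
      remaining <- depth[site]
      p_remaining <- 1
      for (j in seq_len(nrow(rows_here))) {
        pj <- rows_here$vaf[j]
        cnt <- if (p_remaining <= 0) 0L else {
          stats::rbinom(1L, remaining, min(1, pj / p_remaining))
        }
        if (rows_here$allele[j] %in% BASES) {
          intend[site, match(rows_here$allele[j], BASES)] <- cnt
        } else {
          indel_intend[[site]] <- c(indel_intend[[site]],
                                    stats::setNames(cnt, rows_here$allele[j]))
        }
        remaining <- remaining - cnt
        p_remaining <- p_remaining - pj
      }
    }
    indel_tot <- vapply(indel_intend, function(x) {
      if (is.null(x)) 0L else as.integer(sum(x))
    }, integer(1L))
    ref_intend <- depth - rowSums(intend) - indel_tot
    intend[cbind(seq_len(n), ri)] <- intend[cbind(seq_len(n), ri)] + ref_intend

    # substitution errors: each intended read errs with probability e and
    # reports one of the 3 other bases uniformly
    err_in <- matrix(0L, n, 4L)
    clean <- intend
    if (e > 0) {
      for (b in 1L:4L) {
        here <- which(intend[, b] > 0L)
        if (length(here) == 0L) next
        err_out <- stats::rbinom(length(here), intend[here, b], e)
        clean[here, b] <- intend[here, b] - err_out
        spl <- split_errors(err_out)
        for (jj in 1L:3L) {
          tgt <- OTHERS[b, jj]
          err_in[here, tgt] <- err_in[here, tgt] + spl[, jj]
        }
      }
    }
    fwd <- matrix(0L, n, 4L)
    for (b in 1L:4L) {
      fwd[, b] <- stats::rbinom(n, clean[, b], sb) +
        stats::rbinom(n, err_in[, b], esb)
    }
    total <- clean + err_in
    rev <- total - fwd

    indels_col <- vector("list", n)
    for (site in which(indel_tot > 0L)) {
      x <- indel_intend[[site]]
      indels_col[[site]] <- lapply(stats::setNames(as.list(x), names(x)),
                                   function(cnt) {
        f <- stats::rbinom(1L, cnt, sb)
        as.integer(c(f, cnt - f))
      })
    }

    df <- data.frame(sample = s, chrom = chrom, pos = pos, ref = ref,
                     depth = depth, stringsAsFactors = FALSE)
    for (b in 1L:4L) {
      df[[paste0(BASES[b], "_fwd")]] <- fwd[, b]
      df[[paste0(BASES[b], "_rev")]] <- rev[, b]
    }
    df$indels <- indels_col

    if (isTRUE(config$simulate_evidence)) {
      evidence_col <- vector("list", n)
      nonref_cnt <- total
      nonref_cnt[cbind(seq_len(n), ri)] <- 0L
      ev_sites <- which(rowSums(nonref_cnt) > 0L | indel_tot > 0L)
      for (site in ev_sites) {
        ev <- list()
        for (b in which(nonref_cnt[site, ] > 0L)) {
          nf <- fwd[site, b]
          nr <- rev[site, b]
          ev[[BASES[b]]] <- clean_evidence_draw(
            nf + nr, c(rep("+", nf), rep("-", nr)))
        }
        if (!is.null(indels_col[[site]])) {
          for (allele in names(indels_col[[site]])) {
            cc <- indels_col[[site]][[allele]]
            ev[[allele]] <- clean_evidence_draw(
              sum(cc), c(rep("+", cc[1L]), rep("-", cc[2L])))
          }
        }
        evidence_col[[site]] <- ev
      }
      df$evidence <- evidence_col
    }
    rows[[k]] <- df

    tr <- sig
    truth[[k]] <- if (nrow(tr) == 0L) NULL else data.frame(
      sample = s, chrom = chrom, pos = pos[tr$site], ref = ref[tr$site],
      alt = tr$allele, class = tr$class, true_vaf = tr$vaf,
      stringsAsFactors = FALSE
    )
  }
  pileup <- multi_pileup(do.call(rbind, rows))
  truth <- do.call(rbind, truth)
  if (is.null(truth)) {
    truth <- data.frame(sample = character(), chrom = character(),
                        pos = integer(), ref = character(),
                        alt = character(), class = character(),
                        true_vaf = numeric(), stringsAsFactors = FALSE)
  }
  truth <- truth[order(truth$sample, truth$chrom, truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  list(pileup = pileup, truth = truth)
}

#' Simulate a technical-replicate aliquot pair
#'
#' Emulates splitting one well-mixed DNA sample into two aliquots that are
#' sequenced independently: both samples share an identical underlying
#' genome (germline variants, any shared plants, artifact sites) and differ
#' only by sampling noise. The truth therefore contains zero somatic
#' differences between the two samples, which is the null condition for the
#' paired caller and filter cascade.
#'
#' @param config A [sim_config()] with exactly two samples. Any
#'   `somatic_plants` must target both samples (a plant present in only one
#'   aliquot is an error); `artifact_sites` are forced to affect both.
#' @param seed Optional seed overriding `config$seed`.
#' @return As [simulate_pileups()]; the truth carries attribute
#'   `n_somatic_differences = 0`.
#' @export
simulate_aliquot_pair <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), length(config$samples) == 2L)
  for (p in config$somatic_plants) {
    targets <- if (is.null(p$samples)) config$samples[1L] else p$samples
    if (!setequal(targets, config$samples)) {
      stop("aliquot pair: planted variant at site ", p$site,
           " is not carried by both aliquots", call. = FALSE)
    }
  }
  config$artifact_sites <- lapply(config$artifact_sites, function(a) {
    a$sample_fraction <- 1
    a
  })
  out <- simulate_pileups(config, seed = seed)
  attr(out$truth, "n_somatic_differences") <- 0L
  out
}

#' Fluorescence signal model for simulated droplets
#'
#' Empty channels emit baseline noise; channels whose template is present
#' emit a high signal. Defaults (baseline 500 +/- 200, positive
#' 8000 +/- 500 units) straddle typical two-channel positivity thresholds.
#'
#' @param baseline_mean,baseline_sd Normal parameters of the empty-channel
#'   signal (truncated at 0).
#' @param positive_mean,positive_sd Normal parameters of the occupied-channel
#'   signal.
#' @return A `ddpcr_fluor_model` list.
#' @export
ddpcr_fluor_model <- function(baseline_mean = 500, baseline_sd = 200,
                              positive_mean = 8000, positive_sd = 500) {
  stopifnot(baseline_mean >= 0, positive_mean > baseline_mean,
            baseline_sd >= 0, positive_sd >= 0)
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 positive_mean = positive_mean, positive_sd = positive_sd),
            class = "ddpcr_fluor_model")
}

#' Simulate a droplet digital PCR reaction
#'
#' Template molecules are partitioned into droplets as independent Poisson
#' occupancies with means `cn * v_droplet` per channel. A droplet containing
#' at least one variant template emits a high FAM signal, one containing at
#' least one wild-type template a high HEX signal; empty channels emit
#' baseline noise.
#'
#' @param cn_wt,cn_var Wild-type / variant template concentration,
#'   copies per microlitre (>= 0).
#' @param n_droplets Number of droplets (default 15000, a typical reaction).
#' @param v_droplet Droplet volume in microlitres (default 0.00085, i.e.
#'   0.85 nL).
#' @param fluor_model A [ddpcr_fluor_model()].
#' @param seed Optional integer seed.
#' @return A [droplet_set()] with attribute `truth` recording the planted
#'   per-droplet means (`lambda_wt`, `lambda_var`) and occupancy counts.
#' @export
simulate_droplets <- function(cn_wt, cn_var, n_droplets = 15000L,
                              v_droplet = 0.00085,
                              fluor_model = ddpcr_fluor_model(),
                              seed = NULL) {
  stopifnot(cn_wt >= 0, cn_var >= 0, n_droplets > 0L, v_droplet > 0,
            inherits(fluor_model, "ddpcr_fluor_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  lambda_wt <- cn_wt * v_droplet
  lambda_var <- cn_var * v_droplet
  occ_wt <- stats::rpois(n_droplets, lambda_wt)
  occ_var <- stats::rpois(n_droplets, lambda_var)
  draw <- function(occupied) {
    pmax(0, ifelse(
      occupied > 0L,
      stats::rnorm(n_droplets, fluor_model$positive_mean,
                   fluor_model$positive_sd),
      stats::rnorm(n_droplets, fluor_model$baseline_mean,
                   fluor_model$baseline_sd)
    ))
  }
  d <- droplet_set(data.frame(
    droplet_id = seq_len(n_droplets),
    fam_signal = draw(occ_var),
    hex_signal = draw(occ_wt)
  ))
  attr(d, "truth") <- list(lambda_wt = lambda_wt, lambda_var = lambda_var,
                           n_wt_occupied = sum(occ_wt > 0L),
                           n_var_occupied = sum(occ_var > 0L))
  d
}
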