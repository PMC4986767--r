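#' Droplet set container
#'
#' @param df A data.frame with columns `droplet_id`, `fam_signal`,
#'   `hex_signal` (fluorescence units, >= 0).
#' @return A `droplet_set` data.frame.
#' @export
droplet_set <- function(df) {
  required <- c("droplet_id", "fam_signal", "hex_signal")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop("missing droplet column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  if (nrow(df) == 0L) stop("droplet set must be non-empty", call. = FALSE)
  if (any(df$fam_signal < 0) || any(df$hex_signal < 0)) {
    stop("negative fluorescence signals", call. = FALSE)
  }
  class(df) <- c("droplet_set", "data.frame")
  df
}

#' Two-channel positivity thresholds
#'
#' A droplet is variant-positive iff its FAM signal exceeds
#' `fam_min_positive` while its HEX signal stays below `hex_min_positive`;
#' wild-type-positive iff HEX is at or above the HEX threshold with FAM at
#' or below the FAM threshold; double-positive when both channels are high;
#' empty otherwise. Defaults 4000 (FAM) and 3000 (HEX) fluorescence units.
#'
#' @param fam_min_positive FAM threshold (variant channel), exclusive.
#' @param hex_min_positive HEX threshold (wild-type channel).
#' @return A `ddpcr_thresholds` list.
#' @export
ddpcr_thresholds <- function(fam_min_positive = 4000,
                             hex_min_positive = 3000) {
  stopifnot(fam_min_positive > 0, hex_min_positive > 0)
  structure(list(fam_min_positive = fam_min_positive,
                 hex_min_positive = hex_min_positive),
            class = "ddpcr_thresholds")
}

#' Classify droplets by fluorescence
#'
#' Exhaustive, mutually exclusive classification of every droplet into
#' variant-positive, wild-type-positive, double-positive or empty (see
#' [ddpcr_thresholds()]). For Poisson quantification, double-positive
#' droplets count as positive in both channels, since they contain at least
#' one template of each kind.
#'
#' @param d A [droplet_set()].
#' @param t A [ddpcr_thresholds()].
#' @return A named integer vector: `n_var_pos`, `n_wt_pos`, `n_double`,
#'   `n_empty` (summing to the droplet count).
#' @export
classify_droplets <- function(d, t = ddpcr_thresholds()) {
  stopifnot(inherits(d, "droplet_set"))
  fam_hi <- d$fam_signal > t$fam_min_positive
  hex_hi <- d$hex_signal >= t$hex_min_positive
  c(n_var_pos = sum(fam_hi & !hex_hi),
    n_wt_pos = sum(hex_hi & !fam_hi),
    n_double = sum(fam_hi & hex_hi),
    n_empty = sum(!fam_hi & !hex_hi))
}

#' Poisson absolute copy number
#'
#' With templates partitioned independently into droplets, the occupancy of
#' a channel is Poisson and the mean copies per droplet is recovered from
#' the fraction of negative droplets: `lambda = -ln(1 - n_pos / n_total)`.
#' The absolute concentration is `lambda / v_droplet`.
#'
#' @param n_channel_positive Droplets positive in the channel (including
#'   double-positives).
#' @param n_total Total droplets.
#' @param v_droplet Droplet volume in microlitres (default 0.00085).
#' @return Copies per microlitre.
#' @examples
#' poisson_copies(1500, 15000, v_droplet = 0.00085)  # 123.95 copies/uL
#' @export
poisson_copies <- function(n_channel_positive, n_total,
                           v_droplet = 0.00085) {
  stopifnot(n_total > 0L, v_droplet > 0,
            all(n_channel_positive >= 0L))
  if (any(n_channel_positive >= n_total)) {
    stop("saturated reaction: every droplet is positive, lambda is undefined",
         call. = FALSE)
  }
  lambda <- -log1p(-n_channel_positive / n_total)
  lambda / v_droplet
}

#' Variant allele fraction from absolute copy numbers
#'
#' `VAF = CN_VAR / (CN_VAR + CN_WT)`.
#'
#' @param cn_var,cn_wt Variant / wild-type concentrations (copies per
#'   microlitre, >= 0; not both zero).
#' @return The variant allele fraction in \[0, 1\].
#' @export
vaf_from_copies <- function(cn_var, cn_wt) {
  stopifnot(all(cn_var >= 0), all(cn_wt >= 0))
  if (any(cn_var + cn_wt == 0)) {
    stop("undefined VAF: both copy numbers are zero", call. = FALSE)
  }
  cn_var / (cn_var + cn_wt)
}

#' Quantify a droplet digital PCR reaction
#'
#' Classifies the droplets, recovers the per-channel mean occupancies and
#' absolute concentrations by the Poisson law, and computes the variant
#' allele fraction.
#'
#' @param d A [droplet_set()].
#' @param t A [ddpcr_thresholds()].
#' @param v_droplet Droplet volume in microlitres.
#' @return A `ddpcr_quant` list: the four classification counts, `n_total`,
#'   `lambda_var`, `lambda_wt` (mean copies per droplet), `cn_var`, `cn_wt`
#'   (copies per microlitre), `vaf` and `v_droplet`.
#' @export
quantify_droplets <- function(d, t = ddpcr_thresholds(),
                              v_droplet = 0.00085) {
  cls <- classify_droplets(d, t)
  n_total <- nrow(d)
  fam_pos <- cls[["n_var_pos"]] + cls[["n_double"]]
  hex_pos <- cls[["n_wt_pos"]] + cls[["n_double"]]
  cn_var <- poisson_copies(fam_pos, n_total, v_droplet)
  cn_wt <- poisson_copies(hex_pos, n_total, v_droplet)
  vaf <- vaf_from_copies(cn_var, cn_wt)
  structure(list(n_var_pos = cls[["n_var_pos"]],
                 n_wt_pos = cls[["n_wt_pos"]],
                 n_double = cls[["n_double"]],
                 n_empty = cls[["n_empty"]],
                 n_total = n_total,
                 lambda_var = cn_var * v_droplet,
                 lambda_wt = cn_wt * v_droplet,
                 cn_var = cn_var, cn_wt = cn_wt,
                 vaf = vaf, v_droplet = v_droplet),
            class = "ddpcr_quant")
}

#' @export
print.ddpcr_quant <- function(x, ...) {
  cat("<ddpcr_quant>\n")
  cat(sprintf("  droplets: %d (var+ %d, wt+ %d, double %d, empty %d)\n",
              x$n_total, x$n_var_pos, x$n_wt_pos, x$n_double, x$n_empty))
  cat(sprintf("  CN_VAR %.3f, CN_WT %.3f copies/uL (lambda %.4g / %.4g)\n",
              x$cn_var, x$cn_wt, x$lambda_var, x$lambda_wt))
  cat(sprintf("  VAF = %.4f (%.2f%%)\n", x$vaf, 100 * x$vaf))
  invisible(x)
}

#' Read / write droplet fluorescence CSV
#'
#' The droplet CSV has columns `droplet_id`, `fam_signal`, `hex_signal`.
#'
#' @param path CSV file path.
#' @return `read_droplet_csv` returns a [droplet_set()];
#'   `write_droplet_csv` returns `path` invisibly.
#' @export
read_droplet_csv <- function(path) {
  droplet_set(utils::read.csv(path))
}

#' @rdname read_droplet_csv
#' @param d A [droplet_set()].
#' @export
write_droplet_csv <- function(d, path) {
  stopifnot(inherits(d, "droplet_set"))
  utils::write.csv(as.data.frame(d), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
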