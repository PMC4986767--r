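#' @keywords internal
BASES <- c("A", "C", "G", "T")

#' @keywords internal
COUNT_COLS <- paste(rep(BASES, each = 2L), rep(c("fwd", "rev"), 4L), sep = "_")

#' Construct a multi-sample pileup table
#'
#' A `multi_pileup` is the pipeline's atomic observation container: one row
#' per (sample, site) holding the per-strand read count of each base, plus
#' optional indel allele counts and optional per-read supporting evidence.
#' All samples are required to cover the same ordered site list (an aligned
#' pileup), possibly with depth 0 at individual sites.
#'
#' @param df A data.frame with columns `sample`, `chrom`, `pos` (1-based),
#'   `ref` (one of A/C/G/T), `depth`, and the eight stranded count columns
#'   `A_fwd`, `A_rev`, ..., `T_rev`. Two optional list-columns are
#'   recognised: `indels` (per row, a named list mapping an indel allele
#'   symbol to an integer `c(fwd, rev)` pair) and `evidence` (per row, a
#'   named list mapping an allele to a data.frame of per-read evidence; see
#'   [read_evidence_filter()]).
#' @param validate Check the container invariants (default `TRUE`).
#'
#' @return An object of class `multi_pileup` (a data.frame), sorted by
#'   sample, chromosome and position.
#'
#' @details Invariants enforced: all counts non-negative; per row, `depth`
#'   equals the sum of the eight base counts plus any indel counts; no
#'   duplicated (sample, site) rows; every sample covers the same site list.
#'
#' @examples
#' mp <- multi_pileup(data.frame(
#'   sample = "S1", chrom = "chr1", pos = 1L, ref = "A", depth = 10L,
#'   A_fwd = 5L, A_rev = 5L, C_fwd = 0L, C_rev = 0L,
#'   G_fwd = 0L, G_rev = 0L, T_fwd = 0L, T_rev = 0L
#' ))
#' @export
multi_pileup <- function(df, validate = TRUE) {
  required <- c("sample", "chrom", "pos", "ref", "depth", COUNT_COLS)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop("missing pileup column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"indels" %in% names(df)) df$indels <- vector("list", nrow(df))
  if (!"evidence" %in% names(df)) df$evidence <- vector("list", nrow(df))
  df$pos <- as.integer(df$pos)
  df$depth <- as.integer(df$depth)
  for (cc in COUNT_COLS) df[[cc]] <- as.integer(df[[cc]])
  df <- df[order(df$sample, df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("multi_pileup", "data.frame")
  if (validate) validate_multi_pileup(df)
  df
}

#' Validate a multi_pileup's invariants
#'
#' @param mp A [multi_pileup()].
#' @return `mp`, invisibly; errors if an invariant is violated.
#' @export
validate_multi_pileup <- function(mp) {
  if (nrow(mp) == 0L) return(invisible(mp))
  cnt <- as.matrix(mp[COUNT_COLS])
  if (anyNA(cnt) || any(cnt < 0L)) stop("negative or missing allele counts", call. = FALSE)
  if (anyNA(mp$depth) || any(mp$depth < 0L)) stop("negative or missing depth", call. = FALSE)
  itot <- vapply(mp$indels, function(x) {
    if (is.null(x) || length(x) == 0L) 0L else sum(vapply(x, sum, numeric(1L)))
  }, numeric(1L))
  bad <- which(mp$depth != rowSums(cnt) + itot)
  if (length(bad) > 0L) {
    stop("depth does not equal the sum of allele counts at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  key <- paste(mp$sample, mp$chrom, mp$pos, sep = "\r")
  if (anyDuplicated(key) > 0L) stop("duplicated (sample, site) rows", call. = FALSE)
  site_key <- paste(mp$chrom, mp$pos, mp$ref, sep = "\r")
  per_sample <- split(site_key, mp$sample)
  if (length(per_sample) > 1L) {
    ref_sites <- sort(per_sample[[1L]])
    for (s in names(per_sample)[-1L]) {
      if (!identical(sort(per_sample[[s]]), ref_sites)) {
        stop("sample '", s, "' does not cover the same site list as sample '",
             names(per_sample)[1L], "'", call. = FALSE)
      }
    }
  }
  invisible(mp)
}

#' Sample labels present in a pileup
#' @param mp A [multi_pileup()].
#' @return Character vector of sample labels.
#' @export
mp_samples <- function(mp) unique(mp$sample)

#' Site table of a pileup
#' @param mp A [multi_pileup()].
#' @return A data.frame with one row per site (`chrom`, `pos`, `ref`),
#'   in coordinate order.
#' @export
mp_sites <- function(mp) {
  s <- unique(as.data.frame(mp)[c("chrom", "pos", "ref")])
  s <- s[order(s$chrom, s$pos), , drop = FALSE]
  rownames(s) <- NULL
  s
}

# Internal: matrices for one sample, rows aligned with mp_sites() order.
mp_sample_view <- function(mp, sample) {
  d <- as.data.frame(mp)[mp$sample == sample, , drop = FALSE]
  d <- d[order(d$chrom, d$pos), , drop = FALSE]
  list(
    chrom = d$chrom, pos = d$pos, ref = d$ref, depth = d$depth,
    fwd = as.matrix(d[paste0(BASES, "_fwd")]),
    rev = as.matrix(d[paste0(BASES, "_rev")]),
    indels = d$indels, evidence = d$evidence
  )
}

#' @export
print.multi_pileup <- function(x, ...) {
  cat(sprintf("<multi_pileup> %d sites x %d sample(s): %s\n",
              nrow(mp_sites(x)), length(mp_samples(x)),
              paste(mp_samples(x), collapse = ", ")))
  if (nrow(x) > 0L) {
    print(utils::head(as.data.frame(x)[c("sample", "chrom", "pos", "ref",
                                         "depth", COUNT_COLS)], 6L))
    if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  }
  invisible(x)
}
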