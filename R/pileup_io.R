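# Canonical counts TSV dialect: tab-separated, single '#'-prefixed header,
# columns sample chrom pos ref depth A_fwd A_rev ... T_rev indels evidence.
# 'indels' and 'evidence' hold JSON ('.' when empty); inside the evidence
# JSON an infinite distance-to-indel is stored as -1.
TSV_COLS <- c("sample", "chrom", "pos", "ref", "depth", COUNT_COLS,
              "indels", "evidence")

EVIDENCE_COLS <- c("mismatches", "dist_to_read_end", "dist_to_indel",
                   "base_quality", "mapping_quality", "strand")

# serialise one row's indels / evidence to a JSON cell
encode_indels <- function(x) {
  if (is.null(x) || length(x) == 0L) return(".")
  as.character(jsonlite::toJSON(lapply(x, as.integer)))
}

encode_evidence <- function(x) {
  if (is.null(x) || length(x) == 0L) return(".")
  x <- lapply(x, function(ev) {
    ev <- as.data.frame(ev)
    if ("dist_to_indel" %in% names(ev)) {
      ev$dist_to_indel[is.infinite(ev$dist_to_indel)] <- -1
    }
    ev
  })
  as.character(jsonlite::toJSON(x, dataframe = "columns", digits = NA))
}

decode_indels <- function(s) {
  if (is.na(s) || s == "." || s == "") return(NULL)
  x <- jsonlite::fromJSON(s, simplifyVector = TRUE)
  lapply(x, as.integer)
}

decode_evidence <- function(s) {
  if (is.na(s) || s == "." || s == "") return(NULL)
  x <- jsonlite::fromJSON(s, simplifyDataFrame = TRUE)
  lapply(x, function(ev) {
    ev <- as.data.frame(ev)
    if ("dist_to_indel" %in% names(ev)) {
      ev$dist_to_indel[ev$dist_to_indel < 0] <- Inf
    }
    ev
  })
}

#' Write a pileup to the counts TSV dialect
#'
#' The counts TSV is the pipeline's canonical on-disk input: one row per
#' (sample, site) with stranded per-base read counts, plus JSON-encoded
#' indel counts and per-read evidence where present. The round trip through
#' [read_counts_tsv()] is lossless.
#'
#' @param mp A [multi_pileup()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(mp, path) {
  stopifnot(inherits(mp, "multi_pileup"))
  header <- paste0("#", paste(TSV_COLS, collapse = "\t"))
  if (nrow(mp) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  df <- as.data.frame(mp)
  ind <- vapply(df$indels, encode_indels, character(1L))
  evd <- vapply(df$evidence, encode_evidence, character(1L))
  body <- do.call(paste, c(unname(df[c("sample", "chrom", "pos", "ref",
                                       "depth", COUNT_COLS)]),
                           list(ind, evd), sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a counts TSV into a multi_pileup
#'
#' Malformed rows (wrong column count, non-integer or negative counts, a
#' depth that does not equal the sum of its allele counts, duplicated
#' (sample, site) rows) are rejected with the offending line number.
#'
#' @param path Path to a file in the counts TSV dialect
#'   (see [write_counts_tsv()]).
#' @return A [multi_pileup()]. A header-only file yields an empty pileup.
#' @export
read_counts_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty counts file: ", path, call. = FALSE)
  header <- sub("^#", "", lines[[1L]])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  if (!identical(cols, TSV_COLS)) {
    miss <- setdiff(TSV_COLS, cols)
    stop("counts TSV header mismatch",
         if (length(miss) > 0L) paste0("; missing column(s): ",
                                       paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  body <- lines[-1L]
  empty_df <- function() {
    d <- data.frame(sample = character(), chrom = character(),
                    pos = integer(), ref = character(), depth = integer(),
                    stringsAsFactors = FALSE)
    for (cc in COUNT_COLS) d[[cc]] <- integer()
    multi_pileup(d)
  }
  if (length(body) == 0L) return(empty_df())
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(TSV_COLS))) {
    stop("malformed counts row at line ", which(nf != length(TSV_COLS))[1L] + 1L,
         ": expected ", length(TSV_COLS), " fields", call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = length(TSV_COLS), byrow = TRUE)
  colnames(m) <- TSV_COLS
  num_cols <- c("pos", "depth", COUNT_COLS)
  num <- suppressWarnings(
    vapply(num_cols, function(cc) as.integer(m[, cc]), integer(nrow(m)))
  )
  num <- matrix(num, nrow = nrow(m), dimnames = list(NULL, num_cols))
  bad <- which(apply(num, 1L, anyNA))
  if (length(bad) > 0L) {
    stop("non-integer count field at line ", bad[1L] + 1L, call. = FALSE)
  }
  bad <- which(apply(num[, c("depth", COUNT_COLS), drop = FALSE], 1L,
                     function(r) any(r < 0L)))
  if (length(bad) > 0L) {
    stop("negative count at line ", bad[1L] + 1L, call. = FALSE)
  }
  df <- data.frame(sample = m[, "sample"], chrom = m[, "chrom"],
                   pos = num[, "pos"], ref = m[, "ref"],
                   depth = num[, "depth"], stringsAsFactors = FALSE)
  for (cc in COUNT_COLS) df[[cc]] <- num[, cc]
  df$indels <- lapply(m[, "indels"], decode_indels)
  df$evidence <- lapply(m[, "evidence"], decode_evidence)
  itot <- vapply(df$indels, function(x) {
    if (is.null(x)) 0L else sum(vapply(x, sum, numeric(1L)))
  }, numeric(1L))
  bad <- which(df$depth != rowSums(df[COUNT_COLS]) + itot)
  if (length(bad) > 0L) {
    stop("depth does not equal the sum of allele counts at line ",
         bad[1L] + 1L, call. = FALSE)
  }
  key <- paste(df$sample, df$chrom, df$pos, sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad) > 0L) {
    stop("duplicated (sample, site) row at line ", bad[1L] + 1L, call. = FALSE)
  }
  multi_pileup(df)
}

#' Remove low-quality supporting reads from a pileup
#'
#' Applies the pre-calling quality mask: any supporting read recorded in the
#' evidence tables whose base quality or mapping quality falls below the
#' thresholds is removed, with the corresponding allele count and site depth
#' decremented. Alleles that carry counts but no per-read evidence pass
#' through unchanged and the affected rows are flagged in the
#' `no_evidence_rows` attribute of the result. The operation is idempotent
#' and never increases any count.
#'
#' @param mp A [multi_pileup()].
#' @param min_base_q Minimum Phred base quality (default 20).
#' @param min_map_q Minimum Phred mapping quality (default 30).
#' @return A masked [multi_pileup()]; attribute `no_evidence_rows` lists row
#'   indices where non-reference counts had no evidence to mask.
#' @export
apply_quality_mask <- function(mp, min_base_q = 20, min_map_q = 30) {
  stopifnot(inherits(mp, "multi_pileup"))
  if (nrow(mp) == 0L) return(mp)
  df <- as.data.frame(mp)
  no_ev <- integer(0L)
  has_ev <- which(vapply(df$evidence, function(e) !is.null(e) && length(e) > 0L,
                         logical(1L)))
  cnt <- as.matrix(df[COUNT_COLS])
  nonref_any <- vapply(seq_len(nrow(df)), function(i) {
    alt_cols <- setdiff(BASES, df$ref[i])
    any(cnt[i, c(paste0(alt_cols, "_fwd"), paste0(alt_cols, "_rev"))] > 0L) ||
      (!is.null(df$indels[[i]]) && length(df$indels[[i]]) > 0L)
  }, logical(1L))
  for (i in seq_len(nrow(df))) {
    ev <- df$evidence[[i]]
    if (is.null(ev) || length(ev) == 0L) {
      if (nonref_any[i]) no_ev <- c(no_ev, i)
      next
    }
    for (allele in names(ev)) {
      tab <- as.data.frame(ev[[allele]])
      keep <- tab$base_quality >= min_base_q & tab$mapping_quality >= min_map_q
      n_drop <- sum(!keep)
      if (n_drop == 0L) next
      if ("strand" %in% names(tab)) {
        drop_f <- sum(!keep & tab$strand == "+")
        drop_r <- n_drop - drop_f
      } else {
        # no strand annotation: take removals from the forward count first
        if (allele %in% BASES) {
          drop_f <- min(n_drop, df[[paste0(allele, "_fwd")]][i])
        } else {
          drop_f <- min(n_drop, df$indels[[i]][[allele]][1L])
        }
        drop_r <- n_drop - drop_f
      }
      if (allele %in% BASES) {
        df[[paste0(allele, "_fwd")]][i] <- df[[paste0(allele, "_fwd")]][i] - drop_f
        df[[paste0(allele, "_rev")]][i] <- df[[paste0(allele, "_rev")]][i] - drop_r
      } else {
        df$indels[[i]][[allele]] <- df$indels[[i]][[allele]] - c(drop_f, drop_r)
      }
      df$depth[i] <- df$depth[i] - n_drop
      ev[[allele]] <- tab[keep, , drop = FALSE]
      if (nrow(ev[[allele]]) == 0L) ev[[allele]] <- NULL
    }
    df$evidence[[i]] <- if (length(ev) > 0L) ev else NULL
  }
  out <- multi_pileup(df)
  attr(out, "no_evidence_rows") <- no_ev
  out
}

#' Convert samtools-mpileup text output to a multi_pileup
#'
#' A convenience converter for the single-sample six-column text format
#' (`chrom`, `pos`, `ref`, `depth`, read bases, base qualities). The read
#' bases string is parsed with the usual conventions: `.`/`,` reference
#' match on the forward/reverse strand, `ACGT`/`acgt` substitutions by
#' strand, `^X` read-start (its mapping-quality character is skipped), `$`
#' read-end, `+n<seq>`/`-n<seq>` an insertion/deletion carried by the
#' preceding read (that read is re-assigned from its base to the indel
#' allele, written `+SEQ`/`-SEQ` in upper case), `*` a deletion
#' placeholder (counted as allele `*`), and `N`/`n` skipped entirely.
#' Depth is recomputed from the parsed reads. The counts TSV remains the
#' dialect of record; this converter exists to ingest existing pileups.
#'
#' @param path Path to a samtools-mpileup text file.
#' @param sample Sample label to assign to the rows.
#' @return A [multi_pileup()].
#' @export
read_mpileup <- function(path, sample = "sample") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty mpileup file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 5L)) {
    stop("malformed mpileup row at line ",
         which(lengths(fields) < 5L)[1L], call. = FALSE)
  }
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    ref <- toupper(f[3L])
    parsed <- parse_mpileup_bases(f[5L], ref)
    row <- data.frame(sample = sample, chrom = f[1L],
                      pos = as.integer(f[2L]), ref = ref, depth = 0L,
                      stringsAsFactors = FALSE)
    for (b in BASES) {
      row[[paste0(b, "_fwd")]] <- parsed$base[b, 1L]
      row[[paste0(b, "_rev")]] <- parsed$base[b, 2L]
    }
    row$depth <- sum(parsed$base) +
      sum(vapply(parsed$indels, sum, numeric(1L)))
    row$indels <- list(if (length(parsed$indels) > 0L) parsed$indels
                       else NULL)
    out[[i]] <- row
  }
  multi_pileup(do.call(rbind, out))
}

# parse one mpileup read-bases string into stranded base and indel counts
parse_mpileup_bases <- function(bases, ref) {
  chars <- strsplit(bases, "", fixed = TRUE)[[1L]]
  base_cnt <- matrix(0L, 4L, 2L, dimnames = list(BASES, c("fwd", "rev")))
  indels <- list()
  last <- NULL  # the base and strand of the most recent read, for indels
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L           # skip the mapping-quality character too
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      seq <- paste(chars[j:(j + len - 1L)], collapse = "")
      fwd <- identical(seq, toupper(seq))
      allele <- paste0(ch, toupper(seq))
      # the carrying read was counted under its base; re-assign it
      if (!is.null(last)) {
        base_cnt[last$base, last$col] <- base_cnt[last$base, last$col] - 1L
      }
      col <- if (fwd) 1L else 2L
      if (is.null(indels[[allele]])) indels[[allele]] <- c(0L, 0L)
      indels[[allele]][col] <- indels[[allele]][col] + 1L
      last <- NULL
      i <- j + len
    } else if (ch == "*") {
      if (is.null(indels[["*"]])) indels[["*"]] <- c(0L, 0L)
      indels[["*"]][1L] <- indels[["*"]][1L] + 1L
      last <- NULL
      i <- i + 1L
    } else if (ch %in% c("N", "n")) {
      last <- NULL
      i <- i + 1L
    } else {
      fwd <- ch %in% c(".", BASES)
      base <- if (ch == ".") ref else if (ch == ",") ref else toupper(ch)
      if (base %in% BASES) {
        col <- if (fwd) 1L else 2L
        base_cnt[base, col] <- base_cnt[base, col] + 1L
        last <- list(base = base, col = col)
      } else {
        last <- NULL
      }
      i <- i + 1L
    }
  }
  list(base = base_cnt, indels = indels)
}

#' Write a simulation truth table as TSV
#'
#' Columns: sample, chrom, pos, ref, alt, class, true_vaf.
#'
#' @param truth A truth data.frame from [simulate_pileups()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read target regions from a BED file
#'
#' BED input is 0-based half-open; the returned ranges use the 1-based fully
#' closed convention of the rest of the pipeline (conversion is handled by
#' the importer).
#'
#' @param path Path to a BED file.
#' @return A [GenomicRanges::GRanges] of target regions.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Restrict a pileup to target regions
#'
#' @param mp A [multi_pileup()].
#' @param regions A `GRanges` of target regions, or a path to a BED file.
#' @return A [multi_pileup()] containing only sites that fall inside the
#'   regions.
#' @export
restrict_to_regions <- function(mp, regions) {
  if (is.character(regions)) regions <- read_bed(regions)
  if (nrow(mp) == 0L) return(mp)
  gr <- GenomicRanges::GRanges(mp$chrom, IRanges::IRanges(mp$pos, mp$pos))
  hit <- IRanges::overlapsAny(gr, regions)
  multi_pileup(as.data.frame(mp)[hit, , drop = FALSE])
}

#' Write variant calls to a VCF v4.2 file
#'
#' Somatic annotations are carried in INFO: `SS` (status), `SPV` (somatic
#' p-value), `VAFC`/`VAFN` (case/control variant allele fractions),
#' `DPC`/`DPN` (case/control depths), `ADF`/`ADR` (case alt reads on the
#' forward/reverse strand), `SMPL` (case sample) and `CTRL` (control
#' sample(s)). `FILTER` is `PASS` for calls with an empty filter audit and a
#' semicolon-joined list of failed filter names otherwise. Records are
#' written in coordinate order; exact duplicate records are collapsed and
#' conflicting duplicates rejected.
#'
#' @param calls A `variant_calls` data.frame, as returned by
#'   [call_sample_set()] (possibly annotated by [run_cascade()]).
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  meta <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=lensmosaic-",
           as.character(utils::packageVersion("lensmosaic"))),
    "##INFO=<ID=SS,Number=1,Type=String,Description=\"Somatic status (GERMLINE/SOMATIC/LOH/UNKNOWN)\">",
    "##INFO=<ID=SPV,Number=1,Type=Float,Description=\"One-sided Fisher exact somatic p-value\">",
    "##INFO=<ID=VAFC,Number=1,Type=Float,Description=\"Variant allele fraction in the case sample\">",
    "##INFO=<ID=VAFN,Number=1,Type=Float,Description=\"Variant allele fraction in the control sample\">",
    "##INFO=<ID=DPC,Number=1,Type=Integer,Description=\"Read depth in the case sample\">",
    "##INFO=<ID=DPN,Number=1,Type=Integer,Description=\"Read depth in the control sample\">",
    "##INFO=<ID=ADF,Number=1,Type=Integer,Description=\"Case alt-supporting reads, forward strand\">",
    "##INFO=<ID=ADR,Number=1,Type=Integer,Description=\"Case alt-supporting reads, reverse strand\">",
    "##INFO=<ID=SMPL,Number=1,Type=String,Description=\"Case sample label\">",
    "##INFO=<ID=CTRL,Number=.,Type=String,Description=\"Control sample label(s)\">"
  )
  hdr <- "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  if (is.null(calls) || nrow(calls) == 0L) {
    writeLines(c(meta, hdr), path)
    return(invisible(path))
  }
  calls <- calls[order(calls$chrom, calls$pos, calls$alt), , drop = FALSE]
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt,
               calls$sample_case, sep = "\r")
  if (anyDuplicated(key) > 0L) {
    dup <- split(seq_len(nrow(calls)), key)
    for (idx in dup[lengths(dup) > 1L]) {
      sub <- calls[idx, , drop = FALSE]
      if (nrow(unique(sub)) > 1L) {
        stop("conflicting duplicate VCF records at ",
             sub$chrom[1L], ":", sub$pos[1L], " ", sub$ref[1L], ">",
             sub$alt[1L], call. = FALSE)
      }
    }
    calls <- calls[!duplicated(key), , drop = FALSE]
  }
  fnum <- function(x) ifelse(is.na(x), ".", sprintf("%.6g", x))
  fint <- function(x) ifelse(is.na(x), ".", as.character(x))
  ffailed <- ifelse(is.na(calls$filters_failed) | calls$filters_failed == "",
                    "PASS", calls$filters_failed)
  ctrl <- ifelse(is.na(calls$sample_control), ".",
                 ifelse(is.na(calls$sample_control2), calls$sample_control,
                        paste(calls$sample_control, calls$sample_control2,
                              sep = ",")))
  seen <- sort(unique(unlist(strsplit(ffailed[ffailed != "PASS"], ";",
                                      fixed = TRUE))))
  filt_meta <- sprintf("##FILTER=<ID=%s,Description=\"Failed the %s filter\">",
                       seen, seen)
  info <- paste0(
    "SS=", calls$status,
    ";SPV=", fnum(calls$p_somatic),
    ";VAFC=", fnum(calls$vaf_case),
    ";VAFN=", fnum(calls$vaf_control),
    ";DPC=", fint(calls$depth_case),
    ";DPN=", fint(calls$depth_control),
    ";ADF=", fint(calls$alt_fwd_case),
    ";ADR=", fint(calls$alt_rev_case),
    ";SMPL=", calls$sample_case,
    ";CTRL=", ctrl
  )
  body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                ffailed, info, sep = "\t")
  writeLines(c(meta, filt_meta, hdr, body), path)
  invisible(path)
}
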