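#' A single sequencing read
#'
#' @param id read identifier.
#' @param seq DNA over A, C, G, T, N.
#' @param qual integer Phred qualities (one per base, 0-93) or a Phred+33
#'   encoded string.
#' @return object of class `read_record`.
#' @export
read_record <- function(id, seq, qual) {
  if (is.character(qual) && length(qual) == 1 && nchar(qual) == nchar(seq))
    qual <- utf8ToInt(qual) - 33L
  qual <- as.integer(qual)
  stopifnot(nchar(seq) == length(qual), all(qual >= 0), all(qual <= 93))
  structure(list(id = id, seq = seq, qual = qual), class = "read_record")
}

#' Read-filtering parameters
#'
#' Defaults implement the standard Illumina-era filter: ends trimmed while
#' the base quality is below 20, truncation from the second N onwards, and
#' a 30 nt minimum length after trimming; PhiX contamination is detected
#' by canonical k-mer containment against a decoy sequence.
#'
#' @param quality_threshold Phred score below which end bases are trimmed.
#' @param min_length minimum surviving read length.
#' @param phix_k k-mer size of the contaminant screen.
#' @param phix_kmer_fraction fraction of a read's valid k-mers shared with
#'   the decoy at or above which the read is flagged.
#' @param drop_mate discard the mate of a PhiX-flagged read as well.
#' @param adapters optional character vector of adapter sequences removed
#'   by exact prefix/suffix match before any other rule.
#' @return object of class `qc_params`.
#' @export
qc_params <- function(quality_threshold = 20, min_length = 30,
                      phix_k = 21, phix_kmer_fraction = 0.8,
                      drop_mate = TRUE, adapters = NULL) {
  stopifnot(quality_threshold > 0, quality_threshold <= 93, min_length >= 1,
            phix_k >= 3, phix_kmer_fraction > 0, phix_kmer_fraction <= 1)
  structure(list(quality_threshold = quality_threshold,
                 min_length = min_length, phix_k = as.integer(phix_k),
                 phix_kmer_fraction = phix_kmer_fraction,
                 drop_mate = isTRUE(drop_mate), adapters = adapters),
            class = "qc_params")
}

# core trimming rules on (seq, qual ints); returns list(seq, qual) or NULL
trim_core <- function(seq, qual, params) {
  # optional exact-match adapter clipping at either end
  if (!is.null(params$adapters)) {
    for (ad in params$adapters) {
      al <- nchar(ad)
      if (nchar(seq) >= al && substr(seq, 1, al) == ad) {
        seq <- substr(seq, al + 1, nchar(seq)); qual <- qual[-seq_len(al)]
      }
      n <- nchar(seq)
      if (n >= al && substr(seq, n - al + 1, n) == ad) {
        seq <- substr(seq, 1, n - al); qual <- qual[seq_len(n - al)]
      }
    }
  }
  # rule 1: truncate from the second N (inclusive) to the read end
  npos <- which(strsplit(seq, "")[[1]] == "N")
  if (length(npos) >= 2) {
    keep <- npos[2] - 1L
    seq <- substr(seq, 1, keep)
    qual <- qual[seq_len(keep)]
  }
  # rule 2: strip low-quality bases from the 5' then the 3' end
  ok <- qual >= params$quality_threshold
  if (!any(ok)) return(NULL)
  i <- which(ok)[1]
  j <- which(ok)[length(which(ok))]
  seq <- substr(seq, i, j)
  qual <- qual[i:j]
  # rule 3: minimum length
  if (nchar(seq) < params$min_length) return(NULL)
  list(seq = seq, qual = qual)
}

#' Trim a read by quality and N content
#'
#' Applies, in order: truncation from the second N (the N itself is
#' removed along with everything after it); per-base quality trimming
#' from the 5' end then the 3' end, stopping at the first base at or
#' above the threshold on each side; and the minimum-length filter.
#'
#' @param read a [read_record()].
#' @param params a [qc_params()].
#' @return the trimmed `read_record`, or `NULL` when discarded.
#' @export
trim_read <- function(read, params = qc_params()) {
  stopifnot(inherits(read, "read_record"))
  out <- trim_core(read$seq, read$qual, params)
  if (is.null(out)) return(NULL)
  read_record(read$id, out$seq, out$qual)
}

# vectorised trimming over a read tibble (id, seq, qual string);
# returns tibble plus logical `kept` and per-read bases trimmed
trim_reads <- function(tb, params) {
  n <- nrow(tb)
  if (n == 0)
    return(list(tb = tb, kept = logical(0), bases_trimmed = integer(0)))
  seq <- tb$seq
  qual <- tb$qual
  out_seq <- character(n)
  out_qual <- character(n)
  kept <- logical(n)
  trimmed <- integer(n)
  # fast path: no N anywhere and no quality below threshold
  min_q <- cpp_min_char(qual) - 33L
  needs <- grepl("N", seq, fixed = TRUE) |
    min_q < params$quality_threshold
  clean <- !needs & nchar(seq) >= params$min_length &
    is.null(params$adapters)
  out_seq[clean] <- seq[clean]
  out_qual[clean] <- qual[clean]
  kept[clean] <- TRUE
  for (i in which(!clean)) {
    res <- trim_core(seq[i], utf8ToInt(qual[i]) - 33L, params)
    if (!is.null(res)) {
      kept[i] <- TRUE
      out_seq[i] <- res$seq
      out_qual[i] <- intToUtf8(res$qual + 33L)
      trimmed[i] <- nchar(seq[i]) - nchar(res$seq)
    } else {
      trimmed[i] <- nchar(seq[i])
    }
  }
  list(tb = tibble::tibble(id = tb$id, seq = out_seq, qual = out_qual),
       kept = kept, bases_trimmed = trimmed)
}

#' Screen a read against a PhiX-like decoy index
#'
#' A read is flagged when the fraction of its valid (N-free) canonical
#' k-mers shared with the decoy index reaches `phix_kmer_fraction`;
#' reads with no valid k-mer are clean.
#'
#' @param read a [read_record()] or plain sequence string.
#' @param decoy_index a [build_index()] result for the decoy sequence,
#'   built with `k = phix_k`.
#' @param params a [qc_params()].
#' @return `TRUE` (flagged) or `FALSE` (clean).
#' @export
screen_phix <- function(read, decoy_index, params = qc_params()) {
  seq <- if (inherits(read, "read_record")) read$seq else read
  stopifnot(inherits(decoy_index, "kmer_index"))
  fr <- cpp_kmer_containment(seq, decoy_index$kmer, decoy_index$k,
                             params$phix_kmer_fraction)
  fr >= 0 & fr >= params$phix_kmer_fraction
}

#' Run the full paired-end quality filter
#'
#' Each read is trimmed, then screened against the decoy.  If either mate
#' of a pair is PhiX-flagged, both are removed (when `drop_mate`); when
#' only one mate survives trimming, the survivor is kept as an orphan in a
#' separate stream.  Counts are conserved:
#' `kept + discarded_short + discarded_phix == 2 * input pairs`.
#'
#' @param r1,r2 tibbles with columns `id`, `seq`, `qual` (synchronised).
#' @param params a [qc_params()].
#' @param decoy decoy sequence as a string (default the bundled
#'   pseudo-PhiX), or `NULL` to skip the contaminant screen.
#' @return list with tibbles `r1`, `r2` (surviving pairs), `orphans`,
#'   and `stats` (class `qc_stats`).
#' @export
run_qc <- function(r1, r2, params = qc_params(), decoy = phix_decoy()) {
  strip_mate <- function(id) sub("/[12]$", "", id)
  if (nrow(r1) != nrow(r2) || !all(strip_mate(r1$id) == strip_mate(r2$id)))
    stop("paired read streams are desynchronised")
  t1 <- trim_reads(r1, params)
  t2 <- trim_reads(r2, params)
  flag1 <- flag2 <- rep(FALSE, nrow(r1))
  if (!is.null(decoy)) {
    decoy_index <- build_index(decoy,
                               index_params(k = params$phix_k,
                                            retain_fraction = 1))
    if (any(t1$kept))
      flag1[t1$kept] <- screen_phix_batch(t1$tb$seq[t1$kept], decoy_index,
                                          params)
    if (any(t2$kept))
      flag2[t2$kept] <- screen_phix_batch(t2$tb$seq[t2$kept], decoy_index,
                                          params)
  }
  pair_phix <- if (params$drop_mate) flag1 | flag2 else NULL
  drop1 <- flag1; drop2 <- flag2
  if (params$drop_mate) { drop1 <- pair_phix; drop2 <- pair_phix }
  keep1 <- t1$kept & !drop1
  keep2 <- t2$kept & !drop2
  both <- keep1 & keep2
  orph1 <- keep1 & !keep2
  orph2 <- keep2 & !keep1
  n_phix <- sum(drop1 & t1$kept) + sum(drop2 & t2$kept)
  n_short <- sum(!t1$kept) + sum(!t2$kept)
  stats <- structure(list(
    input = 2L * nrow(r1),
    kept = sum(both) * 2L + sum(orph1) + sum(orph2),
    discarded_short = n_short,
    discarded_phix = n_phix,
    bases_trimmed = sum(t1$bases_trimmed[t1$kept]) +
      sum(t2$bases_trimmed[t2$kept])), class = "qc_stats")
  list(r1 = t1$tb[both, ], r2 = t2$tb[both, ],
       orphans = dplyr::bind_rows(t1$tb[orph1, ], t2$tb[orph2, ]),
       stats = stats)
}

screen_phix_batch <- function(seqs, decoy_index, params) {
  fr <- cpp_kmer_containment(seqs, decoy_index$kmer, decoy_index$k,
                             params$phix_kmer_fraction)
  fr >= 0 & fr >= params$phix_kmer_fraction
}

#' @export
print.qc_stats <- function(x, ...) {
  cat(sprintf(paste0("<qc_stats> input %d reads: kept %d, short %d, ",
                     "phix %d, %d bases trimmed\n"),
              x$input, x$kept, x$discarded_short, x$discarded_phix,
              x$bases_trimmed))
  invisible(x)
}

#' Write QC statistics as TSV and JSON
#' @param stats a `qc_stats` object.
#' @param path_tsv,path_json output files (`NULL` to skip either).
#' @return `stats`, invisibly.
#' @export
write_qc_stats <- function(stats, path_tsv = NULL, path_json = NULL) {
  df <- as.data.frame(unclass(stats))
  if (!is.null(path_tsv))
    utils::write.table(df, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(unclass(stats), path_json, auto_unbox = TRUE)
  invisible(stats)
}
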