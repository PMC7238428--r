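#' Indexing parameters
#'
#' @param k odd k-mer size (11-63; default 31).
#' @param retain_fraction fraction of input reads the variable length
#'   cut-off must retain (default 0.90).
#' @return object of class `index_params`.
#' @export
index_params <- function(k = 31, retain_fraction = 0.90) {
  k <- as.integer(k)
  stopifnot(k %% 2 == 1, k >= 11, k <= 63,
            retain_fraction > 0, retain_fraction <= 1)
  structure(list(k = k, retain_fraction = retain_fraction),
            class = "index_params")
}

#' Variable length cut-off retaining a fraction of the reads
#'
#' Returns the largest length `L` such that the proportion of reads of
#' length at least `L` is at least `retain_fraction`.  Reads shorter than
#' `L` are excluded from indexing; longer reads are truncated to `L`, so
#' the index is built from uniform-length sequences.
#'
#' @param read_lengths integer vector of read lengths (non-empty).
#' @param retain_fraction fraction in (0, 1].
#' @return the cut-off length in bases.
#' @export
length_cutoff <- function(read_lengths, retain_fraction = 0.90) {
  if (length(read_lengths) == 0) stop("no read lengths supplied")
  stopifnot(retain_fraction > 0, retain_fraction <= 1)
  n <- length(read_lengths)
  # proportion of reads >= L is non-increasing in L: scan candidates from top
  cand <- sort(unique(read_lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(read_lengths >= L) / n >= retain_fraction) return(as.integer(L))
  }
  as.integer(min(read_lengths))
}

#' Build a canonical k-mer count index from QC-passed reads
#'
#' Applies the variable length cut-off, truncates retained reads to it,
#' and counts canonical k-mers (the lexicographic minimum of a k-mer and
#' its reverse complement).  Windows containing N contribute nothing.
#' Counts saturate at the 32-bit limit rather than wrapping.
#'
#' @param reads character vector of read sequences, or a tibble with a
#'   `seq` column, or a list of such tibbles (e.g. `r1`, `r2` and orphans).
#' @param params an [index_params()].
#' @return object of class `kmer_index` with fields `k`, `length_cutoff`,
#'   `kmer` (sorted), `count`, `total_kmers`, `reads_indexed`.
#' @export
build_index <- function(reads, params = index_params()) {
  stopifnot(inherits(params, "index_params"))
  seqs <- gather_seqs(reads)
  if (length(seqs) == 0) stop("no reads to index")
  lens <- nchar(seqs)
  cutoff <- length_cutoff(lens, params$retain_fraction)
  if (params$k > cutoff)
    stop("k (", params$k, ") exceeds the length cut-off (", cutoff, ")")
  keep <- lens >= cutoff
  seqs <- substring(seqs[keep], 1, cutoff)
  counts <- cpp_count_kmers(seqs, params$k)
  structure(list(k = params$k, length_cutoff = cutoff,
                 kmer = counts$kmer, count = counts$count,
                 total_kmers = sum(as.double(counts$count)),
                 reads_indexed = sum(keep)),
            class = "kmer_index")
}

gather_seqs <- function(reads) {
  if (is.character(reads)) return(toupper(reads))
  if (is.data.frame(reads)) return(toupper(reads$seq))
  if (is.list(reads))
    return(unlist(lapply(reads, gather_seqs), use.names = FALSE))
  stop("unsupported reads container")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf(paste0("<kmer_index> k=%d, cutoff=%d, %d distinct k-mers, ",
                     "%.0f total, %d reads\n"),
              x$k, x$length_cutoff, length(x$kmer), x$total_kmers,
              x$reads_indexed))
  invisible(x)
}

#' Look up counts for a set of k-mers
#'
#' Queries are canonicalised before lookup; absent k-mers return 0.
#'
#' @param index a `kmer_index`.
#' @param kmers character vector of k-mers.
#' @return integer vector of counts.
#' @export
index_lookup <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"))
  rc <- revcomp(kmers)
  canon <- ifelse(kmers <= rc, kmers, rc)
  i <- match(canon, index$kmer)
  out <- index$count[i]
  out[is.na(out)] <- 0L
  out
}

#' Count spectrum of an index
#'
#' @param index a `kmer_index`.
#' @return tibble with columns `count` and `n_kmers` (histogram of the
#'   k-mer count spectrum), useful for choosing coverage thresholds.
#' @export
count_spectrum <- function(index) {
  tb <- table(index$count)
  tibble::tibble(count = as.integer(names(tb)), n_kmers = as.integer(tb))
}

#' Write / read an index as a versioned TSV cache
#'
#' The header line carries a magic tag, format version, `k` and the length
#' cut-off so a stale or foreign cache is refused on read.
#'
#' @param index a `kmer_index`.
#' @param path file path.
#' @return `path` (write) or the restored `kmer_index` (read).
#' @export
write_index <- function(index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#genoskim_index\t1\t%d\t%d\t%d", index$k,
                     index$length_cutoff, index$reads_indexed), con)
  utils::write.table(data.frame(kmer = index$kmer, count = index$count),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  if (hdr[1] != "#genoskim_index" || hdr[2] != "1")
    stop("not a genoskim index cache (or unsupported version)")
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          colClasses = c("character", "integer"))
  structure(list(k = as.integer(hdr[3]), length_cutoff = as.integer(hdr[4]),
                 kmer = df$kmer, count = df$count,
                 total_kmers = sum(as.double(df$count)),
                 reads_indexed = as.integer(hdr[5])),
            class = "kmer_index")
}
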