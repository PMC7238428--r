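# Independent oracles and fixture builders.  These deliberately avoid the
# package's own C++ kernels: reverse complement and translation go through
# Biostrings, alignment through a plain-R dynamic program, enumeration by
# brute force.

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

oracle_translate <- function(x) {
  x <- substr(x, 1, 3 * (nchar(x) %/% 3))
  suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(x),
                          if.fuzzy.codon = "X")))
}

oracle_canon <- function(kmer) {
  rc <- oracle_revcomp(kmer)
  if (kmer <= rc) kmer else rc
}

# enumerate canonical k-mers of a sequence by hand (N windows skipped)
oracle_kmers <- function(seq, k, circular = FALSE) {
  if (circular) seq <- paste0(seq, substr(seq, 1, k - 1))
  n <- nchar(seq)
  if (n < k) return(character(0))
  win <- substring(seq, 1:(n - k + 1), k:n)
  win <- win[!grepl("[^ACGT]", win)]
  vapply(win, oracle_canon, "", USE.NAMES = FALSE)
}

random_peptide <- function(n, first_m = TRUE) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  p <- paste(sample(aa, n, replace = TRUE), collapse = "")
  if (first_m) p <- paste0("M", substr(p, 2, n))
  p
}

random_read <- function(len = 101, n_prob = 0.05, q_lo = 2, q_hi = 40) {
  seq <- paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                      prob = c(rep((1 - n_prob) / 4, 4), n_prob)),
               collapse = "")
  read_record("r", seq, sample(q_lo:q_hi, len, replace = TRUE))
}

# truth sequence of a feature (strandedness applied)
feature_seq <- function(genome, label, copy = 1) {
  f <- genome$features[genome$features$label == label &
                         genome$features$copy == copy, ]
  s <- substring(genome$sequence, f$start + 1, f$end)
  if (f$strand == "-") s <- oracle_revcomp(s)
  s
}

# all sequences equivalent to a quadripartite plastome truth under
# rotation, strand flip and the SSC-orientation isomer
plastome_variants <- function(truth, lsc, ir, ssc) {
  flip <- paste0(substring(truth, 1, lsc + ir),
                 oracle_revcomp(substring(truth, lsc + ir + 1,
                                          lsc + ir + ssc)),
                 substring(truth, lsc + ir + ssc + 1, nchar(truth)))
  vars <- c(truth, flip)
  c(vars, vapply(vars, oracle_revcomp, ""))
}

plastome_equivalent <- function(assembled, truth, lsc, ir, ssc) {
  if (is.null(assembled)) return(FALSE)
  if (nchar(assembled) != nchar(truth)) return(FALSE)
  for (v in plastome_variants(truth, lsc, ir, ssc)) {
    if (grepl(assembled, paste0(v, v), fixed = TRUE)) return(TRUE)
  }
  FALSE
}

circular_equivalent <- function(assembled, truth) {
  if (is.null(assembled) || nchar(assembled) != nchar(truth)) return(FALSE)
  grepl(assembled, paste0(truth, truth), fixed = TRUE) ||
    grepl(assembled, paste0(oracle_revcomp(truth), oracle_revcomp(truth)),
          fixed = TRUE)
}

# plain-R affine-gap local alignment returning the best score; gap of
# length L costs open + (L - 1) * ext
oracle_sw_score <- function(a, b, mat, open, ext) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + open, E[i, j - 1] + ext)
      F[i, j] <- max(H[i - 1, j] + open, F[i - 1, j] + ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# brute-force two-sided Fisher p for a 2x2 table, from first principles
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  prob <- function(x) choose(m, x) * choose(n, k - x) / choose(m + n, k)
  p_obs <- prob(a)
  xs <- lo:hi
  ps <- vapply(xs, prob, 0)
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# default toy spec used across tests: a small quadripartite plastome with
# planted matK/rbcL, a 2-copy rDNA array and nuclear background
toy_spec <- function(seed = 1, matk = NULL, rbcl = NULL, ...) {
  defaults <- list(lsc_len = 4000, ssc_len = 1500, ir_len = 800,
                   nuclear_len = 8000,
                   rdna_subregion_lens = c(500, 200, 150, 220, 700),
                   rdna_flank_len = 600, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  genes <- list()
  if (!is.null(matk))
    genes <- c(genes, list(list(name = "matK", peptide = matk,
                                region = "LSC")))
  if (!is.null(rbcl))
    genes <- c(genes, list(list(name = "rbcL", peptide = rbcl,
                                region = "LSC")))
  args$planted_genes <- genes
  do.call(genome_spec, args)
}
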