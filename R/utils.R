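#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors; characters
#' other than A, C, G, T map to N.
#'
#' @param x character vector of DNA sequences (upper case).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  cpp_revcomp(x)
}

#' Translate DNA to amino acids (standard code)
#'
#' Translates in frame 0; trailing bases short of a codon are dropped.
#' Codons containing non-ACGT characters translate to X; stops to `*`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of peptide sequences.
#' @export
translate_dna <- function(x) {
  stopifnot(is.character(x))
  cpp_translate(x)
}

# random DNA of length n at a given GC fraction (uses the current RNG state)
random_dna <- function(n, gc = 0.37) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# inverse genetic code: amino acid -> codons (standard code, no ambiguity)
codons_by_aa <- function() {
  code <- Biostrings::GENETIC_CODE
  split(names(code), unname(code))
}

# reverse-translate a peptide, sampling synonymous codons with the current RNG
reverse_translate <- function(peptide) {
  tab <- codons_by_aa()
  aas <- strsplit(peptide, "")[[1]]
  bad <- setdiff(aas, names(tab))
  if (length(bad) > 0)
    stop("peptide contains letters without codons: ",
         paste(unique(bad), collapse = ", "))
  paste(vapply(aas, function(a) {
    cs <- tab[[a]]
    cs[sample.int(length(cs), 1)]
  }, character(1)), collapse = "")
}

# rotate a circular sequence so it starts at 0-based offset `at`
rotate_seq <- function(seq, at) {
  n <- nchar(seq)
  at <- at %% n
  if (at == 0) return(seq)
  paste0(substr(seq, at + 1, n), substr(seq, 1, at))
}

# lexicographically minimal rotation (Booth), optionally over both strands
min_rotation <- function(seq, both_strands = TRUE) {
  fwd <- rotate_seq(seq, cpp_min_rotation(seq))
  if (!both_strands) return(fwd)
  rc <- revcomp(seq)
  rev <- rotate_seq(rc, cpp_min_rotation(rc))
  if (rev < fwd) rev else fwd
}

`%||%` <- function(a, b) if (is.null(a)) b else a
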