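#' Alignment parameters for marker extraction
#'
#' @param matrix name of the amino-acid substitution matrix (`"BLOSUM62"`,
#'   taken from Biostrings' bundled score data); in-frame stops are
#'   scored -4 against every residue.
#' @param gap_open,gap_extend affine gap scores (negative); a gap of
#'   length L costs `gap_open + (L - 1) * gap_extend`.
#' @param min_identity minimum fraction of identical aligned residues.
#' @param min_coverage_of_ref minimum fraction of the reference covered
#'   by the alignment.
#' @param nuc_match,nuc_mismatch scores for nucleotide alignment (flank
#'   location for ITS2).
#' @return object of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = -11,
                         gap_extend = -1, min_identity = 0.5,
                         min_coverage_of_ref = 0.7,
                         nuc_match = 2, nuc_mismatch = -3) {
  stopifnot(gap_open < 0, gap_extend < 0,
            min_identity > 0, min_identity <= 1,
            min_coverage_of_ref > 0, min_coverage_of_ref <= 1)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, min_identity = min_identity,
                 min_coverage_of_ref = min_coverage_of_ref,
                 nuc_match = nuc_match, nuc_mismatch = nuc_mismatch),
            class = "align_params")
}

aa_score_matrix <- function(params) {
  m <- get(data(list = params$matrix, package = "Biostrings",
                envir = environment()))
  m["*", ] <- -4
  m[, "*"] <- -4
  m["*", "*"] <- 1
  m
}

nuc_score_matrix <- function(params) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(params$nuc_mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- params$nuc_match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

# local alignment wrapper around the C++ affine-gap Smith-Waterman
local_align <- function(query, subject, score_matrix, params) {
  cpp_smith_waterman(query, subject, score_matrix,
                     params$gap_open, params$gap_extend)
}

#' Align a reference protein to a contig by translated local alignment
#'
#' The protein is aligned (affine-gap Smith-Waterman, BLOSUM62) against
#' all six translation frames of the contig; circular contigs are doubled
#' so hits spanning the origin are found, and coordinates are reported
#' modulo the contig length.  The best-scoring hit is returned if its
#' identity and reference coverage pass the thresholds.  In-frame stop
#' codons inside the hit split it into multiple intervals (a naive exon
#' model, adequate for intronless CDSs such as *matK* and *rbcL*).
#'
#' @param protein a [seed_reference()] of kind `"protein"`.
#' @param contig contig sequence string, or a list with elements `seq`
#'   and `circular`.
#' @param params an [align_params()].
#' @return a `gene_hit` (list with `gene`, `intervals`, `strand`, `frame`,
#'   `score`, `identity`, `coverage`, `peptide`, `cds`) or `NULL`.
#' @export
align_protein_to_contig <- function(protein, contig,
                                    params = align_params()) {
  stopifnot(inherits(protein, "seed_reference"),
            protein$kind == "protein")
  if (is.character(contig)) contig <- list(seq = contig, circular = FALSE)
  L <- nchar(contig$seq)
  if (L < 3) return(NULL)
  seq <- if (isTRUE(contig$circular)) paste0(contig$seq, contig$seq)
         else contig$seq
  mat <- aa_score_matrix(params)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      aa <- translate_dna(substring(s, frame + 1))
      if (nchar(aa) == 0) next
      al <- local_align(protein$sequence, aa, mat, params)
      if (al$score <= 0) next
      if (is.null(best) || al$score > best$al$score)
        best <- list(al = al, strand = strand, frame = frame, s = s)
    }
  }
  if (is.null(best)) return(NULL)
  al <- best$al
  identity <- al$matches / al$aligned
  coverage <- (al$end1 - al$start1 + 1) / nchar(protein$sequence)
  if (identity < params$min_identity ||
      coverage < params$min_coverage_of_ref) return(NULL)
  # split the aligned subject span at in-frame stop codons
  aa_span <- al$start2:al$end2
  aa_full <- translate_dna(substring(best$s, best$frame + 1))
  stops <- aa_span[substring(aa_full, aa_span, aa_span) == "*"]
  keep <- setdiff(aa_span, stops)
  if (length(keep) == 0) return(NULL)
  runs <- split(keep, cumsum(c(1, diff(keep) != 1)))
  n_or <- nchar(best$s)
  # CDS in gene order: runs read left-to-right on the oriented sequence
  cds <- paste(vapply(runs, function(r)
    substring(best$s, best$frame + 3 * (min(r) - 1) + 1,
              best$frame + 3 * max(r)), ""), collapse = "")
  # genomic intervals (0-based half-open, modulo length when circular)
  ivs <- do.call(rbind, lapply(runs, function(r) {
    a0 <- best$frame + 3 * (min(r) - 1)
    a1 <- best$frame + 3 * max(r)
    if (best$strand == "+") c(a0, a1) else c(n_or - a1, n_or - a0)
  }))
  ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
  starts <- ivs[, 1]
  if (isTRUE(contig$circular)) starts <- starts %% L
  structure(list(gene = protein$name,
                 intervals = tibble::tibble(
                   start = as.integer(starts),
                   end = as.integer(starts + (ivs[, 2] - ivs[, 1]))),
                 strand = best$strand, frame = best$frame,
                 score = al$score, identity = identity,
                 coverage = coverage,
                 peptide = translate_dna(cds), cds = cds),
            class = "gene_hit")
}

#' Extract a coding marker from an assembly
#'
#' Aligns the reference protein against every contig (the canonical
#' circular sequence when the plastid assembly is complete) and converts
#' the best qualifying hit into an extracted marker.
#'
#' @param assembly a `plastid_assembly`, `rdna_assembly`, or a character
#'   vector of contig sequences.
#' @param marker_ref a protein [seed_reference()].
#' @param params an [align_params()].
#' @return object of class `extracted_marker`: `marker`, `status`
#'   (`"success"`/`"failed"`), `sequence` (CDS nucleotides, no stop),
#'   `peptide`, and `source` (contig, interval, strand).
#' @export
extract_marker <- function(assembly, marker_ref, params = align_params()) {
  stopifnot(inherits(marker_ref, "seed_reference"))
  contigs <- assembly_contigs(assembly)
  best <- NULL; best_i <- NA_integer_
  for (i in seq_along(contigs)) {
    hit <- align_protein_to_contig(marker_ref, contigs[[i]], params)
    if (!is.null(hit) && (is.null(best) || hit$score > best$score)) {
      best <- hit; best_i <- i
    }
  }
  if (is.null(best))
    return(structure(list(marker = marker_ref$name, status = "failed",
                          sequence = NULL, peptide = NULL, source = NULL),
                     class = "extracted_marker"))
  structure(list(marker = marker_ref$name, status = "success",
                 sequence = best$cds, peptide = best$peptide,
                 source = list(contig = best_i,
                               intervals = best$intervals,
                               strand = best$strand,
                               identity = best$identity,
                               score = best$score)),
            class = "extracted_marker")
}

assembly_contigs <- function(assembly) {
  if (inherits(assembly, "plastid_assembly")) {
    if (assembly$status == "complete")
      return(list(list(seq = assembly$canonical_sequence,
                       circular = TRUE)))
    return(lapply(seq_len(nrow(assembly$contigs)), function(i)
      list(seq = assembly$contigs$seq[i],
           circular = assembly$contigs$circular[i])))
  }
  if (inherits(assembly, "rdna_assembly")) {
    if (assembly$status == "complete")
      return(list(list(seq = assembly$unit_contig, circular = FALSE)))
    return(lapply(seq_len(nrow(assembly$contigs)), function(i)
      list(seq = assembly$contigs$seq[i],
           circular = assembly$contigs$circular[i])))
  }
  if (is.character(assembly))
    return(lapply(assembly, function(s) list(seq = s, circular = FALSE)))
  stop("unsupported assembly object")
}

#' Extract ITS2 by conserved-flank delimitation
#'
#' Locates the 5.8S and 28S references on the assembled rDNA unit by
#' nucleotide local alignment; ITS2 is the interval between the end of
#' the 5.8S hit and the start of the 28S hit on the same strand.  The
#' output is normalised to the 18S-to-28S strand, so a reverse-complement
#' input yields the identical marker.
#'
#' @param rdna a complete `rdna_assembly`, or a unit contig string.
#' @param flank_58s,flank_28s nucleotide [seed_reference()]s for the two
#'   conserved flanks.
#' @param params an [align_params()].
#' @return an `extracted_marker` for ITS2.
#' @export
extract_its2 <- function(rdna, flank_58s, flank_28s,
                         params = align_params()) {
  stopifnot(inherits(flank_58s, "seed_reference"),
            flank_58s$kind == "nucleotide",
            inherits(flank_28s, "seed_reference"),
            flank_28s$kind == "nucleotide")
  unit <- if (inherits(rdna, "rdna_assembly")) {
    if (rdna$status != "complete")
      return(failed_marker("ITS2"))
    rdna$unit_contig
  } else rdna
  mat <- nuc_score_matrix(params)
  locate <- function(ref, subject) {
    al <- local_align(ref$sequence, subject, mat, params)
    if (al$score <= 0) return(NULL)
    if (al$matches / al$aligned < params$min_identity) return(NULL)
    if ((al$end1 - al$start1 + 1) / nchar(ref$sequence) <
        params$min_coverage_of_ref) return(NULL)
    al
  }
  for (strand in c("+", "-")) {
    s <- if (strand == "+") unit else revcomp(unit)
    h58 <- locate(flank_58s, s)
    h28 <- locate(flank_28s, s)
    if (is.null(h58) || is.null(h28)) next
    if (h58$end2 >= h28$start2) next   # flanks out of order on this strand
    its2 <- substring(s, h58$end2 + 1, h28$start2 - 1)
    if (nchar(its2) == 0) next
    return(structure(list(marker = "ITS2", status = "success",
                          sequence = its2, peptide = NULL,
                          source = list(contig = 1L,
                                        intervals = tibble::tibble(
                                          start = h58$end2,
                                          end = h28$start2 - 1L),
                                        strand = strand)),
                     class = "extracted_marker"))
  }
  failed_marker("ITS2")
}

failed_marker <- function(name) {
  structure(list(marker = name, status = "failed", sequence = NULL,
                 peptide = NULL, source = NULL),
            class = "extracted_marker")
}

#' @export
print.extracted_marker <- function(x, ...) {
  cat(sprintf("<extracted_marker> %s: %s%s\n", x$marker, x$status,
              if (x$status == "success")
                sprintf(" (%d nt)", nchar(x$sequence)) else ""))
  invisible(x)
}

#' Write extracted markers as FASTA with BOLD-style headers
#' @param markers list of `extracted_marker` objects.
#' @param sample_id sample identifier for the header (`sample|marker`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_markers_fasta <- function(markers, sample_id, path) {
  ok <- Filter(function(m) m$status == "success", markers)
  if (length(ok) == 0) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(vapply(ok, `[[`, "", "sequence"))
  names(x) <- vapply(ok, function(m) paste(sample_id, m$marker, sep = "|"),
                     "")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Per-sample marker status table
#'
#' @param sample sample identifier.
#' @param markers named list with elements `matK`, `rbcL`, `ITS2`
#'   (`extracted_marker` objects or `NULL`).
#' @return one-row tibble with logical columns `matK`, `rbcL`, `ITS2`,
#'   `all_three`.
#' @export
marker_status_row <- function(sample, markers) {
  ok <- function(m) !is.null(m) && m$status == "success"
  tibble::tibble(sample = sample,
                 matK = ok(markers$matK), rbcL = ok(markers$rbcL),
                 ITS2 = ok(markers$ITS2),
                 all_three = ok(markers$matK) && ok(markers$rbcL) &&
                   ok(markers$ITS2))
}
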