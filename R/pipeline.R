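#' @importFrom rlang .data
NULL

#' Run the full skim assembly pipeline on paired reads
#'
#' Convenience wrapper chaining quality filtering, k-mer indexing, seed
#' finding, graph construction and unfolding for both the chloroplast and
#' the nrDNA target.
#'
#' @param r1,r2 read tibbles (`id`, `seq`, `qual`), e.g. from a
#'   [simulate_read_pairs()] result or [read_fastq()].
#' @param cp_refs protein [seed_reference()]s for chloroplast seeding.
#' @param rdna_refs nucleotide [seed_reference()]s for nrDNA seeding.
#' @param qc a [qc_params()].
#' @param idx an [index_params()].
#' @param gp a [graph_params()].
#' @param decoy PhiX-like decoy sequence (`NULL` disables the screen).
#' @return list with elements `qc` (reads + stats), `index`, `plastid`,
#'   `rdna`.
#' @export
skim_assemble <- function(r1, r2, cp_refs, rdna_refs,
                          qc = qc_params(), idx = index_params(),
                          gp = graph_params(), decoy = phix_decoy()) {
  qcres <- run_qc(r1, r2, qc, decoy)
  reads <- list(qcres$r1, qcres$r2, qcres$orphans)
  index <- build_index(reads, idx)
  plastid <- NULL
  if (!is.null(cp_refs)) {
    cp_seeds <- find_seed_kmers(index, cp_refs, gp, reads)
    plastid <- unfold_plastid(build_graph(index, cp_seeds, gp), gp)
  }
  rdna <- NULL
  if (!is.null(rdna_refs)) {
    nr_seeds <- find_seed_kmers(index, rdna_refs, gp, reads)
    rdna <- unfold_rdna(build_graph(index, nr_seeds, gp), gp)
  }
  list(qc = qcres, index = index, plastid = plastid, rdna = rdna)
}

#' Extract the standard barcodes from an assembled skim
#'
#' @param assembly a [skim_assemble()] result.
#' @param matk_ref,rbcl_ref protein [seed_reference()]s.
#' @param flank_58s,flank_28s nucleotide [seed_reference()]s delimiting
#'   ITS2.
#' @param params an [align_params()].
#' @return named list of `extracted_marker` objects
#'   (`matK`, `rbcL`, `ITS2`).
#' @export
extract_barcodes <- function(assembly, matk_ref = NULL, rbcl_ref = NULL,
                             flank_58s = NULL, flank_28s = NULL,
                             params = align_params()) {
  out <- list()
  if (!is.null(matk_ref))
    out$matK <- extract_marker(assembly$plastid, matk_ref, params)
  if (!is.null(rbcl_ref))
    out$rbcL <- extract_marker(assembly$plastid, rbcl_ref, params)
  if (!is.null(flank_58s) && !is.null(flank_28s))
    out$ITS2 <- extract_its2(assembly$rdna, flank_58s, flank_28s, params)
  out
}
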