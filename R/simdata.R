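#' Specify a toy genome set for simulation
#'
#' A `genome_spec` describes the three compartments emulated by the
#' simulator: a circular quadripartite plastome (large single copy region,
#' inverted repeat, small single copy region, second inverted repeat equal
#' to the reverse complement of the first), a tandemly repeated nuclear
#' ribosomal DNA unit (18S-ITS1-5.8S-ITS2-28S) with unique flanking
#' spacers, and a stretch of single-copy nuclear background.  Protein
#' coding genes (e.g. *matK*, *rbcL*) can be planted as in-frame ORFs in a
#' chosen plastome region.
#'
#' @param lsc_len,ssc_len,ir_len lengths in bases of the LSC, SSC and each
#'   IR copy.  `ir_len = 0` gives a plastome without inverted repeat.
#' @param planted_genes list of lists with elements `name`, `peptide`
#'   (amino acids, must start with M) and `region` (`"LSC"`, `"SSC"` or
#'   `"IR"`).
#' @param rdna_copies number of tandem rDNA units (>= 1).
#' @param rdna_subregion_lens named or unnamed numeric of length 5: bases
#'   for 18S, ITS1, 5.8S, ITS2 and 28S.
#' @param rdna_flank_len unique spacer length on each side of the array.
#' @param nuclear_len bases of single-copy nuclear background.
#' @param gc_fraction GC content of the random background, in `[0, 1]`.
#' @param seed integer seed; all genome construction is deterministic in it.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(lsc_len = 2000, ssc_len = 800, ir_len = 500,
                        planted_genes = list(),
                        rdna_copies = 2,
                        rdna_subregion_lens = c(`18S` = 1800, ITS1 = 250,
                                                `5.8S` = 160, ITS2 = 230,
                                                `28S` = 3400),
                        rdna_flank_len = 2000,
                        nuclear_len = 10000,
                        gc_fraction = 0.37,
                        seed = 1L) {
  stopifnot(lsc_len >= 0, ssc_len >= 0, ir_len >= 0,
            rdna_copies >= 1, all(rdna_subregion_lens > 0),
            rdna_flank_len >= 0, nuclear_len >= 0,
            gc_fraction >= 0, gc_fraction <= 1)
  if (length(rdna_subregion_lens) != 5)
    stop("rdna_subregion_lens must have 5 elements (18S, ITS1, 5.8S, ITS2, 28S)")
  names(rdna_subregion_lens) <- c("18S", "ITS1", "5.8S", "ITS2", "28S")
  region_len <- c(LSC = lsc_len, SSC = ssc_len, IR = ir_len)
  per_region <- table(factor(vapply(planted_genes, `[[`, "", "region"),
                             levels = names(region_len)))
  for (g in planted_genes) {
    stopifnot(is.character(g$name), is.character(g$peptide),
              g$region %in% names(region_len))
    if (substr(g$peptide, 1, 1) != "M")
      stop("planted peptide '", g$name, "' must start with M (its start codon)")
    need <- 3 * (nchar(g$peptide) + 1)
    slot <- floor(region_len[[g$region]] / max(1, per_region[[g$region]]))
    if (need > slot)
      stop("planted gene '", g$name, "' too long for region ", g$region,
           " (needs ", need, " nt, slot is ", slot, " nt)")
  }
  structure(list(lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
                 ir_len = as.integer(ir_len), planted_genes = planted_genes,
                 rdna_copies = as.integer(rdna_copies),
                 rdna_subregion_lens = rdna_subregion_lens,
                 rdna_flank_len = as.integer(rdna_flank_len),
                 nuclear_len = as.integer(nuclear_len),
                 gc_fraction = gc_fraction, seed = as.integer(seed)),
            class = "genome_spec")
}

new_annotated_genome <- function(name, sequence, topology, copy_number,
                                 role, features) {
  structure(list(name = name, sequence = sequence, topology = topology,
                 copy_number = copy_number, role = role,
                 features = features), class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d bp, %s, copy number %g, %d features\n",
              x$name, nchar(x$sequence), x$topology, x$copy_number,
              nrow(x$features)))
  invisible(x)
}

empty_features <- function() {
  tibble::tibble(label = character(), start = integer(), end = integer(),
                 strand = character(), copy = integer())
}

# plant an ORF (peptide codons + stop) into a region sequence at a random
# offset within slot [slot0, slot1); returns list(seq, start, end, strand)
plant_orf <- function(region_seq, peptide, slot0, slot1) {
  orf <- paste0(reverse_translate(peptide),
                sample(c("TAA", "TAG", "TGA"), 1))
  glen <- nchar(orf)
  maxoff <- (slot1 - slot0) - glen
  off <- slot0 + sample.int(maxoff + 1L, 1L) - 1L
  strand <- if (runif(1) < 0.5) "+" else "-"
  ins <- if (strand == "+") orf else revcomp(orf)
  seq <- paste0(substr(region_seq, 1, off), ins,
                substr(region_seq, off + glen + 1, nchar(region_seq)))
  list(seq = seq, start = off, end = off + glen, strand = strand)
}

#' Build the toy circular plastome
#'
#' Lays the genome out LSC-IRb-SSC-IRa with IRa the reverse complement of
#' IRb, and plants each requested gene as an in-frame ORF (peptide codons
#' followed by a stop codon) at a recorded feature interval on a random
#' strand.  Genes targeted at `"IR"` are planted in IRb and appear mirrored
#' in IRa by construction (only the IRb copy is recorded as a feature).
#' Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [genome_spec()].
#' @return an `annotated_genome` (circular, copy number 100, role
#'   `"plastid"`).  Feature coordinates are 0-based half-open.
#' @export
make_plastid_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, {
    regions <- list(LSC = random_dna(spec$lsc_len, spec$gc_fraction),
                    IR  = random_dna(spec$ir_len, spec$gc_fraction),
                    SSC = random_dna(spec$ssc_len, spec$gc_fraction))
    feats <- list()
    by_region <- split(spec$planted_genes,
                       vapply(spec$planted_genes, `[[`, "", "region"))
    for (rg in names(by_region)) {
      genes <- by_region[[rg]]
      rl <- nchar(regions[[rg]])
      slots <- floor(seq(0, rl, length.out = length(genes) + 1))
      for (i in seq_along(genes)) {
        p <- plant_orf(regions[[rg]], genes[[i]]$peptide,
                       slots[i], slots[i + 1])
        regions[[rg]] <- p$seq
        feats[[length(feats) + 1]] <-
          tibble::tibble(label = genes[[i]]$name, start = p$start,
                         end = p$end, strand = p$strand, copy = 1L,
                         region = rg)
      }
    }
    ira <- revcomp(regions$IR)
    seqn <- paste0(regions$LSC, regions$IR, regions$SSC, ira)
    off <- c(LSC = 0L, IR = spec$lsc_len,
             SSC = spec$lsc_len + spec$ir_len)
    gene_feats <- if (length(feats) > 0) {
      gf <- dplyr::bind_rows(feats)
      gf$start <- as.integer(gf$start + unname(off[gf$region]))
      gf$end <- as.integer(gf$end + unname(off[gf$region]))
      gf$region <- NULL
      gf
    } else empty_features()
    bounds <- cumsum(c(0, spec$lsc_len, spec$ir_len, spec$ssc_len,
                       spec$ir_len))
    region_feats <- tibble::tibble(
      label = c("LSC", "IRb", "SSC", "IRa"),
      start = as.integer(bounds[1:4]), end = as.integer(bounds[2:5]),
      strand = "+", copy = 1L)
    region_feats <- region_feats[region_feats$end > region_feats$start, ]
    new_annotated_genome("plastome", seqn, "circular", 100, "plastid",
                         dplyr::bind_rows(region_feats, gene_feats))
  })
}

#' Build the tandem nuclear ribosomal DNA array
#'
#' Produces a linear sequence of `rdna_copies` tandem units, each laid out
#' 18S-ITS1-5.8S-ITS2-28S, with unique spacer sequence flanking the array.
#' Subregion features are recorded per copy.  Deterministic for a fixed
#' `spec$seed` (an offset RNG stream is used so the rDNA differs from the
#' plastome built from the same spec).
#'
#' @param spec a [genome_spec()].
#' @return an `annotated_genome` (linear, copy number 50, role `"rdna"`).
#' @export
make_rdna_unit <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  if (spec$rdna_copies < 1) stop("rdna_copies must be >= 1")
  withr::with_seed(spec$seed + 1L, {
    lens <- spec$rdna_subregion_lens
    subs <- lapply(lens, function(n) random_dna(n, spec$gc_fraction))
    unit <- paste(unlist(subs), collapse = "")
    ulen <- sum(lens)
    flank5 <- random_dna(spec$rdna_flank_len, spec$gc_fraction)
    flank3 <- random_dna(spec$rdna_flank_len, spec$gc_fraction)
    seqn <- paste0(flank5, strrep(unit, spec$rdna_copies), flank3)
    ends <- cumsum(lens)
    starts <- ends - lens
    feats <- dplyr::bind_rows(lapply(seq_len(spec$rdna_copies), function(cp) {
      o <- spec$rdna_flank_len + (cp - 1L) * ulen
      tibble::tibble(label = names(lens),
                     start = as.integer(o + starts),
                     end = as.integer(o + ends),
                     strand = "+", copy = as.integer(cp))
    }))
    new_annotated_genome("rdna_array", seqn, "linear", 50, "rdna", feats)
  })
}

#' Build single-copy nuclear background sequence
#'
#' @param spec a [genome_spec()].
#' @return an `annotated_genome` (linear, copy number 1, role `"nuclear"`).
#' @export
make_nuclear_background <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed + 2L, {
    new_annotated_genome("nuclear_bg", random_dna(spec$nuclear_len,
                                                  spec$gc_fraction),
                         "linear", 1, "nuclear", empty_features())
  })
}

#' Bundled pseudo-PhiX decoy sequence
#'
#' A 5386 bp synthetic stand-in for the Illumina PhiX run control genome,
#' generated once from a fixed internal seed (the screen only needs a
#' stable decoy sequence, not the real PhiX).
#'
#' @return a single character string (circular genome).
#' @export
phix_decoy <- function() {
  if (is.null(.genoskim_env$phix)) {
    .genoskim_env$phix <- withr::with_seed(536870911L,
                                           random_dna(5386, gc = 0.45))
  }
  .genoskim_env$phix
}

.genoskim_env <- new.env(parent = emptyenv())

#' Read-simulation parameters
#'
#' Preservation presets reflect how tissue preparation shapes a library:
#' silica-gel dried material is sonicated to ~350 bp inserts and yields a
#' higher organelle share, while herbarium material is degraded to ~250 bp
#' inserts with a relatively lower plastid and rDNA share (plastid share
#' scaled by 1/1.7 and rDNA by 1/1.5, the depth ratios observed between
#' the two preservation types in large campaigns).
#'
#' @param read_length read length in bases (default 101).
#' @param preservation_preset `"custom"`, `"silica"` or `"herbarium"`.
#' @param insert_mean,insert_sd fragment length distribution (truncated
#'   Normal); defaults from the preset, `insert_sd = 0.1 * insert_mean`.
#' @param target_depth requested fold-coverage of the plastome; other
#'   genomes receive coverage in proportion to `copy_number`.
#' @param n_pairs if given, the exact total number of pairs to simulate
#'   (overrides `target_depth`); pairs are split across genomes in
#'   proportion to effective copy number times length.
#' @param error_rate substitution probability per base.
#' @param n_rate probability a base is replaced by N.
#' @param q_start,q_end Phred quality at the first and last read position
#'   (linear decay between them).
#' @param phix_fraction fraction of all pairs drawn from the PhiX-like decoy.
#' @param max_pairs cap on total pairs (default 3e6, i.e. 6e6 reads).
#' @param seed integer seed.
#' @return an object of class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 101,
                            preservation_preset = c("custom", "silica",
                                                    "herbarium"),
                            insert_mean = NULL, insert_sd = NULL,
                            target_depth = 90, n_pairs = NULL,
                            error_rate = 0, n_rate = 0,
                            q_start = 37, q_end = 28,
                            phix_fraction = 0, max_pairs = 3e6,
                            seed = 1L) {
  preservation_preset <- match.arg(preservation_preset)
  preset <- switch(preservation_preset,
                   silica = list(insert = 350, cp = 1, nr = 1),
                   herbarium = list(insert = 250, cp = 1 / 1.7, nr = 1 / 1.5),
                   custom = list(insert = 350, cp = 1, nr = 1))
  insert_mean <- insert_mean %||% preset$insert
  insert_sd <- insert_sd %||% (0.1 * insert_mean)
  stopifnot(read_length > 0, insert_mean > 0, insert_sd >= 0,
            error_rate >= 0, error_rate <= 1, n_rate >= 0, n_rate <= 1,
            phix_fraction >= 0, phix_fraction < 1,
            q_start >= 2, q_start <= 93, q_end >= 2, q_end <= 93)
  structure(list(read_length = as.integer(read_length),
                 preservation_preset = preservation_preset,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 target_depth = target_depth, n_pairs = n_pairs,
                 error_rate = error_rate, n_rate = n_rate,
                 q_start = q_start, q_end = q_end,
                 cp_depth_factor = preset$cp, nr_depth_factor = preset$nr,
                 phix_fraction = phix_fraction, max_pairs = max_pairs,
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

effective_copy <- function(genome, params) {
  f <- switch(genome$role, plastid = params$cp_depth_factor,
              rdna = params$nr_depth_factor, 1)
  genome$copy_number * f
}

# draw n read pairs from one genome; returns list(r1, r2, truth)
sim_pairs_one <- function(genome, n, params) {
  if (n <= 0)
    return(list(r1 = character(0), r2 = character(0),
                truth = NULL))
  L <- nchar(genome$sequence)
  rl <- params$read_length
  flen <- pmax(rl, pmin(L, round(rnorm(n, params$insert_mean,
                                       params$insert_sd))))
  if (genome$topology == "circular") {
    start <- sample.int(L, n, replace = TRUE) - 1L
    g2 <- paste0(genome$sequence, genome$sequence)
    frag <- substring(g2, start + 1, start + flen)
  } else {
    start <- floor(runif(n) * (L - flen + 1))
    frag <- substring(genome$sequence, start + 1, start + flen)
  }
  minus <- runif(n) < 0.5
  fragseq <- frag
  fragseq[minus] <- revcomp(frag[minus])
  r1 <- substring(fragseq, 1, rl)
  r2 <- revcomp(substring(fragseq, flen - rl + 1, flen))
  # truth intervals on the genome (0-based half-open; circular coordinates
  # reported modulo length, end may exceed L meaning wrap-around)
  left <- start %% L                      # leftmost fragment coordinate
  right_read_start <- (start + flen - rl) %% L
  r1_start <- ifelse(minus, right_read_start, left)
  r2_start <- ifelse(minus, left, right_read_start)
  truth <- tibble::tibble(
    genome = genome$name,
    mate = rep(1:2, each = n),
    start = c(r1_start, r2_start),
    end = c(r1_start, r2_start) + rl,
    strand = c(ifelse(minus, "-", "+"), ifelse(minus, "+", "-")))
  list(r1 = r1, r2 = r2, truth = truth)
}

apply_base_noise <- function(seqs, rate, replacement = NULL) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  rl <- nchar(seqs[1])
  total <- length(seqs) * rl
  nmut <- rbinom(1, total, rate)
  if (nmut == 0) return(seqs)
  pos <- sample.int(total, nmut)
  ri <- (pos - 1L) %/% rl + 1L
  off <- (pos - 1L) %% rl + 1L
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(nmut)) {
    cur <- substr(seqs[ri[j]], off[j], off[j])
    newb <- if (is.null(replacement)) {
      sample(setdiff(bases, cur), 1)
    } else replacement
    substr(seqs[ri[j]], off[j], off[j]) <- newb
  }
  seqs
}

#' Simulate paired-end reads from a set of annotated genomes
#'
#' Fragments are drawn per genome in proportion to effective copy number
#' times length; fragment lengths follow a Normal truncated below at the
#' read length (and above at the genome length); circular genomes wrap;
#' mate 2 is the reverse complement of the fragment end.  Substitution
#' errors, N masking and the linear quality decay are applied after the
#' truth log is recorded, so the log always reflects the error-free
#' coordinates.  Fully deterministic for a fixed `params$seed`.
#'
#' @param genomes list of `annotated_genome` objects (at least one).
#' @param params a [read_sim_params()].
#' @return an object of class `read_sim`: tibbles `r1` and `r2` with
#'   columns `id`, `seq`, `qual` (Phred+33), and a `truth` tibble with
#'   columns `id`, `mate`, `genome`, `start`, `end`, `strand`.
#' @export
simulate_read_pairs <- function(genomes, params = read_sim_params()) {
  if (inherits(genomes, "annotated_genome")) genomes <- list(genomes)
  if (length(genomes) == 0) stop("at least one genome is required")
  stopifnot(all(vapply(genomes, inherits, TRUE, "annotated_genome")),
            inherits(params, "read_sim_params"))
  withr::with_seed(params$seed, {
    eff <- vapply(genomes, effective_copy, 0, params = params)
    lens <- vapply(genomes, function(g) nchar(g$sequence), 0)
    w <- eff * lens
    rl <- params$read_length
    if (!is.null(params$n_pairs)) {
      total <- min(params$n_pairs, params$max_pairs)
      npg <- as.integer(rmultinom(1, total, w))
    } else {
      ref <- which(vapply(genomes, function(g) g$role, "") == "plastid")
      ref <- if (length(ref) > 0) ref[1] else which.max(eff)
      n_ref <- params$target_depth * lens[ref] / (2 * rl)
      npg <- as.integer(round(n_ref * w / w[ref]))
      if (sum(npg) > params$max_pairs)
        npg <- as.integer(round(npg * params$max_pairs / sum(npg)))
    }
    parts <- lapply(seq_along(genomes), function(i)
      sim_pairs_one(genomes[[i]], npg[i], params))
    if (params$phix_fraction > 0) {
      nphix <- round(params$phix_fraction * sum(npg) /
                       (1 - params$phix_fraction))
      decoy <- new_annotated_genome("phix_decoy", phix_decoy(), "circular",
                                    1, "other", empty_features())
      parts[[length(parts) + 1]] <- sim_pairs_one(decoy, nphix, params)
    }
    r1 <- unlist(lapply(parts, `[[`, "r1"))
    r2 <- unlist(lapply(parts, `[[`, "r2"))
    n <- length(r1)
    ids <- sprintf("sim_%07d", seq_len(n))
    truth <- dplyr::bind_rows(lapply(parts, `[[`, "truth"))
    # truth rows are stacked mate1-then-mate2 within each part
    off <- 0L
    idlist <- list()
    for (p in parts) {
      np <- length(p$r1)
      if (np > 0) idlist[[length(idlist) + 1]] <-
          rep(ids[off + seq_len(np)], 2)
      off <- off + np
    }
    truth$id <- unlist(idlist)
    truth <- truth[, c("id", "mate", "genome", "start", "end", "strand")]
    reads <- c(r1, r2)
    reads <- apply_base_noise(reads, params$error_rate)
    reads <- apply_base_noise(reads, params$n_rate, replacement = "N")
    qvec <- as.integer(round(seq(params$q_start, params$q_end,
                                 length.out = rl)))
    qstr <- intToUtf8(qvec + 33L)
    structure(list(
      r1 = tibble::tibble(id = ids, seq = reads[seq_len(n)],
                          qual = rep(qstr, n)),
      r2 = tibble::tibble(id = ids, seq = reads[n + seq_len(n)],
                          qual = rep(qstr, n)),
      truth = truth, params = params), class = "read_sim")
  })
}

#' @export
print.read_sim <- function(x, ...) {
  cat(sprintf("<read_sim> %d pairs, read length %d, preset %s, seed %d\n",
              nrow(x$r1), x$params$read_length,
              x$params$preservation_preset, x$params$seed))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Writers

#' Write a genome to FASTA
#' @param genome an `annotated_genome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(genome$sequence,
                                                genome$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write genome features to GFF3 (1-based inclusive coordinates)
#' @param genome an `annotated_genome`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(genome, path) {
  f <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = rep(genome$name, nrow(f)),
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand)
  if (nrow(f) > 0) {
    S4Vectors::mcols(gr)$type <- rep("region", nrow(f))
    S4Vectors::mcols(gr)$ID <- paste0(f$label, "_", f$copy)
    S4Vectors::mcols(gr)$Name <- f$label
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write simulated pairs as `_R1`/`_R2` FASTQ (Phred+33)
#' @param sim a `read_sim`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq_pairs <- function(sim, dir, prefix = "sim") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_R1.fastq", "_R2.fastq")))
  for (m in 1:2) {
    tb <- if (m == 1) sim$r1 else sim$r2
    write_fastq(tb$seq, tb$qual, paste0(tb$id, "/", m), paths[m])
  }
  invisible(paths)
}

write_fastq <- function(seq, qual, id, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read a FASTQ file into a tibble
#' @param path FASTQ file (Phred+33).
#' @return tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble::tibble(id = names(x), seq = unname(as.character(x)),
                 qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Write the simulation truth log as TSV
#' @param sim a `read_sim`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(sim, path) {
  utils::write.table(sim$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
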