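#' A reference sequence used to seed assembly
#'
#' @param name reference name (e.g. `"matK"`).
#' @param kind `"protein"` or `"nucleotide"`.
#' @param sequence amino acids (one-letter code) or DNA.
#' @return object of class `seed_reference`.
#' @export
seed_reference <- function(name, kind = c("protein", "nucleotide"),
                           sequence) {
  kind <- match.arg(kind)
  sequence <- toupper(sequence)
  if (kind == "nucleotide" && grepl("[^ACGT]", sequence))
    stop("nucleotide reference contains characters outside ACGT")
  if (kind == "protein" && grepl("[^ACDEFGHIKLMNPQRSTVWY]", sequence))
    stop("protein reference contains letters outside the 20-letter alphabet")
  structure(list(name = name, kind = kind, sequence = sequence),
            class = "seed_reference")
}

#' Read seed references from FASTA
#' @param path FASTA file.
#' @param kind `"protein"` or `"nucleotide"`.
#' @return list of [seed_reference()] objects.
#' @export
read_seed_fasta <- function(path, kind = c("protein", "nucleotide")) {
  kind <- match.arg(kind)
  x <- if (kind == "protein") Biostrings::readAAStringSet(path)
       else Biostrings::readDNAStringSet(path)
  lapply(seq_along(x), function(i)
    seed_reference(names(x)[i], kind, as.character(x[[i]])))
}

#' Graph construction parameters
#'
#' @param min_count `"auto"` (threshold = `max(2, mode of seed counts / 4)`)
#'   or an explicit integer coverage threshold.
#' @param max_gap_iterations maximum gap-filling rounds (default 30).
#' @param gap_relax_factor multiplier applied to the threshold per round
#'   during gap filling (0 < factor < 1).
#' @param tip_max_len dead-end branches shorter than this are pruned
#'   (default `2 * k`, resolved at use).
#' @param seed_word_aa amino-acid word length for protein seeding.
#' @param max_gap_depth bound (in nodes) on the reconnection search during
#'   gap filling.
#' @return object of class `graph_params`.
#' @export
graph_params <- function(min_count = "auto", max_gap_iterations = 30,
                         gap_relax_factor = 0.5, tip_max_len = NULL,
                         seed_word_aa = 7, max_gap_depth = 500) {
  stopifnot(max_gap_iterations >= 0, gap_relax_factor > 0,
            gap_relax_factor < 1, seed_word_aa >= 3, max_gap_depth >= 1)
  structure(list(min_count = min_count,
                 max_gap_iterations = as.integer(max_gap_iterations),
                 gap_relax_factor = gap_relax_factor,
                 tip_max_len = tip_max_len,
                 seed_word_aa = as.integer(seed_word_aa),
                 max_gap_depth = as.integer(max_gap_depth)),
            class = "graph_params")
}

#' Find assembly seed k-mers from reference genes
#'
#' Nucleotide references seed with the canonical k-mers they share with
#' the index.  Protein references are matched by re-streaming the reads:
#' every amino-acid word of length `seed_word_aa` from the reference is
#' looked for in the six-frame translation of each read, and the read
#' k-mers overlapping a matched word are harvested (then restricted to
#' k-mers actually present in the index).
#'
#' @param index a [build_index()] result.
#' @param refs list of [seed_reference()] objects (at least one).
#' @param params a [graph_params()].
#' @param reads read sequences to re-stream for protein seeding (character
#'   vector or tibble(s) with a `seq` column); required when any reference
#'   is a protein.
#' @return object of class `seed_set`: tibble with columns `kmer`, `ref`,
#'   `offset` and attribute `k`.
#' @export
find_seed_kmers <- function(index, refs, params = graph_params(),
                            reads = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  if (inherits(refs, "seed_reference")) refs <- list(refs)
  if (length(refs) == 0) stop("at least one seed reference is required")
  stopifnot(all(vapply(refs, inherits, TRUE, "seed_reference")))
  k <- index$k
  out <- list()
  nuc <- Filter(function(r) r$kind == "nucleotide", refs)
  for (r in nuc) {
    L <- nchar(r$sequence)
    if (L < k) next
    starts <- seq_len(L - k + 1)
    win <- substring(r$sequence, starts, starts + k - 1)
    rc <- revcomp(win)
    canon <- ifelse(win <= rc, win, rc)
    hit <- !is.na(match(canon, index$kmer))
    if (any(hit)) {
      tb <- tibble::tibble(kmer = canon[hit], ref = r$name,
                           offset = starts[hit] - 1L)
      out[[length(out) + 1]] <- tb[!duplicated(tb$kmer), ]
    }
  }
  prot <- Filter(function(r) r$kind == "protein", refs)
  if (length(prot) > 0) {
    if (is.null(reads))
      stop("protein references require the reads for re-streaming")
    seqs <- gather_seqs(reads)
    h <- cpp_protein_seed_harvest(seqs,
                                  vapply(prot, `[[`, "", "name"),
                                  vapply(prot, `[[`, "", "sequence"),
                                  params$seed_word_aa, k)
    if (length(h$kmer) > 0) {
      keep <- !is.na(match(h$kmer, index$kmer))
      out[[length(out) + 1]] <- tibble::tibble(kmer = h$kmer[keep],
                                               ref = h$ref[keep],
                                               offset = h$offset[keep])
    }
  }
  seeds <- if (length(out) > 0) dplyr::bind_rows(out) else
    tibble::tibble(kmer = character(), ref = character(),
                   offset = integer())
  seeds <- seeds[!duplicated(seeds$kmer), ]
  seeds <- seeds[order(seeds$kmer), ]
  structure(seeds, k = k, class = c("seed_set", class(seeds)))
}

#' Grow a coverage-filtered De Bruijn graph around the seeds
#'
#' Nodes are canonical k-mers; two nodes are adjacent when some
#' orientation overlaps by k-1.  Starting from the seed k-mers, the graph
#' is extended breadth-first through index k-mers whose count reaches the
#' coverage threshold (in `"auto"` mode, `max(2, mode of seed counts / 4)`:
#' seeds sit on the organelle coverage peak, which makes the rule robust
#' to low-copy nuclear background).  Up to `max_gap_iterations` rounds of
#' gap filling follow: the threshold is relaxed by `gap_relax_factor` per
#' round and only nodes on paths that reconnect a dangling path end to the
#' rest of the graph within `max_gap_depth` steps are admitted.
#'
#' @param index a [build_index()] result.
#' @param seeds a [find_seed_kmers()] result.
#' @param params a [graph_params()].
#' @return object of class `debruijn_graph`: `status` (`"ok"` or
#'   `"no_seed"`), `nodes` tibble (`kmer`, `count`, `is_seed`), the
#'   `threshold` used, and `k`.
#' @export
build_graph <- function(index, seeds, params = graph_params()) {
  stopifnot(inherits(index, "kmer_index"), inherits(seeds, "seed_set"))
  k <- attr(seeds, "k")
  empty <- tibble::tibble(kmer = character(), count = integer(),
                          is_seed = logical())
  if (nrow(seeds) == 0)
    return(structure(list(k = k, status = "no_seed", nodes = empty,
                          threshold = NA_integer_),
                     class = "debruijn_graph"))
  if (identical(params$min_count, "auto")) {
    sc <- index_lookup(index, seeds$kmer)
    sc <- sc[sc > 0]
    if (length(sc) == 0)
      return(structure(list(k = k, status = "no_seed", nodes = empty,
                            threshold = NA_integer_),
                       class = "debruijn_graph"))
    # seeds sit on the organelle coverage peak, but reads with sequencing
    # errors contribute singleton seed k-mers; take the mode above the
    # error band (counts >= 3) whenever it exists
    peak <- sc[sc >= 3]
    if (length(peak) == 0) peak <- sc
    tab <- table(peak)
    mode_count <- as.integer(names(tab)[which.max(tab)])
    threshold <- max(2L, mode_count %/% 4L)
  } else {
    threshold <- as.integer(params$min_count)
  }
  g <- cpp_build_graph(index$kmer, index$count, seeds$kmer, threshold,
                       params$max_gap_iterations, params$gap_relax_factor,
                       params$max_gap_depth)
  nodes <- tibble::tibble(kmer = g$kmer, count = g$count,
                          is_seed = g$is_seed)
  status <- if (nrow(nodes) == 0) "no_seed" else "ok"
  structure(list(k = k, status = status, nodes = nodes,
                 threshold = threshold), class = "debruijn_graph")
}

#' @export
print.debruijn_graph <- function(x, ...) {
  cat(sprintf("<debruijn_graph> k=%d, status=%s, %d nodes, threshold=%s\n",
              x$k, x$status, nrow(x$nodes), x$threshold))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Unitig graph and cleanup

seq_or <- function(seq, o) if (o == "+") seq else revcomp(seq)
flip_or <- function(o) if (o == "+") "-" else "+"

unitigs_of <- function(kmers, counts) {
  u <- cpp_unitigs(kmers, counts)
  list(tigs = tibble::tibble(id = seq_along(u$seq), seq = u$seq,
                             cov = u$cov, circular = u$circular,
                             n_kmers = u$n_kmers),
       links = tibble::tibble(from = u$link_from, from_or = u$link_from_or,
                              to = u$link_to, to_or = u$link_to_or))
}

# out-degree of a unitig end ("+" = right end, "-" = left end)
end_degree <- function(links, u, o) {
  sum(links$from == u & links$from_or == o)
}

has_link <- function(links, u, o, w, ow) {
  any(links$from == u & links$from_or == o &
        links$to == w & links$to_or == ow)
}

# Build the cleaned unitig graph for a node set: prune short dead-end tips,
# collapse simple bubbles to the higher-count branch, and recompute.
unitig_graph <- function(nodes, k, tip_max_len) {
  kmers <- nodes$kmer
  counts <- nodes$count
  repeat {
    ug <- unitigs_of(kmers, counts)
    tigs <- ug$tigs; links <- ug$links
    drop <- integer(0)
    # tips: linear unitigs dangling on exactly one side and short
    for (i in tigs$id) {
      if (tigs$circular[i]) next
      if (nchar(tigs$seq[i]) >= tip_max_len) next
      dr <- end_degree(links, i, "+")  # right end
      dl <- end_degree(links, i, "-")  # left end
      if (xor(dr == 0, dl == 0)) drop <- c(drop, i)
    }
    # bubbles: two parallel linear unitigs with identical link partners
    if (length(drop) == 0 && nrow(tigs) > 1) {
      sig <- vapply(tigs$id, function(i) {
        r <- links[links$from == i & links$from_or == "+", ]
        l <- links[links$from == i & links$from_or == "-", ]
        paste(paste(r$to, r$to_or, collapse = ";"),
              paste(l$to, l$to_or, collapse = ";"), sep = "|")
      }, "")
      linked <- !tigs$circular &
        (vapply(tigs$id, function(i) end_degree(links, i, "+") > 0, TRUE) &
         vapply(tigs$id, function(i) end_degree(links, i, "-") > 0, TRUE))
      for (s in unique(sig[linked])) {
        grp <- tigs$id[linked & sig == s]
        if (length(grp) >= 2 &&
            diff(range(nchar(tigs$seq[grp]))) <= k) {
          keep <- grp[which.max(tigs$cov[grp])]
          drop <- c(drop, setdiff(grp, keep))
        }
      }
    }
    if (length(drop) == 0) return(ug)
    gone <- unlist(lapply(drop, function(i) {
      s <- tigs$seq[i]
      if (tigs$circular[i]) s <- paste0(s, substr(s, 1, k - 1))
      cpp_count_kmers(s, k)$kmer
    }))
    keep <- !(kmers %in% gone)
    if (all(keep)) return(ug)  # safety: no progress
    kmers <- kmers[keep]
    counts <- counts[keep]
    if (length(kmers) == 0)
      return(list(tigs = tibble::tibble(id = integer(), seq = character(),
                                        cov = double(), circular = logical(),
                                        n_kmers = integer()),
                  links = tibble::tibble(from = integer(),
                                         from_or = character(),
                                         to = integer(),
                                         to_or = character())))
  }
}

# ---------------------------------------------------------------------------
# Plastid unfolding

#' Unfold the plastid graph into a (preferably circular) genome
#'
#' Unbranched paths are traversed into contigs.  The inverted repeat is
#' detected as the unitig whose k-mer coverage is roughly twice that of
#' the two flanking single-copy unitigs and whose branch pairs admit the
#' closed LSC-IRb-SSC-IRa walk (each IR node used twice, once per
#' orientation).  When such a walk -- or a single circular unitig for an
#' IR-less genome -- covers every node, the assembly is complete and the
#' circular sequence is reported in canonical form: rotated to start at
#' the LSC (or, without an IR, at the lexicographically minimal rotation),
#' on the strand giving the lexicographically smaller sequence, with the
#' SSC orientation isomer normalised to the lexicographically smaller SSC.
#' Otherwise the separate contigs are reported with status `"partial"`.
#'
#' @param graph a [build_graph()] result.
#' @param params a [graph_params()].
#' @return object of class `plastid_assembly`: `status` (`"complete"`,
#'   `"partial"` or `"no_seed"`), `contigs` tibble, `canonical_sequence`
#'   (when complete), `layout` tibble of 0-based half-open intervals for
#'   LSC/IRb/SSC/IRa (empty when no IR), and `detail`.
#' @export
unfold_plastid <- function(graph, params = graph_params()) {
  stopifnot(inherits(graph, "debruijn_graph"))
  k <- graph$k
  empty_layout <- tibble::tibble(region = character(), start = integer(),
                                 end = integer())
  if (graph$status == "no_seed" || nrow(graph$nodes) == 0)
    return(structure(list(status = "no_seed",
                          contigs = tibble::tibble(seq = character(),
                                                   cov = double(),
                                                   circular = logical()),
                          canonical_sequence = NULL, layout = empty_layout,
                          k = k, detail = "no seed nodes"),
                     class = "plastid_assembly"))
  tip_max <- params$tip_max_len %||% (2L * k)
  ug <- unitig_graph(graph$nodes, k, tip_max)
  tigs <- ug$tigs; links <- ug$links
  contigs <- tibble::tibble(seq = tigs$seq, cov = tigs$cov,
                            circular = tigs$circular)
  # case 1: one circular unitig, nothing else -> complete, no IR
  if (nrow(tigs) == 1 && tigs$circular[1]) {
    cs <- min_rotation(tigs$seq[1], both_strands = TRUE)
    return(structure(list(status = "complete", contigs = contigs,
                          canonical_sequence = cs, layout = empty_layout,
                          k = k, detail = "circular, no IR detected"),
                     class = "plastid_assembly"))
  }
  # case 2: three linear unitigs admitting the quadripartite walk
  if (nrow(tigs) == 3 && !any(tigs$circular)) {
    iid <- tigs$id[which.max(tigs$cov)]
    singles <- setdiff(tigs$id, iid)
    cov_ok <- tigs$cov[iid] >= 1.5 * max(tigs$cov[singles])
    if (cov_ok) {
      for (perm in list(singles, rev(singles))) {
        A <- perm[1]; B <- perm[2]
        for (oA in c("+", "-")) for (oB in c("+", "-")) {
          if (has_link(links, A, oA, iid, "+") &&
              has_link(links, iid, "+", B, oB) &&
              has_link(links, B, oB, iid, "-") &&
              has_link(links, iid, "-", A, oA)) {
            sA <- seq_or(tigs$seq[tigs$id == A], oA)
            sB <- seq_or(tigs$seq[tigs$id == B], oB)
            sI <- tigs$seq[tigs$id == iid]
            if (nchar(sB) > nchar(sA)) {  # LSC is the longer single copy
              tmp <- sA; sA <- sB; sB <- tmp
              sI <- revcomp(sI)
            }
            res <- finish_quadripartite(sA, sI, sB, k)
            return(structure(list(status = "complete", contigs = contigs,
                                  canonical_sequence = res$seq,
                                  layout = res$layout, k = k,
                                  detail = "quadripartite closed walk"),
                             class = "plastid_assembly"))
          }
        }
      }
    }
    detail <- "three contigs but no closed quadripartite walk"
  } else {
    detail <- sprintf("%d contigs; no closed walk found", nrow(tigs))
  }
  structure(list(status = "partial", contigs = contigs,
                 canonical_sequence = NULL, layout = empty_layout,
                 k = k, detail = detail), class = "plastid_assembly")
}

# assemble the closed walk LSC(+IRjunction overlaps), IR, SSC, rc(IR) into
# the canonical circular sequence and its quadripartite layout
finish_quadripartite <- function(sA, sI, sB, k) {
  drop1 <- function(s) substring(s, k)  # drop the k-1 overlap prefix
  cs0 <- paste0(sA, drop1(sI), drop1(sB), drop1(revcomp(sI)))
  n <- nchar(cs0) - (k - 1)
  cs0 <- substr(cs0, 1, n)              # wrap overlap into the LSC
  cs <- rotate_seq(cs0, k - 1)          # start at the biological LSC start
  lsc <- nchar(sA) - 2 * (k - 1)
  ir <- nchar(sI)
  ssc <- nchar(sB) - 2 * (k - 1)
  norm_ssc <- function(s) {
    sscseq <- substr(s, lsc + ir + 1, lsc + ir + ssc)
    rc <- revcomp(sscseq)
    if (rc < sscseq)
      s <- paste0(substr(s, 1, lsc + ir), rc,
                  substr(s, lsc + ir + ssc + 1, nchar(s)))
    s
  }
  cand1 <- norm_ssc(cs)
  alt <- rotate_seq(revcomp(cs), n - lsc)  # other strand, re-anchored at LSC
  cand2 <- norm_ssc(alt)
  best <- if (cand2 < cand1) cand2 else cand1
  layout <- tibble::tibble(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = as.integer(c(0, lsc, lsc + ir, lsc + ir + ssc)),
    end = as.integer(c(lsc, lsc + ir, lsc + ir + ssc, n)))
  list(seq = best, layout = layout)
}

#' @export
print.plastid_assembly <- function(x, ...) {
  cat(sprintf("<plastid_assembly> status=%s, %d contig(s)%s (%s)\n",
              x$status, nrow(x$contigs),
              if (!is.null(x$canonical_sequence))
                sprintf(", %d bp circular", nchar(x$canonical_sequence))
              else "", x$detail))
  invisible(x)
}

# ---------------------------------------------------------------------------
# rDNA unfolding

#' Unfold the nrDNA graph, collapsing the tandem repeat
#'
#' The tandem rDNA array induces a cycle in the De Bruijn graph (one unit
#' long) with the unique flanking spacers attached at the copy junction.
#' The cycle is traversed exactly once, so the reported contig spans
#' flank-unit-flank regardless of the number of tandem copies.  A single
#' linear unitig (one copy with unique flanks) is likewise complete.
#'
#' @param graph a [build_graph()] result (from nrDNA seeds).
#' @param params a [graph_params()].
#' @return object of class `rdna_assembly`: `status`, `unit_contig`
#'   (sequence string when complete), `contigs` tibble, and `k`.
#' @export
unfold_rdna <- function(graph, params = graph_params()) {
  stopifnot(inherits(graph, "debruijn_graph"))
  k <- graph$k
  if (graph$status == "no_seed" || nrow(graph$nodes) == 0)
    return(structure(list(status = "no_seed", unit_contig = NULL,
                          contigs = tibble::tibble(seq = character(),
                                                   cov = double(),
                                                   circular = logical()),
                          k = k), class = "rdna_assembly"))
  tip_max <- params$tip_max_len %||% (2L * k)
  ug <- unitig_graph(graph$nodes, k, tip_max)
  tigs <- ug$tigs; links <- ug$links
  contigs <- tibble::tibble(seq = tigs$seq, cov = tigs$cov,
                            circular = tigs$circular)
  done <- function(seq) structure(list(status = "complete",
                                       unit_contig = seq, contigs = contigs,
                                       k = k), class = "rdna_assembly")
  if (nrow(tigs) == 1 && !tigs$circular[1] && nrow(links) == 0)
    return(done(tigs$seq[1]))
  if (nrow(tigs) == 1 && tigs$circular[1])
    return(done(min_rotation(tigs$seq[1], both_strands = TRUE)))
  # the tandem array induces a cycle: either a self-linked unit path, or a
  # unit path X plus a short bridge unitig B spanning the copy junction
  cyc <- find_unit_cycle(tigs, links)
  if (!is.null(cyc)) {
    X <- cyc$X; oX <- cyc$oX
    members <- c(X, cyc$B)
    into <- links[links$to == X & links$to_or == oX &
                    !(links$from %in% members), ]
    out <- links[links$from == X & links$from_or == oX &
                   !(links$to %in% members), ]
    xseq <- seq_or(tigs$seq[tigs$id == X], oX)
    if (nrow(into) == 1 && nrow(out) == 1 &&
        nrow(tigs) == length(members) + 2) {
      # flank - one unit traversal - flank
      f1 <- seq_or(tigs$seq[tigs$id == into$from], into$from_or)
      f2 <- seq_or(tigs$seq[tigs$id == out$to], out$to_or)
      return(done(paste0(f1, substring(xseq, k), substring(f2, k))))
    }
    if (nrow(tigs) == length(members)) {
      # bare cycle (no flanks assembled): one unit, rotation arbitrary
      u <- xseq
      if (!is.null(cyc$B)) {
        u <- paste0(u, substring(seq_or(tigs$seq[tigs$id == cyc$B],
                                        cyc$oB), k))
        u <- substr(u, 1, nchar(u) - (k - 1))  # trim the wrap overlap
      }
      return(done(u))
    }
  }
  structure(list(status = "partial", unit_contig = NULL, contigs = contigs,
                 k = k), class = "rdna_assembly")
}

# locate the tandem-unit cycle in the unitig graph: a unitig linked to
# itself end-to-start, or a pair (X, B) linked X->B->X; X is the longer
# member (the unit path), B the copy-junction bridge
find_unit_cycle <- function(tigs, links) {
  for (i in seq_len(nrow(links))) {
    u <- links$from[i]; ou <- links$from_or[i]
    w <- links$to[i]; ow <- links$to_or[i]
    if (u == w && ou == ow)
      return(list(X = u, oX = ou, B = NULL, oB = NULL))
    if (u != w && has_link(links, w, ow, u, ou)) {
      if (tigs$n_kmers[tigs$id == u] >= tigs$n_kmers[tigs$id == w])
        return(list(X = u, oX = ou, B = w, oB = ow))
      return(list(X = w, oX = ow, B = u, oB = ou))
    }
  }
  NULL
}

#' @export
print.rdna_assembly <- function(x, ...) {
  cat(sprintf("<rdna_assembly> status=%s, %d contig(s)%s\n",
              x$status, nrow(x$contigs),
              if (!is.null(x$unit_contig))
                sprintf(", unit %d bp", nchar(x$unit_contig)) else ""))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Output formats

#' Write assembled contigs as FASTA
#'
#' Complete plastid assemblies carry the circular flag and quadripartite
#' layout in the description line
#' (`circular=true LSC=0..2000 IRb=2000..2500 ...`).
#'
#' @param assembly a `plastid_assembly` or `rdna_assembly`.
#' @param path output file.
#' @param name sequence name prefix.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(assembly, path, name = "contig") {
  if (inherits(assembly, "plastid_assembly") &&
      assembly$status == "complete") {
    desc <- "circular=true"
    if (nrow(assembly$layout) > 0)
      desc <- paste(desc, paste(sprintf("%s=%d..%d", assembly$layout$region,
                                        assembly$layout$start,
                                        assembly$layout$end),
                                collapse = " "))
    x <- Biostrings::DNAStringSet(assembly$canonical_sequence)
    names(x) <- paste(name, desc)
  } else if (inherits(assembly, "rdna_assembly") &&
             assembly$status == "complete") {
    x <- Biostrings::DNAStringSet(assembly$unit_contig)
    names(x) <- paste(name, "rdna_unit")
  } else {
    x <- Biostrings::DNAStringSet(assembly$contigs$seq)
    names(x) <- sprintf("%s_%d cov=%.1f circular=%s", name,
                        seq_len(nrow(assembly$contigs)),
                        assembly$contigs$cov,
                        tolower(assembly$contigs$circular))
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Dump the unitig graph as GFA 1.0
#'
#' @param graph a [build_graph()] result.
#' @param path output file.
#' @param params a [graph_params()] (tip pruning applies before the dump).
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path, params = graph_params()) {
  stopifnot(inherits(graph, "debruijn_graph"))
  k <- graph$k
  ug <- unitig_graph(graph$nodes, k, params$tip_max_len %||% (2L * k))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  for (i in seq_len(nrow(ug$tigs)))
    writeLines(sprintf("S\t%d\t%s\tDP:f:%.1f", ug$tigs$id[i],
                       ug$tigs$seq[i], ug$tigs$cov[i]), con)
  l <- ug$links
  for (i in seq_len(nrow(l)))
    writeLines(sprintf("L\t%d\t%s\t%d\t%s\t%dM", l$from[i], l$from_or[i],
                       l$to[i], l$to_or[i], k - 1L), con)
  invisible(path)
}
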