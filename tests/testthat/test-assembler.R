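# shared fixture: error-free reads from a small quadripartite plastome
# with planted markers, plus the rDNA array
asm_fixture <- function(seed = 1, depth = 90, lsc = 4000, ssc = 1500,
                        ir = 800) {
  withr::with_seed(seed * 1000 + 7, {
    matk <- random_peptide(30)
    rbcl <- random_peptide(30)
  })
  spec <- toy_spec(seed = seed, matk = matk, rbcl = rbcl,
                   lsc_len = lsc, ssc_len = ssc, ir_len = ir)
  gp <- make_plastid_genome(spec)
  gr <- make_rdna_unit(spec)
  gn <- make_nuclear_background(spec)
  sim <- simulate_read_pairs(list(gp, gr, gn),
                             read_sim_params(target_depth = depth,
                                             seed = seed + 100))
  list(spec = spec, plastid = gp, rdna = gr, nuclear = gn, sim = sim,
       matk = matk, rbcl = rbcl)
}

test_that("nucleotide references seed with exactly the shared k-mers", {
  fx <- asm_fixture(seed = 2, depth = 40)
  reads <- list(fx$sim$r1, fx$sim$r2)
  index <- build_index(reads)
  ref <- substring(fx$rdna$sequence, 601, 3000)
  seeds <- find_seed_kmers(index, seed_reference("nr", "nucleotide", ref),
                           graph_params(), reads)
  shared <- intersect(unique(oracle_kmers(ref, 31)), index$kmer)
  expect_setequal(seeds$kmer, shared)
  expect_true(all(seeds$ref == "nr"))
})

test_that("protein seeding lands inside the planted CDS", {
  fx <- asm_fixture(seed = 3, depth = 40)
  reads <- list(fx$sim$r1, fx$sim$r2)
  index <- build_index(reads)
  seeds <- find_seed_kmers(index,
                           seed_reference("matK", "protein", fx$matk),
                           graph_params(), reads)
  expect_gt(nrow(seeds), 0)
  f <- fx$plastid$features[fx$plastid$features$label == "matK", ]
  margin <- 31L
  locus <- substring(fx$plastid$sequence, max(1, f$start - margin),
                     min(nchar(fx$plastid$sequence), f$end + margin))
  expect_true(any(seeds$kmer %in% oracle_kmers(locus, 31)))
  # all seed k-mers must exist in the index
  expect_true(all(index_lookup(index, seeds$kmer) >= 1))
})

test_that("a random peptide finds no seeds in unrelated reads", {
  withr::with_seed(4, {
    g <- make_nuclear_background(genome_spec(nuclear_len = 10000,
                                             seed = 44))
    sim <- simulate_read_pairs(list(g), read_sim_params(n_pairs = 500,
                                                        seed = 45))
    pep <- random_peptide(100)
  })
  reads <- list(sim$r1, sim$r2)
  index <- build_index(reads)
  seeds <- find_seed_kmers(index, seed_reference("x", "protein", pep),
                           graph_params(), reads)
  expect_equal(nrow(seeds), 0)
  g <- build_graph(index, seeds)
  expect_equal(g$status, "no_seed")
  expect_equal(unfold_plastid(g)$status, "no_seed")
  expect_equal(unfold_rdna(g)$status, "no_seed")
})

test_that("the seeded graph recovers exactly the genome k-mer set", {
  withr::with_seed(5, {
    spec <- genome_spec(lsc_len = 1000, ssc_len = 0, ir_len = 0,
                        planted_genes = list(list(
                          name = "g", peptide = random_peptide(25),
                          region = "LSC")), seed = 55)
  })
  g <- make_plastid_genome(spec)
  sim <- simulate_read_pairs(list(g), read_sim_params(target_depth = 50,
                                                      seed = 56))
  reads <- list(sim$r1, sim$r2)
  index <- build_index(reads)
  pep <- spec$planted_genes[[1]]$peptide
  seeds <- find_seed_kmers(index, seed_reference("g", "protein", pep),
                           graph_params(), reads)
  graph <- build_graph(index, seeds)
  truth_kmers <- unique(oracle_kmers(g$sequence, 31, circular = TRUE))
  expect_setequal(graph$nodes$kmer, truth_kmers)
})

test_that("gap filling restores a window thinned below the threshold", {
  withr::with_seed(6, {
    genome <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                    collapse = "")
  })
  doubled <- paste0(genome, genome)
  # dense tiling; the thinned window kept at ~2x only
  starts <- rep(seq(1, 1000, by = 1), times = 25)
  thin <- starts >= 350 & starts < 560
  keep <- !thin | (seq_along(starts) %% 25 == 0)
  reads <- substring(doubled, starts[keep], starts[keep] + 100)
  index <- build_index(reads, index_params(retain_fraction = 1))
  ref <- substring(genome, 700, 900)
  seeds <- find_seed_kmers(index, seed_reference("s", "nucleotide", ref))
  graph <- build_graph(index, seeds)
  truth_kmers <- unique(oracle_kmers(genome, 31, circular = TRUE))
  expect_gt(graph$threshold, 3)  # the thinned window really is below it
  expect_setequal(graph$nodes$kmer, truth_kmers)
  # and without gap filling the window stays missing
  g0 <- build_graph(index, seeds, graph_params(max_gap_iterations = 0))
  expect_lt(nrow(g0$nodes), length(truth_kmers))
})

test_that("a quadripartite plastome unfolds to a complete circle", {
  fx <- asm_fixture(seed = 7)
  reads <- list(fx$sim$r1, fx$sim$r2)
  index <- build_index(reads)
  seeds <- find_seed_kmers(index,
                           list(seed_reference("matK", "protein", fx$matk),
                                seed_reference("rbcL", "protein", fx$rbcl)),
                           graph_params(), reads)
  asm <- unfold_plastid(build_graph(index, seeds))
  expect_equal(asm$status, "complete")
  expect_true(plastome_equivalent(asm$canonical_sequence,
                                  fx$plastid$sequence, 4000, 800, 1500))
  lay <- asm$layout
  expect_equal(lay$region, c("LSC", "IRb", "SSC", "IRa"))
  expect_equal(lay$end - lay$start, c(4000, 800, 1500, 800))
  # reported IRs are reverse complements of each other
  cs <- asm$canonical_sequence
  irb <- substring(cs, lay$start[2] + 1, lay$end[2])
  ira <- substring(cs, lay$start[4] + 1, lay$end[4])
  expect_identical(ira, oracle_revcomp(irb))
  # IR contig coverage is about twice the single-copy coverage
  covs <- sort(asm$contigs$cov)
  expect_lt(abs(covs[3] / mean(covs[1:2]) - 2), 0.5)
})

test_that("an IR-less circular genome unfolds without an IR layout", {
  withr::with_seed(8, {
    spec <- genome_spec(lsc_len = 3000, ssc_len = 0, ir_len = 0,
                        planted_genes = list(list(
                          name = "g", peptide = random_peptide(25),
                          region = "LSC")), seed = 88)
  })
  g <- make_plastid_genome(spec)
  sim <- simulate_read_pairs(list(g), read_sim_params(target_depth = 60,
                                                      seed = 89))
  reads <- list(sim$r1, sim$r2)
  index <- build_index(reads)
  seeds <- find_seed_kmers(index,
                           seed_reference("g", "protein",
                                          spec$planted_genes[[1]]$peptide),
                           graph_params(), reads)
  asm <- unfold_plastid(build_graph(index, seeds))
  expect_equal(asm$status, "complete")
  expect_equal(nrow(asm$layout), 0)
  expect_true(circular_equivalent(asm$canonical_sequence, g$sequence))
  # canonical form is the lexicographically minimal rotation over strands
  expect_true(asm$canonical_sequence <= g$sequence)
})

test_that("holes in the graph give a partial assembly with contigs", {
  fx <- asm_fixture(seed = 9)
  reads <- list(fx$sim$r1, fx$sim$r2)
  index <- build_index(reads)
  seeds <- find_seed_kmers(index,
                           list(seed_reference("matK", "protein", fx$matk),
                                seed_reference("rbcL", "protein", fx$rbcl)),
                           graph_params(), reads)
  graph <- build_graph(index, seeds)
  # delete two blocks of 100 genome k-mers (in the LSC, away from genes)
  gone <- unique(oracle_kmers(substring(fx$plastid$sequence, 200, 430),
                              31))
  gone <- c(gone, unique(oracle_kmers(substring(fx$plastid$sequence,
                                                3000, 3230), 31)))
  graph$nodes <- graph$nodes[!(graph$nodes$kmer %in% gone), ]
  asm <- unfold_plastid(graph)
  expect_equal(asm$status, "partial")
  expect_gte(nrow(asm$contigs), 2)
})

test_that("the tandem rDNA array collapses to one unit with flanks", {
  for (copies in c(1, 2, 3)) {
    spec <- toy_spec(seed = 20 + copies, rdna_copies = copies)
    gr <- make_rdna_unit(spec)
    gn <- make_nuclear_background(spec)
    sim <- simulate_read_pairs(list(gr, gn),
                               read_sim_params(target_depth = 90,
                                               seed = 30 + copies))
    reads <- list(sim$r1, sim$r2)
    index <- build_index(reads)
    unit_len <- sum(spec$rdna_subregion_lens)
    ref <- substring(gr$sequence, spec$rdna_flank_len + 1,
                     spec$rdna_flank_len + unit_len)
    seeds <- find_seed_kmers(index,
                             seed_reference("nr", "nucleotide", ref))
    asm <- unfold_rdna(build_graph(index, seeds))
    expect_equal(asm$status, "complete")
    # one full 18S..28S span, present exactly once
    span <- paste0("(", ref, ")|(", oracle_revcomp(ref), ")")
    n_units <- lengths(regmatches(asm$unit_contig,
                                  gregexpr(ref, asm$unit_contig,
                                           fixed = TRUE)))
    n_units_rc <- lengths(regmatches(asm$unit_contig,
                                     gregexpr(oracle_revcomp(ref),
                                              asm$unit_contig,
                                              fixed = TRUE)))
    expect_equal(n_units + n_units_rc, 1)
  }
})

test_that("assembly is deterministic for identical inputs", {
  fx <- asm_fixture(seed = 11, depth = 60)
  reads <- list(fx$sim$r1, fx$sim$r2)
  run <- function() {
    index <- build_index(reads)
    seeds <- find_seed_kmers(index,
                             list(seed_reference("matK", "protein",
                                                 fx$matk)),
                             graph_params(), reads)
    graph <- build_graph(index, seeds)
    list(graph = graph, asm = unfold_plastid(graph))
  }
  a <- run(); b <- run()
  expect_identical(a$graph$nodes, b$graph$nodes)
  expect_identical(a$asm$canonical_sequence, b$asm$canonical_sequence)
  expect_identical(a$asm$contigs, b$asm$contigs)
})

test_that("random plastomes are recovered exactly at high depth", {
  for (i in 1:5) {
    withr::with_seed(300 + i, {
      lsc <- sample(3000:5000, 1)
      ssc <- sample(1000:2000, 1)
      ir <- sample(500:1000, 1)
    })
    fx <- asm_fixture(seed = 40 + i, lsc = lsc, ssc = ssc, ir = ir)
    reads <- list(fx$sim$r1, fx$sim$r2)
    index <- build_index(reads)
    seeds <- find_seed_kmers(index,
                             list(seed_reference("matK", "protein",
                                                 fx$matk),
                                  seed_reference("rbcL", "protein",
                                                 fx$rbcl)),
                             graph_params(), reads)
    asm <- unfold_plastid(build_graph(index, seeds))
    expect_equal(asm$status, "complete")
    expect_true(plastome_equivalent(asm$canonical_sequence,
                                    fx$plastid$sequence, lsc, ir, ssc))
  }
})

test_that("deeper sequencing never loses genome k-mers", {
  spec <- toy_spec(seed = 12)
  gp <- make_plastid_genome(spec)
  truth_kmers <- unique(oracle_kmers(gp$sequence, 31, circular = TRUE))
  missing <- integer(0)
  status <- character(0)
  for (depth in c(5, 10, 20, 50)) {
    sim <- simulate_read_pairs(list(gp),
                               read_sim_params(target_depth = depth,
                                               seed = 61))
    reads <- list(sim$r1, sim$r2)
    index <- build_index(reads)
    seeds <- find_seed_kmers(index,
                             seed_reference("lsc", "nucleotide",
                                            substring(gp$sequence, 1,
                                                      2000)))
    graph <- build_graph(index, seeds)
    asm <- unfold_plastid(graph)
    missing <- c(missing, sum(!(truth_kmers %in% graph$nodes$kmer)))
    status <- c(status, asm$status)
  }
  expect_true(all(diff(missing) <= 0))
  expect_true(all(status[missing > 0] != "complete"))
})

test_that("contig FASTA and GFA outputs are well-formed", {
  fx <- asm_fixture(seed = 13, depth = 60)
  reads <- list(fx$sim$r1, fx$sim$r2)
  index <- build_index(reads)
  seeds <- find_seed_kmers(index,
                           seed_reference("matK", "protein", fx$matk),
                           graph_params(), reads)
  graph <- build_graph(index, seeds)
  asm <- unfold_plastid(graph)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "contigs.fasta")
  write_contigs_fasta(asm, fa)
  x <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(x), 1)
  expect_match(names(x), "circular=true")
  expect_match(names(x), "LSC=0\\.\\.4000")
  expect_identical(as.character(x[[1]]), asm$canonical_sequence)
  gfa <- file.path(dir, "graph.gfa")
  write_gfa(graph, gfa)
  lines <- readLines(gfa)
  expect_equal(lines[1], "H\tVN:Z:1.0")
  expect_equal(sum(startsWith(lines, "S\t")), 3)
  expect_true(all(grepl("30M$", lines[startsWith(lines, "L\t")])))
})
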