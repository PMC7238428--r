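test_that("a perfect embedding is found with full identity on + and -", {
  prot <- seed_reference("toy", "protein", "MKT")
  hit <- align_protein_to_contig(prot, "GGGGATGAAAACCGGGG",
                                 align_params())
  expect_false(is.null(hit))
  expect_equal(hit$identity, 1)
  expect_equal(hit$strand, "+")
  expect_equal(nrow(hit$intervals), 1)
  expect_equal(hit$intervals$end - hit$intervals$start, 9)
  expect_identical(hit$cds, "ATGAAAACC")
  expect_identical(hit$peptide, "MKT")
  rc <- oracle_revcomp("GGGGATGAAAACCGGGG")
  hit2 <- align_protein_to_contig(prot, rc, align_params())
  expect_equal(hit2$score, hit$score)
  expect_equal(hit2$strand, "-")
  expect_identical(hit2$cds, "ATGAAAACC")
})

test_that("alignment scores equal the brute-force DP oracle", {
  p <- align_params()
  mat <- genoskim:::aa_score_matrix(p)
  withr::with_seed(21, {
    for (i in 1:60) {
      prot <- random_peptide(sample(3:10, 1), first_m = FALSE)
      contig <- paste(sample(c("A", "C", "G", "T"), sample(15:60, 1),
                             TRUE), collapse = "")
      hit <- align_protein_to_contig(
        seed_reference("q", "protein", prot), contig,
        align_params(min_identity = 1e-9, min_coverage_of_ref = 1e-9))
      best <- 0
      for (s in c(contig, oracle_revcomp(contig))) {
        for (f in 0:2) {
          aa <- oracle_translate(substring(s, f + 1))
          if (nchar(aa) == 0) next
          best <- max(best, oracle_sw_score(prot, aa, mat, p$gap_open,
                                            p$gap_extend))
        }
      }
      expect_equal(if (is.null(hit)) 0 else hit$score, best)
    }
  })
})

test_that("a one-mismatch toy alignment scores as the oracle says", {
  p <- align_params()
  mat <- genoskim:::aa_score_matrix(p)
  # MKTW vs contig encoding MKAW: one substitution under BLOSUM62
  contig <- "ATGAAAGCCTGG"
  hit <- align_protein_to_contig(seed_reference("q", "protein", "MKTW"),
                                 contig,
                                 align_params(min_identity = 0.5))
  oracle <- oracle_sw_score("MKTW", oracle_translate(contig), mat,
                            p$gap_open, p$gap_extend)
  expect_equal(hit$score, oracle)
  expect_equal(hit$identity, 3 / 4)
})

test_that("markers are recovered exactly from an assembled toy plastome", {
  withr::with_seed(23, {
    matk <- random_peptide(30)
    rbcl <- random_peptide(20)
  })
  spec <- toy_spec(seed = 23, matk = matk, rbcl = rbcl)
  gp <- make_plastid_genome(spec)
  sim <- simulate_read_pairs(list(gp), read_sim_params(target_depth = 90,
                                                       seed = 24))
  reads <- list(sim$r1, sim$r2)
  index <- build_index(reads)
  seeds <- find_seed_kmers(index,
                           list(seed_reference("matK", "protein", matk),
                                seed_reference("rbcL", "protein", rbcl)),
                           graph_params(), reads)
  asm <- unfold_plastid(build_graph(index, seeds))
  expect_equal(asm$status, "complete")
  for (gene in list(c("matK", matk), c("rbcL", rbcl))) {
    mk <- extract_marker(asm, seed_reference(gene[1], "protein", gene[2]))
    expect_equal(mk$status, "success")
    truth <- feature_seq(gp, gene[1])
    truth <- substr(truth, 1, nchar(truth) - 3)  # planted ORF minus stop
    expect_identical(mk$sequence, truth)
    expect_identical(mk$peptide, gene[2])
  }
  # a marker absent from the genome fails
  withr::with_seed(25, absent <- random_peptide(40))
  mk <- extract_marker(asm, seed_reference("none", "protein", absent))
  expect_equal(mk$status, "failed")
})

test_that("extraction tolerates sequencing errors at fixed seeds", {
  withr::with_seed(26, matk <- random_peptide(40))
  spec <- toy_spec(seed = 26, matk = matk)
  gp <- make_plastid_genome(spec)
  sim <- simulate_read_pairs(list(gp),
                             read_sim_params(target_depth = 90,
                                             error_rate = 0.01,
                                             seed = 27))
  reads <- list(sim$r1, sim$r2)
  index <- build_index(reads)
  seeds <- find_seed_kmers(index,
                           seed_reference("matK", "protein", matk),
                           graph_params(), reads)
  asm <- unfold_plastid(build_graph(index, seeds))
  mk <- extract_marker(asm, seed_reference("matK", "protein", matk))
  expect_equal(mk$status, "success")
  npep <- nchar(mk$peptide)
  ident <- sum(strsplit(mk$peptide, "")[[1]][seq_len(min(npep, 40))] ==
                 strsplit(matk, "")[[1]][seq_len(min(npep, 40))])
  expect_gte(ident / 40, 0.95)
})

test_that("ITS2 is delimited exactly by its conserved flanks", {
  spec <- toy_spec(seed = 28)
  gr <- make_rdna_unit(spec)
  sim <- simulate_read_pairs(list(gr), read_sim_params(target_depth = 90,
                                                       seed = 29))
  reads <- list(sim$r1, sim$r2)
  index <- build_index(reads)
  unit_len <- sum(spec$rdna_subregion_lens)
  ref <- substring(gr$sequence, spec$rdna_flank_len + 1,
                   spec$rdna_flank_len + unit_len)
  seeds <- find_seed_kmers(index, seed_reference("nr", "nucleotide", ref))
  rdna <- unfold_rdna(build_graph(index, seeds))
  expect_equal(rdna$status, "complete")
  f58 <- seed_reference("5.8S", "nucleotide", feature_seq(gr, "5.8S"))
  f28 <- seed_reference("28S", "nucleotide", feature_seq(gr, "28S"))
  its2 <- extract_its2(rdna, f58, f28)
  expect_equal(its2$status, "success")
  expect_identical(its2$sequence, feature_seq(gr, "ITS2"))
  # reverse-complemented input yields the identical marker
  rc <- extract_its2(oracle_revcomp(rdna$unit_contig), f58, f28)
  expect_identical(rc$sequence, its2$sequence)
  # missing 28S flank: failed
  no28 <- substring(rdna$unit_contig, 1, 100)
  expect_equal(extract_its2(no28, f58, f28)$status, "failed")
})

test_that("strand symmetry holds for extraction from raw contigs", {
  withr::with_seed(31, {
    pep <- random_peptide(25)
    bg <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  })
  orf <- paste0(genoskim:::reverse_translate(pep), "TAA")
  contig <- paste0(substr(bg, 1, 200), orf, substr(bg, 201, 400))
  ref <- seed_reference("g", "protein", pep)
  m1 <- extract_marker(contig, ref)
  m2 <- extract_marker(oracle_revcomp(contig), ref)
  expect_equal(m1$status, "success")
  expect_identical(m1$sequence, m2$sequence)
})

test_that("in-frame stops split a hit into multiple intervals", {
  withr::with_seed(32, {
    pepA <- random_peptide(12, first_m = FALSE)
    pepB <- random_peptide(12, first_m = FALSE)
  })
  prot <- paste0(pepA, pepB)
  dna <- paste0(genoskim:::reverse_translate(pepA), "TGA",
                genoskim:::reverse_translate(pepB))
  contig <- paste0("GGGGG", dna, "GGGGG")
  hit <- align_protein_to_contig(seed_reference("sp", "protein", prot),
                                 contig,
                                 align_params(min_identity = 0.5,
                                              min_coverage_of_ref = 0.5))
  expect_false(is.null(hit))
  expect_gte(nrow(hit$intervals), 2)
  expect_false(grepl("\\*", hit$peptide))
})

test_that("marker status rows feed the per-sample table", {
  ok <- structure(list(marker = "matK", status = "success",
                       sequence = "ATG"), class = "extracted_marker")
  bad <- structure(list(marker = "ITS2", status = "failed",
                        sequence = NULL), class = "extracted_marker")
  row <- marker_status_row("s1", list(matK = ok, rbcL = ok, ITS2 = bad))
  expect_true(row$matK && row$rbcL)
  expect_false(row$ITS2)
  expect_false(row$all_three)
})
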