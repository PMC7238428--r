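test_that("k-mer depth recovers the simulated coverage within 10%", {
  withr::with_seed(51, matk <- random_peptide(30))
  spec <- toy_spec(seed = 51, matk = matk)
  gp <- make_plastid_genome(spec)
  gr <- make_rdna_unit(spec)
  sim <- simulate_read_pairs(list(gp, gr),
                             read_sim_params(target_depth = 90, seed = 52))
  reads <- list(sim$r1, sim$r2)
  index <- build_index(reads)
  seeds <- find_seed_kmers(index, seed_reference("matK", "protein", matk),
                           graph_params(), reads)
  plastid <- unfold_plastid(build_graph(index, seeds))
  unit_ref <- substring(gr$sequence, spec$rdna_flank_len + 1,
                        spec$rdna_flank_len +
                          sum(spec$rdna_subregion_lens))
  rseeds <- find_seed_kmers(index,
                            seed_reference("nr", "nucleotide", unit_ref))
  rdna <- unfold_rdna(build_graph(index, rseeds))
  m <- compute_library_metrics(plastid, rdna, index, sim)
  expect_true(m$cp_complete)
  expect_lt(abs(m$depth_cp - 90) / 90, 0.10)
  # insert estimate within 3 SE of the simulated mean (sd = 0.1 * mean)
  se <- 35 / sqrt(m$insert_n)
  expect_lt(abs(m$insert_mean - 350), 3 * se + 1)
  # empty assemblies give undefined (NA) metrics, not zero
  m0 <- compute_library_metrics(NULL, NULL, index, NULL)
  expect_true(is.na(m0$depth_cp) && is.na(m0$depth_nr))
})

test_that("success rates reproduce the published campaign percentages", {
  sv <- survey_counts()
  pct <- function(g, num, den)
    rate_percent(sv[[num]][sv$group == g], sv[[den]][sv$group == g])
  expect_equal(pct("all", "cp_complete", "specimens"), 67)
  expect_equal(pct("silica", "cp_complete", "libraries"), 70)
  expect_equal(pct("herbarium", "cp_complete", "libraries"), 54)
  expect_equal(pct("all", "nr_complete", "specimens"), 86)
  expect_equal(pct("silica", "nr_complete", "libraries"), 85)
  expect_equal(pct("herbarium", "nr_complete", "libraries"), 83)
  expect_true(is.na(rate_percent(0, 0)))
  expect_equal(rate_percent(0, 10), 0)
})

test_that("success_rates groups, pools and switches denominators", {
  rec <- dplyr::bind_rows(
    lapply(1:10, function(i) library_record(
      paste0("s", i), preservation = "silica",
      metrics = tibble::tibble(cp_complete = i <= 7))),
    lapply(1:10, function(i) library_record(
      paste0("h", i), preservation = "herbarium",
      metrics = tibble::tibble(cp_complete = i <= 5))))
  st <- success_rates(rec, by = "preservation", outcome = "cp_complete")
  expect_equal(st$percent[st$group == "silica"], 70)
  expect_equal(st$percent[st$group == "herbarium"], 50)
  # scale invariance: x10 replication leaves percentages unchanged
  rec10 <- dplyr::bind_rows(lapply(1:10, function(i) {
    r <- rec; r$library <- paste0(r$library, "_", i)
    r$specimen <- r$library; r
  }))
  st10 <- success_rates(rec10, by = "preservation",
                        outcome = "cp_complete")
  expect_equal(st10$percent, st$percent)
  # pooling the groups reproduces the direct pooled rate
  pooled <- success_rates(rec, by = NULL, outcome = "cp_complete")
  expect_equal(pooled$successes, 12)
  expect_equal(pooled$total, 20)
  expect_equal(pooled$percent, round(100 * 12 / 20))
  # specimen denominator: two libraries of one specimen count once
  rec$specimen <- rep(paste0("sp", 1:10), 2)
  sp <- success_rates(rec, by = NULL, outcome = "cp_complete",
                      denominator = "specimens")
  expect_equal(sp$total, 10)
  expect_equal(sp$successes, sum((1:10 <= 7) | (1:10 <= 5)))
})

test_that("Fisher p-values equal enumeration and match stats::fisher.test", {
  # identical group proportions give p = 1
  expect_equal(fisher_exact_2x2(matrix(c(4, 4, 6, 6), 2)), list(
    p.value = 1, estimate = 1,
    method = "Fisher's exact test (hypergeometric enumeration)")[
      c("p.value", "estimate", "method")],
    tolerance = 1e-12, ignore_attr = TRUE)
  # the (3,1;1,3) table against the brute-force enumeration oracle
  p <- fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p.value
  expect_equal(p, oracle_fisher_p(3, 1, 1, 3))
  # random tables against stats::fisher.test (independent route)
  withr::with_seed(53, {
    for (i in 1:50) {
      tab <- matrix(sample(0:12, 4, TRUE), 2)
      if (sum(tab) == 0) next
      expect_equal(fisher_exact_2x2(tab)$p.value,
                   stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    }
  })
})

test_that("rank-sum statistics take their extreme value on separated data", {
  res <- ranksum_test(1:5, 6:10)
  expect_equal(res$U, 0)
  expect_equal(res$rank_sum, 15)  # group 1 holds ranks 1..5
  res2 <- ranksum_test(6:10, 1:5)
  expect_equal(res2$U, 25)
  expect_equal(res2$rank_sum, 40)
  # exact two-sided p for complete separation of two groups of 5
  expect_equal(res$p.value, 2 / choose(10, 5))
  # large tied samples fall back to the corrected normal approximation
  x <- rep(1:20, 3); y <- rep(5:24, 3)
  res3 <- ranksum_test(x, y)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  expect_equal(res3$p.value, wt$p.value)
  expect_match(res3$method, "tie correction")
  expect_error(ranksum_test(numeric(0), 1:3), "non-empty")
})

test_that("compare_preservation dispatches on the variable type", {
  b <- compare_preservation(matrix(c(3, 1, 1, 3), 2), variable = "binary")
  expect_equal(b$p.value, oracle_fisher_p(3, 1, 1, 3))
  expect_error(compare_preservation(matrix(c(0, 1, 0, 3), 2),
                                    variable = "binary"), "empty")
  c_ <- compare_preservation(c(1, 2, 3), c(4, 5, 6),
                             variable = "continuous")
  expect_equal(c_$rank_sum, 6)
})

test_that("preset libraries differ in depth and insert as expected", {
  withr::with_seed(55, matk <- random_peptide(30))
  spec <- toy_spec(seed = 55, matk = matk)
  gp <- make_plastid_genome(spec)
  gr <- make_rdna_unit(spec)
  gn <- make_nuclear_background(spec)
  metrics <- list()
  for (preset in c("silica", "herbarium")) {
    sim <- simulate_read_pairs(list(gp, gr, gn),
                               read_sim_params(preservation_preset = preset,
                                               n_pairs = 6000, seed = 56))
    reads <- list(sim$r1, sim$r2)
    index <- build_index(reads)
    seeds <- find_seed_kmers(index,
                             seed_reference("matK", "protein", matk),
                             graph_params(), reads)
    plastid <- unfold_plastid(build_graph(index, seeds))
    expect_equal(plastid$status, "complete")
    metrics[[preset]] <- compute_library_metrics(plastid, NULL, index, sim)
  }
  # same total read count, but the herbarium library has lower
  # chloroplast depth and shorter inserts
  expect_lt(metrics$herbarium$depth_cp, metrics$silica$depth_cp)
  expect_lt(metrics$herbarium$insert_mean, metrics$silica$insert_mean)
})
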