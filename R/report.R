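#' Published campaign summary counts
#'
#' Per-group totals from the combined PhyloAlps/PhyloCarpates (silica-gel
#' dried) and PhyloNorway (herbarium) genome-skimming campaigns: specimen
#' and library counts, complete chloroplast and nrDNA assemblies, average
#' sequencing depths and library insert sizes.  These printed totals are
#' the input for the success-rate arithmetic in [success_rates()].
#'
#' @return tibble with one row per group (`all`, `silica`, `herbarium`).
#' @export
survey_counts <- function() {
  tibble::tibble(
    group = c("all", "silica", "herbarium"),
    specimens = c(6655L, 4604L, 2051L),
    libraries = c(6817L, 4726L, 2091L),
    cp_complete = c(4439L, 3303L, 1136L),
    depth_cp = c(278, 318, 187),
    nr_complete = c(5748L, 4021L, 1727L),
    depth_nr = c(603, 674, 444),
    insert_mean = c(316, 346, 249))
}

#' Per-library assembly metrics
#'
#' Sequencing depth is estimated from the index as the total count of the
#' assembly's k-mers divided by the number of k-mer positions, corrected
#' for the read-edge effect (a read of length `L` contributes `L - k + 1`
#' k-mers, so k-mer coverage underestimates nucleotide coverage by
#' `(L - k + 1) / L`); k-mers occurring twice in the assembly (the IR)
#' contribute both positions, which keeps the estimate per-locus.  Insert
#' size is estimated by exact-match placement of a subsample of raw pairs
#' on the assembled sequence (outer distance).
#'
#' @param plastid a `plastid_assembly` (possibly partial or `NULL`).
#' @param rdna an `rdna_assembly` (possibly partial or `NULL`).
#' @param index the `kmer_index` the assemblies were built from.
#' @param pairs a `read_sim` or list with `r1`/`r2` tibbles, for insert
#'   estimation (may be `NULL`).
#' @param n_subsample pairs to place for the insert estimate.
#' @return one-row tibble: `depth_cp`, `depth_nr`, `insert_mean`,
#'   `insert_n` (pairs placed), `cp_complete`, `nr_complete`.  Metrics
#'   that cannot be computed are `NA` (undefined, not zero).
#' @export
compute_library_metrics <- function(plastid, rdna, index, pairs = NULL,
                                    n_subsample = 500) {
  depth_for <- function(seqs, circular) {
    if (length(seqs) == 0) return(NA_real_)
    k <- index$k
    wrapped <- ifelse(circular, paste0(seqs, substring(seqs, 1, k - 1)),
                      seqs)
    ak <- cpp_count_kmers(wrapped, k)
    if (length(ak$kmer) == 0) return(NA_real_)
    counts <- index_lookup(index, ak$kmer)
    L <- index$length_cutoff
    (sum(as.double(counts)) / sum(ak$count)) * L / (L - k + 1)
  }
  depth_cp <- if (is.null(plastid)) NA_real_
    else if (plastid$status == "complete")
      depth_for(plastid$canonical_sequence, TRUE)
    else if (nrow(plastid$contigs) > 0)
      depth_for(plastid$contigs$seq, plastid$contigs$circular)
    else NA_real_
  depth_nr <- if (is.null(rdna)) NA_real_
    else if (rdna$status == "complete") depth_for(rdna$unit_contig, FALSE)
    else if (nrow(rdna$contigs) > 0)
      depth_for(rdna$contigs$seq, rdna$contigs$circular)
    else NA_real_
  ins <- c(mean = NA_real_, n = 0)
  if (!is.null(pairs) && !is.null(plastid) &&
      plastid$status == "complete") {
    ins <- estimate_insert(pairs, plastid$canonical_sequence,
                           circular = TRUE, n_subsample = n_subsample)
  }
  tibble::tibble(depth_cp = depth_cp, depth_nr = depth_nr,
                 insert_mean = unname(ins["mean"]),
                 insert_n = as.integer(ins["n"]),
                 cp_complete = !is.null(plastid) &&
                   plastid$status == "complete",
                 nr_complete = !is.null(rdna) &&
                   rdna$status == "complete")
}

# outer distance of exactly placed pairs on a reference sequence
estimate_insert <- function(pairs, ref, circular = TRUE,
                            n_subsample = 500) {
  r1 <- pairs$r1$seq
  r2 <- pairs$r2$seq
  n <- length(r1)
  if (n == 0) return(c(mean = NA_real_, n = 0))
  idx <- if (n > n_subsample)
    round(seq(1, n, length.out = n_subsample)) else seq_len(n)
  L <- nchar(ref)
  target <- if (circular) paste0(ref, ref) else ref
  inserts <- numeric(0)
  for (i in idx) {
    rl1 <- nchar(r1[i]); rl2 <- nchar(r2[i])
    p1 <- regexpr(r1[i], target, fixed = TRUE)[1]
    ins <- NA_real_
    if (p1 > 0) {
      p2 <- regexpr(revcomp(r2[i]), target, fixed = TRUE)[1]
      if (p2 > 0) ins <- (p2 + rl2) - p1
    } else {
      p1b <- regexpr(revcomp(r1[i]), target, fixed = TRUE)[1]
      p2b <- regexpr(r2[i], target, fixed = TRUE)[1]
      if (p1b > 0 && p2b > 0) ins <- (p1b + rl1) - p2b
    }
    if (!is.na(ins)) {
      if (circular) {
        ins <- ins %% L
        if (ins == 0) ins <- L
      }
      if (ins >= min(rl1, rl2) && ins <= L) inserts <- c(inserts, ins)
    }
  }
  if (length(inserts) == 0) return(c(mean = NA_real_, n = 0))
  c(mean = mean(inserts), n = length(inserts))
}

#' Assemble a library record
#'
#' One row of the per-library table that feeds [success_rates()] and
#' [compare_preservation()].
#'
#' @param library library identifier.
#' @param project project name.
#' @param preservation `"silica"` or `"herbarium"`.
#' @param metrics a [compute_library_metrics()] row (or `NULL`).
#' @param matk,rbcl,its2 marker success flags.
#' @param specimen optional specimen identifier (for the specimen
#'   denominator).
#' @param age_years,collection_doy optional covariates.
#' @return one-row tibble.
#' @export
library_record <- function(library, project = NA_character_,
                           preservation = c("silica", "herbarium"),
                           metrics = NULL, matk = NA, rbcl = NA,
                           its2 = NA, specimen = library,
                           age_years = NA_real_,
                           collection_doy = NA_real_) {
  preservation <- match.arg(preservation)
  base <- tibble::tibble(library = library, specimen = specimen,
                         project = project, preservation = preservation,
                         matk = matk, rbcl = rbcl, its2 = its2,
                         age_years = age_years,
                         collection_doy = collection_doy)
  if (!is.null(metrics)) base <- dplyr::bind_cols(base, metrics)
  base
}

#' Success rates by group
#'
#' Percentages are rounded to the nearest integer (the convention of the
#' published tables); raw successes, totals and the unrounded fraction
#' are retained.  The denominator can be libraries (every row counts) or
#' specimens (rows sharing a `specimen` id collapse; the specimen
#' succeeds when any of its libraries does), because published summaries
#' mix both conventions.
#'
#' @param records tibble of library records.
#' @param by grouping column name (e.g. `"preservation"`), or `NULL` for
#'   a single pooled group.
#' @param outcome logical outcome column name (e.g. `"cp_complete"`).
#' @param denominator `"libraries"` or `"specimens"`.
#' @return tibble of class `success_table` with `successes`, `total`,
#'   `fraction`, `percent` per group.
#' @export
success_rates <- function(records, by = NULL, outcome,
                          denominator = c("libraries", "specimens")) {
  denominator <- match.arg(denominator)
  stopifnot(nrow(records) > 0, outcome %in% names(records))
  df <- records
  df$.group <- if (is.null(by)) "all" else df[[by]]
  df$.out <- df[[outcome]]
  if (denominator == "specimens") {
    if (!"specimen" %in% names(df))
      stop("specimen denominator requires a 'specimen' column")
    df <- df |>
      dplyr::group_by(.data$.group, .data$specimen) |>
      dplyr::summarise(.out = any(.data$.out), .groups = "drop")
  }
  out <- df |>
    dplyr::group_by(group = .data$.group) |>
    dplyr::summarise(successes = sum(.data$.out), total = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(fraction = .data$successes / .data$total,
                  percent = round(100 * .data$successes / .data$total))
  class(out) <- c("success_table", class(out))
  out
}

#' Percentage from printed counts
#'
#' @param successes,total integer counts.
#' @return `round(100 * successes / total)`; `NA` (flagged) for a zero
#'   denominator.
#' @export
rate_percent <- function(successes, total) {
  ifelse(total == 0, NA_real_, round(100 * successes / total))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computed by direct enumeration of the hypergeometric support: the
#' p-value is the sum of the probabilities of all tables with the same
#' margins whose probability does not exceed that of the observed table
#' (with the customary relative tolerance for ties).
#'
#' @param tab 2x2 matrix or table of counts.
#' @return list with `p.value`, `estimate` (sample odds ratio) and
#'   `method`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p.value = min(1, p),
       estimate = (a * d) / (b * c_),
       method = "Fisher's exact test (hypergeometric enumeration)")
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Reports the Mann-Whitney U of group 1 and its rank-sum, with an exact
#' p-value when both groups have at most 10 untied observations and the
#' tie-corrected normal approximation (with continuity correction)
#' otherwise.
#'
#' @param x,y numeric samples for the two groups (non-empty).
#' @return list with `U`, `rank_sum`, `p.value`, `method`.
#' @export
ranksum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  ties <- any(duplicated(c(x, y)))
  exact <- length(x) <= 10 && length(y) <= 10 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  U <- unname(wt$statistic)
  list(U = U, rank_sum = U + length(x) * (length(x) + 1) / 2,
       p.value = wt$p.value,
       method = if (exact) "exact rank-sum" else
         "normal approximation with tie correction")
}

#' Compare preservation groups
#'
#' Binary outcomes (assembly or marker success) are compared with the
#' two-sided Fisher's exact test; continuous variables (depth, insert
#' size, age) with the Wilcoxon rank-sum test.
#'
#' @param x for `variable = "binary"`, a 2x2 matrix of counts (groups in
#'   rows, outcome in columns); for `"continuous"`, the numeric sample of
#'   group 1.
#' @param y for `"continuous"`, the numeric sample of group 2.
#' @param variable `"binary"` or `"continuous"`.
#' @return the corresponding test result list.
#' @export
compare_preservation <- function(x, y = NULL,
                                 variable = c("binary", "continuous")) {
  variable <- match.arg(variable)
  if (variable == "binary") {
    if (any(rowSums(as.matrix(x)) == 0)) stop("a group is empty")
    fisher_exact_2x2(x)
  } else {
    ranksum_test(x, y)
  }
}
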