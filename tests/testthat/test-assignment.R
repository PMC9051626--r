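# Phospho-to-Glu substitution, allelic restriction, QC summaries.

test_that("phospho residues substitute to glutamate, idempotently", {
  expect_equal(substitute_phospho_as_glu("ASKTY", c(2, 4, 5)), "AEKEE")
  expect_equal(substitute_phospho_as_glu("ASKTY", integer(0)), "ASKTY")
  once <- substitute_phospho_as_glu("ASKDPSSR", 6)
  expect_equal(once, "ASKDPESR")
  expect_equal(substitute_phospho_as_glu(once, 6), once)  # E stays E
  expect_error(substitute_phospho_as_glu("ASKDP", 1), "S, T or Y")
})

test_that("the percent-rank cutoff is inclusive and alleles come sorted", {
  bg <- stats::setNames(rep(1 / 23, 23), aa_alphabet23())
  m <- train_allele_model("AAAAAAAAA", bg, allele = "AL1")
  # 9 calibration scores below any real score: %rank is exactly
  # 100 * (1 + 0) / 10 = 10 for every query above them
  m$calibration <- stats::setNames(
    rep(list(seq(-100, -92)), length(12:25)), as.character(12:25))
  srow <- tibble::tibble(sample_id = "s1", alleles = list("AL1"))
  res <- assign_peptide("AAAAAAAAAAAA", integer(0), srow,
                        list(AL1 = m), cutoff = 10)
  expect_equal(nrow(res), 1L)
  expect_equal(res$percent_rank, 10)
  expect_equal(attr(res, "status"), "assigned")
  res2 <- assign_peptide("AAAAAAAAAAAA", integer(0), srow,
                         list(AL1 = m), cutoff = 9.99)
  expect_equal(nrow(res2), 0L)
  expect_equal(attr(res2, "status"), "unassigned")
  expect_error(
    assign_peptide("AAAAAAAAAAAA", integer(0),
                   tibble::tibble(sample_id = "s1", alleles = list("AL2")),
                   list(AL1 = m)),
    "AL2")
})

test_that("assignment partitions peptides and respects the sample's alleles", {
  w <- small_world()
  models <- small_models()
  psms <- filter_psms(w$psms)
  phos <- psms[psms$n_phospho > 0, ]
  res <- assign_peptidome(phos, w$manifest, models)
  # partition of unique (sample, peptide) pairs
  key <- function(tb) paste(tb$sample_id, peptide_key(tb$sequence, tb$phospho))
  uniq_in <- unique(key(phos))
  got <- c(unique(key(res$interactions)), key(res$unassigned))
  expect_setequal(got, uniq_in)
  expect_equal(anyDuplicated(got), 0L)
  # every assigned allele belongs to the peptide's sample manifest
  for (i in seq_len(nrow(res$interactions))) {
    sal <- w$manifest$alleles[[
      match(res$interactions$sample_id[i], w$manifest$sample_id)]]
    expect_true(res$interactions$allele[i] %in% sal)
  }
  # raising the cutoff never loses interactions
  res5 <- assign_peptidome(phos, w$manifest, models, cutoff = 5)
  expect_lte(nrow(res5$interactions), nrow(res$interactions))
  expect_true(all(
    paste(res5$interactions$sample_id, res5$interactions$allele,
          key(res5$interactions)) %in%
    paste(res$interactions$sample_id, res$interactions$allele,
          key(res$interactions))))
})

test_that("random phosphosite peptides are excluded more often than planted ligands", {
  w <- small_world()
  models <- small_models()
  psms <- filter_psms(w$psms)
  phos <- psms[psms$n_phospho > 0, ]
  res <- assign_peptidome(phos, w$manifest, models)
  ctrl <- random_peptide_control(res$interactions, w$catalogue, w$proteome,
                                 w$manifest, models, n = 150, seed = 4)
  frac_unassigned <- nrow(res$unassigned) /
    (nrow(res$unassigned) + length(unique(paste(
      res$interactions$sample_id,
      peptide_key(res$interactions$sequence, res$interactions$phospho)))))
  expect_gt(ctrl$fraction_excluded, frac_unassigned)
})

test_that("score separation reproduces Kolmogorov-Smirnov limits and the ECDF gap", {
  tb <- function(x) tibble::tibble(peptide_score = x, delta_score = x)
  same <- qc_score_separation(tb(c(1, 2, 3, 3)), tb(c(3, 1, 2, 3)))
  expect_equal(same$ks_statistic, c(0, 0))
  disjoint <- qc_score_separation(tb(101:150), tb(1:50))
  expect_equal(disjoint$ks_statistic, c(1, 1))
  expect_error(qc_score_separation(tb(1), tb(numeric(0))), "non-empty")
  # two 50-point samples: statistic equals the brute-force max ECDF gap
  set.seed(31)
  x <- rnorm(50); y <- rnorm(50, 0.5)
  got <- qc_score_separation(tb(x), tb(y))$ks_statistic[1]
  gap <- max(vapply(c(x, y), function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1)))
  expect_equal(got, gap, tolerance = 1e-12)
})

test_that("assigned PSMs score higher than unassigned ones in the default world", {
  w <- small_world()
  models <- small_models()
  psms <- filter_psms(w$psms)
  phos <- psms[psms$n_phospho > 0, ]
  res <- assign_peptidome(phos, w$manifest, models)
  ik <- paste(res$interactions$sample_id,
              peptide_key(res$interactions$sequence,
                          res$interactions$phospho))
  pk <- paste(phos$sample_id, peptide_key(phos$sequence, phos$phospho))
  qc <- qc_score_separation(phos[pk %in% ik, ], phos[!pk %in% ik, ])
  expect_true(all(qc$ks_statistic > 0))
  # contaminants carry lower planted scores, so separation is significant
  expect_lt(qc$p_value[1], 0.05)
})

test_that("peptidome summaries count unique peptides and interactions", {
  inter <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2"),
    allele = c("A", "B", "A", "A"),
    sequence = c("AAASSSAAAAAA", "AAASSSAAAAAA", "CCCTTTCCCCCC",
                 "GGGYYYGGGGGGG"),
    phospho = list(4L, 4L, c(4L, 5L), 4L)
  )
  s <- summarize_peptidome(inter)
  expect_equal(s$n_unique, 3L)
  expect_equal(s$n_interactions, 4L)
  expect_equal(s$phospho_histogram$count[s$phospho_histogram$n_phospho == 2],
               1L)
  expect_equal(sum(s$length_histogram$count), 3L)
})

test_that("the planted phosphosite-multiplicity mixture is recovered", {
  w <- small_world()
  truth <- w$truth[w$truth$type == "ligand", ]
  s <- summarize_peptidome(
    tibble::tibble(sample_id = truth$sample_id, allele = truth$allele,
                   sequence = truth$sequence, phospho = truth$phospho))
  frac <- s$phospho_histogram$fraction
  n <- sum(s$phospho_histogram$count)
  mix <- w$config$phospho_mix
  # within binomial error (3 sigma)
  for (k in seq_along(frac)) {
    expect_lt(abs(frac[k] - mix[k]), 3 * sqrt(mix[k] * (1 - mix[k]) / n))
  }
})
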