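# Motif construction, renormalization, distances, intra/inter test.

test_that("motif building restricts to in-core phosphosites when asked", {
  cores <- c("AAAAS[p]AAAA", "AAAAAAAAA")
  m <- build_motif(cores, restrict_phospho_in_core = TRUE)
  expect_equal(attr(m, "n_cores"), 1L)
  expect_equal(unname(m["pS", 5]), 1)
  all_m <- build_motif(cores)
  expect_equal(attr(all_m, "n_cores"), 2L)
  # no core carries an in-core phosphosite: flagged empty
  e <- build_motif(c("AAAAAAAAA", "CCCCCCCCC"),
                   restrict_phospho_in_core = TRUE)
  expect_true(attr(e, "empty"))
  expect_equal(sum(e), 0)
})

test_that("motif frequencies equal brute-force counts on 50 cores", {
  w <- small_world()
  cores <- sample_cores(inject_phospho_pwm(w$planted[[2]]), 50, seed = 12)
  m <- build_motif(cores)
  symtab <- t(vapply(cores, function(co) {
    p <- parse_mod_peptide(co)
    peptide_symbols(p$sequence, p$phospho)
  }, character(9)))
  for (p in 1:9) {
    counts <- table(factor(symtab[, p], levels = aa_alphabet23()))
    expect_equal(unname(m[, p]), as.numeric(counts) / 50)
  }
  expect_equal(unname(colSums(m)), rep(1, 9), tolerance = 1e-9)
})

test_that("dropping phospho rows renormalizes positions correctly", {
  pwm <- matrix(0, 23, 9, dimnames = list(aa_alphabet23(), NULL))
  pwm["A", ] <- 0.5
  pwm["pS", ] <- 0.5
  r <- renormalize_drop_phospho(pwm)
  expect_equal(unname(r["A", ]), rep(1, 9))
  # zero phospho mass: unchanged
  pwm2 <- build_motif(c("AAAAAAAAA", "CCCCCCCCC"))
  expect_equal(renormalize_drop_phospho(pwm2),
               pwm2[rownames(pwm2)[1:20], ], ignore_attr = TRUE)
  # arbitrary PWM: equals elementwise division by canonical column mass
  w <- small_world()
  pwm3 <- build_motif(sample_cores(inject_phospho_pwm(w$planted[[1]]),
                                   60, seed = 9))
  r3 <- renormalize_drop_phospho(pwm3)
  canon <- pwm3[1:20, ]
  for (p in 1:9) {
    expect_equal(unname(r3[, p]), unname(canon[, p] / sum(canon[, p])))
  }
  # degenerate position with all mass on phospho symbols
  pwm4 <- pwm; pwm4["A", ] <- 0; pwm4["pS", ] <- 1
  expect_error(renormalize_drop_phospho(pwm4), "phospho")
})

test_that("the PWM distance is the Euclidean metric", {
  set.seed(44)
  rand_pwm <- function() {
    m <- matrix(stats::rexp(180), 20, 9)
    sweep(m, 2, colSums(m), "/")
  }
  p <- rand_pwm(); q <- rand_pwm(); r <- rand_pwm()
  expect_equal(pwm_distance(p, p), 0)
  expect_equal(pwm_distance(p, q), pwm_distance(q, p))
  # analytic toy: orthogonal unit columns differ by sqrt(2) per position
  a <- matrix(c(1, 0), 2, 1); b <- matrix(c(0, 1), 2, 1)
  expect_equal(pwm_distance(a, b), sqrt(2))
  # flat double-loop recomputation
  acc <- 0
  for (i in 1:20) for (j in 1:9) acc <- acc + (p[i, j] - q[i, j])^2
  expect_equal(pwm_distance(p, q), sqrt(acc))
  # triangle inequality on random triples
  for (k in 1:20) {
    x <- rand_pwm(); y <- rand_pwm(); z <- rand_pwm()
    expect_lte(pwm_distance(x, z), pwm_distance(x, y) + pwm_distance(y, z) + 1e-12)
  }
  expect_error(pwm_distance(p, matrix(0, 23, 9)), "dimensions")
})

test_that("intra/inter distance sets have the right sizes and degenerate safely", {
  w <- small_world()
  mk_pair <- function(al, pwm20) {
    pp <- inject_phospho_pwm(pwm20)
    tibble::tibble(
      allele = al,
      pwm_unmod = list(build_motif(sample_cores(pwm20, 40, seed = 1))),
      pwm_phos = list(build_motif(sample_cores(pp, 40, seed = 2),
                                  restrict_phospho_in_core = TRUE)),
      n_unmod = 40L, n_phos_all = 40L, n_phos_core = 40L
    )
  }
  pairs <- dplyr::bind_rows(lapply(1:3, function(a) {
    mk_pair(paste0("A", a), planted_allele_pwm(w$config, a))
  }))
  res <- intra_vs_inter_distance_test(pairs, min_phos_core = 10)
  expect_length(res$intra, 3L)
  expect_length(res$inter, 6L)
  expect_error(intra_vs_inter_distance_test(pairs[1, ]), "at least 2")
  # identical motif pairs everywhere: all distances 0, flagged degenerate
  same <- pairs
  same$pwm_phos <- lapply(same$pwm_unmod, function(m) {
    rbind(m[1:20, ], pS = 0, pT = 0, pY = 0)
  })
  for (i in 1:3) same$pwm_unmod[[i]] <- same$pwm_unmod[[1]]
  for (i in 1:3) same$pwm_phos[[i]] <- same$pwm_phos[[1]]
  deg <- intra_vs_inter_distance_test(same)
  expect_true(is.na(deg$p_value))
})

test_that("phospho motifs are closer to their own allele's motif than to others", {
  cfg <- synth_config(seed = 5)
  pairs <- dplyr::bind_rows(lapply(1:10, function(a) {
    pwm20 <- planted_allele_pwm(cfg, a)
    pp <- inject_phospho_pwm(pwm20, positions = c(2, 3, 5, 7, 8))
    tibble::tibble(
      allele = paste0("A", a),
      pwm_unmod = list(build_motif(sample_cores(pwm20, 200, seed = 100 + a))),
      pwm_phos = list(build_motif(sample_cores(pp, 200, seed = 200 + a),
                                  restrict_phospho_in_core = TRUE)),
      n_unmod = 200L, n_phos_all = 200L, n_phos_core = 200L
    )
  }))
  res <- intra_vs_inter_distance_test(pairs)
  expect_lt(stats::median(res$intra), stats::median(res$inter))
  expect_lte(res$p_value, 0.05)
})

test_that("anchor preferences of planted alleles are recovered from phospho ligands", {
  cfg <- synth_config(seed = 5)
  recovered <- 0L
  for (a in 1:10) {
    pwm20 <- planted_allele_pwm(cfg, a)
    anchors <- attr(pwm20, "anchors")
    pp <- inject_phospho_pwm(pwm20, positions = c(2, 3, 5, 7, 8))
    motif <- build_motif(sample_cores(pp, 200, seed = 300 + a),
                         restrict_phospho_in_core = TRUE)
    ok <- all(vapply(names(anchors), function(nm) {
      p <- as.integer(sub("P", "", nm))
      names(which.max(motif[, p])) == anchors[[nm]]
    }, logical(1)))
    if (ok) recovered <- recovered + 1L
  }
  expect_gte(recovered, 9L)
})

test_that("motif matrices export with phospho rows flagged", {
  w <- small_world()
  m <- build_motif(sample_cores(inject_phospho_pwm(w$planted[[1]]), 30,
                                seed = 2))
  f <- tempfile(fileext = ".tsv")
  write_motif_matrix(m, f)
  tab <- utils::read.delim(f, check.names = FALSE)
  expect_equal(nrow(tab), 23L)
  expect_equal(sum(tab$phospho), 3L)
  expect_equal(as.numeric(tab[tab$symbol == "A", paste0("P", 1:9)]),
               unname(m["A", ]))
})
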