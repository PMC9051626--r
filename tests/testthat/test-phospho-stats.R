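# Positional phosphosite statistics and kinase-motif machinery.

test_that("core/PFR classification matches an independent per-residue loop", {
  asn <- tibble::tibble(
    sequence = c("AAAAAASAAAAAAAA", "ASAAAAAAAAAAAA"),
    phospho = list(7L, 2L),
    core_offset = c(3L, 4L)
  )
  res <- phospho_core_vs_pfr(asn)
  # 15-mer, core 3..11, pS at 7 -> in core; 14-mer, core 4..12, pS at 2 -> PFR
  expect_equal(res$n_core[res$class == "phosphosites"], 1L)
  expect_equal(res$n_pfr[res$class == "phosphosites"], 1L)
  # oracle on 100 synthetic peptides
  set.seed(77)
  rows <- lapply(1:100, function(i) {
    len <- sample(12:25, 1)
    pep <- random_mod_peptide(len, n_phospho = sample(1:3, 1))
    tibble::tibble(sequence = pep$sequence, phospho = list(pep$phospho),
                   core_offset = sample(len - 8, 1))
  })
  asn2 <- dplyr::bind_rows(rows)
  res2 <- phospho_core_vs_pfr(asn2)
  ph_core <- 0L; ph_all <- 0L; res_core <- 0L; res_all <- 0L
  for (i in 1:100) {
    len <- nchar(asn2$sequence[i]); off <- asn2$core_offset[i]
    for (pos in seq_len(len)) {
      inc <- pos >= off && pos <= off + 8
      res_all <- res_all + 1L
      if (inc) res_core <- res_core + 1L
      if (pos %in% asn2$phospho[[i]]) {
        ph_all <- ph_all + 1L
        if (inc) ph_core <- ph_core + 1L
      }
    }
  }
  expect_equal(res2$frac_core[res2$class == "phosphosites"], ph_core / ph_all)
  expect_equal(res2$frac_core[res2$class == "all_residues"],
               res_core / res_all)
})

test_that("terminal phosphosites are classified by the three-residue rule", {
  asn <- tibble::tibble(
    sequence = c("ASAAAAAAAAAAAT", "AAAAAAASAAAAAA", "SAAAAAAAAAAAAY"),
    phospho = list(c(2L), 8L, c(1L, 14L))
  )
  res <- terminal_phospho_distribution(asn)
  # peptide 1: pos 2 is N-terminal; peptide 2: pos 8 of 14 is neither;
  # peptide 3: pos 1 N-terminal and pos 14 C-terminal
  expect_equal(res$n_term_sites, 2L)
  expect_equal(res$c_term_sites, 1L)
  expect_equal(res$n_term_peptides, 2L)
  expect_equal(res$c_term_peptides, 1L)
  expect_equal(unname(res$nterm_position_counts), c(1L, 1L, 0L))
})

test_that("a planted C/N terminal split is recovered within binomial error", {
  set.seed(55)
  rows <- lapply(1:500, function(i) {
    len <- sample(13:20, 1)
    side_c <- stats::runif(1) < 0.6
    pos <- if (side_c) len - sample(0:2, 1) else sample(1:3, 1)
    sq <- paste(c(rep("A", pos - 1), "S", rep("A", len - pos)),
                collapse = "")
    tibble::tibble(sequence = substr(sq, 1, len), phospho = list(pos))
  })
  res <- terminal_phospho_distribution(dplyr::bind_rows(rows))
  expect_lt(abs(res$frac_c_of_terminal_sites - 0.6),
            3 * sqrt(0.6 * 0.4 / 500))
})

test_that("core-position frequencies count each in-core site once and sum to one", {
  one <- tibble::tibble(sequence = "AAAASAAAAAAAA", phospho = list(5L),
                        core_offset = 1L, allele = "A")
  r1 <- core_position_distribution(one)
  expect_equal(unname(r1$frequencies[5]), 1)
  two <- tibble::tibble(sequence = "ASAAATAAAAAAA", phospho = list(c(2L, 6L)),
                        core_offset = 1L, allele = "A")
  r2 <- core_position_distribution(two)
  expect_equal(unname(r2$counts[c(2, 6)]), c(1L, 1L))
  expect_equal(sum(r2$frequencies), 1)
  # sites outside the core do not contribute
  pfr <- tibble::tibble(sequence = "SAAAAAAAAAAAAA", phospho = list(1L),
                        core_offset = 4L, allele = "A")
  r3 <- core_position_distribution(pfr)
  expect_equal(sum(r3$counts), 0L)
})

test_that("kinase-motif patterns parse, locate their anchor, and round-trip", {
  m1 <- parse_kinase_motif("[pS/pT]P")
  expect_length(m1$pattern, 2L)
  expect_equal(m1$anchor_index, 1L)
  expect_equal(m1$anchor_set, c("pS", "pT"))
  expect_equal(m1$text, "[pS/pT]P")
  m2 <- parse_kinase_motif("RXX[pS/pT]")
  expect_length(m2$pattern, 4L)
  expect_equal(m2$anchor_index, 4L)
  expect_null(m2$pattern[[2]])
  expect_null(m2$pattern[[3]])
  expect_equal(m2$text, "RXX[pS/pT]")
  m3 <- parse_kinase_motif("[pS/pT]XX[D/E]")
  expect_equal(m3$anchor_index, 1L)
  expect_equal(m3$pattern[[4]], c("D", "E"))
  expect_error(parse_kinase_motif("XX"), "anchor")
  expect_error(parse_kinase_motif("[pS/pT"), "column 1")
  expect_error(parse_kinase_motif("R[pS/T]P"), "anchor position mixes")
})

ctx_row <- function(context, sites) {
  tibble::tibble(sequence = gsub("-", "", context),
                 phospho = list(sites),
                 context = context, context_phospho = list(sites),
                 protein = NA_character_, matched = TRUE)
}

test_that("motif scanning counts anchor-type sites and pattern matches", {
  pSP <- parse_kinase_motif("[pS/pT]P")
  # pS followed by P: one match, denominator one
  hit <- ctx_row("AASPGAAAAAAAA", 3L)
  r <- scan_kinase_motif(pSP, hit, phospho_aware = TRUE)
  expect_equal(r$count, 1L)
  expect_equal(r$denominator, 1L)
  # pS not followed by P: no match, still in the denominator
  miss <- ctx_row("AASGGAAAAAAAA", 3L)
  r2 <- scan_kinase_motif(pSP, miss, phospho_aware = TRUE)
  expect_equal(r2$count, 0L)
  expect_equal(r2$denominator, 1L)
  # unmodified counterpart: S/T sites, phosphosites excluded
  r3 <- scan_kinase_motif(pSP, ctx_row("AASPGTPAAAAAA", 3L),
                          phospho_aware = FALSE)
  expect_equal(r3$denominator, 1L)  # only the unmodified T at 6
  expect_equal(r3$count, 1L)        # TP matches [S/T]P
  # windows running into sentinel padding never match but count
  edge <- ctx_row("--SAAAAAAAAAA--", 3L)  # pS at the very protein start
  rss <- scan_kinase_motif(parse_kinase_motif("R[pS/pT]"), edge,
                           phospho_aware = TRUE)
  expect_equal(rss$count, 0L)
  expect_equal(rss$denominator, 1L)
})

test_that("motif scanning agrees with an independent regex oracle on 200 sites", {
  set.seed(404)
  motifs <- lapply(c("[pS/pT]P", "RXX[pS/pT]", "[pS/pT]XX[D/E]",
                     "P[pS/pY]", "[pT/pY]G"), parse_kinase_motif)
  # 200 random context windows, center phosphosite
  rows <- lapply(1:200, function(i) {
    len <- 11L
    res <- sample(c("A", "R", "P", "D", "E", "G", "S", "T", "Y", "K"),
                  len, replace = TRUE)
    center <- 6L
    res[center] <- sample(c("S", "T", "Y"), 1)
    ctx_row(paste(res, collapse = ""), center)
  })
  ext <- dplyr::bind_rows(rows)
  # oracle: lowercase the phosphosite and run a regular expression
  enc <- vapply(seq_len(nrow(ext)), function(i) {
    ch <- strsplit(ext$context[i], "")[[1]]
    ch[ext$context_phospho[[i]]] <- tolower(ch[ext$context_phospho[[i]]])
    paste(ch, collapse = "")
  }, character(1))
  to_regex <- function(m) {
    paste(vapply(m$pattern, function(s) {
      if (is.null(s)) "[A-Z]"
      else {
        alts <- vapply(s, function(x) {
          if (startsWith(x, "p")) tolower(sub("p", "", x)) else x
        }, character(1))
        paste0("[", paste(alts, collapse = ""), "]")
      }
    }, character(1)), collapse = "")
  }
  for (m in motifs) {
    got <- scan_kinase_motif(m, ext, phospho_aware = TRUE)
    anchor_low <- tolower(sub("p", "", m$anchor_set))
    oracle_denom <- sum(vapply(enc, function(e) {
      substr(e, 6, 6) %in% anchor_low
    }, logical(1)))
    oracle_count <- sum(vapply(enc, function(e) {
      if (!substr(e, 6, 6) %in% anchor_low) return(FALSE)
      start <- 6 - m$anchor_index + 1
      win <- substr(e, start, start + length(m$pattern) - 1)
      grepl(paste0("^", to_regex(m), "$"), win)
    }, logical(1)))
    expect_equal(got$denominator, oracle_denom)
    expect_equal(got$count, oracle_count)
  }
})

test_that("enrichment p-values follow the one-sided hypergeometric tail", {
  # 2x2 table [3,1;1,3]: one-sided p = (16 + 1) / 70
  p <- stats::fisher.test(matrix(c(3, 1, 1, 3), 2, byrow = TRUE),
                          alternative = "greater")$p.value
  expect_equal(p, 17 / 70, tolerance = 1e-12)
  # identical frequencies in both strata: no enrichment direction
  phos <- dplyr::bind_rows(lapply(1:20, function(i) {
    ctx_row(if (i <= 10) "AASPAAAAAAAAA" else "AASGAAAAAAAAA", 3L)
  }))
  unmod <- dplyr::bind_rows(lapply(1:20, function(i) {
    tb <- ctx_row(if (i <= 10) "AASPAAAAAAAAA" else "AASGAAAAAAAAA",
                  integer(0))
    tb$context_phospho <- list(integer(0))
    tb
  }))
  res <- kinase_enrichment(list(parse_kinase_motif("[pS/pT]P")),
                           phos, unmod, phos)
  expect_gte(res$p_value, 0.5)
  expect_equal(res$freq_phos, res$freq_unmod)
  expect_equal(res$count_phos / res$denom_phos, res$freq_phos)
})

test_that("redundant motifs are pruned by phospho-stratum subset matching", {
  phos <- dplyr::bind_rows(lapply(1:20, function(i) {
    ctx_row(if (i <= 8) "AASPGAAAAAAAA" else "AASGGAAAAAAAA", 3L)
  }))
  unmod <- phos
  unmod$context_phospho <- rep(list(integer(0)), nrow(unmod))
  unmod$phospho <- rep(list(integer(0)), nrow(unmod))
  motifs <- list(parse_kinase_motif("[pS/pT]P"),
                 parse_kinase_motif("[pS/pT]PG"))  # subset of the first
  res <- kinase_enrichment(motifs, phos, unmod, phos, non_redundant = TRUE)
  expect_equal(nrow(res), 1L)
  expect_equal(res$motif, "[pS/pT]P")
})

test_that("source-gene overlap odds ratios follow the 2x2 definition", {
  uni <- paste0("G", 1:10)
  res <- source_gene_overlap_odds_ratio(paste0("G", 1:5), paste0("G", 3:7),
                                        uni)
  # a=3 (G3-5), b=2 (G1-2), c=2 (G6-7), d=3 -> OR = 9/4
  expect_equal(res$odds_ratio, 2.25)
  expect_false(res$corrected)
  # full containment zeroes a cell: Haldane correction flagged
  res2 <- source_gene_overlap_odds_ratio(paste0("G", 1:6), paste0("G", 2:4),
                                         uni)
  expect_true(res2$corrected)
  expect_error(source_gene_overlap_odds_ratio("G1", "G2", character(0)),
               "empty")
  expect_error(source_gene_overlap_odds_ratio("X", "G2", uni), "subsets")
  # independent random sets: mean OR near 1 over 100 simulations
  set.seed(808)
  uni2 <- paste0("g", 1:200)
  ors <- replicate(100, {
    a <- sample(uni2, 80); b <- sample(uni2, 80)
    source_gene_overlap_odds_ratio(a, b, uni2)$odds_ratio
  })
  expect_gt(mean(ors), 0.9)
  expect_lt(mean(ors), 1.1)
})
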