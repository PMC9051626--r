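# Leave-one-sample-out cross-validation of the phospho-aware predictor
# with phosphosite-pool negatives; AUC / MCC / F1 metrics.

#' Sample negative phosphopeptides from a phosphosite pool
#'
#' Draws peptides by uniformly choosing a catalogued phosphosite, a peptide
#' length in 12-25, and the position of the phosphosite within the peptide,
#' then slicing the source protein. Draws falling outside the protein are
#' resampled; peptides listed in `exclude` (positives) are rejected.
#' Deterministic for a given seed.
#'
#' @param catalogue Phosphosite catalogue tibble.
#' @param proteome Named character vector of proteins.
#' @param n Number of peptides.
#' @param seed Integer seed.
#' @param len_range Inclusive length bounds (lengths drawn uniformly).
#' @param lengths Optional explicit length for each draw (overrides
#'   `len_range`); recycled to `n`.
#' @param exclude Character vector of peptide keys
#'   (`peptide_key(sequence, phospho)`) that must not be returned.
#' @return Tibble with `sequence`, `phospho` (list, single site), `protein`,
#'   `site_position` (position of the catalogued site in the protein).
#' @export
sample_negatives <- function(catalogue, proteome, n, seed = 1,
                             len_range = c(12, 25), lengths = NULL,
                             exclude = NULL) {
  if (!nrow(catalogue)) stop("phosphosite catalogue is empty")
  prot <- unlist(as_proteome_chr(proteome))
  if (!is.null(lengths)) lengths <- rep_len(lengths, max(n, 1L))
  out_seq <- character(n)
  out_pos <- integer(n)
  out_prot <- character(n)
  out_site <- integer(n)
  withr_seed(seed, {
    i <- 1L
    guard <- 0L
    while (i <= n) {
      guard <- guard + 1L
      if (guard > 1000L * max(n, 1L) + 10000L) {
        stop("could not draw ", n, " negatives; catalogue/proteome too small")
      }
      e <- sample.int(nrow(catalogue), 1L)
      L <- if (is.null(lengths)) {
        sample(seq(len_range[1], len_range[2]), 1L)
      } else lengths[i]
      pos_in_pep <- sample.int(L, 1L)
      p <- prot[[catalogue$protein_id[e]]]
      if (is.null(p) || is.na(p)) next
      start <- catalogue$position[e] - pos_in_pep + 1L
      if (start < 1L || start + L - 1L > nchar(p)) next
      sq <- substr(p, start, start + L - 1L)
      if (substr(sq, pos_in_pep, pos_in_pep) != catalogue$residue[e]) next
      if (!is.null(exclude) && peptide_key(sq, pos_in_pep) %in% exclude) next
      out_seq[i] <- sq
      out_pos[i] <- pos_in_pep
      out_prot[i] <- catalogue$protein_id[e]
      out_site[i] <- catalogue$position[e]
      i <- i + 1L
    }
  })
  tibble::tibble(
    sequence = out_seq,
    phospho = as.list(out_pos),
    protein = out_prot,
    site_position = out_site
  )
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive is
#' ranked better than a random negative, with ties counted one half
#' (midranks). With `orientation = "lower"` smaller scores (e.g. percent
#' ranks) are better.
#'
#' @param scores_pos,scores_neg Numeric score vectors.
#' @param orientation `"lower"` (default; percent-rank convention) or
#'   `"higher"`.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores_pos, scores_neg,
                        orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  if (!length(scores_pos) || !length(scores_neg)) {
    stop("both score vectors must be non-empty")
  }
  if (orientation == "lower") {
    scores_pos <- -scores_pos
    scores_neg <- -scores_neg
  }
  np <- length(scores_pos)
  nn <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Matthews correlation coefficient and F1 at a percent-rank threshold
#'
#' Classifies peptides as binders at percent rank <= `threshold` and
#' derives MCC and F1 from the confusion matrix. When an MCC marginal is
#' zero the coefficient is undefined; it is reported as 0 with
#' `mcc_flagged = TRUE`. F1 is 0 when no peptide is called binder.
#'
#' @param scores_pos,scores_neg Percent-rank vectors (lower is better).
#' @param threshold Binder threshold (percent rank).
#' @return List: `mcc`, `f1`, `mcc_flagged`, `confusion` (named vector TP,
#'   FP, FN, TN).
#' @export
compute_mcc_f1 <- function(scores_pos, scores_neg, threshold = 5) {
  if (!length(scores_pos) || !length(scores_neg)) {
    stop("both score vectors must be non-empty")
  }
  tp <- sum(scores_pos <= threshold)
  fn <- length(scores_pos) - tp
  fp <- sum(scores_neg <= threshold)
  tn <- length(scores_neg) - fp
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  flagged <- denom2 == 0
  mcc <- if (flagged) 0 else {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom2)
  }
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(mcc = mcc, f1 = f1, mcc_flagged = flagged,
       confusion = c(TP = tp, FP = fp, FN = fn, TN = tn))
}

#' Paired comparison of two predictor arms
#'
#' Paired two-sided Wilcoxon signed-rank test on per-sample metrics of two
#' predictors. Zero differences are dropped (standard signed-rank
#' convention); if every difference is zero the test is degenerate and
#' p = 1 is returned with a flag.
#'
#' @param metrics_a,metrics_b Equal-length paired numeric vectors.
#' @return List: `p_value`, `flagged` (all differences zero), `n_used`.
#' @export
compare_predictor_arms <- function(metrics_a, metrics_b) {
  stopifnot(length(metrics_a) == length(metrics_b))
  if (length(metrics_a) < 5) {
    warning("fewer than 5 pairs; signed-rank p-values are coarse")
  }
  d <- metrics_a - metrics_b
  d <- d[d != 0]
  if (!length(d)) return(list(p_value = 1, flagged = TRUE, n_used = 0L))
  n <- length(d)
  if (n <= 14) {
    # exact null by enumerating all 2^n sign patterns (handles tied
    # magnitudes, where the classical exact distribution does not apply)
    r <- rank(abs(d))
    w <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_null <- as.numeric(signs %*% r)
    p <- min(1, 2 * min(mean(w_null <= w), mean(w_null >= w)))
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(d, alternative = "two.sided")$p.value
    )
  }
  list(p_value = p, flagged = FALSE, n_used = n)
}

#' Train calibrated allele models from assigned interactions
#'
#' One PWM per allele from the binding cores of its interactions, with
#' percent-rank calibration on random proteome peptides. In arm
#' `"substitute_E"` the cores are phospho-to-glutamate substituted before
#' training (and peptides must be substituted before scoring); in
#' `"native23"` cores keep their phospho symbols.
#'
#' @param interactions Tibble with `allele` and `core` (annotated 9-mer)
#'   columns.
#' @param proteome Named character vector.
#' @param arm `"native23"` or `"substitute_E"`.
#' @param pseudo_weight,phospho_prior PWM regularization (see
#'   [train_allele_model()], [proteome_background()]).
#' @param n_cal,cal_seed Calibration size and seed (see
#'   [calibrate_model()]).
#' @return Named list of calibrated `allele_model`s.
#' @export
train_models_from_interactions <- function(interactions, proteome,
                                           arm = c("native23", "substitute_E"),
                                           pseudo_weight = 5,
                                           phospho_prior = 0.01,
                                           n_cal = 2000, cal_seed = 1) {
  arm <- match.arg(arm)
  bg <- proteome_background(proteome, phospho_prior = phospho_prior)
  alleles <- sort(unique(interactions$allele))
  models <- lapply(alleles, function(al) {
    cores <- interactions$core[interactions$allele == al]
    if (arm == "substitute_E") {
      cores <- vapply(cores, function(co) {
        p <- parse_mod_peptide(co)
        substitute_phospho_as_glu(p$sequence, p$phospho)
      }, character(1), USE.NAMES = FALSE)
    }
    m <- train_allele_model(cores, bg, pseudo_weight = pseudo_weight,
                            allele = al)
    calibrate_model(m, proteome, n_per_length = n_cal, seed = cal_seed)
  })
  stats::setNames(models, alleles)
}

#' Leave-one-sample-out benchmark of the phospho-aware predictor
#'
#' Each sample is held out in turn. Per fold, allele models are retrained
#' on all interactions except the held-out sample's phosphopeptides (a
#' peptide found in several samples is removed from training in every fold
#' that tests it), the held-out sample's unique phosphopeptides are the
#' positives, and `negatives_factor` times as many random phosphosite
#' peptides are the negatives. Each peptide is scored as its best (minimum)
#' percent rank across the sample's alleles. Two arms are evaluated: the
#' phospho-aware 23-letter models (`native23`) and models trained and
#' applied after phospho-to-glutamate substitution (`substitute_E`).
#'
#' A leakage assertion verifies on every fold that no test positive is in
#' the fold's training set.
#'
#' @param interactions Assigned interactions (phospho and unmodified rows).
#' @param manifest Sample manifest.
#' @param catalogue Phosphosite catalogue (negative pool).
#' @param proteome Named character vector.
#' @param negatives_factor Negatives per positive.
#' @param rank_threshold Percent-rank threshold for MCC/F1.
#' @param seed Base seed; fold f draws negatives with seed `seed + f`.
#' @param n_cal Calibration peptides per length per fold.
#' @param pseudo_weight,phospho_prior PWM regularization.
#' @param arms Which predictor arms to run.
#' @return Tibble with one row per fold x arm: `sample_id`, `arm`,
#'   `n_pos`, `n_neg`, `auc`, `mcc`, `f1`, `mcc_flagged`.
#' @export
run_loso <- function(interactions, manifest, catalogue, proteome,
                     negatives_factor = 5, rank_threshold = 5, seed = 17,
                     n_cal = 2000, pseudo_weight = 5, phospho_prior = 0.01,
                     arms = c("native23", "substitute_E")) {
  is_phos <- lengths(interactions$phospho) > 0
  samples <- sort(unique(interactions$sample_id[is_phos]))
  if (length(samples) < 2) stop("need at least 2 samples with positives")
  key_all <- peptide_key(interactions$sequence, interactions$phospho)
  rows <- list()
  for (f in seq_along(samples)) {
    sid <- samples[f]
    srow <- manifest[manifest$sample_id == sid, , drop = FALSE]
    if (!nrow(srow)) stop("sample '", sid, "' missing from manifest")
    test_sel <- interactions$sample_id == sid & is_phos
    test_keys <- unique(key_all[test_sel])
    if (!length(test_keys)) {
      warning("sample '", sid, "' has no positives; fold skipped")
      next
    }
    train_sel <- !(is_phos & key_all %in% test_keys)
    train <- interactions[train_sel, , drop = FALSE]
    # leakage assertion
    stopifnot(!any(peptide_key(train$sequence, train$phospho)[
      lengths(train$phospho) > 0] %in% test_keys))
    pos <- interactions[test_sel, , drop = FALSE]
    pos <- pos[!duplicated(key_all[test_sel]), , drop = FALSE]
    negs <- sample_negatives(catalogue, proteome,
                             n = negatives_factor * nrow(pos),
                             seed = seed + f, exclude = test_keys)
    for (arm in arms) {
      models <- train_models_from_interactions(
        train, proteome, arm = arm, pseudo_weight = pseudo_weight,
        phospho_prior = phospho_prior, n_cal = n_cal, cal_seed = seed)
      alleles <- srow$alleles[[1]]
      avail <- intersect(alleles, names(models))
      if (!length(avail)) {
        warning("no trained model for any allele of '", sid,
                "'; fold skipped for arm ", arm)
        next
      }
      best_rank <- function(sequence, phospho) {
        min(vapply(avail, function(al) {
          if (arm == "substitute_E") {
            score_peptide(models[[al]],
                          substitute_phospho_as_glu(sequence, phospho)
            )$percent_rank
          } else {
            score_peptide(models[[al]], sequence, phospho)$percent_rank
          }
        }, numeric(1)))
      }
      sp <- vapply(seq_len(nrow(pos)), function(i) {
        best_rank(pos$sequence[i], pos$phospho[[i]])
      }, numeric(1))
      sn <- vapply(seq_len(nrow(negs)), function(i) {
        best_rank(negs$sequence[i], negs$phospho[[i]])
      }, numeric(1))
      mf <- compute_mcc_f1(sp, sn, threshold = rank_threshold)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sid, arm = arm, n_pos = nrow(pos), n_neg = nrow(negs),
        auc = compute_auc(sp, sn, orientation = "lower"),
        mcc = mf$mcc, f1 = mf$f1, mcc_flagged = mf$mcc_flagged
      )
    }
  }
  dplyr::bind_rows(rows)
}
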