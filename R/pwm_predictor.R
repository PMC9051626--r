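# Per-allele 9-position PWMs over the 23-letter phospho-aware alphabet,
# max-over-offsets log-odds core scoring, and percent-rank calibration.

CORE_LEN <- 9L
CAL_LENGTHS <- 12:25

#' Background frequencies from a proteome
#'
#' Canonical amino-acid frequencies are counted from the proteome; each
#' phospho symbol receives the frequency of its parent residue multiplied by
#' `phospho_prior`, and the 23-vector is renormalized. Background
#' frequencies of phosphorylated residues cannot be estimated from sequence
#' alone, so the prior is explicit and configurable.
#'
#' @param proteome Named character vector of protein sequences.
#' @param phospho_prior Fraction of a parent residue's background mass
#'   mirrored onto its phospho symbol before renormalization.
#' @return Named numeric 23-vector summing to 1, ordered as
#'   [aa_alphabet23()].
#' @export
proteome_background <- function(proteome, phospho_prior = 0.01) {
  seqs <- paste(unlist(as_proteome_chr(proteome)), collapse = "")
  counts <- table(factor(strsplit(seqs, "", fixed = TRUE)[[1]],
                         levels = AA_CANONICAL))
  freq <- as.numeric(counts)
  if (sum(freq) == 0) stop("proteome is empty")
  freq <- freq / sum(freq)
  names(freq) <- AA_CANONICAL
  bg <- c(freq, freq[PHOSPHO_PARENTS] * phospho_prior)
  names(bg) <- aa_alphabet23()
  bg / sum(bg)
}

#' Train a per-allele PWM model
#'
#' Builds a 9-position position weight matrix over the 23-letter alphabet
#' from aligned binding cores, with background-proportional pseudocounts:
#' the frequency of symbol a at position p is
#' `(count(a, p) + pseudo_weight * background[a]) / (n + pseudo_weight)`.
#'
#' @param cores Character vector of 9-mer cores in annotated form
#'   (`"ASKDPS[p]SR"`-style phospho markers allowed), or a list of
#'   length-9 symbol vectors over [aa_alphabet23()].
#' @param background Named 23-vector of background frequencies (see
#'   [proteome_background()]).
#' @param pseudo_weight Total pseudocount mass; the default keeps the rare
#'   phospho symbols strictly positive without overwhelming the counts.
#' @param allele Allele name stored on the model.
#' @return An object of class `allele_model`: list with `allele`, `pwm`
#'   (23 x 9 matrix, columns sum to 1), `background`, `log_odds`,
#'   `pseudo_weight`, `n_train` and (after [calibrate_model()]) a
#'   `calibration` table.
#' @export
train_allele_model <- function(cores, background, pseudo_weight = 5,
                               allele = NA_character_) {
  mats <- cores_to_index_matrix(cores)
  pwm <- pwm_from_index_matrix(mats, background, pseudo_weight)
  new_allele_model(allele, pwm, background, pseudo_weight, nrow(mats))
}

# cores -> n x 9 matrix of alphabet indices
cores_to_index_matrix <- function(cores) {
  if (!length(cores)) stop("no cores supplied")
  alpha <- aa_alphabet23()
  symlist <- lapply(cores, function(co) {
    if (is.character(co) && length(co) == 1L) {
      p <- parse_mod_peptide(co)
      peptide_symbols(p$sequence, p$phospho)
    } else {
      co
    }
  })
  lens <- lengths(symlist)
  if (any(lens != CORE_LEN)) {
    stop("all cores must have length 9 (found length ",
         paste(unique(lens[lens != CORE_LEN]), collapse = ", "), ")")
  }
  idx <- matrix(match(unlist(symlist), alpha), ncol = CORE_LEN, byrow = TRUE)
  if (anyNA(idx)) {
    bad <- unique(unlist(symlist)[is.na(match(unlist(symlist), alpha))])
    stop("illegal symbol(s) in cores: ", paste(bad, collapse = ", "))
  }
  idx
}

pwm_from_index_matrix <- function(idx, background, pseudo_weight) {
  stopifnot(length(background) == 23L, abs(sum(background) - 1) < 1e-6)
  n <- nrow(idx)
  counts <- vapply(seq_len(CORE_LEN), function(p) {
    tabulate(idx[, p], nbins = 23L)
  }, numeric(23L))
  pwm <- (counts + pseudo_weight * as.numeric(background)) / (n + pseudo_weight)
  rownames(pwm) <- aa_alphabet23()
  colnames(pwm) <- paste0("P", seq_len(CORE_LEN))
  pwm
}

new_allele_model <- function(allele, pwm, background, pseudo_weight, n_train) {
  background <- background / sum(background)
  lo <- log2(sweep(pwm, 1, as.numeric(background), "/"))
  lo[!is.finite(lo)] <- -Inf
  structure(
    list(allele = allele, pwm = pwm, background = background,
         log_odds = lo, pseudo_weight = pseudo_weight, n_train = n_train,
         calibration = NULL),
    class = "allele_model"
  )
}

#' @export
print.allele_model <- function(x, ...) {
  cat("<allele_model> ", x$allele, ": 9x23 PWM from ", x$n_train,
      " cores (pseudo_weight ", x$pseudo_weight, "), calibration ",
      if (is.null(x$calibration)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' Score a peptide against an allele model
#'
#' The raw score is the maximum over all 9-mer windows of the summed
#' log2-odds `log2(PWM[p][a] / background[a])`; ties between windows are
#' broken toward the smallest offset. If the model carries a calibration
#' table the percent rank for the peptide's length is attached.
#'
#' @param model An `allele_model`.
#' @param sequence Peptide sequence (20-letter alphabet).
#' @param phospho 1-based phosphosite positions within `sequence`.
#' @return A one-row tibble (`core_assignment`): `allele`, `sequence`,
#'   `phospho`, `core_offset` (1-based), `core` (annotated 9-mer),
#'   `raw_score`, `percent_rank` (`NA` if uncalibrated).
#' @export
score_peptide <- function(model, sequence, phospho = integer(0)) {
  syms <- peptide_symbols(sequence, phospho)
  L <- length(syms)
  if (L < CORE_LEN) stop("peptide shorter than 9 residues: '", sequence, "'")
  idx <- symbol_index(syms)
  if (anyNA(idx)) stop("illegal symbol in peptide '", sequence, "'")
  lo <- model$log_odds
  n_off <- L - CORE_LEN + 1L
  scores <- vapply(seq_len(n_off), function(o) {
    sum(lo[cbind(idx[o:(o + CORE_LEN - 1L)], seq_len(CORE_LEN))])
  }, numeric(1))
  best <- which.max(scores)
  core_ph <- phospho[phospho >= best & phospho < best + CORE_LEN] - best + 1L
  core_seq <- substr(sequence, best, best + CORE_LEN - 1L)
  pr <- if (is.null(model$calibration)) NA_real_ else {
    percent_rank_score(model, scores[best], L)
  }
  tibble::tibble(
    allele = model$allele,
    sequence = sequence,
    phospho = list(phospho),
    core_offset = as.integer(best),
    core = format_mod_peptide(core_seq, core_ph),
    raw_score = scores[best],
    percent_rank = pr
  )
}

# vectorized scorer for a set of equal-length peptides given as an
# n x L index matrix; returns list(score, offset)
score_index_matrix <- function(model, idx) {
  L <- ncol(idx)
  lo <- model$log_odds
  n_off <- L - CORE_LEN + 1L
  best <- rep(-Inf, nrow(idx))
  best_off <- rep(1L, nrow(idx))
  for (o in seq_len(n_off)) {
    s <- rowSums(vapply(seq_len(CORE_LEN), function(p) {
      lo[cbind(idx[, o + p - 1L], p)]
    }, numeric(nrow(idx))))
    better <- s > best
    best[better] <- s[better]
    best_off[better] <- o
  }
  list(score = best, offset = best_off)
}

#' Calibrate percent ranks on random proteome peptides
#'
#' For each peptide length 12-25, draws `n_per_length` random subsequences
#' of the proteome, scores them against the model, and stores the sorted
#' scores. Percent ranks are computed per length against these null
#' distributions. Deterministic for a given seed.
#'
#' @param model An `allele_model`.
#' @param proteome Named character vector of protein sequences.
#' @param n_per_length Random peptides per length (default gives percent
#'   ranks stable to about 0.1).
#' @param seed Integer seed.
#' @return The model with a `calibration` list (per length: sorted ascending
#'   scores) and `calibration_meta` recording `n_per_length` and `seed`.
#' @export
calibrate_model <- function(model, proteome, n_per_length = 10000, seed = 1) {
  prot <- unlist(as_proteome_chr(proteome))
  if (!length(prot)) stop("proteome is empty")
  alpha_idx <- stats::setNames(seq_len(23L), aa_alphabet23())
  cal <- list()
  withr_seed(seed, {
    for (L in CAL_LENGTHS) {
      ok <- prot[nchar(prot) >= L]
      if (!length(ok)) stop("no protein long enough for length ", L)
      pid <- sample(length(ok), n_per_length, replace = TRUE)
      starts <- vapply(pid, function(i) {
        sample.int(nchar(ok[i]) - L + 1L, 1L)
      }, integer(1))
      seqs <- substr(ok[pid], starts, starts + L - 1L)
      chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                      ncol = L, byrow = TRUE)
      idx <- matrix(alpha_idx[chars], ncol = L)
      if (anyNA(idx)) {
        # non-standard residues (X, U, ...) in the proteome: replace by A
        idx[is.na(idx)] <- 1L
      }
      cal[[as.character(L)]] <- sort(score_index_matrix(model, idx)$score)
    }
  })
  model$calibration <- cal
  model$calibration_meta <- list(n_per_length = n_per_length, seed = seed)
  model
}

# set.seed confined to a block without disturbing the caller's RNG stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Percent rank of a raw score
#'
#' `100 * (1 + #{calibration scores >= raw_score}) / (N + 1)`: the
#' percentile of the score among random proteome peptides of the same
#' length. Lower is better; strictly decreasing in the raw score.
#'
#' @param model A calibrated `allele_model`.
#' @param raw_score Raw log-odds score.
#' @param length Peptide length (12-25).
#' @return Percent rank in (0, 100].
#' @export
percent_rank_score <- function(model, raw_score, length) {
  if (is.null(model$calibration)) stop("model is not calibrated")
  cal <- model$calibration[[as.character(length)]]
  if (is.null(cal)) stop("no calibration for length ", length)
  N <- length(cal)
  # cal is sorted ascending: count of scores >= raw_score by binary search
  n_ge <- N - findInterval(raw_score, cal, left.open = TRUE)
  100 * (1 + n_ge) / (N + 1)
}

#' Write an allele model to a plain-text file
#'
#' Versioned text format: header lines (`allele`, `pseudo_weight`,
#' `n_train`, calibration metadata), the background 23-vector, the 23 x 9
#' frequency block, and one calibration line per peptide length.
#'
#' @param model An `allele_model`.
#' @param path Output path.
#' @export
write_allele_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) format(x, digits = 17, trim = TRUE, scientific = TRUE)
  writeLines(c(
    "# phosphoHLA2 allele model v1",
    paste0("allele\t", model$allele),
    paste0("pseudo_weight\t", num(model$pseudo_weight)),
    paste0("n_train\t", model$n_train),
    paste0("background\t", paste(num(model$background), collapse = "\t"))
  ), con)
  for (p in seq_len(CORE_LEN)) {
    writeLines(paste0("pwm\tP", p, "\t",
                      paste(num(model$pwm[, p]), collapse = "\t")), con)
  }
  if (!is.null(model$calibration)) {
    writeLines(paste0("calibration_meta\t",
                      model$calibration_meta$n_per_length, "\t",
                      model$calibration_meta$seed), con)
    for (L in names(model$calibration)) {
      writeLines(paste0("calibration\t", L, "\t",
                        paste(num(model$calibration[[L]]), collapse = "\t")),
                 con)
    }
  }
  invisible(path)
}

#' Read an allele model written by [write_allele_model()]
#' @param path Model file.
#' @return An `allele_model`.
#' @export
read_allele_model <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "# phosphoHLA2 allele model v1") {
    stop("'", path, "' is not a phosphoHLA2 allele model file")
  }
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  key <- vapply(fields, `[[`, character(1), 1L)
  getf <- function(k) fields[[which(key == k)[1]]][-1]
  allele <- getf("allele")
  pseudo <- as.numeric(getf("pseudo_weight"))
  n_train <- as.integer(getf("n_train"))
  background <- as.numeric(getf("background"))
  names(background) <- aa_alphabet23()
  pwm <- matrix(NA_real_, 23L, CORE_LEN,
                dimnames = list(aa_alphabet23(),
                                paste0("P", seq_len(CORE_LEN))))
  for (i in which(key == "pwm")) {
    p <- as.integer(sub("^P", "", fields[[i]][2]))
    pwm[, p] <- as.numeric(fields[[i]][-(1:2)])
  }
  model <- new_allele_model(allele, pwm, background, pseudo, n_train)
  cal_rows <- which(key == "calibration")
  if (length(cal_rows)) {
    cal <- list()
    for (i in cal_rows) {
      cal[[fields[[i]][2]]] <- as.numeric(fields[[i]][-(1:2)])
    }
    model$calibration <- cal
    meta <- fields[[which(key == "calibration_meta")[1]]][-1]
    model$calibration_meta <- list(n_per_length = as.integer(meta[1]),
                                   seed = as.integer(meta[2]))
  }
  model
}
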