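# Synthetic immunopeptidomics worlds with known ground truth: planted
# allele motifs, planted phosphosites, score-distributed true and
# contaminant PSMs, a proteome the peptides are embedded in, and a
# phosphosite catalogue.

# rough human-proteome amino-acid frequencies used for proteome residues
# and non-anchor motif positions
BG20_DEFAULT <- c(
  A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.037, G = 0.066,
  H = 0.026, I = 0.043, K = 0.057, L = 0.100, M = 0.021, N = 0.036,
  P = 0.063, Q = 0.048, R = 0.056, S = 0.083, T = 0.054, V = 0.060,
  W = 0.012, Y = 0.027
)

# anchor-symbol pools for planted motifs; allele i takes the i-th entry of
# each pool (cycled), giving distinct anchor combinations
ANCHOR_POOLS <- list(
  P1 = c("F", "Y", "W", "I", "L", "V", "M", "A", "Q", "H"),
  P4 = c("D", "N", "Q", "E", "S", "A", "T", "G", "K", "M"),
  P6 = c("K", "R", "H", "G", "T", "N", "S", "A", "P", "D"),
  P9 = c("L", "V", "M", "A", "I", "F", "Y", "S", "K", "E")
)

#' Configuration for a synthetic immunopeptidomics world
#'
#' Defaults emulate the statistical structure of curated HLA-II
#' phosphopeptidomics data: ligand lengths peaked at 15-mers within 12-25,
#' a mono/di/tri phosphosite mixture of 85.4/13.3/1.3 percent, phosphosites
#' preferring the center of the binding core (P5) and avoiding the P1
#' anchor, terminal phosphosites favoring the C-terminus 63/37, true PSMs
#' with higher identification and delta scores than co-eluted contaminants,
#' and well-localized phosphosites on true ligands.
#'
#' @param seed Integer seed; the whole world is deterministic given it.
#' @param n_alleles Number of planted alleles.
#' @param n_samples Number of samples; the first `n_alleles` are
#'   monoallelic, the rest draw 2-3 alleles.
#' @param n_ligands_per_sample Phosphorylated ligands per sample.
#' @param n_unmod_per_sample Unmodified ligands per sample.
#' @param contaminant_fraction Fraction of phospho PSMs that are
#'   contaminants (random proteome slices with lower score distributions).
#' @param phospho_mix Probabilities of 1, 2, 3 phosphosites per ligand.
#' @param core_weight Probability that a phosphosite falls inside the core.
#' @param core_pos_weights Relative placement weights over core positions
#'   P1..P9 (P5-peaked, P1-depleted by default).
#' @param pfr_c_weight Probability that a PFR phosphosite falls on the
#'   C-terminal side.
#' @param sty_probs Residue mixture for planted phosphosites (S, T, Y).
#' @param anchor_strength Frequency of the preferred symbol at anchor
#'   positions of planted motifs.
#' @param length_peak,length_sd Ligand length distribution (discretized
#'   normal truncated to 12-25).
#' @param n_proteins,mean_protein_length Proteome size (lengths are
#'   geometric with the given mean, floored at 60).
#' @param n_extra_catalogue_sites Random phosphosites added to the
#'   catalogue beyond the planted ones.
#' @param true_score,true_delta,cont_score,cont_delta Length-2 vectors
#'   (mean, sd) of the normal score distributions, truncated at 0.
#' @param true_locprob,cont_locprob Length-2 beta shape parameters for
#'   localization probabilities.
#' @param noiseless Convenience switch: no contaminants and score/
#'   localization distributions placed entirely above the curation
#'   thresholds, so every planted PSM survives filtering.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 42,
                         n_alleles = 3,
                         n_samples = 6,
                         n_ligands_per_sample = 60,
                         n_unmod_per_sample = 120,
                         contaminant_fraction = 0.25,
                         phospho_mix = c(0.854, 0.133, 0.013),
                         core_weight = 0.6,
                         core_pos_weights = c(0.02, 0.10, 0.10, 0.12, 0.25,
                                              0.12, 0.10, 0.12, 0.07),
                         pfr_c_weight = 0.63,
                         sty_probs = c(S = 0.75, T = 0.20, Y = 0.05),
                         anchor_strength = 0.9,
                         length_peak = 15, length_sd = 2,
                         n_proteins = 500, mean_protein_length = 450,
                         n_extra_catalogue_sites = 2000,
                         true_score = c(120, 25), true_delta = c(40, 15),
                         cont_score = c(70, 25), cont_delta = c(12, 8),
                         true_locprob = c(40, 2), cont_locprob = c(4, 2),
                         noiseless = FALSE) {
  if (noiseless) {
    contaminant_fraction <- 0
    true_score <- c(140, 15)
    true_delta <- c(60, 10)
    true_locprob <- c(120, 2)
  }
  cfg <- list(
    seed = seed, n_alleles = n_alleles, n_samples = n_samples,
    n_ligands_per_sample = n_ligands_per_sample,
    n_unmod_per_sample = n_unmod_per_sample,
    contaminant_fraction = contaminant_fraction,
    phospho_mix = phospho_mix / sum(phospho_mix),
    core_weight = core_weight,
    core_pos_weights = core_pos_weights / sum(core_pos_weights),
    pfr_c_weight = pfr_c_weight,
    sty_probs = sty_probs / sum(sty_probs),
    anchor_strength = anchor_strength,
    length_peak = length_peak, length_sd = length_sd,
    n_proteins = n_proteins, mean_protein_length = mean_protein_length,
    n_extra_catalogue_sites = n_extra_catalogue_sites,
    true_score = true_score, true_delta = true_delta,
    cont_score = cont_score, cont_delta = cont_delta,
    true_locprob = true_locprob, cont_locprob = cont_locprob
  )
  stopifnot(cfg$n_samples >= cfg$n_alleles,
            all(cfg$phospho_mix >= 0), all(cfg$core_pos_weights >= 0),
            cfg$contaminant_fraction >= 0, cfg$contaminant_fraction < 1,
            cfg$mean_protein_length >= 60)
  structure(cfg, class = "synth_config")
}

#' Planted canonical PWM of one allele
#'
#' 20 x 9 frequency matrix: `anchor_strength` on the allele's preferred
#' symbol at P1/P4/P6/P9, background elsewhere.
#'
#' @param config A `synth_config`.
#' @param allele_index Allele number (1-based).
#' @return 20 x 9 matrix, unit column sums; attribute `anchors` names the
#'   preferred symbols.
#' @export
planted_allele_pwm <- function(config, allele_index) {
  pwm <- matrix(rep(BG20_DEFAULT, CORE_LEN), nrow = 20,
                dimnames = list(AA_CANONICAL, paste0("P", 1:CORE_LEN)))
  anchors <- vapply(ANCHOR_POOLS, function(pool) {
    pool[(allele_index - 1L) %% length(pool) + 1L]
  }, character(1))
  for (nm in names(anchors)) {
    p <- as.integer(sub("P", "", nm))
    col <- BG20_DEFAULT
    col[anchors[nm]] <- 0
    col <- col / sum(col) * (1 - config$anchor_strength)
    col[anchors[nm]] <- config$anchor_strength
    pwm[, p] <- col
  }
  pwm <- sweep(pwm, 2, colSums(pwm), "/")
  attr(pwm, "anchors") <- anchors
  pwm
}

#' Sample aligned cores from a PWM
#'
#' Independent per-position multinomial draws; useful for parameter
#' recovery tests.
#'
#' @param pwm Frequency matrix (rows are symbols, 9 columns).
#' @param n Number of cores.
#' @param seed Integer seed.
#' @return Character vector of annotated cores.
#' @export
sample_cores <- function(pwm, n, seed = 1) {
  syms <- rownames(pwm)
  withr_seed(seed, {
    cores <- vapply(seq_len(n), function(i) {
      drawn <- vapply(seq_len(ncol(pwm)), function(p) {
        sample(syms, 1L, prob = pwm[, p])
      }, character(1))
      seq20 <- sub("^p", "", drawn)
      ph <- which(startsWith(drawn, "p"))
      format_mod_peptide(paste(seq20, collapse = ""), ph)
    }, character(1))
  })
  cores
}

rtrunc_norm <- function(n, mean, sd, lo = 0) {
  pmax(lo, stats::rnorm(n, mean, sd))
}

#' Generate a complete synthetic world
#'
#' Emits everything the pipeline consumes: a proteome with the ligands
#' embedded as exact substrings, a phosphosite catalogue covering planted
#' and random sites, a sample manifest, PSM tables mixing true ligands and
#' contaminants with distinct score distributions, and a ground-truth
#' ledger recording every peptide's allele, core offset and phosphosites.
#' Deterministic (byte-identical files via [write_world()]) for a fixed
#' seed.
#'
#' @param config A [synth_config()].
#' @return List of class `synth_world`: `config`, `proteome` (named
#'   character), `catalogue`, `manifest`, `psms` (parsed PSM tibble),
#'   `truth` (ledger tibble: `sample_id`, `allele`, `sequence`, `phospho`,
#'   `core_offset`, `type`, `protein`, `start`), `planted` (per-allele
#'   planted PWMs).
#' @export
generate_world <- function(config = synth_config()) {
  cfg <- config
  max_pep <- 25L
  if (cfg$mean_protein_length < 2L * max_pep) {
    stop("proteins too short to host 25-mer ligands")
  }
  withr_seed(cfg$seed, {
    # ---- proteome -----------------------------------------------------
    plen <- pmax(60L, stats::rgeom(cfg$n_proteins,
                                   1 / cfg$mean_protein_length) + 1L)
    prot_chars <- lapply(plen, function(L) {
      sample(AA_CANONICAL, L, replace = TRUE, prob = BG20_DEFAULT)
    })
    prot_ids <- sprintf("SYNPROT%04d", seq_len(cfg$n_proteins))
    occupied <- lapply(seq_len(cfg$n_proteins), function(i) NULL)

    place_peptide <- function(len) {
      for (try in 1:200) {
        pi <- sample.int(cfg$n_proteins, 1L)
        if (plen[pi] < len) next
        start <- sample.int(plen[pi] - len + 1L, 1L)
        occ <- occupied[[pi]]
        clash <- FALSE
        if (!is.null(occ)) {
          clash <- any(start <= occ[, 2] & start + len - 1L >= occ[, 1])
        }
        if (!clash) {
          occupied[[pi]] <<- rbind(occ, c(start, start + len - 1L))
          return(list(protein = pi, start = start))
        }
      }
      stop("could not place peptide; proteome too crowded")
    }

    planted <- lapply(seq_len(cfg$n_alleles),
                      function(a) planted_allele_pwm(cfg, a))
    allele_names <- sprintf("SYNA_%02d", seq_len(cfg$n_alleles))
    names(planted) <- allele_names

    # ---- manifest -----------------------------------------------------
    sample_ids <- sprintf("sample%02d", seq_len(cfg$n_samples))
    sample_alleles <- lapply(seq_len(cfg$n_samples), function(s) {
      if (s <= cfg$n_alleles) {
        allele_names[s]
      } else {
        k <- sample(2:min(3L, cfg$n_alleles), 1L)
        sort(sample(allele_names, k))
      }
    })
    manifest <- tibble::tibble(
      sample_id = sample_ids,
      alleles = sample_alleles,
      capture = ifelse(seq_len(cfg$n_samples) <= cfg$n_alleles,
                       "DR-only", "pan-II-only")
    )

    # ---- ligand drawing ----------------------------------------------
    len_support <- 12:25
    len_w <- stats::dnorm(len_support, cfg$length_peak, cfg$length_sd)
    draw_length <- function() sample(len_support, 1L, prob = len_w)

    draw_ligand <- function(allele_idx, phospho = TRUE) {
      pwm <- planted[[allele_idx]]
      len <- draw_length()
      off <- sample.int(len - CORE_LEN + 1L, 1L)
      res <- sample(AA_CANONICAL, len, replace = TRUE, prob = BG20_DEFAULT)
      for (p in seq_len(CORE_LEN)) {
        res[off + p - 1L] <- sample(AA_CANONICAL, 1L, prob = pwm[, p])
      }
      ph <- integer(0)
      if (phospho) {
        k <- sample(1:3, 1L, prob = cfg$phospho_mix)
        guard <- 0L
        while (length(ph) < k && guard < 100L) {
          guard <- guard + 1L
          in_core <- stats::runif(1) < cfg$core_weight
          if (in_core) {
            pos <- off + sample.int(CORE_LEN, 1L,
                                    prob = cfg$core_pos_weights) - 1L
          } else {
            pfr_n <- seq_len(off - 1L)
            pfr_c <- if (off + CORE_LEN <= len) (off + CORE_LEN):len else
              integer(0)
            side_c <- stats::runif(1) < cfg$pfr_c_weight
            cand <- if (side_c) pfr_c else pfr_n
            if (!length(cand)) cand <- c(pfr_n, pfr_c)
            if (!length(cand)) next
            pos <- if (length(cand) == 1L) cand else sample(cand, 1L)
          }
          if (pos %in% ph) next
          res[pos] <- sample(names(cfg$sty_probs), 1L, prob = cfg$sty_probs)
          ph <- sort(c(ph, pos))
        }
      }
      list(sequence = paste(res, collapse = ""), phospho = ph,
           core_offset = off, length = len)
    }

    # ---- per-sample PSMs ---------------------------------------------
    truth_rows <- list()
    psm_rows <- list()
    add_psm <- function(sid, lig, type, prot_id, start, allele) {
      is_true <- type != "contaminant"
      sc <- if (is_true) cfg$true_score else cfg$cont_score
      dl <- if (is_true) cfg$true_delta else cfg$cont_delta
      lp <- if (is_true) cfg$true_locprob else cfg$cont_locprob
      nph <- length(lig$phospho)
      psm_rows[[length(psm_rows) + 1L]] <<- tibble::tibble(
        sample_id = sid,
        sequence = lig$sequence,
        phospho = list(lig$phospho),
        loc_probs = list(if (nph) round(stats::rbeta(nph, lp[1], lp[2]), 4)
                         else numeric(0)),
        peptide_score = round(rtrunc_norm(1, sc[1], sc[2]), 3),
        delta_score = round(rtrunc_norm(1, dl[1], dl[2]), 3),
        proteins = list(prot_id),
        n_phospho = nph
      )
      truth_rows[[length(truth_rows) + 1L]] <<- tibble::tibble(
        sample_id = sid, allele = allele, sequence = lig$sequence,
        phospho = list(lig$phospho), core_offset = lig$core_offset,
        type = type, protein = prot_id, start = start
      )
    }

    for (s in seq_len(cfg$n_samples)) {
      als <- sample_alleles[[s]]
      for (i in seq_len(cfg$n_ligands_per_sample)) {
        al <- if (length(als) == 1L) als else sample(als, 1L)
        lig <- draw_ligand(match(al, allele_names), phospho = TRUE)
        pl <- place_peptide(lig$length)
        prot_chars[[pl$protein]][pl$start:(pl$start + lig$length - 1L)] <-
          strsplit(lig$sequence, "", fixed = TRUE)[[1]]
        add_psm(sample_ids[s], lig, "ligand", prot_ids[pl$protein],
                pl$start, al)
      }
      for (i in seq_len(cfg$n_unmod_per_sample)) {
        al <- if (length(als) == 1L) als else sample(als, 1L)
        lig <- draw_ligand(match(al, allele_names), phospho = FALSE)
        pl <- place_peptide(lig$length)
        prot_chars[[pl$protein]][pl$start:(pl$start + lig$length - 1L)] <-
          strsplit(lig$sequence, "", fixed = TRUE)[[1]]
        add_psm(sample_ids[s], lig, "unmod_ligand", prot_ids[pl$protein],
                pl$start, al)
      }
    }

    # contaminants: random slices of the final proteome (drawn after all
    # embeddings so they are exact substrings), shorter lengths, one
    # forced phosphosite, lower scores
    for (s in seq_len(cfg$n_samples)) {
      n_cont <- round(cfg$contaminant_fraction * cfg$n_ligands_per_sample /
                        max(1e-9, 1 - cfg$contaminant_fraction))
      ci <- 0L
      guard <- 0L
      while (ci < n_cont && guard < 200L * max(1L, n_cont)) {
        guard <- guard + 1L
        len <- max(8L, min(25L,
                           round(stats::rnorm(1, cfg$length_peak - 2, 2))))
        pi <- sample.int(cfg$n_proteins, 1L)
        if (plen[pi] < len) next
        start <- sample.int(plen[pi] - len + 1L, 1L)
        res <- prot_chars[[pi]][start:(start + len - 1L)]
        sty <- which(res %in% c("S", "T", "Y"))
        if (!length(sty)) next
        ph <- if (length(sty) == 1L) sty else sample(sty, 1L)
        lig <- list(sequence = paste(res, collapse = ""), phospho = ph,
                    core_offset = NA_integer_, length = len)
        add_psm(sample_ids[s], lig, "contaminant", prot_ids[pi], start,
                NA_character_)
        ci <- ci + 1L
      }
    }

    proteome <- stats::setNames(
      vapply(prot_chars, paste, character(1), collapse = ""), prot_ids)
    truth <- dplyr::bind_rows(truth_rows)
    psms <- dplyr::bind_rows(psm_rows)

    # ---- phosphosite catalogue ---------------------------------------
    cat_rows <- list()
    for (i in seq_len(nrow(truth))) {
      ph <- truth$phospho[[i]]
      if (!length(ph) || is.na(truth$start[i])) next
      pos <- truth$start[i] + ph - 1L
      cat_rows[[length(cat_rows) + 1L]] <- tibble::tibble(
        protein_id = truth$protein[i], position = pos,
        residue = substring(proteome[truth$protein[i]], pos, pos)
      )
    }
    extra <- 0L
    while (extra < cfg$n_extra_catalogue_sites) {
      pi <- sample.int(cfg$n_proteins, 1L)
      pos <- sample.int(plen[pi], 1L)
      res <- substr(proteome[pi], pos, pos)
      if (!res %in% c("S", "T", "Y")) next
      cat_rows[[length(cat_rows) + 1L]] <- tibble::tibble(
        protein_id = prot_ids[pi], position = pos, residue = res)
      extra <- extra + 1L
    }
    catalogue <- dplyr::distinct(dplyr::bind_rows(cat_rows))
  })
  structure(
    list(config = cfg, proteome = proteome, catalogue = catalogue,
         manifest = manifest, psms = psms, truth = truth,
         planted = planted),
    class = "synth_world"
  )
}

#' @export
print.synth_world <- function(x, ...) {
  cat("<synth_world> ", length(x$proteome), " proteins, ",
      nrow(x$psms), " PSMs (", sum(x$truth$type == "ligand"),
      " phospho ligands, ", sum(x$truth$type == "contaminant"),
      " contaminants), ", x$config$n_alleles, " alleles, ",
      x$config$n_samples, " samples, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic world to standard-format files
#'
#' Emits `proteome.fasta`, `manifest.tsv`, `catalogue.tsv`, `msms.txt`
#' (MaxQuant dialect) and `truth.tsv` into a directory.
#'
#' @param world A `synth_world`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_proteome(world$proteome, file.path(dir, "proteome.fasta"))
  write_sample_manifest(world$manifest, file.path(dir, "manifest.tsv"))
  write_phosphosite_catalogue(world$catalogue,
                              file.path(dir, "catalogue.tsv"))
  write_psm_table(world$psms, file.path(dir, "msms.txt"))
  truth <- world$truth
  tab <- data.frame(
    sample_id = truth$sample_id, allele = truth$allele,
    peptide = mapply(format_mod_peptide, truth$sequence, truth$phospho,
                     USE.NAMES = FALSE),
    sites = vapply(truth$phospho, paste, character(1), collapse = ";"),
    core_offset = truth$core_offset, type = truth$type,
    protein = truth$protein, start = truth$start
  )
  utils::write.table(tab, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Train discovery models from a world's unmodified ligands
#'
#' Builds per-allele models from the true cores of the world's unmodified
#' ligands (the standard discovery situation: motifs of unmodified ligands
#' are known, phosphopeptides are assigned against them).
#'
#' @param world A `synth_world`.
#' @param pseudo_weight,phospho_prior,n_cal,cal_seed See
#'   [train_models_from_interactions()].
#' @return Named list of calibrated `allele_model`s.
#' @export
train_models_from_truth <- function(world, pseudo_weight = 5,
                                    phospho_prior = 0.01, n_cal = 2000,
                                    cal_seed = 1) {
  tr <- world$truth[world$truth$type == "unmod_ligand", , drop = FALSE]
  inter <- tibble::tibble(
    allele = tr$allele,
    core = substr(tr$sequence, tr$core_offset, tr$core_offset + CORE_LEN - 1L)
  )
  train_models_from_interactions(inter, world$proteome, arm = "native23",
                                 pseudo_weight = pseudo_weight,
                                 phospho_prior = phospho_prior,
                                 n_cal = n_cal, cal_seed = cal_seed)
}
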