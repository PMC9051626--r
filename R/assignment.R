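# Allelic restriction of filtered phosphopeptides: score each peptide
# against every allele of its sample, keep alleles passing the percent-rank
# cutoff, and summarize the resulting phosphopeptidome.

#' Substitute phosphorylated residues by glutamic acid
#'
#' Maps a phospho-annotated peptide onto the plain 20-letter alphabet by
#' replacing every phosphosite with E, mimicking the negative charge of the
#' phosphate group. Used to score phosphopeptides with models trained on
#' unmodified ligands only. Idempotent.
#'
#' @param sequence Peptide sequence.
#' @param phospho 1-based phosphosite positions.
#' @return 20-letter sequence of the same length.
#' @export
substitute_phospho_as_glu <- function(sequence, phospho = integer(0)) {
  if (!length(phospho)) return(sequence)
  syms <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(syms[phospho] %in% c("S", "T", "Y", "E"))) {
    stop("phosphosites must sit on S, T or Y")
  }
  syms[phospho] <- "E"
  paste(syms, collapse = "")
}

#' Assign a peptide to the alleles of its sample
#'
#' Scores one peptide against every allele model listed for the sample and
#' keeps alleles whose percent rank is at or below `cutoff` (inclusive),
#' sorted best-first. In mode `"substitute_E"` the peptide is scored after
#' phospho-to-glutamate substitution (the discovery convention, usable with
#' models trained on unmodified ligands); in `"native23"` the 23-letter
#' sequence is scored directly (requires phospho-aware models).
#'
#' @param sequence,phospho Peptide and its phosphosites.
#' @param sample One row of a sample manifest (list/tibble row with
#'   `sample_id` and `alleles`).
#' @param models Named list of calibrated `allele_model`s covering every
#'   allele of the sample.
#' @param cutoff Percent-rank cutoff; alleles with rank <= cutoff are kept.
#' @param mode `"substitute_E"` or `"native23"`.
#' @return Tibble with one row per passing allele (`sample_id`, `allele`,
#'   `sequence`, `phospho`, `core`, `core_offset`, `raw_score`,
#'   `percent_rank`), plus attribute `status` (`"assigned"`/`"unassigned"`).
#' @export
assign_peptide <- function(sequence, phospho, sample, models, cutoff = 10,
                           mode = c("substitute_E", "native23")) {
  mode <- match.arg(mode)
  alleles <- if (is.list(sample$alleles)) sample$alleles[[1]] else sample$alleles
  missing_m <- setdiff(alleles, names(models))
  if (length(missing_m)) {
    stop("no model for allele(s): ", paste(missing_m, collapse = ", "))
  }
  rows <- lapply(alleles, function(al) {
    m <- models[[al]]
    ca <- if (mode == "substitute_E") {
      score_peptide(m, substitute_phospho_as_glu(sequence, phospho))
    } else {
      score_peptide(m, sequence, phospho)
    }
    tibble::tibble(
      sample_id = sample$sample_id,
      allele = al,
      sequence = sequence,
      phospho = list(phospho),
      core = ca$core,
      core_offset = ca$core_offset,
      raw_score = ca$raw_score,
      percent_rank = ca$percent_rank
    )
  })
  res <- dplyr::bind_rows(rows)
  res <- res[res$percent_rank <= cutoff, , drop = FALSE]
  res <- res[order(res$percent_rank), , drop = FALSE]
  # core/core_offset refer to the natively annotated peptide: re-annotate
  # phospho marks on the core for substitute_E mode
  if (nrow(res)) {
    res$core <- vapply(seq_len(nrow(res)), function(i) {
      off <- res$core_offset[i]
      ph <- phospho[phospho >= off & phospho < off + 9L] - off + 1L
      format_mod_peptide(substr(sequence, off, off + 8L), ph)
    }, character(1))
  }
  attr(res, "status") <- if (nrow(res)) "assigned" else "unassigned"
  res
}

#' Assign a filtered peptidome to sample alleles
#'
#' Applies [assign_peptide()] to every unique (sample, peptide) pair of a
#' filtered PSM table. Identical peptides found in several samples are
#' assigned per sample.
#'
#' @param psms Filtered PSM tibble (see [filter_psms()]).
#' @param manifest Sample manifest tibble (see [read_sample_manifest()]).
#' @param models Named list of calibrated `allele_model`s.
#' @param cutoff Percent-rank cutoff (inclusive).
#' @param mode Scoring mode, as in [assign_peptide()].
#' @param best_only Keep only the best-ranked passing allele per peptide.
#' @return List with `interactions` (one row per passing peptide x allele,
#'   as in [assign_peptide()]) and `unassigned` (the peptide rows with no
#'   passing allele). Together they partition the unique input peptides.
#' @export
assign_peptidome <- function(psms, manifest, models, cutoff = 10,
                             mode = c("substitute_E", "native23"),
                             best_only = FALSE) {
  mode <- match.arg(mode)
  key <- paste(psms$sample_id, peptide_key(psms$sequence, psms$phospho))
  uniq <- psms[!duplicated(key), , drop = FALSE]
  inter <- list()
  unass <- list()
  for (i in seq_len(nrow(uniq))) {
    srow <- manifest[manifest$sample_id == uniq$sample_id[i], , drop = FALSE]
    if (!nrow(srow)) {
      stop("sample '", uniq$sample_id[i], "' is not in the manifest")
    }
    res <- assign_peptide(uniq$sequence[i], uniq$phospho[[i]], srow, models,
                          cutoff = cutoff, mode = mode)
    if (nrow(res)) {
      if (best_only) res <- res[1, , drop = FALSE]
      inter[[length(inter) + 1L]] <- res
    } else {
      unass[[length(unass) + 1L]] <- uniq[i, , drop = FALSE]
    }
  }
  empty_inter <- tibble::tibble(
    sample_id = character(), allele = character(), sequence = character(),
    phospho = list(), core = character(), core_offset = integer(),
    raw_score = numeric(), percent_rank = numeric()
  )
  list(
    interactions = if (length(inter)) dplyr::bind_rows(inter) else empty_inter,
    unassigned = if (length(unass)) dplyr::bind_rows(unass) else
      uniq[0, , drop = FALSE]
  )
}

#' Write an interactions table
#'
#' Tab-separated: `sample_id`, `allele`, annotated `peptide`, `sites`
#' (1-based, semicolon-separated), `core` (annotated 9-mer), `core_offset`
#' (1-based), `raw_score`, `percent_rank`.
#'
#' @param interactions Interactions tibble from [assign_peptidome()].
#' @param path Output path.
#' @export
write_interactions <- function(interactions, path) {
  tab <- data.frame(
    sample_id = interactions$sample_id,
    allele = interactions$allele,
    peptide = mapply(format_mod_peptide, interactions$sequence,
                     interactions$phospho, USE.NAMES = FALSE),
    sites = vapply(interactions$phospho, paste, character(1),
                   collapse = ";"),
    core = interactions$core,
    core_offset = interactions$core_offset,
    raw_score = interactions$raw_score,
    percent_rank = interactions$percent_rank
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an interactions table written by [write_interactions()]
#' @param path Input path.
#' @return Interactions tibble.
#' @export
read_interactions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  parsed <- lapply(tab$peptide, parse_mod_peptide)
  tibble::tibble(
    sample_id = as.character(tab$sample_id),
    allele = as.character(tab$allele),
    sequence = vapply(parsed, `[[`, character(1), "sequence"),
    phospho = lapply(parsed, function(p) as.integer(p$phospho)),
    core = as.character(tab$core),
    core_offset = as.integer(tab$core_offset),
    raw_score = as.numeric(tab$raw_score),
    percent_rank = as.numeric(tab$percent_rank)
  )
}

#' Score-distribution separation between assigned and unassigned PSMs
#'
#' Two-sample Kolmogorov-Smirnov tests comparing identification scores and
#' delta scores between PSMs whose peptides were assigned to at least one
#' allele and PSMs whose peptides were not. Contaminants and wrongly
#' identified peptides are expected to skew the unassigned group toward
#' lower scores.
#'
#' @param assigned,unassigned PSM tibbles with `peptide_score` and
#'   `delta_score` columns.
#' @return Tibble with one row per score type: `score_type`, `ks_statistic`,
#'   `p_value`.
#' @export
qc_score_separation <- function(assigned, unassigned) {
  if (!nrow(assigned) || !nrow(unassigned)) {
    stop("both groups must be non-empty")
  }
  one <- function(type, x, y) {
    kt <- suppressWarnings(stats::ks.test(x, y))
    tibble::tibble(score_type = type,
                   ks_statistic = unname(kt$statistic),
                   p_value = kt$p.value)
  }
  dplyr::bind_rows(
    one("peptide_score", assigned$peptide_score, unassigned$peptide_score),
    one("delta_score", assigned$delta_score, unassigned$delta_score)
  )
}

#' Summarize an assigned phosphopeptidome
#'
#' Histograms are computed over unique peptides (keyed by sequence plus
#' phosphosite set); interactions are counted over distinct
#' (peptide, allele) pairs.
#'
#' @param interactions Interactions tibble from [assign_peptidome()].
#' @return List: `n_unique` (unique peptides), `n_interactions`
#'   (peptide x allele pairs), `length_histogram` (tibble length/count),
#'   `phospho_histogram` (tibble n_phospho/count/fraction), `n_alleles`.
#' @export
summarize_peptidome <- function(interactions) {
  key <- peptide_key(interactions$sequence, interactions$phospho)
  uniq <- interactions[!duplicated(key), , drop = FALSE]
  lens <- nchar(uniq$sequence)
  nph <- lengths(uniq$phospho)
  lt <- table(lens)
  lh <- tibble::tibble(length = as.integer(names(lt)),
                       count = as.integer(lt))
  pt <- table(nph)
  ph <- tibble::tibble(n_phospho = as.integer(names(pt)),
                       count = as.integer(pt))
  ph$fraction <- ph$count / sum(ph$count)
  list(
    n_unique = nrow(uniq),
    n_interactions = nrow(unique(tibble::tibble(
      key = key, allele = interactions$allele))),
    length_histogram = lh,
    phospho_histogram = ph,
    n_alleles = length(unique(interactions$allele))
  )
}

#' Assignment rate of length-matched random phosphosite peptides
#'
#' Control for the enrichment of the observed phosphopeptidome in true
#' ligands: draws random peptides around known phosphosites with the same
#' length distribution as the query set (sampling lengths with
#' replacement), runs the same assignment, and reports the fraction
#' excluded.
#'
#' @param interactions Assigned interactions (supplies the length
#'   distribution and the sample x allele context).
#' @param catalogue Phosphosite catalogue tibble.
#' @param proteome Named character vector of proteins.
#' @param manifest Sample manifest.
#' @param models Named list of calibrated models.
#' @param n Number of random peptides.
#' @param cutoff,mode As in [assign_peptidome()].
#' @param seed Integer seed.
#' @return List with `n`, `n_excluded`, `fraction_excluded`.
#' @export
random_peptide_control <- function(interactions, catalogue, proteome,
                                   manifest, models, n = 500, cutoff = 10,
                                   mode = "substitute_E", seed = 1) {
  key <- peptide_key(interactions$sequence, interactions$phospho)
  uniq <- interactions[!duplicated(key), , drop = FALSE]
  lens <- nchar(uniq$sequence)
  samples <- unique(interactions$sample_id)
  excluded <- 0L
  withr_seed(seed, {
    negs <- sample_negatives(catalogue, proteome, n = n,
                             lengths = sample(lens, n, replace = TRUE),
                             seed = sample.int(2^30, 1))
    sids <- sample(samples, n, replace = TRUE)
    for (i in seq_len(n)) {
      srow <- manifest[manifest$sample_id == sids[i], , drop = FALSE]
      res <- assign_peptide(negs$sequence[i], negs$phospho[[i]], srow,
                            models, cutoff = cutoff, mode = mode)
      if (!nrow(res)) excluded <- excluded + 1L
    }
  })
  list(n = n, n_excluded = excluded, fraction_excluded = excluded / n)
}
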