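# Readers, writers and PSM-level filters for immunopeptidomics tables.
#
# All coordinates in this package are 1-based and intervals are closed,
# following base-R convention; binding-core positions are reported with the
# standard P1..P9 labels.

MAXQUANT_COLUMNS <- c(
  sequence   = "Sequence",
  modified   = "Modified sequence",
  score      = "Score",
  delta      = "Delta score",
  loc_probs  = "Phospho (STY) Probabilities",
  proteins   = "Proteins",
  sample     = "Raw file"
)

#' Read an MS identification table
#'
#' Reads a tab-separated peptide-spectrum-match (PSM) table in the MaxQuant
#' `msms.txt` dialect and parses modification strings into phosphosite
#' positions. Rows whose modification syntax cannot be parsed are excluded
#' with a warning (their count is kept in the `n_excluded` attribute), never
#' silently dropped.
#'
#' @param path Path to a tab-separated file.
#' @param dialect Table dialect; only `"maxquant"` is built in.
#' @param column_map Optional named character vector overriding the dialect's
#'   column names (names as in `MAXQUANT_COLUMNS`).
#' @return A tibble with one row per PSM: `sample_id`, `sequence`, `phospho`
#'   (list of 1-based phosphosite positions), `loc_probs` (list of per-site
#'   localization probabilities), `peptide_score`, `delta_score`, `proteins`
#'   (list of source-protein identifiers), `n_phospho`. Attribute
#'   `n_excluded` counts malformed rows.
#' @export
read_psm_table <- function(path, dialect = "maxquant", column_map = NULL) {
  stopifnot(file.exists(path))
  cmap <- MAXQUANT_COLUMNS
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(cmap), names(tab))
  if (length(missing_cols)) {
    stop("PSM table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(tab)
  out <- vector("list", n)
  bad <- logical(n)
  for (i in seq_len(n)) {
    parsed <- tryCatch(
      parse_maxquant_modified(tab[[cmap["modified"]]][i],
                              tab[[cmap["sequence"]]][i]),
      error = function(e) e
    )
    if (inherits(parsed, "error")) {
      warning("row ", i, ": ", conditionMessage(parsed), "; row excluded",
              call. = FALSE)
      bad[i] <- TRUE
      next
    }
    probs <- parse_localization_probs(tab[[cmap["loc_probs"]]][i],
                                      parsed$phospho)
    out[[i]] <- tibble::tibble(
      sample_id = as.character(tab[[cmap["sample"]]][i]),
      sequence = parsed$sequence,
      phospho = list(parsed$phospho),
      loc_probs = list(probs),
      peptide_score = as.numeric(tab[[cmap["score"]]][i]),
      delta_score = as.numeric(tab[[cmap["delta"]]][i]),
      proteins = list(strsplit(as.character(tab[[cmap["proteins"]]][i]),
                               ";", fixed = TRUE)[[1]]),
      n_phospho = length(parsed$phospho)
    )
  }
  res <- dplyr::bind_rows(out[!bad])
  if (!nrow(res)) {
    res <- tibble::tibble(
      sample_id = character(), sequence = character(), phospho = list(),
      loc_probs = list(), peptide_score = numeric(), delta_score = numeric(),
      proteins = list(), n_phospho = integer()
    )
  }
  attr(res, "n_excluded") <- sum(bad)
  res
}

# "_AS(ph)KDPS(ph)SR_" -> sequence + phospho positions; non-phospho variable
# modifications ((ox), (ac), ...) are parsed and ignored downstream.
parse_maxquant_modified <- function(modified, sequence = NULL) {
  txt <- gsub("^_|_$", "", modified)
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  seq_chars <- character(0)
  phospho <- integer(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      close <- NULL
      j <- i + 1L
      while (j <= n) {
        if (chars[j] == ")") { close <- j; break }
        j <- j + 1L
      }
      if (is.null(close)) stop("unclosed modification bracket in '", modified, "'")
      mod <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      if (mod == "ph") {
        if (!length(seq_chars)) {
          stop("phospho modification with no preceding residue in '",
               modified, "'")
        }
        res <- seq_chars[length(seq_chars)]
        if (!res %in% c("S", "T", "Y")) {
          stop("phospho modification on non-STY residue '", res, "' in '",
               modified, "'")
        }
        phospho <- c(phospho, length(seq_chars))
      }
      i <- close + 1L
    } else if (ch %in% c(AA_CANONICAL, "X", "U")) {
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in modified sequence '",
           modified, "'")
    }
  }
  seq_out <- paste(seq_chars, collapse = "")
  if (!is.null(sequence) && nzchar(sequence) && seq_out != sequence) {
    stop("modified sequence '", modified, "' does not match sequence '",
         sequence, "'")
  }
  list(sequence = seq_out, phospho = phospho)
}

# "AS(0.99)KDPS(0.91)SR": probability in parentheses attaches to the
# preceding residue; returns the probabilities at the assigned phosphosites
# (NA where the column does not report the site).
parse_localization_probs <- function(prob_text, phospho) {
  if (!length(phospho)) return(numeric(0))
  if (is.null(prob_text) || is.na(prob_text) || !nzchar(prob_text)) {
    return(rep(NA_real_, length(phospho)))
  }
  chars <- strsplit(prob_text, "", fixed = TRUE)[[1]]
  pos <- 0L
  probs <- c()
  prob_at <- integer(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (chars[i] == "(") {
      j <- i + 1L
      while (j <= n && chars[j] != ")") j <- j + 1L
      if (j > n) return(rep(NA_real_, length(phospho)))
      probs <- c(probs, as.numeric(paste(chars[(i + 1L):(j - 1L)], collapse = "")))
      prob_at <- c(prob_at, pos)
      i <- j + 1L
    } else {
      pos <- pos + 1L
      i <- i + 1L
    }
  }
  vapply(phospho, function(p) {
    hit <- which(prob_at == p)
    if (length(hit)) probs[hit[1]] else NA_real_
  }, numeric(1))
}

#' Write a PSM table in the MaxQuant dialect
#'
#' Inverse of [read_psm_table()]; round-trips exactly on tables produced by
#' the synthetic-data generator.
#'
#' @param psms A PSM tibble as returned by [read_psm_table()].
#' @param path Output path.
#' @export
write_psm_table <- function(psms, path) {
  modseq <- vapply(seq_len(nrow(psms)), function(i) {
    syms <- strsplit(psms$sequence[i], "", fixed = TRUE)[[1]]
    ph <- psms$phospho[[i]]
    syms[ph] <- paste0(syms[ph], "(ph)")
    paste0("_", paste(syms, collapse = ""), "_")
  }, character(1))
  probseq <- vapply(seq_len(nrow(psms)), function(i) {
    ph <- psms$phospho[[i]]
    if (!length(ph)) return("")
    syms <- strsplit(psms$sequence[i], "", fixed = TRUE)[[1]]
    pr <- psms$loc_probs[[i]]
    syms[ph] <- paste0(syms[ph], "(", format(pr, trim = TRUE), ")")
    paste(syms, collapse = "")
  }, character(1))
  tab <- data.frame(
    check.names = FALSE,
    `Raw file` = psms$sample_id,
    Sequence = psms$sequence,
    `Modified sequence` = modseq,
    Score = psms$peptide_score,
    `Delta score` = psms$delta_score,
    `Phospho (STY) Probabilities` = probseq,
    Proteins = vapply(psms$proteins, paste, character(1), collapse = ";")
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter PSMs on identification quality and length
#'
#' Keeps PSMs with identification score >= `min_score`, delta score >=
#' `min_delta`, every phosphosite localization probability strictly greater
#' than `min_locprob`, and peptide length within `len_range` (inclusive).
#' The defaults are the standard curation thresholds for phosphopeptide
#' identifications in HLA-II peptidomics. The filter is pure: order is
#' preserved and it is idempotent.
#'
#' @param psms PSM tibble from [read_psm_table()].
#' @param min_score Minimum identification (Andromeda) score.
#' @param min_delta Minimum delta score (difference to the second-best match).
#' @param min_locprob Phosphosite localization probabilities must exceed this
#'   value strictly; sites with unknown probability fail.
#' @param len_range Length-2 numeric, inclusive peptide-length bounds.
#' @return The filtered subset of `psms`, same columns and order.
#' @export
filter_psms <- function(psms, min_score = 40, min_delta = 10,
                        min_locprob = 0.75, len_range = c(12, 25)) {
  if (!nrow(psms)) return(psms)
  len <- nchar(psms$sequence)
  loc_ok <- vapply(psms$loc_probs, function(p) {
    !length(p) || all(!is.na(p) & p > min_locprob)
  }, logical(1))
  keep <- psms$peptide_score >= min_score &
    psms$delta_score >= min_delta &
    loc_ok &
    len >= len_range[1] & len <= len_range[2]
  psms[keep, , drop = FALSE]
}

#' Read a sample manifest
#'
#' @param path Tab-separated file with columns `sample_id`, `alleles`
#'   (semicolon-separated HLA-II allele names) and `capture` (one of
#'   `DR-only`, `pan-II-only`, `both`).
#' @return Tibble with `sample_id`, `alleles` (list column), `capture`.
#' @export
read_sample_manifest <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "alleles", "capture") %in% names(tab)))
  alleles <- strsplit(tab$alleles, ";", fixed = TRUE)
  for (i in seq_along(alleles)) {
    if (!length(alleles[[i]])) {
      stop("sample '", tab$sample_id[i], "' lists no alleles")
    }
    if (anyDuplicated(alleles[[i]])) {
      stop("sample '", tab$sample_id[i], "' lists duplicate alleles")
    }
  }
  tibble::tibble(
    sample_id = as.character(tab$sample_id),
    alleles = alleles,
    capture = as.character(tab$capture)
  )
}

#' Write a sample manifest
#' @param manifest Tibble as returned by [read_sample_manifest()].
#' @param path Output path.
#' @export
write_sample_manifest <- function(manifest, path) {
  tab <- data.frame(
    sample_id = manifest$sample_id,
    alleles = vapply(manifest$alleles, paste, character(1), collapse = ";"),
    capture = manifest$capture
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phosphosite catalogue
#'
#' @param path Tab-separated file with columns `protein_id`, `position`
#'   (1-based) and `residue` (S, T or Y).
#' @param proteome Optional proteome (see [read_proteome()]); when supplied,
#'   each entry's residue is checked against the protein sequence.
#' @return Tibble with `protein_id`, `position`, `residue`.
#' @export
read_phosphosite_catalogue <- function(path, proteome = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "position", "residue") %in% names(tab)))
  cat <- tibble::tibble(
    protein_id = as.character(tab$protein_id),
    position = as.integer(tab$position),
    residue = as.character(tab$residue)
  )
  if (!all(cat$residue %in% c("S", "T", "Y"))) {
    stop("catalogue residues must be S, T or Y")
  }
  if (!is.null(proteome)) {
    prot <- as_proteome_chr(proteome)
    ok <- vapply(seq_len(nrow(cat)), function(i) {
      p <- prot[[cat$protein_id[i]]]
      !is.null(p) && !is.na(p) && cat$position[i] <= nchar(p) &&
        substr(p, cat$position[i], cat$position[i]) == cat$residue[i]
    }, logical(1))
    if (!all(ok)) {
      stop(sum(!ok), " catalogue entries do not match the proteome")
    }
  }
  cat
}

#' Write a phosphosite catalogue
#' @param catalogue Tibble with `protein_id`, `position`, `residue`.
#' @param path Output path.
#' @export
write_phosphosite_catalogue <- function(catalogue, path) {
  utils::write.table(as.data.frame(catalogue), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a proteome from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of protein sequences (names are the first
#'   whitespace-delimited token of each FASTA header).
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

#' Write a proteome to FASTA
#' @param proteome Named character vector of protein sequences.
#' @param path Output path.
#' @export
write_proteome <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

as_proteome_chr <- function(proteome) {
  if (is.character(proteome)) return(as.list(proteome))
  as.list(as.character(proteome))
}

#' Extend peptides with source-protein context
#'
#' Maps each peptide to its source protein by exact substring match and
#' appends `flank` residues of protein context on each side. Positions
#' beyond the protein termini are padded with the sentinel symbol `-`, which
#' matches no motif position. When a peptide maps to several proteins the
#' lexicographically smallest protein identifier is used (deterministic);
#' within a protein the leftmost occurrence is taken. Peptides with no exact
#' match are flagged and returned with sentinel padding only.
#'
#' @param peptides Tibble with columns `sequence`, `phospho` (list) and
#'   optionally `proteins` (list of candidate source proteins), or a plain
#'   character vector of sequences.
#' @param proteome Named character vector (see [read_proteome()]).
#' @param flank Number of context residues on each side.
#' @return Tibble with `sequence`, `phospho`, `context` (string of length
#'   `nchar(sequence) + 2 * flank`), `context_phospho` (phosphosites in
#'   context coordinates, shifted by `flank`), `protein` (chosen id or `NA`)
#'   and `matched` (logical).
#' @export
extend_peptide_context <- function(peptides, proteome, flank = 4) {
  if (is.character(peptides)) {
    peptides <- tibble::tibble(
      sequence = peptides,
      phospho = rep(list(integer(0)), length(peptides))
    )
  }
  prot <- unlist(as_proteome_chr(proteome))
  ids_sorted <- sort(names(prot))
  pad <- strrep(SENTINEL, flank)
  n <- nrow(peptides)
  context <- character(n)
  protein <- rep(NA_character_, n)
  matched <- logical(n)
  has_src <- "proteins" %in% names(peptides)
  for (i in seq_len(n)) {
    sq <- peptides$sequence[i]
    cand <- ids_sorted
    if (has_src) {
      listed <- intersect(sort(peptides$proteins[[i]]), ids_sorted)
      if (length(listed)) cand <- listed
    }
    hit <- NA_character_
    at <- NA_integer_
    for (id in cand) {
      m <- regexpr(sq, prot[[id]], fixed = TRUE)
      if (m > 0) { hit <- id; at <- as.integer(m); break }
    }
    if (is.na(hit) && has_src) {
      # listed proteins missed: fall back to a full-proteome search
      for (id in ids_sorted) {
        m <- regexpr(sq, prot[[id]], fixed = TRUE)
        if (m > 0) { hit <- id; at <- as.integer(m); break }
      }
    }
    if (is.na(hit)) {
      context[i] <- paste0(pad, sq, pad)
    } else {
      p <- prot[[hit]]
      lo <- at - flank
      hi <- at + nchar(sq) - 1L + flank
      left <- substr(p, max(1L, lo), at - 1L)
      right <- substr(p, at + nchar(sq), min(nchar(p), hi))
      context[i] <- paste0(
        strrep(SENTINEL, flank - nchar(left)), left, sq, right,
        strrep(SENTINEL, flank - nchar(right))
      )
      protein[i] <- hit
      matched[i] <- TRUE
    }
  }
  tibble::tibble(
    sequence = peptides$sequence,
    phospho = peptides$phospho,
    context = context,
    context_phospho = lapply(peptides$phospho, function(p) p + flank),
    protein = protein,
    matched = matched
  )
}

#' Read a filtered peptide table written by [write_peptide_table()]
#' @param path Input path.
#' @return Tibble with `sample_id`, `sequence`, `phospho`,
#'   `peptide_score`, `delta_score`, `proteins`, `n_phospho`.
#' @export
read_peptide_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  parsed <- lapply(tab$peptide, parse_mod_peptide)
  tibble::tibble(
    sample_id = as.character(tab$sample_id),
    sequence = vapply(parsed, `[[`, character(1), "sequence"),
    phospho = lapply(parsed, function(p) as.integer(p$phospho)),
    loc_probs = lapply(parsed, function(p) rep(NA_real_, length(p$phospho))),
    peptide_score = as.numeric(tab$peptide_score),
    delta_score = as.numeric(tab$delta_score),
    proteins = strsplit(as.character(tab$proteins), ";", fixed = TRUE),
    n_phospho = vapply(parsed, function(p) length(p$phospho), integer(1))
  )
}

#' Write a filtered peptide table
#'
#' Tab-separated output with explicit phospho annotation (`AS[p]K...`) and a
#' 1-based site-list column.
#'
#' @param psms PSM tibble.
#' @param path Output path.
#' @export
write_peptide_table <- function(psms, path) {
  tab <- data.frame(
    sample_id = psms$sample_id,
    peptide = mapply(format_mod_peptide, psms$sequence, psms$phospho,
                     USE.NAMES = FALSE),
    sites = vapply(psms$phospho, paste, character(1), collapse = ";"),
    peptide_score = psms$peptide_score,
    delta_score = psms$delta_score,
    proteins = vapply(psms$proteins, paste, character(1), collapse = ";")
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
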