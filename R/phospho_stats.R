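# Positional statistics of phosphosites within HLA-II ligands and kinase
# substrate-motif enrichment with source-gene bias control.

#' Phosphosites and residues in binding core versus flanking regions
#'
#' Classifies every residue of every assigned peptide as inside the 9-mer
#' binding core (`[core_offset, core_offset + 8]`) or in the peptide
#' flanking regions (PFR), and does the same for phosphosites only. Similar
#' core/PFR fractions for phosphosites and for all residues indicate no
#' regional preference of phosphorylation.
#'
#' @param assignments Tibble with `sequence`, `phospho` (list) and
#'   `core_offset` columns.
#' @return Tibble with rows `phosphosites` and `all_residues`:
#'   `n_core`, `n_pfr`, `frac_core`, `frac_pfr`.
#' @export
phospho_core_vs_pfr <- function(assignments) {
  ph_core <- 0L; ph_pfr <- 0L; all_core <- 0L; all_pfr <- 0L
  for (i in seq_len(nrow(assignments))) {
    len <- nchar(assignments$sequence[i])
    off <- assignments$core_offset[i]
    in_core <- function(pos) pos >= off & pos <= off + CORE_LEN - 1L
    ph <- assignments$phospho[[i]]
    ph_core <- ph_core + sum(in_core(ph))
    ph_pfr <- ph_pfr + sum(!in_core(ph))
    all_core <- all_core + CORE_LEN
    all_pfr <- all_pfr + (len - CORE_LEN)
  }
  tibble::tibble(
    class = c("phosphosites", "all_residues"),
    n_core = c(ph_core, all_core),
    n_pfr = c(ph_pfr, all_pfr),
    frac_core = c(ph_core / max(1L, ph_core + ph_pfr),
                  all_core / max(1L, all_core + all_pfr)),
    frac_pfr = c(ph_pfr / max(1L, ph_core + ph_pfr),
                 all_pfr / max(1L, all_core + all_pfr))
  )
}

#' Terminal phosphosite distribution
#'
#' Counts phosphosites in the first three positions (N-terminal) and the
#' last three positions (C-terminal) of each peptide, and the per-position
#' breakdown within the first three N-terminal positions. A peptide with
#' terminal phosphosites at both ends contributes to both counts. Both
#' site-level and peptide-level countings are reported (a peptide counts
#' once per terminus at peptide level).
#'
#' @param assignments Tibble with `sequence` and `phospho` columns; rows
#'   should be unique peptides.
#' @return List: `n_term_sites`, `c_term_sites`, `n_term_peptides`,
#'   `c_term_peptides`, `frac_c_of_terminal_sites`,
#'   `nterm_position_counts` (named vector, positions 1-3),
#'   `nterm_position_fractions`.
#' @export
terminal_phospho_distribution <- function(assignments) {
  n_sites <- 0L; c_sites <- 0L; n_pep <- 0L; c_pep <- 0L
  pos_counts <- stats::setNames(integer(3), as.character(1:3))
  for (i in seq_len(nrow(assignments))) {
    len <- nchar(assignments$sequence[i])
    ph <- assignments$phospho[[i]]
    at_n <- ph[ph <= 3L]
    at_c <- ph[ph > len - 3L]
    n_sites <- n_sites + length(at_n)
    c_sites <- c_sites + length(at_c)
    if (length(at_n)) n_pep <- n_pep + 1L
    if (length(at_c)) c_pep <- c_pep + 1L
    for (p in at_n) pos_counts[p] <- pos_counts[p] + 1L
  }
  term <- n_sites + c_sites
  list(
    n_term_sites = n_sites, c_term_sites = c_sites,
    n_term_peptides = n_pep, c_term_peptides = c_pep,
    frac_c_of_terminal_sites = if (term) c_sites / term else NA_real_,
    frac_c_of_terminal_peptides = if (n_pep + c_pep)
      c_pep / (n_pep + c_pep) else NA_real_,
    nterm_position_counts = pos_counts,
    nterm_position_fractions = if (sum(pos_counts))
      pos_counts / sum(pos_counts) else pos_counts * NA_real_
  )
}

#' Positional distribution of phosphosites within the binding core
#'
#' Only peptides with at least one phosphosite inside the core contribute;
#' each in-core phosphosite counts once at its core position, so the
#' overall frequencies sum to one across P1..P9. Multiply phosphorylated
#' cores contribute each in-core site independently. Per-allele frequency
#' vectors are returned to quantify dispersion across alleles.
#'
#' @param assignments Tibble with `sequence`, `phospho`, `core_offset` and
#'   `allele` columns.
#' @return List: `counts` (named integer, P1..P9), `frequencies` (sums to
#'   1), `per_allele` (matrix alleles x 9 of per-allele frequencies).
#' @export
core_position_distribution <- function(assignments) {
  counts <- stats::setNames(integer(CORE_LEN),
                            paste0("P", seq_len(CORE_LEN)))
  per_allele <- list()
  for (i in seq_len(nrow(assignments))) {
    off <- assignments$core_offset[i]
    ph <- assignments$phospho[[i]]
    core_pos <- ph[ph >= off & ph <= off + CORE_LEN - 1L] - off + 1L
    if (!length(core_pos)) next
    al <- assignments$allele[i]
    if (is.null(per_allele[[al]])) per_allele[[al]] <- integer(CORE_LEN)
    for (p in core_pos) {
      counts[p] <- counts[p] + 1L
      per_allele[[al]][p] <- per_allele[[al]][p] + 1L
    }
  }
  freq <- if (sum(counts)) counts / sum(counts) else counts * NA_real_
  pa <- if (length(per_allele)) {
    m <- do.call(rbind, lapply(per_allele, function(x) x / max(1L, sum(x))))
    colnames(m) <- names(counts)
    m
  } else {
    matrix(numeric(0), 0, CORE_LEN, dimnames = list(NULL, names(counts)))
  }
  list(counts = counts, frequencies = freq, per_allele = pa)
}

# ---- kinase motifs ----------------------------------------------------

#' Parse a kinase-motif pattern
#'
#' Bracket grammar: each position is a single residue, a bracketed
#' alternative set like `[pS/pT]` or `[D/E]`, or the wildcard `X` (any
#' residue). Exactly one position — the anchor — must contain phospho
#' symbols.
#'
#' @param pattern_text Pattern, e.g. `"RXX[pS/pT]"`.
#' @param name Optional motif name.
#' @return Object of class `kinase_motif`: list with `pattern` (list of
#'   character sets, `NULL` for wildcard), `anchor_index`, `anchor_set`,
#'   `name`, `text` (canonical form).
#' @export
parse_kinase_motif <- function(pattern_text, name = pattern_text) {
  chars <- strsplit(pattern_text, "", fixed = TRUE)[[1]]
  pattern <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket at column ", i, " in '",
                      pattern_text, "'")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      toks <- strsplit(body, "/", fixed = TRUE)[[1]]
      if (!length(toks) || !all(toks %in% c(AA_CANONICAL, PHOSPHO_SYMBOLS))) {
        stop("malformed alternative set '[", body, "]' at column ", i,
             " in '", pattern_text, "'")
      }
      pattern[[length(pattern) + 1L]] <- toks
      i <- j + 1L
    } else if (ch == "X") {
      pattern[length(pattern) + 1L] <- list(NULL)
      i <- i + 1L
    } else if (ch == "p") {
      if (i + 1L > n || !chars[i + 1L] %in% c("S", "T", "Y")) {
        stop("malformed phospho symbol at column ", i, " in '",
             pattern_text, "'")
      }
      pattern[[length(pattern) + 1L]] <- paste0("p", chars[i + 1L])
      i <- i + 2L
    } else if (ch %in% AA_CANONICAL) {
      pattern[[length(pattern) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' at column ", i, " in '",
           pattern_text, "'")
    }
  }
  if (!length(pattern)) stop("empty pattern")
  is_phos <- vapply(pattern, function(s) {
    !is.null(s) && any(s %in% PHOSPHO_SYMBOLS)
  }, logical(1))
  if (sum(is_phos) != 1L) {
    stop("pattern '", pattern_text,
         "' must contain exactly one phospho anchor position (found ",
         sum(is_phos), ")")
  }
  anchor <- which(is_phos)
  if (!all(pattern[[anchor]] %in% PHOSPHO_SYMBOLS)) {
    stop("anchor position mixes phospho and canonical symbols in '",
         pattern_text, "'")
  }
  canonical <- vapply(pattern, function(s) {
    if (is.null(s)) "X"
    else if (length(s) == 1L) s[[1]]
    else paste0("[", paste(s, collapse = "/"), "]")
  }, character(1))
  structure(
    list(pattern = pattern, anchor_index = anchor,
         anchor_set = pattern[[anchor]], name = name,
         text = paste(canonical, collapse = "")),
    class = "kinase_motif"
  )
}

#' @export
print.kinase_motif <- function(x, ...) {
  cat("<kinase_motif> ", x$name, ": ", x$text, " (anchor at position ",
      x$anchor_index, ")\n", sep = "")
  invisible(x)
}

#' Read a kinase-motif list
#'
#' Plain text, one pattern per line in the bracket grammar, optional name
#' after a tab; `#` lines are comments.
#'
#' @param path Input file.
#' @return List of `kinase_motif` objects.
#' @export
read_kinase_motifs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parse_kinase_motif(parts[1],
                       name = if (length(parts) > 1) parts[2] else parts[1])
  })
}

#' Scan peptides for a kinase motif
#'
#' Counts, among candidate sites whose residue type matches the motif's
#' anchor set, those whose surrounding context matches the full pattern.
#' With `phospho_aware = TRUE` candidate sites are the phosphosites of the
#' matching residue types (e.g. pS and pT for a `[pS/pT]` anchor); with
#' `phospho_aware = FALSE` they are the unmodified parent residues (S and
#' T), matching the unmodified-counterpart convention. The denominator is
#' the number of candidate sites; windows that run into sentinel padding
#' never match but still count in the denominator.
#'
#' @param motif A `kinase_motif`.
#' @param extended Tibble from [extend_peptide_context()] (columns
#'   `sequence`, `context`, `context_phospho`).
#' @param phospho_aware Scan phosphosites (`TRUE`) or unmodified sites.
#' @return List: `count`, `denominator`, `matches` (site identifiers
#'   `"row:position"` of matching sites).
#' @export
scan_kinase_motif <- function(motif, extended, phospho_aware = TRUE) {
  parents <- unname(PHOSPHO_PARENTS[motif$anchor_set])
  count <- 0L
  denom <- 0L
  matches <- character(0)
  for (i in seq_len(nrow(extended))) {
    ctx <- strsplit(extended$context[i], "", fixed = TRUE)[[1]]
    flank <- (length(ctx) - nchar(extended$sequence[i])) %/% 2L
    span <- (flank + 1L):(flank + nchar(extended$sequence[i]))
    ph <- extended$context_phospho[[i]]
    if (phospho_aware) {
      sites <- ph[ctx[ph] %in% parents]
    } else {
      sites <- span[ctx[span] %in% parents & !(span %in% ph)]
    }
    if (!length(sites)) next
    denom <- denom + length(sites)
    for (s in sites) {
      if (match_window(motif, ctx, ph, s, phospho_aware)) {
        count <- count + 1L
        matches <- c(matches, paste0(i, ":", s))
      }
    }
  }
  list(count = count, denominator = denom, matches = matches)
}

# does the pattern match around site position s in context ctx?
match_window <- function(motif, ctx, ph, s, phospho_aware) {
  L <- length(motif$pattern)
  start <- s - motif$anchor_index + 1L
  for (k in seq_len(L)) {
    pos <- start + k - 1L
    if (pos < 1L || pos > length(ctx)) return(FALSE)
    ch <- ctx[pos]
    if (ch == SENTINEL) return(FALSE)
    sym <- if (pos %in% ph) paste0("p", ch) else ch
    spec <- motif$pattern[[k]]
    if (is.null(spec)) next  # wildcard
    if (k == motif$anchor_index && !phospho_aware) {
      spec <- unname(PHOSPHO_PARENTS[spec])
    }
    if (!sym %in% spec) return(FALSE)
  }
  TRUE
}

#' Context windows around catalogued phosphosites
#'
#' Turns a phosphosite catalogue into the extended-peptide shape consumed
#' by [scan_kinase_motif()]: one window of `flank` residues on each side of
#' every site, with the central residue phosphorylated.
#'
#' @param catalogue Tibble `protein_id`, `position`, `residue`.
#' @param proteome Named character vector.
#' @param flank Context residues on each side.
#' @return Tibble compatible with [scan_kinase_motif()].
#' @export
catalogue_context <- function(catalogue, proteome, flank = 4) {
  prot <- unlist(as_proteome_chr(proteome))
  n <- nrow(catalogue)
  ctx <- character(n)
  for (i in seq_len(n)) {
    p <- prot[[catalogue$protein_id[i]]]
    pos <- catalogue$position[i]
    lo <- pos - flank
    hi <- pos + flank
    left <- substr(p, max(1L, lo), pos - 1L)
    right <- substr(p, pos + 1L, min(nchar(p), hi))
    ctx[i] <- paste0(strrep(SENTINEL, flank - nchar(left)), left,
                     catalogue$residue[i], right,
                     strrep(SENTINEL, flank - nchar(right)))
  }
  tibble::tibble(
    sequence = catalogue$residue,
    phospho = rep(list(1L), n),
    context = ctx,
    context_phospho = rep(list(flank + 1L), n),
    protein = catalogue$protein_id,
    matched = TRUE
  )
}

#' Kinase-motif enrichment across ligand strata
#'
#' Scans each motif in the phosphorylated-ligand stratum (phospho-aware),
#' the unmodified-ligand stratum (unmodified counterpart) and the
#' phosphoproteome stratum, normalizes counts by the number of anchor-type
#' sites in each stratum, and tests enrichment of the motif in
#' phosphorylated versus unmodified HLA-II ligands with a one-sided
#' Fisher's exact test. Results are sorted by decreasing phosphoproteome
#' frequency. With `non_redundant = TRUE`, motifs whose phospho-stratum
#' match set is a subset of a shorter retained motif's match set are
#' dropped.
#'
#' @param motifs List of `kinase_motif` objects.
#' @param phos_extended Extended phosphorylated ligands
#'   ([extend_peptide_context()] output).
#' @param unmod_extended Extended unmodified ligands.
#' @param phosphoproteome Extended phosphoproteome windows
#'   ([catalogue_context()] output).
#' @param non_redundant Apply subset pruning.
#' @return Tibble with one row per motif: `motif`, `name`, counts and
#'   denominators per stratum, `freq_*`, `p_value` (`NA` flagged when a
#'   stratum denominator is zero), `tested`.
#' @export
kinase_enrichment <- function(motifs, phos_extended, unmod_extended,
                              phosphoproteome, non_redundant = FALSE) {
  scans <- lapply(motifs, function(m) {
    list(
      motif = m,
      phos = scan_kinase_motif(m, phos_extended, phospho_aware = TRUE),
      unmod = scan_kinase_motif(m, unmod_extended, phospho_aware = FALSE),
      ppro = scan_kinase_motif(m, phosphoproteome, phospho_aware = TRUE)
    )
  })
  if (non_redundant && length(scans) > 1) {
    ord <- order(vapply(scans, function(s) length(s$motif$pattern),
                        integer(1)))
    kept <- list()
    for (i in ord) {
      redundant <- any(vapply(kept, function(k) {
        length(k$motif$pattern) < length(scans[[i]]$motif$pattern) &&
          all(scans[[i]]$phos$matches %in% k$phos$matches)
      }, logical(1)))
      if (!redundant) kept[[length(kept) + 1L]] <- scans[[i]]
    }
    scans <- kept
  }
  rows <- lapply(scans, function(s) {
    freq <- function(x) if (x$denominator) x$count / x$denominator else NA_real_
    tested <- s$phos$denominator > 0 && s$unmod$denominator > 0
    p <- if (tested) {
      tab <- matrix(c(s$phos$count, s$phos$denominator - s$phos$count,
                      s$unmod$count, s$unmod$denominator - s$unmod$count),
                    nrow = 2, byrow = TRUE)
      stats::fisher.test(tab, alternative = "greater")$p.value
    } else NA_real_
    tibble::tibble(
      motif = s$motif$text, name = s$motif$name,
      count_phos = s$phos$count, denom_phos = s$phos$denominator,
      count_unmod = s$unmod$count, denom_unmod = s$unmod$denominator,
      count_phosphoproteome = s$ppro$count,
      denom_phosphoproteome = s$ppro$denominator,
      freq_phos = freq(s$phos), freq_unmod = freq(s$unmod),
      freq_phosphoproteome = freq(s$ppro),
      p_value = p, tested = tested
    )
  })
  res <- dplyr::bind_rows(rows)
  res[order(-ifelse(is.na(res$freq_phosphoproteome), -Inf,
                    res$freq_phosphoproteome)), , drop = FALSE]
}

#' Source-gene overlap odds ratio
#'
#' Tests whether genes contributing motif-bearing phosphosites are depleted
#' or enriched among source genes of HLA-II ligands, via the 2x2 partition
#' of a gene universe by membership in the two sets. The odds ratio is
#' `(a*d)/(b*c)`; when any cell is zero the Haldane correction (+0.5 to
#' every cell) is applied and flagged.
#'
#' @param hla_ligand_genes,motif_phosphosite_genes Character sets, both
#'   subsets of `universe`.
#' @param universe Character set of all considered source genes.
#' @return List: `odds_ratio`, `table` (2x2 matrix), `corrected` (logical).
#' @export
source_gene_overlap_odds_ratio <- function(hla_ligand_genes,
                                           motif_phosphosite_genes,
                                           universe) {
  if (!length(universe)) stop("empty gene universe")
  if (!all(hla_ligand_genes %in% universe) ||
      !all(motif_phosphosite_genes %in% universe)) {
    stop("gene sets must be subsets of the universe")
  }
  in_a <- universe %in% hla_ligand_genes
  in_b <- universe %in% motif_phosphosite_genes
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("ligand", "not_ligand"),
                                c("motif", "not_motif")))
  corrected <- any(tab == 0)
  t2 <- if (corrected) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(odds_ratio = unname(or), table = tab, corrected = corrected)
}
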