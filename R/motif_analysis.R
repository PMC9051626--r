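# Binding-motif construction for unmodified and phosphorylated ligands and
# motif-similarity statistics.

#' Build a display motif from aligned binding cores
#'
#' Pure position frequencies (zero pseudocount) over the 23-letter alphabet.
#' With `restrict_phospho_in_core = TRUE`, cores carrying no phosphorylated
#' residue within the 9 core positions are dropped before counting, so the
#' motif reflects only ligands whose phosphosite sits in the binding groove.
#'
#' @param cores Character vector of annotated 9-mers (phospho marked as in
#'   [format_mod_peptide()]) or list of symbol vectors.
#' @param restrict_phospho_in_core Drop cores without an in-core phosphosite.
#' @return A 23 x 9 frequency matrix with attributes `n_cores` (cores used)
#'   and `empty` (`TRUE` when no core survived the restriction; the matrix
#'   is then all zero).
#' @export
build_motif <- function(cores, restrict_phospho_in_core = FALSE) {
  empty_pwm <- matrix(0, 23L, CORE_LEN,
                      dimnames = list(aa_alphabet23(),
                                      paste0("P", seq_len(CORE_LEN))))
  if (!length(cores)) {
    return(structure(empty_pwm, n_cores = 0L, empty = TRUE))
  }
  idx <- cores_to_index_matrix(cores)
  if (restrict_phospho_in_core) {
    has_ph <- apply(idx, 1, function(r) any(r > 20L))
    idx <- idx[has_ph, , drop = FALSE]
  }
  if (!nrow(idx)) {
    return(structure(empty_pwm, n_cores = 0L, empty = TRUE))
  }
  counts <- vapply(seq_len(CORE_LEN), function(p) {
    tabulate(idx[, p], nbins = 23L)
  }, numeric(23L))
  pwm <- counts / nrow(idx)
  dimnames(pwm) <- dimnames(empty_pwm)
  structure(pwm, n_cores = nrow(idx), empty = FALSE)
}

#' Renormalize a PWM onto the canonical 20-letter alphabet
#'
#' Removes the phospho rows and rescales each position's remaining
#' frequencies to sum to one. Needed for comparing phospho motifs against
#' motifs of unmodified ligands on a common alphabet.
#'
#' @param pwm 23 x 9 (or 20 x 9) frequency matrix.
#' @return 20 x 9 matrix with unit column sums.
#' @export
renormalize_drop_phospho <- function(pwm) {
  if (nrow(pwm) == 20L) return(pwm)
  stopifnot(nrow(pwm) == 23L)
  canon <- pwm[AA_CANONICAL, , drop = FALSE]
  mass <- colSums(canon)
  if (any(mass <= 0)) {
    stop("position(s) ", paste(which(mass <= 0), collapse = ", "),
         " carry all their mass on phospho symbols; cannot renormalize")
  }
  sweep(canon, 2, mass, "/")
}

#' Euclidean distance between two PWMs
#'
#' Square root of the summed squared frequency differences over all cells.
#'
#' @param p,q Frequency matrices of identical dimensions.
#' @return Non-negative scalar; zero iff the matrices are equal.
#' @export
pwm_distance <- function(p, q) {
  if (!all(dim(p) == dim(q))) {
    stop("PWM dimensions differ: ", paste(dim(p), collapse = "x"), " vs ",
         paste(dim(q), collapse = "x"))
  }
  sqrt(sum((p - q)^2))
}

#' Build per-allele motif pairs from assigned interactions
#'
#' For each allele, the unmodified motif is built from the cores of
#' unmodified ligands and the phospho motif from the cores of
#' phosphorylated ligands restricted to in-core phosphosites.
#'
#' @param interactions Interactions tibble (needs `allele`, `core`,
#'   `phospho` columns); rows with empty `phospho` count as unmodified.
#' @return Tibble with one row per allele: `allele`, `pwm_unmod`,
#'   `pwm_phos` (list columns of matrices), `n_unmod`, `n_phos_all`,
#'   `n_phos_core`.
#' @export
motif_pairs <- function(interactions) {
  is_phos <- lengths(interactions$phospho) > 0
  alleles <- sort(unique(interactions$allele))
  rows <- lapply(alleles, function(al) {
    sel <- interactions$allele == al
    unmod_cores <- interactions$core[sel & !is_phos]
    phos_cores <- interactions$core[sel & is_phos]
    pu <- build_motif(unmod_cores)
    pp <- build_motif(phos_cores, restrict_phospho_in_core = TRUE)
    tibble::tibble(
      allele = al,
      pwm_unmod = list(pu),
      pwm_phos = list(pp),
      n_unmod = length(unmod_cores),
      n_phos_all = length(phos_cores),
      n_phos_core = attr(pp, "n_cores")
    )
  })
  dplyr::bind_rows(rows)
}

#' Intra- versus inter-allele motif-distance test
#'
#' For each allele, the intra-allele distance compares its phospho motif
#' (renormalized onto the 20-letter alphabet) with the unmodified motif of
#' the same allele; inter-allele distances compare it with the unmodified
#' motifs of every other allele. A one-sided Wilcoxon rank-sum test asks
#' whether intra-allele distances are smaller, i.e. whether phospho motifs
#' resemble their own allele's motif more than other alleles'.
#'
#' Alleles with fewer than `min_phos_core` in-core phospho cores are
#' excluded (unstable motifs) and reported.
#'
#' @param pairs Motif-pair tibble from [motif_pairs()].
#' @param min_phos_core Minimum in-core phospho cores per allele.
#' @return List: `intra` (length-n numeric), `inter` (length n*(n-1)),
#'   `p_value` (one-sided, `NA` flagged degenerate when all distances are
#'   equal), `alleles_used`, `alleles_excluded`.
#' @export
intra_vs_inter_distance_test <- function(pairs, min_phos_core = 10) {
  keep <- pairs$n_phos_core >= min_phos_core &
    !vapply(pairs$pwm_phos, function(m) isTRUE(attr(m, "empty")), logical(1))
  excluded <- pairs$allele[!keep]
  pairs <- pairs[keep, , drop = FALSE]
  n <- nrow(pairs)
  if (n < 2) stop("need at least 2 alleles with usable phospho motifs")
  phos20 <- lapply(pairs$pwm_phos, renormalize_drop_phospho)
  unmod20 <- lapply(pairs$pwm_unmod, renormalize_drop_phospho)
  intra <- vapply(seq_len(n), function(i) {
    pwm_distance(phos20[[i]], unmod20[[i]])
  }, numeric(1))
  inter <- numeric(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) inter <- c(inter, pwm_distance(phos20[[i]], unmod20[[j]]))
    }
  }
  p <- if (length(unique(c(intra, inter))) == 1L) {
    NA_real_  # degenerate: all distances identical
  } else {
    suppressWarnings(
      stats::wilcox.test(intra, inter, alternative = "less")$p.value
    )
  }
  list(intra = intra, inter = inter, p_value = p,
       alleles_used = pairs$allele, alleles_excluded = excluded)
}

#' Export motif matrices as tab-separated text
#'
#' Writes the 23 x 9 motif (and, when renormalizable, the 20 x 9
#' renormalized motif) for downstream logo rendering; phospho rows are
#' marked in a `phospho` column so renderers can color them distinctly.
#'
#' @param pwm Motif matrix from [build_motif()].
#' @param path Output path.
#' @export
write_motif_matrix <- function(pwm, path) {
  tab <- data.frame(symbol = rownames(pwm),
                    phospho = rownames(pwm) %in% PHOSPHO_SYMBOLS,
                    as.data.frame(pwm, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
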