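# 23-letter alphabet: 20 canonical amino acids plus phospho-S/T/Y.

#' The 23-symbol phospho-aware amino-acid alphabet
#'
#' The 20 canonical amino acids in one-letter code (alphabetical order)
#' followed by the three phosphorylated residues `pS`, `pT`, `pY`. The order
#' is fixed; all position weight matrices in the package index their rows by
#' this vector.
#'
#' @return Character vector of length 23.
#' @export
#' @examples
#' aa_alphabet23()
aa_alphabet23 <- function() {
  c(AA_CANONICAL, PHOSPHO_SYMBOLS)
}

AA_CANONICAL <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

PHOSPHO_SYMBOLS <- c("pS", "pT", "pY")

# residues that can carry a phosphate
PHOSPHO_PARENTS <- c(pS = "S", pT = "T", pY = "Y")

# out-of-protein padding; matches no motif position and no PWM row
SENTINEL <- "-"

#' Convert a peptide to its 23-letter symbol vector
#'
#' @param sequence Character scalar over the canonical 20-letter alphabet.
#' @param phospho Integer vector of 1-based phosphosite positions (must point
#'   at S, T or Y).
#' @return Character vector, one symbol per residue; phosphosites appear as
#'   `pS`/`pT`/`pY`.
#' @export
peptide_symbols <- function(sequence, phospho = integer(0)) {
  syms <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(phospho)) {
    res <- syms[phospho]
    bad <- !res %in% PHOSPHO_PARENTS
    if (any(bad)) {
      stop("phosphosite at position ", paste(phospho[bad], collapse = ", "),
           " does not point at S, T or Y in '", sequence, "'")
    }
    syms[phospho] <- paste0("p", res)
  }
  syms
}

#' Map symbols to alphabet indices
#'
#' @param symbols Character vector of symbols from [aa_alphabet23()].
#' @return Integer indices 1..23; unknown symbols (including the sentinel)
#'   map to `NA`.
#' @export
symbol_index <- function(symbols) {
  match(symbols, aa_alphabet23())
}

#' Annotated peptide string
#'
#' Formats a peptide with explicit phospho annotation, e.g. `"ASKDPS[p]SR"`
#' for a phosphosite on the serine at position 6.
#'
#' @param sequence Peptide sequence (20-letter).
#' @param phospho 1-based phosphosite positions.
#' @return Character scalar with `[p]` after each phosphorylated residue.
#' @export
format_mod_peptide <- function(sequence, phospho = integer(0)) {
  if (!length(phospho)) return(sequence)
  syms <- strsplit(sequence, "", fixed = TRUE)[[1]]
  syms[phospho] <- paste0(syms[phospho], "[p]")
  paste(syms, collapse = "")
}

#' Parse an annotated peptide string
#'
#' Inverse of [format_mod_peptide()].
#'
#' @param text Peptide string with optional `[p]` markers.
#' @return List with `sequence` and integer `phospho` positions.
#' @export
parse_mod_peptide <- function(text) {
  pos <- integer(0)
  seq_chars <- character(0)
  i <- 1L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      if (i + 2L > n || chars[i + 1L] != "p" || chars[i + 2L] != "]" ||
          !length(seq_chars)) {
        stop("malformed phospho annotation in '", text, "' at character ", i)
      }
      pos <- c(pos, length(seq_chars))
      i <- i + 3L
    } else {
      seq_chars <- c(seq_chars, ch)
      i <- i + 1L
    }
  }
  list(sequence = paste(seq_chars, collapse = ""), phospho = pos)
}

#' Key identifying a modified peptide
#'
#' Peptides with identical sequence but different phosphosite placements
#' are distinct objects; this key (sequence plus sorted site list) is the
#' identity used for uniqueness and cross-validation leakage checks.
#'
#' @param sequence Peptide sequence(s).
#' @param phospho Integer vector of sites, or a list of such vectors when
#'   `sequence` is a vector.
#' @return Character key(s).
#' @export
peptide_key <- function(sequence, phospho) {
  if (is.list(phospho)) {
    mapply(function(s, p) peptide_key(s, p), sequence, phospho, USE.NAMES = FALSE)
  } else {
    paste0(sequence, "|", paste(sort(phospho), collapse = ";"))
  }
}
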