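# Shared synthetic fixtures, built once per test run.

# modest default-condition world: 3 alleles, 4 samples, contaminants present
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_world(synth_config(
        seed = 101, n_samples = 4, n_ligands_per_sample = 30,
        n_unmod_per_sample = 60, n_proteins = 200,
        n_extra_catalogue_sites = 500
      ))
    }
    cache
  }
})

# discovery models trained on the small world's unmodified ligands
small_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- train_models_from_truth(small_world(), n_cal = 1000,
                                        cal_seed = 5)
    }
    cache
  }
})

# phospho-aware 23-letter PWM: canonical planted motif with a share of
# S/T/Y mass moved onto pS/pT/pY at the given core positions
inject_phospho_pwm <- function(pwm20, positions = 2:8, share = 0.2) {
  pwm <- rbind(pwm20, pS = 0, pT = 0, pY = 0)
  for (p in positions) {
    for (r in c("S", "T", "Y")) {
      moved <- pwm[r, p] * share
      pwm[r, p] <- pwm[r, p] - moved
      pwm[paste0("p", r), p] <- moved
    }
  }
  sweep(pwm, 2, colSums(pwm), "/")
}

# structured random PWM over the full 23-symbol alphabet: independent
# Dirichlet(alpha) columns
random_pwm23 <- function(seed, alpha = 0.5) {
  set.seed(seed)
  m <- matrix(stats::rgamma(23 * 9, shape = alpha), 23, 9,
              dimnames = list(aa_alphabet23(), paste0("P", 1:9)))
  sweep(m, 2, colSums(m), "/")
}

# random annotated peptide over the 23-letter alphabet
random_mod_peptide <- function(len, n_phospho = 1) {
  res <- sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                len, replace = TRUE)
  ph <- integer(0)
  if (n_phospho > 0) {
    pos <- sample(len, min(n_phospho, len))
    res[pos] <- sample(c("S", "T", "Y"), length(pos), replace = TRUE)
    ph <- sort(pos)
  }
  list(sequence = paste(res, collapse = ""), phospho = ph)
}
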