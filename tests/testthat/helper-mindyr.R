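# Shared builders: tiny expression fixtures and hand-made record tables.

tiny_expr <- function(n_genes = 3, n_samples = 9, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), nrow = n_genes,
              dimnames = list(paste0("G", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  m
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Conditional-record table with chosen MI ranks and modulated flags.
make_records <- function(n, modulated_idx, tf = "TF1", modulator = "M1",
                         dmi = 0.4) {
  tibble::tibble(
    tf = tf, modulator = modulator,
    target = sprintf("T%03d", seq_len(n)),
    mi_top = 0.5, mi_bottom = 0.3,
    mi_original = seq(n, 1) / n,  # target 1 strongest
    dmi = ifelse(seq_len(n) %in% modulated_idx, dmi, 0),
    mi_shift = NA_real_, p_perm = 1, stability = 0,
    modulated = seq_len(n) %in% modulated_idx,
    degenerate = FALSE
  )
}

quick_cohort <- function(..., seed = 1) {
  simulate_cohort(sim_config(..., seed = seed))
}
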