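# Shared fixture builders; everything is generated in code.

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

random_dna_string <- function(n, seed) {
  generate_dna(n, seed = seed)$bases
}

# Small supervised set over a learnable signal: sum of sinusoids.
sinusoid_supervised <- function(n = 80L, lookback = 8L, channels = 1L) {
  t <- seq_len(n)
  base <- 3 + sin(2 * pi * t / 20) + 0.5 * sin(2 * pi * t / 7)
  M <- sapply(seq_len(channels), function(ci) base * ci / channels)
  make_supervised(as.matrix(M), lookback = lookback, target = 1L)
}
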