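# Small in-code fixtures shared across test files.

tiny_matrix <- function(m = 3, n = 2, seed = 42) {
  withr::with_seed(seed, {
    v <- matrix(round(stats::runif(m * n, 1, 100), 3), m, n)
  })
  expression_matrix(v, paste0("gene", seq_len(m)), paste0("samp", seq_len(n)))
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
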