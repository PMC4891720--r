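# shared fixtures and independent oracles

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

make_records <- function(...) {
  seqs <- c(...)
  tibble::tibble(id = paste0("p", seq_along(seqs)), sequence = seqs)
}

write_fasta_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# regex-based longest-run oracle, independent of the rle-based scanner
regex_longest <- function(sequence, aa) {
  m <- gregexpr(paste0(aa, "+"), sequence, fixed = FALSE)[[1]]
  if (m[1] == -1L) 0L else max(attr(m, "match.length"))
}
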