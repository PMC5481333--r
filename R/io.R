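# TSV helpers: fixed formatting so identical tables are byte-identical files.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
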