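## Shared plain-text serialization helpers.
## All numeric output goes through signif(x, 9) so repeated runs with the same
## config and seed are byte-identical across platforms.

#' @keywords internal
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 9), digits = 9, format = "g"))
}

#' Write a data frame as TSV with 9-significant-digit numeric formatting
#' @keywords internal
write_tsv_file <- function(df, path) {
  df2 <- df
  for (nm in names(df2)) {
    if (is.numeric(df2[[nm]])) df2[[nm]] <- fmt_num(df2[[nm]])
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a square matrix as whitespace-delimited text with a one-line header
#'
#' The header line is `# N <n> k_modes <k>`; rows follow, one per line.
#' @keywords internal
write_square_matrix <- function(mat, path, k_modes = NA) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N %d k_modes %s", nrow(mat),
                     if (is.na(k_modes)) "NA" else as.character(k_modes)), con)
  apply(mat, 1L, function(r) writeLines(paste(fmt_num(r), collapse = " "), con))
  invisible(path)
}

#' @keywords internal
read_square_matrix <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  mat <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  stopifnot(nrow(mat) == ncol(mat))
  mat
}

#' Write a distance matrix in PHYLIP square format
#' @keywords internal
write_phylip_square <- function(mat, ids, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(mat)), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(formatC(ids[i], width = 10, flag = "-"),
                     paste(fmt_num(mat[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
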