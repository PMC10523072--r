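# Write a CSV atomically: to a temp file in the target directory, then
# rename into place, so a crashed run never leaves a truncated table.
write_csv_atomic <- function(df, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(pattern = paste0(".", basename(path), "."), tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  if (!file.rename(tmp, path))
    stop("could not move ", tmp, " to ", path, call. = FALSE)
  invisible(path)
}

read_table_checked <- function(path, required_cols, what) {
  if (!file.exists(path))
    stop(what, " file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop(what, " file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}
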