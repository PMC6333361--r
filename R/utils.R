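# shared internal helpers

GROUP_TYPES <- c("consumer", "producer", "detritus")
DOMAINS <- c("benthic", "demersal", "pelagic")

# first column of `df` holds row codes; remaining columns become a numeric
# matrix. NA cells become 0 unless keep_na.
df_to_matrix <- function(df, keep_na = FALSE) {
  df <- as.data.frame(df)
  codes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (!keep_na) m[is.na(m)] <- 0
  rownames(m) <- codes
  m
}

matrix_to_df <- function(m, code_col = "group") {
  out <- tibble::as_tibble(m, rownames = code_col)
  out
}

# rows/cols guaranteed present and ordered; absent entries 0
conform_matrix <- function(m, rows, cols, what = "matrix") {
  out <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  if (is.null(m) || length(m) == 0) return(out)
  bad_r <- setdiff(rownames(m), rows)
  bad_c <- setdiff(colnames(m), cols)
  if (length(bad_r) > 0) {
    abort(sprintf("%s: unresolvable group name(s): %s", what,
                  paste(bad_r, collapse = ", ")))
  }
  if (length(bad_c) > 0) {
    abort(sprintf("%s: unresolvable column name(s): %s", what,
                  paste(bad_c, collapse = ", ")))
  }
  out[rownames(m), colnames(m)] <- m
  out
}

row_sums <- function(m) if (ncol(m) == 0) rep(0, nrow(m)) else rowSums(m)
col_sums <- function(m) if (nrow(m) == 0) rep(0, ncol(m)) else colSums(m)

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
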