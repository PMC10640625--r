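# Shared TSV conventions: tab-separated, header row, decimal point, UTF-8.

read_tsv_strict <- function(path, numeric_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fill = FALSE, blank.lines.skip = FALSE,
                          fileEncoding = "UTF-8")
  if (!is.null(numeric_cols)) {
    for (cn in numeric_cols) {
      if (!cn %in% names(df)) stop("missing column '", cn, "' in ", path, call. = FALSE)
      v <- df[[cn]]
      if (is.character(v)) {
        suppressWarnings(vn <- as.numeric(v))
        bad <- which(is.na(vn) & !is.na(v))
        if (length(bad) > 0)
          stop("non-numeric value in ", path, " column '", cn, "', row ",
               bad[1], ": '", v[bad[1]], "'", call. = FALSE)
        v <- vn
      }
      na <- which(is.na(v))
      if (length(na) > 0)
        stop("missing value in ", path, " column '", cn, "', row ", na[1],
             call. = FALSE)
      df[[cn]] <- v
    }
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Numeric matrix from a data frame, erroring with row/column coordinates on
# blanks or non-numeric cells (readers must never impute).
df_to_matrix <- function(df, path = "<table>") {
  m <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df),
              dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & nzchar(trimws(v)))
      if (length(bad) > 0)
        stop("non-numeric cell in ", path, " at row ", bad[1], ", column '",
             names(df)[j], "': '", v[bad[1]], "'", call. = FALSE)
      v <- vn
    }
    v <- as.numeric(v)
    na <- which(!is.finite(v))
    if (length(na) > 0)
      stop("missing or non-finite cell in ", path, " at row ", na[1],
           ", column '", names(df)[j], "'", call. = FALSE)
    m[, j] <- v
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
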