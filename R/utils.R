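# Internal helpers shared across modules.

# Deterministic chain-identifier sequence: A-Z, a-z, 0-9, then two-character
# combinations of the same alphabet (AA, AB, ...). PDB columns allow >1 char
# only in some dialects; two-character ids are written left-justified.
chain_id_sequence <- function(n) {
  base <- c(LETTERS, letters, as.character(0:9))
  if (n <= length(base)) return(base[seq_len(n)])
  two <- as.vector(t(outer(base, base, paste0)))
  c(base, two)[seq_len(n)]
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Fixed-format numeric rendering for deterministic, byte-stable TSV output.
fmt_num <- function(x, digits = 10) {
  out <- sprintf(paste0("%.", digits, "g"), x)
  out[is.na(x)] <- "NA"
  out
}

# Write a data.frame as TSV with deterministic formatting (numbers already
# rendered to character by the caller or via fmt_num here).
write_tsv_det <- function(df, path, header_lines = character()) {
  df[] <- lapply(df, function(col) if (is.numeric(col)) fmt_num(col) else as.character(col))
  con <- file(path, open = "wb")  # binary: fixed "\n" on every platform
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con, sep = "\n")
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con, sep = "\n")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_identity_op <- function(op, tol = 1e-6) {
  max(abs(op$rotation - diag(3))) < tol && max(abs(op$translation)) < tol
}
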