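# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok)
    stopf("'%s' = %s is outside the allowed range %s%s, %s%s", name,
          format(x), if (strict) "(" else "[", format(lower),
          format(upper), if (strict) ")" else "]")
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min)
    stopf("'%s' must be an integer >= %d", name, min)
  as.integer(x)
}

# Locale-independent sort: feature ids must order identically on any system.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a per-stage seed from a root seed; keeps results below .Machine
# integer range and decoupled across stages.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587)
}

write_tsv <- function(df, path) {
  write.table(df, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, na = "NA", eol = "\n",
              fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

# Normalise a nucleotide string to uppercase RNA; reject bad alphabets.
normalize_rna <- function(seq, what = "sequence") {
  s <- toupper(seq)
  s <- chartr("T", "U", s)
  if (grepl("[^ACGU]", s))
    stopf("%s contains characters outside A/C/G/U/T", what)
  s
}

revcomp_rna <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(rev(unname(RNA_COMPLEMENT[chars])), collapse = "")
}

# All (possibly overlapping) 1-based start positions of `pattern` in `x`.
find_all_occurrences <- function(x, pattern) {
  nx <- nchar(x); np <- nchar(pattern)
  if (np > nx) return(integer(0))
  starts <- seq_len(nx - np + 1L)
  starts[substring(x, starts, starts + np - 1L) == pattern]
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
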