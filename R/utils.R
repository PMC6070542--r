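# Internal validation and matrix helpers shared across modules.

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min)
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

assert_square_matrix <- function(m, name = "matrix") {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m))
    stop(sprintf("'%s' must be a square numeric matrix", name), call. = FALSE)
  invisible(m)
}

assert_connectivity_matrix <- function(m, name = "matrix", tol = 1e-8) {
  assert_square_matrix(m, name)
  if (any(!is.finite(m)))
    stop(sprintf("'%s' contains non-finite entries", name), call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop(sprintf("'%s' is not symmetric", name), call. = FALSE)
  if (any(abs(diag(m)) > tol))
    stop(sprintf("'%s' has a non-zero diagonal", name), call. = FALSE)
  if (min(m) < -tol || max(m) > 1 + tol)
    stop(sprintf("'%s' has entries outside [0, 1]", name), call. = FALSE)
  invisible(m)
}

# Values of the strict upper triangle, column-major order (the package's
# canonical edge ordering: edge e maps to (i, j), i < j).
upper_tri_values <- function(m) m[upper.tri(m)]

# Rebuild a symmetric matrix (zero diagonal) from upper-triangle values.
matrix_from_upper_tri <- function(values, n, labels = NULL) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- values
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# 12 significant digits: enough to make text output reproduce doubles across
# platforms for checksumming without printing noise digits.
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  out[num] <- lapply(df[num], format_num)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m))
  labels <- colnames(m)
  if (is.null(labels)) labels <- sprintf("n%03d", seq_len(ncol(m)))
  txt <- apply(m, 1, function(r) paste(format_num(r), collapse = "\t"))
  writeLines(c(paste(labels, collapse = "\t"), txt), path)
  invisible(path)
}

# Delimiter autodetection for square matrix files: tab wins over comma.
read_matrix_file <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- !all(grepl("^[-+0-9.eE]*$",
                           strsplit(first, sep, fixed = TRUE)[[1]]))
  df <- read.delim(path, sep = sep, header = has_header,
                   check.names = FALSE, strip.white = TRUE)
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop(sprintf("non-numeric entries in matrix file '%s'", path),
         call. = FALSE)
  if (nrow(m) != ncol(m))
    stop(sprintf("matrix in '%s' is not square (%d x %d)",
                 path, nrow(m), ncol(m)), call. = FALSE)
  rownames(m) <- colnames(m)
  m
}
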