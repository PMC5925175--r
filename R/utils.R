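## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = "tissuecut_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## 3-vector cross product (right-handed).
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

norm3 <- function(v) sqrt(sum(v * v))

normalize3 <- function(v) {
  n <- norm3(v)
  if (n < .Machine$double.eps) stopf("cannot normalize a zero vector")
  v / n
}

## Coerce to an n x 3 numeric matrix; accepts vectors of length 3.
as_mat3 <- function(x, what = "points") {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stopf("%s must be length-3 or an n x 3 matrix", what)
    x <- matrix(as.numeric(x), nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stopf("%s must have 3 columns", what)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

## Row-wise Euclidean norms of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == as.integer(x)

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
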