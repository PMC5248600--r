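`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
}

# min-max rescale a matrix to [0, 1]; constant matrices map to all zeros
.rescale01 <- function(A) {
  rng <- range(A)
  if (diff(rng) < .Machine$double.eps) return(A * 0)
  (A - rng[1]) / (rng[2] - rng[1])
}

# clip negative eigenvalues at zero (PSD repair); skips the decomposition
# when the matrix is already numerically PSD
.psdClip <- function(A, tol = 1e-8) {
  e <- eigen(A, symmetric = TRUE)
  if (min(e$values) >= -tol * max(abs(e$values), 1)) return(A)
  v <- pmax(e$values, 0)
  B <- e$vectors %*% (v * t(e$vectors))
  (B + t(B)) / 2
}

# sample standard deviation column-wise without apply() overhead
.colSds <- function(x) {
  n <- nrow(x)
  sqrt((colSums(x^2) - n * colMeans(x)^2) / (n - 1))
}
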