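# Internal helpers shared across modules.

# 2D cumulative (summed-area) table, robust to single-row/col matrices.
sat2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  cm <- m
  if (nr > 1L) cm <- apply(cm, 2L, cumsum)
  cm <- matrix(cm, nr, nc)
  if (nc > 1L) cm <- t(apply(cm, 1L, cumsum))
  matrix(cm, nr, nc)
}

# Sum of every k x k window fully inside the matrix, via a summed-area table.
# Returns an (nrow-k+1) x (ncol-k+1) matrix whose [i, j] entry is
# sum(m[i:(i+k-1), j:(j+k-1)]).
window_sums <- function(m, k) {
  stopifnot(is.matrix(m), k >= 1, k <= nrow(m), k <= ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- sat2d(m)
  i <- seq_len(nr - k + 1L); j <- seq_len(nc - k + 1L)
  S[i + k, j + k, drop = FALSE] - S[i, j + k, drop = FALSE] -
    S[i + k, j, drop = FALSE] + S[i, j, drop = FALSE]
}

# Box-sum over a centered k x k neighborhood, truncated at image edges.
box_sum <- function(m, k) {
  if (k <= 1L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  h <- (k - 1L) %/% 2L
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- sat2d(m)
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + (k - 1L - h), nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + (k - 1L - h), nc)
  S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

# Validate and coerce a grid of ion counts.
as_integerish <- function(x, what = "counts") {
  if (any(!is.finite(x)) || any(x < 0) || any(abs(x - round(x)) > 1e-9))
    stop(sprintf("%s must be finite non-negative integers", what), call. = FALSE)
  round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
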