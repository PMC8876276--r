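#' @keywords internal
"_PACKAGE"

## Rigid integer shift with zero-filled borders: out[r, c] = m[r - dy, c - dx].
shift_zero <- function(m, dy, dx) {
  out <- matrix(0, nrow(m), ncol(m))
  storage.mode(out) <- storage.mode(m)
  r <- seq_len(nrow(m)); cc <- seq_len(ncol(m))
  rs <- r - dy; cs <- cc - dx
  okr <- rs >= 1L & rs <= nrow(m)
  okc <- cs >= 1L & cs <= ncol(m)
  out[r[okr], cc[okc]] <- m[rs[okr], cs[okc]]
  out
}

## Cyclic shift (used by the cross-correlation search and tests).
roll2 <- function(m, dy, dx) {
  m[((seq_len(nrow(m)) - 1L - dy) %% nrow(m)) + 1L,
    ((seq_len(ncol(m)) - 1L - dx) %% ncol(m)) + 1L, drop = FALSE]
}

## Sum a matrix over k x k blocks; trailing partial blocks are dropped.
block_sum <- function(m, k) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (k == 1L) return(m)
  nbr <- nrow(m) %/% k
  nbc <- ncol(m) %/% k
  m <- m[seq_len(nbr * k), seq_len(nbc * k), drop = FALSE]
  g1 <- rep(seq_len(nbr), each = k)
  s1 <- rowsum(m, g1, reorder = FALSE)            # nbr x (nbc*k)
  t(rowsum(t(s1), rep(seq_len(nbc), each = k), reorder = FALSE))
}

## Evaluate expr with an error prefix naming the pipeline stage.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

is_count_matrix <- function(m) {
  is.numeric(m) && all(is.finite(m)) && all(m >= 0) && all(m == round(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
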