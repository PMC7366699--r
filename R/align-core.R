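# Gotoh global alignment with affine gaps, shared by the RNA
# sequence+structure aligner and the built-in protein aligner.
#
# Gap convention: a gap of length L costs open + (L - 1) * extend (the
# first gapped position pays the full opening penalty). Terminal gaps are
# penalized. Traceback ties are broken diagonal > up > left, where "up"
# advances the first sequence (gap in the second).

#' Pairwise alignment container
#'
#' @param pairs Integer matrix with columns `i`, `j` (one row per
#'   alignment column; `NA` marks a gap on that side).
#' @param score Total alignment score.
#' @param n_a,n_b Lengths of the two aligned sequences.
#' @return Object of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(pairs, score, n_a = NA_integer_, n_b = NA_integer_) {
  pairs <- matrix(as.integer(pairs), ncol = 2, dimnames = list(NULL, c("i", "j")))
  if (nrow(pairs) > 0 && any(rowSums(is.na(pairs)) == 2)) {
    abort("an alignment column cannot be gap/gap")
  }
  for (k in 1:2) {
    v <- pairs[!is.na(pairs[, k]), k]
    if (is.unsorted(v, strictly = TRUE)) abort("aligned indices must increase")
  }
  structure(list(pairs = pairs, score = score, length = nrow(pairs),
                 n_a = as.integer(n_a), n_b = as.integer(n_b)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  n_match <- sum(!is.na(x$pairs[, 1]) & !is.na(x$pairs[, 2]))
  cat("<pairwise_alignment> ", x$length, " columns (", n_match,
      " aligned), score ", format(x$score), "\n", sep = "")
  invisible(x)
}

#' @describeIn pairwise_alignment One row per alignment column
#'   (`column`, `i`, `j`).
#' @param x A `pairwise_alignment`.
#' @param ... Unused.
#' @export
tidy.pairwise_alignment <- function(x, ...) {
  tibble::tibble(column = seq_len(x$length),
                 i = x$pairs[, 1], j = x$pairs[, 2])
}

# aligned (i, j) index pairs as a data.frame (gap columns dropped)
aligned_pairs <- function(alignment) {
  p <- alignment$pairs
  keep <- !is.na(p[, 1]) & !is.na(p[, 2])
  p[keep, , drop = FALSE]
}

# score_matrix: n_a x n_b substitution scores
gotoh_align <- function(score_matrix, gap_open, gap_extend) {
  n <- nrow(score_matrix)
  m <- ncol(score_matrix)
  stopifnot(n >= 1, m >= 1, gap_open > 0, gap_extend > 0)
  NEG <- -Inf
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  # pointer codes: 1 = from M, 2 = from X, 3 = from Y
  pM <- pX <- pY <- matrix(0L, n + 1, m + 1)
  M[1, 1] <- 0
  gap_cost <- function(L) gap_open + (L - 1) * gap_extend
  if (n >= 1) for (i in seq_len(n)) { X[i + 1, 1] <- -gap_cost(i); pX[i + 1, 1] <- 2L }
  if (m >= 1) for (j in seq_len(m)) { Y[1, j + 1] <- -gap_cost(j); pY[1, j + 1] <- 3L }
  pX[2, 1] <- 1L
  pY[1, 2] <- 1L
  argmax3 <- function(a, b, c) {
    # fixed preference M > X > Y on ties
    if (a >= b && a >= c) 1L else if (b >= c) 2L else 3L
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      # match state
      a <- M[i, j]; b <- X[i, j]; c <- Y[i, j]
      w <- argmax3(a, b, c)
      M[i + 1, j + 1] <- c(a, b, c)[w] + score_matrix[i, j]
      pM[i + 1, j + 1] <- w
      # gap in second sequence (consume i): open from M/Y, extend from X
      a <- M[i, j + 1] - gap_open
      b <- X[i, j + 1] - gap_extend
      c <- Y[i, j + 1] - gap_open
      w <- argmax3(a, b, c)
      X[i + 1, j + 1] <- c(a, b, c)[w]
      pX[i + 1, j + 1] <- w
      # gap in first sequence (consume j)
      a <- M[i + 1, j] - gap_open
      b <- X[i + 1, j] - gap_open
      c <- Y[i + 1, j] - gap_extend
      w <- argmax3(a, b, c)
      Y[i + 1, j + 1] <- c(a, b, c)[w]
      pY[i + 1, j + 1] <- w
    }
  }
  final <- argmax3(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  score <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])[final]
  # traceback
  cols <- list()
  i <- n; j <- m; state <- final
  while (i > 0 || j > 0) {
    if (state == 1L) {
      cols[[length(cols) + 1L]] <- c(i, j)
      state <- pM[i + 1, j + 1]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      cols[[length(cols) + 1L]] <- c(i, NA_integer_)
      state <- pX[i + 1, j + 1]
      i <- i - 1L
    } else {
      cols[[length(cols) + 1L]] <- c(NA_integer_, j)
      state <- pY[i + 1, j + 1]
      j <- j - 1L
    }
  }
  pairs <- do.call(rbind, rev(cols))
  pairwise_alignment(pairs, score, n_a = n, n_b = m)
}
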