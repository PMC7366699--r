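# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration for the aligner,
# direct formula evaluation for the metrics.

# Enumerate every global alignment of sequences of lengths n x m as move
# strings (M = match column, U = consume a, L = consume b) and return the
# maximal score. Affine gaps: a maximal run of U (or L) of length k costs
# open + (k - 1) * ext; adjacent U and L runs are separate gaps.
brute_force_align_score <- function(sa, sb, subst, open, ext) {
  n <- length(sa); m <- length(sb)
  best <- -Inf
  recurse <- function(i, j, moves) {
    if (i == n && j == m) {
      best <<- max(best, score_moves(moves, sa, sb, subst, open, ext))
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1, j + 1, c(moves, "M"))
    if (i < n) recurse(i + 1, j, c(moves, "U"))
    if (j < m) recurse(i, j + 1, c(moves, "L"))
  }
  score_moves <- function(moves, sa, sb, subst, open, ext) {
    i <- 0; j <- 0; s <- 0; prev <- ""
    for (mv in moves) {
      if (mv == "M") {
        i <- i + 1; j <- j + 1
        s <- s + subst[sa[i], sb[j]]
      } else {
        if (mv == "U") i <- i + 1 else j <- j + 1
        s <- s - if (prev == mv) ext else open
      }
      prev <- mv
    }
    s
  }
  recurse(0, 0, character())
  best
}

# direct evaluation of the printed metric formulas (zero denominators -> 0)
naive_metrics <- function(tp, fp, tn, fn) {
  safe <- function(num, den) if (den == 0) 0 else num / den
  sn <- safe(tp, tp + fn)
  sp <- safe(tn, tn + fp)
  pre <- safe(tp, tp + fp)
  acc <- (tp + tn) / (tp + fp + tn + fn)
  mcc <- safe(tp * tn - fp * fn,
              sqrt((tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)))
  strength <- (sn + sp) / 2
  f <- safe(2 * pre * sn, pre + sn)
  c(sn = sn, sp = sp, pre = pre, acc = acc, mcc = mcc,
    strength = strength, f = f)
}

# gap-free identity alignment over n positions
identity_alignment <- function(n, score = NA_real_) {
  pairwise_alignment(cbind(seq_len(n), seq_len(n)), score, n_a = n, n_b = n)
}

# uniformly random proper rotation matrix
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# scorer with an all-zero structure matrix: alignment score is purely the
# nucleotide term times the bonus
zero_structure_scorer <- function(bonus) {
  chars <- bear_alphabet()$char
  build_scorer(substitution_matrix(chars, matrix(0, length(chars), length(chars))),
               bonus = bonus)
}

# all-unpaired secondary structure for a plain sequence
unpaired_ss <- function(seq) {
  encode_bear(parse_dot_bracket(strrep(".", nchar(seq)), seq))
}

# one-row hit (list form) from explicit alignments and scores
manual_hit <- function(protein_alignment, rna_alignment, tm = 1, ssi = 1,
                       weight = 0.8, template_id = "manual") {
  list(template_id = template_id, tm_score = tm, ssi = ssi,
       score3d2d = score_3d2d(tm, ssi, weight),
       protein_alignment = protein_alignment, rna_alignment = rna_alignment)
}

# random non-crossing dot-bracket string of length n
random_dotbracket <- function(n) {
  if (n <= 0) return("")
  if (n == 1 || runif(1) < 0.5) {
    return(paste0(".", random_dotbracket(n - 1)))
  }
  k <- sample(0:(n - 2), 1)
  paste0("(", random_dotbracket(k), ")", random_dotbracket(n - 2 - k))
}

# the package's match/mismatch fallback scorer at the default bonus
default_scorer_for_tests <- function(bonus = 0.2) {
  prime3d2d:::default_structure_scorer(bonus)
}
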