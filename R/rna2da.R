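# RNA2dA: global alignment of RNAs over combined sequence + secondary
# structure scores, and the alignment statistics SPS and SSI.

#' Gap penalty parameters
#'
#' A gap of length L costs `open + (L - 1) * extend`; terminal gaps are
#' penalized like internal ones. Defaults are the aligner's published
#' constants (open 10, extend 2).
#'
#' @param open Gap opening penalty (> 0, default 10).
#' @param extend Gap extension penalty (> 0, at most `open`, default 2).
#' @return List of class `gap_params`.
#' @export
gap_params <- function(open = 10, extend = 2) {
  stopifnot(open > 0, extend > 0, extend <= open)
  structure(list(open = open, extend = extend), class = "gap_params")
}

#' Global RNA alignment over sequence and secondary structure
#'
#' Needleman-Wunsch/Gotoh global alignment with affine gaps, scoring each
#' position pair with the combined scorer
#' (structure matrix on the structural-alphabet characters plus
#' `bonus` times the nucleotide matrix). Traceback ties are resolved
#' deterministically (diagonal > up > left).
#'
#' @param a,b [secondary_structure()] objects; encoded with
#'   [encode_bear()] on the fly when their `bear` field is empty.
#' @param scorer A [build_scorer()] combined scorer.
#' @param gaps A [gap_params()].
#' @param alphabet Structural alphabet used when encoding is needed.
#' @return A [pairwise_alignment()] with attributes `bear_a`, `bear_b`.
#' @export
global_align <- function(a, b, scorer, gaps = gap_params(),
                         alphabet = bear_alphabet()) {
  stopifnot(inherits(a, "secondary_structure"),
            inherits(b, "secondary_structure"),
            inherits(scorer, "combined_scorer"))
  if (nchar(a$sequence) == 0 || nchar(b$sequence) == 0) {
    abort("cannot align an empty structure")
  }
  if (is.null(a$bear)) a <- encode_bear(a, alphabet)
  if (is.null(b$bear)) b <- encode_bear(b, alphabet)
  S <- scorer_matrix(scorer, a, b)
  aln <- gotoh_align(S, gaps$open, gaps$extend)
  attr(aln, "bear_a") <- a$bear
  attr(aln, "bear_b") <- b$bear
  aln
}

#' Sum-of-pairs score of a test alignment against a reference
#'
#' Fraction of the reference's aligned (i, j) nucleotide pairs that the
#' test alignment reproduces. A reference with no aligned pairs scores 0.
#'
#' @param test,reference [pairwise_alignment()]s over the same two
#'   sequences.
#' @return Fraction in `[0, 1]`.
#' @export
compute_sps <- function(test, reference) {
  same_len <- function(x, y) is.na(x) || is.na(y) || x == y
  if (!same_len(test$n_a, reference$n_a) || !same_len(test$n_b, reference$n_b)) {
    abort("test and reference align different sequences")
  }
  ref <- aligned_pairs(reference)
  if (nrow(ref) == 0) return(0)
  tst <- aligned_pairs(test)
  key <- function(p) paste(p[, 1], p[, 2])
  sum(key(ref) %in% key(tst)) / nrow(ref)
}

#' Secondary structure identity of an alignment
#'
#' Fraction of alignment columns in which both sides are aligned (no gap)
#' and carry the same structural-alphabet character. By default the
#' denominator is the full alignment length (gap columns count against
#' identity); `denominator = "shorter"` divides by the shorter sequence
#' length instead.
#'
#' @param alignment A [pairwise_alignment()] (e.g. from [global_align()]).
#' @param bear_a,bear_b Structural-alphabet strings of the two RNAs;
#'   taken from the alignment's attributes when omitted.
#' @param denominator `"alignment"` (default) or `"shorter"`.
#' @return Identity fraction in `[0, 1]`.
#' @export
compute_ssi <- function(alignment, bear_a = NULL, bear_b = NULL,
                        denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  bear_a <- bear_a %||% attr(alignment, "bear_a")
  bear_b <- bear_b %||% attr(alignment, "bear_b")
  if (is.null(bear_a) || is.null(bear_b)) {
    abort("structural-alphabet strings are required")
  }
  ca <- strsplit(bear_a, "")[[1]]
  cb <- strsplit(bear_b, "")[[1]]
  p <- alignment$pairs
  if (any(p[, 1] > length(ca), na.rm = TRUE) ||
      any(p[, 2] > length(cb), na.rm = TRUE)) {
    abort("alignment indices exceed the structural strings")
  }
  both <- !is.na(p[, 1]) & !is.na(p[, 2])
  n_match <- sum(ca[p[both, 1]] == cb[p[both, 2]])
  denom <- switch(denominator,
                  alignment = alignment$length,
                  shorter = min(length(ca), length(cb)))
  if (denom == 0) return(0)
  n_match / denom
}

#' Render an alignment of two structures as text
#'
#' Three-line gapped view (sequence a, match line, sequence b), useful for
#' reports and the command-line tool.
#'
#' @param alignment A [pairwise_alignment()].
#' @param a,b The aligned [secondary_structure()] objects.
#' @return Character vector of three lines.
#' @export
format_alignment <- function(alignment, a, b) {
  ca <- strsplit(a$sequence, "")[[1]]
  cb <- strsplit(b$sequence, "")[[1]]
  p <- alignment$pairs
  row_a <- ifelse(is.na(p[, 1]), "-", ca[p[, 1]])
  row_b <- ifelse(is.na(p[, 2]), "-", cb[p[, 2]])
  mid <- ifelse(!is.na(p[, 1]) & !is.na(p[, 2]),
                ifelse(row_a == row_b, "|", "."), " ")
  c(paste(row_a, collapse = ""), paste(mid, collapse = ""),
    paste(row_b, collapse = ""))
}

# ---- built-in protein aligner ---------------------------------------------

# Sequence-guided protein alignment: global alignment of one-letter
# sequences (match 2 / mismatch -1, affine gaps), scored structurally by
# tm_score(). Hermetic fallback when TM-align is absent; parity with the
# TM-align binary is not claimed.
align_protein_builtin <- function(moving, fixed, l_target = NULL) {
  sa <- strsplit(chain_sequence(moving), "")[[1]]
  sb <- strsplit(chain_sequence(fixed), "")[[1]]
  S <- matrix(-1, length(sa), length(sb))
  S[outer(sa, sb, "==")] <- 2
  aln <- gotoh_align(S, gap_open = 11, gap_extend = 1)
  tm <- tm_score(aln, moving, fixed, l_target = l_target)
  list(alignment = aln, tm_score = as.numeric(tm),
       transform = attr(tm, "transform"))
}
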