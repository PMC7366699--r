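# BLOSUM-style substitution matrix over the RNA structural alphabet,
# trained from gapless blocks of seed alignments, plus the combined
# structure + nucleotide scorer used by the aligner.

#' Read a Stockholm alignment
#'
#' Minimal Stockholm 1.0 reader sufficient for Rfam-style seed alignments:
#' aligned sequence lines plus the `#=GC SS_cons` consensus structure
#' annotation. Wrapped (multi-paragraph) alignments are concatenated.
#'
#' @param path Path to a Stockholm file.
#' @return List with `sequences` (named character vector of aligned rows),
#'   `ss_cons` (consensus structure string) and `id` (from `#=GF AC`/`ID`
#'   if present, else the file name).
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  seqs <- list()
  ss <- character()
  id <- NULL
  for (ln in lines) {
    if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
      ss <- c(ss, sub("^#=GC\\s+SS_cons\\s+", "", ln))
    } else if (grepl("^#=GF\\s+(AC|ID)\\s", ln) && is.null(id)) {
      id <- strsplit(trimws(ln), "\\s+")[[1]][3]
    } else if (!grepl("^#", ln) && !grepl("^//", ln) && nzchar(trimws(ln))) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) == 2) seqs[[f[1]]] <- c(seqs[[f[1]]], f[2])
    }
  }
  if (length(ss) == 0) abort("Stockholm file has no #=GC SS_cons line")
  sequences <- vapply(seqs, paste, "", collapse = "")
  ss_cons <- paste(ss, collapse = "")
  if (any(nchar(sequences) != nchar(ss_cons))) {
    abort("sequence rows and SS_cons have unequal lengths")
  }
  list(sequences = sequences, ss_cons = ss_cons,
       id = id %||% basename(path))
}

# WUSS consensus structure -> pair matrix (1-based); bracket layers
# <>, (), [], {} are paired, everything else unpaired; crossings between
# layers resolved greedily.
wuss_pairs <- function(ss_cons) {
  canonical <- chartr("<>", "()", ss_cons)
  chars <- strsplit(canonical, "")[[1]]
  chars[!chars %in% c("(", ")", "[", "]", "{", "}")] <- "."
  pairs <- dot_bracket_pairs(paste(chars, collapse = ""))
  resolve_pseudoknots(pairs)$pairs
}

#' Extract gapless training blocks from a seed alignment
#'
#' Maximal runs of columns in which no row has a gap, of length at least
#' `min_len` (default 6: alignment fragments longer than five columns),
#' become blocks. The consensus structure is restricted to the block
#' (pairs with both ends inside it) and re-encoded in the structural
#' alphabet; each row of the block carries the encoding of that restricted
#' consensus. With `pair_filter = "canonical"` a consensus pair is kept
#' for a row only when that row's nucleotides can form a Watson-Crick or
#' wobble pair (AU/GC/GU), giving per-row encodings.
#'
#' @param alignment Result of [read_stockholm()] (or a compatible list).
#' @param min_len Minimum block width (default 6).
#' @param pair_filter `"none"` (consensus pairs applied to every row) or
#'   `"canonical"` (row-specific pair filtering).
#' @param alphabet A [bear_alphabet()].
#' @return List of blocks: each a list with `rows` (structural-alphabet
#'   strings, one per sequence), `sequences` (nucleotide strings),
#'   `source_id`, `columns`.
#' @export
extract_blocks <- function(alignment, min_len = 6,
                           pair_filter = c("none", "canonical"),
                           alphabet = bear_alphabet()) {
  pair_filter <- match.arg(pair_filter)
  seqs <- alignment$sequences
  if (is.null(alignment$ss_cons)) abort("alignment lacks a consensus structure")
  n <- nchar(alignment$ss_cons)
  gap_chars <- c("-", ".", "_", "~")
  seq_mat <- do.call(rbind, strsplit(toupper(chartr("T", "U", seqs)), ""))
  is_gap <- matrix(seq_mat %in% gap_chars, nrow = nrow(seq_mat))
  clean <- !apply(is_gap, 2, any)
  pairs <- wuss_pairs(alignment$ss_cons)
  runs <- rle(clean)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  blocks <- list()
  for (r in seq_along(runs$values)) {
    if (!runs$values[r] || runs$lengths[r] < min_len) next
    cols <- starts[r]:ends[r]
    keep <- nrow(pairs) > 0 & pairs[, 1] %in% cols & pairs[, 2] %in% cols
    local <- pairs[keep, , drop = FALSE]
    local[] <- match(local, cols)  # reindex to block coordinates
    row_seqs <- apply(seq_mat[, cols, drop = FALSE], 1, paste, collapse = "")
    rows <- vapply(row_seqs, function(sq) {
      p <- local
      if (pair_filter == "canonical" && nrow(p) > 0) {
        nt <- strsplit(sq, "")[[1]]
        ok <- paste0(nt[p[, 1]], nt[p[, 2]]) %in%
          c("AU", "UA", "GC", "CG", "GU", "UG")
        p <- p[ok, , drop = FALSE]
      }
      ss <- secondary_structure(gsub("[^ACGUN]", "N", sq), p)
      encode_bear(ss, alphabet)$bear
    }, "")
    blocks[[length(blocks) + 1L]] <- list(
      rows = unname(rows), sequences = unname(row_seqs),
      source_id = alignment$id %||% "block", columns = length(cols)
    )
  }
  blocks
}

#' Cluster block rows by structural-alphabet identity
#'
#' Single-linkage clustering: rows whose pairwise identity (fraction of
#' equal characters x 100) reaches `identity` are linked, and clusters are
#' the connected components. Row weight is 1 / cluster size, so a family
#' of near-identical rows counts as one. `identity = 100` disables
#' redundancy removal entirely (every row is its own cluster), matching
#' the "BLOSUM100" reading of the clustering percentage.
#'
#' @param rows Character vector of equal-length structural-alphabet strings.
#' @param identity Clustering identity percentage in (0, 100].
#' @return List with `cluster` (integer assignment) and `weight`
#'   (numeric, 1 / cluster size).
#' @export
cluster_rows <- function(rows, identity = 80) {
  stopifnot(identity > 0, identity <= 100)
  n <- length(rows)
  cluster <- seq_len(n)
  if (identity < 100 && n > 1) {
    mat <- do.call(rbind, strsplit(rows, ""))
    # union-find over pairs meeting the identity threshold
    find <- function(k) { while (cluster[k] != k) k <- cluster[k]; k }
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        id_ab <- 100 * mean(mat[a, ] == mat[b, ])
        if (id_ab >= identity) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) cluster[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
    cluster <- vapply(seq_len(n), find, 1L)
    cluster <- match(cluster, unique(cluster))
  }
  size <- table(cluster)
  list(cluster = cluster, weight = 1 / as.numeric(size[as.character(cluster)]))
}

#' Substitution matrix container
#'
#' @param alphabet Ordered character vector.
#' @param scores Symmetric numeric matrix (rows/cols in alphabet order).
#' @param clustering_identity Identity percentage used at training
#'   (`NA` for fixed matrices such as the nucleotide matrix).
#' @return Object of class `substitution_matrix`.
#' @export
substitution_matrix <- function(alphabet, scores, clustering_identity = NA_real_) {
  scores <- as.matrix(scores)
  dimnames(scores) <- list(alphabet, alphabet)
  if (!isTRUE(all.equal(scores, t(scores)))) abort("scores must be symmetric")
  structure(list(alphabet = alphabet, scores = scores,
                 clustering_identity = clustering_identity),
            class = "substitution_matrix")
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("<substitution_matrix> ", length(x$alphabet), " characters",
      if (!is.na(x$clustering_identity))
        paste0(", clustering identity ", x$clustering_identity), "\n", sep = "")
  print(x$scores)
  invisible(x)
}

#' Train a log-odds substitution matrix from blocks
#'
#' Henikoff-style construction on the structural alphabet. Within each
#' block, rows are clustered at `identity` percent ([cluster_rows()]) and
#' every column contributes weighted character pairs between rows of
#' distinct clusters (weight = product of row weights). From the pooled
#' counts: observed pair frequency `q_ab`, background `p_a = q_aa +
#' sum(q_ab)/2`, expected `e_aa = p_a^2`, `e_ab = 2 p_a p_b`, and score
#' `s_ab = round(2 log2(q_ab / e_ab))` in half-bit units (round half away
#' from zero). Pairs of observed characters never seen together are scored
#' with a single pseudo-pair (count 1 against the augmented total), so no
#' score is infinite; characters absent from the data score 0 against
#' everything and are flagged in attribute `unobserved`.
#'
#' @param blocks List of blocks from [extract_blocks()] (only `rows` is
#'   required).
#' @param identity Clustering identity percentage (default 80, the matrix
#'   used by the default scorer).
#' @param alphabet Optional character vector fixing the matrix alphabet;
#'   defaults to the characters observed in `blocks`.
#' @return A [substitution_matrix()] with attributes `frequencies`
#'   (list `q`, `p`, `n_pairs`) and `unobserved`.
#' @export
compute_rnablosum <- function(blocks, identity = 80, alphabet = NULL) {
  if (length(blocks) == 0) abort("at least one block is required")
  rows_list <- lapply(blocks, function(b) if (is.list(b)) b$rows else b)
  chars_seen <- sort(unique(unlist(strsplit(unlist(rows_list), ""))))
  alphabet <- alphabet %||% chars_seen
  K <- length(alphabet)
  counts <- matrix(0, K, K, dimnames = list(alphabet, alphabet))
  for (rows in rows_list) {
    if (length(rows) < 2) next
    cl <- cluster_rows(rows, identity)
    mat <- do.call(rbind, strsplit(rows, ""))
    nr <- nrow(mat)
    for (a in seq_len(nr - 1)) {
      for (b in (a + 1):nr) {
        if (cl$cluster[a] == cl$cluster[b]) next
        w <- cl$weight[a] * cl$weight[b]
        for (col in seq_len(ncol(mat))) {
          x <- mat[a, col]; y <- mat[b, col]
          counts[x, y] <- counts[x, y] + w / 2
          counts[y, x] <- counts[y, x] + w / 2
        }
      }
    }
  }
  # unordered pair counts: c_aa = counts[a,a], c_ab = counts[a,b]+counts[b,a]
  total <- sum(counts)
  if (total <= 0) abort("no between-cluster pairs observed; lower the clustering identity")
  q <- (counts + t(counts)) / 2 / total   # q[a,b] + q[b,a] = freq of unordered pair
  p <- rowSums(q)
  scores <- matrix(0, K, K, dimnames = list(alphabet, alphabet))
  q_pseudo <- 1 / (total + 1)
  for (a in seq_len(K)) {
    for (b in a:K) {
      if (p[a] == 0 || p[b] == 0) next
      q_ab <- if (a == b) q[a, a] else 2 * q[a, b]
      e_ab <- if (a == b) p[a]^2 else 2 * p[a] * p[b]
      if (q_ab == 0) q_ab <- q_pseudo
      s <- round_half_away(2 * log2(q_ab / e_ab))
      scores[a, b] <- scores[b, a] <- s
    }
  }
  out <- substitution_matrix(alphabet, scores, clustering_identity = identity)
  attr(out, "frequencies") <- list(q = q, p = p, n_pairs = total)
  attr(out, "unobserved") <- alphabet[p == 0]
  out
}

#' Nucleotide substitution matrix (match 5, mismatch -4)
#'
#' The 4x4 A/C/G/U submatrix of the standard NUC.4.4 DNA scoring matrix:
#' matched nucleotides score 5, mismatched nucleotides -4. Ambiguity codes
#' are not part of the alphabet and are rejected by the scorer.
#'
#' @return A [substitution_matrix()] over A, C, G, U.
#' @export
nuc44 <- function() {
  nts <- c("A", "C", "G", "U")
  m <- matrix(-4, 4, 4, dimnames = list(nts, nts))
  diag(m) <- 5
  substitution_matrix(nts, m)
}

#' Combined structure + nucleotide scorer
#'
#' Per-position score used by the aligner:
#' `score(i, j) = structure_matrix[bear_i, bear_j] +
#'  nucleotide_matrix[nt_i, nt_j] * bonus`.
#' With `bonus = 0` only the secondary structure drives the alignment;
#' the default `bonus = 0.2` mixes in sequence identity.
#'
#' @param structure_matrix A [substitution_matrix()] over the structural
#'   alphabet.
#' @param bonus Non-negative weight on the nucleotide term (default 0.2).
#' @param nucleotide_matrix A [substitution_matrix()] over A/C/G/U
#'   (default [nuc44()]).
#' @return Object of class `combined_scorer`.
#' @export
build_scorer <- function(structure_matrix, bonus = 0.2,
                         nucleotide_matrix = nuc44()) {
  stopifnot(bonus >= 0)
  structure(list(structure_matrix = structure_matrix,
                 nucleotide_matrix = nucleotide_matrix,
                 bonus = bonus),
            class = "combined_scorer")
}

#' @export
print.combined_scorer <- function(x, ...) {
  cat("<combined_scorer> bonus ", x$bonus, ", structure alphabet of ",
      length(x$structure_matrix$alphabet), " characters\n", sep = "")
  invisible(x)
}

# n_a x n_b matrix of combined scores for two encoded structures
scorer_matrix <- function(scorer, ss_a, ss_b) {
  nt_a <- strsplit(ss_a$sequence, "")[[1]]
  nt_b <- strsplit(ss_b$sequence, "")[[1]]
  bad <- setdiff(c(nt_a, nt_b), scorer$nucleotide_matrix$alphabet)
  if (length(bad) > 0) {
    abort(paste0("nucleotide(s) outside the scorer alphabet: ",
                 paste(bad, collapse = ", ")))
  }
  be_a <- strsplit(ss_a$bear, "")[[1]]
  be_b <- strsplit(ss_b$bear, "")[[1]]
  sm <- scorer$structure_matrix$scores
  miss <- setdiff(c(be_a, be_b), rownames(sm))
  if (length(miss) > 0) {
    abort(paste0("structural character(s) missing from the matrix: ",
                 paste(miss, collapse = ", ")))
  }
  sm[be_a, be_b, drop = FALSE] +
    scorer$nucleotide_matrix$scores[nt_a, nt_b, drop = FALSE] * scorer$bonus
}

#' Write / read a substitution matrix in NCBI matrix text format
#'
#' `#`-prefixed comment header (records the alphabet order and, for
#' trained matrices, the clustering identity), a header row of the
#' alphabet, then one labelled row per character.
#'
#' @param matrix A [substitution_matrix()].
#' @param path File path.
#' @return `path` (write) or a [substitution_matrix()] (read).
#' @export
write_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# Substitution matrix (half-bit log-odds unless stated otherwise)",
    paste0("# alphabet: ", paste(matrix$alphabet, collapse = " ")),
    if (!is.na(matrix$clustering_identity))
      paste0("# clustering_identity: ", matrix$clustering_identity)
  ), con)
  writeLines(paste(c(" ", matrix$alphabet), collapse = " "), con)
  for (a in matrix$alphabet) {
    writeLines(paste(c(a, format(matrix$scores[a, ], trim = TRUE)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  ident <- NA_real_
  id_line <- grep("^# clustering_identity:", lines, value = TRUE)
  if (length(id_line) > 0) {
    ident <- as.numeric(sub("^# clustering_identity:\\s*", "", id_line[1]))
  }
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  alphabet <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  scores <- do.call(rbind, lapply(rows, function(f) as.numeric(f[-1])))
  substitution_matrix(alphabet, scores, clustering_identity = ident)
}
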