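# RNA secondary structure: parsing, pseudoknot resolution, structural
# alphabet (BEAR-style) encoding.
#
# Indexing is 1-based throughout (R convention); file formats that are
# 1-based on disk (CT) map directly.

#' Construct an RNA secondary structure object
#'
#' Bundles an RNA sequence with its base-pair set, dot-bracket string and
#' (optionally) its structural-alphabet encoding. Most users will call
#' [parse_dot_bracket()] or [ct_to_dot_bracket()] instead of this
#' constructor.
#'
#' @param sequence Nucleotide string (A/C/G/U, upper case).
#' @param pairs Integer matrix with two columns (i, j), 1-based, i < j,
#'   each index in at most one pair, non-crossing.
#' @param bear Optional structural-alphabet string (same length as
#'   `sequence`); computed lazily by [encode_bear()] when `NULL`.
#' @return An object of class `secondary_structure` with fields
#'   `sequence`, `pairs`, `dot_bracket`, `bear`.
#' @seealso [parse_dot_bracket()], [encode_bear()]
#' @export
secondary_structure <- function(sequence, pairs, bear = NULL) {
  sequence <- toupper(gsub("T", "U", sequence))
  n <- nchar(sequence)
  if (!grepl("^[ACGUN]*$", sequence)) {
    abort("sequence may contain only A/C/G/U/N characters")
  }
  pairs <- normalize_pairs(pairs)
  if (nrow(pairs) > 0) {
    idx <- as.vector(pairs)
    if (any(idx < 1L) || any(idx > n)) abort("pair index out of range")
    if (anyDuplicated(idx)) abort("an index appears in more than one pair")
    if (has_crossing(pairs)) abort("pairs are crossing (pseudoknot); resolve first")
  }
  ss <- structure(
    list(
      sequence = sequence,
      pairs = pairs,
      dot_bracket = render_dot_bracket(pairs, n),
      bear = bear
    ),
    class = "secondary_structure"
  )
  if (!is.null(bear) && nchar(bear) != n) {
    abort("bear string length must equal sequence length")
  }
  ss
}

normalize_pairs <- function(pairs) {
  if (is.null(pairs) || length(pairs) == 0) {
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  pairs <- t(apply(pairs, 1, sort))
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

# crossing: i1 < i2 < j1 < j2
has_crossing <- function(pairs) {
  n <- nrow(pairs)
  if (n < 2) return(FALSE)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      i1 <- pairs[a, 1]; j1 <- pairs[a, 2]
      i2 <- pairs[b, 1]; j2 <- pairs[b, 2]
      if (i1 < i2 && i2 < j1 && j1 < j2) return(TRUE)
      if (i2 < i1 && i1 < j2 && j2 < j1) return(TRUE)
    }
  }
  FALSE
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("<secondary_structure> ", nchar(x$sequence), " nt, ",
      nrow(x$pairs), " base pairs\n", sep = "")
  cat(" ", x$sequence, "\n ", x$dot_bracket, "\n", sep = "")
  if (!is.null(x$bear)) cat(" ", x$bear, "\n", sep = "")
  invisible(x)
}

#' @export
length.secondary_structure <- function(x) nchar(x$sequence)

#' Parse dot-bracket (Vienna) notation
#'
#' @param text Dot-bracket string; characters `.` and `()` (the extended
#'   sets `[]`, `{}`, `<>` are accepted and treated as independent bracket
#'   layers, resolved against crossings afterwards).
#' @param sequence Nucleotide string of the same length.
#' @return A [secondary_structure()].
#' @examples
#' parse_dot_bracket("((..))", "GGAACC")
#' @export
parse_dot_bracket <- function(text, sequence) {
  if (nchar(text) != nchar(sequence)) {
    abort(sprintf("structure length (%d) != sequence length (%d)",
                  nchar(text), nchar(sequence)))
  }
  pairs <- dot_bracket_pairs(text)
  if (has_crossing(pairs)) {
    res <- resolve_pseudoknots(pairs)
    pairs <- res$pairs
  }
  secondary_structure(sequence, pairs)
}

# stack-based pair extraction, one stack per bracket layer
dot_bracket_pairs <- function(text) {
  chars <- strsplit(text, "")[[1]]
  openers <- c("(", "[", "{", "<")
  closers <- c(")", "]", "}", ">")
  unpaired <- c(".", ",", "_", "-", ":", "~")
  stacks <- rep(list(integer()), length(openers))
  out <- list()
  for (k in seq_along(chars)) {
    ch <- chars[k]
    io <- match(ch, openers)
    ic <- match(ch, closers)
    if (!is.na(io)) {
      stacks[[io]] <- c(stacks[[io]], k)
    } else if (!is.na(ic)) {
      st <- stacks[[ic]]
      if (length(st) == 0) {
        abort(sprintf("unbalanced bracket '%s' at position %d", ch, k))
      }
      out[[length(out) + 1L]] <- c(st[length(st)], k)
      stacks[[ic]] <- st[-length(st)]
    } else if (!(ch %in% unpaired) && !grepl("[A-Za-z]", ch)) {
      abort(sprintf("unexpected character '%s' at position %d", ch, k))
    }
  }
  for (io in seq_along(stacks)) {
    if (length(stacks[[io]]) > 0) {
      abort(sprintf("unbalanced bracket '%s' at position %d",
                    openers[io], stacks[[io]][1]))
    }
  }
  normalize_pairs(do.call(rbind, out))
}

#' Render a pair set as dot-bracket
#'
#' @param pairs Two-column integer matrix of non-crossing pairs (1-based).
#' @param n Sequence length.
#' @return Dot-bracket string of length `n`.
#' @export
render_dot_bracket <- function(pairs, n) {
  chars <- rep(".", n)
  pairs <- normalize_pairs(pairs)
  if (nrow(pairs) > 0) {
    chars[pairs[, 1]] <- "("
    chars[pairs[, 2]] <- ")"
  }
  paste(chars, collapse = "")
}

#' Remove crossing base pairs (pseudoknot resolution)
#'
#' Dot-bracket with a single bracket layer cannot express crossing pairs.
#' Crossings are removed greedily: while any crossing remains, the pair
#' involved in the largest number of crossings is dropped; ties are broken
#' by dropping the pair with the larger opening index. The greedy rule
#' keeps the pair set large (dropping the most entangled pair first).
#'
#' @param pairs Two-column integer matrix (1-based).
#' @return List with `pairs` (non-crossing survivors) and `removed`
#'   (dropped pairs, possibly empty).
#' @export
resolve_pseudoknots <- function(pairs) {
  pairs <- normalize_pairs(pairs)
  removed <- list()
  repeat {
    n <- nrow(pairs)
    if (n < 2) break
    cross <- integer(n)
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        i1 <- pairs[a, 1]; j1 <- pairs[a, 2]
        i2 <- pairs[b, 1]; j2 <- pairs[b, 2]
        if ((i1 < i2 && i2 < j1 && j1 < j2) ||
            (i2 < i1 && i1 < j2 && j2 < j1)) {
          cross[a] <- cross[a] + 1L
          cross[b] <- cross[b] + 1L
        }
      }
    }
    if (all(cross == 0)) break
    worst <- which(cross == max(cross))
    # tie: drop the pair with the larger opening index
    drop <- worst[which.max(pairs[worst, 1])]
    removed[[length(removed) + 1L]] <- pairs[drop, ]
    pairs <- pairs[-drop, , drop = FALSE]
  }
  list(pairs = pairs, removed = normalize_pairs(do.call(rbind, removed)))
}

#' Convert CT records to a secondary structure
#'
#' @param records Data frame with columns `index` (1-based position),
#'   `base` (nucleotide) and `partner` (1-based paired position, 0 if
#'   unpaired), as read from a CT file.
#' @return A [secondary_structure()]; crossing pairs are resolved by
#'   [resolve_pseudoknots()] and the removed pairs are attached as
#'   attribute `removed_pairs`.
#' @export
ct_to_dot_bracket <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("index", "base", "partner") %in% names(records)))
  records <- records[order(records$index), ]
  if (!identical(as.integer(records$index), seq_len(nrow(records)))) {
    abort("CT indices must be 1..n without gaps")
  }
  partner <- as.integer(records$partner)
  paired <- which(partner > 0L)
  for (k in paired) {
    p <- partner[k]
    if (p > nrow(records) || partner[p] != k) {
      abort(sprintf("inconsistent CT partner fields at position %d", k))
    }
  }
  pairs <- unique(t(apply(cbind(paired, partner[paired]), 1, sort)))
  res <- resolve_pseudoknots(pairs)
  ss <- secondary_structure(paste(records$base, collapse = ""), res$pairs)
  attr(ss, "removed_pairs") <- res$removed
  ss
}

#' Read a CT file
#'
#' Standard CT layout: a header line (length + title) followed by one row
#' per nucleotide with columns index, base, previous, next, partner,
#' natural numbering.
#'
#' @param path Path to the CT file.
#' @return A [secondary_structure()] via [ct_to_dot_bracket()].
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  body <- lines[2:(n + 1)]
  fields <- strsplit(trimws(body), "\\s+")
  records <- data.frame(
    index = as.integer(vapply(fields, `[[`, "", 1L)),
    base = vapply(fields, `[[`, "", 2L),
    partner = as.integer(vapply(fields, `[[`, "", 5L))
  )
  ct_to_dot_bracket(records)
}

#' Read a dot-bracket (Vienna) file
#'
#' Three-line records: `>header`, sequence, structure.
#'
#' @param path Path to the file.
#' @return A named list of [secondary_structure()] objects (one per
#'   record), named by header.
#' @export
read_dbn <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) abort("no '>' header found in dot-bracket file")
  out <- list()
  for (s in starts) {
    if (s + 2 > length(lines)) abort("truncated dot-bracket record")
    name <- sub("^>\\s*", "", lines[s])
    out[[name]] <- parse_dot_bracket(trimws(lines[s + 2]), trimws(lines[s + 1]))
  }
  out
}

#' Write secondary structures to a dot-bracket file
#'
#' @param ss A [secondary_structure()] or named list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dbn <- function(ss, path) {
  if (inherits(ss, "secondary_structure")) ss <- list(rna = ss)
  lines <- unlist(lapply(names(ss), function(nm) {
    c(paste0(">", nm), ss[[nm]]$sequence, ss[[nm]]$dot_bracket)
  }))
  writeLines(lines, path)
  invisible(path)
}

# ---- structural alphabet ---------------------------------------------------

#' Structural alphabet for secondary-structure encoding
#'
#' A per-nucleotide encoding in the BEAR style: each character records the
#' type of the secondary-structure element containing the position (stem,
#' hairpin loop, internal loop or bulge, exterior/unpaired) and the length
#' of that element, capped at `max_length`. The default table ("BEAR-lite")
#' uses four disjoint character ranges: stems `a`-`i`, hairpin loops
#' `j`-`r`, internal loops/bulges `A`-`I`, exterior `J`-`R`, indexed by
#' element length 1..`max_length` (longer elements share the cap class).
#' A user-supplied table (e.g. to reproduce another published encoding)
#' can be loaded with [read_bear_alphabet()].
#'
#' @param max_length Length cap per element type (default 9).
#' @param mapping Optional data frame with columns `type`, `length`,
#'   `char` overriding the default table.
#' @return Object of class `bear_alphabet`: a tibble (`type`, `length`,
#'   `char`) with attribute `max_length`.
#' @export
bear_alphabet <- function(max_length = 9, mapping = NULL) {
  types <- c("stem", "hairpin_loop", "internal_or_bulge", "exterior")
  if (is.null(mapping)) {
    if (max_length > 9) abort("default table supports max_length <= 9")
    chars <- list(
      stem = letters[1:9],
      hairpin_loop = letters[10:18],
      internal_or_bulge = LETTERS[1:9],
      exterior = LETTERS[10:18]
    )
    mapping <- dplyr::bind_rows(lapply(types, function(tp) {
      tibble::tibble(type = tp, length = seq_len(max_length),
                     char = chars[[tp]][seq_len(max_length)])
    }))
  } else {
    mapping <- tibble::as_tibble(mapping)
    stopifnot(all(c("type", "length", "char") %in% names(mapping)))
    max_length <- max(mapping$length)
  }
  if (anyDuplicated(mapping$char)) abort("alphabet mapping must be injective")
  need <- expand.grid(type = types, length = seq_len(max_length),
                      stringsAsFactors = FALSE)
  key <- paste(mapping$type, pmin(mapping$length, max_length))
  if (!all(paste(need$type, need$length) %in% key)) {
    abort("mapping must cover every (type, length <= cap) combination")
  }
  structure(mapping, class = c("bear_alphabet", class(mapping)),
            max_length = max_length)
}

#' Read a structural-alphabet table from a TSV file
#'
#' Columns: `type` (stem / hairpin_loop / internal_or_bulge / exterior),
#' `length`, `char`.
#'
#' @param path TSV path.
#' @return A [bear_alphabet()].
#' @export
read_bear_alphabet <- function(path) {
  bear_alphabet(mapping = read.table(path, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE))
}

#' Decompose a secondary structure into elements
#'
#' Every position is assigned to exactly one element: stems are maximal
#' helices of stacked pairs (length = number of pairs); unpaired runs are
#' hairpin loops when closed by a single pair, internal loops/bulges (and
#' multiloop segments) when enclosed by some pair, and exterior otherwise
#' (length = run length).
#'
#' @param ss A [secondary_structure()].
#' @return Tibble with columns `position`, `type`, `length`.
#' @export
decompose_elements <- function(ss) {
  n <- nchar(ss$sequence)
  pairs <- ss$pairs
  type <- character(n)
  elen <- integer(n)
  partner <- integer(n)
  if (nrow(pairs) > 0) {
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
  }
  # helices: stack pairs (i, j) and (i + 1, j - 1)
  if (nrow(pairs) > 0) {
    helix_id <- integer(nrow(pairs))
    current <- 0L
    for (k in seq_len(nrow(pairs))) {
      if (k > 1 &&
          pairs[k, 1] == pairs[k - 1, 1] + 1L &&
          pairs[k, 2] == pairs[k - 1, 2] - 1L) {
        helix_id[k] <- current
      } else {
        current <- current + 1L
        helix_id[k] <- current
      }
    }
    for (h in unique(helix_id)) {
      members <- pairs[helix_id == h, , drop = FALSE]
      pos <- as.vector(members)
      type[pos] <- "stem"
      elen[pos] <- nrow(members)
    }
  }
  # unpaired runs
  up <- which(partner == 0L)
  if (length(up) > 0) {
    run_id <- cumsum(c(1L, diff(up) != 1L))
    for (r in unique(run_id)) {
      pos <- up[run_id == r]
      l <- min(pos); rgt <- max(pos)
      if (l > 1 && rgt < n && partner[l - 1] == rgt + 1) {
        tp <- "hairpin_loop"
      } else if (is_enclosed(l, rgt, pairs)) {
        tp <- "internal_or_bulge"
      } else {
        tp <- "exterior"
      }
      type[pos] <- tp
      elen[pos] <- length(pos)
    }
  }
  tibble::tibble(position = seq_len(n), type = type, length = elen)
}

is_enclosed <- function(l, r, pairs) {
  nrow(pairs) > 0 && any(pairs[, 1] < l & pairs[, 2] > r)
}

#' Encode a secondary structure in the structural alphabet
#'
#' One character per nucleotide, determined only by the type and (capped)
#' length of the element containing the position.
#'
#' @param ss A [secondary_structure()].
#' @param alphabet A [bear_alphabet()] (default table when omitted).
#' @return The input structure with its `bear` field set.
#' @export
encode_bear <- function(ss, alphabet = bear_alphabet()) {
  cap <- attr(alphabet, "max_length")
  el <- decompose_elements(ss)
  key <- paste(el$type, pmin(el$length, cap))
  lut <- setNames(alphabet$char, paste(alphabet$type, alphabet$length))
  chars <- lut[key]
  if (anyNA(chars)) abort("alphabet does not cover an element class")
  ss$bear <- paste(chars, collapse = "")
  ss
}

#' Write structural-alphabet encodings as FASTA-like records
#'
#' @param ss Named list of encoded [secondary_structure()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bear_fasta <- function(ss, path) {
  if (inherits(ss, "secondary_structure")) ss <- list(rna = ss)
  lines <- unlist(lapply(names(ss), function(nm) {
    if (is.null(ss[[nm]]$bear)) abort("structure not encoded; call encode_bear()")
    c(paste0(">", nm), ss[[nm]]$bear)
  }))
  writeLines(lines, path)
  invisible(path)
}
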