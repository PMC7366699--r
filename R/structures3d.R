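# 3D structure handling: PDB I/O, interface annotation at a heavy-atom
# distance cutoff, Kabsch superposition, TM-score, interface RMSD and
# ligand RMSD, plus optional wrappers for external aligners.

#' Chain structure container
#'
#' One polymer chain with its heavy atoms and a representative atom per
#' residue (C-alpha for proteins, C3' for RNA) used in alignment and
#' superposition.
#'
#' @param atoms Data frame with columns `resno` (author numbering),
#'   `resname`, `elety` (atom name), `x`, `y`, `z` (Angstrom).
#' @param type `"protein"` or `"rna"`.
#' @param chain_id Chain identifier (single character).
#' @return Object of class `chain_structure` with fields `atoms` (tibble),
#'   `residues` (tibble: `index`, `resno`, `resname`, `has_rep`),
#'   `rep_xyz` (n x 3 matrix, `NA` rows where the representative atom is
#'   missing), `type`, `chain_id`, `rep_atom`.
#' @export
chain_structure <- function(atoms, type = c("protein", "rna"), chain_id = "A") {
  type <- match.arg(type)
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("resno", "resname", "elety", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort("atom coordinates must be finite")
  }
  rep_atom <- if (type == "protein") "CA" else "C3'"
  key <- paste(atoms$resno, atoms$resname)
  ord <- unique(key)
  index <- match(key, ord)
  residues <- tibble::tibble(
    index = seq_along(ord),
    resno = atoms$resno[!duplicated(key)],
    resname = atoms$resname[!duplicated(key)]
  )
  rep_rows <- which(atoms$elety %in% rep_names(rep_atom))
  rep_xyz <- matrix(NA_real_, nrow(residues), 3)
  rep_xyz[index[rep_rows], ] <- as.matrix(atoms[rep_rows, c("x", "y", "z")])
  residues$has_rep <- !is.na(rep_xyz[, 1])
  structure(list(atoms = atoms, residues = residues, rep_xyz = rep_xyz,
                 type = type, chain_id = chain_id, rep_atom = rep_atom,
                 res_index = index),
            class = "chain_structure")
}

rep_names <- function(rep_atom) {
  if (rep_atom == "C3'") c("C3'", "C3*") else rep_atom
}

#' @export
print.chain_structure <- function(x, ...) {
  cat("<chain_structure> ", x$type, " chain ", x$chain_id, ": ",
      nrow(x$residues), " residues, ", nrow(x$atoms), " heavy atoms (",
      sum(x$residues$has_rep), " with ", x$rep_atom, ")\n", sep = "")
  invisible(x)
}

#' @export
length.chain_structure <- function(x) nrow(x$residues)

#' Representative-atom coordinates of a chain
#'
#' @param chain A [chain_structure()].
#' @param indices Residue indices (1-based chain order); default all
#'   residues having the representative atom.
#' @return Numeric matrix (length(indices) x 3).
#' @export
rep_coords <- function(chain, indices = NULL) {
  indices <- indices %||% which(chain$residues$has_rep)
  if (any(!chain$residues$has_rep[indices])) {
    abort("a requested residue lacks its representative atom")
  }
  chain$rep_xyz[indices, , drop = FALSE]
}

#' One-letter sequence of a chain
#'
#' Proteins use the standard three-to-one amino-acid mapping (unknown
#' residues become `X`); RNA residue names `A`/`C`/`G`/`U` (with or
#' without a leading `R`, e.g. `RA`) map to the nucleotide letter.
#'
#' @param chain A [chain_structure()].
#' @return Single-letter sequence string.
#' @export
chain_sequence <- function(chain) {
  rn <- chain$residues$resname
  if (chain$type == "protein") {
    paste(bio3d::aa321(rn), collapse = "")
  } else {
    one <- toupper(sub("^R", "", rn))
    one[!one %in% c("A", "C", "G", "U")] <- "N"
    paste(one, collapse = "")
  }
}

#' Protein-RNA complex container
#'
#' @param protein,rna [chain_structure()] objects.
#' @param id Complex identifier.
#' @return Object of class `complex_structure`; interface sets are empty
#'   until [annotate_interface()] is called.
#' @export
complex_structure <- function(protein, rna, id = "complex") {
  stopifnot(inherits(protein, "chain_structure"),
            inherits(rna, "chain_structure"),
            protein$type == "protein", rna$type == "rna")
  structure(list(id = id, protein = protein, rna = rna,
                 interface_protein = integer(), interface_rna = integer(),
                 interface_cutoff = NA_real_),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("<complex_structure> ", x$id, ": protein ", nrow(x$protein$residues),
      " aa, RNA ", nrow(x$rna$residues), " nt", sep = "")
  if (!is.na(x$interface_cutoff)) {
    cat("; interface (", x$interface_cutoff, " A): ",
        length(x$interface_protein), " residues / ",
        length(x$interface_rna), " nucleotides", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Read a protein-RNA complex from a PDB file
#'
#' Hydrogens and waters are dropped; alternate locations other than
#' blank/'A' are discarded. Residues lacking the representative atom stay
#' in the chain (their heavy atoms still count for interface annotation)
#' but are excluded from alignment and superposition, with a warning.
#'
#' @param path PDB file path.
#' @param protein_chain,rna_chain Chain identifiers.
#' @param id Complex identifier (default: file base name).
#' @return A [complex_structure()].
#' @export
read_structure <- function(path, protein_chain, rna_chain,
                           id = sub("\\.pdb$", "", basename(path))) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), ]
  is_h <- if (!is.null(at$elesy) && !all(is.na(at$elesy))) {
    trimws(at$elesy) %in% c("H", "D")
  } else {
    grepl("^[0-9]*H", trimws(at$elety))
  }
  at <- at[!is_h, ]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ]
  pick <- function(ch, type) {
    sel <- at[at$chain == ch, ]
    if (nrow(sel) == 0) {
      abort(sprintf("chain '%s' not found; available chains: %s",
                    ch, paste(sort(unique(at$chain)), collapse = ", ")))
    }
    chain <- chain_structure(
      tibble::tibble(resno = sel$resno, resname = trimws(sel$resid),
                     elety = trimws(sel$elety),
                     x = sel$x, y = sel$y, z = sel$z),
      type = type, chain_id = ch
    )
    n_missing <- sum(!chain$residues$has_rep)
    if (n_missing > 0) {
      warn(sprintf("chain '%s': %d residue(s) lack the %s atom and are excluded from alignment",
                   ch, n_missing, chain$rep_atom))
    }
    chain
  }
  complex_structure(pick(protein_chain, "protein"), pick(rna_chain, "rna"),
                    id = id)
}

#' Write a complex as a two-chain PDB file
#'
#' @param cx A [complex_structure()].
#' @param path Output path.
#' @param remarks Optional character vector written as `REMARK` records
#'   (e.g. template id and ranking score of a model).
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(cx, path, remarks = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(remarks)) {
    writeLines(sprintf("REMARK %3d %s", 99, remarks), con)
  }
  serial <- 0L
  for (chain in list(cx$protein, cx$rna)) {
    a <- chain$atoms
    for (k in seq_len(nrow(a))) {
      serial <- serial + 1L
      name <- a$elety[k]
      name_fmt <- if (nchar(name) >= 4) substr(name, 1, 4) else
        sprintf(" %-3s", name)
      writeLines(sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                         serial, name_fmt, a$resname[k], chain$chain_id,
                         a$resno[k], a$x[k], a$y[k], a$z[k], 1, 0), con)
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Annotate the protein-RNA interface
#'
#' A residue (nucleotide) is an interface position iff the minimum
#' distance between any of its heavy atoms and any heavy atom of the
#' other chain is at most `cutoff` (default 4.5 Angstrom).
#'
#' @param cx A [complex_structure()].
#' @param cutoff Distance cutoff in Angstrom.
#' @return The complex with `interface_protein`, `interface_rna`
#'   (residue indices in chain order) and `interface_cutoff` filled in.
#' @export
annotate_interface <- function(cx, cutoff = 4.5) {
  pa <- as.matrix(cx$protein$atoms[, c("x", "y", "z")])
  ra <- as.matrix(cx$rna$atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rep(1, nrow(ra))) +
    outer(rep(1, nrow(pa)), rowSums(ra^2)) - 2 * pa %*% t(ra)
  d2[d2 < 0] <- 0
  hit <- d2 <= cutoff^2
  prot_idx <- cx$protein$res_index
  rna_idx <- cx$rna$res_index
  cx$interface_protein <- sort(unique(prot_idx[rowSums(hit) > 0]))
  cx$interface_rna <- sort(unique(rna_idx[colSums(hit) > 0]))
  cx$interface_cutoff <- cutoff
  cx
}

# ---- superposition ---------------------------------------------------------

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping `moving` onto `fixed`
#' via SVD of the cross-covariance matrix, with the determinant
#' correction enforcing a proper rotation. Points are row vectors; the
#' fitted transform is `y = x %*% rotation + translation`.
#'
#' @param moving,fixed Numeric n x 3 matrices, n >= 3.
#' @return Object of class `rigid_transform`: `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` (the minimized value).
#' @export
kabsch <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) abort("point sets must have equal size")
  if (nrow(moving) < 3) abort("at least 3 points are required")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm); Q <- sweep(fixed, 2, cf)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  translation <- cf - as.vector(cm %*% R)
  moved <- moving %*% R + matrix(translation, nrow(moving), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  structure(list(rotation = R, translation = translation, rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rmsd ", format(x$rmsd, digits = 4), " A\n", sep = "")
  invisible(x)
}

#' Apply or invert a rigid transform
#'
#' @param coords Numeric n x 3 matrix of row-vector points.
#' @param tf A `rigid_transform`.
#' @return Transformed coordinates / the inverse transform.
#' @export
apply_transform <- function(coords, tf) {
  coords <- as.matrix(coords)
  coords %*% tf$rotation + matrix(tf$translation, nrow(coords), 3, byrow = TRUE)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(tf) {
  Rinv <- t(tf$rotation)
  structure(list(rotation = Rinv,
                 translation = as.vector(-tf$translation %*% Rinv),
                 rmsd = tf$rmsd),
            class = "rigid_transform")
}

# apply a rigid transform to every atom and representative of a chain
transform_chain <- function(chain, tf) {
  xyz <- apply_transform(as.matrix(chain$atoms[, c("x", "y", "z")]), tf)
  chain$atoms$x <- xyz[, 1]; chain$atoms$y <- xyz[, 2]; chain$atoms$z <- xyz[, 3]
  ok <- !is.na(chain$rep_xyz[, 1])
  chain$rep_xyz[ok, ] <- apply_transform(chain$rep_xyz[ok, , drop = FALSE], tf)
  chain
}

#' TM-score of a residue mapping
#'
#' Length-normalized structural similarity in (0, 1]:
#' `max over superpositions of (1/L_target) * sum 1/(1 + (d_i/d0)^2)`
#' with `d0 = max(0.5, 1.24 (L_target - 15)^(1/3) - 1.8)`. The maximum is
#' searched with the usual iterative fragment heuristic: Kabsch fits
#' seeded on fragments of the alignment (full, half, quarter length, and
#' length 4), each refined by re-fitting on the residue subset within the
#' inclusion distance until the subset is stable.
#'
#' @param mapping A [pairwise_alignment()] whose `i` indices refer to
#'   residues of `moving` and `j` to residues of `fixed` (chain order).
#' @param moving,fixed [chain_structure()] objects.
#' @param l_target Normalization length; defaults to the number of
#'   residues of `fixed` (the target being modelled).
#' @return TM-score (numeric scalar) with attributes `transform` (the
#'   best `rigid_transform`) and `d0`.
#' @export
tm_score <- function(mapping, moving, fixed, l_target = NULL) {
  ap <- aligned_pairs(mapping)
  ok <- moving$residues$has_rep[ap[, 1]] & fixed$residues$has_rep[ap[, 2]]
  ap <- ap[ok, , drop = FALSE]
  if (nrow(ap) < 3) abort("at least 3 aligned residue pairs are required")
  P <- rep_coords(moving, ap[, 1])
  Q <- rep_coords(fixed, ap[, 2])
  l_target <- l_target %||% nrow(fixed$residues)
  d0 <- tm_d0(l_target)
  n <- nrow(P)
  d_cut <- max(d0, 4.5)
  best <- -Inf; best_tf <- NULL
  frag_lens <- unique(pmax(4L, c(n, ceiling(n / 2), ceiling(n / 4))))
  frag_lens <- frag_lens[frag_lens <= n & frag_lens >= 3]
  for (fl in frag_lens) {
    step <- max(1L, floor(fl / 2))
    starts <- unique(c(seq(1L, n - fl + 1L, by = step), n - fl + 1L))
    for (s in starts) {
      subset <- s:(s + fl - 1L)
      for (iter in 1:20) {
        tf <- kabsch(P[subset, , drop = FALSE], Q[subset, , drop = FALSE])
        d <- sqrt(rowSums((apply_transform(P, tf) - Q)^2))
        sc <- sum(1 / (1 + (d / d0)^2)) / l_target
        if (sc > best) { best <- sc; best_tf <- tf }
        new_subset <- which(d < d_cut)
        if (length(new_subset) < 3) {
          new_subset <- order(d)[1:min(4L, n)]
        }
        if (identical(new_subset, subset)) break
        subset <- new_subset
      }
    }
  }
  structure(best, transform = best_tf, d0 = d0)
}

tm_d0 <- function(l_target) {
  x <- l_target - 15
  cbrt <- sign(x) * abs(x)^(1 / 3)
  max(0.5, 1.24 * cbrt - 1.8)
}

# TM-score sum for given distances (closed form of the per-residue term)
tm_score_from_distances <- function(d, d0, l_target) {
  sum(1 / (1 + (d / d0)^2)) / l_target
}

#' Interface RMSD between two complexes
#'
#' Measures how similar two binding modes are: representative atoms of
#' positions that are interface in either complex and aligned in both the
#' protein and RNA maps are superposed (Kabsch, both chains jointly) and
#' the minimized RMSD is returned.
#'
#' @param a,b [complex_structure()] objects with annotated interfaces.
#' @param protein_map,rna_map [pairwise_alignment()]s mapping `a`'s chain
#'   residue indices (`i`) to `b`'s (`j`).
#' @return RMSD in Angstrom, or `NA` (with a warning) when fewer than 3
#'   usable interface positions exist.
#' @export
irmsd <- function(a, b, protein_map, rna_map) {
  gather <- function(map, chain_a, chain_b, int_a, int_b) {
    ap <- aligned_pairs(map)
    keep <- (ap[, 1] %in% int_a | ap[, 2] %in% int_b) &
      chain_a$residues$has_rep[ap[, 1]] & chain_b$residues$has_rep[ap[, 2]]
    ap <- ap[keep, , drop = FALSE]
    list(a = rep_coords(chain_a, ap[, 1]), b = rep_coords(chain_b, ap[, 2]))
  }
  p <- gather(protein_map, a$protein, b$protein,
              a$interface_protein, b$interface_protein)
  r <- gather(rna_map, a$rna, b$rna, a$interface_rna, b$interface_rna)
  A <- rbind(p$a, r$a); B <- rbind(p$b, r$b)
  if (nrow(A) < 3) {
    warn("fewer than 3 usable interface positions; iRMSD undefined")
    return(NA_real_)
  }
  kabsch(B, A)$rmsd
}

#' Ligand RMSD of a model against the native complex
#'
#' The model protein is superposed onto the native protein over C-alpha
#' atoms (1:1 residue correspondence), the transform is applied to the
#' model RNA, and the RMSD over corresponding C3' atoms is returned. A
#' model with ligand RMSD of at most 10 Angstrom is conventionally called
#' acceptable.
#'
#' @param model,native [complex_structure()] objects for the same target
#'   (equal chain lengths, position-wise correspondence).
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(model, native) {
  if (nrow(model$protein$residues) != nrow(native$protein$residues) ||
      nrow(model$rna$residues) != nrow(native$rna$residues)) {
    abort("model and native must have 1:1 residue/nucleotide correspondence")
  }
  ok_p <- model$protein$residues$has_rep & native$protein$residues$has_rep
  ok_r <- model$rna$residues$has_rep & native$rna$residues$has_rep
  tf <- kabsch(rep_coords(model$protein, which(ok_p)),
               rep_coords(native$protein, which(ok_p)))
  moved <- apply_transform(rep_coords(model$rna, which(ok_r)), tf)
  sqrt(mean(rowSums((moved - rep_coords(native$rna, which(ok_r)))^2)))
}

# ---- external aligners -----------------------------------------------------

external_exe <- c(tmalign = "TMalign", locarna = "mlocarna")

#' Probe for an external alignment executable
#'
#' @param kind `"tmalign"` or `"locarna"`.
#' @param executable_path Optional explicit path.
#' @return `TRUE` when the executable is available.
#' @export
has_external <- function(kind = c("tmalign", "locarna"), executable_path = NULL) {
  kind <- match.arg(kind)
  exe <- executable_path %||% Sys.which(external_exe[[kind]])
  nzchar(exe) && file.exists(exe)
}

#' Run an external structure aligner
#'
#' Thin wrapper around the TM-align or (m)LocARNA executables; their text
#' output is parsed into a [pairwise_alignment()]. When the executable is
#' absent ([has_external()] is `FALSE`) callers should fall back to the
#' built-in aligners; this function then raises an error of class
#' `external_unavailable`.
#'
#' @param kind `"tmalign"` or `"locarna"`.
#' @param inputs Character vector of input file paths (two PDB files for
#'   TM-align; a FASTA of the two RNAs for LocARNA).
#' @param executable_path Optional explicit executable path.
#' @return List with `alignment` (a [pairwise_alignment()]), `score`
#'   (TM-score or alignment score) and `provenance` (command + raw output).
#' @export
run_external_aligner <- function(kind = c("tmalign", "locarna"), inputs,
                                 executable_path = NULL) {
  kind <- match.arg(kind)
  exe <- executable_path %||% Sys.which(external_exe[[kind]])
  if (!has_external(kind, exe)) {
    abort(sprintf("external aligner '%s' is not available", kind),
          class = "external_unavailable")
  }
  out <- tryCatch(
    system2(exe, shQuote(inputs), stdout = TRUE, stderr = TRUE),
    warning = function(w) abort(paste0(kind, " failed: ", conditionMessage(w)),
                                class = "external_tool_error")
  )
  status <- attr(out, "status") %||% 0L
  if (status != 0) {
    abort(sprintf("%s exited with status %d:\n%s", kind, status,
                  paste(tail(out, 5), collapse = "\n")),
          class = "external_tool_error")
  }
  parsed <- switch(kind,
                   tmalign = parse_tmalign_output(out),
                   locarna = parse_locarna_output(out))
  parsed$provenance <- list(command = paste(exe, paste(inputs, collapse = " ")),
                            output = out)
  parsed
}

#' Parse TM-align text output
#'
#' Extracts the TM-score normalized by chain 2 and the residue mapping
#' from the three-line alignment block.
#'
#' @param text Character vector of output lines.
#' @return List with `alignment` and `score`.
#' @export
parse_tmalign_output <- function(text) {
  score_lines <- grep("^TM-score=", text, value = TRUE)
  if (length(score_lines) == 0) abort("no TM-score line found",
                                      class = "external_tool_error")
  scores <- as.numeric(sub("^TM-score=\\s*([0-9.]+).*", "\\1", score_lines))
  chain2 <- grepl("Chain_2", score_lines)
  score <- if (any(chain2)) scores[chain2][1] else scores[length(scores)]
  anchor <- grep("denotes", text)
  if (length(anchor) == 0) abort("no alignment block found",
                                 class = "external_tool_error")
  block <- text[(anchor[1] + 1):(anchor[1] + 3)]
  list(alignment = gapped_strings_to_alignment(block[1], block[3], score),
       score = score)
}

#' Parse (m)LocARNA text output
#'
#' Reads the final pairwise alignment (two `name sequence` rows) and the
#' `Score:` line when present.
#'
#' @param text Character vector of output lines.
#' @return List with `alignment` and `score`.
#' @export
parse_locarna_output <- function(text) {
  score_line <- grep("^Score:", text, value = TRUE)
  score <- if (length(score_line) > 0) {
    as.numeric(sub("^Score:\\s*(-?[0-9.]+).*", "\\1", score_line[1]))
  } else NA_real_
  rows <- grep("^\\S+\\s+[A-Za-z.~_-]+\\s*$", text, value = TRUE)
  rows <- rows[!grepl("^(Score|#|alifold)", rows)]
  if (length(rows) < 2) abort("no alignment rows found",
                              class = "external_tool_error")
  per_name <- split(rows, sub("\\s.*$", "", rows))
  if (length(per_name) < 2) abort("expected two aligned sequences",
                                  class = "external_tool_error")
  seqs <- vapply(per_name[1:2], function(r)
    paste(sub("^\\S+\\s+", "", r), collapse = ""), "")
  list(alignment = gapped_strings_to_alignment(seqs[1], seqs[2], score),
       score = score)
}

# two gapped strings -> pairwise_alignment (indices count non-gap chars)
gapped_strings_to_alignment <- function(ga, gb, score = NA_real_) {
  a <- strsplit(ga, "")[[1]]
  b <- strsplit(gb, "")[[1]]
  if (length(a) != length(b)) abort("gapped strings have unequal lengths")
  gap <- c("-", ".", "~", "_")
  ia <- cumsum(!a %in% gap)
  ib <- cumsum(!b %in% gap)
  pairs <- cbind(ifelse(a %in% gap, NA_integer_, ia),
                 ifelse(b %in% gap, NA_integer_, ib))
  keep <- !(is.na(pairs[, 1]) & is.na(pairs[, 2]))
  pairwise_alignment(pairs[keep, , drop = FALSE], score,
                     n_a = max(ia), n_b = max(ib))
}
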