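# Deterministic synthetic fixtures: toy protein-RNA complexes with a
# planted interface, planted template libraries, and toy Stockholm
# alignments. Geometry is schematic by design (helical C-alpha trace,
# straight C3' trace) -- sufficient to exercise every pipeline stage
# hermetically, not physically realistic.

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# helical C-alpha trace with two dummy heavy atoms per residue
helix_protein <- function(n_residues, sequence1 = NULL) {
  i <- seq_len(n_residues)
  ang <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
  cb <- ca + cbind(1.5 * cos(ang), 1.5 * sin(ang), 0)
  o <- ca + matrix(c(0, 0, 0.9), n_residues, 3, byrow = TRUE)
  sequence1 <- sequence1 %||% paste(sample(AA1, n_residues, replace = TRUE),
                                    collapse = "")
  res3 <- bio3d::aa123(strsplit(sequence1, "")[[1]])
  atoms <- tibble::tibble(
    resno = rep(i, each = 3),
    resname = rep(res3, each = 3),
    elety = rep(c("CA", "CB", "O"), n_residues),
    x = as.vector(t(cbind(ca[, 1], cb[, 1], o[, 1]))),
    y = as.vector(t(cbind(ca[, 2], cb[, 2], o[, 2]))),
    z = as.vector(t(cbind(ca[, 3], cb[, 3], o[, 3])))
  )
  chain_structure(atoms, type = "protein", chain_id = "A")
}

# random self-avoiding-ish 3D walk protein (decoy fold)
walk_protein <- function(n_residues, step = 3.8) {
  dirs <- matrix(stats::rnorm(3 * n_residues), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ca <- apply(dirs * step, 2, cumsum)
  atoms <- tibble::tibble(
    resno = rep(seq_len(n_residues), each = 2),
    resname = rep(bio3d::aa123(sample(AA1, n_residues, replace = TRUE)), each = 2),
    elety = rep(c("CA", "CB"), n_residues),
    x = as.vector(rbind(ca[, 1], ca[, 1] + 1.2)),
    y = as.vector(rbind(ca[, 2], ca[, 2])),
    z = as.vector(rbind(ca[, 3], ca[, 3]))
  )
  chain_structure(atoms, type = "protein", chain_id = "A")
}

random_rigid_transform <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  structure(list(rotation = R, translation = stats::rnorm(3, sd = 20),
                 rmsd = NA_real_),
            class = "rigid_transform")
}

# hairpin dot-bracket for n nucleotides with a GC stem
hairpin_secondary <- function(n_nucleotides) {
  stopifnot(n_nucleotides >= 4)
  k <- max(0, (n_nucleotides - 4) %/% 2)
  loop <- n_nucleotides - 2 * k
  db <- paste0(strrep("(", k), strrep(".", loop), strrep(")", k))
  seq <- paste0(strrep("G", k),
                paste(sample(c("A", "C", "G", "U"), loop, replace = TRUE),
                      collapse = ""),
                strrep("C", k))
  parse_dot_bracket(db, seq)
}

#' Generate a toy protein-RNA complex with a planted interface
#'
#' The protein is a helical C-alpha trace with dummy heavy atoms; the RNA
#' C3' trace runs parallel at a distance far outside the interface
#' cutoff, except for the planted nucleotides, which are placed 3.5
#' Angstrom from a protein residue. Annotating the interface at 4.5
#' Angstrom therefore recovers exactly the planted RNA positions. The
#' RNA secondary structure is a consistent hairpin.
#'
#' @param seed RNG seed (same seed, same complex).
#' @param n_residues,n_nucleotides Chain sizes (>= 4).
#' @param planted_interface RNA nucleotide indices to place at the
#'   interface.
#' @param noise_sigma Gaussian coordinate noise in Angstrom applied to
#'   every atom (default 0).
#' @param dir Optional directory: when given, a PDB (`<id>.pdb`) and a
#'   dot-bracket file (`<id>.dbn`) are written, with the seed recorded in
#'   the headers.
#' @param id Complex identifier.
#' @return List with `complex` (interface-annotated
#'   [complex_structure()]), `secondary` (encoded
#'   [secondary_structure()]), `planted_interface`, `seed`, and `files`
#'   (paths, when written).
#' @export
make_toy_complex <- function(seed = 1, n_residues = 30, n_nucleotides = 16,
                             planted_interface = c(3, 8, 12),
                             noise_sigma = 0, dir = NULL, id = "toy") {
  stopifnot(n_residues >= 4, n_nucleotides >= 4,
            all(planted_interface >= 1),
            all(planted_interface <= n_nucleotides))
  with_seed(seed, {
    protein <- helix_protein(n_residues)
    ss <- hairpin_secondary(n_nucleotides)
    i <- seq_len(n_nucleotides)
    c3 <- cbind(20 + 0 * i, 3 * i - 1.5 * n_nucleotides, 1.5 * i)
    # anchor each planted nucleotide 3.5 A from a distinct protein CA
    anchors <- round(seq(2, n_residues - 1, length.out =
                           max(1, length(planted_interface))))
    ca <- protein$rep_xyz
    for (k in seq_along(planted_interface)) {
      a <- anchors[k]
      radial <- c(ca[a, 1], ca[a, 2], 0)
      radial <- radial / sqrt(sum(radial^2))
      c3[planted_interface[k], ] <- ca[a, ] + 3.5 * radial
    }
    o3 <- c3 + matrix(c(0.7, 0.7, 0), n_nucleotides, 3, byrow = TRUE)
    nt <- strsplit(ss$sequence, "")[[1]]
    atoms <- tibble::tibble(
      resno = rep(i, each = 2),
      resname = rep(nt, each = 2),
      elety = rep(c("C3'", "O3'"), n_nucleotides),
      x = as.vector(rbind(c3[, 1], o3[, 1])),
      y = as.vector(rbind(c3[, 2], o3[, 2])),
      z = as.vector(rbind(c3[, 3], o3[, 3]))
    )
    rna <- chain_structure(atoms, type = "rna", chain_id = "B")
    if (noise_sigma > 0) {
      jiggle <- function(chain) {
        xyz <- as.matrix(chain$atoms[, c("x", "y", "z")]) +
          matrix(stats::rnorm(3 * nrow(chain$atoms), sd = noise_sigma), ncol = 3)
        chain$atoms$x <- xyz[, 1]; chain$atoms$y <- xyz[, 2]
        chain$atoms$z <- xyz[, 3]
        chain_structure(chain$atoms, type = chain$type,
                        chain_id = chain$chain_id)
      }
      protein <- jiggle(protein); rna <- jiggle(rna)
    }
    cx <- annotate_interface(complex_structure(protein, rna, id = id), 4.5)
    if (noise_sigma == 0 &&
        !identical(cx$interface_rna, sort(unique(as.integer(planted_interface))))) {
      abort("planted interface geometry infeasible for these sizes")
    }
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      pdb <- file.path(dir, paste0(id, ".pdb"))
      write_complex_pdb(cx, pdb, remarks = c(
        paste0("synthetic toy complex '", id, "' seed ", seed),
        paste0("planted RNA interface: ",
               paste(planted_interface, collapse = " "))
      ))
      dbn <- file.path(dir, paste0(id, ".dbn"))
      write_dbn(setNames(list(ss), paste0(id, " seed=", seed)), dbn)
      files <- c(pdb = pdb, dbn = dbn)
    }
    list(complex = cx, secondary = encode_bear(ss),
         planted_interface = sort(unique(as.integer(planted_interface))),
         seed = seed, files = files)
  })
}

#' Generate a planted template library around a toy target
#'
#' Builds a target complex ([make_toy_complex()]) and a library in which
#' the entries' similarity to the target is controlled by construction:
#' `"rigid"` entries are rigidly moved copies (TM-score and SSI near 1),
#' `"variant"` entries are rigid copies whose RNA secondary structure is
#' partly unwound (intermediate SSI, protein unchanged), and `"decoy"`
#' entries pair a random-walk protein fold with an unstructured RNA (low
#' scores). Searching the library with the default weight therefore
#' returns the rigid entries first, then the variants, with decoys below
#' any sensible cutoff.
#'
#' @param seed RNG seed.
#' @param kinds Character vector of entry kinds in id order (subset of
#'   `"rigid"`, `"variant"`, `"decoy"`).
#' @param n_residues,n_nucleotides Target chain sizes.
#' @param planted_interface Planted RNA interface of the target.
#' @param dir Optional output directory: PDB/dbn per entry plus a
#'   `manifest.tsv` (id, kind, pdb, protein_chain, rna_chain, dbn).
#' @return List with `target` (a [docking_target()]), `native` (the
#'   target's native [complex_structure()]), `truth` (native interface
#'   sets), `entries` (list of [template_entry()]), `manifest` (tibble).
#' @export
make_template_library <- function(seed = 1,
                                  kinds = c("rigid", "variant", "variant",
                                            rep("decoy", 3)),
                                  n_residues = 30, n_nucleotides = 16,
                                  planted_interface = c(3, 8, 12),
                                  dir = NULL) {
  base <- make_toy_complex(seed, n_residues, n_nucleotides, planted_interface)
  with_seed(seed + 1000L, {
    entries <- list()
    manifest <- list()
    for (k in seq_along(kinds)) {
      kind <- kinds[k]
      id <- sprintf("tpl%02d", k)
      if (kind == "rigid") {
        tf <- random_rigid_transform()
        cx <- complex_structure(transform_chain(base$complex$protein, tf),
                                transform_chain(base$complex$rna, tf), id = id)
        ss <- base$secondary
      } else if (kind == "variant") {
        tf <- random_rigid_transform()
        cx <- complex_structure(transform_chain(base$complex$protein, tf),
                                transform_chain(base$complex$rna, tf), id = id)
        # unwind part of the hairpin stem: same sequence, weaker SSI
        n_pairs <- nrow(base$secondary$pairs)
        drop <- seq_len(max(1, ceiling(n_pairs / 2)))
        ss <- secondary_structure(base$secondary$sequence,
                                  base$secondary$pairs[-drop, , drop = FALSE])
        ss <- encode_bear(ss)
      } else {
        prot <- walk_protein(n_residues)
        nts <- paste(sample(c("A", "C", "G", "U"), n_nucleotides,
                            replace = TRUE), collapse = "")
        ss <- encode_bear(secondary_structure(nts, NULL))
        c3 <- apply(matrix(stats::rnorm(3 * n_nucleotides, sd = 2), ncol = 3),
                    2, cumsum) + 30
        atoms <- tibble::tibble(
          resno = seq_len(n_nucleotides),
          resname = strsplit(nts, "")[[1]],
          elety = "C3'", x = c3[, 1], y = c3[, 2], z = c3[, 3])
        cx <- complex_structure(prot,
                                chain_structure(atoms, "rna", "B"), id = id)
      }
      entry <- template_entry(id, annotate_interface(cx, 4.5), ss)
      entries[[k]] <- entry
      files <- c(pdb = NA_character_, dbn = NA_character_)
      if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        files["pdb"] <- file.path(dir, paste0(id, ".pdb"))
        write_complex_pdb(entry$complex, files["pdb"],
                          remarks = paste0("synthetic template '", id,
                                           "' kind ", kind, " seed ", seed))
        files["dbn"] <- file.path(dir, paste0(id, ".dbn"))
        write_dbn(setNames(list(ss), id), files["dbn"])
      }
      manifest[[k]] <- tibble::tibble(
        id = id, kind = kind, pdb = files["pdb"],
        protein_chain = "A", rna_chain = "B", dbn = files["dbn"])
    }
    manifest <- dplyr::bind_rows(manifest)
    if (!is.null(dir)) {
      write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    list(
      target = docking_target("target", base$complex$protein,
                              base$secondary, rna = base$complex$rna),
      native = base$complex,
      truth = list(protein = base$complex$interface_protein,
                   rna = base$complex$interface_rna),
      entries = entries,
      manifest = manifest
    )
  })
}

#' Generate a toy Stockholm alignment with planted gap-free runs
#'
#' Columns form alternating gap-free runs (of the requested lengths) and
#' single gap-bearing separator columns, under a hairpin consensus
#' structure per run. Optionally the first row is duplicated to plant
#' redundancy for clustering tests.
#'
#' @param seed RNG seed.
#' @param run_lengths Lengths of the gap-free runs.
#' @param n_rows Number of distinct sequence rows.
#' @param n_duplicates Extra copies of row 1 appended (default 0).
#' @param path Optional output path for the Stockholm file.
#' @return List with `lines` (the Stockholm text), `alignment` (parsed,
#'   as from [read_stockholm()]) and `path` (when written).
#' @export
make_toy_blocks <- function(seed = 1, run_lengths = c(8, 7), n_rows = 3,
                            n_duplicates = 0, path = NULL) {
  with_seed(seed, {
    ncol_total <- sum(run_lengths) + length(run_lengths) - 1
    seqs <- matrix(sample(c("A", "C", "G", "U"), n_rows * ncol_total,
                          replace = TRUE), nrow = n_rows)
    ss <- character(ncol_total)
    pos <- 1L
    for (r in seq_along(run_lengths)) {
      L <- run_lengths[r]
      k <- max(1, (L - 4) %/% 2)
      loop <- L - 2 * k
      ss[pos:(pos + L - 1)] <- strsplit(
        paste0(strrep("<", k), strrep(".", loop), strrep(">", k)), "")[[1]]
      pos <- pos + L
      if (r < length(run_lengths)) {
        # separator column: gap in one row, unpaired consensus
        seqs[1 + (r %% n_rows), pos] <- "-"
        ss[pos] <- "."
        pos <- pos + 1L
      }
    }
    rows <- apply(seqs, 1, paste, collapse = "")
    names <- sprintf("seq%02d", seq_len(n_rows))
    if (n_duplicates > 0) {
      rows <- c(rows, rep(rows[1], n_duplicates))
      names <- c(names, sprintf("dup%02d", seq_len(n_duplicates)))
    }
    lines <- c(
      "# STOCKHOLM 1.0",
      paste0("#=GF ID toyfam_seed", seed),
      sprintf("%-12s %s", names, rows),
      sprintf("%-12s %s", "#=GC SS_cons", paste(ss, collapse = "")),
      "//"
    )
    if (!is.null(path)) writeLines(lines, path)
    alignment <- list(sequences = setNames(rows, names),
                      ss_cons = paste(ss, collapse = ""),
                      id = paste0("toyfam_seed", seed))
    list(lines = lines, alignment = alignment, path = path)
  })
}
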