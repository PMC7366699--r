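toy <- make_toy_complex(seed = 21)

test_that("PDB writing and reading round-trips a synthetic complex", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "toy.pdb")
  write_complex_pdb(toy$complex, path, remarks = "toy fixture")
  cx <- read_structure(path, protein_chain = "A", rna_chain = "B")
  expect_equal(nrow(cx$protein$residues), nrow(toy$complex$protein$residues))
  expect_equal(nrow(cx$rna$residues), nrow(toy$complex$rna$residues))
  expect_equal(rep_coords(cx$protein), rep_coords(toy$complex$protein),
               tolerance = 1e-3)
  expect_equal(rep_coords(cx$rna), rep_coords(toy$complex$rna),
               tolerance = 1e-3)
  expect_error(read_structure(path, protein_chain = "X", rna_chain = "B"),
               "available chains.*A, B")
})

test_that("residues lacking the representative atom are flagged, not dropped", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "gap.pdb")
  write_complex_pdb(toy$complex, path)
  # remove one C3' record
  lines <- readLines(path)
  drop <- grep("C3'", lines)[2]
  writeLines(lines[-drop], path)
  expect_warning(cx <- read_structure(path, "A", "B"), "1 residue")
  expect_equal(sum(!cx$rna$residues$has_rep), 1L)
  expect_equal(nrow(cx$rna$residues), nrow(toy$complex$rna$residues))
  expect_error(rep_coords(cx$rna, which(!cx$rna$residues$has_rep)),
               "lacks")
})

test_that("interface annotation applies the heavy-atom cutoff exactly", {
  # two single-residue chains with the closest heavy atoms at distance d
  mini <- function(d) {
    p <- chain_structure(tibble::tibble(
      resno = 1L, resname = "ALA", elety = c("CA", "CB"),
      x = c(0, 1), y = 0, z = 0), "protein", "A")
    r <- chain_structure(tibble::tibble(
      resno = 1L, resname = "A", elety = "C3'",
      x = 1 + d, y = 0, z = 0), "rna", "B")
    annotate_interface(complex_structure(p, r), 4.5)
  }
  close_cx <- mini(4.4)
  expect_equal(close_cx$interface_protein, 1L)
  expect_equal(close_cx$interface_rna, 1L)
  far_cx <- mini(4.6)
  expect_length(far_cx$interface_protein, 0)
  expect_length(far_cx$interface_rna, 0)
  distant <- mini(100)
  expect_length(distant$interface_rna, 0)
})

test_that("interface sets grow monotonically with the cutoff", {
  for (cutoff in c(3, 4.5, 6, 10, 20)) {
    prev <- annotate_interface(toy$complex, cutoff)
    nxt <- annotate_interface(toy$complex, cutoff + 2)
    expect_true(all(prev$interface_protein %in% nxt$interface_protein))
    expect_true(all(prev$interface_rna %in% nxt$interface_rna))
  }
})

test_that("Kabsch recovers planted rigid transforms", {
  set.seed(77)
  pts <- matrix(rnorm(30, sd = 5), ncol = 3)
  # identity
  tf0 <- kabsch(pts, pts)
  expect_equal(tf0$rmsd, 0, tolerance = 1e-9)
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-9)
  # pure translation
  tf1 <- kabsch(pts, pts + matrix(c(1, 2, 3), 10, 3, byrow = TRUE))
  expect_equal(tf1$rmsd, 0, tolerance = 1e-9)
  expect_equal(tf1$translation, c(1, 2, 3), tolerance = 1e-9)
  # planted rotations, noise-free: recovered to 1e-6
  for (rep in 1:200) {
    R <- random_rotation()
    t0 <- rnorm(3, sd = 10)
    moved <- pts %*% R + matrix(t0, 10, 3, byrow = TRUE)
    tf <- kabsch(pts, moved)
    expect_lt(max(abs(tf$rotation - R)), 1e-6)
    expect_lt(tf$rmsd, 1e-9)
  }
  # with noise the rmsd matches the direct residual of the fit
  noisy <- pts + matrix(rnorm(30, sd = 0.1), ncol = 3)
  tf2 <- kabsch(pts, noisy)
  resid <- sqrt(mean(rowSums((apply_transform(pts, tf2) - noisy)^2)))
  expect_equal(tf2$rmsd, resid)
  expect_lt(tf2$rmsd, 0.3)
  expect_error(kabsch(pts[1:2, ], pts[1:2, ]), "3 points")
  expect_error(kabsch(pts[1:4, ], pts), "equal size")
})

test_that("Kabsch rmsd is invariant under rigid pre-motion", {
  set.seed(123)
  for (rep in 1:200) {
    n <- sample(4:20, 1)
    A <- matrix(rnorm(3 * n, sd = 4), ncol = 3)
    B <- matrix(rnorm(3 * n, sd = 4), ncol = 3)
    base <- kabsch(A, B)$rmsd
    R <- random_rotation()
    A2 <- A %*% R + matrix(rnorm(3, sd = 15), n, 3, byrow = TRUE)
    expect_equal(kabsch(A2, B)$rmsd, base, tolerance = 1e-8)
  }
})

test_that("transforms invert and compose correctly", {
  set.seed(3)
  pts <- matrix(rnorm(30), ncol = 3)
  tf <- kabsch(pts, pts %*% random_rotation() + 5)
  back <- apply_transform(apply_transform(pts, tf), invert_transform(tf))
  expect_equal(back, pts, tolerance = 1e-9)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
})

test_that("TM-score is 1 for self and follows the closed form at d = d0", {
  p <- toy$complex$protein
  aln <- identity_alignment(nrow(p$residues))
  expect_equal(as.numeric(tm_score(aln, p, p)), 1, tolerance = 1e-9)
  # d0 for a 20-residue target; all distances equal to d0 halve each term
  d0 <- prime3d2d:::tm_d0(20)
  expect_equal(prime3d2d:::tm_score_from_distances(rep(d0, 15), d0, 20),
               (15 / 20) * 0.5)
  # very distant chains score near 0 but stay positive
  far <- transform_chain(p, structure(list(rotation = diag(3),
                                           translation = c(500, 0, 0),
                                           rmsd = NA_real_),
                                      class = "rigid_transform"))
  sc <- as.numeric(tm_score(aln, far, p))
  expect_gt(sc, 0)
  expect_equal(sc, 1, tolerance = 1e-9)  # rigid motion is removed by the fit
  expect_error(tm_score(identity_alignment(2), p, p), "3 aligned")
})

test_that("iRMSD vanishes for identical or rigidly moved binding modes", {
  cx <- toy$complex
  n_p <- nrow(cx$protein$residues); n_r <- nrow(cx$rna$residues)
  pm <- identity_alignment(n_p); rm_ <- identity_alignment(n_r)
  expect_equal(irmsd(cx, cx, pm, rm_), 0, tolerance = 1e-9)
  tf <- structure(list(rotation = random_rotation(),
                       translation = c(10, -4, 2), rmsd = NA_real_),
                  class = "rigid_transform")
  moved <- complex_structure(transform_chain(cx$protein, tf),
                             transform_chain(cx$rna, tf))
  moved <- annotate_interface(moved, 4.5)
  expect_equal(irmsd(cx, moved, pm, rm_), 0, tolerance = 1e-9)
})

test_that("iRMSD of a displaced RNA equals the direct Kabsch residual", {
  cx <- toy$complex
  shift <- structure(list(rotation = diag(3), translation = c(3, 0, 0),
                          rmsd = NA_real_), class = "rigid_transform")
  b <- annotate_interface(
    complex_structure(cx$protein, transform_chain(cx$rna, shift)), 4.5)
  n_p <- nrow(cx$protein$residues); n_r <- nrow(cx$rna$residues)
  pm <- identity_alignment(n_p); rm_ <- identity_alignment(n_r)
  got <- irmsd(cx, b, pm, rm_)
  # oracle: gather the interface representative atoms explicitly and run
  # a plain Kabsch fit on those coordinates
  ip <- sort(union(cx$interface_protein, b$interface_protein))
  ir <- sort(union(cx$interface_rna, b$interface_rna))
  A <- rbind(rep_coords(cx$protein, ip), rep_coords(cx$rna, ir))
  B <- rbind(rep_coords(b$protein, ip), rep_coords(b$rna, ir))
  expect_equal(got, kabsch(B, A)$rmsd, tolerance = 1e-9)
  expect_gt(got, 0)
})

test_that("iRMSD with too few usable positions is missing", {
  cx <- toy$complex
  empty <- pairwise_alignment(rbind(c(1, 1), c(2, 2)), 0)
  expect_warning(v <- irmsd(cx, cx, empty, empty), "fewer than 3")
  expect_true(is.na(v))
})

test_that("ligand RMSD measures RNA displacement in the protein frame", {
  cx <- toy$complex
  expect_equal(ligand_rmsd(cx, cx), 0, tolerance = 1e-12)
  # RNA translated by 2 A with identical proteins: exactly 2
  shift <- structure(list(rotation = diag(3), translation = c(0, 2, 0),
                          rmsd = NA_real_), class = "rigid_transform")
  model <- complex_structure(cx$protein, transform_chain(cx$rna, shift))
  expect_equal(ligand_rmsd(model, cx), 2, tolerance = 1e-9)
  # invariant under rigid motion of the whole model complex
  tf <- structure(list(rotation = random_rotation(),
                       translation = c(-8, 3, 12), rmsd = NA_real_),
                  class = "rigid_transform")
  moved <- complex_structure(transform_chain(model$protein, tf),
                             transform_chain(model$rna, tf))
  expect_equal(ligand_rmsd(moved, cx), 2, tolerance = 1e-9)
  # the 10 A acceptability threshold is a strict boundary
  for (d in c(9.9, 10.1)) {
    s <- structure(list(rotation = diag(3), translation = c(d, 0, 0),
                        rmsd = NA_real_), class = "rigid_transform")
    m <- complex_structure(cx$protein, transform_chain(cx$rna, s))
    expect_equal(ligand_rmsd(m, cx) <= 10, d <= 10)
  }
  bad <- make_toy_complex(seed = 4, n_nucleotides = 12)$complex
  expect_error(ligand_rmsd(bad, cx), "correspondence")
})

test_that("external aligner probing and parsing work without the binaries", {
  expect_false(has_external("tmalign", executable_path = "/nonexistent/TMalign"))
  expect_error(run_external_aligner("tmalign", c("a.pdb", "b.pdb"),
                                    executable_path = "/nonexistent/TMalign"),
               class = "external_unavailable")
  # synthetic TM-align output: 4 aligned pairs, chain-2-normalized score
  out <- parse_tmalign_output(readLines(test_path("fixtures",
                                                  "synthetic-tmalign-output.txt")))
  expect_equal(out$score, 0.65432)
  ap <- prime3d2d:::aligned_pairs(out$alignment)
  expect_equal(unname(ap), cbind(1:4, 1:4))
  # synthetic LocARNA output round-trips to the same gapped rows
  lines <- readLines(test_path("fixtures", "synthetic-locarna-output.txt"))
  loc <- parse_locarna_output(lines)
  expect_equal(loc$score, -1234)
  p <- loc$alignment$pairs
  ga <- paste(ifelse(is.na(p[, 1]), "-",
                     strsplit("GGGAAACCC", "")[[1]][p[, 1]]), collapse = "")
  gb <- paste(ifelse(is.na(p[, 2]), "-",
                     strsplit("GGGAAUCCC", "")[[1]][p[, 2]]), collapse = "")
  expect_equal(ga, "GGGAAA-CCC")
  expect_equal(gb, "GGG-AAUCCC")
})
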