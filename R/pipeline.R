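# Template-based docking pipeline: 3D2D scoring, template search, model
# building, binding-site transfer, and the evaluation analyses (top-N
# success rate, phase transition).

#' Combined protein/RNA template similarity (3D2D score)
#'
#' `score = weight * tm + (1 - weight) * ssi`: the protein 3D similarity
#' (TM-score) and the RNA secondary-structure identity (SSI) mixed by a
#' single weight. The default weight 0.8 and the template cutoff 0.45
#' are the benchmark-calibrated operating point.
#'
#' @param tm TM-score in `[0, 1]`.
#' @param ssi Secondary-structure identity in `[0, 1]`.
#' @param weight Protein weight W in `[0, 1]` (default 0.8).
#' @return The combined score (vectorized).
#' @export
score_3d2d <- function(tm, ssi, weight = 0.8) {
  if (any(tm < 0 | tm > 1) || any(ssi < 0 | ssi > 1)) {
    abort("tm and ssi must lie in [0, 1]")
  }
  if (any(weight < 0 | weight > 1)) abort("weight must lie in [0, 1]")
  weight * tm + (1 - weight) * ssi
}

#' Reference transition points per weight
#'
#' The calibrated phase-transition score (template cutoff) observed for
#' each protein weight W on the benchmark set, shipped as reference data.
#'
#' @return Tibble with columns `weight`, `transition_score`.
#' @export
reference_transitions <- function() {
  tibble::tibble(
    weight = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4),
    transition_score = c(0.40, 0.45, 0.50, 0.60, 0.65, 0.70)
  )
}

#' Template library entry
#'
#' A solved protein-RNA complex converted to a template: the protein
#' keeps its 3D structure, the RNA is represented by its secondary
#' structure (encoded in the structural alphabet), and the interface is
#' annotated at the heavy-atom cutoff.
#'
#' @param id Template identifier.
#' @param complex A [complex_structure()].
#' @param rna_secondary A [secondary_structure()] for the template RNA
#'   (same length as the RNA chain).
#' @param cutoff Interface cutoff in Angstrom (default 4.5).
#' @param alphabet Structural alphabet for encoding.
#' @return Object of class `template_entry`.
#' @export
template_entry <- function(id, complex, rna_secondary, cutoff = 4.5,
                           alphabet = bear_alphabet()) {
  stopifnot(inherits(complex, "complex_structure"),
            inherits(rna_secondary, "secondary_structure"))
  if (nchar(rna_secondary$sequence) != nrow(complex$rna$residues)) {
    abort("secondary structure length must equal the RNA chain length")
  }
  if (is.null(rna_secondary$bear)) {
    rna_secondary <- encode_bear(rna_secondary, alphabet)
  }
  if (is.na(complex$interface_cutoff) || complex$interface_cutoff != cutoff) {
    complex <- annotate_interface(complex, cutoff)
  }
  structure(list(id = id, complex = complex, rna_secondary = rna_secondary),
            class = "template_entry")
}

#' Docking target
#'
#' @param id Target identifier (targets sharing an id with a library
#'   entry are excluded from their own template search).
#' @param protein A protein [chain_structure()].
#' @param rna_secondary A [secondary_structure()] of the target RNA.
#' @param rna Optional RNA [chain_structure()] (3D); when absent the
#'   pipeline runs in 2D-only mode: binding-site transfer works, model
#'   building is unavailable.
#' @return Object of class `docking_target`.
#' @export
docking_target <- function(id, protein, rna_secondary, rna = NULL) {
  stopifnot(inherits(protein, "chain_structure"),
            inherits(rna_secondary, "secondary_structure"))
  if (!is.null(rna) && nchar(rna_secondary$sequence) != nrow(rna$residues)) {
    abort("secondary structure length must equal the RNA chain length")
  }
  structure(list(id = id, protein = protein,
                 rna_secondary = rna_secondary, rna = rna),
            class = "docking_target")
}

#' Search a template library for a docking target
#'
#' Each template is compared to the target: the protein chains are
#' aligned structurally (TM-score), the RNAs are aligned over sequence +
#' secondary structure (SSI), and the two similarities are combined into
#' the 3D2D score. Templates sharing the target's id are excluded
#' (self-hit removal); hits below `cutoff` are dropped; the rest are
#' ranked by score (ties by template id). A template whose alignment
#' fails is skipped with a warning.
#'
#' @param target A [docking_target()].
#' @param library List of [template_entry()] objects.
#' @param weight Protein weight W (default 0.8).
#' @param cutoff Minimum 3D2D score for a usable template (default 0.45).
#' @param scorer Combined RNA scorer (default: structure matrix trained
#'   elsewhere is not required — a neutral all-zero structure matrix over
#'   the default alphabet with bonus 0.2 is a poor scorer, so callers
#'   normally pass one built from [compute_rnablosum()]); when `NULL`,
#'   SSI is computed from an alignment driven by structure-character
#'   match/mismatch (+2/-1) plus the nucleotide term.
#' @param gaps [gap_params()] for the RNA alignment.
#' @param bonus Nucleotide bonus used when `scorer` is `NULL`.
#' @return Object of class `template_search`: field `hits` is a tibble
#'   (`template_id`, `tm_score`, `ssi`, `score3d2d`, list-columns
#'   `protein_alignment`, `rna_alignment`) sorted by score.
#' @export
search_templates <- function(target, library, weight = 0.8, cutoff = 0.45,
                             scorer = NULL, gaps = gap_params(), bonus = 0.2) {
  stopifnot(inherits(target, "docking_target"), length(library) > 0)
  scorer <- scorer %||% default_structure_scorer(bonus)
  rows <- list()
  for (entry in library) {
    if (identical(entry$id, target$id)) next
    hit <- tryCatch({
      pa <- align_protein_builtin(target$protein, entry$complex$protein,
                                  l_target = nrow(target$protein$residues))
      ra <- global_align(target$rna_secondary, entry$rna_secondary,
                         scorer, gaps)
      ssi <- compute_ssi(ra)
      tibble::tibble(
        template_id = entry$id,
        tm_score = pa$tm_score,
        ssi = ssi,
        score3d2d = score_3d2d(pa$tm_score, ssi, weight),
        protein_alignment = list(pa$alignment),
        rna_alignment = list(ra)
      )
    }, error = function(e) {
      warn(sprintf("template '%s' skipped: %s", entry$id, conditionMessage(e)))
      NULL
    })
    if (!is.null(hit)) rows[[length(rows) + 1L]] <- hit
  }
  hits <- dplyr::bind_rows(rows)
  if (nrow(hits) > 0) {
    hits <- hits |>
      dplyr::filter(.data$score3d2d >= cutoff) |>
      dplyr::arrange(dplyr::desc(.data$score3d2d), .data$template_id)
  }
  structure(list(hits = hits, target_id = target$id,
                 weight = weight, cutoff = cutoff,
                 n_templates = length(library)),
            class = "template_search")
}

# match/mismatch structure scorer used when no trained matrix is supplied
default_structure_scorer <- function(bonus = 0.2, alphabet = bear_alphabet()) {
  chars <- alphabet$char
  m <- matrix(-1, length(chars), length(chars), dimnames = list(chars, chars))
  diag(m) <- 2
  build_scorer(substitution_matrix(chars, m), bonus = bonus)
}

#' @export
print.template_search <- function(x, ...) {
  cat("<template_search> target '", x$target_id, "': ", nrow(x$hits),
      " of ", x$n_templates, " templates at score >= ", x$cutoff,
      " (W = ", x$weight, ")\n", sep = "")
  if (nrow(x$hits) == 0) cat("  no usable template\n")
  else print(tidy(x), n = 5)
  invisible(x)
}

#' @describeIn search_templates Hit table without list-columns.
#' @param x A `template_search`.
#' @param ... Unused.
#' @export
tidy.template_search <- function(x, ...) {
  dplyr::select(x$hits, "template_id", "tm_score", "ssi", "score3d2d")
}

#' @describeIn search_templates One-row summary (target, templates
#'   searched, hits retained, best score).
#' @export
glance.template_search <- function(x, ...) {
  tibble::tibble(
    target_id = x$target_id, n_templates = x$n_templates,
    n_hits = nrow(x$hits), weight = x$weight, cutoff = x$cutoff,
    best_score = if (nrow(x$hits) > 0) x$hits$score3d2d[1] else NA_real_
  )
}

#' Build a rigid-body complex model from a template hit
#'
#' The target protein is moved into the template frame by the Kabsch
#' superposition over the protein alignment's C-alpha pairs, and the
#' target RNA by the superposition over the RNA alignment's C3' pairs
#' (target RNA 3D is required). The model inherits the template's
#' relative protein/RNA placement.
#'
#' @param target A [docking_target()] with a 3D RNA chain.
#' @param hit One row of a [search_templates()] hit table (a list or
#'   one-row tibble with `protein_alignment`, `rna_alignment`).
#' @param template The matching [template_entry()].
#' @return A [complex_structure()] model in the template frame, with
#'   attribute `template_id`; `NULL` (with a warning) when fewer than 3
#'   C3' pairs are aligned.
#' @export
build_model <- function(target, hit, template) {
  if (is.null(target$rna)) {
    abort("model building requires the target RNA 3D structure (2D-only mode)")
  }
  pa <- if (is.data.frame(hit)) hit$protein_alignment[[1]] else hit$protein_alignment
  ra <- if (is.data.frame(hit)) hit$rna_alignment[[1]] else hit$rna_alignment
  app <- aligned_pairs(pa)
  ok <- target$protein$residues$has_rep[app[, 1]] &
    template$complex$protein$residues$has_rep[app[, 2]]
  app <- app[ok, , drop = FALSE]
  apr <- aligned_pairs(ra)
  ok <- target$rna$residues$has_rep[apr[, 1]] &
    template$complex$rna$residues$has_rep[apr[, 2]]
  apr <- apr[ok, , drop = FALSE]
  if (nrow(app) < 3) {
    warn("fewer than 3 aligned C-alpha pairs; no model built")
    return(NULL)
  }
  if (nrow(apr) < 3) {
    warn("fewer than 3 aligned C3' pairs; no model built")
    return(NULL)
  }
  tf_p <- kabsch(rep_coords(target$protein, app[, 1]),
                 rep_coords(template$complex$protein, app[, 2]))
  tf_r <- kabsch(rep_coords(target$rna, apr[, 1]),
                 rep_coords(template$complex$rna, apr[, 2]))
  model <- complex_structure(transform_chain(target$protein, tf_p),
                             transform_chain(target$rna, tf_r),
                             id = paste0(target$id, "|", template$id))
  attr(model, "template_id") <- template$id
  model
}

#' Transfer binding sites from a template through the alignments
#'
#' A target position is predicted to be a binding site iff it is aligned
#' (no gap on either side) to an interface position of the template;
#' positions aligned to non-interface template positions, and unaligned
#' positions, are predicted negative. Applied independently to the
#' protein (residues) and the RNA (nucleotides).
#'
#' @param hit One row of a hit table (list or one-row tibble with the
#'   two alignments and `score3d2d`).
#' @param template The matching [template_entry()].
#' @return Object of class `site_prediction`: `protein_sites`,
#'   `rna_sites` (target indices), `template_id`, `score3d2d`.
#' @export
transfer_sites <- function(hit, template) {
  pa <- if (is.data.frame(hit)) hit$protein_alignment[[1]] else hit$protein_alignment
  ra <- if (is.data.frame(hit)) hit$rna_alignment[[1]] else hit$rna_alignment
  score <- if (is.data.frame(hit)) hit$score3d2d[[1]] else hit$score3d2d
  map_sites <- function(aln, template_sites) {
    ap <- aligned_pairs(aln)
    sort(unname(ap[ap[, 2] %in% template_sites, 1]))
  }
  structure(list(
    protein_sites = map_sites(pa, template$complex$interface_protein),
    rna_sites = map_sites(ra, template$complex$interface_rna),
    template_id = template$id,
    score3d2d = score %||% NA_real_
  ), class = "site_prediction")
}

#' @export
print.site_prediction <- function(x, ...) {
  cat("<site_prediction> from '", x$template_id, "' (score ",
      format(x$score3d2d, digits = 3), "): ", length(x$protein_sites),
      " protein / ", length(x$rna_sites), " RNA sites\n", sep = "")
  invisible(x)
}

site_set <- function(prediction, side = c("protein", "rna")) {
  side <- match.arg(side)
  if (side == "protein") prediction$protein_sites else prediction$rna_sites
}

#' Aggregate ranked site predictions over the top n templates
#'
#' `mode = "best"` (the evaluation convention: the single prediction
#' among the top n maximizing MCC against the truth) requires truth
#' labels; `mode = "union"` (label-free aggregation for prospective use)
#' predicts the union of the top-n predicted sites.
#'
#' @param predictions List of [transfer_sites()] predictions in template
#'   rank order.
#' @param n Number of top templates to consider.
#' @param side `"protein"` or `"rna"`.
#' @param truth True site indices (required for `mode = "best"`).
#' @param universe All evaluable positions (required for `mode = "best"`).
#' @param mode `"best"` or `"union"`.
#' @return For `"best"`: the selected `site_prediction` with attribute
#'   `mcc`; for `"union"`: an integer vector of predicted positions.
#' @export
aggregate_topn <- function(predictions, n, side = c("protein", "rna"),
                           truth = NULL, universe = NULL,
                           mode = c("best", "union")) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  if (length(predictions) == 0) {
    abort("no predictions available (no usable template)",
          class = "no_template")
  }
  top <- predictions[seq_len(min(n, length(predictions)))]
  if (mode == "union") {
    return(sort(unique(unlist(lapply(top, site_set, side = side)))))
  }
  if (is.null(truth) || is.null(universe)) {
    abort("mode = 'best' needs truth and universe")
  }
  mccs <- vapply(top, function(p) {
    evaluate_confusion(confusion(site_set(p, side), truth, universe))$mcc
  }, 0)
  best <- which.max(mccs)
  out <- top[[best]]
  attr(out, "mcc") <- mccs[best]
  attr(out, "rank") <- best
  out
}

#' Best-model metric curve over top-n predictions
#'
#' For each n, evaluates the single prediction among the top n that
#' maximizes MCC (the "best model in top n" convention) and reports its
#' full metric row.
#'
#' @inheritParams aggregate_topn
#' @param n_max Largest n (default: number of predictions).
#' @return Tibble with `n` plus the metric columns of
#'   [evaluate_confusion()].
#' @export
topn_metrics <- function(predictions, truth, universe,
                         side = c("protein", "rna"),
                         n_max = length(predictions)) {
  side <- match.arg(side)
  purrr::map_dfr(seq_len(n_max), function(n) {
    best <- aggregate_topn(predictions, n, side = side,
                           truth = truth, universe = universe, mode = "best")
    m <- evaluate_confusion(confusion(site_set(best, side), truth, universe))
    dplyr::bind_cols(tibble::tibble(n = n), m)
  })
}

#' Top-n docking success rate
#'
#' The fraction of targets with at least one acceptable model (ligand
#' RMSD at most `threshold`, default 10 Angstrom) among their top n
#' ranked models. A target with no models counts as a failure.
#'
#' @param ranked_rmsds List (one element per target) of numeric ligand
#'   RMSD vectors in model rank order (possibly empty).
#' @param n Integer vector of list sizes to evaluate.
#' @param threshold Acceptability threshold in Angstrom (default 10).
#' @return Tibble of class `success_rate_curve` with columns `n`,
#'   `success_rate`.
#' @export
success_rate <- function(ranked_rmsds, n = seq_len(max(1, lengths(ranked_rmsds))),
                         threshold = 10) {
  stopifnot(all(n >= 1))
  out <- tibble::tibble(
    n = as.integer(n),
    success_rate = vapply(n, function(k) {
      mean(vapply(ranked_rmsds, function(r) {
        length(r) > 0 && any(head(r, k) <= threshold, na.rm = TRUE)
      }, TRUE))
    }, 0)
  )
  class(out) <- c("success_rate_curve", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Phase-transition analysis of score vs binding-mode similarity
#'
#' Bins template-comparison scores in `[0, 1)` (width 0.05) and computes,
#' per bin, the fraction of pairs whose interface RMSD is at most
#' `irmsd_cut` (5 Angstrom). The transition point is the left edge of the
#' lowest-score non-empty bin from which every non-empty bin upward has a
#' positive fraction — the score at which similar binding modes start to
#' appear.
#'
#' @param scores Combined similarity scores in `[0, 1]`.
#' @param irmsd Interface RMSDs (same length, Angstrom).
#' @param bin_width Bin width (default 0.05).
#' @param irmsd_cut Similar-binding-mode cutoff (default 5).
#' @return Object of class `phase_transition`: `bins` (tibble with
#'   `bin_left`, `bin_right`, `n`, `n_below`, `fraction`) and
#'   `transition` (score, `NA` when no pair falls below `irmsd_cut`).
#' @export
phase_transition <- function(scores, irmsd, bin_width = 0.05, irmsd_cut = 5) {
  stopifnot(length(scores) == length(irmsd))
  if (length(scores) == 0) abort("no score/iRMSD pairs supplied")
  if (any(scores < 0 | scores > 1)) abort("scores must lie in [0, 1]")
  n_bins <- ceiling(1 / bin_width)
  bin <- pmin(floor(scores / bin_width) + 1L, n_bins)
  bins <- tibble::tibble(
    bin_left = (seq_len(n_bins) - 1L) * bin_width,
    bin_right = pmin(seq_len(n_bins) * bin_width, 1),
    n = vapply(seq_len(n_bins), function(k) sum(bin == k), 0L),
    n_below = vapply(seq_len(n_bins), function(k)
      sum(bin == k & irmsd <= irmsd_cut), 0L)
  )
  bins$fraction <- ifelse(bins$n > 0, bins$n_below / bins$n, NA_real_)
  nonempty <- which(bins$n > 0)
  transition <- NA_real_
  if (sum(bins$n_below) > 0) {
    for (k in nonempty) {
      upper <- nonempty[nonempty >= k]
      if (all(bins$fraction[upper] > 0)) {
        transition <- bins$bin_left[k]
        break
      }
    }
  }
  structure(list(bins = bins, transition = transition,
                 bin_width = bin_width, irmsd_cut = irmsd_cut),
            class = "phase_transition")
}

#' @export
print.phase_transition <- function(x, ...) {
  cat("<phase_transition> ", sum(x$bins$n), " pairs in ",
      sum(x$bins$n > 0), " bins; transition at ",
      if (is.na(x$transition)) "NA (no similar binding modes)"
      else format(x$transition), "\n", sep = "")
  invisible(x)
}

#' @describeIn phase_transition Per-bin table.
#' @param x A `phase_transition`.
#' @param ... Unused.
#' @export
tidy.phase_transition <- function(x, ...) x$bins

#' @describeIn phase_transition One-row summary.
#' @export
glance.phase_transition <- function(x, ...) {
  tibble::tibble(transition = x$transition, bin_width = x$bin_width,
                 irmsd_cut = x$irmsd_cut, n_pairs = sum(x$bins$n))
}

#' Per-position binding-site table for a target
#'
#' Runs the template search's predictions through site transfer and
#' reports, per target position and side, the 0/1 prediction with the
#' best supporting template and its score (the per-position confidence is
#' the maximum 3D2D score over templates predicting that position
#' positive, 0 otherwise).
#'
#' @param search A [search_templates()] result.
#' @param library The template library (list of [template_entry()]).
#' @param n_protein,n_rna Target chain lengths.
#' @param top_n Number of top templates to use (default 10).
#' @return Tibble: `side`, `position`, `predicted` (0/1), `support`
#'   (template id or `NA`), `score`.
#' @export
predict_binding_sites <- function(search, library, n_protein, n_rna,
                                  top_n = 10) {
  hits <- search$hits
  lib_ids <- vapply(library, `[[`, "", "id")
  preds <- purrr::map(seq_len(min(top_n, nrow(hits))), function(k) {
    transfer_sites(hits[k, ], library[[match(hits$template_id[k], lib_ids)]])
  })
  one_side <- function(side, n_pos) {
    score <- numeric(n_pos)
    support <- rep(NA_character_, n_pos)
    for (p in preds) {
      s <- site_set(p, side)
      better <- s[p$score3d2d > score[s]]
      score[better] <- p$score3d2d
      support[better] <- p$template_id
    }
    tibble::tibble(side = side, position = seq_len(n_pos),
                   predicted = as.integer(score > 0),
                   support = support, score = score)
  }
  dplyr::bind_rows(one_side("protein", n_protein), one_side("rna", n_rna))
}
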