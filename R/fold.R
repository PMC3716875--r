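# Target base pair probabilities: a built-in simplified windowed
# partition-function folder standing in for external local-folding
# tools, plus ensemble structure probabilities and constrained
# minimum-energy folding used by the decoy designer.

#' Simplified pair-additive RNA energy model
#'
#' A Nussinov-Boltzmann stand-in for the nearest-neighbor model: each
#' canonical base pair contributes a fixed negative energy, hairpin
#' loops have a minimum size, and lonely pairs (helices of a single
#' pair) can be excluded.  Probabilities computed under this model are
#' consistent across folding, decoy design and scanning, which is what
#' the synthetic benchmark requires; externally computed probabilities
#' can always be substituted through [read_bpp()].
#'
#' Energies are in units of RT at `rt = 1`.  Defaults keep the
#' GC : AU : GU stability ratio at 3 : 2 : 1 but are scaled so that a
#' single missing pair in a designed helix costs ~ exp(-6): with weaker
#' pairs the ensemble weight of stem truncations alone would cap the
#' probability of any multi-helix template below the 0.75 design
#' target (see the methods vignette).
#'
#' @param gc,au,gu pair energies (negative)
#' @param helix_init energy penalty charged once per helix (`>= 0`);
#'   an optional stand-in for loop initiation costs.  The default is 0:
#'   the background pairing "noise" of an unpenalized ensemble is what
#'   dilutes the template pairs of merely structure-compatible decoys,
#'   and damping it was measured to blur the stability contrast the
#'   benchmark relies on
#' @param min_loop minimum hairpin loop size
#' @param rt thermodynamic scale
#' @param no_lonely_pairs exclude isolated pairs (helices must stack
#'   at least two pairs)
#' @return object of class `energy_model`
#' @export
energy_model <- function(gc = -6, au = -4, gu = -2, helix_init = 0,
                         min_loop = 3, rt = 1, no_lonely_pairs = TRUE) {
  stopifnot(gc < 0, au < 0, gu < 0, helix_init >= 0, min_loop >= 0, rt > 0)
  E <- matrix(0, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  E["A", "U"] <- E["U", "A"] <- au
  E["C", "G"] <- E["G", "C"] <- gc
  E["G", "U"] <- E["U", "G"] <- gu
  structure(list(pair_energy = E, helix_init = helix_init,
                 min_loop = as.integer(min_loop),
                 rt = rt, no_lonely_pairs = no_lonely_pairs),
            class = "energy_model")
}

# numeric scale (log per nucleotide) keeping doubles in range for
# GC-dense and unstructured windows alike
fold_scale <- function(model) {
  max(0, -min(model$pair_energy) / model$rt * 0.5 * 0.5)
}

#' Local base pair probabilities by windowed partition-function folding
#'
#' For each window of length `window` (step 1) the Boltzmann ensemble
#' of non-crossing canonical structures under the energy model is
#' summed (pair span limited to `span`, hairpins >= `min_loop`, lonely
#' pairs excluded if configured); a pair's probability is averaged over
#' all windows that fully contain it, and entries below `floor` are
#' dropped.
#'
#' @param target residue string (or encoded integer vector)
#' @param window folding window size W
#' @param span maximal base pair span L (`<= window`)
#' @param model an [energy_model()]
#' @param floor probability floor; computed entries below it are
#'   discarded (the benchmark parameterization uses 0.5)
#' @return a [bpp_matrix()] with `max_span = span`
#' @export
local_partition_fold <- function(target, window = 200, span = 100,
                                 model = energy_model(), floor = 0.01) {
  code <- if (is.character(target)) encode_residues(target) else
    as.integer(target)
  n <- length(code)
  if (window < span) stop("window must be >= span", call. = FALSE)
  if (span < 1) stop("span must be >= 1", call. = FALSE)
  if (n < model$min_loop + 2) {
    return(bpp_matrix(max(n, 1), max_span = as.integer(span), p_min = floor))
  }
  res <- c_window_bpp(code, as.integer(window), as.integer(span),
                      model$pair_energy, model$min_loop,
                      model$no_lonely_pairs, model$rt, floor,
                      fold_scale(model), model$helix_init)
  p <- pmin(res$p, 1)
  # Averaging over per-pair window counts can push a position's total
  # pairing probability slightly above 1 (windows sliding over a locus
  # may favor different partners).  Rescale the entries of any such
  # position so the matrix stays substochastic.
  if (length(p) > 0) {
    tot <- rowsum(c(p, p), c(res$i, res$j))
    f <- setNames(pmin(1, 1 / tot[, 1]), rownames(tot))
    p <- p * pmin(f[as.character(res$i)], f[as.character(res$j)])
    keep <- p >= floor
    res$i <- res$i[keep]; res$j <- res$j[keep]; p <- p[keep]
  }
  bpp_matrix(n, res$i, res$j, unname(p), max_span = as.integer(span),
             p_min = floor)
}

# validity of a structure under the model; returns NULL or a reason
structure_violation <- function(code, pairs, model) {
  if (nrow(pairs) == 0) return(NULL)
  if (!noncrossing(pairs[, 1], pairs[, 2])) return("crossing base pairs")
  if (any(pairs[, 2] - pairs[, 1] - 1 < model$min_loop)) {
    return("pair violates the minimum loop size")
  }
  if (!all(is_canonical_code(code[pairs[, 1]], code[pairs[, 2]]))) {
    return("non-canonical base pair")
  }
  if (model$no_lonely_pairs) {
    key <- paste(pairs[, 1], pairs[, 2])
    support <- paste(pairs[, 1] + 1L, pairs[, 2] - 1L) %in% key |
      paste(pairs[, 1] - 1L, pairs[, 2] + 1L) %in% key
    if (!all(support)) return("lonely base pair")
  }
  NULL
}

#' Ensemble probability of a secondary structure
#'
#' `p(R) = exp(-E(R)/RT) / Z` with the partition function of the whole
#' sequence (single window, unlimited span).  Structures containing a
#' pair that cannot form under the model (non-canonical, crossing, too
#' small a loop, or lonely with `no_lonely_pairs`) have probability 0.
#'
#' @param target residue string or encoded vector
#' @param structure dot-bracket string or pair matrix
#' @param model an [energy_model()]
#' @return probability in `[0, 1]`
#' @export
structure_probability <- function(target, structure, model = energy_model()) {
  code <- if (is.character(target)) encode_residues(target) else
    as.integer(target)
  pairs <- if (is.character(structure)) db_pairs(structure) else structure
  if (!is.null(structure_violation(code, pairs, model))) return(0)
  c_structure_prob(code, pairs[, 1], pairs[, 2], model$pair_energy,
                   model$min_loop, model$no_lonely_pairs, model$rt,
                   fold_scale(model), model$helix_init)
}

#' Constrained minimum-energy structure
#'
#' Folds under the energy model with hard constraints: `(` and `)`
#' enforce the given base pairs, `x` forbids pairing of a position, and
#' `.` leaves a position unconstrained.  Returns the first optimum in a
#' fixed deterministic trace order.
#'
#' @param target residue string or encoded vector
#' @param constraint constraint string (same length as target), or
#'   `NULL` for unconstrained folding
#' @param model an [energy_model()]
#' @return list with `structure` (dot-bracket), `pairs`, `energy`
#' @export
constrained_fold <- function(target, constraint = NULL,
                             model = energy_model()) {
  code <- if (is.character(target)) encode_residues(target) else
    as.integer(target)
  n <- length(code)
  cons <- rep(-1L, n)
  forced <- matrix(integer(0), ncol = 2)
  if (!is.null(constraint)) {
    if (nchar(constraint) != n) {
      stop("constraint length != sequence length", call. = FALSE)
    }
    chars <- strsplit(constraint, "", fixed = TRUE)[[1]]
    cons[chars == "x"] <- -2L
    forced <- db_pairs(gsub("x", ".", constraint))
    if (nrow(forced) > 0) {
      bad <- !is_canonical_code(code[forced[, 1]], code[forced[, 2]])
      if (any(bad)) {
        stop("constraint enforces non-canonical pair(s) at positions ",
             paste(sprintf("(%d,%d)", forced[bad, 1], forced[bad, 2]),
                   collapse = ", "), call. = FALSE)
      }
      if (any(forced[, 2] - forced[, 1] - 1 < model$min_loop)) {
        stop("constraint violates the minimum loop size", call. = FALSE)
      }
      cons[forced[, 1]] <- forced[, 2] - 1L  # 0-based partner for C++
      cons[forced[, 2]] <- forced[, 1] - 1L
    }
  }
  res <- c_mfe_fold(code, cons, model$pair_energy, model$min_loop,
                    model$no_lonely_pairs, model$rt, model$helix_init)
  if (!res$forced_ok) {
    stop("constraint is infeasible under the energy model", call. = FALSE)
  }
  pairs <- cbind(i = res$i, j = res$j)
  if (nrow(pairs) > 0) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  list(structure = pairs_to_db(pairs, n), pairs = pairs,
       energy = res$energy)
}
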