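# Synthetic benchmark: cloverleaf structure templates, thermodynamically
# stabilized vs. non-stabilized decoys, pseudogenome assembly, and
# overlap-based evaluation of scan hits.
#
# All sampling uses R's RNG; callers seed with set.seed() for
# reproducibility.

#' Project an aligned row and consensus structure to an ungapped decoy
#'
#' Removes the gap columns of one alignment row together with the
#' corresponding symbols of the consensus dot-bracket; when this
#' deletes only one parenthesis of a pair, the surviving one becomes a
#' dot.
#'
#' @param aligned_row gapped sequence row (gap symbols `-` or `.`)
#' @param consensus consensus dot-bracket of the alignment
#' @return list with `sequence` and `structure` (both ungapped)
#' @export
project_structure <- function(aligned_row, consensus) {
  chars <- strsplit(toupper(aligned_row), "", fixed = TRUE)[[1]]
  if (nchar(consensus) != length(chars)) {
    stop("row and consensus must have equal length", call. = FALSE)
  }
  db <- strsplit(consensus, "", fixed = TRUE)[[1]]
  keep <- !(chars %in% c("-", "."))
  pairs <- db_pairs(consensus)
  if (nrow(pairs) > 0) {
    half <- xor(keep[pairs[, 1]], keep[pairs[, 2]])
    for (r in which(half)) {
      db[pairs[r, 1]] <- "."
      db[pairs[r, 2]] <- "."
    }
  }
  seq <- paste(chars[keep], collapse = "")
  seq <- gsub("T", "U", seq, fixed = TRUE)
  list(sequence = seq, structure = paste(db[keep], collapse = ""))
}

#' Random cloverleaf structure template
#'
#' Emulates drawing a tRNA-shaped consensus structure: an acceptor stem
#' of 6-8 bp enclosing three hairpin arms (stems 3-6 bp, loops 4-9 nt)
#' separated by short single-stranded linkers, with a short 3' tail;
#' total length 70-92 nt.
#'
#' @return object of class `structure_template`: `structure`
#'   (dot-bracket), `length`, `source`
#' @export
make_cloverleaf_template <- function() {
  for (try in 1:1000) {
    acc <- sample(6:8, 1)
    stems <- sample(3:6, 3, replace = TRUE)
    loops <- sample(4:9, 3, replace = TRUE)
    links <- sample(1:3, 3, replace = TRUE)
    varloop <- sample(0:2, 1)
    tail <- sample(4:7, 1)
    len <- 2 * acc + sum(2 * stems + loops) + sum(links) + varloop + tail
    if (len >= 70 && len <= 92) {
      arm <- function(h, l) {
        paste0(strrep("(", h), strrep(".", l), strrep(")", h))
      }
      db <- paste0(strrep("(", acc),
                   strrep(".", links[1]), arm(stems[1], loops[1]),
                   strrep(".", links[2]), arm(stems[2], loops[2]),
                   strrep(".", links[3]), arm(stems[3], loops[3]),
                   strrep(".", varloop),
                   strrep(")", acc), strrep(".", tail))
      return(structure(list(structure = db, length = nchar(db),
                            source = "cloverleaf"),
                       class = "structure_template"))
    }
  }
  stop("failed to sample a template in range", call. = FALSE)
}

#' Load a structure template from an aligned row
#'
#' The field-standard path when a structure-annotated alignment (e.g.
#' an Rfam seed) is available: project one row and its consensus
#' structure.
#'
#' @param aligned_row gapped row
#' @param consensus consensus dot-bracket
#' @return a `structure_template` (with the projected sequence in
#'   `sequence`)
#' @export
template_from_alignment <- function(aligned_row, consensus) {
  pr <- project_structure(aligned_row, consensus)
  structure(list(structure = pr$structure, length = nchar(pr$structure),
                 source = "alignment", sequence = pr$sequence),
            class = "structure_template")
}

#' Energy margin equivalent to a structure probability
#'
#' `delta_E = -RT * ln(p)`: a structure whose energy lies within
#' `delta_E` of the ensemble free energy has ensemble probability at
#' least `p`.
#'
#' @param p probability in (0, 1)
#' @param rt thermodynamic scale
#' @return energy difference
#' @export
p_equivalent_energy <- function(p, rt = 1) {
  stopifnot(p > 0, p < 1)
  -rt * log(p)
}

random_compatible_sequence <- function(pairs, len) {
  code <- sample(0:3, len, replace = TRUE)
  if (nrow(pairs) > 0) {
    can <- cbind(c(0L, 3L, 1L, 2L, 2L, 3L), c(3L, 0L, 2L, 1L, 3L, 2L))
    pick <- sample(6, nrow(pairs), replace = TRUE)
    code[pairs[, 1]] <- can[pick, 1]
    code[pairs[, 2]] <- can[pick, 2]
  }
  code
}

#' Design a thermodynamically stabilized decoy
#'
#' Inverse folding by a stochastic adaptive walk: starting from a
#' random sequence compatible with the template structure R (paired
#' positions canonical), single-position mutations (pair-preserving
#' double mutations at paired positions) are accepted whenever the
#' ensemble probability of R increases, until
#' `p(R) >= p_target` -- equivalently until the energy gap
#' `E(R|S) - F(S)` drops below `-RT ln(p_target)`.
#'
#' @param template a `structure_template`
#' @param model an [energy_model()]
#' @param p_target stopping probability (default 0.75)
#' @param max_iter proposals per walk
#' @param retry_max restarts before giving up
#' @return object of class `decoy`: `sequence`, `structure`,
#'   `class = "stabilized"`, `structure_probability`
#' @export
make_stabilized_decoy <- function(template, model = energy_model(),
                                  p_target = 0.75, max_iter = 4000,
                                  retry_max = 3) {
  stopifnot(p_target > 0, p_target < 1)
  pairs <- db_pairs(template$structure)
  len <- template$length
  partner <- rep(NA_integer_, len)
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]
  can <- cbind(c(0L, 3L, 1L, 2L, 2L, 3L), c(3L, 0L, 2L, 1L, 3L, 2L))
  for (attempt in seq_len(retry_max)) {
    code <- random_compatible_sequence(pairs, len)
    p <- structure_probability(code, pairs, model)
    it <- 0
    while (p < p_target && it < max_iter) {
      it <- it + 1
      pos <- sample.int(len, 1)
      cand <- code
      if (is.na(partner[pos])) {
        cand[pos] <- sample(0:3, 1)
      } else {
        pick <- can[sample.int(6, 1), ]
        a <- min(pos, partner[pos])
        b <- max(pos, partner[pos])
        cand[a] <- pick[1]
        cand[b] <- pick[2]
      }
      if (identical(cand, code)) next
      p2 <- structure_probability(cand, pairs, model)
      if (p2 > p) {
        code <- cand
        p <- p2
      }
    }
    if (p >= p_target) {
      return(structure(list(sequence = decode_residues(code),
                            structure = template$structure,
                            class = "stabilized",
                            structure_probability = p),
                       class = "decoy"))
    }
  }
  stop("inverse folding failed to reach p_target = ", p_target,
       " within ", retry_max, " restarts", call. = FALSE)
}

#' Generate a non-stabilized decoy
#'
#' Unpaired positions and left base pair ends are drawn i.i.d. from
#' `mono_freq`; right pair ends are the Watson-Crick complement of the
#' left end (GU disallowed).  The decoy admits the template's canonical
#' pairing but its thermodynamic stability is purely by chance.
#'
#' @param template a `structure_template`
#' @param mono_freq nucleotide distribution (A, C, G, U), typically the
#'   pooled frequencies of the stabilized set
#' @return object of class `decoy` with `class = "nonstabilized"`
#' @export
make_nonstabilized_decoy <- function(template, mono_freq) {
  stopifnot(length(mono_freq) == 4, abs(sum(mono_freq) - 1) < 1e-6)
  pairs <- db_pairs(template$structure)
  len <- template$length
  code <- sample(0:3, len, replace = TRUE, prob = mono_freq)
  if (nrow(pairs) > 0) {
    comp <- c(3L, 2L, 1L, 0L)  # A->U, C->G, G->C, U->A
    code[pairs[, 2]] <- comp[code[pairs[, 1]] + 1L]
  }
  structure(list(sequence = decode_residues(code),
                 structure = template$structure,
                 class = "nonstabilized",
                 structure_probability = NA_real_),
            class = "decoy")
}

#' Mononucleotide frequencies of a set of decoys
#' @param decoys list of `decoy` objects
#' @return numeric vector (A, C, G, U) summing to 1
#' @export
decoy_mono_freq <- function(decoys) {
  all <- unlist(lapply(decoys, function(d) {
    code <- encode_residues(d$sequence)
    code[code < 4]
  }))
  tabulate(all + 1L, 4) / length(all)
}

#' Assemble a pseudogenome from decoys
#'
#' Decoys are shuffled and placed one per `spacing`-block: decoy k
#' starts at position `(k-1) * spacing + 1`; gaps are padded i.i.d.
#' from `mono_freq`.  Genome length is `length(decoys) * spacing`.
#'
#' @param decoys list of `decoy` objects (each shorter than `spacing`)
#' @param spacing block length (default 200)
#' @param mono_freq padding nucleotide distribution
#' @param shuffle randomize decoy order
#' @return object of class `pseudogenome`: `sequence` and
#'   `annotations` (data.frame start, end, decoy_id, class, 1-based
#'   inclusive)
#' @export
build_pseudogenome <- function(decoys, spacing = 200,
                               mono_freq = rep(0.25, 4), shuffle = TRUE) {
  lens <- vapply(decoys, function(d) nchar(d$sequence), integer(1))
  if (any(lens > spacing)) {
    stop("decoy longer than spacing", call. = FALSE)
  }
  ord <- if (shuffle) sample(seq_along(decoys)) else seq_along(decoys)
  nblocks <- length(decoys)
  if (nblocks == 0) {
    return(structure(list(sequence = "", annotations = data.frame()),
                     class = "pseudogenome"))
  }
  seqs <- character(nblocks)
  ann <- data.frame(start = integer(nblocks), end = integer(nblocks),
                    decoy_id = character(nblocks), class = character(nblocks),
                    stringsAsFactors = FALSE)
  for (b in seq_len(nblocks)) {
    d <- decoys[[ord[b]]]
    dl <- nchar(d$sequence)
    pad <- spacing - dl
    padseq <- if (pad > 0) {
      decode_residues(sample(0:3, pad, replace = TRUE, prob = mono_freq))
    } else ""
    seqs[b] <- paste0(d$sequence, padseq)
    ann$start[b] <- (b - 1L) * spacing + 1L
    ann$end[b] <- (b - 1L) * spacing + dl
    ann$decoy_id[b] <- sprintf("decoy%03d", ord[b])
    ann$class[b] <- d$class
  }
  structure(list(sequence = paste(seqs, collapse = ""), annotations = ann),
            class = "pseudogenome")
}

#' Assign scan occurrences to decoys and evaluate class separation
#'
#' An occurrence counts for a decoy when it overlaps at least 10% of
#' the decoy's nucleotides; per decoy the best-scoring overlapping
#' occurrence is kept.  Reports the per-threshold recovery counts of
#' both classes and the ROC AUC of stabilized-vs-nonstabilized
#' separation by best score (missed decoys rank below every hit).
#'
#' @param occurrences data.frame with `left_end`, `j` (right end) and
#'   `score`
#' @param annotations pseudogenome annotation table
#' @param min_overlap minimal overlap fraction of the decoy length
#' @return list with `per_decoy` (annotations + best_score),
#'   `thresholds` (score, stabilized_found, nonstabilized_found) and
#'   `auc`
#' @export
evaluate_hits <- function(occurrences, annotations, min_overlap = 0.10) {
  nd <- nrow(annotations)
  best <- rep(-Inf, nd)
  occ <- occurrences[!is.na(occurrences$left_end), , drop = FALSE]
  for (r in seq_len(nrow(occ))) {
    ol <- pmin(occ$j[r], annotations$end) -
      pmax(occ$left_end[r], annotations$start) + 1
    dlen <- annotations$end - annotations$start + 1
    hit <- ol >= min_overlap * dlen
    best[hit] <- pmax(best[hit], occ$score[r])
  }
  per_decoy <- cbind(annotations, best_score = best)
  is_stab <- annotations$class == "stabilized"
  thr <- sort(unique(best[is.finite(best)]), decreasing = TRUE)
  thresholds <- data.frame(
    score = thr,
    stabilized_found = vapply(thr, function(t) sum(best[is_stab] >= t), 0),
    nonstabilized_found = vapply(thr, function(t) sum(best[!is_stab] >= t), 0))
  auc <- NA_real_
  if (any(is_stab) && any(!is_stab)) {
    rk <- rank(best)  # -Inf ties share the lowest ranks
    n1 <- sum(is_stab)
    n0 <- sum(!is_stab)
    auc <- (sum(rk[is_stab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(per_decoy = per_decoy, thresholds = thresholds, auc = auc)
}
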