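# Scoring model: parameters, query profiles, and the additive score of
# a sequence-structure alignment.
#
# All score contributions are natural-log log-odds, multiplied by 100
# and rounded half away from zero to integer centi-units.  The
# published parameterization (struct-weight = 200, tau = 400,
# indel = -100, indel-opening = -500) is expressed directly in these
# units: `struct_weight` is the centi-unit score of a certain base pair
# (probability 1), `tau_weight = tau/100` multiplies the pair sequence
# term, `gamma` and `gap_opening` are centi-unit gap costs.

#' Scoring parameters
#'
#' @param gamma gap score per gapped position, centi-units, negative
#' @param gap_opening additional score per maximal gap run,
#'   centi-units, `<= 0`; 0 gives the linear gap model
#' @param struct_weight centi-unit score of a base pair of probability
#'   1; multiplies the structure log-odds term
#' @param tau_weight multiplier on the paired-columns sequence term
#' @param p_min probability cutoff for admissible base pairs
#' @param max_span maximal span `j - i` of target base pairs; also the
#'   width of the scanner's memory band
#' @return object of class `score_params`
#' @export
score_params <- function(gamma = -100, gap_opening = -500,
                         struct_weight = 200, tau_weight = 4,
                         p_min = 0.01, max_span = 100) {
  stopifnot(gamma < 0, gap_opening <= 0, p_min > 0, p_min < 1,
            max_span >= 1, struct_weight >= 0, tau_weight >= 0)
  structure(list(gamma = round_half_away(gamma),
                 gap_opening = round_half_away(gap_opening),
                 struct_weight = struct_weight,
                 tau_weight = tau_weight,
                 p_min = p_min,
                 max_span = as.integer(max_span)),
            class = "score_params")
}

#' Query input: alignment rows plus optional consensus structure
#'
#' A single sequence is a one-row alignment.  Rows may contain gap
#' symbols `-` or `.`; all rows must have equal length, and the
#' consensus structure (dot-bracket) must have that length too.
#'
#' @param rows character vector of aligned rows
#' @param structure consensus dot-bracket string, or `NULL`
#' @param id query identifier
#' @return object of class `query_input`
#' @export
query_input <- function(rows, structure = NULL, id = "query") {
  stopifnot(length(rows) >= 1)
  m <- nchar(rows[1])
  if (m < 1) stop("query must have length >= 1", call. = FALSE)
  if (any(nchar(rows) != m)) {
    stop("all query alignment rows must have equal length", call. = FALSE)
  }
  rowmat <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  rowmat[rowmat == "T"] <- "U"
  ok <- rowmat %in% c(RNA_BASES, "N", "-", ".")
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop("invalid query symbol '", rowmat[bad], "'", call. = FALSE)
  }
  if (!is.null(structure)) {
    if (nchar(structure) != m) {
      stop("consensus structure length != alignment length", call. = FALSE)
    }
    db_pairs(structure)  # validates balance
  }
  structure(list(rows = rowmat, m = as.integer(m), structure = structure,
                 id = id), class = "query_input")
}

#' Base pair probability matrix of a known query structure
#'
#' The structure's base pairs get probability exactly 1; everything
#' else is absent.
#'
#' @param structure dot-bracket string
#' @param m structure length (defaults to `nchar(structure)`)
#' @return a [bpp_matrix()]
#' @export
query_bpp_from_structure <- function(structure, m = nchar(structure)) {
  pairs <- db_pairs(structure)
  bpp_matrix(m, pairs[, 1], pairs[, 2], rep(1, nrow(pairs)), max_span = NULL,
             p_min = 0)
}

#' Build a query profile
#'
#' Per-column nucleotide frequencies and per-pair-of-columns pair
#' frequencies with additive pseudocounts proportional to the
#' query-wide mononucleotide background (floored at 0.01 per
#' nucleotide).  Pair tables are computed only for columns paired in
#' `query_bpp`; observed non-canonical combinations are pooled into a
#' fixed floor mass of 1e-3.  Gap symbols and N are excluded from
#' counts; a column with no counted residue falls back to the uniform
#' background (with a warning if it is all gaps).
#'
#' @param query a [query_input()]
#' @param pseudocount_mass total pseudocount mass added per column
#' @param query_bpp a [bpp_matrix()] for the query; defaults to the
#'   matrix of the query's consensus structure (or no pairs)
#' @return object of class `query_profile`
#' @export
build_profile <- function(query, pseudocount_mass = 1, query_bpp = NULL) {
  stopifnot(inherits(query, "query_input"), pseudocount_mass >= 0)
  m <- query$m
  rows <- query$rows
  if (is.null(query_bpp)) {
    query_bpp <- if (!is.null(query$structure)) {
      query_bpp_from_structure(query$structure, m)
    } else {
      bpp_matrix(m)
    }
  }
  # query-wide mononucleotide background, floored and renormalized
  all_res <- rows[rows %in% RNA_BASES]
  bg <- if (length(all_res) > 0) {
    tabulate(match(all_res, RNA_BASES), 4) / length(all_res)
  } else {
    rep(0.25, 4)
  }
  bg <- pmax(bg, 0.01)
  bg <- bg / sum(bg)

  single <- matrix(0.25, nrow = 4, ncol = m,
                   dimnames = list(RNA_BASES, NULL))
  gap_only <- logical(m)
  for (k in seq_len(m)) {
    col <- rows[, k]
    cnt <- tabulate(match(col[col %in% RNA_BASES], RNA_BASES), 4)
    ng <- sum(cnt)
    if (ng == 0) {
      gap_only[k] <- all(col %in% c("-", "."))
      next  # background fallback
    }
    single[, k] <- (cnt + pseudocount_mass * bg) / (ng + pseudocount_mass)
  }
  if (any(gap_only)) {
    warning("query column(s) ", paste(which(gap_only), collapse = ","),
            " contain only gaps; using background frequencies",
            call. = FALSE)
  }

  # pair tables for (k,l) in the query bpp
  can_idx <- cbind(match(CANONICAL_PAIRS[, 1], RNA_BASES),
                   match(CANONICAL_PAIRS[, 2], RNA_BASES))
  bg_pair <- bg[can_idx[, 1]] * bg[can_idx[, 2]]
  bg_pair <- bg_pair / sum(bg_pair)
  nc_mass <- 1e-3
  npair <- length(query_bpp$i)
  pair_tables <- vector("list", npair)
  pair_uninformative <- logical(npair)
  for (t in seq_len(npair)) {
    k <- query_bpp$i[t]; l <- query_bpp$j[t]
    a <- rows[, k]; b <- rows[, l]
    both <- a %in% RNA_BASES & b %in% RNA_BASES
    tab <- matrix(0, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
    ncan <- 0
    if (any(both)) {
      ai <- match(a[both], RNA_BASES); bi <- match(b[both], RNA_BASES)
      can <- is_canonical_code(ai - 1L, bi - 1L)
      for (r in which(can)) tab[ai[r], bi[r]] <- tab[ai[r], bi[r]] + 1
      ncan <- sum(can)
    }
    f <- matrix(0, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
    if (!any(both) || (ncan == 0 && pseudocount_mass == 0)) {
      # no usable observations: uninformative column pair, tau == 0
      f[can_idx] <- 1 / 6
      pair_uninformative[t] <- TRUE
    } else {
      fc <- (tab[can_idx] + pseudocount_mass * bg_pair) /
        (ncan + pseudocount_mass)
      f[can_idx] <- fc * (1 - nc_mass)
      f[f == 0] <- nc_mass / 10
    }
    pair_tables[[t]] <- f
  }

  structure(list(m = m, single_freq = single, background = bg,
                 background_single = rep(0.25, 4),
                 pair_tables = pair_tables,
                 pair_uninformative = pair_uninformative,
                 pseudocount_mass = pseudocount_mass,
                 query_bpp = query_bpp, id = query$id),
            class = "query_profile")
}

#' Single-stranded sequence similarity (log-odds, centi-units)
#'
#' `sigma(t, k) = round(100 * ln(f_k(t) / (1/4)))`; N scores 0.
#'
#' @param t target nucleotide (character or code 0..4)
#' @param k query column index
#' @param profile a query profile (see [build_profile()])
#' @return centi-unit score
#' @export
sigma_score <- function(t, k, profile) {
  if (is.character(t)) t <- encode_residues(t)
  if (t >= 4) return(0)
  f <- unname(profile$single_freq[t + 1L, k])
  round_half_away(100 * log(f / 0.25))
}

#' Paired-columns sequence similarity (log-odds, centi-units)
#'
#' `tau = tau_weight * round(100 * ln(f_kl(t, t') / (1/6)))`; the
#' unweighted term is discretized first so that integer weights scale
#' centi-units exactly.  Uninformative pair columns (no observed
#' residues) score 0 for every input pair.
#'
#' @param t,t2 target nucleotides at the pair ends
#' @param k,l query column indices; `(k, l)` must be a pair of the
#'   profile's query bpp
#' @param profile a query profile (see [build_profile()])
#' @param tau_weight weight (defaults to 1)
#' @return centi-unit score
#' @export
tau_score <- function(t, t2, k, l, profile, tau_weight = 1) {
  if (is.character(t)) t <- encode_residues(t)
  if (is.character(t2)) t2 <- encode_residues(t2)
  if (t >= 4 || t2 >= 4) return(0)
  idx <- which(profile$query_bpp$i == k & profile$query_bpp$j == l)
  if (length(idx) != 1) {
    stop("(", k, ",", l, ") is not a pair of the query bpp", call. = FALSE)
  }
  if (profile$pair_uninformative[idx]) return(0)
  f <- unname(profile$pair_tables[[idx]][t + 1L, t2 + 1L])
  base <- round_half_away(100 * log(f / (1 / 6)))
  round_half_away(tau_weight * base)
}

#' Structure term from a base pair probability (centi-units)
#'
#' `psi(p) = struct_weight * ln(p / p_min) / ln(1 / p_min)` for
#' `p >= p_min` (so `psi` ranges in (0, struct_weight]); below the
#' cutoff the reserved minus-infinity sentinel (`-Inf` at the R level).
#'
#' @param p base pair probability (or a vector)
#' @param params a [score_params()]
#' @return centi-unit score(s); `-Inf` below `p_min`
#' @export
psi_score <- function(p, params) {
  out <- round_half_away(params$struct_weight * log(p / params$p_min) /
                           log(1 / params$p_min))
  out[p < params$p_min] <- -Inf
  out
}

# ---- alignment / consensus structure validation and direct scoring ----

validate_alignment <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0) return(invisible(TRUE))
  ord <- order(edges[, 1])
  e <- edges[ord, , drop = FALSE]
  if (anyDuplicated(e[, 1]) || anyDuplicated(e[, 2])) {
    stop("alignment edges must be one-to-one", call. = FALSE)
  }
  if (is.unsorted(e[, 2], strictly = TRUE)) {
    stop("alignment edges must be monotone (non-crossing)", call. = FALSE)
  }
  invisible(TRUE)
}

noncrossing <- function(i, j) {
  # pairs (i, j), i < j: no sharing of ends, no crossing
  if (length(i) <= 1) return(TRUE)
  if (anyDuplicated(c(i, j))) return(FALSE)
  ord <- order(i)
  i <- i[ord]; j <- j[ord]
  for (a in seq_along(i)) {
    for (b in seq_len(a - 1)) {
      # b opened before a
      if (i[b] < i[a] && i[a] < j[b] && j[b] < j[a]) return(FALSE)
    }
  }
  TRUE
}

validate_consensus <- function(spairs, edges) {
  if (is.null(spairs) || nrow(spairs) == 0) return(invisible(TRUE))
  if (!noncrossing(spairs[, 1], spairs[, 2]) ||
      !noncrossing(spairs[, 3], spairs[, 4])) {
    stop("consensus structure is crossing or shares pair ends",
         call. = FALSE)
  }
  key <- paste(edges[, 1], edges[, 2])
  need <- c(paste(spairs[, 1], spairs[, 3]), paste(spairs[, 2], spairs[, 4]))
  if (!all(need %in% key)) {
    stop("consensus structure inconsistent with alignment", call. = FALSE)
  }
  invisible(TRUE)
}

gap_run_cost <- function(unmatched, gamma, gap_opening) {
  # unmatched: logical vector over the scored range
  if (length(unmatched) == 0 || !any(unmatched)) return(0)
  runs <- rle(unmatched)
  nrun <- sum(runs$values)
  gamma * sum(unmatched) + gap_opening * nrun
}

#' Score of a sequence-structure alignment
#'
#' Evaluates the additive score of a consistent pair (A, S): structure
#' terms `psi_T + psi_Q + tau` per matched base pair, `sigma` per
#' remaining alignment edge, and affine gap costs.  In semi-global mode
#' target deletions outside `[min i, max i]` are free; in global mode
#' all positions count.
#'
#' @param edges integer matrix, columns (i, k): target position, query
#'   column; may have zero rows
#' @param spairs integer matrix, columns (i, j, k, l): matched base
#'   pairs; may be `NULL`
#' @param target target residue string (or encoded vector)
#' @param target_bpp a [bpp_matrix()] for the target
#' @param profile a query profile (see [build_profile()])
#' @param params a [score_params()]
#' @param mode `"semiglobal"`, `"global"`, or `"free_left"` (the prefix
#'   subscore with free deletions only at the target's left end)
#' @param n target length (defaults to `target_bpp$length`)
#' @return centi-unit score
#' @export
total_score <- function(edges, spairs, target, target_bpp, profile, params,
                        mode = c("semiglobal", "global", "free_left"),
                        n = target_bpp$length) {
  mode <- match.arg(mode)
  tcode <- if (is.character(target)) encode_residues(target) else target
  m <- profile$m
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  validate_alignment(edges)
  if (!is.null(spairs) && nrow(spairs) > 0) validate_consensus(spairs, edges)

  sc <- 0
  pair_end_edges <- character(0)
  if (!is.null(spairs) && nrow(spairs) > 0) {
    for (r in seq_len(nrow(spairs))) {
      i <- spairs[r, 1]; j <- spairs[r, 2]
      k <- spairs[r, 3]; l <- spairs[r, 4]
      pt <- target_bpp$p[target_bpp$i == i & target_bpp$j == j]
      pq <- profile$query_bpp$p[profile$query_bpp$i == k &
                                  profile$query_bpp$j == l]
      if (length(pt) != 1 || length(pq) != 1) {
        stop("consensus pair not present in the bpp matrices", call. = FALSE)
      }
      sc <- sc + psi_score(pt, params) + psi_score(pq, params) +
        tau_score(tcode[i], tcode[j], k, l, profile, params$tau_weight)
      pair_end_edges <- c(pair_end_edges, paste(i, k), paste(j, l))
    }
  }
  if (nrow(edges) > 0) {
    single <- !(paste(edges[, 1], edges[, 2]) %in% pair_end_edges)
    for (r in which(single)) {
      sc <- sc + sigma_score(tcode[edges[r, 1]], edges[r, 2], profile)
    }
  }
  # gaps
  tmatched <- rep(FALSE, n)
  qmatched <- rep(FALSE, m)
  if (nrow(edges) > 0) {
    tmatched[edges[, 1]] <- TRUE
    qmatched[edges[, 2]] <- TRUE
  }
  trange <- if (nrow(edges) == 0) {
    if (mode == "global") seq_len(n) else integer(0)
  } else {
    switch(mode,
           semiglobal = seq(min(edges[, 1]), max(edges[, 1])),
           free_left = seq(min(edges[, 1]), n),
           global = seq_len(n))
  }
  sc <- sc + gap_run_cost(!tmatched[trange], params$gamma, params$gap_opening)
  sc <- sc + gap_run_cost(!qmatched, params$gamma, params$gap_opening)
  sc
}
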