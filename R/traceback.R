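# Recovering occurrence alignments by bounded recomputation.
#
# The scan stores no matrices; for a reported right end j we bound the
# occurrence length, recompute the S* block over the bounded region
# (and the D entries it can reach) and trace deterministically through
# the matrices, recomputing S slices on the trace.

#' Bound on the query/occurrence length difference
#'
#' `Delta = max(0, ceil((s_j - m * max(sigma_max, tau_max / 2)) /
#' gamma))`, where `sigma_max` is the maximal single-base match score
#' and `tau_max` the maximal base-pair match contribution including
#' both sequence (tau) and structure (psi) terms.  The occurrence
#' length is then searched within `[m - Delta, m + Delta]`.
#'
#' @param s_j recorded occurrence score (centi-units)
#' @param m query length
#' @param params a [score_params()]
#' @param sigma_max,tau_max instantiated score maxima (see
#'   [score_maxima()])
#' @return nonnegative integer Delta
#' @export
length_bound <- function(s_j, m, params, sigma_max, tau_max) {
  best_per_col <- max(sigma_max, tau_max / 2)
  if (!is.finite(best_per_col)) best_per_col <- sigma_max
  max(0, ceiling((s_j - m * best_per_col) / params$gamma))
}

#' Score maxima of an instantiated scan
#'
#' @param result a `scan_result`
#' @return list with `sigma_max` (maximal single-base match) and
#'   `tau_max` (maximal pair match: tau + psi_T + psi_Q); `tau_max` is
#'   `-Inf` when either side has no admissible pairs
#' @export
score_maxima <- function(result) {
  sigma_max <- max(result$sigma_table[1:4, , drop = FALSE])
  tau_max <- -Inf
  nq <- length(result$qpairs$k)
  if (nq > 0 && length(result$tpairs$i) > 0) {
    max_psi_t <- max(result$tpairs$psi)
    per_q <- vapply(seq_len(nq), function(t) {
      result$qpairs$psi[t] + max(result$tau_tables[t, ])
    }, numeric(1))
    tau_max <- max_psi_t + max(per_q)
  }
  list(sigma_max = sigma_max, tau_max = tau_max)
}

#' Recover the alignment of a reported occurrence
#'
#' Recomputes `S*` over the bounded region and traces the occurrence
#' with right end `j`.  The recomputed `S*(j, m)` must equal the
#' recorded score exactly; a mismatch is a fatal internal error
#' (it would indicate a scoring or bound bug).
#'
#' @param result a `scan_result` from [scan_target()]
#' @param j occurrence right end
#' @param s_j recorded score; defaults to the stored trace value
#' @return list with `left_end`, `delta`, `region_start`, `score`,
#'   `edges` (matrix i, k), `pairs` (matrix i, j, k, l) and rendered
#'   alignment strings `aln_target`, `aln_query`, `aln_structure`
#' @export
trace_occurrence <- function(result, j, s_j = NULL) {
  if (is.null(s_j)) {
    if (is.null(result$score_trace)) {
      stop("no stored score trace; supply s_j", call. = FALSE)
    }
    s_j <- result$score_trace[j]
  }
  m <- result$m
  mx <- score_maxima(result)
  delta <- length_bound(s_j, m, result$params, mx$sigma_max, mx$tau_max)
  i0 <- max(1, j - m - delta)
  nq <- length(result$qpairs$k)
  res <- c_traceback(result$target_code, m,
                     matrix(as.numeric(result$sigma_table), nrow = 5),
                     as.integer(result$tpairs$i),
                     as.integer(result$tpairs$j),
                     as.numeric(result$tpairs$psi),
                     as.integer(result$qpairs$k),
                     as.integer(result$qpairs$l),
                     as.numeric(result$qpairs$psi),
                     matrix(as.numeric(result$tau_tables),
                            nrow = max(nq, 1))[seq_len(nq), , drop = FALSE],
                     result$params$gamma, result$params$gap_opening,
                     result$params$max_span, as.integer(j), as.integer(i0))
  if (!isTRUE(all.equal(res$score, s_j))) {
    stop("internal consistency error: recomputed S*(", j, ",", m, ") = ",
         res$score, " differs from recorded score ", s_j, call. = FALSE)
  }
  edges <- cbind(i = res$edge_i, k = res$edge_k)
  if (nrow(edges) > 0) edges <- edges[order(edges[, 1]), , drop = FALSE]
  pairs <- cbind(i = res$pair_ti, j = res$pair_tj,
                 k = res$pair_qk, l = res$pair_ql)
  left_end <- if (nrow(edges) > 0) min(edges[, 1]) else NA_integer_
  aln <- render_alignment(result, j, edges, pairs, left_end)
  list(left_end = left_end, delta = delta, region_start = i0,
       score = res$score, edges = edges, pairs = pairs,
       aln_target = aln$target, aln_query = aln$query,
       aln_structure = aln$structure)
}

# Render target/query/structure rows of an occurrence alignment.
render_alignment <- function(result, j, edges, pairs, left_end) {
  if (is.na(left_end)) {
    return(list(target = "", query = "", structure = ""))
  }
  tchars <- strsplit(decode_residues(result$target_code), "", fixed = TRUE)[[1]]
  m <- result$m
  # query consensus characters: majority residue of the profile column
  qcons <- vapply(seq_len(m), function(k) {
    f <- result$profile$single_freq[, k]
    if (!result$seq_scores || max(f) <= 0.25 + 1e-9) "N" else
      RNA_BASES[which.max(f)]
  }, character(1))
  qdb <- rep(".", m)
  if (nrow(pairs) > 0) {
    qdb[pairs[, 3]] <- "("
    qdb[pairs[, 4]] <- ")"
  }
  trow <- character(0)
  qrow <- character(0)
  srow <- character(0)
  ti <- left_end
  qi <- 1L
  er <- 1L
  edge_i <- edges[, 1]
  edge_k <- edges[, 2]
  while (ti <= j || qi <= m) {
    if (er <= length(edge_i) && ti == edge_i[er] && qi == edge_k[er]) {
      trow <- c(trow, tchars[ti])
      qrow <- c(qrow, qcons[qi])
      srow <- c(srow, qdb[qi])
      ti <- ti + 1L
      qi <- qi + 1L
      er <- er + 1L
    } else if (er <= length(edge_i) && ti < edge_i[er] || qi > m) {
      if (ti > j) break
      trow <- c(trow, tchars[ti])
      qrow <- c(qrow, "-")
      srow <- c(srow, "-")
      ti <- ti + 1L
    } else {
      trow <- c(trow, "-")
      qrow <- c(qrow, qcons[qi])
      srow <- c(srow, qdb[qi])
      qi <- qi + 1L
    }
  }
  list(target = paste(trow, collapse = ""),
       query = paste(qrow, collapse = ""),
       structure = paste(srow, collapse = ""))
}

#' Annotate pruned occurrences with left ends and alignments
#'
#' Runs [trace_occurrence()] for each row of an occurrence table.
#'
#' @param result a `scan_result`
#' @param occurrences data.frame with `j`, `score`
#' @return the table extended by `left_end`, `aln_target`, `aln_query`,
#'   `aln_structure`
#' @export
trace_occurrences <- function(result, occurrences) {
  n <- nrow(occurrences)
  occurrences$left_end <- rep(NA_integer_, n)
  occurrences$aln_target <- rep(NA_character_, n)
  occurrences$aln_query <- rep(NA_character_, n)
  occurrences$aln_structure <- rep(NA_character_, n)
  for (r in seq_len(n)) {
    tr <- trace_occurrence(result, occurrences$j[r], occurrences$score[r])
    occurrences$left_end[r] <- tr$left_end
    occurrences$aln_target[r] <- tr$aln_target
    occurrences$aln_query[r] <- tr$aln_query
    occurrences$aln_structure[r] <- tr$aln_structure
  }
  occurrences
}
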