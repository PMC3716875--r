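# The scanning front end: builds the discretized score tables from a
# profile and parameters and drives the banded DP engine.

# sigma table: 5 x m centi-unit matrix (rows A,C,G,U,N)
profile_sigma_table <- function(profile, seq_scores = TRUE) {
  m <- profile$m
  tab <- matrix(0, nrow = 5, ncol = m)
  if (seq_scores) {
    for (b in 0:3) {
      tab[b + 1, ] <- round_half_away(100 * log(profile$single_freq[b + 1, ] /
                                                  0.25))
    }
  }
  tab
}

# tau tables: n_query_pairs x 16 centi-unit matrix (index t*4 + t2)
profile_tau_tables <- function(profile, tau_weight, seq_scores = TRUE) {
  nq <- length(profile$query_bpp$i)
  tab <- matrix(0, nrow = max(nq, 1), ncol = 16)
  if (nq == 0) return(tab[0, , drop = FALSE])
  if (seq_scores) {
    for (t in seq_len(nq)) {
      if (profile$pair_uninformative[t]) next
      f <- profile$pair_tables[[t]]
      base <- round_half_away(100 * log(f / (1 / 6)))
      tab[t, ] <- round_half_away(tau_weight * as.vector(t(base)))
    }
  }
  tab[seq_len(nq), , drop = FALSE]
}

#' Run the scanning DP on raw score tables
#'
#' Low-level entry point used by [scan_target()] and by tests that need
#' full control over the scoring functions (arbitrary finite sigma /
#' tau / psi tables).  All scores are integer centi-units.
#'
#' @param target_code encoded target residues (0..4; see
#'   [encode_residues()])
#' @param m query length
#' @param sigma_table 5 x m matrix of single-position scores
#' @param tpairs data.frame/list with `i`, `j`, `psi` for target pairs
#'   (span <= `max_span`)
#' @param qpairs data.frame/list with `k`, `l`, `psi` for query pairs
#' @param tau_tables matrix `nrow(qpairs) x 16` of pair sequence scores
#'   indexed by `4 * t + t2` (0-based codes)
#' @param gamma,gap_opening centi-unit gap costs
#' @param max_span band width L
#' @param global use global instead of semi-global initialization (for
#'   consistency checks)
#' @return list with `sj` (score trace, length n), `peak_live`
#'   (instrumented peak number of simultaneously live DP entries) and
#'   `cells` (DP cells evaluated)
#' @export
scan_engine <- function(target_code, m, sigma_table, tpairs, qpairs,
                        tau_tables, gamma, gap_opening, max_span,
                        global = FALSE) {
  stopifnot(nrow(sigma_table) == 5, ncol(sigma_table) == m)
  n <- length(target_code)
  nt <- length(tpairs$i)
  nq <- length(qpairs$k)
  if (nt > 0) {
    if (any(tpairs$i < 1 | tpairs$j > n | tpairs$i >= tpairs$j)) {
      stop("target pairs must satisfy 1 <= i < j <= n", call. = FALSE)
    }
    if (any(tpairs$j - tpairs$i > max_span)) {
      stop("target pair span exceeds max_span", call. = FALSE)
    }
    if (anyDuplicated(paste(tpairs$i, tpairs$j))) {
      stop("duplicate target pairs", call. = FALSE)
    }
  }
  if (nq > 0) {
    if (any(qpairs$k < 1 | qpairs$l > m | qpairs$k >= qpairs$l)) {
      stop("query pairs must satisfy 1 <= k < l <= m", call. = FALSE)
    }
    if (anyDuplicated(paste(qpairs$k, qpairs$l))) {
      stop("duplicate query pairs", call. = FALSE)
    }
  }
  if (is.null(tau_tables) || nrow(tau_tables) != nq) {
    stop("tau_tables must have one row per query pair", call. = FALSE)
  }
  c_scan(as.integer(target_code), as.integer(m),
         matrix(as.numeric(sigma_table), nrow = 5),
         as.integer(tpairs$i %||% integer(0)),
         as.integer(tpairs$j %||% integer(0)),
         as.numeric(tpairs$psi %||% numeric(0)),
         as.integer(qpairs$k %||% integer(0)),
         as.integer(qpairs$l %||% integer(0)),
         as.numeric(qpairs$psi %||% numeric(0)),
         matrix(as.numeric(tau_tables), nrow = max(nq, 1))[seq_len(nq), ,
                                                           drop = FALSE],
         gamma, gap_opening, as.integer(max_span), isTRUE(global))
}

#' Scan a target for occurrences of a structure-annotated query
#'
#' One left-to-right pass computes the semi-global prefix scores
#' `s_j = S*(j, m)` for every target position: the best score of an
#' alignment of the full query against a target subsequence ending at
#' `j`, combining sequence log-odds, structure log-odds of matched base
#' pairs, and affine gap costs.  Peak memory depends on
#' `params$max_span` and the query length only.
#'
#' @param target residue string or encoded vector
#' @param target_bpp a [bpp_matrix()] with the target's base pair
#'   probabilities (span-limited)
#' @param profile a query profile (see [build_profile()])
#' @param params a [score_params()]
#' @param seq_scores use sequence information (sigma and tau); if
#'   `FALSE` both are identically 0 and scanning is structure-only
#' @param target_id identifier carried into reports
#' @param keep_trace keep the full score trace in the result
#' @return object of class `scan_result`: the score trace, the engine
#'   instrumentation, and the inputs needed for traceback
#' @export
scan_target <- function(target, target_bpp, profile,
                        params = score_params(), seq_scores = TRUE,
                        target_id = "target", keep_trace = TRUE) {
  code <- if (is.character(target)) encode_residues(target) else
    as.integer(target)
  n <- length(code)
  if (n < 1) stop("target must have length >= 1", call. = FALSE)
  L <- params$max_span

  # admissible target pairs: above p_min, within span, no N end
  ti <- target_bpp$i; tj <- target_bpp$j; tp <- target_bpp$p
  keep <- tp >= params$p_min & (tj - ti) <= L &
    code[ti] < 4L & code[tj] < 4L
  tpairs <- list(i = ti[keep], j = tj[keep],
                 psi = psi_score(tp[keep], params))
  qb <- profile$query_bpp
  qkeep <- qb$p >= params$p_min
  qpairs <- list(k = qb$i[qkeep], l = qb$j[qkeep],
                 psi = psi_score(qb$p[qkeep], params))
  qpair_rows <- which(qkeep)

  sig <- profile_sigma_table(profile, seq_scores)
  tau <- profile_tau_tables(profile, params$tau_weight, seq_scores)
  tau <- tau[qpair_rows, , drop = FALSE]

  eng <- scan_engine(code, profile$m, sig, tpairs, qpairs, tau,
                     params$gamma, params$gap_opening, L)
  structure(list(target_id = target_id, n = n, m = profile$m,
                 score_trace = if (keep_trace) eng$sj else NULL,
                 peak_live = eng$peak_live, cells = eng$cells,
                 params = params, profile = profile,
                 seq_scores = seq_scores,
                 target_code = code, sigma_table = sig,
                 tpairs = tpairs, qpairs = qpairs, tau_tables = tau),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("scan_result:", x$target_id, "(n =", x$n, ", m =", x$m, ")\n")
  if (!is.null(x$score_trace)) {
    cat("  best s_j:", max(x$score_trace) / 100, "at j =",
        which.max(x$score_trace), "\n")
  }
  cat("  peak live DP entries:", x$peak_live, "; cells:", x$cells, "\n")
  invisible(x)
}

# Global subscore of one S block (test hook for the slice recursion)
subscore_block <- function(target_code, m, sigma_table, tpairs, qpairs,
                           tau_tables, gamma, gap_opening, max_span,
                           i, j, k, l) {
  nq <- length(qpairs$k)
  c_subscore(as.integer(target_code), as.integer(m),
             matrix(as.numeric(sigma_table), nrow = 5),
             as.integer(tpairs$i %||% integer(0)),
             as.integer(tpairs$j %||% integer(0)),
             as.numeric(tpairs$psi %||% numeric(0)),
             as.integer(qpairs$k %||% integer(0)),
             as.integer(qpairs$l %||% integer(0)),
             as.numeric(qpairs$psi %||% numeric(0)),
             matrix(as.numeric(tau_tables), nrow = max(nq, 1))[seq_len(nq), ,
                                                               drop = FALSE],
             gamma, gap_opening, as.integer(max_span),
             as.integer(i), as.integer(j), as.integer(k), as.integer(l))
}
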