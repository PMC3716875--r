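# Streaming occurrence reporting: local maxima of the score trace,
# online domination pruning with a bounded list, top-K selection, and
# empirical significance from an affine fit to the right tail of the
# locally-maximal score distribution.

#' Local maxima of a score trace
#'
#' Emits the positions `j` with `s_j >= max(s_{j-1}, s_{j+1})`;
#' missing neighbors at the boundaries count as `-Inf` (every point of
#' a plateau qualifies; domination pruning resolves plateaus).
#'
#' @param s numeric score vector (`s_j`, j = 1..n)
#' @return data.frame with columns `j`, `score`
#' @export
local_maxima <- function(s) {
  n <- length(s)
  if (n == 0) return(data.frame(j = integer(0), score = numeric(0)))
  left <- c(-Inf, s[-n])
  right <- c(s[-1], -Inf)
  keep <- s >= pmax(left, right) & is.finite(s)
  data.frame(j = which(keep), score = s[keep])
}

#' Domination between nearby occurrences
#'
#' `j` dominates `j2` iff they lie within query length `m` of each
#' other and `s_j > s_j2`, or the scores are equal and `j < j2`.
#'
#' @param j,j2 positions
#' @param s_j,s_j2 their scores
#' @param m query length (distance threshold)
#' @return logical
#' @export
dominates <- function(j, j2, s_j, s_j2, m) {
  abs(j - j2) <= m & (s_j > s_j2 | (s_j == s_j2 & j < j2))
}

#' Online pruning of dominated local maxima
#'
#' Streams over the local maxima in position order keeping a short
#' list that satisfies three invariants: entries increase in position,
#' successive entries are at most `m` apart, and scores strictly
#' increase.  When a new maximum is at distance `> m` from the list's
#' last entry the list is resolved: the last entry is reported, the
#' entries it dominates are dropped, and the procedure repeats;
#' reporting never needs memory beyond the list.
#'
#' @param maxima data.frame with `j`, `score` (as from
#'   [local_maxima()]), in increasing `j`
#' @param m query length
#' @return data.frame with `j`, `score` of the non-dominated maxima
#'   (sorted by `j`); attribute `max_list_length` carries the peak list
#'   length for the memory-bound diagnostics
#' @export
online_prune <- function(maxima, m) {
  lj <- numeric(0)
  ls <- numeric(0)
  out_j <- numeric(0)
  out_s <- numeric(0)
  maxlen <- 0
  resolve <- function() {
    while (length(lj) > 0) {
      last <- length(lj)
      out_j <<- c(out_j, lj[last])
      out_s <<- c(out_s, ls[last])
      dom <- dominates(lj[last], lj, ls[last], ls, m)
      dom[last] <- TRUE
      lj <<- lj[!dom]
      ls <<- ls[!dom]
    }
  }
  for (r in seq_len(nrow(maxima))) {
    j <- maxima$j[r]
    s <- maxima$score[r]
    if (length(lj) > 0 && j - m > lj[length(lj)]) resolve()
    if (length(lj) == 0 || !dominates(lj[length(lj)], j, ls[length(ls)], s, m)) {
      lj <- c(lj, j)
      ls <- c(ls, s)
      maxlen <- max(maxlen, length(lj))
    }
  }
  resolve()
  ord <- order(out_j)
  structure(data.frame(j = out_j[ord], score = out_s[ord]),
            max_list_length = maxlen)
}

#' Keep the K best occurrences
#'
#' Retains the `K` best-scoring occurrences; at the cut, ties are
#' broken by evicting the larger position first (smaller `j` kept).
#'
#' @param occurrences data.frame with `j`, `score`
#' @param k maximal number kept; `Inf` for unlimited
#' @return data.frame sorted by decreasing score (then increasing `j`)
#' @export
top_k <- function(occurrences, k = Inf) {
  ord <- order(-occurrences$score, occurrences$j)
  occurrences[head(ord, n = if (is.finite(k)) k else nrow(occurrences)), ,
              drop = FALSE]
}

#' Affine fit to the right tail of the locally-maximal score histogram
#'
#' Standard score distributions fit the empirical scan-score histogram
#' poorly; for calling extreme scores it suffices to approximate the
#' right tail, which is well described by an affine function of the
#' score on a log survival-count scale.  Fits least squares of
#' `log10(#\{maxima with score >= s\})` against `s` over the top
#' `tail_fraction` of scores.
#'
#' @param scores numeric vector of locally maximal scores, or a
#'   data.frame with columns `score`, `count` (a histogram)
#' @param tail_fraction fraction of the histogram mass used (default
#'   0.05)
#' @return object of class `tail_fit` with `slope`, `intercept`,
#'   `tail_fraction`, `effective_trials`; `NULL` (with a warning) when
#'   fewer than 30 scores are available
#' @export
fit_tail <- function(scores, tail_fraction = 0.05) {
  if (is.data.frame(scores)) {
    hist <- scores[order(scores$score), , drop = FALSE]
  } else {
    tb <- table(scores)
    hist <- data.frame(score = as.numeric(names(tb)),
                       count = as.numeric(tb))
  }
  ntot <- sum(hist$count)
  if (ntot < 30) {
    warning("fewer than 30 locally maximal scores; ",
            "significance estimation disabled", call. = FALSE)
    return(NULL)
  }
  surv <- rev(cumsum(rev(hist$count)))
  ntail <- max(2, ceiling(tail_fraction * ntot))
  use <- which(surv <= ntail)
  if (length(use) < 2) use <- seq(nrow(hist) - 1, nrow(hist))
  fit <- lm(log10(surv[use]) ~ hist$score[use])
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 tail_fraction = tail_fraction,
                 effective_trials = ntot),
            class = "tail_fit")
}

#' E-value of a score under an affine tail fit
#'
#' `evalue(s) = min(effective_trials, 10^(intercept + slope * s))`.
#'
#' @param fit a `tail_fit` (or `NULL`, giving `NA`)
#' @param s score(s), centi-units
#' @return expected number of locally maximal scores `>= s`
#' @export
evalue <- function(fit, s) {
  if (is.null(fit)) return(rep(NA_real_, length(s)))
  pmin(fit$effective_trials, 10^(fit$intercept + fit$slope * s))
}

#' Write occurrences as tab-separated hits
#'
#' One line per occurrence: target id, left end, right end, score
#' (centi-units rendered as a decimal), e-value and, when traceback
#' has been run, the aligned target row, query consensus row and
#' consensus structure.  Header lines prefixed `#` carry parameters
#' and calibration constants.
#'
#' @param occurrences data.frame with at least `j`, `score`; optional
#'   `left_end`, `evalue`, `aln_target`, `aln_query`, `aln_structure`
#' @param path output file
#' @param target_id target identifier
#' @param params a [score_params()] (for the header)
#' @param fit optional `tail_fit` (for the header)
#' @export
write_hits <- function(occurrences, path, target_id = "target",
                       params = NULL, fit = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    writeLines(sprintf(
      "# gamma=%g gap_opening=%g struct_weight=%g tau_weight=%g p_min=%g max_span=%d",
      params$gamma, params$gap_opening, params$struct_weight,
      params$tau_weight, params$p_min, params$max_span), con)
  }
  if (!is.null(fit)) {
    writeLines(sprintf(
      "# tail_fit slope=%.10g intercept=%.10g effective_trials=%d",
      fit$slope, fit$intercept, fit$effective_trials), con)
  }
  writeLines(paste("# target", "left_end", "right_end", "score", "evalue",
                   "aln_target", "aln_query", "aln_structure", sep = "\t"),
             con)
  n <- nrow(occurrences)
  if (n == 0) return(invisible(path))
  get <- function(col, default) {
    if (col %in% names(occurrences)) occurrences[[col]] else
      rep(default, n)
  }
  lines <- paste(target_id,
                 get("left_end", NA),
                 occurrences$j,
                 sprintf("%.2f", occurrences$score / 100),
                 ifelse(is.na(get("evalue", NA)), "NA",
                        sprintf("%.3g", get("evalue", NA))),
                 get("aln_target", "."),
                 get("aln_query", "."),
                 get("aln_structure", "."), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write occurrences as BED6
#'
#' Coordinates are converted to 0-based half-open at this writer
#' boundary only; everything internal stays 1-based inclusive.
#'
#' @param occurrences data.frame with `left_end`, `j`, `score`
#' @param path output file
#' @param target_id chromosome/sequence name
#' @export
write_bed <- function(occurrences, path, target_id = "target") {
  occ <- occurrences[!is.na(occurrences$left_end), , drop = FALSE]
  lines <- paste(target_id,
                 occ$left_end - 1L,     # 0-based start
                 occ$j,                 # half-open end
                 sprintf("occ%d", seq_len(nrow(occ))),
                 round(occ$score / 100),
                 "+", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
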