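# Independent oracles used across the suite.  These deliberately share
# no code with the package engines: alignment scores come from direct
# enumeration of (A, S) pairs under the additive score definition, and
# folding quantities from exhaustive enumeration of secondary
# structures.

# ---- alignment-scoring oracle -------------------------------------

# Best score over all alignments A (monotone matchings) and consistent
# consensus structures S, scored directly from the instantiated tables.
# mode:
#   free_left  - prefix subscore for 1..n with free left-end target
#                deletions (the quantity s_n = S*(n, m))
#   semiglobal - free deletions at both target ends (max_j s_j)
#   global     - all gaps scored
oracle_enumerate <- function(n, m, sigma_table, tpairs, qpairs, tau_tables,
                             gamma, gap_opening, tcode,
                             mode = c("free_left", "semiglobal", "global")) {
  mode <- match.arg(mode)
  best <- -Inf
  nt <- length(tpairs$i)
  nq <- length(qpairs$k)
  run_cost <- function(unmatched) {
    if (!length(unmatched) || !any(unmatched)) return(0)
    r <- rle(unmatched)
    gamma * sum(unmatched) + gap_opening * sum(r$values)
  }
  cross <- function(a, b) {
    if (length(a) <= 1) return(FALSE)
    for (x in seq_along(a)) for (y in seq_along(a)) {
      if (x != y && a[x] < a[y] && a[y] < b[x] && b[x] < b[y]) return(TRUE)
    }
    FALSE
  }
  score_A <- function(ei, ek) {
    nA <- length(ei)
    cand <- list()
    if (nt > 0 && nq > 0 && nA > 1) {
      map <- rep(NA_integer_, m)
      map[ek] <- ei
      for (t in seq_len(nt)) for (q in seq_len(nq)) {
        k <- qpairs$k[q]; l <- qpairs$l[q]
        if (!is.na(map[k]) && !is.na(map[l]) &&
            map[k] == tpairs$i[t] && map[l] == tpairs$j[t]) {
          cand[[length(cand) + 1]] <- c(t, q)
        }
      }
    }
    sig_all <- 0
    for (r in seq_len(nA)) {
      sig_all <- sig_all + sigma_table[tcode[ei[r]] + 1L, ek[r]]
    }
    tmatched <- rep(FALSE, n); qmatched <- rep(FALSE, m)
    tmatched[ei] <- TRUE; qmatched[ek] <- TRUE
    trange <- if (nA == 0) {
      if (mode == "global") seq_len(n) else integer(0)
    } else {
      switch(mode,
             semiglobal = seq(min(ei), max(ei)),
             free_left = seq(min(ei), n),
             global = seq_len(n))
    }
    base <- sig_all + run_cost(!tmatched[trange]) + run_cost(!qmatched)
    bestS <- base
    nc <- length(cand)
    if (nc > 0) {
      for (mask in 1:(2^nc - 1)) {
        sel <- cand[bitwAnd(mask, 2^(seq_len(nc) - 1)) > 0]
        ti <- vapply(sel, function(x) tpairs$i[x[1]], 1)
        tj <- vapply(sel, function(x) tpairs$j[x[1]], 1)
        qk <- vapply(sel, function(x) qpairs$k[x[2]], 1)
        ql <- vapply(sel, function(x) qpairs$l[x[2]], 1)
        if (anyDuplicated(c(ti, tj)) || anyDuplicated(c(qk, ql))) next
        if (cross(ti, tj) || cross(qk, ql)) next
        sc <- base
        for (s in seq_along(sel)) {
          t <- sel[[s]][1]; q <- sel[[s]][2]
          sc <- sc + tpairs$psi[t] + qpairs$psi[q] +
            tau_tables[q, tcode[ti[s]] * 4 + tcode[tj[s]] + 1] -
            sigma_table[tcode[ti[s]] + 1L, qk[s]] -
            sigma_table[tcode[tj[s]] + 1L, ql[s]]
        }
        bestS <- max(bestS, sc)
      }
    }
    bestS
  }
  rec <- function(kpos, imin, ei, ek) {
    best <<- max(best, score_A(ei, ek))
    if (kpos > m || imin > n) return(invisible())
    for (k in kpos:m) for (i in imin:n) {
      rec(k + 1, i + 1, c(ei, i), c(ek, k))
    }
  }
  rec(1, 1, integer(0), integer(0))
  best
}

# random tiny scan instance (tables, pairs, gaps) under the current RNG
random_scan_instance <- function(nmax = 9, mmax = 5, affine = TRUE) {
  n <- sample(4:nmax, 1)
  m <- sample(2:mmax, 1)
  tcode <- sample(0:3, n, replace = TRUE)
  sigma_table <- matrix(sample(-300:300, 5 * m, replace = TRUE), nrow = 5)
  sigma_table[5, ] <- 0
  rpair <- function(lo, hi) {
    i <- sample(seq_len(hi - 1), 1)
    j <- if (i + 1 == hi) hi else sample((i + 1):hi, 1)
    c(i, j)
  }
  tpairs <- list(i = integer(0), j = integer(0), psi = numeric(0))
  for (t in seq_len(sample(0:2, 1))) {
    p <- rpair(1, n)
    if (any(tpairs$i == p[1] & tpairs$j == p[2])) next
    tpairs$i <- c(tpairs$i, p[1]); tpairs$j <- c(tpairs$j, p[2])
    tpairs$psi <- c(tpairs$psi, sample(0:400, 1))
  }
  qpairs <- list(k = integer(0), l = integer(0), psi = numeric(0))
  if (m >= 2) {
    for (t in seq_len(sample(0:2, 1))) {
      p <- rpair(1, m)
      if (any(qpairs$k == p[1] & qpairs$l == p[2])) next
      qpairs$k <- c(qpairs$k, p[1]); qpairs$l <- c(qpairs$l, p[2])
      qpairs$psi <- c(qpairs$psi, sample(0:400, 1))
    }
  }
  nq <- length(qpairs$k)
  tau_tables <- matrix(sample(-200:700, max(nq, 1) * 16, replace = TRUE),
                       nrow = max(nq, 1))[seq_len(nq), , drop = FALSE]
  L <- sample(c(3, 5, n), 1)
  keep <- (tpairs$j - tpairs$i) <= L
  tpairs <- list(i = tpairs$i[keep], j = tpairs$j[keep],
                 psi = tpairs$psi[keep])
  list(n = n, m = m, tcode = tcode, sigma_table = sigma_table,
       tpairs = tpairs, qpairs = qpairs, tau_tables = tau_tables,
       gamma = -sample(50:150, 1),
       go = if (affine && runif(1) < 0.5) -sample(100:500, 1) else 0,
       L = L)
}

# ---- textbook semi-global sequence aligner (linear gaps) ----------

# Independent Needleman-Wunsch with free end gaps on the target only at
# the left (prefix scores), for the sequence-only cross-check.
nw_free_left_prefix <- function(tcode, m, sigma_table, gamma) {
  n <- length(tcode)
  S <- matrix(-Inf, n + 1, m + 1)
  S[, 1] <- 0
  S[1, ] <- gamma * (0:m)
  for (j in 1:n) for (l in 1:m) {
    S[j + 1, l + 1] <- max(S[j, l] + sigma_table[tcode[j] + 1, l],
                           S[j, l + 1] + gamma,
                           S[j + 1, l] + gamma)
  }
  S[-1, m + 1]
}

# ---- secondary-structure enumeration oracle -----------------------

# All valid structures under the pair-additive model: canonical pairs,
# non-crossing, hairpin loops >= min_loop, every pair stacked when
# lonely pairs are excluded.
enumerate_structures <- function(code, model) {
  n <- length(code)
  canp <- function(a, b) model$pair_energy[a + 1, b + 1] != 0
  allp <- list()
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (j - i - 1 >= model$min_loop && canp(code[i], code[j])) {
        allp[[length(allp) + 1]] <- c(i, j)
      }
    }
  }
  out <- list()
  rec <- function(idx, chosen) {
    if (idx > length(allp)) {
      out[[length(out) + 1]] <<- chosen
      return(invisible())
    }
    rec(idx + 1, chosen)
    p <- allp[[idx]]
    ok <- TRUE
    for (q in chosen) {
      if (p[1] %in% q || p[2] %in% q) { ok <- FALSE; break }
      if (q[1] < p[1] && p[1] < q[2] && q[2] < p[2]) { ok <- FALSE; break }
      if (p[1] < q[1] && q[1] < p[2] && p[2] < q[2]) { ok <- FALSE; break }
    }
    if (ok) rec(idx + 1, c(chosen, list(p)))
  }
  rec(1, list())
  if (model$no_lonely_pairs) {
    out <- Filter(function(st) {
      if (!length(st)) return(TRUE)
      key <- vapply(st, function(p) paste(p[1], p[2]), "")
      all(vapply(st, function(p) {
        paste(p[1] + 1, p[2] - 1) %in% key ||
          paste(p[1] - 1, p[2] + 1) %in% key
      }, TRUE))
    }, out)
  }
  out
}

structure_energy_oracle <- function(code, st, model) {
  if (!length(st)) return(0)
  e <- sum(vapply(st, function(p) {
    model$pair_energy[code[p[1]] + 1, code[p[2]] + 1]
  }, 1.0))
  key <- vapply(st, function(p) paste(p[1], p[2]), "")
  nhel <- sum(vapply(st, function(p) {
    !(paste(p[1] - 1, p[2] + 1) %in% key)
  }, TRUE))
  e + model$helix_init * nhel
}

# Boltzmann pair probabilities by enumeration; returns list(Z, probs)
# where probs is an environment keyed "i j".
enumerate_bpp <- function(code, model) {
  sts <- enumerate_structures(code, model)
  w <- vapply(sts, function(st) {
    exp(-structure_energy_oracle(code, st, model) / model$rt)
  }, 1.0)
  Z <- sum(w)
  probs <- new.env()
  for (s in seq_along(sts)) {
    for (p in sts[[s]]) {
      k <- paste(p[1], p[2])
      prev <- if (exists(k, probs, inherits = FALSE)) {
        get(k, probs, inherits = FALSE)
      } else 0
      assign(k, prev + w[s] / Z, probs)
    }
  }
  list(Z = Z, probs = probs, structures = sts, weights = w)
}

# ---- offline pruning oracle ---------------------------------------

# Greedy best-first suppression: take maxima by decreasing score
# (ties: smaller position first); report unless within m of an already
# reported occurrence.
offline_prune_oracle <- function(maxima, m) {
  ord <- order(-maxima$score, maxima$j)
  rep_j <- numeric(0)
  rep_s <- numeric(0)
  for (r in ord) {
    j <- maxima$j[r]
    if (!any(abs(rep_j - j) <= m)) {
      rep_j <- c(rep_j, j)
      rep_s <- c(rep_s, maxima$score[r])
    }
  }
  o <- order(rep_j)
  data.frame(j = rep_j[o], score = rep_s[o])
}

# random structured target instance for end-to-end scans: plants a
# hairpin-annotated element into a random background
planted_instance <- function(n = 300, stem = 4, loop = 5, at = NULL) {
  qlen <- 2 * stem + loop
  at <- at %||% sample(seq(qlen + 5, n - qlen - 5), 1)
  bases <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  target <- paste(bases, collapse = "")
  qi <- at + seq_len(stem) - 1
  qj <- at + qlen - seq_len(stem)
  tb <- bpp_matrix(n, i = qi, j = qj, p = runif(stem, 0.6, 0.95),
                   max_span = 50)
  structure_str <- paste0(strrep("(", stem), strrep(".", loop),
                          strrep(")", stem))
  list(target = target, target_bpp = tb, at = at, qlen = qlen,
       query = query_input(strrep("N", qlen), structure = structure_str))
}
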