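# The banded scanning DP: boundary cases, worked examples, oracle
# equivalence on tiny instances, and the memory/complexity contracts.

# hook tables: match +200 / mismatch -100 between explicit sequences
hook_sigma <- function(tcode_query, m) {
  sig <- matrix(-100, nrow = 5, ncol = m)
  for (k in seq_len(m)) sig[tcode_query[k] + 1, k] <- 200
  sig[5, ] <- 0
  sig
}

no_pairs <- list(i = integer(0), j = integer(0), psi = numeric(0))
no_qpairs <- list(k = integer(0), l = integer(0), psi = numeric(0))
no_tau <- matrix(0, 0, 16)

test_that("S block initialization follows the subscore definition", {
  # empty target range vs query k..l: one deletion per query position
  # (the printed initialization gamma*(l-k) is off by one against the
  # subscore definition; we keep the consistent form)
  tcode <- encode_residues("AAGG")
  sig <- hook_sigma(encode_residues("GGG"), 3)
  v <- structscan:::subscore_block(tcode, 3, sig, no_pairs, no_qpairs,
                                   no_tau, -100, 0, 4, i = 5, j = 4,
                                   k = 1, l = 3)
  expect_equal(v, -300)
  # empty query range vs target i..j
  v2 <- structscan:::subscore_block(tcode, 3, sig, no_pairs, no_qpairs,
                                    no_tau, -100, 0, 4, i = 2, j = 4,
                                    k = 4, l = 3)
  expect_equal(v2, -300)
  # both empty
  v3 <- structscan:::subscore_block(tcode, 3, sig, no_pairs, no_qpairs,
                                    no_tau, -100, 0, 4, i = 5, j = 4,
                                    k = 4, l = 3)
  expect_equal(v3, 0)
})

test_that("S slice matches brute force on the AAGG/GG example", {
  tcode <- encode_residues("AAGG")
  sig <- hook_sigma(encode_residues("GG"), 2)
  v <- structscan:::subscore_block(tcode, 2, sig, no_pairs, no_qpairs,
                                   no_tau, -100, 0, 4, i = 3, j = 4,
                                   k = 1, l = 2)
  expect_equal(v, 400)  # exact GG/GG block
  # whole-target block: deleting AA costs two gamma
  v2 <- structscan:::subscore_block(tcode, 2, sig, no_pairs, no_qpairs,
                                    no_tau, -100, 0, 4, i = 1, j = 4,
                                    k = 1, l = 2)
  expect_equal(v2, 200)
})

test_that("semi-global initialization gives free left target deletions", {
  tcode <- encode_residues("AAGG")
  sig <- hook_sigma(encode_residues("GG"), 2)
  eng <- scan_engine(tcode, 2, sig, no_pairs, no_qpairs, no_tau,
                     gamma = -100, gap_opening = 0, max_span = 4)
  expect_equal(eng$sj[4], 400)  # s_4 = S*(4,2)
  # all-deleted query floor: s_j >= gamma * m everywhere
  expect_true(all(eng$sj >= -200))
})

test_that("a query with no positive contribution scores gamma * m", {
  set.seed(7)
  tcode <- sample(0:3, 30, replace = TRUE)
  sig <- matrix(0, 5, 2)
  sig[1:4, ] <- -50  # every match is negative
  eng <- scan_engine(tcode, 2, sig, no_pairs, no_qpairs, no_tau,
                     gamma = -100, gap_opening = 0, max_span = 10)
  expect_true(all(eng$sj == -200 | eng$sj == -100 | eng$sj >= -200))
  # with sigma identically 0 the best is two matches for free
  sig0 <- matrix(0, 5, 2)
  eng0 <- scan_engine(tcode, 2, sig0, no_pairs, no_qpairs, no_tau,
                      gamma = -100, gap_opening = 0, max_span = 10)
  expect_equal(eng0$sj[-1], rep(0, 29))
  expect_equal(eng0$sj[1], -100)  # only one target position available
})

test_that("hairpin D composition matches the worked example", {
  # GAAAC against itself with one certain pair and neutral sequence
  tcode <- encode_residues("GAAAC")
  sig <- matrix(0, 5, 5)
  tp <- list(i = 1L, j = 5L, psi = 200)
  qp <- list(k = 1L, l = 5L, psi = 200)
  tau <- matrix(0, 1, 16)
  eng <- scan_engine(tcode, 5, sig, tp, qp, tau, gamma = -100,
                     gap_opening = 0, max_span = 5)
  expect_equal(eng$sj[5], 400)
  # adding a tau contribution for the aligned G-C pair
  tau2 <- matrix(0, 1, 16)
  tau2[1, 2 * 4 + 1 + 1] <- 179  # (G, C) = codes (2, 1)
  eng2 <- scan_engine(tcode, 5, sig, tp, qp, tau2, gamma = -100,
                      gap_opening = 0, max_span = 5)
  expect_equal(eng2$sj[5], 579)
})

test_that("scan equals brute-force enumeration on random tiny instances", {
  set.seed(1234)
  for (rep in 1:40) {
    inst <- random_scan_instance()
    eng <- scan_engine(inst$tcode, inst$m, inst$sigma_table, inst$tpairs,
                       inst$qpairs, inst$tau_tables, inst$gamma, inst$go,
                       inst$L)
    o_fl <- oracle_enumerate(inst$n, inst$m, inst$sigma_table, inst$tpairs,
                             inst$qpairs, inst$tau_tables, inst$gamma,
                             inst$go, inst$tcode, "free_left")
    o_sg <- oracle_enumerate(inst$n, inst$m, inst$sigma_table, inst$tpairs,
                             inst$qpairs, inst$tau_tables, inst$gamma,
                             inst$go, inst$tcode, "semiglobal")
    expect_identical(eng$sj[inst$n], o_fl)
    expect_identical(max(eng$sj), o_sg)
  }
})

test_that("global initialization reproduces the global score", {
  set.seed(4321)
  for (rep in 1:15) {
    inst <- random_scan_instance()
    eng <- scan_engine(inst$tcode, inst$m, inst$sigma_table, inst$tpairs,
                       inst$qpairs, inst$tau_tables, inst$gamma, inst$go,
                       inst$L, global = TRUE)
    o_gl <- oracle_enumerate(inst$n, inst$m, inst$sigma_table, inst$tpairs,
                             inst$qpairs, inst$tau_tables, inst$gamma,
                             inst$go, inst$tcode, "global")
    expect_identical(eng$sj[inst$n], o_gl)
  }
})

test_that("the planted cloverleaf-arm fixture peaks at the right end", {
  set.seed(11)
  bg <- sample(c("A", "C", "G", "U"), 500, replace = TRUE)
  bg[201:209] <- strsplit("GGGAAACCC", "")[[1]]
  target <- paste(bg, collapse = "")
  tb <- bpp_matrix(500, i = c(201, 202, 203), j = c(209, 208, 207),
                   p = rep(0.9, 3), max_span = 100)
  q <- query_input("NNNNNNNNN", structure = "(((...)))")
  prof <- build_profile(q)
  params <- score_params(gamma = -100, gap_opening = 0,
                         struct_weight = 200, p_min = 0.01, max_span = 100)
  res <- scan_target(target, tb, prof, params, seq_scores = FALSE)
  expect_equal(which.max(res$score_trace), 209)
  expect_equal(max(res$score_trace),
               3 * (psi_score(0.9, params) + 200))
})

test_that("increasing p_min never increases any s_j", {
  set.seed(77)
  inst <- planted_instance(n = 200)
  prof <- build_profile(inst$query)
  lo <- score_params(p_min = 0.05, max_span = 50, gap_opening = 0)
  hi <- score_params(p_min = 0.7, max_span = 50, gap_opening = 0)
  r_lo <- scan_target(inst$target, inst$target_bpp, prof, lo,
                      seq_scores = FALSE)
  r_hi <- scan_target(inst$target, inst$target_bpp, prof, hi,
                      seq_scores = FALSE)
  expect_true(all(r_hi$score_trace <= r_lo$score_trace))
})

test_that("peak live DP entries are bounded and independent of n", {
  mkbpp <- function(n) {
    starts <- seq(1, n - 20, by = 100)
    bpp_matrix(n, i = c(starts, starts + 1), j = c(starts + 15, starts + 14),
               p = rep(0.8, 2 * length(starts)), max_span = 20)
  }
  q <- query_input(strrep("N", 30),
                   structure = paste0(strrep("(", 5), strrep(".", 20),
                                      strrep(")", 5)))
  prof <- build_profile(q)
  params <- score_params(max_span = 20)
  set.seed(5)
  t1 <- paste(sample(c("A", "C", "G", "U"), 1000, TRUE), collapse = "")
  t2 <- paste(sample(c("A", "C", "G", "U"), 10000, TRUE), collapse = "")
  r1 <- scan_target(t1, mkbpp(1000), prof, params, seq_scores = FALSE)
  r2 <- scan_target(t2, mkbpp(10000), prof, params, seq_scores = FALSE)
  expect_identical(r1$peak_live, r2$peak_live)
  # c * L * m bound with a generous constant
  expect_lt(r1$peak_live, 10 * 20 * 30)
})

test_that("cell-count work scales about linearly with n", {
  mk <- function(n) {
    set.seed(9)
    starts <- seq(1, n - 20, by = 50)
    list(t = paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = ""),
         b = bpp_matrix(n, i = c(starts, starts + 1),
                        j = c(starts + 15, starts + 14),
                        p = rep(0.8, 2 * length(starts)), max_span = 20))
  }
  q <- query_input(strrep("N", 16),
                   structure = paste0("((", strrep(".", 12), "))"))
  prof <- build_profile(q)
  params <- score_params(max_span = 20)
  a <- mk(2000); b <- mk(4000)
  ra <- scan_target(a$t, a$b, prof, params, seq_scores = FALSE)
  rb <- scan_target(b$t, b$b, prof, params, seq_scores = FALSE)
  ratio <- rb$cells / ra$cells
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.6)
})

test_that("scan_engine rejects malformed pair inputs", {
  sig <- matrix(0, 5, 3)
  expect_error(scan_engine(c(0L, 1L, 2L, 3L), 3, sig,
                           list(i = 3, j = 2, psi = 10), no_qpairs, no_tau,
                           -100, 0, 4), "i < j")
  expect_error(scan_engine(c(0L, 1L, 2L, 3L), 3, sig,
                           list(i = 1, j = 4, psi = 10), no_qpairs, no_tau,
                           -100, 0, 2), "span")
  expect_error(scan_engine(c(0L, 1L, 2L, 3L), 3, sig, no_pairs,
                           list(k = 2, l = 2, psi = 10),
                           matrix(0, 1, 16), -100, 0, 4), "k < l")
})
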