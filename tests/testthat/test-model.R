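# Scoring model: log-odds terms, profiles, psi, and the direct
# alignment score.

test_that("sigma is the discretized single-column log-odds", {
  # uniform column: zero for every nucleotide
  pu <- build_profile(query_input(c("ACGU", "CAUG", "GUAC", "UGCA")),
                      pseudocount_mass = 0)
  for (t in c("A", "C", "G", "U")) {
    expect_equal(sigma_score(t, 1, pu), 0)
  }
  # pure column without pseudocounts: log(4) nats = 139 centi-units
  p1 <- build_profile(query_input("AC"), pseudocount_mass = 0)
  expect_equal(sigma_score("A", 1, p1), 139)
  expect_equal(sigma_score("C", 2, p1), 139)
  # N carries no evidence
  expect_equal(sigma_score("N", 1, p1), 0)
  # single-row "A" with pseudocount 1: hand-evaluated formula
  pa <- build_profile(query_input("A"), pseudocount_mass = 1)
  bg <- pmax(c(1, 0, 0, 0), 0.01); bg <- bg / sum(bg)
  fG <- (0 + bg[3]) / 2
  expect_equal(sigma_score("G", 1, pa),
               round_half_away(100 * log(fG / 0.25)))
  expect_equal(sigma_score("G", 1, pa), -394)
})

test_that("tau is the discretized pair log-odds, weighted after rounding", {
  # all-GC pair column without pseudocounts
  rows <- rep("GAAAC", 4)
  q <- query_input(rows, structure = "(...)")
  pg <- build_profile(q, pseudocount_mass = 0)
  expect_equal(tau_score("G", "C", 1, 5, pg, tau_weight = 1), 179)
  expect_equal(tau_score("G", "C", 1, 5, pg, tau_weight = 4), 4 * 179)
  # uninformative (all-N) pair columns score 0 for any input pair
  pn <- build_profile(query_input("NAAAN", structure = "(...)"))
  for (pr in list(c("A", "U"), c("G", "C"), c("U", "G"))) {
    expect_equal(tau_score(pr[1], pr[2], 1, 5, pn, tau_weight = 4), 0)
  }
  # non-pair columns are rejected
  expect_error(tau_score("G", "C", 2, 3, pg), "not a pair")
})

test_that("tau of a near-uniform observed pair distribution is 0", {
  rows <- c("GAAAC", "CAAAG", "AAAAU", "UAAAA", "GAAAU", "UAAAG")
  pg <- build_profile(query_input(rows, structure = "(...)"),
                      pseudocount_mass = 0)
  expect_equal(tau_score("G", "C", 1, 5, pg, tau_weight = 1), 0)
})

test_that("psi maps probabilities to (0, struct_weight] and cuts at p_min", {
  params <- score_params(struct_weight = 200, p_min = 0.01)
  expect_equal(psi_score(1, params), 200)
  expect_equal(psi_score(0.005, params), -Inf)
  expect_equal(psi_score(0.8, params),
               round_half_away(200 * log(80) / log(100)))
  expect_equal(psi_score(0.8, params), 190)
  # strictly increasing on [p_min, 1]
  ps <- seq(0.01, 1, length.out = 50)
  v <- psi_score(ps, params)
  expect_true(all(diff(v) >= 0))
  expect_true(v[1] < v[50])
})

test_that("build_profile computes column frequencies with pseudocounts", {
  p0 <- build_profile(query_input("AC"), pseudocount_mass = 0)
  expect_equal(unname(p0$single_freq["A", 1]), 1)
  expect_equal(unname(p0$single_freq["C", 2]), 1)
  p2 <- build_profile(query_input(c("A", "G")), pseudocount_mass = 0)
  expect_equal(unname(p2$single_freq["A", 1]), 0.5)
  expect_equal(unname(p2$single_freq["G", 1]), 0.5)
  # column {A, -} with query-wide mono (0.5, 0.25, 0.25, 0), pc = 1
  q <- query_input(c("AAC", "G--"))
  pp <- build_profile(q, pseudocount_mass = 1)
  bg <- pmax(c(0.5, 0.25, 0.25, 0), 0.01); bg <- bg / sum(bg)
  expect_equal(unname(pp$single_freq["A", 2]), (1 + bg[1]) / 2)
  expect_equal(unname(pp$single_freq["C", 2]), bg[2] / 2)
  # single frequencies are distributions
  expect_equal(unname(colSums(pp$single_freq)), rep(1, 3))
  # all-gap column warns and falls back to background
  expect_warning(pg <- build_profile(query_input(c("A-C", "A-C"))),
                 "only gaps")
  expect_equal(pg$single_freq[, 2], setNames(rep(0.25, 4), c("A", "C", "G", "U")))
})

test_that("query_bpp_from_structure sets structure pairs to 1", {
  b <- query_bpp_from_structure("((...))")
  expect_equal(b$i, c(1, 2))
  expect_equal(b$j, c(7, 6))
  expect_equal(b$p, c(1, 1))
  expect_equal(length(query_bpp_from_structure(".......")$i), 0)
  expect_error(query_bpp_from_structure("((.)"), "position 1")
  expect_error(query_bpp_from_structure("())."), "position 3")
})

test_that("total_score matches hand-computed cases", {
  params <- score_params(gamma = -100, gap_opening = 0,
                         struct_weight = 200, p_min = 0.01, max_span = 100)
  # full diagonal self-alignment: sum of sigma, no gaps
  q <- query_input("ACGU")
  prof <- build_profile(q, pseudocount_mass = 0)
  tb <- bpp_matrix(4)
  edges <- cbind(1:4, 1:4)
  sc <- total_score(edges, NULL, "ACGU", tb, prof, params)
  expect_equal(sc, 4 * 139)
  # empty alignment, global: gamma * (n + m)
  sc0 <- total_score(NULL, NULL, "ACG", bpp_matrix(3),
                     build_profile(query_input("AC")), params,
                     mode = "global")
  expect_equal(sc0, -500)
  # structure-only hairpin: 3 * (psi_T + psi_Q)
  tb2 <- bpp_matrix(9, i = 1:3, j = 9:7, p = rep(0.9, 3), max_span = 100)
  qn <- query_input("NNNNNNNNN", structure = "(((...)))")
  profn <- build_profile(qn)
  edges <- cbind(1:9, 1:9)
  spairs <- cbind(1:3, 9:7, 1:3, 9:7)
  scs <- total_score(edges, spairs, "GGGAAACCC", tb2, profn, params)
  expect_equal(scs, 3 * (psi_score(0.9, params) + 200))
})

test_that("total_score is invariant under summation order and validates", {
  params <- score_params(gamma = -100, gap_opening = 0)
  tb <- bpp_matrix(9, i = 1:3, j = 9:7, p = rep(0.9, 3), max_span = 100)
  profn <- build_profile(query_input("NNNNNNNNN", structure = "(((...)))"))
  edges <- cbind(1:9, 1:9)
  spairs <- cbind(1:3, 9:7, 1:3, 9:7)
  perm <- c(3, 1, 2)
  expect_equal(
    total_score(edges, spairs, "GGGAAACCC", tb, profn, params),
    total_score(edges[sample(9), , drop = FALSE],
                spairs[perm, , drop = FALSE], "GGGAAACCC", tb, profn,
                params))
  # inconsistent structure: pair ends not aligned to each other
  bad <- cbind(1, 9, 2, 8)
  expect_error(total_score(edges, bad, "GGGAAACCC", tb, profn, params),
               "inconsistent")
  # crossing alignment
  expect_error(total_score(cbind(c(1, 2), c(2, 1)), NULL, "GGGAAACCC",
                           tb, profn, params), "monotone")
})

test_that("semi-global total_score with no structure matches textbook NW", {
  # linear gaps, free target end deletions on both sides
  set.seed(421)
  for (rep in 1:50) {
    n <- sample(5:10, 1); m <- sample(2:5, 1)
    tcode <- sample(0:3, n, replace = TRUE)
    sig <- matrix(sample(-250:250, 5 * m, replace = TRUE), nrow = 5)
    sig[5, ] <- 0
    eng <- scan_engine(tcode, m, sig,
                       list(i = integer(0), j = integer(0), psi = numeric(0)),
                       list(k = integer(0), l = integer(0), psi = numeric(0)),
                       matrix(0, 0, 16), gamma = -100, gap_opening = 0,
                       max_span = n)
    expect_equal(eng$sj, nw_free_left_prefix(tcode, m, sig, -100))
  }
})

test_that("bpp_matrix validates its invariants", {
  expect_error(bpp_matrix(5, i = 2, j = 2, p = 0.5), "i < j")
  expect_error(bpp_matrix(5, i = 1, j = 4, p = 1.2), "\\(0, 1\\]")
  expect_error(bpp_matrix(5, i = c(1, 1), j = c(4, 4), p = c(0.4, 0.3)),
               "duplicate")
  expect_error(bpp_matrix(5, i = 1, j = 5, p = 0.9, max_span = 2), "span")
  # substochasticity per position
  expect_error(bpp_matrix(5, i = c(1, 1), j = c(4, 5), p = c(0.6, 0.6)),
               "sum")
  b <- bpp_matrix(5, i = c(1, 1), j = c(4, 5), p = c(0.5, 0.5))
  expect_s3_class(b, "bpp_matrix")
  # p_min filtering on construction
  b2 <- bpp_matrix(5, i = c(1, 2), j = c(5, 5), p = c(0.4, 0.05),
                   p_min = 0.1)
  expect_equal(length(b2$i), 1)
})

test_that("read_bpp parses, filters and round-trips", {
  f <- withr::local_tempfile(fileext = ".bpp")
  writeLines(c("# comment", "1\t9\t0.8", "2\t8\t0.8", "3\t7\t0.8"), f)
  b <- read_bpp(f)
  expect_equal(length(b$i), 3)
  expect_equal(b$max_span, 8L)
  expect_equal(b$length, 9L)
  # empty file
  writeLines("# nothing", f)
  expect_equal(length(read_bpp(f)$i), 0)
  # invalid probability
  writeLines("1\t9\t1.2", f)
  expect_error(read_bpp(f), "line 1")
  writeLines(c("1\t9\t0.8", "1\t9\t0.7"), f)
  expect_error(read_bpp(f), "duplicate")
  writeLines("1\tx\t0.5", f)
  expect_error(read_bpp(f), "malformed")
  # round trip incl. length header
  b3 <- bpp_matrix(20, i = c(2, 5), j = c(9, 12), p = c(0.25, 0.75))
  write_bpp(b3, f)
  b4 <- read_bpp(f)
  expect_equal(b4$length, 20L)
  expect_equal(b4[c("i", "j")], b3[c("i", "j")])
  expect_equal(b4$p, b3$p, tolerance = 1e-9)
})
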