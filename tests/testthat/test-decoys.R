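# Decoy generation, pseudogenome assembly and hit evaluation.

test_that("project_structure removes gap columns and dots half-pairs", {
  p1 <- project_structure("GC-GC", "((.))")
  expect_equal(p1$sequence, "GCGC")
  expect_equal(p1$structure, "(())")
  p2 <- project_structure("G-AAC", "(...)")
  expect_equal(p2$sequence, "GAAC")
  expect_equal(p2$structure, "(..)")
  p3 <- project_structure("-CAAG", "(...)")
  expect_equal(p3$sequence, "CAAG")
  expect_equal(p3$structure, "....")
  # result is always balanced
  expect_silent(db_pairs(p3$structure))
  expect_error(project_structure("AC", "(.)"), "equal length")
})

test_that("cloverleaf templates are balanced, bounded and diverse", {
  set.seed(31)
  tpls <- replicate(100, make_cloverleaf_template(), simplify = FALSE)
  lens <- vapply(tpls, `[[`, 1L, "length")
  expect_true(all(lens >= 70 & lens <= 92))
  for (t in tpls[1:20]) {
    prs <- db_pairs(t$structure)          # balanced or error
    expect_true(all(prs[, 2] - prs[, 1] - 1 >= 3))  # min loop respected
    expect_silent(query_bpp_from_structure(t$structure))
  }
  # distinct seeds give distinct templates
  expect_lt(mean(duplicated(vapply(tpls, `[[`, "", "structure"))), 0.05)
})

test_that("the p-equivalent energy difference matches the closed form", {
  expect_equal(p_equivalent_energy(0.75, rt = 1), -log(0.75),
               tolerance = 1e-12)
  expect_equal(p_equivalent_energy(0.75, rt = 1), 0.2876820724,
               tolerance = 1e-9)
  expect_equal(p_equivalent_energy(0.5, rt = 2), 2 * log(2),
               tolerance = 1e-12)
})

test_that("stabilized decoys reach the stopping probability", {
  set.seed(32)
  tpl <- make_cloverleaf_template()
  mod <- energy_model()
  for (rep in 1:3) {
    d <- make_stabilized_decoy(tpl, mod, p_target = 0.75)
    expect_gte(d$structure_probability, 0.75)
    # the reported probability is reproducible from the sequence
    expect_equal(structure_probability(d$sequence, d$structure, mod),
                 d$structure_probability, tolerance = 1e-12)
    expect_equal(nchar(d$sequence), tpl$length)
  }
})

test_that("two-state inverse folding succeeds iff the energy suffices", {
  # GGAAACC-shaped template: one helix-2 structure + open chain; the
  # walk can reach p >= 0.75 iff exp(-E)/(1+exp(-E)) >= 0.75
  tpl <- structure(list(structure = "((...))", length = 7L,
                        source = "test"), class = "structure_template")
  set.seed(33)
  strong <- energy_model()  # GC helix: e^12/(1+e^12) ~ 1
  d <- make_stabilized_decoy(tpl, strong)
  expect_gte(d$structure_probability, 0.75)
  # a model whose best helix cannot pass ln(3): 2 pairs at -0.5 each
  weak <- energy_model(gc = -0.5, au = -0.4, gu = -0.3)
  expect_error(make_stabilized_decoy(tpl, weak, max_iter = 150,
                                     retry_max = 2),
               "failed to reach")
})

test_that("non-stabilized decoys follow the printed sampling law", {
  set.seed(34)
  tpl <- make_cloverleaf_template()
  mono <- c(0.35, 0.25, 0.25, 0.15)
  decs <- lapply(1:200, function(i) make_nonstabilized_decoy(tpl, mono))
  prs <- db_pairs(tpl$structure)
  leftA <- rightU <- leftG <- rightC <- 0
  for (d in decs) {
    code <- encode_residues(d$sequence)
    leftA <- leftA + sum(code[prs[, 1]] == 0)
    rightU <- rightU + sum(code[prs[, 2]] == 3)
    leftG <- leftG + sum(code[prs[, 1]] == 2)
    rightC <- rightC + sum(code[prs[, 2]] == 1)
    # right ends are exact Watson-Crick complements (no GU)
    comp <- c(3L, 2L, 1L, 0L)
    expect_identical(code[prs[, 2]], comp[code[prs[, 1]] + 1L])
  }
  expect_identical(rightU, leftA)
  expect_identical(rightC, leftG)
  # all-dot template: plain i.i.d. sequence
  flat <- structure(list(structure = strrep(".", 60), length = 60L,
                         source = "test"), class = "structure_template")
  d0 <- make_nonstabilized_decoy(flat, mono)
  expect_equal(nchar(d0$sequence), 60)
})

test_that("stabilized decoys are more stable than non-stabilized ones", {
  set.seed(35)
  tpl <- make_cloverleaf_template()
  mod <- energy_model()
  stab <- lapply(1:6, function(i) make_stabilized_decoy(tpl, mod))
  mono <- decoy_mono_freq(stab)
  nons <- lapply(1:6, function(i) make_nonstabilized_decoy(tpl, mono))
  ps <- vapply(stab, `[[`, 1.0, "structure_probability")
  pn <- vapply(nons, function(d) {
    structure_probability(d$sequence, d$structure, mod)
  }, 1.0)
  expect_gt(mean(ps), mean(pn))
  # class mononucleotide frequencies agree within sampling error
  freq_n <- decoy_mono_freq(nons)
  se <- sqrt(mono * (1 - mono) / (6 * tpl$length))
  expect_true(all(abs(freq_n - mono) <= 4 * se + 0.03))
})

test_that("pseudogenome layout and annotations are exact", {
  set.seed(36)
  tpl <- structure(list(structure = paste0("((((", strrep(".", 72), "))))"),
                        length = 80L, source = "test"),
                   class = "structure_template")
  decs <- lapply(1:3, function(i) {
    make_nonstabilized_decoy(tpl, rep(0.25, 4))
  })
  pg <- build_pseudogenome(decs, spacing = 200, mono_freq = rep(0.25, 4))
  expect_equal(nchar(pg$sequence), 600)
  expect_equal(pg$annotations$start, c(1, 201, 401))
  expect_equal(pg$annotations$end, c(80, 280, 480))
  # non-overlapping intervals
  expect_true(all(diff(pg$annotations$start) >
                    (pg$annotations$end - pg$annotations$start)[-3]))
  # zero decoys: empty genome
  expect_equal(nchar(build_pseudogenome(list())$sequence), 0)
  # oversized decoy rejected
  big <- structure(list(sequence = strrep("A", 300), class = "x"),
                   class = "decoy")
  expect_error(build_pseudogenome(list(big), spacing = 200), "longer")
})

test_that("evaluate_hits applies the 10% overlap rule and best score", {
  ann <- data.frame(start = c(201, 401), end = c(280, 480),
                    decoy_id = c("d1", "d2"),
                    class = c("stabilized", "nonstabilized"))
  occ <- data.frame(left_end = c(195, 1, 430), j = c(215, 100, 470),
                    score = c(700, 900, 300))
  ev <- evaluate_hits(occ, ann)
  # [195,215] overlaps d1 by 15 >= 8 nt; [1,100] hits nothing
  expect_equal(ev$per_decoy$best_score, c(700, 300))
  # multiple occurrences on one decoy keep the best
  occ2 <- rbind(occ, data.frame(left_end = 240, j = 290, score = 1200))
  ev2 <- evaluate_hits(occ2, ann)
  expect_equal(ev2$per_decoy$best_score[1], 1200)
  # missed decoys count as missed at every threshold
  expect_true(all(ev$thresholds$nonstabilized_found <= 1))
  # AUC of a perfect split
  ann3 <- data.frame(start = c(1, 201), end = c(80, 280),
                     decoy_id = c("a", "b"),
                     class = c("stabilized", "nonstabilized"))
  occ3 <- data.frame(left_end = 1, j = 80, score = 500)
  expect_equal(evaluate_hits(occ3, ann3)$auc, 1)
})
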