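test_that("schema constants match the published consensus patterns", {
  s <- cif_schemas()
  expect_identical(
    s$pattern[s$name == "dub"],
    "HWVTLVI---------YY-DSL--------I---L-----D---------QQ-DG---CG----EN")
  expect_identical(
    s$pattern[s$name == "nuclease"],
    "DL-LL-R----------PIIIELK---------------------DLVL----------PIGLELK")
  expect_identical(s$pattern[s$name == "nls"], "KRAR")
  expect_identical(s$required_count, c(23L, 23L, 4L, 4L))
  expect_identical(nchar(s$pattern[s$name == "nls"]), 4L)
  # T4SS pattern renders R-X(7)-R-X-R-X-R: 13 positions, 4 required arginines
  t4 <- s$pattern[s$name == "t4ss"]
  expect_identical(nchar(t4), 13L)
  expect_identical(gsub("-", "", t4), "RRRR")
})

test_that("a filled schema occurring as a substring scores exactly 1", {
  s <- cif_schemas()
  for (k in seq_len(nrow(s))) {
    filled <- gsub("-", "A", s$pattern[k])
    expect_equal(score_schema(filled, s$name[k]), 1.0)
    embedded <- paste0("GGSS", filled, "SSGG")
    expect_equal(score_schema(embedded, s$name[k]), 1.0)
  }
  expect_equal(score_schema("", "dub"), 0.0)
})

test_that("schema alignment agrees with the brute-force DP oracle", {
  set.seed(101)
  s <- cif_schemas()
  for (i in 1:100) {
    prot <- random_protein_str(sample(0:40, 1))
    pat <- s$pattern[[sample.int(4, 1)]]
    got <- score_schema(prot, pat)
    want <- min(1, max(0, oracle_align_score(prot, pat) /
                            sum(strsplit(pat, "")[[1]] != "-")))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("partial motif matches earn proportional alignment credit", {
  # KRAA vs KRAR: three matches then a terminal mismatch (-0.5) -> 2.5/4
  expect_equal(score_nls("KRAA"), 0.625)
  expect_equal(score_nls("KRAA"), oracle_align_score("KRAA", "KRAR") / 4)
  # a single interior substitution in the DUB schema: 22 matches - 0.5
  filled <- gsub("-", "A", cif_schemas()$pattern[1])
  substr(filled, 20, 20) <- "P"  # position 20 is a required D
  got <- score_schema(filled, "dub")
  expect_equal(got, 21.5 / 23, tolerance = 1e-9)
  expect_gt(got, 0.9); expect_lt(got, 1)
})

test_that("full motif presence pins NLS and T4SS scores to 1", {
  expect_equal(score_nls("GGKRARGG"), 1.0)
  expect_equal(score_t4ss("RAAAAAAARARAR"), 1.0)
  expect_equal(score_t4ss("GGRAAAAAAARARARGG"), 1.0)
  # stops cannot stand in for wildcard positions of the full motif
  expect_lt(score_t4ss("RAAA*AAARARAG"), 1.0)
  # inserting the literal motif never lowers the score
  set.seed(33)
  for (i in 1:20) {
    p <- random_protein_str(sample(5:60, 1))
    at <- sample.int(nchar(p), 1)
    with_motif <- paste0(substr(p, 1, at), "KRAR",
                         substr(p, at + 1, nchar(p)))
    expect_gte(score_nls(with_motif), score_nls(p))
    expect_equal(score_nls(with_motif), 1.0)
  }
})

test_that("binding score follows the sliding-window tally, floored and capped", {
  expect_equal(score_binding(strrep("K", 11), strrep("D", 11)), 1.0)
  expect_equal(score_binding(strrep("K", 30), strrep("D", 30)), 1.0) # capped
  expect_equal(score_binding("", "DDDD"), 0.0)
  expect_equal(score_binding("KD", "KD"), 1 / 11)  # best offset: K over D
  expect_equal(score_binding("KKKK", "KKKK"), 0.0) # all repulsion, floored
})

test_that("binding agrees with exhaustive offset enumeration", {
  set.seed(202)
  alphabet <- c("K", "R", "D", "E", "A", "G", "S")
  for (i in 1:100) {
    a <- random_protein_str(sample(0:30, 1), alphabet)
    b <- random_protein_str(sample(0:30, 1), alphabet)
    want <- min(11, max(0, oracle_binding_tally(a, b))) / 11
    expect_equal(score_binding(a, b), want, tolerance = 1e-9)
    expect_equal(score_binding(a, b), score_binding(b, a))
  }
})

test_that("histidine joins the positive set only on request", {
  expect_equal(score_binding("HHH", "DDD"), 0.0)
  expect_equal(score_binding("HHH", "DDD", positive = "KRH"), 3 / 11)
})

test_that("parsimony penalty is zero up to threshold, then linear", {
  expect_equal(parsimony_penalty(c(0, 4000, 4500)), c(0, 0, 0))
  expect_equal(parsimony_penalty(4501, coefficient = 0.002), 0.002)
  expect_equal(parsimony_penalty(5500), 5e-4 * 1000)
  bp <- seq(4500, 6000, by = 100)
  expect_true(all(diff(parsimony_penalty(bp)) > 0))
})

test_that("ta_fitness sums the five components minus the penalty", {
  ta <- make_perfect_ta(5)
  expect_equal(ta$fitness,
               ta$binding + ta$nuclease + ta$dub + ta$nls + ta$t4ss -
                 ta$parsimony)
  empty <- ta_fitness(tibble::tibble(toxin = "", antidote = ""))
  expect_equal(empty$fitness, 0)
  expect_equal(empty$binding, 0)
  expect_identical(empty$nls_loc, "absent")
})

test_that("sub-scores stay in [0,1] and totals never exceed 5 on random DNA", {
  set.seed(77)
  pop <- tibble::tibble(toxin = random_dna(rep(150, 25)),
                        antidote = random_dna(rep(90, 25)))
  ev <- ta_fitness(pop)
  for (col in c("binding", "nuclease", "dub", "nls", "t4ss")) {
    expect_true(all(ev[[col]] >= 0 & ev[[col]] <= 1))
  }
  expect_true(all(ev$fitness <= 5 + 1e-12))
})

test_that("locate_signal reports the gene of residence", {
  in_ant <- make_partial_ta("nls", nls_in = "antidote")
  expect_identical(in_ant$nls_loc, "antidote")
  in_tox <- make_partial_ta("nls", nls_in = "toxin")
  expect_identical(in_tox$nls_loc, "toxin")
  none <- make_partial_ta(character())
  expect_identical(none$nls_loc, "absent")
  both <- ta_fitness(tibble::tibble(
    toxin = reverse_translate("GGKRARGG"),
    antidote = reverse_translate("SSKRARSS")))
  expect_identical(both$nls_loc, "both")
  # works from raw DNA frames too
  expect_identical(
    locate_signal(tibble::tibble(toxin = reverse_translate("GGKRARGG"),
                                 antidote = reverse_translate("GGSSGG")),
                  "nls"),
    "toxin")
})
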