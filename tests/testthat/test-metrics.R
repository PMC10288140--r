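clonal_pop <- function(n = 12, seed = 9) {
  ta <- make_perfect_ta(seed)
  ta_fitness(tibble::tibble(id = seq_len(n), born = 0L,
                            toxin = ta$toxin, antidote = ta$antidote,
                            mut_rolls = 0L))
}

test_that("diversity index is 0 for clones and high for unrelated proteins", {
  expect_equal(diversity_index(clonal_pop()), 0)
  set.seed(71)
  rand <- ta_fitness(tibble::tibble(toxin = random_dna(rep(600, 10)),
                                    antidote = random_dna(rep(300, 10))))
  expect_gt(diversity_index(rand), 0.5)
})

test_that("diversity sampling is seed-reproducible and banding is exact on small strings", {
  set.seed(72)
  # 50-residue toxins: the default band (half-width 64) covers the full
  # matrix, so banded and unbanded identities must agree exactly
  pop <- ta_fitness(tibble::tibble(toxin = random_dna(rep(150, 30)),
                                   antidote = random_dna(rep(90, 30))))
  set.seed(1); d1 <- diversity_index(pop)
  set.seed(1); d2 <- diversity_index(pop)
  expect_identical(d1, d2)
  set.seed(1); d_full <- diversity_index(pop, band = Inf)
  expect_equal(d1, d_full, tolerance = 1e-12)
})

test_that("pairwise identity matches the full-DP traceback oracle", {
  set.seed(73)
  for (i in 1:60) {
    a <- random_protein_str(sample(0:40, 1))
    b <- random_protein_str(sample(0:40, 1))
    got <- cifevo:::cpp_pairwise_identity(c(a, b), 1, -0.5, 1, 0.1, 100)
    expect_equal(got, oracle_align_identity(a, b), tolerance = 1e-9,
                 info = paste(a, b))
  }
})

test_that("location bias averages carrier codes and is NA with no carriers", {
  tox <- make_partial_ta("nls", nls_in = "toxin")
  ant <- make_partial_ta("nls", nls_in = "antidote")
  none <- make_partial_ta(character())
  all_tox <- dplyr::bind_rows(tox, tox, tox)
  expect_equal(location_bias(all_tox, "nls"), 1)
  half <- dplyr::bind_rows(tox, ant, tox, ant)
  expect_equal(location_bias(half, "nls"), 0.5)
  expect_true(is.na(location_bias(dplyr::bind_rows(none, none), "nls")))
  # non-carriers are excluded, not counted as 0.5
  mixed <- dplyr::bind_rows(tox, none, none, none)
  expect_equal(location_bias(mixed, "nls"), 1)
})

test_that("generation summary reports all fifteen observables coherently", {
  pop <- clonal_pop(n = 15)
  gs <- generation_summary(pop, generation = 3L)
  expect_identical(gs$generation, 3L)
  expect_equal(gs$avgTAfitness_ATF, 5)
  expect_equal(gs$highestTAFitness_HTF, 5)
  expect_equal(gs$diversityIndex_DI, 0)
  expect_equal(gs$avgNLSSITELocation_NLSL, 1)  # built toxin-side
  expect_identical(gs$nlsCarriers, 15L)
  expect_equal(gs$avgToxinLength_ATL, nchar(pop$toxin[1]))
  expect_equal(gs$avgToxinAALength_ATAL, nchar(pop$toxin_aa[1]))
  expect_true(all(cifevo:::observable_names %in% names(gs)))
  expect_length(cifevo:::observable_names, 15L)
})

test_that("max fitness never falls below the mean in any log", {
  run <- ea_run(tiny_config(generations = 6))
  expect_true(all(run$log$highestTAFitness_HTF >=
                    run$log$avgTAfitness_ATF - 1e-12))
})

test_that("replicate summary gives terminal mean/sd per observable", {
  cfg <- tiny_config(generations = 3)
  reps <- ea_replicates(cfg, n = 3, seeds = c(5L, 5L, 5L))
  rs <- replicate_summary(reps)
  expect_setequal(unique(rs$observable), cifevo:::observable_names)
  expect_setequal(unique(rs$statistic), c("mean", "sd"))
  # identical seeds -> zero variance everywhere it is defined
  sds <- rs$value[rs$statistic == "sd"]
  expect_true(all(is.na(sds) | sds == 0))
  # round-trips through CSV with one row per (observable, statistic)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rs, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(nrow(back), nrow(rs))
})

test_that("trajectory summary has one row per generation and observable", {
  cfg <- tiny_config(generations = 4)
  reps <- ea_replicates(cfg, n = 2)
  traj <- trajectory_summary(reps)
  expect_identical(nrow(traj), 5L * 15L)
  expect_true(all(traj$n <= 2))
})

test_that("tidy, glance and autoplot methods work on runs and replicates", {
  run <- ea_run(tiny_config(generations = 3))
  expect_identical(generics::tidy(run), run$log)
  g <- generics::glance(run)
  expect_identical(nrow(g), 1L)
  expect_true(all(c("best_fitness", "t4ss_location") %in% names(g)))
  p <- ggplot2::autoplot(run)
  expect_s3_class(p, "ggplot")
  reps <- ea_replicates(tiny_config(generations = 2), n = 2)
  expect_s3_class(generics::glance(reps), "tbl_df")
  expect_s3_class(ggplot2::autoplot(reps), "ggplot")
})
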