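test_that("simulation_config validates its invariants", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_categories = 1), "n_categories")
  expect_error(simulation_config(n_planted_degraders = 99, n_mags = 10),
               "n_planted_degraders")
  expect_error(simulation_config(assoc_strength = 2), "assoc_strength")
  expect_error(simulation_config(degrader_noise = -1), "degrader_noise")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- simulation_config(seed = 9)
  p1 <- gen_panel_profiles(cfg)
  p2 <- gen_panel_profiles(cfg)
  expect_identical(p1, p2)
  m1 <- gen_mag_profiles(cfg, p1)
  m2 <- gen_mag_profiles(cfg, p1)
  expect_identical(m1, m2)
  a1 <- gen_abundance_and_phenotype(cfg, m1$truth)
  a2 <- gen_abundance_and_phenotype(cfg, m1$truth)
  expect_identical(a1, a2)
  f1 <- gen_sequence_fixture(cfg)
  expect_identical(f1, gen_sequence_fixture(cfg))
  # a different seed changes the draw
  expect_false(identical(p1, gen_panel_profiles(simulation_config(seed = 10))))
  # generators leave the global RNG stream untouched
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(gen_panel_profiles(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("panel profiles are normalised and internally similar", {
  cfg <- simulation_config(seed = 1)
  panel <- gen_panel_profiles(cfg)
  expect_length(panel, 12)
  for (p in panel) {
    expect_length(p$probabilities, cfg$n_categories)
    expect_equal(sum(p$probabilities), 1, tolerance = 1e-12)
  }
  # all 66 pairwise divergences sit inside the decision region
  pj <- utils::combn(12, 2, function(ij)
    jsd(panel[[ij[1]]], panel[[ij[2]]]))
  expect_length(pj, 66)
  expect_true(all(pj < 0.0558))
})

test_that("planted degraders and background MAGs separate around the threshold", {
  cfg <- simulation_config(seed = 7)
  panel <- gen_panel_profiles(cfg)
  mags <- gen_mag_profiles(cfg, panel)
  expect_length(mags$profiles, 60)
  expect_equal(sum(mags$truth$is_degrader), 10)
  sc <- score_all(mags$profiles, reference_panel(panel))
  planted <- sc$min_jsd[mags$truth$is_degrader]
  background <- sc$min_jsd[!mags$truth$is_degrader]
  expect_lt(max(planted), 0.0558)
  expect_gt(min(background), 0.0558)
  # degrader_noise -> 0 collapses planted MAGs onto their panel source
  cfg0 <- simulation_config(seed = 7, degrader_noise = 0)
  m0 <- gen_mag_profiles(cfg0, panel)
  s0 <- score_all(m0$profiles, reference_panel(panel))
  expect_equal(max(s0$min_jsd[m0$truth$is_degrader]), 0)
})

test_that("abundance rows are compositions and bodyweight follows the diet pattern", {
  cfg <- simulation_config(seed = 2)
  ab <- gen_abundance_and_phenotype(cfg)
  expect_equal(dim(ab$abundance), c(12, 60))
  expect_true(all(abs(rowSums(ab$abundance) - 1) < 1e-9))
  expect_true(all(ab$counts >= 0))
  expect_true(all(rowSums(ab$counts) == cfg$depth))
  expect_equal(sum(ab$truth$is_differential), 8)
  expect_equal(sum(ab$truth$is_associated), 6)
  # expected ordering Model > SjC > Control holds on group means
  mw <- tapply(ab$phenotype$bodyweight, ab$phenotype$group, mean)
  expect_gt(mw[["Model"]], mw[["SjC"]])
  expect_gt(mw[["SjC"]], mw[["Control"]])
})

test_that("noise-free planted associations reach |rho| = 1 after closure", {
  cfg <- simulation_config(seed = 4, assoc_strength = 1, noise_sd = 0,
                           effect_size = 0)
  ab <- gen_abundance_and_phenotype(cfg)
  w <- ab$phenotype$bodyweight
  for (j in which(ab$truth$is_associated)) {
    rho <- spearman_cor(ab$abundance[, j], w, exact_max_n = 0)$rho
    expect_equal(abs(rho), 1)
    expect_equal(sign(rho), ab$truth$assoc_sign[j])
  }
})

test_that("planted group effects are detected when noise is small", {
  cfg <- simulation_config(seed = 6, effect_size = 3, noise_sd = 0.2,
                           assoc_strength = 0)
  ab <- gen_abundance_and_phenotype(cfg)
  res <- group_test(ab$abundance, ab$phenotype$group)
  expect_true(all(res$significant[ab$truth$is_differential]))
})

test_that("the sequence fixture plants cases on every side of both cutoffs", {
  cfg <- simulation_config(seed = 1)
  fx <- gen_sequence_fixture(cfg)
  expect_gte(nrow(fx$expected), 4)
  with(fx$expected, {
    expect_true(any(expected_link))
    expect_true(any(expected_identity > 99 & expected_length <= 300))
    expect_true(any(expected_identity <= 99 & expected_length > 300))
    expect_true(any(expected_identity <= 99 & expected_length <= 300))
  })
  hits <- align_all(fx$queries, fx$subjects)
  links <- link_hits(hits, fx$taxonomy)
  # recovered identity/length of each planted pair match construction
  for (i in seq_len(nrow(fx$expected))) {
    h <- hits[hits$query_id == fx$expected$repseq_id[i] &
                hits$mag_id == fx$expected$mag_id[i], ]
    expect_equal(h$percent_identity, fx$expected$expected_identity[i],
                 tolerance = 1e-9)
    expect_equal(h$alignment_length, fx$expected$expected_length[i])
  }
  got <- links[links$accepted, ]
  want <- fx$expected[fx$expected$expected_link, ]
  expect_setequal(paste(got$mag_id, got$repseq_id),
                  paste(want$mag_id, want$repseq_id))
})

test_that("simulate_dataset writes a complete, reloadable input set", {
  cfg <- simulation_config(seed = 3, n_mags = 15, n_planted_degraders = 4,
                           n_differential = 3, n_associated = 3)
  dir <- withr::local_tempdir()
  paths <- simulate_dataset(cfg, dir)
  expect_true(all(file.exists(unlist(paths))))
  panel <- read_profiles(paths$panel)
  expect_length(panel, 12)
  ab <- read_matrix_tsv_for_test(paths$abundance)
  expect_equal(dim(ab), c(12, 15))
  expect_true(all(abs(rowSums(ab) - 1) < 1e-6))
  cfg_back <- yaml::read_yaml(paths$config)
  expect_equal(cfg_back$seed, 3)
  q <- Biostrings::readDNAStringSet(paths$queries)
  expect_equal(names(q), paste0("repseq", 1:5))
})
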