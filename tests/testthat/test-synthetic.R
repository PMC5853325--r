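test_that("truth generation honours exact labels, proportions and the seed", {
  # degenerate all-flat settings force every label
  flat <- generate_truth(100, archetype_props = c(descending = 0,
                                                  ascending = 0,
                                                  parabolic = 0, flat = 1),
                         n_c4_up = 0, n_c3_up = 0, effect_fold = 1, seed = 1)
  expect_equal(nrow(flat), 100)
  expect_true(all(flat$archetype == "flat"))
  expect_true(all(flat$pathway_effect == "none"))

  truth <- generate_truth(8000,
                          archetype_props = c(descending = 0.4,
                                              ascending = 0.2,
                                              parabolic = 0.1, flat = 0.3),
                          n_c4_up = 200, n_c3_up = 100, effect_fold = 4,
                          seed = 7)
  expect_equal(sum(truth$pathway_effect == "C4_up"), 200)
  expect_equal(sum(truth$pathway_effect == "C3_up"), 100)
  # descending count inside the Binomial(8000, 0.4) 99% interval
  ci <- qbinom(c(0.005, 0.995), 8000, 0.4)
  n_desc <- sum(truth$archetype == "descending")
  expect_gte(n_desc, ci[1])
  expect_lte(n_desc, ci[2])

  # seed reproducibility
  again <- generate_truth(8000,
                          archetype_props = c(descending = 0.4,
                                              ascending = 0.2,
                                              parabolic = 0.1, flat = 0.3),
                          n_c4_up = 200, n_c3_up = 100, effect_fold = 4,
                          seed = 7)
  expect_identical(truth, again)
})

test_that("truth generation rejects inconsistent requests", {
  expect_error(generate_truth(10, archetype_props = c(descending = 0.5,
                                                      ascending = 0.5,
                                                      parabolic = 0.2,
                                                      flat = 0)),
               "sum to 1")
  expect_error(generate_truth(10, n_c4_up = -1), ">= 0")
  expect_error(generate_truth(10, n_c4_up = 8, n_c3_up = 5), "exceeds")
  expect_error(generate_truth(10, effect_fold = 0.5), ">= 1")
})

test_that("zero-noise all-flat simulation is constant and column-normalized", {
  truth <- generate_truth(50, archetype_props = c(descending = 0,
                                                  ascending = 0,
                                                  parabolic = 0, flat = 1),
                          effect_fold = 1, seed = 2)
  sim <- simulate_expression(truth, noise_cv = 0, species_effect_sd = 0,
                             scheme = annotation_scheme(50, 50), seed = 3)
  v <- expr_values(sim$expression)
  expect_equal(unname(colSums(v)), rep(1e6, ncol(v)), tolerance = 1e-9)
  # constant across stages and identical replicates within species
  s <- sample_info(sim$expression)
  for (sp in unique(s$species)) {
    cols <- s$sample[s$species == sp]
    expect_true(all(abs(v[, cols] - v[, cols[1]]) < 1e-6))
  }
})

test_that("planted descending contrast survives column rescaling", {
  # one descending gene among flat genes, no noise: its base-group /
  # tip-group ratio must match the archetype multiplier table
  truth <- generate_truth(40, archetype_props = c(descending = 0,
                                                  ascending = 0,
                                                  parabolic = 0, flat = 1),
                          effect_fold = 5, seed = 4)
  truth$archetype[1] <- "descending"
  sim <- simulate_expression(truth, noise_cv = 0, species_effect_sd = 0,
                             scheme = annotation_scheme(40, 40), seed = 5)
  sm <- average_replicates(sim$expression)
  s <- sample_info(sm)
  cols <- s$sample[s$species == "Fp"][order(s$stage[s$species == "Fp"])]
  # TPM rescaling multiplies each stage by a common factor; a planted flat
  # gene recovers that factor, so dividing stage-wise restores the profile
  profile <- expr_values(sm)[truth$gene_id[1], cols] /
    expr_values(sm)[truth$gene_id[2], cols]
  mult <- archetype_multipliers(5)["descending", ]
  expect_equal(unname(profile / profile[6]), unname(mult),
               tolerance = 1e-8)
  grouping <- stage_grouping(6)
  observed <- mean(profile[grouping == "base"]) /
    mean(profile[grouping == "tip"])
  expect_equal(observed, 5, tolerance = 1e-8)
  # calibration: the group contrast of the multiplier table is the fold
  expect_equal(mean(mult[grouping == "base"]) /
                 mean(mult[grouping == "tip"]), 5)
})

test_that("simulation is seed-reproducible and validates inputs", {
  truth <- generate_truth(30, seed = 1)
  a <- simulate_expression(truth, scheme = annotation_scheme(20, 25),
                           seed = 9)
  b <- simulate_expression(truth, scheme = annotation_scheme(20, 25),
                           seed = 9)
  expect_identical(expr_values(a$expression), expr_values(b$expression))
  expect_identical(a$annotation, b$annotation)
  expect_error(simulate_expression(truth, noise_cv = -0.1), ">= 0")
})

test_that("annotation maps realize the sharing scheme", {
  truth <- generate_truth(200, n_c4_up = 10, n_c3_up = 5, seed = 6)
  sim <- simulate_expression(truth, scheme = annotation_scheme(120, 160),
                             seed = 7)
  per_species <- vapply(sim$annotated_genes, length, 0L)
  expect_true(all(per_species == 160))
  shared <- shared_annotation_set(sim$annotation)
  expect_gte(length(shared), 120)
  # planted effects always analyzable in the shared core
  effects <- truth$gene_id[truth$pathway_effect != "none"]
  expect_true(all(effects %in% shared))
  # a contig maps to exactly one gene
  for (m in sim$annotation) expect_false(anyDuplicated(m$contig) > 0)
})

test_that("count-mode simulation feeds counts_to_tpm", {
  truth <- generate_truth(40, seed = 3)
  cm <- simulate_counts(truth, design = sample_design(n_stages = 3,
                                                      n_replicates = 1),
                        seed = 4)
  expect_equal(cm$counts$kind, "counts")
  tpm <- counts_to_tpm(cm$counts, cm$lengths)
  expect_equal(unname(colSums(expr_values(tpm))),
               rep(1e6, ncol(expr_values(tpm))), tolerance = 1e-9)
})
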