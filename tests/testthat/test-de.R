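test_that("shared annotation set is the intersection of gene images", {
  maps <- list(
    data.frame(contig = paste0("a", 1:3), gene = c("A", "B", "C")),
    data.frame(contig = paste0("b", 1:2), gene = c("B", "C")),
    data.frame(contig = paste0("c", 1:3), gene = c("B", "C", "D")),
    data.frame(contig = paste0("d", 1:2), gene = c("B", "C"))
  )
  expect_setequal(shared_annotation_set(maps), c("B", "C"))
  # identical maps: all genes
  expect_setequal(shared_annotation_set(maps[c(1, 1)]), c("A", "B", "C"))
  expect_warning(
    empty <- shared_annotation_set(list(
      data.frame(contig = "a", gene = "A"),
      data.frame(contig = "b", gene = "B")
    )),
    "no gene"
  )
  expect_length(empty, 0)
  expect_error(shared_annotation_set(maps[1]), "two")
})

de_fixture <- function(c4_means, c3_means, gene = "g1") {
  tiny_stage_means(list(
    Fp = matrix(c3_means[1], 1, 6, dimnames = list(gene, NULL)),
    Fr = matrix(c3_means[2], 1, 6, dimnames = list(gene, NULL)),
    Fb = matrix(c4_means[1], 1, 6, dimnames = list(gene, NULL)),
    Ft = matrix(c4_means[2], 1, 6, dimnames = list(gene, NULL))
  ))
}

test_that("stage calls require consistency across both congeners", {
  # identical expression: none
  same <- de_fixture(c(10, 10), c(10, 10))
  expect_equal(call_stage_de(same, 1)$direction, "none")

  # C4 {40, 50} vs C3 {10, 5}: 40 >= 2 x 10 -> C4_up
  up <- call_stage_de(de_fixture(c(40, 50), c(10, 5)), 3)
  expect_equal(up$direction, "C4_up")
  expect_equal(up$min_cross_fold, 4)

  # C4 {40, 15} vs C3 {10, 5}: 15 < 2 x 10 -> none
  expect_equal(call_stage_de(de_fixture(c(40, 15), c(10, 5)), 3)$direction,
               "none")

  # floor: favoured pair below 1 TPM is not called
  expect_equal(call_stage_de(de_fixture(c(0.8, 0.9), c(0.1, 0.1)),
                             1)$direction, "none")

  # a species absent at the stage is an error
  sm <- de_fixture(c(40, 50), c(10, 5))
  drop <- sm$samples$sample != "Ft_s3"
  cut <- stage_mean_matrix(sm$values[, sm$samples$sample[drop],
                                     drop = FALSE],
                           sm$samples[drop, ])
  expect_error(call_stage_de(cut, 3), "Ft")
})

test_that("swapping pathway labels exactly swaps the call directions", {
  sim <- small_simulation(n_genes = 300, n_c4_up = 15, n_c3_up = 5, seed = 8)
  sm <- average_replicates(sim$expression)
  swapped_map <- c(Fp = "C4", Fr = "C4", Fb = "C3", Ft = "C3")
  x2 <- expression_matrix(expr_values(sim$expression),
                          species_pathway = swapped_map)
  sm2 <- average_replicates(x2)
  for (st in c(1, 4, 6)) {
    a <- call_stage_de(sm, st)
    b <- call_stage_de(sm2, st)
    b <- b[match(a$gene, b$gene), ]
    expect_identical(a$direction == "C4_up", b$direction == "C3_up")
    expect_identical(a$direction == "C3_up", b$direction == "C4_up")
  }
})

test_that("increasing the fold margin never increases call counts", {
  sim <- small_simulation(n_genes = 300, n_c4_up = 15, n_c3_up = 5, seed = 9)
  sm <- average_replicates(sim$expression)
  sweep <- de_fold_sweep(sm, folds = c(1.5, 2, 3))
  for (st in unique(sweep$stage)) {
    sub <- sweep[sweep$stage == st, ]
    sub <- sub[order(sub$fold), ]
    expect_true(all(diff(sub$C4_up) <= 0))
    expect_true(all(diff(sub$C3_up) <= 0))
  }
})

test_that("planted tip effects are recovered and null data stays quiet", {
  tip_counts <- numeric(5)
  for (i in 1:5) {
    truth <- generate_truth(1000, n_c4_up = 50, n_c3_up = 0, seed = 20 + i)
    sim <- simulate_expression(truth, noise_cv = 0.1, species_effect_sd = 0,
                               scheme = annotation_scheme(800, 950),
                               seed = 30 + i)
    sm <- average_replicates(sim$expression)
    shared <- shared_annotation_set(sim$annotation)
    prof <- de_profile(call_stage_de(sm, 6, genes = shared))
    tip_counts[i] <- prof$C4_up[prof$stage == 6]
  }
  # recovery of the planted count under the default rule (50 planted)
  expect_true(all(tip_counts >= 45 & tip_counts <= 55))

  # null fixture: false calls at most 1% of genes per stage
  null_truth <- generate_truth(1000, n_c4_up = 0, n_c3_up = 0, seed = 40)
  null_sim <- simulate_expression(null_truth, noise_cv = 0.1,
                                  species_effect_sd = 0,
                                  scheme = annotation_scheme(800, 950),
                                  seed = 41)
  nsm <- average_replicates(null_sim$expression)
  nshared <- shared_annotation_set(null_sim$annotation)
  calls <- call_de_all_stages(nsm, genes = nshared)
  prof <- de_profile(calls)
  expect_true(all((prof$C4_up + prof$C3_up) <= 0.01 * length(nshared)))

  # empty call set gives a zero table
  expect_equal(nrow(de_profile(calls[0, ])), 0)
})

test_that("de_profile groups calls across base/mid/tip stages", {
  calls <- data.frame(
    gene = c("g1", "g1", "g2", "g3"),
    stage = c(5, 6, 5, 2),
    direction = c("C4_up", "C4_up", "C4_up", "C3_up")
  )
  prof <- de_profile(calls, grouping = stage_grouping(6))
  groups <- attr(prof, "groups")
  expect_setequal(groups$tip$C4_up$union, c("g1", "g2"))
  expect_equal(groups$tip$C4_up$intersection, "g1")
  expect_equal(groups$base$C3_up$union, "g3")
})

test_that("the Welch variant agrees on strong, clean contrasts", {
  truth <- generate_truth(200, n_c4_up = 10, n_c3_up = 0, seed = 50)
  sim <- simulate_expression(truth, noise_cv = 0.05, species_effect_sd = 0,
                             scheme = annotation_scheme(200, 200), seed = 51)
  welch <- call_stage_de_welch(sim$expression, 6, alpha = 0.01)
  planted <- truth$gene_id[truth$pathway_effect == "C4_up"]
  expect_gte(mean(welch$direction[welch$gene %in% planted] == "C4_up"), 0.9)
})
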