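# shared fixture builders; everything is generated in code at test time

two_pathway_map <- function() c(Fp = "C3", Fr = "C3", Fb = "C4", Ft = "C4")

# tiny expression matrix with explicit values: one column per
# (species, stage, replicate) in `design`
tiny_expression <- function(values,
                            design = sample_design(species = c(Fp = "C3"),
                                                   n_stages = 2,
                                                   n_replicates = 1)) {
  meta <- c4gradient:::design_samples(design)
  stopifnot(ncol(values) == nrow(meta))
  colnames(values) <- meta$sample
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  expression_matrix(values, kind = "tpm", species_pathway = design$species)
}

# stage-mean matrix from a named list species -> genes x stages matrix
tiny_stage_means <- function(per_species,
                             species_pathway = two_pathway_map()) {
  sp <- names(per_species)
  mats <- lapply(sp, function(s) {
    m <- per_species[[s]]
    colnames(m) <- paste0(s, "_s", seq_len(ncol(m)))
    m
  })
  values <- do.call(cbind, mats)
  samples <- do.call(rbind, lapply(sp, function(s) {
    n <- ncol(per_species[[s]])
    data.frame(sample = paste0(s, "_s", seq_len(n)), species = s,
               pathway = unname(species_pathway[s]), stage = seq_len(n),
               stringsAsFactors = FALSE)
  }))
  stage_mean_matrix(values, samples)
}

# standard study-condition fixture, small gene count for unit tests
small_simulation <- function(n_genes = 500, n_c4_up = 20, n_c3_up = 10,
                             noise_cv = 0.2, species_effect_sd = 0.3,
                             seed = 1) {
  truth <- generate_truth(n_genes, n_c4_up = n_c4_up, n_c3_up = n_c3_up,
                          seed = seed)
  simulate_expression(
    truth,
    noise_cv = noise_cv, species_effect_sd = species_effect_sd,
    scheme = annotation_scheme(shared_core = round(0.8 * n_genes),
                               per_species = round(0.95 * n_genes)),
    seed = seed + 1000
  )
}
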