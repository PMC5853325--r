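ARCHETYPES <- c("descending", "ascending", "parabolic", "flat")
PATHWAY_EFFECTS <- c("C4_up", "C3_up", "none")

#' Stage-multiplier table for the four profile archetypes
#'
#' Descending transcripts decay geometrically from base to tip, ascending
#' mirror them, parabolic transcripts are high at both ends and lowest
#' mid-leaf, flat transcripts are constant. Exponents are scaled so that the
#' base-group versus tip-group contrast of a descending/ascending gene (and
#' the end-versus-mid contrast of a parabolic gene, up to the arithmetic-mean
#' inequality which can only enlarge it) equals `effect_fold` exactly under
#' the supplied stage grouping — i.e. `effect_fold` is the contrast the
#' behaviour classifier thresholds, not the raw stage-1:stage-n ratio.
#'
#' @param effect_fold planted fold contrast, >= 1.
#' @param n_stages number of leaf stages.
#' @param grouping a [stage_grouping()] used to calibrate the contrast.
#' @return 4 x `n_stages` matrix, rows named by archetype.
#' @export
#' @examples
#' archetype_multipliers(4)
archetype_multipliers <- function(effect_fold, n_stages = 6L,
                                  grouping = stage_grouping(n_stages)) {
  if (effect_fold < 1) stop("`effect_fold` must be >= 1")
  s <- seq_len(n_stages)
  e <- (n_stages - s) / (n_stages - 1)                # 1 at base, 0 at tip
  d_base <- mean(e[grouping == "base"]) - mean(e[grouping == "tip"])
  mono <- e / d_base
  centre <- (n_stages + 1) / 2
  d <- abs(s - centre) / max(abs(s - centre))         # 1 at ends, min mid
  d_par <- mean(d[grouping == "base"]) - mean(d[grouping == "mid"])
  par <- d / d_par
  rbind(
    descending = effect_fold^mono,
    ascending = effect_fold^rev(mono),
    parabolic = effect_fold^par,
    flat = rep(1, n_stages)
  )
}

#' Generate a planted ground-truth table
#'
#' Assigns every gene a stage-profile archetype (multinomially, from
#' `archetype_props`), a pathway-effect label (exactly `n_c4_up` genes
#' `C4_up` and `n_c3_up` genes `C3_up`, the rest `none`), a fold contrast and
#' a log-normal baseline abundance.
#'
#' @param n_genes size of the simulated gene universe.
#' @param archetype_props probability vector over
#'   `c("descending", "ascending", "parabolic", "flat")`; must sum to 1.
#' @param n_c4_up,n_c3_up exact numbers of genes planted up in the C4 (resp.
#'   C3) pathway pair.
#' @param effect_fold planted fold contrast (>= 1) used for both archetype
#'   gradients and pathway effects.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline TPM-scale abundance.
#' @param seed integer RNG seed recorded in the table.
#' @return data.frame of class `"SyntheticTruth"` with columns `gene_id`,
#'   `archetype`, `pathway_effect`, `effect_fold`, `baseline`, `seed`.
#' @export
#' @examples
#' truth <- generate_truth(100, seed = 1)
#' table(truth$archetype)
generate_truth <- function(n_genes,
                           archetype_props = c(descending = 0.4,
                                               ascending = 0.2,
                                               parabolic = 0.1,
                                               flat = 0.3),
                           n_c4_up = 0L, n_c3_up = 0L, effect_fold = 4,
                           baseline_meanlog = log(50), baseline_sdlog = 1,
                           seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (n_genes < 1) stop("`n_genes` must be positive")
  if (length(archetype_props) != 4) {
    stop("`archetype_props` must have 4 entries (",
         paste(ARCHETYPES, collapse = ", "), ")")
  }
  if (is.null(names(archetype_props))) names(archetype_props) <- ARCHETYPES
  if (!setequal(names(archetype_props), ARCHETYPES)) {
    stop("`archetype_props` names must be: ",
         paste(ARCHETYPES, collapse = ", "))
  }
  archetype_props <- archetype_props[ARCHETYPES]
  if (any(archetype_props < 0)) stop("archetype proportions must be >= 0")
  if (abs(sum(archetype_props) - 1) > 1e-8) {
    stop("`archetype_props` must sum to 1 (got ", sum(archetype_props), ")")
  }
  n_c4_up <- as.integer(n_c4_up); n_c3_up <- as.integer(n_c3_up)
  if (n_c4_up < 0 || n_c3_up < 0) stop("planted effect counts must be >= 0")
  if (n_c4_up + n_c3_up > n_genes) {
    stop("n_c4_up + n_c3_up exceeds n_genes")
  }
  if (effect_fold < 1) stop("`effect_fold` must be >= 1")

  set.seed(seed)
  archetype <- sample(ARCHETYPES, n_genes, replace = TRUE,
                      prob = archetype_props)
  pathway_effect <- rep("none", n_genes)
  idx <- sample.int(n_genes, n_c4_up + n_c3_up)
  if (n_c4_up > 0) pathway_effect[idx[seq_len(n_c4_up)]] <- "C4_up"
  if (n_c3_up > 0) pathway_effect[idx[n_c4_up + seq_len(n_c3_up)]] <- "C3_up"
  baseline <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)

  truth <- data.frame(
    gene_id = sprintf("G%06d", seq_len(n_genes)),
    archetype = archetype,
    pathway_effect = pathway_effect,
    effect_fold = effect_fold,
    baseline = baseline,
    seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
  class(truth) <- c("SyntheticTruth", "data.frame")
  truth
}

#' Describe how reference-gene annotations are shared across species
#'
#' Each species annotates the shared core plus a species-specific sample of
#' the remaining universe; each annotated gene is represented by one or more
#' contigs (1 + Poisson multiplicity).
#'
#' @param shared_core number of reference genes annotated in every species.
#' @param per_species total annotated reference genes per species.
#' @param contig_rate Poisson rate of extra contigs per gene (expected
#'   contigs per gene is `1 + contig_rate`; the default targets roughly
#'   12,475 contigs for 9,500 genes).
#' @return list of class `"AnnotationScheme"`.
#' @export
annotation_scheme <- function(shared_core = 8000L, per_species = 9500L,
                              contig_rate = 0.313) {
  shared_core <- as.integer(shared_core)
  per_species <- as.integer(per_species)
  if (shared_core < 1) stop("`shared_core` must be positive")
  if (per_species < shared_core) {
    stop("`per_species` must be >= `shared_core`")
  }
  if (contig_rate < 0) stop("`contig_rate` must be >= 0")
  structure(list(shared_core = shared_core, per_species = per_species,
                 contig_rate = contig_rate),
            class = "AnnotationScheme")
}

#' Simulate a multi-species gradient expression fixture
#'
#' The mean profile of gene g in species p at stage s is
#' `baseline_g * archetype_multiplier_g(s) * pathway_multiplier_g(p) *
#' species_multiplier_{g,p}`; replicate values are drawn multiplicatively
#' log-normal with coefficient of variation `noise_cv` (mean-preserving),
#' genes not annotated in a species are zeroed in that species, and every
#' sample column is rescaled to sum to 10^6 (TPM). Pathway multipliers apply
#' `effect_fold` to both species of the favoured pathway at all stages.
#' Genes carrying a planted pathway effect are always placed in the shared
#' annotation core so the cross-species contrast can see them.
#'
#' @param truth a [generate_truth()] table.
#' @param design a [sample_design()].
#' @param noise_cv replicate-level coefficient of variation, >= 0.
#' @param species_effect_sd log-scale sd of the per-gene, per-species
#'   idiosyncratic multiplier (mean-preserving log-normal), >= 0.
#' @param scheme an [annotation_scheme()]; its sizes are capped at
#'   `nrow(truth)`.
#' @param seed integer RNG seed (independent of the truth's seed).
#' @return list of class `"GradientSimulation"` with elements `expression`
#'   (TPM [expression_matrix()]), `annotation` (named list of contig->gene
#'   data.frames, one per species), `annotated_genes` (named list of gene-ID
#'   vectors), `truth`, `design`, `scheme`, `seed`.
#' @export
simulate_expression <- function(truth, design = sample_design(),
                                noise_cv = 0.2, species_effect_sd = 0.3,
                                scheme = annotation_scheme(), seed = 1L) {
  if (!inherits(truth, "SyntheticTruth") || nrow(truth) == 0) {
    stop("`truth` must be a non-empty SyntheticTruth table")
  }
  if (!inherits(design, "SampleDesign")) stop("`design` must be a SampleDesign")
  if (noise_cv < 0) stop("`noise_cv` must be >= 0")
  if (species_effect_sd < 0) stop("`species_effect_sd` must be >= 0")
  has_effects <- any(truth$pathway_effect != "none")
  if (has_effects && length(unique(design$species)) < 2) {
    stop("pathway effects planted but the design lacks one of C3/C4")
  }

  n_genes <- nrow(truth)
  sp <- names(design$species)
  n_sp <- length(sp)
  set.seed(seed)

  # stage multipliers per gene
  mult <- archetype_multipliers(truth$effect_fold[1], design$n_stages)
  stage_mult <- mult[truth$archetype, , drop = FALSE]
  if (length(unique(truth$effect_fold)) > 1) {
    # per-gene folds: recompute rows where the fold differs from the first
    for (f in unique(truth$effect_fold)) {
      rows <- which(truth$effect_fold == f)
      stage_mult[rows, ] <- archetype_multipliers(f, design$n_stages)[
        truth$archetype[rows], , drop = FALSE]
    }
  }

  # pathway multipliers per gene x species
  path_mult <- matrix(1, n_genes, n_sp, dimnames = list(NULL, sp))
  for (j in seq_len(n_sp)) {
    pw <- design$species[j]
    up <- if (pw == "C4") "C4_up" else "C3_up"
    hit <- truth$pathway_effect == up
    path_mult[hit, j] <- truth$effect_fold[hit]
  }

  # idiosyncratic species effects, mean-preserving log-normal
  sp_mult <- matrix(
    stats::rlnorm(n_genes * n_sp, -species_effect_sd^2 / 2,
                  species_effect_sd),
    n_genes, n_sp, dimnames = list(NULL, sp)
  )
  if (species_effect_sd == 0) sp_mult[] <- 1

  # per-species annotated gene sets: effect genes forced into shared core
  core_n <- min(scheme$shared_core, n_genes)
  per_sp_n <- min(scheme$per_species, n_genes)
  effect_idx <- which(truth$pathway_effect != "none")
  if (length(effect_idx) > core_n) {
    stop("shared core smaller than the number of planted pathway effects")
  }
  rest <- setdiff(seq_len(n_genes), effect_idx)
  core_idx <- c(effect_idx, sample(rest, core_n - length(effect_idx)))
  noncore <- setdiff(seq_len(n_genes), core_idx)
  annotated <- lapply(sp, function(s) {
    extra <- if (per_sp_n > core_n) sample(noncore, per_sp_n - core_n)
             else integer()
    sort(c(core_idx, extra))
  })
  names(annotated) <- sp

  # expression values
  meta <- design_samples(design)
  sdlog <- sqrt(log(1 + noise_cv^2))
  values <- matrix(0, n_genes, nrow(meta),
                   dimnames = list(truth$gene_id, meta$sample))
  for (k in seq_len(nrow(meta))) {
    s <- meta$species[k]
    mu <- truth$baseline * stage_mult[, meta$stage[k]] *
      path_mult[, s] * sp_mult[, s]
    noise <- if (noise_cv > 0) stats::rlnorm(n_genes, -sdlog^2 / 2, sdlog)
             else 1
    v <- mu * noise
    v[-annotated[[s]]] <- 0
    values[, k] <- v / sum(v) * 1e6
  }

  # contig->gene maps realizing the multiplicity distribution
  annotation <- lapply(sp, function(s) {
    genes <- truth$gene_id[annotated[[s]]]
    n_contig <- 1L + stats::rpois(length(genes), scheme$contig_rate)
    data.frame(
      contig = sprintf("%s_c%06d", s, seq_len(sum(n_contig))),
      gene = rep(genes, n_contig),
      stringsAsFactors = FALSE
    )
  })
  names(annotation) <- sp

  structure(
    list(
      expression = expression_matrix(values, kind = "tpm",
                                     species_pathway = design$species),
      annotation = annotation,
      annotated_genes = lapply(annotated, function(i) truth$gene_id[i]),
      truth = truth, design = design, scheme = scheme,
      seed = as.integer(seed)
    ),
    class = "GradientSimulation"
  )
}

#' @export
print.GradientSimulation <- function(x, ...) {
  cat("GradientSimulation: ", nrow(x$truth), " genes, ",
      length(x$design$species), " species, seed ", x$seed, "\n", sep = "")
  print(x$expression)
  invisible(x)
}

#' Simulate an integer count matrix with transcript lengths
#'
#' Companion to [simulate_expression()] for exercising the counts-to-TPM
#' path: expected counts are proportional to (relative molar abundance x
#' transcript length), Poisson-sampled at the requested depth.
#'
#' @param truth a [generate_truth()] table.
#' @param design a [sample_design()].
#' @param lib_size expected reads per sample.
#' @param length_range transcript lengths drawn uniformly from this range.
#' @param seed integer RNG seed.
#' @return list with elements `counts` (counts [expression_matrix()]) and
#'   `lengths` (named numeric vector).
#' @export
simulate_counts <- function(truth, design = sample_design(),
                            lib_size = 5e5, length_range = c(500, 3000),
                            seed = 1L) {
  if (!inherits(truth, "SyntheticTruth") || nrow(truth) == 0) {
    stop("`truth` must be a non-empty SyntheticTruth table")
  }
  set.seed(seed)
  n_genes <- nrow(truth)
  lengths <- stats::setNames(
    round(stats::runif(n_genes, length_range[1], length_range[2])),
    truth$gene_id
  )
  mult <- archetype_multipliers(truth$effect_fold[1], design$n_stages)
  stage_mult <- mult[truth$archetype, , drop = FALSE]
  meta <- design_samples(design)
  counts <- matrix(0, n_genes, nrow(meta),
                   dimnames = list(truth$gene_id, meta$sample))
  for (k in seq_len(nrow(meta))) {
    w <- truth$baseline * stage_mult[, meta$stage[k]] * lengths
    counts[, k] <- stats::rpois(n_genes, w / sum(w) * lib_size)
  }
  list(
    counts = expression_matrix(counts, kind = "counts",
                               species_pathway = design$species),
    lengths = lengths
  )
}
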