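#' Map leaf stages to base/mid/tip groups
#'
#' Default for six stages: stages 1-2 are base, 3-4 mid, 5-6 tip.
#'
#' @param n_stages number of stages; must be divisible by 3 for the default
#'   equal split, otherwise supply `groups` explicitly.
#' @param groups optional character vector of length `n_stages` with values
#'   in `c("base", "mid", "tip")`.
#' @return Character vector of length `n_stages`, names `"1"..."n"`.
#' @export
#' @examples
#' stage_grouping(6)
stage_grouping <- function(n_stages = 6L, groups = NULL) {
  n_stages <- as.integer(n_stages)
  if (is.null(groups)) {
    if (n_stages %% 3 != 0) {
      stop("default grouping needs `n_stages` divisible by 3; ",
           "supply `groups` explicitly")
    }
    groups <- rep(c("base", "mid", "tip"), each = n_stages / 3)
  }
  if (length(groups) != n_stages) {
    stop("`groups` must have one entry per stage")
  }
  if (!all(groups %in% c("base", "mid", "tip"))) {
    stop("group labels must be base/mid/tip")
  }
  if (!all(c("base", "mid", "tip") %in% groups)) {
    stop("every group (base, mid, tip) must be non-empty")
  }
  stats::setNames(groups, as.character(seq_len(n_stages)))
}

#' Base/mid/tip group means per gene and species
#'
#' Arithmetic mean of the replicate-averaged stage means within each group.
#'
#' @param sm a [stage_mean_matrix()].
#' @param grouping a [stage_grouping()] covering every stage in `sm`.
#' @return data.frame with columns `gene`, `species`, `base`, `mid`, `tip`.
#' @export
group_means <- function(sm, grouping = stage_grouping(max(sample_info(sm)$stage))) {
  s <- sample_info(sm)
  missing <- setdiff(unique(s$stage), as.integer(names(grouping)))
  if (length(missing) > 0) {
    stop("stage(s) missing from the grouping: ",
         paste(missing, collapse = ", "))
  }
  values <- expr_values(sm)
  species <- unique(s$species)
  res <- lapply(species, function(sp) {
    out <- data.frame(gene = rownames(values), species = sp,
                      stringsAsFactors = FALSE)
    for (grp in c("base", "mid", "tip")) {
      stages <- as.integer(names(grouping)[grouping == grp])
      cols <- s$sample[s$species == sp & s$stage %in% stages]
      out[[grp]] <- rowMeans(values[, cols, drop = FALSE])
    }
    out
  })
  do.call(rbind, res)
}

#' Classify base-to-tip transcript behaviour
#'
#' Rules, applied in order per gene and species to the base/mid/tip group
#' means: genes with all groups below `floor` are `flat`; `descending` iff
#' base >= `fold_threshold` x tip; `ascending` iff tip >= `fold_threshold` x
#' base; `parabolic` iff min(base, tip) >= `fold_threshold` x mid and
#' neither monotone rule fired; otherwise `flat`. Exact ties at the
#' threshold resolve to the monotone class.
#'
#' @param gm a [group_means()] data.frame.
#' @param fold_threshold fold contrast (> 1) required for a non-flat call.
#' @param floor expression floor (TPM scale) below which a gene is treated
#'   as not expressed.
#' @return `gm` with an added `class` column, class `"BehaviorCall"`.
#' @export
#' @examples
#' gm <- data.frame(gene = "g1", species = "Fp",
#'                  base = 10, mid = 5, tip = 2)
#' classify_behavior(gm)$class
classify_behavior <- function(gm, fold_threshold = 2, floor = 1) {
  if (fold_threshold <= 1) stop("`fold_threshold` must be > 1")
  stopifnot(all(c("gene", "species", "base", "mid", "tip") %in% names(gm)))
  base <- gm$base; mid <- gm$mid; tip <- gm$tip
  cls <- rep("flat", nrow(gm))
  expressed <- base >= floor | mid >= floor | tip >= floor
  desc <- expressed & base >= fold_threshold * tip
  asc <- expressed & !desc & tip >= fold_threshold * base
  par <- expressed & !desc & !asc &
    pmin(base, tip) >= fold_threshold * mid
  cls[desc] <- "descending"
  cls[asc] <- "ascending"
  cls[par] <- "parabolic"
  out <- gm
  out$class <- cls
  attr(out, "fold_threshold") <- fold_threshold
  attr(out, "floor") <- floor
  class(out) <- c("BehaviorCall", "data.frame")
  out
}

#' Per-species behaviour-class fractions and four-species average
#'
#' Fractions are taken over the genes called in each species (the annotated
#' universe of that species); the `average` row is the unweighted mean
#' across species.
#'
#' @param calls a [classify_behavior()] table.
#' @return data.frame: one row per species plus `average`, columns
#'   `descending`, `ascending`, `parabolic`, `flat`, `n_genes`.
#' @export
behavior_summary <- function(calls) {
  if (nrow(calls) == 0) stop("no behaviour calls to summarize")
  species <- unique(calls$species)
  rows <- lapply(species, function(sp) {
    sub <- calls[calls$species == sp, ]
    frac <- vapply(ARCHETYPES, function(cl) mean(sub$class == cl), 0)
    data.frame(species = sp, t(frac), n_genes = nrow(sub),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  avg <- data.frame(species = "average",
                    t(colMeans(out[, ARCHETYPES, drop = FALSE])),
                    n_genes = sum(out$n_genes), stringsAsFactors = FALSE)
  rbind(out, avg)
}
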