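#' Reference genes annotated in every species
#'
#' Intersection of the gene-ID images of per-species annotation maps.
#'
#' @param maps list (>= 2) of annotation data.frames with a `gene` column,
#'   or of gene-ID character vectors.
#' @return Character vector of shared gene IDs (possibly empty, with a
#'   warning).
#' @export
shared_annotation_set <- function(maps) {
  if (length(maps) < 2) stop("need at least two annotation maps")
  sets <- lapply(maps, function(m) {
    if (is.data.frame(m)) unique(m$gene) else unique(as.character(m))
  })
  shared <- Reduce(intersect, sets)
  if (length(shared) == 0) {
    warning("no gene is annotated in all species")
  }
  shared
}

#' Pathway-consistent differential calls at one leaf stage
#'
#' A gene is `C4_up` at a stage iff the *smallest* C4-species stage mean is
#' at least `fold` times the *largest* C3-species stage mean and is at least
#' `floor`; `C3_up` is symmetric; otherwise `none`. The min-over-pair versus
#' max-over-pair margin operationalizes "up in both species of a pathway".
#'
#' @param sm a [stage_mean_matrix()] containing all four species at `stage`.
#' @param stage leaf stage to test.
#' @param fold consistency fold margin, >= 1.
#' @param floor TPM floor the favoured pair must reach.
#' @param genes optional gene-ID subset (e.g. the shared annotation set).
#' @return data.frame of class `"DifferentialCall"`: `gene`, `stage`,
#'   `direction`, one mean column per species, `min_cross_fold`.
#' @export
call_stage_de <- function(sm, stage, fold = 2, floor = 1, genes = NULL) {
  if (fold < 1) stop("`fold` must be >= 1")
  s <- sample_info(sm)
  pw <- unique(s[, c("species", "pathway")])
  if (length(unique(pw$pathway)) < 2) {
    stop("both pathways must be present in the design")
  }
  at_stage <- s[s$stage == stage, ]
  missing <- setdiff(pw$species, at_stage$species)
  if (length(missing) > 0) {
    stop("species absent at stage ", stage, ": ",
         paste(missing, collapse = ", "))
  }
  values <- expr_values(sm)
  if (!is.null(genes)) {
    unknown <- setdiff(genes, rownames(values))
    if (length(unknown) > 0) {
      stop("gene(s) not in the matrix: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    values <- values[genes, , drop = FALSE]
  }
  cols <- stats::setNames(at_stage$sample, at_stage$species)
  m <- values[, cols, drop = FALSE]
  colnames(m) <- names(cols)
  c4_sp <- pw$species[pw$pathway == "C4"]
  c3_sp <- pw$species[pw$pathway == "C3"]
  c4_min <- do.call(pmin, as.data.frame(m[, c4_sp, drop = FALSE]))
  c4_max <- do.call(pmax, as.data.frame(m[, c4_sp, drop = FALSE]))
  c3_min <- do.call(pmin, as.data.frame(m[, c3_sp, drop = FALSE]))
  c3_max <- do.call(pmax, as.data.frame(m[, c3_sp, drop = FALSE]))

  c4_up <- c4_min >= fold * c3_max & c4_min >= floor
  c3_up <- !c4_up & c3_min >= fold * c4_max & c3_min >= floor
  direction <- ifelse(c4_up, "C4_up", ifelse(c3_up, "C3_up", "none"))
  ratio_c4 <- ifelse(c3_max > 0, c4_min / c3_max, ifelse(c4_min > 0, Inf, 0))
  ratio_c3 <- ifelse(c4_max > 0, c3_min / c4_max, ifelse(c3_min > 0, Inf, 0))
  out <- data.frame(gene = rownames(values), stage = stage,
                    direction = direction, m,
                    min_cross_fold = pmax(ratio_c4, ratio_c3),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "fold") <- fold
  attr(out, "floor") <- floor
  class(out) <- c("DifferentialCall", "data.frame")
  out
}

#' Differential calls across all stages
#'
#' @inheritParams call_stage_de
#' @return A single `DifferentialCall` data.frame over all stages.
#' @export
call_de_all_stages <- function(sm, fold = 2, floor = 1, genes = NULL) {
  stages <- sort(unique(sample_info(sm)$stage))
  out <- do.call(rbind, lapply(stages, function(st) {
    call_stage_de(sm, st, fold = fold, floor = floor, genes = genes)
  }))
  attr(out, "fold") <- fold
  attr(out, "floor") <- floor
  class(out) <- c("DifferentialCall", "data.frame")
  out
}

#' Per-stage counts of pathway-consistent calls
#'
#' @param calls a `DifferentialCall` table (any number of stages).
#' @param grouping optional [stage_grouping()]; when supplied, the union and
#'   intersection of called gene sets within each base/mid/tip group are
#'   attached.
#' @return data.frame `stage` x (`C4_up`, `C3_up`) counts; when `grouping`
#'   is given, attribute `"groups"` holds per-group union/intersection gene
#'   sets by direction.
#' @export
de_profile <- function(calls, grouping = NULL) {
  stages <- sort(unique(calls$stage))
  if (length(stages) == 0) {
    return(data.frame(stage = integer(), C4_up = integer(),
                      C3_up = integer()))
  }
  counts <- data.frame(
    stage = stages,
    C4_up = vapply(stages, function(st)
      sum(calls$stage == st & calls$direction == "C4_up"), 0L),
    C3_up = vapply(stages, function(st)
      sum(calls$stage == st & calls$direction == "C3_up"), 0L)
  )
  if (!is.null(grouping)) {
    groups <- lapply(c("base", "mid", "tip"), function(grp) {
      gs <- as.integer(names(grouping)[grouping == grp])
      lapply(c(C4_up = "C4_up", C3_up = "C3_up"), function(dir) {
        per_stage <- lapply(gs, function(st) {
          calls$gene[calls$stage == st & calls$direction == dir]
        })
        list(union = Reduce(union, per_stage),
             intersection = Reduce(intersect, per_stage))
      })
    })
    names(groups) <- c("base", "mid", "tip")
    attr(counts, "groups") <- groups
  }
  counts
}

#' Count differential calls across a grid of fold margins
#'
#' The consistency cutoff behind the per-stage counts is a declared choice,
#' not an estimate; sweeping it makes its influence explicit.
#'
#' @param sm a [stage_mean_matrix()].
#' @param folds numeric vector of fold margins.
#' @inheritParams call_stage_de
#' @return data.frame with columns `fold`, `stage`, `C4_up`, `C3_up`.
#' @export
de_fold_sweep <- function(sm, folds = c(1.5, 2, 3), floor = 1,
                          genes = NULL) {
  out <- lapply(folds, function(f) {
    prof <- de_profile(call_de_all_stages(sm, fold = f, floor = floor,
                                          genes = genes))
    cbind(fold = f, prof)
  })
  do.call(rbind, out)
}

#' Welch-test variant of the per-stage pathway contrast
#'
#' Sensitivity-analysis alternative to the consistency margin: per gene and
#' stage, a Welch t-test of log2(x + 1) replicate values, C4 species pooled
#' versus C3 species pooled.
#'
#' @param x a replicate-level [expression_matrix()].
#' @param stage leaf stage to test.
#' @param alpha significance level for a non-`none` call.
#' @param floor TPM floor the favoured pathway's pooled mean must reach.
#' @return data.frame `gene`, `stage`, `direction`, `p_value`.
#' @export
call_stage_de_welch <- function(x, stage, alpha = 0.05, floor = 1) {
  s <- sample_info(x)
  sel <- s$stage == stage
  if (!any(sel)) stop("no samples at stage ", stage)
  v <- log2(expr_values(x)[, s$sample[sel], drop = FALSE] + 1)
  is_c4 <- s$pathway[sel] == "C4"
  if (!any(is_c4) || all(is_c4)) stop("both pathways needed at the stage")
  res <- apply(v, 1, function(row) {
    if (stats::sd(row) == 0) return(c(p = 1, d = 0))
    t <- tryCatch(stats::t.test(row[is_c4], row[!is_c4]),
                  error = function(e) NULL)
    if (is.null(t)) return(c(p = 1, d = 0))
    c(p = t$p.value, d = mean(row[is_c4]) - mean(row[!is_c4]))
  })
  p <- res["p", ]; d <- res["d", ]
  mean_c4 <- 2^apply(v[, is_c4, drop = FALSE], 1, mean) - 1
  mean_c3 <- 2^apply(v[, !is_c4, drop = FALSE], 1, mean) - 1
  direction <- ifelse(p <= alpha & d > 0 & mean_c4 >= floor, "C4_up",
                      ifelse(p <= alpha & d < 0 & mean_c3 >= floor,
                             "C3_up", "none"))
  data.frame(gene = rownames(v), stage = stage, direction = direction,
             p_value = p, stringsAsFactors = FALSE, row.names = NULL)
}
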