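#' Pathway-contrast ranking scores for one species and stage
#'
#' Score of a gene = |log2((own stage mean + 1) / (mean of the other
#' pathway's species at that stage + 1))|; the ranking behind "top decile of
#' differentially expressed genes".
#'
#' @param sm a [stage_mean_matrix()] with both pathways present.
#' @param species species whose contrast is scored.
#' @param stage leaf stage.
#' @return Named numeric vector of scores.
#' @export
pathway_contrast_scores <- function(sm, species, stage) {
  s <- sample_info(sm)
  own <- s$sample[s$species == species & s$stage == stage]
  if (length(own) != 1) stop("species/stage not found: ", species, ", ", stage)
  own_pw <- s$pathway[s$sample == own]
  other <- s$sample[s$pathway != own_pw & s$stage == stage]
  if (length(other) == 0) stop("no other-pathway samples at stage ", stage)
  values <- expr_values(sm)
  ref <- rowMeans(values[, other, drop = FALSE])
  abs(log2((values[, own] + 1) / (ref + 1)))
}

#' Select the top decile of a scored gene list
#'
#' Keeps the top `ceiling(0.1 * n)` genes by score; ties are broken by
#' lexicographic gene-ID order so the selection is deterministic.
#'
#' @param scores named numeric vector (gene -> score), no missing values,
#'   at least 10 genes.
#' @return Character vector of selected gene IDs.
#' @export
#' @examples
#' top_decile(stats::setNames(1:100, sprintf("g%03d", 1:100)))
top_decile <- function(scores) {
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("`scores` must be named by gene ID")
  }
  if (anyNA(scores)) {
    stop("unscored gene(s): ",
         paste(utils::head(names(scores)[is.na(scores)], 5), collapse = ", "))
  }
  if (length(scores) < 10) stop("need at least 10 scored genes")
  n_sel <- ceiling(0.1 * length(scores))
  ord <- order(-scores, names(scores))
  names(scores)[ord[seq_len(n_sel)]]
}

#' Hypergeometric category over-representation with BH control
#'
#' For each category, the upper-tail hypergeometric probability
#' P(X >= k) with X ~ Hypergeom(N = |universe|, K = |category in universe|,
#' n = |selected|) where k is the category/selection overlap;
#' Benjamini-Hochberg q-values across the categories tested in this call
#' (one stage x species context).
#'
#' @param selected gene set of interest; must be a subset of `universe`.
#' @param universe background gene set.
#' @param categories named list, category id -> gene IDs
#'   (see [read_category_table()]); categories are intersected with the
#'   universe, and empty intersections are dropped.
#' @return data.frame of class `"EnrichmentResult"`, sorted by p: `category`,
#'   `N`, `K`, `n`, `k`, `p_value`, `q_value`.
#' @export
hypergeom_enrich <- function(selected, universe, categories) {
  selected <- unique(selected)
  universe <- unique(universe)
  outside <- setdiff(selected, universe)
  if (length(outside) > 0) {
    stop("selected gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "),
         if (length(outside) > 5) ", ...")
  }
  if (length(categories) == 0) stop("no categories to test")
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(categories), function(id) {
    cat_genes <- intersect(unique(categories[[id]]), universe)
    K <- length(cat_genes)
    if (K == 0) return(NULL)
    k <- length(intersect(cat_genes, selected))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = id, N = N, K = K, n = n, k = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no category overlaps the universe")
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$category), ]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}
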