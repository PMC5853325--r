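#' Convert a count matrix to transcripts per million
#'
#' Per sample, `rate_g = count_g / length_g` and
#' `TPM_g = rate_g / sum(rate) * 1e6`, so every column sums to 10^6.
#'
#' @param counts a counts-mode [expression_matrix()].
#' @param lengths named numeric vector of positive transcript lengths; taken
#'   from the matrix's `"lengths"` attribute if missing.
#' @return A TPM-mode `ExpressionMatrix`.
#' @export
counts_to_tpm <- function(counts, lengths = attr(counts, "lengths")) {
  if (!inherits(counts, "ExpressionMatrix") || counts$kind != "counts") {
    stop("`counts` must be a counts-mode ExpressionMatrix")
  }
  if (is.null(lengths)) stop("transcript `lengths` are required")
  values <- counts$values
  missing <- setdiff(rownames(values), names(lengths))
  if (length(missing) > 0) {
    stop("missing transcript length(s) for: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...")
  }
  len <- lengths[rownames(values)]
  if (any(len <= 0)) stop("transcript lengths must be positive")
  zero_cols <- colnames(values)[colSums(values) == 0]
  if (length(zero_cols) > 0) {
    stop("all-zero count column(s): ", paste(zero_cols, collapse = ", "))
  }
  rate <- values / len
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  expression_matrix(tpm, kind = "tpm",
                    species_pathway = pathway_map_of(counts))
}

pathway_map_of <- function(x) {
  s <- sample_info(x)
  m <- unique(s[, c("species", "pathway")])
  stats::setNames(m$pathway, m$species)
}

#' Collapse a contig-level matrix to reference-gene level
#'
#' The value for a gene is the sum of its contigs' values; contigs absent
#' from the annotation map are dropped (count reported via a message).
#'
#' @param x a contig-level [expression_matrix()].
#' @param map data.frame with columns `contig`, `gene`
#'   (see [read_annotation_map()]).
#' @return A gene-level `ExpressionMatrix` of the same kind.
#' @export
collapse_by_annotation <- function(x, map) {
  if (!inherits(x, "ExpressionMatrix")) {
    stop("`x` must be an ExpressionMatrix")
  }
  values <- x$values
  annotated <- intersect(rownames(values), map$contig)
  if (length(annotated) == 0) {
    stop("no contig in the matrix is covered by the annotation map")
  }
  dropped <- nrow(values) - length(annotated)
  if (dropped > 0) {
    message(dropped, " unannotated contig(s) dropped during collapse")
  }
  sub <- values[annotated, , drop = FALSE]
  genes <- stats::setNames(map$gene, map$contig)[annotated]
  out <- rowsum(sub, group = genes, reorder = TRUE)
  expression_matrix(out, kind = x$kind,
                    species_pathway = pathway_map_of(x))
}

#' Average replicates into a stage-mean matrix
#'
#' Arithmetic mean over replicates for every (species, stage) cell; uneven
#' replicate counts are tolerated with a warning as long as every cell
#' retains at least one replicate.
#'
#' @param x an [expression_matrix()].
#' @return A [stage_mean_matrix()].
#' @export
average_replicates <- function(x) {
  if (!inherits(x, "ExpressionMatrix")) {
    stop("`x` must be an ExpressionMatrix")
  }
  s <- x$samples
  key <- paste0(s$species, "_s", s$stage)
  cells <- unique(s[, c("species", "pathway", "stage")])
  cells <- cells[order(match(cells$species, unique(s$species)), cells$stage), ]
  cell_key <- paste0(cells$species, "_s", cells$stage)
  n_rep <- table(key)
  if (length(unique(as.integer(n_rep))) > 1) {
    warning("uneven replicate counts across (species, stage) cells; ",
            "averaging the replicates present")
  }
  out <- vapply(cell_key, function(k) {
    rowMeans(x$values[, key == k, drop = FALSE])
  }, numeric(nrow(x$values)))
  if (nrow(x$values) == 1) out <- matrix(out, nrow = 1, dimnames = list(rownames(x$values), cell_key))
  colnames(out) <- cell_key
  cells$sample <- cell_key
  stage_mean_matrix(out, cells[, c("sample", "species", "pathway", "stage")])
}

#' Per-gene Z-scores across samples
#'
#' Each row is centred and scaled to unit sample standard deviation (n-1
#' denominator) across all columns; rows with zero variance are mapped to
#' all-zero and flagged in the `"constant_genes"` attribute. An optional
#' `log2(x + 1)` transform can be applied first.
#'
#' @param x a `StageMeanMatrix`, `ExpressionMatrix` or numeric matrix.
#' @param log_transform apply `log2(x + 1)` before scaling.
#' @return Numeric matrix of Z-scores with attribute `"constant_genes"`.
#' @export
#' @examples
#' zscore(matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", paste0("s", 1:3))))
zscore <- function(x, log_transform = FALSE) {
  values <- expr_values(x)
  if (ncol(values) < 2) stop("Z-scores need at least 2 columns")
  if (log_transform) values <- log2(values + 1)
  mu <- rowMeans(values)
  sd <- apply(values, 1, stats::sd)
  constant <- sd == 0 | is.na(sd)
  z <- (values - mu) / ifelse(constant, 1, sd)
  z[constant, ] <- 0
  attr(z, "constant_genes") <- rownames(values)[constant]
  z
}
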