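#' Read a gene-by-sample expression table
#'
#' The file is tab-separated with a header `gene` followed by sample columns
#' named `<species>_s<stage>_r<rep>`. In `counts` mode a side file of
#' transcript lengths (two columns: gene, length) must be supplied so the
#' matrix can later be converted to TPM.
#'
#' @param path path to the TSV file.
#' @param value_kind `"tpm"` or `"counts"`.
#' @param species_pathway named character vector, species code -> pathway.
#' @param lengths_path optional two-column TSV (gene, length); required when
#'   `value_kind = "counts"`.
#' @return An [expression_matrix()]; in counts mode the length map is
#'   attached as attribute `"lengths"` (named numeric vector).
#' @export
read_expression <- function(path, value_kind = c("tpm", "counts"),
                            species_pathway = flaveria_pathways(),
                            lengths_path = NULL) {
  value_kind <- match.arg(value_kind)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2 || names(tab)[1] != "gene") {
    stop("expression table must start with a 'gene' column: ", path)
  }
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene ID(s) in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric expression values in ", path)
  rownames(values) <- genes
  x <- expression_matrix(values, kind = value_kind,
                         species_pathway = species_pathway)
  if (value_kind == "counts") {
    if (is.null(lengths_path)) {
      stop("counts mode requires `lengths_path` (gene, length TSV)")
    }
    attr(x, "lengths") <- read_lengths(lengths_path)
  }
  x
}

read_lengths <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("length table must have two columns: ", path)
  len <- as.numeric(tab[[2]])
  if (any(is.na(len) | len <= 0)) {
    stop("transcript lengths must be positive: ", path)
  }
  stats::setNames(len, as.character(tab[[1]]))
}

#' Write an expression or stage-mean table
#'
#' Writes the canonical TSV dialect (`gene` column then sample columns) read
#' back by [read_expression()].
#'
#' @param x an `ExpressionMatrix`, `StageMeanMatrix` or matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  values <- expr_values(x)
  out <- data.frame(gene = rownames(values), values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a contig-to-reference-gene annotation map
#'
#' Two-column TSV (contig, gene), as produced by reciprocal-best-BLAST
#' annotation against a reference proteome. Many contigs may map to one
#' gene; a contig maps to at most one gene.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `contig`, `gene`.
#' @export
read_annotation_map <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) NULL
  )
  if (is.null(tab) || nrow(tab) == 0) {
    warning("empty annotation map: ", path)
    return(data.frame(contig = character(), gene = character(),
                      stringsAsFactors = FALSE))
  }
  map <- data.frame(contig = as.character(tab[[1]]),
                    gene = as.character(tab[[2]]),
                    stringsAsFactors = FALSE)
  map <- unique(map)
  dup <- unique(map$contig[duplicated(map$contig)])
  if (length(dup) > 0) {
    stop("contig(s) mapped to more than one gene in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  map
}

#' Write an annotation map
#'
#' @param map data.frame with columns `contig`, `gene`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_map <- function(map, path) {
  utils::write.table(map[, c("contig", "gene")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-category table
#'
#' Two-column TSV (gene, category), MapMan-bin or flat GO-term style. Genes
#' within a category are deduplicated.
#'
#' @param path path to the TSV file.
#' @return Named list: category id -> character vector of gene IDs.
#' @export
read_category_table <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) NULL
  )
  if (is.null(tab) || nrow(tab) == 0) {
    stop("empty category table (enrichment impossible): ", path)
  }
  gene <- as.character(tab[[1]])
  category <- as.character(tab[[2]])
  lapply(split(gene, category), unique)
}

#' Read a candidate gene-ID list
#'
#' One ID per line; `#` starts a comment; blank lines ignored. Order is
#' preserved; duplicates are removed with a warning.
#'
#' @param path path to the list file.
#' @return Character vector of gene IDs in file order.
#' @export
read_candidate_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  ids <- lines[nzchar(lines)]
  if (anyDuplicated(ids)) {
    warning("duplicate candidate ID(s) removed: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    ids <- ids[!duplicated(ids)]
  }
  ids
}

#' Write a truth table or other plain data.frame as TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
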