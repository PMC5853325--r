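#' Construct an expression matrix with sample metadata
#'
#' Wraps a non-negative numeric gene-by-sample matrix whose column names
#' follow the `<species>_s<stage>_r<rep>` convention, together with parsed
#' per-sample metadata and a value-kind flag (`"tpm"` or `"counts"`).
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns.
#' @param kind `"tpm"` or `"counts"`.
#' @param species_pathway named character vector, species code -> pathway.
#' @return An object of class `"ExpressionMatrix"`: a list with elements
#'   `values` (the matrix), `samples` (metadata data.frame) and `kind`.
#' @export
#' @examples
#' m <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"),
#'                                        c("Fp_s1_r1", "Fb_s6_r3")))
#' expression_matrix(m, kind = "tpm")
expression_matrix <- function(values, kind = c("tpm", "counts"),
                              species_pathway = flaveria_pathways()) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values))) stop("`values` must have gene rownames")
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ID(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (is.null(colnames(values))) stop("`values` must have sample colnames")
  if (anyNA(values)) stop("expression values must not be missing")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative expression value at gene '", rownames(values)[bad[1]],
         "', sample '", colnames(values)[bad[2]], "'")
  }
  samples <- parse_sample_names(colnames(values), species_pathway)
  structure(list(values = values, samples = samples, kind = kind),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix (", x$kind, "): ", nrow(x$values), " genes x ",
      ncol(x$values), " samples; ",
      length(unique(x$samples$species)), " species, stages ",
      min(x$samples$stage), "-", max(x$samples$stage), "\n", sep = "")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Extract the numeric matrix from a container
#'
#' @param x an `ExpressionMatrix`, `StageMeanMatrix` or plain matrix.
#' @return The underlying numeric matrix.
#' @export
expr_values <- function(x) {
  if (inherits(x, c("ExpressionMatrix", "StageMeanMatrix"))) return(x$values)
  if (is.matrix(x)) return(x)
  stop("cannot extract values from class ", paste(class(x), collapse = "/"))
}

#' Sample metadata of an expression container
#'
#' @param x an `ExpressionMatrix` or `StageMeanMatrix`.
#' @return data.frame of per-column metadata.
#' @export
sample_info <- function(x) {
  if (inherits(x, c("ExpressionMatrix", "StageMeanMatrix"))) return(x$samples)
  stop("cannot extract sample metadata from class ",
       paste(class(x), collapse = "/"))
}

#' Construct a replicate-averaged stage-mean matrix
#'
#' Columns are named `<species>_s<stage>`; one column per (species, stage).
#'
#' @param values numeric non-negative matrix, genes x species-stage columns.
#' @param samples data.frame with columns `sample`, `species`, `pathway`,
#'   `stage` matching the columns of `values`.
#' @return An object of class `"StageMeanMatrix"`.
#' @export
stage_mean_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), is.numeric(values),
            identical(colnames(values), samples$sample))
  if (any(values < 0)) stop("stage means must be non-negative")
  if (anyDuplicated(samples[, c("species", "stage")])) {
    stop("duplicate (species, stage) columns")
  }
  structure(list(values = values, samples = samples),
            class = "StageMeanMatrix")
}

#' @export
print.StageMeanMatrix <- function(x, ...) {
  cat("StageMeanMatrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " species-stage columns\n", sep = "")
  invisible(x)
}

#' @export
dim.StageMeanMatrix <- function(x) dim(x$values)
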