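#' Default species-to-pathway map for the Flaveria four-species design
#'
#' Two C3 species (*F. pringlei* `Fp`, *F. robusta* `Fr`) and two C4 species
#' (*F. bidentis* `Fb`, *F. trinervia* `Ft`).
#'
#' @return Named character vector mapping species code to `"C3"` or `"C4"`.
#' @export
#' @examples
#' flaveria_pathways()
flaveria_pathways <- function() {
  c(Fp = "C3", Fr = "C3", Fb = "C4", Ft = "C4")
}

#' Describe a multi-species gradient sampling design
#'
#' A design is the full factorial of species, leaf stage (1 = base ... tip)
#' and biological replicate; every combination occurs exactly once.
#'
#' @param species named character vector, species code -> pathway
#'   (`"C3"`/`"C4"`).
#' @param n_stages number of equal leaf sections base to tip.
#' @param n_replicates biological replicates per species and stage.
#' @return An object of class `"SampleDesign"`.
#' @export
sample_design <- function(species = flaveria_pathways(), n_stages = 6L,
                          n_replicates = 3L) {
  if (is.null(names(species)) || any(!nzchar(names(species)))) {
    stop("`species` must be a named vector (species code -> pathway)")
  }
  if (anyDuplicated(names(species))) {
    stop("duplicated species codes in `species`")
  }
  if (!all(species %in% c("C3", "C4"))) {
    stop("pathway labels must be 'C3' or 'C4'")
  }
  n_stages <- as.integer(n_stages)
  n_replicates <- as.integer(n_replicates)
  if (n_stages < 2L) stop("`n_stages` must be >= 2")
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1")
  structure(
    list(species = species, n_stages = n_stages, n_replicates = n_replicates),
    class = "SampleDesign"
  )
}

#' @export
print.SampleDesign <- function(x, ...) {
  cat("SampleDesign:", length(x$species), "species (",
      paste0(names(x$species), "=", x$species, collapse = ", "), "), ",
      x$n_stages, "stages x", x$n_replicates, "replicates\n")
  invisible(x)
}

design_samples <- function(design) {
  sp <- names(design$species)
  grid <- expand.grid(
    replicate = seq_len(design$n_replicates),
    stage = seq_len(design$n_stages),
    species = sp,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("species", "stage", "replicate")]
  grid$pathway <- unname(design$species[grid$species])
  grid$sample <- sprintf("%s_s%d_r%d", grid$species, grid$stage,
                         grid$replicate)
  grid[, c("sample", "species", "pathway", "stage", "replicate")]
}

#' Parse canonical sample names
#'
#' Sample columns follow the `<species>_s<stage>_r<rep>` convention, e.g.
#' `Fp_s1_r1`.
#'
#' @param x character vector of sample names.
#' @param species_pathway named character vector, species code -> pathway.
#' @return data.frame with columns `sample`, `species`, `pathway`, `stage`,
#'   `replicate`.
#' @export
parse_sample_names <- function(x, species_pathway = flaveria_pathways()) {
  pat <- "^([A-Za-z][A-Za-z0-9]*)_s([0-9]+)_r([0-9]+)$"
  bad <- x[!grepl(pat, x)]
  if (length(bad) > 0) {
    stop("malformed sample name(s): ", paste(bad, collapse = ", "),
         " (expected <species>_s<stage>_r<rep>)")
  }
  species <- sub(pat, "\\1", x)
  unknown <- setdiff(unique(species), names(species_pathway))
  if (length(unknown) > 0) {
    stop("species code(s) not in the pathway map: ",
         paste(unknown, collapse = ", "))
  }
  meta <- data.frame(
    sample = x,
    species = species,
    pathway = unname(species_pathway[species]),
    stage = as.integer(sub(pat, "\\2", x)),
    replicate = as.integer(sub(pat, "\\3", x)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(meta$sample)) {
    stop("duplicated sample name(s): ",
         paste(unique(meta$sample[duplicated(meta$sample)]), collapse = ", "))
  }
  meta
}
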