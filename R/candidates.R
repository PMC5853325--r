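#' Intersect an external C4-candidate list with the four-species analysis
#'
#' Tallies, for a candidate gene-ID list from an independent C4 lineage:
#' how many candidates are detected in all four species (present in the
#' shared annotation set and, when stage means are supplied, above `floor`
#' in at least one stage mean in every species); how many are called
#' `C4_up` / `C3_up` in the mature (tip) stage group; and how many are both
#' ascending in both C4 species and `C4_up`.
#'
#' @param candidates character vector of candidate gene IDs (duplicates
#'   ignored).
#' @param shared shared gene-ID set from [shared_annotation_set()].
#' @param behaviors a [classify_behavior()] table covering the shared set.
#' @param de_calls a [call_de_all_stages()] table covering the shared set.
#' @param stage_means optional [stage_mean_matrix()] used for the detection
#'   floor.
#' @param tip_stages stages counted as mature tissue.
#' @param floor TPM detection floor.
#' @param c4_species species codes of the C4 pair, used for the
#'   ascending-in-both-C4 tally.
#' @param list_name label for the report.
#' @return list of class `"CandidateReport"`: `list_name`, `n_candidates`,
#'   `n_detected`, `n_c4_up`, `n_c3_up`, `n_ascending_c4_up`, and `genes`
#'   (per-gene data.frame with `gene`, `detected`, `c4_up`, `c3_up`,
#'   `ascending_c4`).
#' @export
intersect_candidates <- function(candidates, shared, behaviors, de_calls,
                                 stage_means = NULL, tip_stages = c(5, 6),
                                 floor = 1,
                                 c4_species = names(flaveria_pathways())[
                                   flaveria_pathways() == "C4"],
                                 list_name = "candidates") {
  candidates <- unique(candidates)
  n_cand <- length(candidates)
  if (n_cand == 0) {
    return(structure(
      list(list_name = list_name, n_candidates = 0L, n_detected = 0L,
           n_c4_up = 0L, n_c3_up = 0L, n_ascending_c4_up = 0L,
           genes = data.frame(gene = character(), detected = logical(),
                              c4_up = logical(), c3_up = logical(),
                              ascending_c4 = logical())),
      class = "CandidateReport"
    ))
  }
  detected <- intersect(candidates, shared)
  if (!is.null(stage_means) && length(detected) > 0) {
    values <- expr_values(stage_means)
    s <- sample_info(stage_means)
    keep <- vapply(detected, function(g) {
      if (!g %in% rownames(values)) return(FALSE)
      all(vapply(unique(s$species), function(sp) {
        max(values[g, s$sample[s$species == sp]]) >= floor
      }, logical(1)))
    }, logical(1))
    detected <- detected[keep]
  }

  c4_species <- intersect(c4_species, unique(behaviors$species))
  missing_beh <- detected[!vapply(detected, function(g)
    any(behaviors$gene == g), logical(1))]
  missing_de <- detected[!vapply(detected, function(g)
    any(de_calls$gene == g), logical(1))]
  if (length(missing_beh) > 0 || length(missing_de) > 0) {
    stop("calls missing for detected gene(s): ",
         paste(union(missing_beh, missing_de), collapse = ", "))
  }

  tip_de <- de_calls[de_calls$stage %in% tip_stages, ]
  per_gene <- lapply(candidates, function(g) {
    det <- g %in% detected
    c4 <- det && any(tip_de$gene == g & tip_de$direction == "C4_up")
    c3 <- det && any(tip_de$gene == g & tip_de$direction == "C3_up")
    asc <- det && all(vapply(c4_species, function(sp) {
      any(behaviors$gene == g & behaviors$species == sp &
            behaviors$class == "ascending")
    }, logical(1))) && length(c4_species) > 0 && c4
    data.frame(gene = g, detected = det, c4_up = c4, c3_up = c3,
               ascending_c4 = asc, stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, per_gene)
  structure(
    list(list_name = list_name,
         n_candidates = n_cand,
         n_detected = length(detected),
         n_c4_up = sum(genes$c4_up),
         n_c3_up = sum(genes$c3_up),
         n_ascending_c4_up = sum(genes$ascending_c4),
         genes = genes),
    class = "CandidateReport"
  )
}

#' @export
print.CandidateReport <- function(x, ...) {
  cat("CandidateReport '", x$list_name, "': ", x$n_candidates,
      " candidates; ", x$n_detected, " detected in all species; ",
      x$n_c4_up, " C4_up / ", x$n_c3_up, " C3_up at the tip; ",
      x$n_ascending_c4_up, " ascending-and-C4_up\n", sep = "")
  invisible(x)
}
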