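#' Write a cohort to a directory of plain-text files
#'
#' Serializes a synthetic cohort as CSV matrices plus a JSON manifest:
#' per-participant betas and trial indices, the scene table (mean embeddings,
#' categories), ground-truth weights, and the brain mask / region map.
#' Plain-text storage keeps cohorts portable and diffable.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("Package 'jsonlite' is required to write cohorts.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- cohort$scenes
  utils::write.csv(
    data.frame(scene_id = sc$scene_ids, sc$mean_embedding,
               check.names = FALSE),
    file.path(dir, "mean_embeddings.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(scene_id = sc$scene_ids, sc$categories, check.names = FALSE),
    file.path(dir, "categories.csv"), row.names = FALSE)
  bb <- cohort$base_brain
  utils::write.csv(
    data.frame(voxel = seq_along(bb$region_id),
               in_brain = as.integer(bb$in_brain),
               region_id = bb$region_id, noise_sd = bb$noise_sd),
    file.path(dir, "voxels.csv"), row.names = FALSE)
  for (i in seq_along(cohort$participants)) {
    p <- cohort$participants[[i]]
    utils::write.csv(as.data.frame(p$trials$betas),
                     file.path(dir, sprintf("betas_p%02d.csv", i)),
                     row.names = FALSE)
    utils::write.csv(as_tibble(p$trials),
                     file.path(dir, sprintf("trials_p%02d.csv", i)),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(p$brain$W_true),
                     file.path(dir, sprintf("w_true_p%02d.csv", i)),
                     row.names = FALSE)
  }
  manifest <- list(
    n_participants = length(cohort$participants),
    grid_shape = cohort$base_brain$grid_shape,
    shared_ids = cohort$shared_ids,
    unique_ids = cohort$unique_ids,
    seed = attr(cohort, "seed"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Export per-stimulus average response volumes to NIfTI
#'
#' Writes a 4D NIfTI (x, y, z, stimulus) of average responses, for
#' interoperability with standard neuroimaging tools. Requires the RNifti
#' package.
#'
#' @param responses An `avg_responses` over all grid voxels.
#' @param grid_shape Integer 3-vector.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_responses_nifti <- function(responses, grid_shape, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("Package 'RNifti' is required for NIfTI export.")
  }
  stopifnot(inherits(responses, "avg_responses"))
  vol <- array(t(responses$values),
               dim = c(grid_shape, nrow(responses$values)))
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}
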