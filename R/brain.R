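#' Build a synthetic brain model on a 3D voxel grid
#'
#' Creates a ground-truth linear embedding-to-response map on a voxel grid.
#' Each region is a block of in-brain voxels selective for a designated
#' subspace of the embedding: its weight rows are supported on the region's
#' embedding dimensions, plus optional small isotropic leakage onto the other
#' dimensions. Voxels outside the brain mask have zero weights.
#'
#' @param grid_shape Integer vector of length 3, grid dimensions in voxels.
#' @param regions List of region specs, each a list with `name`, `voxels`
#'   (integer vector of linear voxel indices into the grid) and `dims`
#'   (embedding dimensions the region is selective for). Regions must be
#'   disjoint. If `NULL`, `default_regions()` is used.
#' @param d Embedding dimension.
#' @param noise_sd Per-voxel noise standard deviation (scalar recycled, or one
#'   value per voxel); must be non-negative.
#' @param leakage Sd of the off-subspace leakage weights (0 for perfectly
#'   selective regions).
#' @param in_brain Optional logical 3D array mask; defaults to the union of
#'   region voxels.
#' @param weight_sd Sd of the on-subspace weights.
#' @param seed Integer seed.
#'
#' @return A `brain_model`: list with `grid_shape`, `in_brain` (logical 3D
#'   array), `region_id` (integer per voxel, 0 = unassigned), `region_names`,
#'   `region_dims`, `W_true` (`p_voxels x d`, zero rows outside the mask),
#'   `noise_sd` (length `p_voxels`).
#' @export
build_brain_model <- function(grid_shape, regions = NULL, d, noise_sd = 1,
                              leakage = 0, in_brain = NULL, weight_sd = 1,
                              seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 1)) {
    abort("`grid_shape` must be three positive integers.")
  }
  grid_shape <- as.integer(grid_shape)
  d <- check_count(d, "d")
  leakage <- check_number(leakage, "leakage", min = 0)
  p <- prod(grid_shape)

  if (is.null(regions)) regions <- default_regions(grid_shape, d)
  all_vox <- unlist(lapply(regions, `[[`, "voxels"))
  if (anyDuplicated(all_vox)) abort("Regions must reference disjoint voxels.")
  if (any(all_vox < 1 | all_vox > p)) abort("Region voxels outside the grid.")
  for (r in regions) {
    if (any(r$dims < 1 | r$dims > d)) {
      abort("Region embedding dims outside 1..d.")
    }
  }

  if (is.null(in_brain)) {
    in_brain <- array(FALSE, grid_shape)
    in_brain[all_vox] <- TRUE
  } else {
    stopifnot(identical(dim(in_brain), grid_shape))
    if (!all(in_brain[all_vox])) {
      abort("All region voxels must lie inside `in_brain`.")
    }
  }

  noise_sd <- rep_len(as.numeric(noise_sd), p)
  if (any(noise_sd < 0)) abort("`noise_sd` must be non-negative.")

  region_id <- integer(p)
  for (i in seq_along(regions)) region_id[regions[[i]]$voxels] <- i

  with_seed(derive_seed(seed, "brain"), {
    W <- matrix(0, p, d)
    for (i in seq_along(regions)) {
      vox <- regions[[i]]$voxels
      dims <- regions[[i]]$dims
      W[vox, dims] <- rnorm(length(vox) * length(dims), sd = weight_sd)
      if (leakage > 0) {
        other <- setdiff(seq_len(d), dims)
        if (length(other)) {
          W[vox, other] <- rnorm(length(vox) * length(other), sd = leakage)
        }
      }
    }
    # in-brain voxels not claimed by a region respond weakly and diffusely
    free <- which(in_brain & region_id == 0)
    if (length(free)) {
      W[free, ] <- rnorm(length(free) * d, sd = 0.1 * weight_sd)
    }
    W[!in_brain, ] <- 0

    structure(
      list(grid_shape = grid_shape, in_brain = in_brain,
           region_id = region_id,
           region_names = vapply(regions, `[[`, "", "name"),
           region_dims = lapply(regions, `[[`, "dims"),
           W_true = W, noise_sd = noise_sd),
      seed = seed, class = "brain_model"
    )
  })
}

#' Default two-region layout for a grid
#'
#' Splits the grid along its first axis into two equal blocks, selective for
#' the first and second halves of the embedding dimensions respectively.
#'
#' @param grid_shape Integer 3-vector.
#' @param d Embedding dimension.
#' @return A list of two region specs.
#' @export
default_regions <- function(grid_shape, d) {
  idx <- array(seq_len(prod(grid_shape)), grid_shape)
  half_x <- floor(grid_shape[1] / 2)
  dims_a <- seq_len(floor(d / 2))
  list(
    list(name = "region_A", voxels = as.vector(idx[seq_len(half_x), , ]),
         dims = dims_a),
    list(name = "region_B",
         voxels = as.vector(idx[(half_x + 1):grid_shape[1], , ]),
         dims = setdiff(seq_len(d), dims_a))
  )
}

#' @export
print.brain_model <- function(x, ...) {
  cat(sprintf("<brain_model> grid %s, %d in-brain voxels, %d regions, d = %d\n",
              paste(x$grid_shape, collapse = "x"), sum(x$in_brain),
              length(x$region_names), ncol(x$W_true)))
  invisible(x)
}

#' Noiseless responses of a brain model to a scene set
#'
#' @param brain A `brain_model`.
#' @param scenes A `scene_set` (its true embeddings are used).
#' @return Matrix `n_scenes x p_voxels` of noiseless responses.
#' @export
true_responses <- function(brain, scenes) {
  stopifnot(inherits(brain, "brain_model"), inherits(scenes, "scene_set"))
  if (ncol(scenes$true_embedding) != ncol(brain$W_true)) {
    abort("Embedding dimension of scenes does not match brain model.")
  }
  r <- scenes$true_embedding %*% t(brain$W_true)
  rownames(r) <- scenes$scene_ids
  r
}

#' Per-voxel noise sd achieving a target signal-to-noise ratio
#'
#' SNR is defined as the ratio of per-voxel signal variance (variance of the
#' noiseless response across scenes) to single-trial noise variance. Voxels
#' with no signal get noise sd equal to the in-brain median so they are not
#' silent.
#'
#' @param brain A `brain_model`.
#' @param scenes A `scene_set`.
#' @param snr Target variance ratio (> 0).
#' @return Numeric vector of per-voxel noise sds.
#' @export
noise_sd_for_snr <- function(brain, scenes, snr) {
  snr <- check_number(snr, "snr", min = 1e-12)
  sig <- true_responses(brain, scenes)
  v <- apply(sig, 2, stats::var)
  out <- sqrt(v / snr)
  silent <- out == 0 & brain$in_brain
  if (any(silent)) out[silent] <- stats::median(out[brain$in_brain & out > 0])
  out[!brain$in_brain] <- 0
  out
}

#' RDM of the generative ground truth under the measurement pipeline
#'
#' Computes the noiseless responses, standardizes each voxel across stimuli
#' (mirroring the per-session z-scoring applied to measured betas - pattern
#' correlation RDMs are not invariant to per-voxel scaling, so the ground
#' truth must be standardized the same way), and returns the Pearson-distance
#' RDM. Use this as the "true model" in recovery tests.
#'
#' @inheritParams true_responses
#' @param voxels Optional voxel subset (indices or logical mask vector).
#' @return An `rdm` object.
#' @export
true_response_rdm <- function(brain, scenes, voxels = NULL) {
  r <- true_responses(brain, scenes)
  if (is.null(voxels)) voxels <- which(as.vector(brain$in_brain))
  r <- r[, voxels, drop = FALSE]
  sds <- apply(r, 2, sd)
  keep_scale <- ifelse(sds > 0, sds, 1)
  r <- sweep(sweep(r, 2, colMeans(r)), 2, keep_scale, "/")
  compute_rdm(avg_responses(r, scenes$scene_ids))
}
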