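#' Searchlight sphere membership over a brain mask
#'
#' For every in-brain voxel, candidate sphere members are the integer lattice
#' points at Euclidean distance `<= radius` (in voxel units, isotropic grid)
#' from the center. A sphere is kept only if strictly more than
#' `min_inside_fraction` of its lattice points lie inside the mask (points
#' falling outside the volume bounds count as outside); out-of-mask voxels
#' are excluded from the member list.
#'
#' @param mask Logical 3D array (in-brain mask).
#' @param radius Sphere radius in voxels (>= 0; default 6).
#' @param min_inside_fraction Strict lower bound on the in-mask fraction
#'   (default 0.5).
#' @return A list of spheres, each a list with `center` (linear voxel index),
#'   `center_xyz` (1-based grid coordinates), and `members` (linear indices
#'   of in-mask member voxels, always including the center).
#' @export
searchlight_spheres <- function(mask, radius = 6, min_inside_fraction = 0.5) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  radius <- check_number(radius, "radius", min = 0)
  if (!any(mask)) abort("`mask` is empty.")
  dims <- dim(mask)

  off <- sphere_offsets(radius)
  n_off <- nrow(off)

  centers <- which(mask)
  cxyz <- arrayInd(centers, dims)
  n_c <- length(centers)

  # member linear indices per offset (column) per center (row); NA = outside
  # the volume bounds
  inside_mask_count <- integer(n_c)
  member_idx <- matrix(NA_integer_, n_c, n_off)
  for (j in seq_len(n_off)) {
    x <- cxyz[, 1] + off[j, 1]
    y <- cxyz[, 2] + off[j, 2]
    z <- cxyz[, 3] + off[j, 3]
    ok <- x >= 1 & x <= dims[1] & y >= 1 & y <= dims[2] & z >= 1 & z <= dims[3]
    lin <- rep(NA_integer_, n_c)
    lin[ok] <- (z[ok] - 1L) * dims[1] * dims[2] + (y[ok] - 1L) * dims[1] +
      x[ok]
    in_mask <- ok & mask[ifelse(is.na(lin), 1L, lin)] & !is.na(lin)
    inside_mask_count <- inside_mask_count + in_mask
    lin[!in_mask] <- NA_integer_
    member_idx[, j] <- lin
  }

  keep <- inside_mask_count / n_off > min_inside_fraction
  idx_keep <- which(keep)
  lapply(idx_keep, function(i) {
    list(center = centers[i], center_xyz = cxyz[i, ],
         members = sort(member_idx[i, !is.na(member_idx[i, ])]))
  })
}

# integer lattice offsets with Euclidean norm <= radius
sphere_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

#' Searchlight subset-sampled RSA map
#'
#' Runs [sampled_rsa()] within each searchlight sphere, using only that
#' sphere's member voxels. The same subset partition (drawn once from
#' `seed`) is reused across all spheres and should be reused across models,
#' so maps and contrasts compare like with like.
#'
#' Spheres with fewer than 2 in-mask member voxels get `NA`.
#'
#' @param responses An `avg_responses` over all voxels of the grid.
#' @param model Model RDM or feature matrix (as in [sampled_rsa()]).
#' @param spheres Output of [searchlight_spheres()].
#' @param subset_size Stimuli per subset.
#' @param seed Seed for the shared partition.
#' @param subsets Optional precomputed partition to reuse.
#' @return A tibble with one row per sphere center: `center`, `x`, `y`, `z`,
#'   `n_members`, `mean_r`, `n_splits`.
#' @export
searchlight_rsa <- function(responses, model, spheres, subset_size = 100L,
                            seed = 1L, subsets = NULL) {
  stopifnot(inherits(responses, "avg_responses"))
  if (is.null(subsets)) {
    subsets <- sample_subsets(responses$stimulus_ids, subset_size, seed)
  }
  # model subset RDMs are sphere-independent: compute once
  model_rdms <- lapply(subsets, function(ss) model_subset_rdm(model, ss))
  subset_rows <- lapply(subsets, function(ss) {
    match(ss, responses$stimulus_ids)
  })

  rows <- purrr::map(spheres, function(sp) {
    if (length(sp$members) < 2L) {
      return(tibble(center = sp$center, x = sp$center_xyz[1],
                    y = sp$center_xyz[2], z = sp$center_xyz[3],
                    n_members = length(sp$members), mean_r = NA_real_,
                    n_splits = length(subsets)))
    }
    vals <- responses$values[, sp$members, drop = FALSE]
    rs <- vapply(seq_along(subsets), function(i) {
      brain <- compute_rdm(
        avg_responses(vals[subset_rows[[i]], , drop = FALSE], subsets[[i]]))
      rdm_correlation(brain, model_rdms[[i]])
    }, numeric(1))
    tibble(center = sp$center, x = sp$center_xyz[1], y = sp$center_xyz[2],
           z = sp$center_xyz[3], n_members = length(sp$members),
           mean_r = mean(rs), n_splits = length(subsets))
  })
  dplyr::bind_rows(rows)
}
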