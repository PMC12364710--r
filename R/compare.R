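#' Noise-ceiling-corrected ROI model comparison
#'
#' For every participant, ROI and feature model: subset-sampled RSA between
#' the participant's ROI responses and the model, divided by that
#' participant's leave-one-out noise ceiling on the shared stimuli (computed
#' within the same ROI). Correction is by ratio `r / ceiling`; a participant
#' whose ceiling is not positive is excluded from correction with a warning.
#' Pairwise model differences in corrected r are tested with paired
#' two-tailed t-tests across participants, BH-FDR corrected across the family
#' of all pairwise comparisons within each ROI.
#'
#' The same subset partition (per participant) is reused across models and
#' ROIs, so comparisons contrast like with like.
#'
#' @param responses List of `avg_responses`, one per participant (full
#'   stimulus sets; used for the RSA).
#' @param shared_responses List of `avg_responses` on the shared stimuli
#'   (same order across participants; used for the ceilings).
#' @param rois Named list of voxel index vectors.
#' @param models Named list of feature matrices / RDMs (see [sampled_rsa()]).
#' @param subset_size Stimuli per RSA subset.
#' @param seed Seed for the subset partitions.
#' @param alpha FDR level for the pairwise tests.
#' @return A `model_comparison`: list with `scores` (tibble: model,
#'   participant, roi, raw_r, ceiling, corrected_r) and `pairwise` (tibble:
#'   roi, model_a, model_b, estimate, t, p, q, sig).
#' @export
roi_model_comparison <- function(responses, shared_responses, rois, models,
                                 subset_size = 100L, seed = 1L,
                                 alpha = 0.05) {
  if (length(models) < 2L) abort("At least 2 models are required.")
  if (is.null(names(models)) || is.null(names(rois))) {
    abort("`models` and `rois` must be named.")
  }
  n_part <- length(responses)

  partitions <- lapply(responses, function(r) {
    sample_subsets(r$stimulus_ids, subset_size, seed)
  })

  scores <- purrr::map_dfr(names(rois), function(roi_name) {
    vox <- rois[[roi_name]]
    ceil <- rsa_noise_ceiling(shared_responses, voxels = vox)
    purrr::map_dfr(seq_len(n_part), function(i) {
      resp_roi <- avg_responses(
        responses[[i]]$values[, vox, drop = FALSE],
        responses[[i]]$stimulus_ids)
      ceiling_i <- ceil$ceiling[i]
      purrr::map_dfr(names(models), function(mod) {
        raw <- sampled_rsa(resp_roi, models[[mod]],
                           subsets = partitions[[i]])$mean_r
        tibble(model = mod, participant = i, roi = roi_name, raw_r = raw,
               ceiling = ceiling_i,
               corrected_r = if (ceiling_i > 0) raw / ceiling_i else NA_real_)
      })
    })
  })
  if (anyNA(scores$corrected_r)) {
    warn("Participant(s) with non-positive noise ceiling excluded from correction.")
  }

  pairs <- utils::combn(names(models), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(names(rois), function(roi_name) {
    purrr::map_dfr(pairs, function(pr) {
      a <- scores$corrected_r[scores$roi == roi_name & scores$model == pr[1]]
      b <- scores$corrected_r[scores$roi == roi_name & scores$model == pr[2]]
      diffs <- a - b
      diffs <- diffs[!is.na(diffs)]
      n <- length(diffs)
      est <- mean(diffs)
      sdd <- sd(diffs)
      if (n >= 2 && sdd > 0) {
        tstat <- est / (sdd / sqrt(n))
        pval <- 2 * pt(-abs(tstat), df = n - 1)
      } else if (n >= 2 && est == 0) {
        tstat <- 0
        pval <- 1
      } else {
        tstat <- NA_real_
        pval <- NA_real_
      }
      tibble(roi = roi_name, model_a = pr[1], model_b = pr[2],
             estimate = est, n = n, t = tstat, p = pval)
    })
  })
  ok <- !is.na(pairwise$p)
  pairwise$q <- NA_real_
  pairwise$q[ok] <- p.adjust(pairwise$p[ok], method = "BH")
  pairwise$sig <- !is.na(pairwise$q) & pairwise$q <= alpha

  structure(list(scores = scores, pairwise = pairwise),
            alpha = alpha, class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %d models, %d ROIs, %d participants\n",
              length(unique(x$scores$model)), length(unique(x$scores$roi)),
              length(unique(x$scores$participant))))
  invisible(x)
}

#' Group contrast between two searchlight maps
#'
#' Per-center paired difference of the per-participant searchlight
#' correlations for two models, tested with a group t-test and BH-FDR
#' corrected across centers. Centers missing (NA) in either map for a
#' participant are excluded pairwise.
#'
#' @param maps_a,maps_b Lists (one element per participant) of
#'   [searchlight_rsa()] tibbles over identical sphere centers.
#' @param alpha FDR level.
#' @return A `group_result` tibble (one row per center, `location` = center
#'   index).
#' @export
searchlight_contrast <- function(maps_a, maps_b, alpha = 0.05) {
  if (length(maps_a) != length(maps_b)) {
    abort("Both map lists must have one entry per participant.")
  }
  centers <- maps_a[[1]]$center
  for (m in c(maps_a, maps_b)) {
    if (!identical(m$center, centers)) {
      abort("All maps must share the same sphere centers.")
    }
  }
  diffs <- t(vapply(seq_along(maps_a), function(i) {
    maps_a[[i]]$mean_r - maps_b[[i]]$mean_r
  }, numeric(length(centers))))
  colnames(diffs) <- as.character(centers)
  group_inference(diffs, alpha = alpha)
}
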