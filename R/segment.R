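#' Segment a slide into predicted tumor polygons
#'
#' Runs the full inference chain: tissue masking (Otsu), grid patch
#' extraction, reconstruction with the frozen model (patches are
#' area-downsampled to the model's maximum resolution when needed),
#' per-pixel absolute errors, Mahalanobis distances under the NERD,
#' thresholding, per-patch polygonization and cross-patch merging.
#' Whitespace pixels within tissue patches (8-bit luminance at or above
#' the slide's Otsu threshold) are forced normal, so anomaly calls are
#' made on tissue only.
#' Predicted polygons are reported in level-0 slide coordinates; when the
#' model works below the extraction resolution the polygons are scaled up
#' by the patch-size ratio. Pixels outside tissue patches are never
#' predicted anomalous.
#'
#' @param slide a `pcead_slide`.
#' @param model a frozen `pcead_model` or an [oracle_reconstructor()].
#' @param nerd a `pcead_nerd`.
#' @param tau a `pcead_threshold`.
#' @param patch_size extraction patch side in level-0 pixels.
#' @param min_tissue_fraction minimum tissue coverage per patch.
#' @param mask_downsample thumbnail downsample for the tissue mask.
#' @param min_area minimum predicted-component area (level-0 px^2).
#' @param closing_radius optional morphological closing radius.
#' @return A `pcead_polyset` (role `"predicted"`); the tissue bounding box
#'   is attached as attribute `tissue_bbox`.
#' @export
segment_slide <- function(slide, model, nerd, tau, patch_size = 64L,
                          min_tissue_fraction = 0.5, mask_downsample = 16L,
                          min_area = 256, closing_radius = 0) {
  stage <- function(name, origin, expr) {
    tryCatch(expr, error = function(e) stop(sprintf(
      "[%s @(%d,%d) slide '%s'] %s", name, origin[1], origin[2],
      slide$id, conditionMessage(e)), call. = FALSE))
  }
  mask <- stage("tissue-mask", c(0L, 0L),
                compute_tissue_mask(slide, mask_downsample))
  patches <- stage("extract-patches", c(0L, 0L),
                   extract_patches(slide, mask, patch_size,
                                   min_tissue_fraction))
  bbox <- tissue_bbox(mask, slide)
  if (length(patches) == 0L) {
    out <- polygon_set(slide = slide$id, role = "predicted")
    attr(out, "tissue_bbox") <- bbox
    return(out)
  }
  model_max <- if (inherits(model, "pcead_model"))
    model$config$max_resolution else Inf
  parts <- vector("list", length(patches))
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    org <- c(p$x, p$y)
    if (p$size > model_max) {
      pyr <- stage("pyramid", org,
                   build_resolution_pyramid(p, min_size = model_max))
      p <- pyr[[length(pyr)]]
    }
    rec <- stage("reconstruct", org, reconstruct(model, p))
    err <- stage("error", org, reconstruction_error(p, rec))
    dmap <- stage("mahalanobis", org, mahalanobis_map(err, nerd))
    am <- stage("binarize", org, binarize(dmap, tau))
    am <- am & patch_tissue_mask(p, mask$threshold)
    parts[[i]] <- stage("polygonize", org, mask_to_polygons(
      am, origin = org, scale = p$span / p$size, min_area = min_area,
      closing_radius = closing_radius, slide = slide$id,
      role = "predicted"))
  }
  out <- merge_patch_polygons(parts)
  out$slide <- slide$id
  attr(out, "tissue_bbox") <- bbox
  out
}
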