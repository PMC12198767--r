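#' Atlas label volume
#'
#' A 3-D integer array of atlas labels (0 = background, k = region k), as read
#' from a NIfTI parcellation already aligned to the lesion masks. Overlap is
#' computed in voxel counts on this shared grid; no resampling is performed,
#' so inputs must be pre-aligned.
#'
#' @param labels 3-D non-negative integer array (or a NIfTI image object).
#' @param voxel_dims voxel dimensions in mm (length 3); cosmetic metadata.
#' @return an object of class `atlas_volume`.
#' @export
atlas_volume <- function(labels, voxel_dims = c(1, 1, 1)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3-D array", call. = FALSE)
  labels <- array(as.integer(labels), dim(labels)) # plain array, no image metadata
  if (anyNA(labels) || any(labels < 0L)) {
    stop("labels must be non-negative integers", call. = FALSE)
  }
  region_ids <- sort(unique(as.vector(labels)))
  region_ids <- region_ids[region_ids > 0L]
  if (length(region_ids) == 0L) stop("atlas contains no regions", call. = FALSE)
  structure(
    list(labels = labels, voxel_dims = as.numeric(voxel_dims),
         region_ids = region_ids),
    class = "atlas_volume"
  )
}

#' Read an atlas label volume or binary lesion mask from NIfTI
#'
#' @param path path to a NIfTI file.
#' @return for `read_atlas_volume`, an [atlas_volume]; for
#'   `read_lesion_mask`, a logical 3-D array (any nonzero voxel is in the
#'   mask).
#' @export
read_atlas_volume <- function(path) {
  img <- RNifti::readNifti(path)
  atlas_volume(round(as.array(img)), voxel_dims = RNifti::pixdim(img)[1:3])
}

#' @rdname read_atlas_volume
#' @export
read_lesion_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("mask must be a 3-D volume", call. = FALSE)
  arr != 0
}

#' Per-region overlap fractions of a lesion mask
#'
#' For every atlas region r, the fraction of its voxels that fall inside the
#' binary mask: `|voxels of r in mask| / |voxels of r|`. Regions untouched by
#' the mask get 0.
#'
#' @param atlas an [atlas_volume].
#' @param mask logical or 0/1 3-D array with the same dimensions as the atlas.
#' @return named numeric vector of fractions in `[0, 1]`, one per region id.
#' @export
region_overlap_fractions <- function(atlas, mask) {
  stopifnot(inherits(atlas, "atlas_volume"))
  mask <- as.array(mask)
  if (!identical(dim(mask), dim(atlas$labels))) {
    stop("atlas and mask dimensions differ; volumes must share one grid", call. = FALSE)
  }
  mask <- mask != 0
  lab <- as.vector(atlas$labels)
  sizes <- tabulate(lab, nbins = max(atlas$region_ids))
  hits <- tabulate(lab[as.vector(mask)], nbins = max(atlas$region_ids))
  frac <- hits[atlas$region_ids] / sizes[atlas$region_ids]
  stats::setNames(frac, as.character(atlas$region_ids))
}

#' Lesioned-region set from overlap fractions
#'
#' A region counts as lesioned when at least `threshold` of its voxels lie in
#' the lesion mask (boundary inclusive by default; `strict_greater = TRUE`
#' requires strictly more than the threshold).
#'
#' @param fractions named fraction vector from [region_overlap_fractions()].
#' @param threshold overlap fraction in `(0, 1]`; default 0.5.
#' @param strict_greater require fraction strictly above the threshold.
#' @param mask_id identifier recorded in the result.
#' @param source `"clinical_mask"` or `"synthetic"`.
#' @return an object of class `lesion_region_set`: list with `mask_id`,
#'   `regions` (character), `overlap_fraction` (named numeric) and `source`.
#' @export
lesioned_regions <- function(fractions, threshold = 0.5, strict_greater = FALSE,
                             mask_id = "mask", source = "clinical_mask") {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("`threshold` must lie in (0, 1]", call. = FALSE)
  }
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  hit <- if (strict_greater) fractions > threshold else fractions >= threshold
  lesion_region_set(mask_id, names(fractions)[hit], fractions, source)
}

lesion_region_set <- function(mask_id, regions, overlap_fraction = NULL,
                              source = "synthetic") {
  source <- match.arg(source, c("clinical_mask", "synthetic"))
  structure(
    list(mask_id = as.character(mask_id), regions = as.character(regions),
         overlap_fraction = overlap_fraction, source = source),
    class = "lesion_region_set"
  )
}

#' @exportS3Method base::print
print.lesion_region_set <- function(x, ...) {
  cat(sprintf("<lesion_region_set> %s (%s): %d regions\n",
              x$mask_id, x$source, length(x$regions)))
  invisible(x)
}

#' Map a directory-free set of masks onto lesioned-region sets
#'
#' Applies [region_overlap_fractions()] + [lesioned_regions()] to each mask.
#'
#' @param atlas an [atlas_volume].
#' @param masks named list of binary 3-D arrays.
#' @inheritParams lesioned_regions
#' @return list of `lesion_region_set` objects.
#' @export
map_lesions <- function(atlas, masks, threshold = 0.5, strict_greater = FALSE) {
  if (is.null(names(masks))) names(masks) <- sprintf("mask%03d", seq_along(masks))
  lapply(names(masks), function(id) {
    lesioned_regions(region_overlap_fractions(atlas, masks[[id]]),
                     threshold = threshold, strict_greater = strict_greater,
                     mask_id = id, source = "clinical_mask")
  })
}

#' Write a lesion library to disk
#'
#' Emits one flat region-id list per line (`<mask_id>\t<region ids comma
#' separated>`) plus a JSON sidecar with per-mask provenance (source and
#' overlap fractions where known).
#'
#' @param library list of `lesion_region_set` objects.
#' @param path path of the flat text file; the JSON sidecar gets `.json`
#'   appended.
#' @return `path`, invisibly.
#' @export
write_lesion_library <- function(library, path) {
  lines <- vapply(library, function(l) {
    paste0(l$mask_id, "\t", paste(l$regions, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  side <- lapply(library, function(l) {
    list(mask_id = l$mask_id, source = l$source, regions = l$regions,
         overlap_fraction = as.list(l$overlap_fraction))
  })
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lesion_library
#' @export
read_lesion_library <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    regions <- if (length(parts) < 2 || !nzchar(parts[2])) character(0)
               else strsplit(parts[2], ",", fixed = TRUE)[[1]]
    lesion_region_set(parts[1], regions)
  })
}
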