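#' Labeled voxel volume
#'
#' The phantom container: a 3-D integer label grid with physical spacing (mm),
#' world origin (mm) and a label-to-tissue map. Label 0 is reserved for
#' exterior air. Voxel centers sit at `origin + index * spacing` with 0-based
#' indices and axis order (x, y, z).
#'
#' @param data 3-D integer array of tissue labels (0 = exterior air).
#' @param spacing numeric length-3, voxel spacing in mm (strictly positive).
#' @param origin numeric length-3, world coordinates of voxel (0,0,0) in mm.
#' @param labels named integer vector or data.frame mapping label integers to
#'   tissue names; every nonzero label present in `data` must appear.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         labels = integer()) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)")
  if (length(origin) != 3L) stop("`origin` must have length 3")
  if (prod(dim(data)) == 0L) stop("`data` must be non-empty")
  storage.mode(data) <- "integer"
  if (any(data < 0L, na.rm = TRUE)) stop("labels must be non-negative")
  lab <- as_label_map(labels)
  present <- sort(unique(as.vector(data)))
  present <- present[present != 0L]
  missing <- setdiff(present, lab$label)
  if (length(missing))
    stop("labels present in `data` but absent from the label map: ",
         paste(missing, collapse = ", "))
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin), labels = lab),
    class = "label_volume"
  )
}

as_label_map <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("label", "tissue") %in% names(labels)))
    lab <- data.frame(label = as.integer(labels$label),
                      tissue = as.character(labels$tissue),
                      stringsAsFactors = FALSE)
  } else if (length(labels) == 0L) {
    lab <- data.frame(label = integer(), tissue = character())
  } else {
    if (is.null(names(labels))) stop("`labels` must be named (tissue names)")
    lab <- data.frame(label = as.integer(labels),
                      tissue = names(labels), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(lab$label)) stop("duplicate label integers in label map")
  if (any(lab$label == 0L)) stop("label 0 is reserved for exterior air")
  lab[order(lab$label), , drop = FALSE]
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<label_volume> ", paste(d, collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "), " mm\n",
      sep = "")
  n <- sum(x$data != 0L)
  cat("  labeled voxels: ", n, " (", nrow(x$labels), " tissues)\n", sep = "")
  invisible(x)
}

#' Tissue name for each label integer
#' @param vol a `label_volume`
#' @return named character vector indexed by label
#' @export
label_tissues <- function(vol) {
  setNames(vol$labels$tissue, vol$labels$label)
}

#' Voxel volume in mm^3
#' @param vol a `label_volume` (or spacing vector)
#' @export
voxel_volume_mm3 <- function(vol) {
  sp <- if (inherits(vol, "label_volume")) vol$spacing else vol
  prod(sp)
}

#' World coordinates of voxel centers along one axis
#' @param vol a `label_volume`
#' @param axis 1, 2 or 3
#' @export
axis_coords <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}

#' Write / read a label volume as NIfTI-1 plus a label-map CSV
#'
#' The grid goes to a NIfTI file (spacing carried in the header `pixdim`);
#' the label map to a CSV with columns `label`, `tissue`.
#'
#' @param vol a `label_volume`
#' @param path NIfTI file path (`.nii` or `.nii.gz`)
#' @param labels_path label-map CSV path; defaults to `<path>.labels.csv`
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path, labels_path = NULL) {
  if (is.null(labels_path)) labels_path <- paste0(path, ".labels.csv")
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  RNifti::writeNifti(img, path)
  write.csv(vol$labels, labels_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path, labels_path = NULL) {
  if (is.null(labels_path)) labels_path <- paste0(path, ".labels.csv")
  img <- RNifti::readNifti(path)
  lab <- read.csv(labels_path, stringsAsFactors = FALSE)
  arr <- array(as.integer(round(img)), dim = dim(img))
  label_volume(arr, spacing = RNifti::pixdim(img)[1:3], labels = lab)
}

#' Embed a label volume centered inside a larger empty domain
#'
#' Pads with exterior air (label 0) so that the phantom sits centered in a
#' domain of `dim_out` voxels at the same spacing. Used to place a head
#' phantom inside the EM computational domain.
#'
#' @param vol a `label_volume`
#' @param dim_out integer length-3 target grid size (each >= current size)
#' @return a `label_volume` on the larger grid
#' @export
embed_volume <- function(vol, dim_out) {
  d <- dim(vol$data)
  dim_out <- as.integer(dim_out)
  if (any(dim_out < d)) stop("target dimensions smaller than the volume")
  out <- array(0L, dim = dim_out)
  off <- (dim_out - d) %/% 2L
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])] <-
    vol$data
  label_volume(out, spacing = vol$spacing,
               origin = vol$origin - off * vol$spacing, labels = vol$labels)
}
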