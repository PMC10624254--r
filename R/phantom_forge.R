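# Synthetic phantom construction: layered heads, priority merging, the
# supplant rule, Lanczos/nearest resampling and rater-mask perturbation.

#' Build a synthetic layered spherical head phantom
#'
#' Concentric spherical shells stand in for the head of an anatomical voxel
#' model: an outer skin shell (1.0 mm thick by default), then e.g. skull,
#' CSF, grey matter, and a white-matter core, with an optional internal air
#' cavity. Layer `i` occupies radii `(layer_radii[i+1], layer_radii[i]]`; the
#' innermost layer fills the core.
#'
#' When the outermost (skin) layer is thinner than the grid spacing it cannot
#' be realized by radial binning; it is then snapped to a one-voxel outward
#' shell around the remaining layers and the achieved thickness (= spacing)
#' is recorded in the `skin_thickness_achieved` attribute. Any *inner* layer
#' thinner than the spacing is rejected.
#'
#' @param layer_radii numeric, outer radii of each layer in mm, strictly
#'   decreasing, outermost first. Default: 5-layer head of an approximately
#'   3.5-year-old (skin to 80 mm, skull to 79, CSF to 75, grey matter to 71,
#'   white matter core 67 mm) with a 1.0 mm skin shell.
#' @param layer_tissues character, tissue name per layer (same length).
#' @param spacing voxel spacing in mm (scalar isotropic or length 3).
#' @param air_cavity optional `list(center = c(x,y,z), radius = r)` in mm
#'   relative to the sphere center; labeled as internal air.
#' @return a [label_volume] with layers labeled 1..n (internal air n+1),
#'   attribute `skin_thickness_achieved` in mm.
#' @export
make_layered_head <- function(layer_radii = c(80, 79, 75, 71, 67),
                              layer_tissues = c("Skin", "Skull cortical",
                                                "Cerebrospinal fluid",
                                                "Brain (grey matter)",
                                                "Brain (white matter)"),
                              spacing = 1,
                              air_cavity = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  n <- length(layer_radii)
  if (n < 1L) stop("at least one layer is required")
  if (length(layer_tissues) != n)
    stop("`layer_tissues` must match `layer_radii` in length")
  if (n > 1L && any(diff(layer_radii) >= 0))
    stop("`layer_radii` must be strictly decreasing (outermost first)")
  thick <- if (n > 1L) c(-diff(layer_radii), layer_radii[n]) else layer_radii
  smax <- max(spacing)
  if (n > 1L && any(thick[-1] < smax))
    stop("spacing (", smax, " mm) larger than the thinnest inner shell (",
         min(thick[-1]), " mm); refine the grid or thicken the shells")
  snap_skin <- n > 1L && thick[1] < smax

  r_out <- layer_radii[1]
  half <- r_out + 2 * spacing   # one-voxel pad beyond outer radius
  nvox <- pmax(3L, as.integer(ceiling(2 * half / spacing)) + 1L)
  cx <- lapply(1:3, function(a) ((seq_len(nvox[a]) - 1) -
                                   (nvox[a] - 1) / 2) * spacing[a])
  r2 <- outer(outer(cx[[1]]^2, cx[[2]]^2, `+`), cx[[3]]^2, `+`)
  r <- sqrt(r2)

  data <- array(0L, dim = nvox)
  if (snap_skin) {
    # bin layers 2..n by radius, then add a one-voxel skin shell outward
    for (i in 2:n) {
      inner <- if (i < n) layer_radii[i + 1] else -1
      data[r <= layer_radii[i] & r > inner] <- i
    }
    body <- data > 0L
    shell <- dilate6(body) & !body
    data[shell] <- 1L
    skin_thick <- max(spacing)
  } else {
    for (i in seq_len(n)) {
      inner <- if (i < n) layer_radii[i + 1] else -1
      data[r <= layer_radii[i] & r > inner] <- i
    }
    skin_thick <- thick[1]
  }

  labels <- data.frame(label = seq_len(n), tissue = layer_tissues)
  if (!is.null(air_cavity)) {
    stopifnot(is.list(air_cavity), !is.null(air_cavity$radius))
    ctr <- air_cavity$center %||% c(0, 0, 0)
    d2 <- outer(outer((cx[[1]] - ctr[1])^2, (cx[[2]] - ctr[2])^2, `+`),
                (cx[[3]] - ctr[3])^2, `+`)
    cav <- d2 <= air_cavity$radius^2 & data > 0L
    data[cav] <- n + 1L
    labels <- rbind(labels,
                    data.frame(label = n + 1L, tissue = "Air (internal)"))
  }
  vol <- label_volume(data, spacing = spacing,
                      origin = -((nvox - 1) / 2) * spacing, labels = labels)
  attr(vol, "skin_thickness_achieved") <- skin_thick
  vol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge binary masks with label-priority semantics
#'
#' Each voxel takes the highest label among the masks covering it (higher
#' label number = higher priority, the convention used when hierarchical
#' segmentations overlap); voxels covered by no mask stay 0.
#'
#' @param masks list of `list(label = <positive int>, mask = <logical/0-1
#'   array>)`, all masks on one grid.
#' @param spacing,origin grid geometry passed to the result.
#' @param labels optional label map; defaults to `tissue_<label>` names.
#' @return a [label_volume]
#' @export
merge_with_priority <- function(masks, spacing = c(1, 1, 1),
                                origin = c(0, 0, 0), labels = NULL) {
  if (!length(masks)) stop("no masks given")
  dims <- lapply(masks, function(m) dim(m$mask))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("mask shapes differ; all masks must share one grid")
  out <- array(0L, dim = dims[[1]])
  labs <- integer(0)
  for (m in masks) {
    l <- as.integer(m$label)
    if (l <= 0L) stop("labels must be positive")
    labs <- c(labs, l)
    out <- pmax(out, l * (m$mask != 0))
  }
  out <- array(as.integer(out), dim = dims[[1]])
  if (is.null(labels)) {
    labs <- sort(unique(labs))
    labels <- data.frame(label = labs, tissue = paste0("tissue_", labs))
  }
  label_volume(out, spacing = spacing, origin = origin, labels = labels)
}

#' Assign unlabeled in-body voxels to the nearest labeled tissue
#'
#' The supplant rule of phantom finalization: every voxel inside the body
#' mask that carries no tissue label receives the label of its nearest
#' labeled voxel (Euclidean distance between voxel centers, in mm). Among
#' equidistant donors the smallest label wins, which makes the fill
#' deterministic. Already-labeled voxels are never changed.
#'
#' @param vol a [label_volume]
#' @param body_mask logical array on the same grid; must contain all labeled
#'   voxels.
#' @return a [label_volume] with no unassigned voxels inside `body_mask`.
#' @export
supplant_unassigned <- function(vol, body_mask) {
  stopifnot(inherits(vol, "label_volume"))
  if (!identical(dim(body_mask), dim(vol$data)))
    stop("body_mask shape differs from the volume")
  body_mask <- body_mask != 0
  lab <- vol$data
  if (any(lab > 0L & !body_mask))
    stop("body_mask must contain every labeled voxel")
  src <- which(lab > 0L)
  if (!length(src)) stop("no labeled voxel inside body_mask to supplant from")
  holes <- which(body_mask & lab == 0L)
  if (!length(holes)) return(vol)

  d <- dim(lab)
  src_ijk <- arrayInd(src, d)
  hole_ijk <- arrayInd(holes, d)
  sp <- vol$spacing
  src_mm <- sweep(src_ijk, 2, sp, `*`)
  src_lab <- lab[src]
  # order donors by label so that which.min resolves ties to the smallest label
  o <- order(src_lab)
  src_mm <- src_mm[o, , drop = FALSE]
  src_lab <- src_lab[o]

  out <- lab
  chunk <- max(1L, floor(2e6 / length(src)))
  for (s in seq(1, length(holes), by = chunk)) {
    idx <- s:min(s + chunk - 1L, length(holes))
    hm <- sweep(hole_ijk[idx, , drop = FALSE], 2, sp, `*`)
    # squared distances, holes in rows
    d2 <- outer(rowSums(hm^2), rowSums(src_mm^2), `+`) -
      2 * hm %*% t(src_mm)
    d2 <- round(d2, 9)  # stabilize exact ties against FP noise
    nearest <- max.col(-d2, ties.method = "first")
    out[holes[idx]] <- src_lab[nearest]
  }
  label_volume(out, spacing = vol$spacing, origin = vol$origin,
               labels = vol$labels)
}

# ---- Lanczos resampling -----------------------------------------------------

#' Lanczos kernel
#' @param x evaluation points; @param a kernel order (default 3)
#' @return kernel values; `sinc(x) * sinc(x/a)` inside `|x| < a`, 0 outside
#' @export
lanczos_kernel <- function(x, a = 3) {
  out <- numeric(length(x))
  inside <- abs(x) < a
  xi <- x[inside]
  s <- ifelse(xi == 0, 1, sin(pi * xi) / (pi * xi))
  sa <- ifelse(xi == 0, 1, sin(pi * xi / a) / (pi * xi / a))
  out[inside] <- s * sa
  out
}

# Weight matrix (n_out x n_in) for one axis; rows normalized to sum 1 so a
# constant signal is preserved exactly. Border samples are clamped.
lanczos_weights <- function(n_in, s_in, s_out, a = 3) {
  n_out <- max(1L, as.integer(round(n_in * s_in / s_out)))
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    p <- (j - 1) * s_out / s_in            # position in input index units
    i0 <- floor(p) - a + 1
    idx <- i0:(i0 + 2 * a - 1)
    w <- lanczos_kernel(p - idx, a)
    idx <- pmin(pmax(idx, 0), n_in - 1)    # clamp to border
    for (k in seq_along(idx)) W[j, idx[k] + 1] <- W[j, idx[k] + 1] + w[k]
    W[j, ] <- W[j, ] / sum(W[j, ])
  }
  W
}

nearest_weights <- function(n_in, s_in, s_out) {
  n_out <- max(1L, as.integer(round(n_in * s_in / s_out)))
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    i <- min(max(round((j - 1) * s_out / s_in), 0), n_in - 1)
    W[j, i + 1] <- 1
  }
  W
}

apply_axis <- function(arr, W, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a2 <- aperm(arr, perm)
  m <- matrix(a2, nrow = d[axis])
  r <- W %*% m
  d2 <- c(nrow(W), d[setdiff(1:3, axis)])
  out <- array(r, dim = d2)
  aperm(out, order(perm))
}

#' Resample a scalar grid or label volume to a new spacing
#'
#' Scalar grids are resampled with a separable, normalized Lanczos kernel
#' (order `a = 3`); label grids always use nearest-neighbor so labels stay
#' integral. The physical extent is preserved to within one voxel.
#'
#' @param vol a 3-D numeric array or a [label_volume]
#' @param target_spacing new spacing in mm (scalar or length 3, > 0)
#' @param spacing current spacing when `vol` is a plain array
#' @param method `"lanczos"` (scalar default) or `"nearest"`
#' @param a Lanczos order
#' @return resampled array (attribute `spacing`) or [label_volume]
#' @export
resample_volume <- function(vol, target_spacing, spacing = c(1, 1, 1),
                            method = NULL, a = 3) {
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stop("target spacing must be strictly positive")
  if (inherits(vol, "label_volume")) {
    arr <- vol$data; spacing <- vol$spacing
    method <- method %||% "nearest"
    if (method != "nearest")
      stop("label grids must use nearest-neighbor resampling")
  } else {
    arr <- vol
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    method <- method %||% "lanczos"
  }
  d <- dim(arr)
  out <- arr * 1.0
  for (ax in 1:3) {
    W <- if (method == "lanczos")
      lanczos_weights(d[ax], spacing[ax], target_spacing[ax], a)
    else nearest_weights(d[ax], spacing[ax], target_spacing[ax])
    out <- apply_axis(out, W, ax)
  }
  if (inherits(vol, "label_volume")) {
    out <- array(as.integer(round(out)), dim = dim(out))
    return(label_volume(out, spacing = target_spacing, origin = vol$origin,
                        labels = vol$labels))
  }
  attr(out, "spacing") <- target_spacing
  out
}

# ---- binary morphology (6-connected) ---------------------------------------

shift_zero <- function(m, axis, by) {
  d <- dim(m); out <- array(FALSE, d)
  idx_src <- lapply(d, seq_len); idx_dst <- idx_src
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) { idx_dst[[axis]] <- (1 + by):n; idx_src[[axis]] <- 1:(n - by) }
  else if (by < 0) { idx_dst[[axis]] <- 1:(n + by); idx_src[[axis]] <- (1 - by):n }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

dilate6 <- function(m) {
  m <- m != 0
  out <- m
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out | shift_zero(m, ax, by)
  out
}

erode6 <- function(m) {
  m <- m != 0
  out <- m
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out & shift_zero(m, ax, by)
  out
}

# boundary voxels: labeled with at least one face-adjacent background
# neighbor (grid edge counts as background)
boundary_mask <- function(m) {
  m <- m != 0
  m & !erode6(m)
}

#' Perturb a binary mask to emulate inter-rater segmentation variability
#'
#' Deterministic given `seed`. `dilate`/`erode` apply the 6-connected
#' structuring element `magnitude` times; `boundary-noise` flips each
#' boundary voxel (either side of the interface) independently with
#' probability `prob`, `magnitude` times.
#'
#' @param mask logical/0-1 3-D array
#' @param mode `"dilate"`, `"erode"` or `"boundary-noise"`
#' @param magnitude non-negative integer, repetitions
#' @param seed integer RNG seed (used by `boundary-noise`)
#' @param prob flip probability for `boundary-noise`
#' @return logical array of the same shape
#' @export
perturb_mask <- function(mask, mode = c("dilate", "erode", "boundary-noise"),
                         magnitude = 1, seed = 1, prob = 0.5) {
  mode <- match.arg(mode)
  if (magnitude < 0) stop("magnitude must be non-negative")
  if (magnitude > max(dim(mask)))
    stop("magnitude exceeds the mask size")
  m <- mask != 0
  if (magnitude == 0) return(m)
  if (mode == "boundary-noise") {
    set.seed(as.integer(seed))
    for (i in seq_len(magnitude)) {
      b <- which((dilate6(m) & !erode6(m)))   # both sides of the interface
      if (!length(b)) break
      flip <- b[stats::runif(length(b)) < prob]
      m[flip] <- !m[flip]
    }
  } else {
    f <- if (mode == "dilate") dilate6 else erode6
    for (i in seq_len(magnitude)) m <- f(m)
    if (mode == "erode" && !any(m))
      stop("magnitude exceeds the mask size: erosion emptied the mask")
  }
  m
}

#' Generate a gold mask plus perturbed rater masks
#'
#' Synthetic stand-in for a multi-rater segmentation study: the gold standard
#' is a supplied (or spherical) mask; each rater's mask is a seeded
#' perturbation of it.
#'
#' @param gold logical 3-D array, the gold-standard mask
#' @param n_raters number of raters
#' @param modes,magnitudes,probs recycled per rater, see [perturb_mask]
#' @param seed base seed; rater `i` uses `seed + i`
#' @param tissue tissue name tag
#' @param spacing grid spacing in mm
#' @return object of class `rater_mask_set`: `gold`, `raters` (named list),
#'   `tissue`, `spacing`
#' @export
make_rater_set <- function(gold, n_raters = 3,
                           modes = "boundary-noise", magnitudes = 1,
                           probs = 0.5, seed = 1, tissue = "tissue",
                           spacing = c(1, 1, 1)) {
  modes <- rep_len(modes, n_raters)
  magnitudes <- rep_len(magnitudes, n_raters)
  probs <- rep_len(probs, n_raters)
  raters <- lapply(seq_len(n_raters), function(i)
    perturb_mask(gold, modes[i], magnitudes[i], seed = seed + i,
                 prob = probs[i]))
  names(raters) <- paste0("rater", seq_len(n_raters))
  structure(list(gold = gold != 0, raters = raters, tissue = tissue,
                 spacing = spacing),
            class = "rater_mask_set")
}
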