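# Multi-rater segmentation validation: Dice similarity, average Hausdorff
# (symmetric mean boundary-to-boundary) distance in mm, organ weight from
# density x volume, literature-range pass/fail, and rater summary statistics.

#' Dice similarity coefficient
#'
#' `DSC = 2|X intersect Y| / (|X| + |Y|)`. Two empty masks agree perfectly
#' (DSC 1); empty vs non-empty is 0.
#'
#' @param X,Y binary masks (logical/0-1 arrays) on the same grid
#' @return DSC in `[0, 1]`
#' @export
dice <- function(X, Y) {
  if (!identical(dim(X), dim(Y))) stop("mask shapes differ")
  x <- X != 0; y <- Y != 0
  nx <- sum(x); ny <- sum(y)
  if (nx + ny == 0L) return(1.0)
  2 * sum(x & y) / (nx + ny)
}

#' Average (symmetric mean boundary) Hausdorff distance in mm
#'
#' The classical Hausdorff distance is a maximum; segmentation QC tables
#' instead report the *average* variant: the mean over boundary voxels of X
#' of the distance to Y's boundary, averaged with the reverse direction.
#' Boundary voxels are labeled voxels with at least one face-adjacent
#' background neighbor (the grid edge counts as background); distances are
#' Euclidean between boundary-voxel centers in physical mm.
#'
#' @param X,Y non-empty binary masks on the same grid
#' @param spacing voxel spacing in mm (scalar or length 3)
#' @return distance in mm (>= 0; 0 when X == Y)
#' @export
hausdorff_average <- function(X, Y, spacing = c(1, 1, 1)) {
  if (!identical(dim(X), dim(Y))) stop("mask shapes differ")
  if (!any(X != 0) || !any(Y != 0))
    stop("average Hausdorff distance is undefined for an empty mask")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  bx <- which(boundary_mask(X))
  by <- which(boundary_mask(Y))
  d <- dim(X)
  px <- sweep(arrayInd(bx, d), 2, spacing, `*`)
  py <- sweep(arrayInd(by, d), 2, spacing, `*`)
  dxy <- mean(.min_dists(px, py))
  dyx <- mean(.min_dists(py, px))
  (dxy + dyx) / 2
}

# for each row of `from`, distance to the nearest row of `to` (chunked)
.min_dists <- function(from, to, chunk_elems = 4e6) {
  nt <- nrow(to)
  chunk <- max(1L, floor(chunk_elems / nt))
  t2 <- rowSums(to^2)
  out <- numeric(nrow(from))
  for (s in seq(1, nrow(from), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(from))
    f <- from[idx, , drop = FALSE]
    d2 <- outer(rowSums(f^2), t2, `+`) - 2 * f %*% t(to)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Organ weight from a mask, spacing and density
#'
#' Weight = voxel count x voxel volume x density, reported in grams
#' (density from a reference tissue database, volume from the segmentation).
#'
#' @param mask binary mask
#' @param spacing voxel spacing in mm
#' @param density tissue mass density in kg m^-3 (> 0)
#' @return weight in g
#' @export
organ_weight <- function(mask, spacing = c(1, 1, 1), density) {
  if (density <= 0) stop("density must be positive")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  v_mm3 <- sum(mask != 0) * prod(spacing)
  v_mm3 * 1e-9 * density * 1e3   # mm^3 -> m^3, kg -> g
}

#' Pass/fail check of a measurement against a literature range
#'
#' Pass iff `low <= value <= high`. The signed percent deviation is 0 inside
#' the range, otherwise `100 * (value - nearest bound) / nearest bound`
#' (negative below the lower bound).
#'
#' @param value measured value
#' @param low,high literature range bounds (`low <= high`); a single
#'   reference value is expressed as `low == high`
#' @return list with `verdict` ("pass"/"fail") and `deviation_pct`
#' @export
literature_check <- function(value, low, high) {
  if (low > high) stop("invalid range: low > high")
  if (value >= low && value <= high)
    return(list(verdict = "pass", deviation_pct = 0))
  bound <- if (value < low) low else high
  list(verdict = "fail", deviation_pct = 100 * (value - bound) / bound)
}

#' Ratio of two bone lengths
#' @param length_a,length_b lengths in cm (> 0)
#' @return dimensionless ratio a/b
#' @export
bone_length_ratio <- function(length_a, length_b) {
  if (length_b <= 0) stop("denominator length must be positive")
  if (length_a <= 0) stop("lengths must be positive")
  length_a / length_b
}

#' Build a per-tissue, per-rater score table
#'
#' @param tissue,rater,dsc,hausdorff_mm equal-length vectors; `(tissue,
#'   rater)` pairs must be unique, DSC in `[0, 1]`, distances >= 0
#' @return data.frame of class `score_table`
#' @export
score_table <- function(tissue, rater, dsc, hausdorff_mm) {
  tab <- data.frame(tissue = as.character(tissue),
                    rater = as.character(rater),
                    dsc = as.numeric(dsc),
                    hausdorff_mm = as.numeric(hausdorff_mm),
                    stringsAsFactors = FALSE)
  if (any(tab$dsc < 0 | tab$dsc > 1)) stop("DSC outside [0, 1]")
  if (any(tab$hausdorff_mm < 0)) stop("negative Hausdorff distance")
  if (anyDuplicated(tab[c("tissue", "rater")]))
    stop("(tissue, rater) pairs must be unique")
  class(tab) <- c("score_table", "data.frame")
  tab
}

#' Load the packaged multi-rater score fixture (or a compatible CSV)
#' @param path CSV with columns tissue, rater, dsc, hausdorff_mm
#' @return a `score_table`
#' @export
load_score_table <- function(path = system.file("extdata",
                                                "segmentor_scores.csv",
                                                package = "voxdosim",
                                                mustWork = TRUE)) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  score_table(tab$tissue, tab$rater, tab$dsc, tab$hausdorff_mm)
}

#' Load the packaged literature-range table
#' @param path CSV path
#' @return data.frame with tissue, measurement, measured, low, high columns
#' @export
load_literature_ranges <- function(path = system.file("extdata",
                                                      "literature_ranges.csv",
                                                      package = "voxdosim",
                                                      mustWork = TRUE)) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (any(tab$low > tab$high)) stop("invalid range rows (low > high)")
  tab
}

#' Summary statistics of a score table
#'
#' Per-rater and overall min / max / mean / SD of the DSC and average
#' Hausdorff columns. "Overall" pools every (tissue, rater) cell. The SD is
#' the population SD by default (divide by n), switchable to the sample SD.
#'
#' @param table a `score_table` (non-empty)
#' @param sd_type "population" or "sample"
#' @return list with data.frames `per_rater` and `overall`
#' @export
summarize_scores <- function(table, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!nrow(table)) stop("empty score table")
  sdev <- function(x) {
    if (sd_type == "sample") sd(x) else sqrt(mean((x - mean(x))^2))
  }
  stat <- function(x) c(min = min(x), max = max(x), mean = mean(x),
                        sd = sdev(x))
  raters <- sort(unique(table$rater))
  per <- do.call(rbind, lapply(raters, function(r) {
    sub <- table[table$rater == r, ]
    data.frame(rater = r,
               t(setNames(stat(sub$dsc),
                          paste0("dsc_", names(stat(sub$dsc))))),
               t(setNames(stat(sub$hausdorff_mm),
                          paste0("hd_", c("min", "max", "mean", "sd")))),
               row.names = NULL)
  }))
  overall <- data.frame(
    t(setNames(stat(table$dsc), paste0("dsc_", c("min", "max", "mean", "sd")))),
    t(setNames(stat(table$hausdorff_mm),
               paste0("hd_", c("min", "max", "mean", "sd")))),
    row.names = NULL)
  list(per_rater = per, overall = overall)
}

#' Round for reporting at table precision
#'
#' 2 decimal places with round-half-to-even (the IEC 60559 behavior of
#' [round()]), matching the precision of the published score tables.
#' @param x numeric
#' @param digits decimal places
#' @export
report_round <- function(x, digits = 2) round(x, digits)
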