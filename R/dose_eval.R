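#' Soft-tissue evaluation mask
#'
#' Marks the voxels entering dose comparisons: everything denser than the
#' air threshold, so surrounding air, bronchi and bowel gas drop out while
#' lung parenchyma (~0.26 g/cm3) stays in.
#'
#' @param density `voxel_grid` of g/cm3.
#' @param air_threshold density cut in g/cm3.
#' @return logical array.
#' @export
evaluation_mask <- function(density, air_threshold = 0.05) {
  density$values > air_threshold
}

#' Mean dose over a volume of interest
#' @param dose `voxel_grid` of Gy.
#' @param mask logical array aligned with `dose`.
#' @export
voi_mean_dose <- function(dose, mask) {
  if (!identical(dim(mask), dim(dose$values)))
    stop("mask and dose dimensions differ")
  if (!any(mask)) stop("empty mask")
  mean(dose$values[mask])
}

#' Percentage difference versus a reference dose
#'
#' `PD = |d_ref - d| / d_ref * 100`. The scalar form requires
#' `d_ref > 0`; the elementwise form (arrays) returns `NA` where the
#' reference is zero and reports how many voxels were excluded via the
#' `"n_excluded"` attribute.
#'
#' @param d_ref reference dose (scalar or array).
#' @param d comparison dose, same shape.
#' @export
percentage_difference <- function(d_ref, d) {
  if (length(d_ref) == 1L) {
    if (d_ref <= 0) stop("reference dose must be > 0")
    return(abs(d_ref - d) / d_ref * 100)
  }
  pd <- array(NA_real_, dim(d_ref))
  ok <- d_ref > 0
  pd[ok] <- abs(d_ref[ok] - d[ok]) / d_ref[ok] * 100
  attr(pd, "n_excluded") <- sum(!ok)
  pd
}

#' Voxel-wise PD map between two dose grids
#' @param ref,test `voxel_grid`s of Gy, aligned.
#' @return array of PD percent with `NA` where the reference is zero.
#' @export
pd_map <- function(ref, test) {
  stop_unless_aligned(ref, test, "dose grids")
  percentage_difference(ref$values, test$values)
}

#' Region statistics of a PD map
#'
#' Mean and standard deviation of the voxel-wise PD over the whole
#' evaluation mask and its overlap / non-overlap partition. `NA` PD
#' voxels (zero reference) are dropped.
#'
#' @param pd array of PD percent (may contain `NA`).
#' @param eval_mask logical array: voxels entering the evaluation.
#' @param overlap_mask logical array: the patch-overlap bands.
#' @return data.frame with rows `WB`, `overlap`, `non_overlap` and columns
#'   `mean`, `sd`, `n`.
#' @export
region_statistics <- function(pd, eval_mask, overlap_mask) {
  if (!identical(dim(pd), dim(eval_mask)) ||
      !identical(dim(pd), dim(overlap_mask)))
    stop("masks and PD map must be aligned")
  one <- function(m) {
    v <- pd[m]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(c(mean = NA_real_, sd = NA_real_, n = 0))
    c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0, n = length(v))
  }
  res <- rbind(WB = one(eval_mask),
               overlap = one(eval_mask & overlap_mask),
               non_overlap = one(eval_mask & !overlap_mask))
  as.data.frame(res)
}

#' 1-D line profile through a volume
#'
#' @param grid `voxel_grid` (or array).
#' @param axis 1, 2 or 3: the axis to run along.
#' @param fixed the two fixed indices of the transverse axes, in axis
#'   order with `axis` removed.
#' @export
line_profile <- function(grid, axis, fixed) {
  vals <- if (is_voxel_grid(grid)) grid$values else grid
  d <- dim(vals)
  axis <- as.integer(axis)
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  others <- setdiff(1:3, axis)
  if (any(fixed < 1L) || any(fixed > d[others]))
    stop("fixed indices out of range")
  idx <- vector("list", 3)
  idx[[axis]] <- seq_len(d[axis])
  idx[[others[1]]] <- fixed[1]
  idx[[others[2]]] <- fixed[2]
  as.vector(vals[idx[[1]], idx[[2]], idx[[3]]])
}

#' Efficiency factor
#'
#' `EF = 1 / (T * U^2)`: a figure of merit trading computation time `T`
#' (hours) against percentage statistical uncertainty `U`. Strictly
#' decreasing in both arguments.
#'
#' @param time_h computation time in hours (> 0).
#' @param uncertainty_pct mean percentage uncertainty (> 0).
#' @export
efficiency_factor <- function(time_h, uncertainty_pct) {
  if (any(time_h <= 0) || any(uncertainty_pct <= 0))
    stop("time and uncertainty must be > 0")
  1 / (time_h * uncertainty_pct^2)
}

#' Histogram of a PD map as binned counts
#'
#' @param pd array of PD percent (NA dropped).
#' @param bin_width bin width in PD percent.
#' @return data.frame with `lower`, `upper`, `count`.
#' @export
pd_histogram <- function(pd, bin_width = 1) {
  v <- pd[!is.na(pd)]
  if (length(v) == 0L) return(data.frame(lower = numeric(0),
                                         upper = numeric(0),
                                         count = integer(0)))
  breaks <- seq(0, max(v) + bin_width, by = bin_width)
  h <- hist(v, breaks = breaks, plot = FALSE)
  data.frame(lower = head(breaks, -1), upper = breaks[-1], count = h$counts)
}
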