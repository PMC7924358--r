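#' Conical crevice geometry
#'
#' Describes the convergent crevice formed between a conical trunnion and its
#' bore: the small angular mismatch `alpha` between the two cones sets the
#' nominal gap, which is widest at the crevice mouth (x = 0) and closes
#' toward the deep end (x = L). `r_int` is the trunnion radius; the metal
#' taper over the crevice length (a few um) is neglected and `r_int` held
#' constant.
#'
#' @param alpha Mismatch angle between trunnion and bore cones, degrees
#'   (default 0.02).
#' @param length_L Crevice length, mm (default 13).
#' @param r_int Inner (trunnion) radius, mm (default 6).
#' @param dx Discretization step along the axis, mm (default 1e-3 = 1 um).
#' @param gap_floor Minimum admissible gap, mm (default 1e-4 = 0.1 um). Where
#'   a roughness peak touches the bore the nominal gap vanishes; a residual
#'   asperity-scale film is kept so that no segment has infinite resistance.
#' @return An object of class `crevice_geometry`.
#' @export
crevice_geometry <- function(alpha = 0.02, length_L = 13, r_int = 6,
                             dx = 1e-3, gap_floor = 1e-4) {
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (length_L <= 0) stop("length_L must be positive", call. = FALSE)
  if (r_int <= 0) stop("r_int must be positive", call. = FALSE)
  if (dx <= 0 || dx > length_L)
    stop("dx must satisfy 0 < dx <= length_L", call. = FALSE)
  if (gap_floor <= 0) stop("gap_floor must be positive", call. = FALSE)
  structure(list(alpha = alpha, length_L = length_L, r_int = r_int,
                 dx = dx, gap_floor = gap_floor),
            class = "crevice_geometry")
}

#' @export
print.crevice_geometry <- function(x, ...) {
  cat(sprintf(
    "crevice_geometry: alpha = %g deg, L = %g mm, r_int = %g mm\n",
    x$alpha, x$length_L, x$r_int))
  cat(sprintf("  dx = %g mm, gap_floor = %g mm, nominal mouth aperture = %.3g um\n",
              x$dx, x$gap_floor, nominal_mouth_aperture(x) * 1000))
  invisible(x)
}

#' Nominal aperture at the crevice mouth
#'
#' The gap at x = 0 for a perfectly smooth cone pair:
#' `tan(alpha) * L` (plus `C` when a roughness profile is present).
#'
#' @param geometry A [crevice_geometry()].
#' @param c_max Maximum roughness height C, mm (default 0: smooth surface).
#' @return Aperture in mm.
#' @export
nominal_mouth_aperture <- function(geometry, c_max = 0) {
  stopifnot(inherits(geometry, "crevice_geometry"))
  tan(geometry$alpha * pi / 180) * geometry$length_L + c_max
}

#' Build the crevice gap profile
#'
#' Combines the conical mismatch with the surface roughness trace into the
#' local gap between trunnion and bore,
#' `y_g(x) = tan(alpha) * (L - x) + C - y_p(x)`,
#' with x measured from the crevice mouth (x = 0) toward the closed end
#' (x = L). `C = max(y_p)` guarantees `y_g >= 0` analytically; values below
#' the geometry's `gap_floor` (roughness peaks touching the bore) are clamped
#' to it.
#'
#' @param geometry A [crevice_geometry()].
#' @param profile A `surface_profile` spanning `[0, L]` on the geometry's
#'   grid — typically a single machining period passed through
#'   [tile_profile()]. A single-period profile with a set period is tiled
#'   automatically.
#' @return An object of class `gap_profile`: list with `x` (mm), `gap` (mm),
#'   `clamped` (logical, gap floored), plus the `geometry` and the profile
#'   `c_max`.
#' @export
build_gap_profile <- function(geometry, profile) {
  stopifnot(inherits(geometry, "crevice_geometry"),
            inherits(profile, "surface_profile"))
  span <- max(profile$positions)
  if (span < geometry$length_L - 1e-9) {
    if (!is.na(profile$period))
      profile <- tile_profile(profile, geometry$length_L)
    else
      stop("profile spans ", span, " mm but the crevice is ",
           geometry$length_L, " mm and no period is set for tiling",
           call. = FALSE)
  }
  if (abs(profile$dx - geometry$dx) > 1e-9)
    stop("profile sampling step (", profile$dx,
         " mm) does not match geometry dx (", geometry$dx, " mm)",
         call. = FALSE)
  n <- as.integer(floor(geometry$length_L / geometry$dx + 1e-9)) + 1L
  x <- (seq_len(n) - 1) * geometry$dx
  yp <- profile$heights[seq_len(n)]
  gap_raw <- tan(geometry$alpha * pi / 180) * (geometry$length_L - x) +
    profile$c_max - yp
  gap <- pmax(gap_raw, geometry$gap_floor)
  structure(list(x = x, gap = gap, clamped = gap_raw < geometry$gap_floor,
                 geometry = geometry, c_max = profile$c_max),
            class = "gap_profile")
}

#' @export
print.gap_profile <- function(x, ...) {
  cat(sprintf(
    "gap_profile: %d samples, mouth gap %.3g um, min gap %.3g um (%d clamped)\n",
    length(x$x), x$gap[1] * 1000, min(x$gap) * 1000, sum(x$clamped)))
  invisible(x)
}
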