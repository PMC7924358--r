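#' Surface roughness profiles
#'
#' A `surface_profile` holds a sampled line trace of machined surface
#' roughness along the cone axis: uniformly spaced positions (mm), heights
#' relative to the centerline (mm), the repeat length of the machining
#' pattern (mm), and the maximum height `c_max` (the constant C entering the
#' gap construction). Heights are usually centerline-normalized (mean zero);
#' [normalize_profile()] enforces that.
#'
#' @param positions Numeric vector of positions along the cone axis, in mm.
#'   Must be strictly increasing and uniformly spaced (within 1e-9 mm).
#' @param heights Numeric vector of roughness heights, in mm, same length as
#'   `positions`.
#' @param period Repeat length of the machining pattern, in mm (`NA` if the
#'   trace is not periodic or the period is unknown).
#' @param normalized Logical; whether `heights` already have zero mean.
#'
#' @return An object of class `surface_profile`: a list with elements
#'   `positions`, `heights`, `period`, `c_max` (= `max(heights)`), `dx`
#'   (sampling step, mm) and `normalized`.
#' @seealso [normalize_profile()], [average_periods()], [tile_profile()],
#'   [generate_fixture_profile()]
#' @export
surface_profile <- function(positions, heights, period = NA_real_,
                            normalized = FALSE) {
  positions <- as.numeric(positions)
  heights <- as.numeric(heights)
  if (length(positions) < 2L)
    stop("a surface profile needs at least 2 samples", call. = FALSE)
  if (length(positions) != length(heights))
    stop("positions and heights must have the same length", call. = FALSE)
  steps <- diff(positions)
  if (any(steps <= 0))
    stop("positions must be strictly increasing", call. = FALSE)
  if (diff(range(steps)) > 1e-9)
    stop("positions must be uniformly spaced (within 1e-9 mm)", call. = FALSE)
  if (!is.na(period) && period <= 0)
    stop("period must be positive", call. = FALSE)
  structure(
    list(positions = positions, heights = heights,
         period = as.numeric(period), c_max = max(heights),
         dx = mean(steps), normalized = isTRUE(normalized)),
    class = "surface_profile")
}

#' @export
print.surface_profile <- function(x, ...) {
  cat(sprintf(
    "surface_profile: %d samples over %.4g mm (dx = %.4g mm)\n",
    length(x$positions), diff(range(x$positions)), x$dx))
  cat(sprintf("  period: %s mm, C (max height): %.4g um, normalized: %s\n",
              format(x$period), x$c_max * 1000, x$normalized))
  invisible(x)
}

# Coerce bare height vectors to a surface_profile on a default 1 um grid.
as_surface_profile <- function(x, dx = 1e-3, period = NA_real_) {
  if (inherits(x, "surface_profile")) return(x)
  surface_profile(positions = (seq_along(x) - 1) * dx, heights = x,
                  period = period)
}

#' Centerline-normalize a roughness profile
#'
#' Shifts the heights so that their mean (the centerline average) is zero,
#' and records the post-normalization maximum as `c_max`. The shape is
#' preserved up to the additive constant; applying the operation twice equals
#' applying it once.
#'
#' @param profile A [surface_profile()], or a bare numeric vector of heights
#'   (mm) which is placed on a uniform grid of step `dx`.
#' @param dx Sampling step (mm) used when `profile` is a bare vector.
#' @param period Period (mm) attached when `profile` is a bare vector.
#' @return A `surface_profile` with zero-mean heights and updated `c_max`.
#' @export
normalize_profile <- function(profile, dx = 1e-3, period = NA_real_) {
  p <- as_surface_profile(profile, dx = dx, period = period)
  h <- p$heights - mean(p$heights)
  surface_profile(p$positions, h, period = p$period, normalized = TRUE)
}

#' Average repeated machining periods into a single representative period
#'
#' Extracts `n_periods` consecutive full periods from a measured trace,
#' re-anchors each so that it starts at its highest sample (peak first),
#' averages them point-wise, and centerline-normalizes the result. Averaging
#' several periods damps measurement noise in any single one.
#'
#' @param profile_trace A [surface_profile()] or bare height vector (mm).
#' @param period Repeat length, in mm (default 0.27 mm, the peak-to-peak
#'   periodicity of a fine-machined trunnion thread).
#' @param n_periods Number of periods to average (default 3).
#' @param dx Sampling step (mm) when `profile_trace` is a bare vector.
#' @return A normalized single-period `surface_profile` (peak first).
#' @export
average_periods <- function(profile_trace, period = 0.27, n_periods = 3L,
                            dx = 1e-3) {
  p <- as_surface_profile(profile_trace, dx = dx, period = period)
  m <- as.integer(round(period / p$dx))
  if (m < 2L)
    stop("period must span at least 2 samples at this dx", call. = FALSE)
  if (length(p$heights) < n_periods * m)
    stop(sprintf("trace holds %d samples but %d periods of %d samples are required",
                 length(p$heights), n_periods, m), call. = FALSE)
  chunks <- lapply(seq_len(n_periods), function(k) {
    chunk <- p$heights[((k - 1L) * m + 1L):(k * m)]
    i <- which.max(chunk)              # re-anchor: peak-first rotation
    if (i > 1L) chunk <- c(chunk[i:m], chunk[seq_len(i - 1L)])
    chunk
  })
  avg <- Reduce(`+`, chunks) / n_periods
  normalize_profile(surface_profile((seq_len(m) - 1) * p$dx, avg,
                                    period = period))
}

#' Tile a single-period profile along the crevice length
#'
#' Repeats the machining pattern periodically so that the profile spans the
#' whole crevice, `[0, L]`. Every output sample equals the source sample at
#' the corresponding position modulo the period.
#'
#' @param profile A `surface_profile` whose `period` is set; at least one full
#'   period of samples must be present.
#' @param length_L Target length, in mm.
#' @return A `surface_profile` spanning `[0, length_L]` with the same period,
#'   `c_max` and normalization state as the source period.
#' @export
tile_profile <- function(profile, length_L) {
  stopifnot(inherits(profile, "surface_profile"))
  if (is.na(profile$period) || profile$period <= 0)
    stop("profile period must be positive to tile", call. = FALSE)
  if (length_L <= 0) stop("length_L must be positive", call. = FALSE)
  m <- as.integer(round(profile$period / profile$dx))
  if (length(profile$heights) < m)
    stop("profile holds less than one full period", call. = FALSE)
  base <- profile$heights[seq_len(m)]
  n_out <- as.integer(floor(length_L / profile$dx + 1e-9)) + 1L
  idx <- ((seq_len(n_out) - 1L) %% m) + 1L
  out <- surface_profile((seq_len(n_out) - 1) * profile$dx, base[idx],
                         period = profile$period,
                         normalized = profile$normalized)
  # the tiled c_max is the period's own maximum even if the tail is partial
  out$c_max <- max(base)
  out
}

#' Rescale roughness heights
#'
#' Multiplies the heights by a positive factor (for roughness-sensitivity
#' studies, e.g. a 5-fold smoother surface uses `scale = 0.2`), then
#' re-normalizes so the centerline average stays zero and `c_max` is
#' recomputed.
#'
#' @param profile A `surface_profile`.
#' @param scale Positive multiplicative factor on heights.
#' @return A normalized `surface_profile`.
#' @export
scale_profile <- function(profile, scale) {
  stopifnot(inherits(profile, "surface_profile"))
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a positive number", call. = FALSE)
  normalize_profile(surface_profile(profile$positions,
                                    profile$heights * scale,
                                    period = profile$period))
}

#' Generate a synthetic machined-surface profile
#'
#' Produces one period of an idealized machining pattern: a triangular wave
#' (thread-like, the default), a sinusoid, or a triangular wave with seeded
#' uniform height jitter (`"jitter"`). All kinds start at their peak, matching
#' the peak-first anchoring used when averaging measured periods, and are
#' centerline-normalized. Triangle and sine traces are deterministic;
#' the jittered kind is reproducible for a given `seed`.
#'
#' @param kind One of `"triangle"`, `"sine"`, `"jitter"`.
#' @param period Repeat length, mm (default 0.27).
#' @param amplitude Half peak-to-valley height, mm (default 0.015, i.e. 15 um).
#' @param dx Sampling step, mm (default 1e-3, resolving the default period
#'   with 270 samples).
#' @param seed Integer seed consumed only by the `"jitter"` kind.
#' @param jitter_sd Relative jitter magnitude (fraction of `amplitude`) for
#'   the `"jitter"` kind.
#' @return A normalized single-period `surface_profile`.
#' @export
generate_fixture_profile <- function(kind = c("triangle", "sine", "jitter"),
                                     period = 0.27, amplitude = 0.015,
                                     dx = 1e-3, seed = 0L, jitter_sd = 0.1) {
  kind <- match.arg(kind)
  if (period <= 0 || amplitude <= 0 || dx <= 0)
    stop("period, amplitude and dx must be positive", call. = FALSE)
  m <- as.integer(round(period / dx))
  if (m < 4L) stop("dx too coarse for this period", call. = FALSE)
  phase <- (seq_len(m) - 1) / m
  h <- switch(kind,
    triangle = amplitude * (1 - 4 * pmin(phase, 1 - phase)),
    sine = amplitude * cos(2 * pi * phase),
    jitter = {
      base <- amplitude * (1 - 4 * pmin(phase, 1 - phase))
      noise <- withr_seed(seed, stats::runif(m, -1, 1)) * jitter_sd * amplitude
      base + noise
    })
  normalize_profile(surface_profile((seq_len(m) - 1) * dx, h, period = period))
}

# Evaluate expr under a temporary RNG seed without disturbing the session RNG.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Read a roughness or polarization trace from a two-column text file
#'
#' Plain-text, two numeric columns (whitespace- or comma-delimited), comment
#' lines starting with `#`. For profiles, a header comment `# units: um` or
#' `# units: mm` declares the length unit (default um); both columns are
#' converted to mm.
#'
#' @param path File path.
#' @param period Period (mm) to attach to the profile, if known.
#' @return A `surface_profile` (positions and heights in mm).
#' @export
read_profile_file <- function(path, period = NA_real_) {
  dat <- read_two_columns(path)
  unit <- attr(dat, "units")
  fac <- if (identical(unit, "mm")) 1 else 1e-3
  surface_profile(dat[[1]] * fac, dat[[2]] * fac, period = period)
}

read_two_columns <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  units <- "um"
  hdr <- grep("^\\s*#\\s*units\\s*:", lines, value = TRUE)
  if (length(hdr))
    units <- trimws(sub("^\\s*#\\s*units\\s*:", "", hdr[1]))
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  parts <- strsplit(trimws(body), "[,[:space:]]+")
  if (any(vapply(parts, length, 1L) < 2L))
    stop("expected two numeric columns in ", path, call. = FALSE)
  dat <- data.frame(x = as.numeric(vapply(parts, `[`, "", 1L)),
                    y = as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(dat)) stop("non-numeric data in ", path, call. = FALSE)
  attr(dat, "units") <- units
  dat
}
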