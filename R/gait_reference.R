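#' Reference gait trajectories
#'
#' Constructs smooth periodic hip and knee reference angle curves for one gait
#' cycle. Each joint curve is a sum of two harmonics, rescaled so that its
#' peak-to-peak excursion equals the configured range of motion (ROM) exactly,
#' and shifted so that its midrange equals the configured offset. The knee
#' flexion peak falls in mid swing and the hip flexion peak near terminal
#' swing, as in treadmill gait. The absolute curve shape is a physiological
#' surrogate: the downstream analysis depends on deviations from the
#' reference, not on the reference itself.
#'
#' @param cadence Gait cycles per minute. Default 40 (slow treadmill walking,
#'   200 cycles per 5-minute training block).
#' @param rom_hip,rom_knee Peak-to-peak range of motion in degrees.
#' @param offset_hip,offset_knee Midrange angle in degrees.
#'
#' @return An object of class `gait_reference`: a list with the configured
#'   parameters and vectorized functions `hip_angle(fraction)` and
#'   `knee_angle(fraction)` returning degrees for cycle fractions in `[0, 1)`
#'   (values outside are wrapped, so the curves are periodic).
#'
#' @examples
#' ref <- gait_reference()
#' ref$knee_angle(c(0, 0.25, 0.78))
#' @export
gait_reference <- function(cadence = 40, rom_hip = 40, rom_knee = 60,
                           offset_hip = 10, offset_knee = 30) {
  check_scalar_positive(cadence, "cadence")
  check_scalar_positive(rom_hip, "rom_hip")
  check_scalar_positive(rom_knee, "rom_knee")
  if (!is.numeric(offset_hip) || !is.numeric(offset_knee)) {
    stop_invalid("offsets must be numeric.")
  }

  # two-harmonic raw shapes; peak location set by the phase shift
  hip_raw <- make_two_harmonic(peak = 0.88, second = 0.20)
  knee_raw <- make_two_harmonic(peak = 0.78, second = 0.45)

  structure(
    list(
      cadence = cadence,
      rom_hip = rom_hip, rom_knee = rom_knee,
      offset_hip = offset_hip, offset_knee = offset_knee,
      hip_angle = normalize_curve(hip_raw, rom_hip, offset_hip),
      knee_angle = normalize_curve(knee_raw, rom_knee, offset_knee)
    ),
    class = "gait_reference"
  )
}

#' @rdname gait_reference
#' @param ... Passed to `gait_reference()`.
#' @export
make_reference <- function(...) gait_reference(...)

make_two_harmonic <- function(peak, second) {
  force(peak); force(second)
  function(x) cos(2 * pi * (x - peak)) + second * cos(4 * pi * (x - peak))
}

# Rescale a periodic raw curve so its exact peak-to-peak equals `rom` and its
# midrange equals `offset`. Extrema are located on a fine grid and then
# refined with stats::optimize so the ROM invariant holds to ~1e-9 degrees.
normalize_curve <- function(raw, rom, offset) {
  grid <- seq(0, 1, length.out = 4097L)[-4097L]
  vals <- raw(grid)
  hi <- refine_extremum(raw, grid[which.max(vals)], maximum = TRUE)
  lo <- refine_extremum(raw, grid[which.min(vals)], maximum = FALSE)
  mid <- (hi + lo) / 2
  scale <- rom / (hi - lo)
  function(fraction) {
    x <- fraction %% 1
    offset + scale * (raw(x) - mid)
  }
}

refine_extremum <- function(f, x0, maximum) {
  opt <- optimize(f, interval = c(x0 - 4e-4, x0 + 4e-4),
                  maximum = maximum, tol = 1e-12)
  opt[[2L]]
}

#' @export
print.gait_reference <- function(x, ...) {
  cat(sprintf(
    "<gait_reference> cadence %g cycles/min; hip ROM %g deg (offset %g); knee ROM %g deg (offset %g)\n",
    x$cadence, x$rom_hip, x$offset_hip, x$rom_knee, x$offset_knee
  ))
  invisible(x)
}

#' Sample a reference trajectory into a table
#'
#' @param reference A [gait_reference()].
#' @param n Number of equally spaced cycle fractions in `[0, 1)`.
#'
#' @return A tibble with columns `fraction`, `hip_deg`, `knee_deg`.
#' @examples
#' reference_curve(gait_reference(), n = 8)
#' @export
reference_curve <- function(reference, n = 1000) {
  stopifnot(inherits(reference, "gait_reference"))
  check_scalar_positive(n, "n")
  fraction <- seq(0, 1, length.out = n + 1L)[seq_len(n)]
  tibble(
    fraction = fraction,
    hip_deg = reference$hip_angle(fraction),
    knee_deg = reference$knee_angle(fraction)
  )
}

#' Equal-width window grid over the gait cycle
#'
#' The gait cycle is divided into `n_windows` equal windows of cycle
#' fraction; joint impedance is adapted independently in each window.
#'
#' @param n_windows Number of windows (default 30).
#' @return An object of class `window_grid` with fields `n_windows` and
#'   `boundaries` (the `n_windows + 1` window edges in cycle fraction).
#' @examples
#' window_grid()
#' @export
window_grid <- function(n_windows = 30) {
  if (!is.numeric(n_windows) || length(n_windows) != 1L ||
      n_windows < 1 || n_windows != floor(n_windows)) {
    stop_invalid("`n_windows` must be a positive whole number.")
  }
  n_windows <- as.integer(n_windows)
  structure(
    list(n_windows = n_windows,
         boundaries = seq(0, 1, length.out = n_windows + 1L)),
    class = "window_grid"
  )
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %d equal windows over [0, 1)\n", x$n_windows))
  invisible(x)
}

#' Gait-cycle subphase boundaries
#'
#' Splits the cycle into stance followed by the three analyzed swing
#' subphases: initial swing (IS), mid swing (MS) and terminal swing (TS).
#' Defaults put IS at 10.5%, MS at 14% and TS at 13% of the gait cycle;
#' stance is the complement (62.5%) so the four fractions sum to one exactly.
#'
#' @param is_fraction,ms_fraction,ts_fraction Swing subphase fractions of the
#'   gait cycle.
#' @return An object of class `subphase_map` with the four fractions and the
#'   cumulative boundaries.
#' @examples
#' subphase_map()
#' @export
subphase_map <- function(is_fraction = 0.105, ms_fraction = 0.14,
                         ts_fraction = 0.13) {
  for (nm in c("is_fraction", "ms_fraction", "ts_fraction")) {
    check_scalar_positive(get(nm), nm)
  }
  swing <- is_fraction + ms_fraction + ts_fraction
  if (swing >= 1) {
    stop_invalid("swing subphase fractions must sum to less than 1.")
  }
  stance <- 1 - swing
  structure(
    list(
      stance_fraction = stance,
      is_fraction = is_fraction,
      ms_fraction = ms_fraction,
      ts_fraction = ts_fraction,
      boundaries = cumsum(c(0, stance, is_fraction, ms_fraction, ts_fraction))
    ),
    class = "subphase_map"
  )
}

#' @export
print.subphase_map <- function(x, ...) {
  cat(sprintf(
    "<subphase_map> stance %.1f%% | IS %.1f%% | MS %.1f%% | TS %.1f%%\n",
    100 * x$stance_fraction, 100 * x$is_fraction,
    100 * x$ms_fraction, 100 * x$ts_fraction
  ))
  invisible(x)
}

subphase_levels <- c("stance", "IS", "MS", "TS")

#' Label a cycle fraction with its gait subphase
#'
#' Subphases are half-open intervals in cycle fraction, ordered
#' stance, IS, MS, TS; a boundary point belongs to the later phase.
#'
#' @param fraction Cycle fraction(s) in `[0, 1)`.
#' @param map A [subphase_map()].
#' @return A factor with levels `stance`, `IS`, `MS`, `TS`.
#' @examples
#' segment_subphase(c(0.5, 0.70, 0.99), subphase_map())
#' @export
segment_subphase <- function(fraction, map = subphase_map()) {
  stopifnot(inherits(map, "subphase_map"))
  check_fraction_domain(fraction)
  idx <- findInterval(fraction, map$boundaries, left.open = FALSE,
                      rightmost.closed = FALSE)
  factor(subphase_levels[idx], levels = subphase_levels)
}

#' Window index of a cycle fraction
#'
#' @param fraction Cycle fraction(s) in `[0, 1)`.
#' @param grid A [window_grid()].
#' @return Integer window index (or indices) in `[0, n_windows)`.
#' @examples
#' window_of(c(0, 0.5, 0.999), window_grid())
#' @export
window_of <- function(fraction, grid = window_grid()) {
  stopifnot(inherits(grid, "window_grid"))
  check_fraction_domain(fraction)
  as.integer(floor(fraction * grid$n_windows))
}

#' Assign each window to a gait subphase
#'
#' A window straddling a subphase boundary is assigned to the subphase that
#' covers the majority of its width; ties go to the earlier subphase, so the
#' assignment is a deterministic total function of the grid and the map.
#'
#' @param grid A [window_grid()].
#' @param map A [subphase_map()].
#' @return A factor of length `n_windows` (window 0 first) with levels
#'   `stance`, `IS`, `MS`, `TS`.
#' @examples
#' table(window_subphases())
#' @export
window_subphases <- function(grid = window_grid(), map = subphase_map()) {
  stopifnot(inherits(grid, "window_grid"), inherits(map, "subphase_map"))
  lo <- grid$boundaries[-length(grid$boundaries)]
  hi <- grid$boundaries[-1L]
  cuts <- map$boundaries # length 5, cuts[1] = 0, cuts[5] = 1
  overlap <- vapply(seq_len(4L), function(p) {
    pmax(0, pmin(hi, cuts[p + 1L]) - pmax(lo, cuts[p]))
  }, numeric(grid$n_windows))
  overlap <- matrix(overlap, nrow = grid$n_windows)
  # which.max on each row returns the first (earlier) maximum: the tie rule
  idx <- apply(overlap, 1L, which.max)
  factor(subphase_levels[idx], levels = subphase_levels)
}
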