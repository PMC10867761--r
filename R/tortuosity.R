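# Tortuosity metrics on vessel segments.
#
# The estimator works on a smoothed, arc-length-resampled polyline. Raster
# skeletons carry up to half a pixel of lateral quantization noise, which
# turning-angle metrics integrate; three guards keep that noise out of the
# curvature estimates while leaving genuine vessel waviness intact:
#   1. position smoothing (moving average over a fixed arc-length window),
#   2. tangent-angle smoothing before differencing,
#   3. a dead-band (`angle_floor_rad`) zeroing angles indistinguishable from
#      quantization, plus trimming of the unreliable near-tip angles.
# CTI (arc/chord) uses only the smoothed polyline and is unaffected by the
# angle dead-band.

#' Tortuosity analysis configuration
#'
#' Tunable parameters of the vessel-graph tortuosity pipeline, with the
#' package defaults. All lengths are in pixels.
#'
#' @param spacing_px target inter-point spacing of the resampled polyline
#'   (default 5). Sets the scale over which turning angles are measured.
#' @param smoothing_window moving-average window (in px of arc length) for
#'   position smoothing of the skeleton chain (default 9); odd integer.
#' @param tangent_window_px window (px of arc length) for smoothing the
#'   tangent-angle sequence before turning angles are differenced
#'   (default 35). Values at or below `spacing_px` disable this stage.
#' @param angle_floor_rad dead-band: turning angles below this are treated
#'   as 0 (default 0.03 rad; above the quantization-noise ceiling at the
#'   default smoothing). Curvature below `angle_floor_rad / spacing_px` per pixel
#'   is therefore not detectable.
#' @param end_trim number of resampling spacings at each segment end over
#'   which turning angles are down-weighted to 0 (default 5); the truncated
#'   smoothing windows and tip extension leave residual noise there.
#' @param cti_formula `"arc_chord"` (default) or `"angle_sum"`. The
#'   arc-to-chord ratio is scale invariant and equals 1 for straight
#'   vessels; the angle-sum variant `1 + IC / arc` (rad/px) is exposed for
#'   sensitivity analysis.
#' @param aggregate `"mean"` (default, unweighted across segments) or
#'   `"length_weighted"` for image-level summaries.
#' @param min_length_px minimum segment arc length (default 20).
#' @param spur_length_px spur-pruning threshold (default 10).
#' @param disc_radius_px exclusion radius around the optic disc
#'   (default 50; 0 disables).
#' @param tip_extension extend free vessel tips to the mask boundary
#'   (default TRUE).
#' @return An object of class `tortuosity_config` (a validated named list).
#' @export
tortuosity_config <- function(spacing_px = 5, smoothing_window = 9,
                              tangent_window_px = 35, angle_floor_rad = 0.03,
                              end_trim = 5,
                              cti_formula = c("arc_chord", "angle_sum"),
                              aggregate = c("mean", "length_weighted"),
                              min_length_px = 20, spur_length_px = 10,
                              disc_radius_px = 50, tip_extension = TRUE) {
  cti_formula <- match.arg(cti_formula)
  aggregate <- match.arg(aggregate)
  stopifnot(spacing_px > 0, smoothing_window >= 1, tangent_window_px >= 0,
            angle_floor_rad >= 0, end_trim >= 0, min_length_px >= 0,
            spur_length_px >= 0, disc_radius_px >= 0)
  structure(list(spacing_px = spacing_px,
                 smoothing_window = as.integer(smoothing_window),
                 tangent_window_px = tangent_window_px,
                 angle_floor_rad = angle_floor_rad,
                 end_trim = as.integer(end_trim),
                 cti_formula = cti_formula, aggregate = aggregate,
                 min_length_px = min_length_px,
                 spur_length_px = spur_length_px,
                 disc_radius_px = disc_radius_px,
                 tip_extension = isTRUE(tip_extension)),
            class = "tortuosity_config")
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialization; recorded in every output table
#' so results can be traced to the exact parameter set.
#'
#' @param config a `tortuosity_config` (or any serializable list).
#' @return Character scalar (32 hex digits).
#' @export
config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

dedupe_points <- function(pts) {
  if (nrow(pts) < 2) return(pts)
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  pts[c(TRUE, d > 1e-12), , drop = FALSE]
}

# Resample a polyline at uniform arc-length spacing; endpoints exact.
resample_uniform <- function(pts, spacing) {
  pts <- dedupe_points(pts)
  if (nrow(pts) < 2) return(pts)
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(d)); L <- s[length(s)]
  n_out <- max(2, round(L / spacing) + 1)
  ss <- seq(0, L, length.out = n_out)
  cbind(stats::approx(s, pts[, 1], ss)$y, stats::approx(s, pts[, 2], ss)$y)
}

# Centered moving average with symmetric truncation at the ends (window
# shrinks near the boundary so the endpoints are preserved exactly).
box_smooth <- function(x, window) {
  n <- NROW(x)
  if (window <= 1 || n < 3) return(x)
  half <- window %/% 2
  xm <- as.matrix(x)
  cs <- rbind(0, apply(xm, 2, cumsum))
  i <- seq_len(n)
  h <- pmin(half, i - 1, n - i)
  lo <- i - h; hi <- i + h
  out <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  if (is.matrix(x)) out else as.numeric(out)
}

#' Smooth and resample a pixel chain
#'
#' The chain is first resampled at 1 px arc spacing (so smoothing acts over
#' a direction-independent arc-length window), smoothed by a centered moving
#' average of positions (window truncated symmetrically at the ends, so both
#' endpoints are preserved exactly), and finally resampled by arc length at
#' `spacing_px`.
#'
#' @param chain an n x 2 matrix of (row, col) points, n >= 2, or a
#'   `vessel_segment`.
#' @param spacing_px target spacing (default 5).
#' @param smoothing_window moving-average window in px (default 9).
#' @return A `resampled_polyline`: list with `points`, `spacing_px`,
#'   `smoothing_window`.
#' @export
resample_chain <- function(chain, spacing_px = 5, smoothing_window = 9) {
  if (inherits(chain, "vessel_segment")) chain <- chain$chain
  chain <- as.matrix(chain)
  if (nrow(chain) < 2) stop("chain must have at least 2 points")
  if (nrow(chain) == 2) {
    pts <- chain
  } else {
    u <- resample_uniform(chain, 1)
    sm <- box_smooth(u, smoothing_window)
    pts <- resample_uniform(sm, spacing_px)
  }
  structure(list(points = unname(pts), spacing_px = spacing_px,
                 smoothing_window = smoothing_window),
            class = "resampled_polyline")
}

#' Turning angles of a polyline
#'
#' The absolute angle between successive displacement vectors at each
#' interior point, each in `[0, pi]`.
#'
#' @param poly a `resampled_polyline` or an n x 2 matrix of points.
#' @return Numeric vector of length `n - 2` (empty when `n < 3`).
#' @export
turning_angles <- function(poly) {
  pts <- if (inherits(poly, "resampled_polyline")) poly$points else as.matrix(poly)
  if (nrow(pts) < 3) return(numeric(0))
  v <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  a <- v[-nrow(v), , drop = FALSE]; b <- v[-1, , drop = FALSE]
  dotp <- rowSums(a * b)
  crossp <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  atan2(abs(crossp), dotp)
}

# Turning angles via the smoothed tangent-angle sequence, with the
# quantization dead-band and fractional end-weighting. Angles within
# `end_trim` spacings of either end (where truncated smoothing windows and
# tip extension leave residual noise) get weight 0, ramping linearly to 1
# over one spacing; the soft ramp keeps IC continuous under the +/- 1
# vertex-count quantization of resampling. Reduces to turning_angles()
# (unit weights) when tangent_window_px <= spacing, end_trim = 0 and
# angle_floor_rad = 0.
processed_angles <- function(pts, config) {
  if (nrow(pts) < 3) return(list(theta = numeric(0), weight = numeric(0)))
  v <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  phi <- atan2(v[, 1], v[, 2])
  dphi <- diff(phi)
  dphi <- ((dphi + pi) %% (2 * pi)) - pi  # unwrap
  phi <- cumsum(c(phi[1], dphi))
  win <- max(1, round(config$tangent_window_px / config$spacing_px))
  phi_s <- box_smooth(phi, win)
  th <- abs(diff(phi_s))
  # soft dead-band: exactly 0 below the floor, full weight above
  # floor * 4/3, linear ramp between -- the soft shoulder keeps IC stable
  # when rasterization noise jitters angles across the threshold
  fl <- config$angle_floor_rad
  if (fl > 0) th <- th * pmin(1, pmax(0, (th - fl) / (fl / 3)))
  n <- length(th)
  if (config$end_trim > 0 && n > 0) {
    d <- pmin(seq_len(n), n + 1 - seq_len(n))  # distance to nearer end, in spacings
    w <- pmin(1, pmax(0, d - config$end_trim + 0.5))
  } else {
    w <- rep(1, n)
  }
  list(theta = th, weight = w)
}

#' Tortuosity metrics of one vessel segment
#'
#' Computes the cumulative tortuosity index (CTI), integrated curvature
#' (IC) and overall curvature (OC) of a segment on its smoothed, resampled
#' polyline:
#' \itemize{
#'   \item CTI = polyline arc length / chord length (>= 1; 1 for a straight
#'     vessel). With `cti_formula = "angle_sum"`, `1 + IC / arc` instead.
#'   \item IC = total absolute turning, `sum(w_i * theta_i)` (radians),
#'     with the fractional end weights `w_i` described in
#'     [tortuosity_config()].
#'   \item OC = mean absolute turning angle, `IC / sum(w_i)` (radians).
#' }
#' Segments whose chord is shorter than the resampling spacing (closed
#' loops) are flagged and excluded from image-level means.
#'
#' @param segment a `vessel_segment` (or n x 2 chain matrix).
#' @param config a [tortuosity_config()].
#' @return A `segment_tortuosity`: `segment_id`, `theta`, `theta_weight`,
#'   `cti`, `ic`, `oc`, `arc_length_px`, `chord_length_px`, `flagged`.
#' @export
segment_tortuosity <- function(segment, config = tortuosity_config()) {
  seg_id <- if (inherits(segment, "vessel_segment")) segment$segment_id else NA_character_
  poly <- resample_chain(segment, spacing_px = config$spacing_px,
                         smoothing_window = config$smoothing_window)
  pts <- poly$points
  arc <- step_sum(pts)
  chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  flagged <- chord < config$spacing_px
  pa <- processed_angles(pts, config)
  ic <- sum(pa$theta * pa$weight)
  # mean turning per resampling step over the measured (end-trimmed) span;
  # the arc-length denominator is continuous where a vertex count would
  # jump by one with the resampling grid
  denom <- (arc - 2 * config$end_trim * config$spacing_px) / config$spacing_px
  oc <- if (denom > 0 && sum(pa$weight) > 0) ic / denom else 0
  cti <- if (flagged) NA_real_
  else if (config$cti_formula == "arc_chord") arc / chord
  else 1 + ic / arc
  structure(list(segment_id = seg_id, theta = pa$theta,
                 theta_weight = pa$weight, cti = cti, ic = ic, oc = oc,
                 arc_length_px = arc, chord_length_px = chord,
                 flagged = flagged),
            class = "segment_tortuosity")
}

#' Image-level tortuosity summary
#'
#' Aggregates per-segment CTI/IC/OC into image-level values (unweighted
#' arithmetic means by default, arc-length-weighted means optionally).
#' Flagged (degenerate) segments are excluded.
#'
#' @param segments list of `segment_tortuosity` objects.
#' @param image_id image identifier.
#' @param config the [tortuosity_config()] used (recorded in the result).
#' @return A `tortuosity_result`: `image_id`, `cti`, `ic`, `oc`,
#'   `n_segments`, `segments`, `config`, `config_hash`.
#' @export
image_tortuosity <- function(segments, image_id = "image",
                             config = tortuosity_config()) {
  ok <- Filter(function(s) !isTRUE(s$flagged), segments)
  if (length(ok) == 0)
    stop(sprintf("no usable vessel segments for image '%s'", image_id))
  w <- if (config$aggregate == "length_weighted")
    vapply(ok, function(s) s$arc_length_px, numeric(1)) else rep(1, length(ok))
  w <- w / sum(w)
  agg <- function(f) sum(w * vapply(ok, f, numeric(1)))
  structure(list(image_id = image_id,
                 cti = agg(function(s) s$cti),
                 ic = agg(function(s) s$ic),
                 oc = agg(function(s) s$oc),
                 n_segments = length(ok),
                 n_flagged = length(segments) - length(ok),
                 segments = segments,
                 config = config,
                 config_hash = config_hash(config)),
            class = "tortuosity_result")
}

#' @export
print.tortuosity_result <- function(x, ...) {
  cat(sprintf("<tortuosity_result> %s: CTI %.4f, IC %.3f rad, OC %.4f rad (%d segments)\n",
              x$image_id, x$cti, x$ic, x$oc, x$n_segments))
  invisible(x)
}

#' Full tortuosity pipeline for one mask
#'
#' Skeletonizes the mask, builds the vessel graph, removes the optic-disc
#' region, extracts oriented vessel segments and computes per-segment and
#' image-level tortuosity.
#'
#' @param mask a [binary_mask()].
#' @param disc optional [disc_center()]; enables disc exclusion and
#'   proximal-to-distal orientation.
#' @param config a [tortuosity_config()].
#' @return A `tortuosity_result` (see [image_tortuosity()]).
#' @export
measure_tortuosity <- function(mask, disc = NULL, config = tortuosity_config()) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.null(disc)) {
    if (disc$row > nrow(mask$pixels) - 1 || disc$col > ncol(mask$pixels) - 1)
      stop(sprintf("disc center (%g, %g) outside mask bounds for image '%s'",
                   disc$row, disc$col, mask$image_id))
  }
  skel <- skeletonize_mask(mask)
  graph <- build_vessel_graph(skel)
  tip_mask <- mask
  if (!is.null(disc) && config$disc_radius_px > 0) {
    graph <- exclude_disc_region(graph, disc, config$disc_radius_px)
    # clear the disc region from the mask used for tip extension, so the
    # proximal cut ends stay at the exclusion boundary instead of being
    # extended back into the excluded confluence
    rr <- matrix(seq_len(nrow(mask$pixels)), nrow(mask$pixels), ncol(mask$pixels))
    cc <- matrix(seq_len(ncol(mask$pixels)), nrow(mask$pixels), ncol(mask$pixels),
                 byrow = TRUE)
    inside <- (rr - (disc$row + 1))^2 + (cc - (disc$col + 1))^2 <=
      config$disc_radius_px^2
    tip_mask <- binary_mask(mask$pixels & !inside, image_id = mask$image_id)
  }
  segs <- extract_segments(graph, disc = disc,
                           min_length_px = config$min_length_px,
                           spur_length_px = config$spur_length_px,
                           mask = tip_mask, tip_extension = config$tip_extension)
  st <- lapply(segs, segment_tortuosity, config = config)
  image_tortuosity(st, image_id = mask$image_id, config = config)
}

#' Per-segment table of a tortuosity result
#'
#' @param result a `tortuosity_result`.
#' @return data frame with one row per segment.
#' @export
segment_table <- function(result) {
  stopifnot(inherits(result, "tortuosity_result"))
  do.call(rbind, lapply(result$segments, function(s) {
    data.frame(image_id = result$image_id, segment_id = s$segment_id,
               cti = s$cti, ic = s$ic, oc = s$oc,
               arc_length_px = s$arc_length_px,
               chord_length_px = s$chord_length_px,
               flagged = s$flagged, stringsAsFactors = FALSE)
  }))
}
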