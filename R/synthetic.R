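# Synthetic flat-mount phantom generator.
#
# Radial vessels emanate from the optic disc and are perturbed by a
# sinusoid perpendicular to the radial direction; amplitude is the single
# tortuosity dial. The perturbation is tapered to zero near the disc, which
# mirrors the relatively straight peri-papillary course of the major
# vessels and keeps neighbouring vessels from colliding at high amplitude.
# Ground truth (arc length, chord, arc/chord ratio) is computed by
# numerical quadrature on the continuous centerline before rasterization.

#' Synthetic retina configuration
#'
#' @param image_size `c(rows, cols)` of the mask (default 1024 x 1024).
#' @param disc_center 0-based `(row, col)` of the optic disc; default image
#'   center.
#' @param n_vessels number of major radial vessels (default 8, the typical
#'   count of major arcades in a murine flat-mount).
#' @param stroke_width_px rasterized vessel width (default 5).
#' @param amplitude_px sinusoidal perturbation amplitude `a` in px
#'   (default 20, a strongly tortuous, disease-like phenotype; 0 gives
#'   perfectly straight vessels).
#' @param wavelength_px sinusoid wavelength (default 150; chosen so that at
#'   the largest amplitudes of interest the minimum radius of curvature
#'   stays well above the stroke radius and the tube does not self-overlap).
#' @param amplitude_jitter relative per-vessel amplitude variation,
#'   uniform in `a * (1 +/- jitter)` (default 0.15).
#' @param branch_prob probability that a vessel spawns one side branch
#'   (default 0; per-vessel ground truth is exact only without branches).
#' @param r_start_px radial distance at which vessels start (default 30).
#' @param r_end_px maximum radial extent; `NULL` extends each vessel to the
#'   image border minus a safety margin.
#' @param taper_px distance over which the amplitude ramps from 0 to `a`
#'   moving away from the disc (default 100).
#' @param rotation_deg rigid rotation of the whole vascular field about the
#'   disc, applied to the continuous centerlines before rasterization.
#' @param offset_px rigid translation `c(row, col)` applied likewise.
#' @param seed RNG seed fixing all randomness; `NULL` uses the current RNG
#'   stream.
#' @return A `synth_config` list.
#' @export
synth_config <- function(image_size = c(1024, 1024), disc_center = NULL,
                         n_vessels = 8, stroke_width_px = 5,
                         amplitude_px = 20, wavelength_px = 150,
                         amplitude_jitter = 0.15, branch_prob = 0,
                         r_start_px = 30, r_end_px = NULL, taper_px = 100,
                         rotation_deg = 0, offset_px = c(0, 0), seed = NULL) {
  stopifnot(length(image_size) == 2, all(image_size > 0), n_vessels >= 1,
            stroke_width_px > 0, amplitude_px >= 0, wavelength_px > 0,
            amplitude_jitter >= 0, branch_prob >= 0, branch_prob <= 1,
            r_start_px >= 0, taper_px >= 0, length(offset_px) == 2)
  if (is.null(disc_center)) disc_center <- (image_size - 1) / 2
  structure(list(image_size = as.integer(image_size),
                 disc_center = as.numeric(disc_center),
                 n_vessels = as.integer(n_vessels),
                 stroke_width_px = stroke_width_px,
                 amplitude_px = amplitude_px, wavelength_px = wavelength_px,
                 amplitude_jitter = amplitude_jitter,
                 branch_prob = branch_prob,
                 r_start_px = r_start_px, r_end_px = r_end_px,
                 taper_px = taper_px, rotation_deg = rotation_deg,
                 offset_px = as.numeric(offset_px), seed = seed),
            class = "synth_config")
}

# Tapered amplitude envelope and its derivative.
taper_envelope <- function(t, t0, taper) {
  if (taper <= 0) return(list(A = rep(1, length(t)), dA = rep(0, length(t))))
  u <- (t - t0) / taper
  list(A = pmin(1, pmax(0, u)), dA = ifelse(u > 0 & u < 1, 1 / taper, 0))
}

# Continuous centerline of one vessel and its analytic speed |c'(t)|.
vessel_curve <- function(t, disc, ang, amp, lambda, phase, t0, taper) {
  u <- c(-sin(ang), cos(ang))        # radial direction (row, col)
  v <- c(cos(ang), sin(ang))         # perpendicular
  env <- taper_envelope(t, t0, taper)
  k <- 2 * pi / lambda
  th <- k * t + phase
  off <- amp * env$A * sin(th)
  doff <- amp * (env$dA * sin(th) + env$A * k * cos(th))
  pts <- cbind(disc[1] + t * u[1] + off * v[1],
               disc[2] + t * u[2] + off * v[2])
  list(pts = pts, speed = sqrt(1 + doff^2))
}

simpson_w <- function(n) {
  # n odd
  w <- rep(c(4, 2), length.out = n - 2)
  c(1, w, 1)
}

rot2 <- function(pts, deg, center) {
  if (deg == 0) return(pts)
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(pts, 2, center) %*% t(R), 2, center, "+")
}

stamp_centerlines <- function(centerlines, width, image_size) {
  img <- matrix(FALSE, image_size[1], image_size[2])
  rad <- width / 2
  rng <- -ceiling(rad):ceiling(rad)
  offs <- expand.grid(dr = rng, dc = rng)
  offs <- offs[offs$dr^2 + offs$dc^2 <= rad^2, ]
  for (pts in centerlines) {
    # dense resample at 0.25 px so stamping leaves no gaps
    dense <- resample_uniform(pts, 0.25)
    rr <- dense[, 1] + 1; cc <- dense[, 2] + 1   # 0-based -> matrix indices
    for (k in seq_len(nrow(offs))) {
      ri <- round(rr + offs$dr[k]); ci <- round(cc + offs$dc[k])
      ok <- ri >= 1 & ri <= image_size[1] & ci >= 1 & ci <= image_size[2]
      img[cbind(ri[ok], ci[ok])] <- TRUE
    }
  }
  img
}

#' Generate a synthetic flat-mount vessel mask with ground truth
#'
#' Radial vessels with sinusoidal perturbation are laid out as continuous
#' curves, measured by quadrature (composite Simpson on the analytic speed)
#' and only then rasterized by stamping a disc of the stroke radius along a
#' densely sampled centerline. Fully reproducible for a fixed seed.
#'
#' @param config a [synth_config()].
#' @param image_id identifier for the generated mask.
#' @return List with `mask` ([binary_mask()]), `disc` ([disc_center()]),
#'   `truth` (data frame: `vessel_id`, `amplitude_px`, `arc_length_px`,
#'   `chord_length_px`, `true_ratio`) and `centerlines` (list of n x 2
#'   matrices, 0-based coordinates).
#' @export
generate_retina <- function(config = synth_config(), image_id = "synthetic") {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nr <- config$image_size[1]; nc <- config$image_size[2]
  disc <- config$disc_center
  n <- config$n_vessels
  angs <- 2 * pi * (seq_len(n) - 1) / n + stats::runif(n, -0.15, 0.15)
  amps <- config$amplitude_px *
    (1 + config$amplitude_jitter * stats::runif(n, -1, 1))
  phases <- stats::runif(n, 0, 2 * pi)
  has_branch <- stats::runif(n) < config$branch_prob

  margin <- config$amplitude_px + config$stroke_width_px + 4
  # extent limits apply to the transformed (rotated + translated) curve
  disc_eff <- disc + config$offset_px
  rot_rad <- config$rotation_deg * pi / 180
  extent_to_border <- function(ang) {
    u <- c(-sin(ang + rot_rad), cos(ang + rot_rad))
    lim <- function(p0, d, lo, hi) {
      if (abs(d) < 1e-12) return(Inf)
      if (d > 0) (hi - p0) / d else (lo - p0) / d
    }
    min(lim(disc_eff[1], u[1], 0, nr - 1), lim(disc_eff[2], u[2], 0, nc - 1))
  }

  centerlines <- list(); truth <- list(); vid <- 0
  add_vessel <- function(origin, t0, t1, ang, amp, phase, taper_from) {
    tt <- seq(t0, t1, length.out = 2001)
    cv <- vessel_curve(tt, origin, ang, amp, config$wavelength_px, phase,
                       taper_from, config$taper_px)
    h <- (t1 - t0) / (length(tt) - 1)
    arc <- h / 3 * sum(simpson_w(length(tt)) * cv$speed)
    pts <- rot2(cv$pts, config$rotation_deg, disc)
    pts <- sweep(pts, 2, config$offset_px, "+")
    chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
    vid <<- vid + 1
    centerlines[[vid]] <<- pts
    truth[[vid]] <<- data.frame(
      vessel_id = sprintf("v%02d", vid), amplitude_px = amp,
      arc_length_px = arc, chord_length_px = chord,
      true_ratio = arc / chord)
  }

  for (i in seq_len(n)) {
    t_max <- extent_to_border(angs[i]) - margin
    if (!is.null(config$r_end_px)) t_max <- min(t_max, config$r_end_px)
    if (t_max < config$r_start_px + 50)
      stop(sprintf("vessel %d does not fit inside the image (extent %.0f px)", i, t_max))
    add_vessel(disc, config$r_start_px, t_max, angs[i], amps[i], phases[i],
               config$r_start_px)
    if (has_branch[i]) {
      tb <- stats::runif(1, 0.45, 0.65) * t_max
      dang <- sample(c(-1, 1), 1) * stats::runif(1, 0.35, 0.6)
      bang <- angs[i] + dang
      # branch starts on the parent centerline
      pb <- vessel_curve(tb, disc, angs[i], amps[i], config$wavelength_px,
                         phases[i], config$r_start_px, config$taper_px)$pts[1, ]
      bt_max <- extent_to_border(bang) - margin - tb
      if (bt_max > 60)
        add_vessel(pb, 0, bt_max, bang,
                   config$amplitude_px * (1 + config$amplitude_jitter * stats::runif(1, -1, 1)),
                   stats::runif(1, 0, 2 * pi), 0)
    }
  }

  img <- stamp_centerlines(centerlines, config$stroke_width_px,
                           config$image_size)
  disc_out <- disc + config$offset_px
  list(mask = binary_mask(img, image_id = image_id),
       disc = disc_center(disc_out[1], disc_out[2], image_id = image_id),
       truth = do.call(rbind, truth),
       centerlines = centerlines)
}

#' Generate a cohort of synthetic retinas on disk
#'
#' Writes one PNG mask per image plus `disc_centers.csv`, `groups.csv` and
#' `truth.csv` into `out_dir`. Group conditions are defined by configuration
#' overrides, e.g. a low-amplitude "NOX-like" and a high-amplitude
#' "OIR-like" group.
#'
#' @param groups named list; each element is a list of [synth_config()]
#'   overrides for that condition (e.g.
#'   `list(NOX = list(amplitude_px = 3), OIR = list(amplitude_px = 20))`).
#' @param n_per_group images per group.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed fixing the whole cohort.
#' @param base_config shared [synth_config()] defaults.
#' @param timepoint optional timepoint label written to `groups.csv`.
#' @return The manifest data frame (`image_id`, `condition`, `timepoint`,
#'   `path`), invisibly.
#' @export
generate_cohort <- function(groups, n_per_group, out_dir, seed = 1,
                            base_config = synth_config(), timepoint = NA) {
  stopifnot(is.list(groups), length(groups) >= 1, n_per_group >= 1)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("`groups` must be a named list of config overrides")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  manifest <- list(); discs <- list(); truths <- list()
  for (g in names(groups)) {
    cfg <- base_config
    for (k in names(groups[[g]])) cfg[[k]] <- groups[[g]][[k]]
    cfg$seed <- NULL  # one stream for the whole cohort
    for (j in seq_len(n_per_group)) {
      id <- sprintf("%s_%03d", g, j)
      ret <- generate_retina(cfg, image_id = id)
      path <- file.path(out_dir, paste0(id, ".png"))
      write_mask(ret$mask, path)
      manifest[[id]] <- data.frame(image_id = id, condition = g,
                                   timepoint = timepoint, path = path,
                                   stringsAsFactors = FALSE)
      discs[[id]] <- ret$disc
      tr <- ret$truth; tr$image_id <- id
      truths[[id]] <- tr
    }
  }
  manifest <- do.call(rbind, manifest); rownames(manifest) <- NULL
  utils::write.csv(do.call(rbind, discs),
                   file.path(out_dir, "disc_centers.csv"), row.names = FALSE)
  utils::write.csv(manifest[, c("image_id", "condition", "timepoint")],
                   file.path(out_dir, "groups.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, truths),
                   file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Rasterize a continuous curve into a binary mask
#'
#' Stamps a disc of half the stroke width along a densely resampled
#' centerline, the same rasterization used by [generate_retina()]. Useful
#' for building validation phantoms from analytic curves.
#'
#' @param points n x 2 matrix of (row, col) points, 0-based coordinates.
#' @param stroke_width_px stroke width in pixels.
#' @param image_size `c(rows, cols)` of the output mask.
#' @param image_id identifier for the mask.
#' @return A [binary_mask()].
#' @export
rasterize_curve <- function(points, stroke_width_px = 5,
                            image_size = c(512, 512), image_id = "curve") {
  img <- stamp_centerlines(list(as.matrix(points)), stroke_width_px,
                           as.integer(image_size))
  binary_mask(img, image_id = image_id)
}
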