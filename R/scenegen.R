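#' Synthetic surgical-scene scenario
#'
#' Describes one temporal scenario of the synthetic endoscopic scene
#' generator: a tissue-toned textured background, bright low-saturation
#' elongated instruments (the segmentation targets) and dark-red blood
#' accumulation blobs (whose visible area defines the frame class).
#' Scenarios can include a precursor phase, in which brief low-area
#' "oozing" bursts repeat every ~300 ms before frank bleeding, followed by
#' a sustained bleeding phase with persistent supra-threshold blobs.
#'
#' @param duration_s Sequence duration in seconds (> 0).
#' @param fps Frame rate in frames/second (> 0).
#' @param precursor_onset_s Start of the precursor (oozing) phase in
#'   seconds, or `NULL` for none.
#' @param bleed_onset_s Start of the sustained bleeding phase in seconds,
#'   or `NULL` for none. Must exceed `precursor_onset_s` when both given.
#' @param n_tools Number of instruments rendered per frame.
#' @param blob_growth_rate Blood-blob area growth during the sustained
#'   phase, in pixels^2/second.
#' @param background_texture_seed Seed for the background texture phases.
#' @param rng_seed Master seed; all per-scenario and per-frame randomness
#'   derives from it (no global RNG state is consumed).
#' @param size Square frame size in pixels.
#' @param min_blob_frac Minimum visible blob area, as a fraction of the
#'   frame pixels, for a frame to be labelled "blood accumulation" (1).
#' @return A `scene_scenario` list.
#' @examples
#' sc <- scene_scenario(duration_s = 10, fps = 25, precursor_onset_s = 4,
#'                      bleed_onset_s = 7, rng_seed = 42)
#' @export
scene_scenario <- function(duration_s, fps = 25, precursor_onset_s = NULL,
                           bleed_onset_s = NULL, n_tools = 2,
                           blob_growth_rate = 40,
                           background_texture_seed = 1L, rng_seed = 1L,
                           size = 64, min_blob_frac = 0.01) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop_validation("duration_s must be > 0")
  }
  if (!is.numeric(fps) || fps <= 0) stop_validation("fps must be > 0")
  if (!is.null(precursor_onset_s) && !is.null(bleed_onset_s) &&
      precursor_onset_s >= bleed_onset_s) {
    stop_validation("precursor_onset_s must precede bleed_onset_s")
  }
  structure(list(
    duration_s = duration_s, fps = fps,
    precursor_onset_s = precursor_onset_s, bleed_onset_s = bleed_onset_s,
    n_tools = as.integer(n_tools), blob_growth_rate = blob_growth_rate,
    background_texture_seed = as.integer(background_texture_seed),
    rng_seed = as.integer(rng_seed), size = as.integer(size),
    min_blob_frac = min_blob_frac
  ), class = "scene_scenario")
}

# Static scene layout drawn once per scenario from rng_seed: tool geometry,
# blob cluster shape and colours. Deterministic; does not touch global RNG.
scene_statics <- function(scenario) {
  with_seed(scenario$rng_seed, {
    s <- scenario$size
    tools <- lapply(seq_len(scenario$n_tools), function(i) {
      list(
        cx = runif(1, 0.2 * s, 0.8 * s), cy = runif(1, 0.2 * s, 0.8 * s),
        angle = runif(1, 0, pi), len = runif(1, 0.45 * s, 0.7 * s),
        halfwidth = runif(1, 0.03 * s, 0.055 * s),
        gray = runif(1, 0.72, 0.9), drift_phase = runif(1, 0, 2 * pi)
      )
    })
    # Blob centre: the candidate furthest from every tool axis, so the
    # sustained-phase blob is not occluded into a lower class.
    cand <- cbind(runif(8, 0.25 * s, 0.75 * s), runif(8, 0.25 * s, 0.75 * s))
    dmin <- apply(cand, 1, function(p) {
      min(vapply(tools, function(tl) {
        seg_dist(p[1], p[2], tl)
      }, numeric(1)))
    })
    blob <- list(
      cx = cand[which.max(dmin), 1], cy = cand[which.max(dmin), 2],
      angle = runif(1, 0, pi), ecc = runif(1, 1.2, 1.8),
      sat_angle = runif(2, 0, 2 * pi),
      red = runif(1, 0.5, 0.8), green = runif(1, 0.08, 0.22),
      blue = runif(1, 0.08, 0.22)
    )
    tex <- with_seed(scenario$background_texture_seed, {
      list(fx = runif(3, 0.5, 2.5), fy = runif(3, 0.5, 2.5),
           phx = runif(3, 0, 2 * pi), phy = runif(3, 0, 2 * pi),
           amp = runif(3, 0.01, 0.03))
    })
    list(tools = tools, blob = blob, tex = tex)
  })
}

# Distance from point (px, py) to the (undrifted) axis segment of a tool.
seg_dist <- function(px, py, tl) {
  dx <- cos(tl$angle) * tl$len / 2
  dy <- sin(tl$angle) * tl$len / 2
  x0 <- tl$cx - dx; y0 <- tl$cy - dy
  x1 <- tl$cx + dx; y1 <- tl$cy + dy
  vx <- x1 - x0; vy <- y1 - y0
  tt <- ((px - x0) * vx + (py - y0) * vy) / (vx^2 + vy^2)
  tt <- pmin(pmax(tt, 0), 1)
  sqrt((px - (x0 + tt * vx))^2 + (py - (y0 + tt * vy))^2)
}

# Target visible blood area (fraction of frame pixels) at time t.
blood_area_frac <- function(scenario, t, frame_index) {
  s2 <- scenario$size^2
  mn <- scenario$min_blob_frac
  bleed <- scenario$bleed_onset_s
  pre <- scenario$precursor_onset_s
  if (!is.null(bleed) && t >= bleed) {
    return(min(0.15, 1.3 * mn + scenario$blob_growth_rate * (t - bleed) / s2))
  }
  if (!is.null(pre) && t >= pre &&
      (is.null(bleed) || t < bleed)) {
    per <- max(2L, as.integer(round(0.3 * scenario$fps)))
    k <- frame_index - as.integer(round(pre * scenario$fps))
    if (k %% per < 2L) {
      burst <- k %/% per
      return(if (burst %% 4L == 3L) 1.3 * mn else 0.5 * mn)
    }
    return(0)
  }
  0
}

#' Render one synthetic frame
#'
#' Deterministic given `(scenario, t)`: scene layout derives from the
#' scenario seed, per-pixel noise from a per-frame substream. The blood
#' label is recomputed from the *visible* (non-occluded) blob pixel count,
#' so emitted labels always match the rendered content.
#'
#' @param scenario A [scene_scenario()].
#' @param t Time in seconds, within `[0, duration_s]`.
#' @param blood_frac_override Optional explicit target blob-area fraction,
#'   used by the iid training-frame generator; `NULL` follows the
#'   scenario's temporal schedule.
#' @return A `frame_sample` list: `image` (`size x size x 3` in `[0, 1]`),
#'   `tool_mask` (binary matrix), `blood_label` (0/1), `blood_area_px`
#'   (visible blood pixel count, from which the label derives),
#'   `timestamp_s`, `frame_index`.
#' @export
render_frame <- function(scenario, t, blood_frac_override = NULL) {
  stopifnot(inherits(scenario, "scene_scenario"))
  if (t < 0 || t > scenario$duration_s) {
    stop_validation("t = %g outside [0, %g]", t, scenario$duration_s)
  }
  s <- scenario$size
  frame_index <- as.integer(round(t * scenario$fps))
  st <- scene_statics(scenario)

  xs <- matrix(rep(seq_len(s), each = s), nrow = s)   # column coordinate
  ys <- matrix(rep(seq_len(s), times = s), nrow = s)  # row coordinate

  # tissue-toned background; texture modulates luminance only
  base <- c(0.55, 0.42, 0.40)
  lum <- matrix(0, s, s)
  for (i in 1:3) {
    lum <- lum + st$tex$amp[i] *
      sin(2 * pi * st$tex$fx[i] * xs / s + st$tex$phx[i]) *
      sin(2 * pi * st$tex$fy[i] * ys / s + st$tex$phy[i])
  }
  img <- array(0, dim = c(s, s, 3))
  for (ch in 1:3) img[, , ch] <- base[ch] + lum

  # blood blobs: main ellipse plus two satellites, scaled to the target area
  frac <- blood_frac_override %||% blood_area_frac(scenario, t, frame_index)
  blood_mask <- matrix(FALSE, s, s)
  if (frac > 0) {
    bl <- st$blob
    # analytic area of the three disjoint ellipses: pi*a*b*(1 + 2*0.35^2)
    unit <- pi * bl$ecc * (1 + 2 * 0.35^2)
    a1 <- sqrt(frac * s^2 / unit) * bl$ecc
    b1 <- a1 / bl$ecc
    ca <- cos(bl$angle); sa <- sin(bl$angle)
    ell <- function(cx, cy, a, b) {
      u <- (xs - cx) * ca + (ys - cy) * sa
      v <- -(xs - cx) * sa + (ys - cy) * ca
      (u / a)^2 + (v / b)^2 <= 1
    }
    blood_mask <- ell(bl$cx, bl$cy, a1, b1)
    for (k in 1:2) {
      off <- (a1 + 0.35 * a1) * 1.05
      scx <- bl$cx + off * cos(bl$sat_angle[k])
      scy <- bl$cy + off * sin(bl$sat_angle[k])
      blood_mask <- blood_mask | ell(scx, scy, 0.35 * a1, 0.35 * b1)
    }
    img[, , 1][blood_mask] <- bl$red
    img[, , 2][blood_mask] <- bl$green
    img[, , 3][blood_mask] <- bl$blue
  }

  # instruments on top: drifting bright low-saturation capsules
  tool_mask <- matrix(FALSE, s, s)
  for (tl in st$tools) {
    drift <- 0.05 * s * sin(2 * pi * 0.2 * t + tl$drift_phase)
    tl2 <- tl
    tl2$cx <- tl$cx + drift * cos(tl$angle + pi / 2)
    tl2$cy <- tl$cy + drift * sin(tl$angle + pi / 2)
    d <- seg_dist(xs, ys, tl2)
    m <- d <= tl$halfwidth
    tool_mask <- tool_mask | m
    for (ch in 1:3) img[, , ch][m] <- tl$gray + (ch - 2) * 0.015
  }

  visible_blood <- sum(blood_mask & !tool_mask)
  blood_label <- as.integer(visible_blood >= scenario$min_blob_frac * s^2)

  img <- with_seed(derive_seed(scenario$rng_seed, frame_index), {
    img + array(rnorm(length(img), sd = 0.02), dim = dim(img))
  })
  img[img < 0] <- 0
  img[img > 1] <- 1

  structure(list(image = img, tool_mask = tool_mask * 1L,
                 blood_label = blood_label, blood_area_px = visible_blood,
                 timestamp_s = t, frame_index = frame_index),
            class = "frame_sample")
}

#' Generate a full temporal sequence of frames
#'
#' Renders `round(duration_s * fps)` frames. During the precursor window
#' the scene contains intermittent small blobs (sub-threshold in most
#' frames, briefly supra-threshold); from the bleeding onset blobs are
#' persistent and supra-threshold.
#'
#' @param scenario A [scene_scenario()].
#' @return A list with `frames` (list of `frame_sample`) and `onsets`
#'   (list with `precursor_onset_s`, `bleed_onset_s`).
#' @export
generate_sequence <- function(scenario) {
  stopifnot(inherits(scenario, "scene_scenario"))
  n <- as.integer(round(scenario$duration_s * scenario$fps))
  frames <- lapply(seq_len(n) - 1L, function(i) {
    render_frame(scenario, i / scenario$fps)
  })
  list(frames = frames,
       onsets = list(precursor_onset_s = scenario$precursor_onset_s,
                     bleed_onset_s = scenario$bleed_onset_s))
}

#' Generate balanced iid labelled frames for network training
#'
#' Draws independent single-frame scenes: half with a supra-threshold
#' blood blob of random area (label 1), half without blood (label 0).
#' Layout, instruments and noise vary per frame via derived seeds.
#'
#' @param n Total number of frames (balanced across the two classes).
#' @param size Frame size in pixels.
#' @param seed Master seed.
#' @return List of `frame_sample` objects in interleaved class order.
#' @export
make_frame_dataset <- function(n, size = 64, seed = 1L) {
  stopifnot(n >= 2)
  lapply(seq_len(n), function(i) {
    label <- as.integer(i %% 2L == 0L)
    tries <- 0L
    repeat {
      sc <- scene_scenario(duration_s = 1, fps = 25,
                           rng_seed = derive_seed(seed, i + tries * 100003L),
                           background_texture_seed =
                             derive_seed(seed, 7L * i + 13L + tries),
                           size = size)
      frac <- if (label == 1L) {
        with_seed(derive_seed(seed, 3L * i + 1L + tries), runif(1, 0.015, 0.08))
      } else {
        NULL
      }
      fr <- render_frame(sc, 0, blood_frac_override = frac)
      if (fr$blood_label == label) return(fr)
      tries <- tries + 1L
      if (tries > 20L) stop("could not render a frame with the requested class")
    }
  })
}

#' Write a rendered dataset to disk
#'
#' Writes one 8-bit RGB PNG per frame, one single-channel PNG per
#' instrument mask, and a JSON manifest that round-trips losslessly.
#'
#' @param samples List of `frame_sample` objects.
#' @param manifest_path Output path of the JSON manifest.
#' @param image_dir Directory for the PNG files (created if needed).
#' @param fps Frames/second recorded in the manifest.
#' @param precursor_onset_s,bleed_onset_s Ground-truth onsets (or `NULL`).
#' @param seed Seed recorded in the manifest.
#' @return The manifest, invisibly, as a `dataset_manifest` list.
#' @export
write_dataset <- function(samples, manifest_path, image_dir, fps = 25,
                          precursor_onset_s = NULL, bleed_onset_s = NULL,
                          seed = NULL) {
  ok <- dir.exists(image_dir) || dir.create(image_dir, recursive = TRUE,
                                            showWarnings = FALSE)
  if (!ok) stop_io("cannot create image directory: %s", image_dir)
  frames <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    sm <- samples[[i]]
    path <- file.path(image_dir, sprintf("frame_%05d.png", i))
    mask_path <- file.path(image_dir, sprintf("mask_%05d.png", i))
    tryCatch({
      png::writePNG(sm$image, path)
      png::writePNG(sm$tool_mask + 0, mask_path)
    }, error = function(e) stop_io("cannot write PNG: %s", conditionMessage(e)))
    frames[[i]] <- list(path = path, mask_path = mask_path,
                        label = sm$blood_label, t = sm$timestamp_s)
  }
  manifest <- structure(list(
    fps = fps, frames = frames,
    precursor_onset_s = precursor_onset_s, bleed_onset_s = bleed_onset_s,
    seed = seed
  ), class = "dataset_manifest")
  json <- jsonlite::toJSON(unclass(manifest), auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  tryCatch(writeLines(json, manifest_path),
           error = function(e) stop_io("cannot write manifest: %s",
                                       conditionMessage(e)))
  invisible(manifest)
}

#' Read a dataset manifest (and optionally its frames)
#'
#' @param manifest_path Path to a manifest JSON written by
#'   [write_dataset()].
#' @param check_paths Verify that every listed file exists.
#' @return A `dataset_manifest` list.
#' @export
read_manifest <- function(manifest_path, check_paths = TRUE) {
  if (!file.exists(manifest_path)) {
    stop_io("manifest not found: %s", manifest_path)
  }
  m <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  if (check_paths) {
    for (fr in m$frames) {
      if (!file.exists(fr$path)) stop_io("missing frame file: %s", fr$path)
      if (!is.null(fr$mask_path) && !file.exists(fr$mask_path)) {
        stop_io("missing mask file: %s", fr$mask_path)
      }
    }
  }
  structure(m, class = "dataset_manifest")
}

#' Load manifest frames from disk as frame samples
#'
#' @param manifest A `dataset_manifest` (from [read_manifest()]).
#' @return List of `frame_sample` objects with PNG-decoded images.
#' @export
load_frames <- function(manifest) {
  lapply(seq_along(manifest$frames), function(i) {
    fr <- manifest$frames[[i]]
    img <- png::readPNG(fr$path)
    mask <- if (!is.null(fr$mask_path)) round(png::readPNG(fr$mask_path)) else NULL
    structure(list(image = img, tool_mask = mask,
                   blood_label = as.integer(fr$label), timestamp_s = fr$t,
                   frame_index = as.integer(round(fr$t * manifest$fps))),
              class = "frame_sample")
  })
}
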