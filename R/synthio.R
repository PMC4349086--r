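# Parametric synthetic fly renderer.
#
# A fly is modelled in a body-centred coordinate frame: origin at the thorax
# centre, +y pointing posterior (towards the abdomen), x lateral. The body is
# three overlapping ellipses (head, thorax, abdomen); wings are closed
# perturbed-ellipse polygons with four longitudinal veins (L2-L5) drawn from
# the hinge; six legs move between frames; males carry a compact sex comb on
# the foreleg tip. Two channels are rendered per frame:
#   blue  - backlit silhouette: dark fly on bright background, wings
#           semi-transparent with darker outline/veins where off-body;
#   red   - transillumination: bright thorax/head/abdomen (sex-dependent
#           abdominal luminance gradient, ocelli dots, dark compound eyes),
#           wing veins visible as attenuation over the body, dark elsewhere.
# All luminances are 8-bit levels / 255.

LUM <- list(
  blue_bg = 230 / 255, blue_body = 40 / 255, blue_membrane = 200 / 255,
  blue_structure = 120 / 255, blue_leg = 60 / 255,
  red_bg = 70 / 255, red_thorax = 180 / 255, red_head = 200 / 255,
  red_eye = 60 / 255, red_abdomen = 185 / 255, red_leg = 55 / 255,
  red_comb = 10 / 255, ocelli_amp = 70 / 255,
  membrane_atten = 0.07, structure_atten = 0.5
)

# ---------------------------------------------------------------------------
# Canonical wing geometry (unit wing length, hinge at the origin, wing axis
# +u). The outline is an ellipse through (0,0) and (1,0) with low-order
# harmonic radial perturbation; veins are quadratic Beziers from the hinge to
# anchor points on the outline. Vein L3 runs along the axis so that
# wing length == |hinge - outline∩L3| is exactly 1 in canonical units.

canonical_wing <- function(aspect = 0.235,
                           vein_angles = c(L2 = 1.05, L3 = 0, L4 = -0.55,
                                           L5 = -1.25),
                           bumps = c(0, 0)) {
  outline_fun <- function(a) {
    d <- (bumps[1] * sin(a) + bumps[2] * sin(2 * a)) * sin(a)
    cbind(0.5 + 0.5 * cos(a) * (1 + d), aspect * sin(a) * (1 + d))
  }
  anchors <- outline_fun(vein_angles)
  rownames(anchors) <- names(vein_angles)
  vein_fun <- function(k, t) {
    e <- anchors[k, ]
    ctrl <- c(0.5 * e[1], 0.62 * e[2])          # gentle bend towards the axis
    cbind((1 - t)^2 * 0 + 2 * (1 - t) * t * ctrl[1] + t^2 * e[1],
          (1 - t)^2 * 0 + 2 * (1 - t) * t * ctrl[2] + t^2 * e[2])
  }
  list(aspect = aspect, vein_angles = vein_angles, bumps = bumps,
       outline_fun = outline_fun, vein_fun = vein_fun,
       anchors = anchors, hinge = c(0, 0))
}

# Dense point samples of a canonical wing: outline (closed) and veins (open),
# with curve parameters attached.
sample_canonical_wing <- function(wing, n_outline = 192, n_vein = 32) {
  t_out <- seq(0, 1 - 1 / n_outline, length.out = n_outline)
  out <- wing$outline_fun(2 * pi * t_out)
  veins <- lapply(c("L2", "L3", "L4", "L5"), function(k) {
    tv <- seq(0, 1, length.out = n_vein)
    list(pts = wing$vein_fun(k, tv), t = tv)
  })
  names(veins) <- c("L2", "L3", "L4", "L5")
  list(outline = list(pts = out, t = t_out), veins = veins)
}

# Map canonical wing coordinates (u, v) to the body frame for one wing.
# `side` +1 = right (x > 0), -1 = left. `phi` is the sweep-back angle of the
# wing axis from the +y (posterior) body axis, rotated laterally.
wing_to_body <- function(uv, hinge, phi, wl, side) {
  d <- c(sin(phi), cos(phi))       # wing axis direction in body frame (right)
  p <- c(cos(phi), -sin(phi))      # +v direction
  x <- hinge[1] + wl * (uv[, 1] * d[1] + uv[, 2] * p[1])
  y <- hinge[2] + wl * (uv[, 1] * d[2] + uv[, 2] * p[2])
  cbind(side * x, y)
}

# ---------------------------------------------------------------------------

#' Sample a synthetic fly with exact ground truth
#'
#' Draws one fly from the generator's population model: sex-specific overall
#' scale (females larger), independently jittered body-segment ellipses, a
#' wing whose length is drawn from a sex-specific normal distribution
#' (female mean 100 px, male mean 85 px, sd 5 px by default), jittered wing
#' aspect ratio and vein anchor angles, a sex-dependent abdominal luminance
#' gradient, and a sex comb present iff the fly is male.
#'
#' @param seed integer; fixes every random draw (identical seed, identical fly).
#' @param sex `"male"`, `"female"` or `NULL` (coin flip).
#' @param pop population parameters, see [fly_population()].
#' @return an object of class `fly_truth`; see Details.
#' @details Ground-truth trait fields (all in px): `iod_px` (inner eye-edge
#'   separation on the ocelli line), `sw_px` (shoulder width, twice the thorax
#'   ellipse semi-minor axis), `wl_px` (hinge to outline-vein-L3 intersection),
#'   `ww_px` (outline-L2 to outline-L5 intersection), `wa_px2` (shoelace area
#'   of the outline polygon).
#' @export
sample_fly <- function(seed, sex = NULL, pop = fly_population()) {
  with_seed(seed, function() {
    if (is.null(sex)) sex <- if (stats::runif(1) < 0.5) "male" else "female"
    sex <- match.arg(sex, c("male", "female"))
    sp <- if (sex == "male") pop$male else pop$female
    s <- stats::rnorm(1, sp$size, sp$size * 0.04)
    jit <- function(m, cv) m * (1 + stats::rnorm(1, 0, cv))
    thorax <- list(a = jit(30 * s, 0.03), b = jit(22 * s, 0.03))
    head <- list(a = jit(17 * s, 0.03), b = jit(20 * s, 0.03))
    abdomen <- list(a = jit(46 * s, 0.04), b = jit(27 * s, 0.04))
    thorax$cy <- 0
    head$cy <- -(thorax$a + head$a) * 0.89
    abdomen$cy <- (thorax$a + abdomen$a) * 0.76
    iod_frac <- stats::rnorm(1, 0.60, 0.025)
    iod <- iod_frac * 2 * head$b
    ocelli <- list(y = head$cy + 0.55 * head$a, sep = 0.45 * iod,
                   anterior_offset = 6 * s, sigma = 1.4)
    wl <- stats::rnorm(1, sp$wl_mean, sp$wl_sd)
    aspect <- stats::rnorm(1, 0.235, 0.008)
    va <- c(L2 = 1.05, L3 = 0, L4 = -0.55, L5 = -1.25)
    va[c("L2", "L4", "L5")] <- va[c("L2", "L4", "L5")] +
      stats::rnorm(3, 0, 0.03)
    bumps <- stats::rnorm(2, 0, 0.012)
    phi <- (28 + stats::rnorm(1, 0, 2)) * pi / 180
    hinge <- c(0.75 * thorax$b, 0.35 * thorax$a)
    wing_canon <- canonical_wing(aspect, va, bumps)
    samp <- sample_canonical_wing(wing_canon)
    wings <- lapply(c(right = 1, left = -1), function(side) {
      outline <- wing_to_body(samp$outline$pts, hinge, phi, wl, side)
      veins <- lapply(samp$veins, function(v)
        wing_to_body(v$pts, hinge, phi, wl, side))
      anchors <- wing_to_body(wing_canon$anchors, hinge, phi, wl, side)
      rownames(anchors) <- rownames(wing_canon$anchors)
      list(side = side, outline = outline, veins = veins, anchors = anchors,
           hinge = c(side * hinge[1], hinge[2]), phi = phi, wl = wl)
    })
    lum <- if (sex == "male") {
      list(type = "male", band_center = stats::rnorm(1, 0.55, 0.03),
           band_width = 0.06, depth = stats::rnorm(1, 0.55, 0.04))
    } else {
      list(type = "female", ramp = stats::rnorm(1, 0.12, 0.02),
           band_amp = 0.06, band_freq = 3.5)
    }
    comb_radius <- stats::runif(1, 1.5, 2.0)
    w <- wings$right
    truth <- list(
      seed = seed, sex = sex, scale = s,
      head = head, thorax = thorax, abdomen = abdomen,
      iod_px = iod, ocelli = ocelli,
      sw_px = 2 * thorax$b,
      wing = list(aspect = aspect, vein_angles = va, bumps = bumps,
                  phi = phi, hinge = hinge, wl = wl),
      wings = wings,
      wl_px = wl * sqrt(sum((wing_canon$anchors["L3", ] -
                               wing_canon$hinge)^2)),
      ww_px = wl * sqrt(sum((wing_canon$anchors["L2", ] -
                               wing_canon$anchors["L5", ])^2)),
      wa_px2 = shoelace_area(w$outline),
      abdomen_luminance = lum,
      sexcomb_present = sex == "male",
      comb_radius = comb_radius,
      comb_frame_fraction = 0.6,
      leg_phase = child_seed(seed, 7919)
    )
    truth$body_length_px <- (abdomen$cy + abdomen$a) - (head$cy - head$a)
    class(truth) <- "fly_truth"
    truth
  })
}

#' Generator population parameters
#'
#' Means and standard deviations of the trait distributions used by
#' [sample_fly()]. Wing length is in px (female 100 +/- 5, male 85 +/- 5);
#' `size` is the overall body scale factor relative to the canonical female.
#'
#' @param female,male lists with `size`, `wl_mean`, `wl_sd`.
#' @export
fly_population <- function(female = list(size = 1, wl_mean = 100, wl_sd = 5),
                           male = list(size = 0.88, wl_mean = 85, wl_sd = 5)) {
  list(female = female, male = male)
}

#' @export
print.fly_truth <- function(x, ...) {
  cat(sprintf(
    "<fly_truth> sex=%s  IOD=%.1f  SW=%.1f  WL=%.1f  WW=%.1f  WA=%.0f px\n",
    x$sex, x$iod_px, x$sw_px, x$wl_px, x$ww_px, x$wa_px2))
  invisible(x)
}

# Abdominal luminance gradient g(u), u in [0, 1] anterior -> posterior.
abdomen_gradient <- function(lum, u) {
  if (lum$type == "male") {
    1 - lum$depth / (1 + exp(-(u - lum$band_center) / lum$band_width))
  } else {
    1 - lum$ramp * u + lum$band_amp * sin(2 * pi * lum$band_freq * u)
  }
}

# Leg polylines (body frame) for one frame: 3 legs per side, each a 3-point
# polyline anchor -> knee -> tip, tip jittered per frame. `jit` is a 12-vector
# of U(-8, 8) draws.
leg_polylines <- function(truth, jit) {
  s <- truth$scale
  anchors <- rbind(c(0.80, -0.55 * truth$thorax$a / s),
                   c(0.95, 0),
                   c(0.80, 0.50 * truth$thorax$a / s))
  anchors[, 1] <- anchors[, 1] * truth$thorax$b
  anchors[, 2] <- anchors[, 2] * s
  # hind legs stay medial (occluded by the abdomen) so they never cross the
  # wing blades; forelegs reach anterior to the head (sex-comb scan region)
  tips <- rbind(c(28, -78), c(58, 8), c(16, 85)) * s
  knee_out <- c(10, 10, 2) * s
  out <- list()
  idx <- 1
  for (side in c(1, -1)) {
    for (i in 1:3) {
      tip <- tips[i, ] + c(jit[idx], jit[idx + 1])
      idx <- idx + 2
      knee <- (anchors[i, ] + tip) / 2 + c(knee_out[i], 0)
      out[[length(out) + 1]] <- list(
        pts = cbind(side * c(anchors[i, 1], knee[1], tip[1]),
                    c(anchors[i, 2], knee[2], tip[2])),
        is_foreleg = i == 1, side = side, tip = c(side * tip[1], tip[2]))
    }
  }
  out
}

# ---------------------------------------------------------------------------

#' Rendering configuration
#'
#' @param width,height frame size in px (portrait tunnel, default 600 x 1800).
#' @param n_frames number of frames per sequence (>= 1).
#' @param mm_per_px pixel calibration carried into the sequence (> 0).
#' @param noise_sd Gaussian sensor-noise sd in luminance units.
#' @param defocus_frames,defocus_sigma frame indices blurred with a Gaussian
#'   of the given sigma (px), emulating out-of-focus frames.
#' @param border_touch_frames frame indices where the fly is placed against
#'   the image border.
#' @param reflection_frames frame indices with a saturated specular blob on
#'   the right wing in the red channel.
#' @param folded_wing_frames frame indices rendered with the right wing
#'   folded onto the body (breaks bilateral symmetry and the dorsal
#'   wing-exposure check).
#' @param rotation_deg maximum |in-plane body rotation| per frame (uniform).
#' @param jitter_px maximum |translation| of the fly centre per frame.
#' @param seed integer; fixes all randomness, output is bit-reproducible.
#' @return a list of class `render_config`.
#' @export
render_config <- function(width = 600, height = 1800, n_frames = 6,
                          mm_per_px = 0.02, noise_sd = 2 / 255,
                          defocus_frames = integer(0), defocus_sigma = 4,
                          border_touch_frames = integer(0),
                          reflection_frames = integer(0),
                          folded_wing_frames = integer(0),
                          rotation_deg = 3, jitter_px = 15, seed = 1) {
  stopifnot(n_frames >= 1, mm_per_px > 0, width >= 64, height >= 64)
  structure(list(width = width, height = height, n_frames = n_frames,
                 mm_per_px = mm_per_px, noise_sd = noise_sd,
                 defocus_frames = as.integer(defocus_frames),
                 defocus_sigma = defocus_sigma,
                 border_touch_frames = as.integer(border_touch_frames),
                 reflection_frames = as.integer(reflection_frames),
                 folded_wing_frames = as.integer(folded_wing_frames),
                 rotation_deg = rotation_deg, jitter_px = jitter_px,
                 seed = as.integer(seed)),
            class = "render_config")
}

# Smooth background illumination fields (slight vignette).
background_fields <- function(cfg) {
  x <- (seq_len(cfg$width) - (cfg$width + 1) / 2) / (cfg$width / 2)
  y <- (seq_len(cfg$height) - (cfg$height + 1) / 2) / (cfg$height / 2)
  r2 <- outer(y^2, x^2, "+")
  list(blue = LUM$blue_bg * (1 - 0.04 * r2),
       red = LUM$red_bg * (1 - 0.05 * r2))
}

#' Render a two-channel frame sequence for one fly
#'
#' Produces `cfg$n_frames` registered blue/red frame pairs plus a fly-free
#' background pair. The fly's pose (in-plane rotation and translation) and
#' leg placement change between frames; nuisance frames are degraded as
#' configured. Identical `truth` + `cfg` give byte-identical output.
#'
#' @param truth a `fly_truth` from [sample_fly()].
#' @param cfg a [render_config()].
#' @return object of class `frame_sequence`: list with `frames` (each a list
#'   with `blue` and `red` matrices in \[0,1\]), `background` (same
#'   structure), `poses` (per-frame centre and angle actually rendered),
#'   `mm_per_px`, `cfg`.
#' @export
render_sequence <- function(truth, cfg = render_config()) {
  stopifnot(inherits(truth, "fly_truth"), inherits(cfg, "render_config"))
  bg <- background_fields(cfg)
  with_seed(cfg$seed, function() {
    n <- cfg$n_frames
    thetas <- stats::runif(n, -cfg$rotation_deg, cfg$rotation_deg) * pi / 180
    centers <- cbind(
      (cfg$width + 1) / 2 + stats::runif(n, -cfg$jitter_px, cfg$jitter_px),
      (cfg$height + 1) / 2 + stats::runif(n, -cfg$jitter_px, cfg$jitter_px))
    leg_jit <- matrix(stats::runif(n * 12, -8, 8), nrow = n)
    comb_draw <- stats::runif(n)
    ext <- fly_extent(truth)
    # sensor noise and 8-bit quantization are applied inside the composed
    # region; outside it the frame equals the quantized background field
    bgq <- list(blue = quantize8(bg$blue), red = quantize8(bg$red))
    frames <- vector("list", n)
    for (k in seq_len(n)) {
      center <- centers[k, ]
      border <- k %in% cfg$border_touch_frames
      if (border) center[1] <- ext$ex - 18   # push against the left border
      half_w <- abs(cos(thetas[k])) * ext$ex + abs(sin(thetas[k])) * ext$ey
      half_h <- abs(sin(thetas[k])) * ext$ex + abs(cos(thetas[k])) * ext$ey
      if (!border && (center[1] - half_w < 1 || center[1] + half_w > cfg$width ||
                      center[2] - half_h < 1 || center[2] + half_h > cfg$height))
        stop("fly geometry exceeds image bounds in a non-border frame")
      sub <- compose_frame(
        truth, bg, cfg, center = center, theta = thetas[k],
        leg_jit = leg_jit[k, ],
        comb = truth$sexcomb_present && comb_draw[k] < truth$comb_frame_fraction,
        folded = k %in% cfg$folded_wing_frames,
        reflection = k %in% cfg$reflection_frames)
      if (k %in% cfg$defocus_frames) {
        sub$blue <- from_ebimage(EBImage::gblur(as_ebimage(sub$blue),
                                                sigma = cfg$defocus_sigma))
        sub$red <- from_ebimage(EBImage::gblur(as_ebimage(sub$red),
                                               sigma = cfg$defocus_sigma))
      }
      fr <- list(blue = bgq$blue, red = bgq$red)
      fr$blue[sub$ys, sub$xs] <-
        quantize8(sub$blue + stats::rnorm(length(sub$blue), 0, cfg$noise_sd))
      fr$red[sub$ys, sub$xs] <-
        quantize8(sub$red + stats::rnorm(length(sub$red), 0, cfg$noise_sd))
      frames[[k]] <- fr
    }
    background <- list(
      blue = quantize8(bg$blue + stats::rnorm(length(bg$blue), 0, cfg$noise_sd)),
      red = quantize8(bg$red + stats::rnorm(length(bg$red), 0, cfg$noise_sd)))
    structure(list(frames = frames, background = background,
                   poses = list(centers = centers, thetas = thetas),
                   mm_per_px = cfg$mm_per_px, cfg = cfg),
              class = "frame_sequence")
  })
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames, %d x %d px, %.3f mm/px\n",
              length(x$frames), x$cfg$width, x$cfg$height, x$mm_per_px))
  invisible(x)
}

# Half-extent of the fly (body frame, px), wings and legs included.
fly_extent <- function(truth) {
  pts <- rbind(truth$wings$right$outline, truth$wings$left$outline)
  ex <- max(abs(pts[, 1]), 65 * truth$scale) + 14
  ey <- max(abs(pts[, 2]), abs(truth$head$cy - truth$head$a),
            abs(truth$abdomen$cy + truth$abdomen$a), 90 * truth$scale) + 14
  list(ex = ceiling(ex), ey = ceiling(ey))
}

# alpha blend: base towards value with coverage alpha
blend <- function(base, value, alpha) base * (1 - alpha) + value * alpha

# soft-edge alpha for an ellipse at (0, cy) with semi-axes (b across, a along)
ellipse_alpha <- function(xb, yb, cy, a, b) {
  f <- sqrt((xb / b)^2 + ((yb - cy) / a)^2)
  clamp(0.5 - (f - 1) * min(a, b), 0, 1)
}

# soft-edge alpha for a stroked polyline of the given width
stroke_alpha <- function(xb, yb, pts, width) {
  lo <- c(min(pts[, 1]) - width - 2, min(pts[, 2]) - width - 2)
  hi <- c(max(pts[, 1]) + width + 2, max(pts[, 2]) + width + 2)
  sel <- xb >= lo[1] & xb <= hi[1] & yb >= lo[2] & yb <= hi[2]
  a <- numeric(length(xb))
  if (any(sel)) {
    d <- polyline_distance(xb[sel], yb[sel], pts)
    a[sel] <- clamp(width / 2 + 0.5 - d, 0, 1)
  }
  a
}

# soft-edge alpha for a filled closed polygon
polygon_alpha <- function(xb, yb, pts, pad = 2) {
  lo <- c(min(pts[, 1]) - pad, min(pts[, 2]) - pad)
  hi <- c(max(pts[, 1]) + pad, max(pts[, 2]) + pad)
  sel <- xb >= lo[1] & xb <= hi[1] & yb >= lo[2] & yb <= hi[2]
  a <- numeric(length(xb))
  if (any(sel)) {
    ring <- rbind(pts, pts[1, ])
    d <- polyline_distance(xb[sel], yb[sel], ring)
    inside <- point_in_polygon(xb[sel], yb[sel], pts)
    sd <- ifelse(inside, d, -d)
    a[sel] <- clamp(0.5 + sd, 0, 1)
  }
  a
}

disc_alpha <- function(xb, yb, center, radius) {
  d <- sqrt((xb - center[1])^2 + (yb - center[2])^2)
  clamp(radius + 0.5 - d, 0, 1)
}

# Render one frame (both channels, no noise/quantization).
compose_frame <- function(truth, bg, cfg, center, theta, leg_jit,
                          comb = FALSE, folded = FALSE, reflection = FALSE) {
  ext <- fly_extent(truth)
  half_w <- ceiling(abs(cos(theta)) * ext$ex + abs(sin(theta)) * ext$ey)
  half_h <- ceiling(abs(sin(theta)) * ext$ex + abs(cos(theta)) * ext$ey)
  xs <- max(1, floor(center[1] - half_w)):min(cfg$width, ceiling(center[1] + half_w))
  ys <- max(1, floor(center[2] - half_h)):min(cfg$height, ceiling(center[2] + half_h))
  X <- rep(xs, each = length(ys))
  Y <- rep(ys, times = length(xs))
  ct <- cos(theta); st <- sin(theta)
  xb <- ct * (X - center[1]) + st * (Y - center[2])
  yb <- -st * (X - center[1]) + ct * (Y - center[2])

  wings <- truth$wings
  if (folded) {
    # fold the right wing onto the body: steep inward angle, half scale
    w <- truth$wing
    canon <- canonical_wing(w$aspect, w$vein_angles, w$bumps)
    samp <- sample_canonical_wing(canon)
    phi_f <- 6 * pi / 180
    wings$right <- list(
      side = 1,
      outline = wing_to_body(samp$outline$pts, w$hinge, phi_f, w$wl * 0.55, 1),
      veins = lapply(samp$veins, function(v)
        wing_to_body(v$pts, w$hinge, phi_f, w$wl * 0.55, 1)),
      hinge = w$hinge, phi = phi_f, wl = w$wl * 0.55)
  }

  legs <- leg_polylines(truth, leg_jit)

  blue <- bg$blue[ys, xs, drop = FALSE]
  red <- bg$red[ys, xs, drop = FALSE]
  Lb <- as.vector(blue)   # column-major: y fastest, matches X/Y construction
  Lr <- as.vector(red)

  # --- wing membranes and structures (computed once, reused per channel)
  mem_a <- numeric(length(X))
  str_a <- numeric(length(X))
  for (w in wings) {
    # subsampled polygons: chord error ~0.06 px, well under the 1 px
    # soft-edge width
    sub <- w$outline[seq(1, nrow(w$outline), by = 2), , drop = FALSE]
    mem_a <- pmax(mem_a, polygon_alpha(xb, yb, sub))
    str_a <- pmax(str_a, stroke_alpha(xb, yb, rbind(sub, sub[1, ]),
                                      width = 1.8))
    for (v in w$veins) {
      vs <- v[seq(1, nrow(v), by = 2), , drop = FALSE]
      str_a <- pmax(str_a, stroke_alpha(xb, yb, vs, width = 1.8))
    }
  }

  # --- blue channel: wings, legs, then opaque body
  Lb <- blend(Lb, LUM$blue_membrane, mem_a)
  Lb <- blend(Lb, LUM$blue_structure, str_a)
  leg_a <- numeric(length(X))
  for (lg in legs) leg_a <- pmax(leg_a, stroke_alpha(xb, yb, lg$pts, width = 2.2))
  Lb <- blend(Lb, LUM$blue_leg, leg_a)
  head_a <- ellipse_alpha(xb, yb, truth$head$cy, truth$head$a, truth$head$b)
  thor_a <- ellipse_alpha(xb, yb, truth$thorax$cy, truth$thorax$a, truth$thorax$b)
  abd_a <- ellipse_alpha(xb, yb, truth$abdomen$cy, truth$abdomen$a, truth$abdomen$b)
  body_a <- pmax(head_a, thor_a, abd_a)
  Lb <- blend(Lb, LUM$blue_body, body_a)

  # --- red channel
  Lr <- blend(Lr, LUM$red_leg, leg_a)
  if (comb) {
    fore <- legs[[1]]                       # right foreleg carries the comb
    Lr <- blend(Lr, LUM$red_comb, disc_alpha(xb, yb, fore$tip, truth$comb_radius))
  }
  Lr <- blend(Lr, LUM$red_thorax, thor_a)
  u <- clamp((yb - (truth$abdomen$cy - truth$abdomen$a)) /
               (2 * truth$abdomen$a), 0, 1)
  g <- abdomen_gradient(truth$abdomen_luminance, u)
  Lr <- blend(Lr, LUM$red_abdomen * g, abd_a)
  Lr <- blend(Lr, LUM$red_head, head_a)
  eye_a <- head_a * clamp(abs(xb) - truth$iod_px / 2 + 0.5, 0, 1)
  Lr <- blend(Lr, LUM$red_eye, eye_a)
  oc <- truth$ocelli
  dots <- rbind(c(-oc$sep / 2, oc$y), c(oc$sep / 2, oc$y),
                c(0, oc$y - oc$anterior_offset))
  for (i in 1:3) {
    r2 <- (xb - dots[i, 1])^2 + (yb - dots[i, 2])^2
    Lr <- Lr + head_a * LUM$ocelli_amp * exp(-r2 / (2 * oc$sigma^2))
  }
  Lr <- pmin(Lr, 0.98)
  # wings over the body: membrane and veins attenuate transmitted light
  Lr <- Lr * (1 - LUM$membrane_atten * mem_a)
  Lr <- Lr * (1 - LUM$structure_atten * str_a)
  if (reflection) {
    w <- wings$right
    spot <- w$hinge + w$wl * 0.55 * c(sin(w$phi), cos(w$phi)) +
      w$wl * 0.12 * c(cos(w$phi), -sin(w$phi))
    spot[1] <- abs(spot[1])
    Lr <- blend(Lr, 1, disc_alpha(xb, yb, spot, 4))
  }

  list(blue = matrix(Lb, nrow = length(ys)),
       red = matrix(Lr, nrow = length(ys)),
       ys = ys, xs = xs)
}

# ---------------------------------------------------------------------------

#' Render a population of synthetic flies
#'
#' @param n number of flies (>= 1).
#' @param seed master seed; per-fly seeds are derived deterministically.
#' @param cfg a [render_config()]; its `seed` field is re-derived per fly.
#' @param sex `"mixed"` (default), `"male"` or `"female"`.
#' @param out_dir if non-`NULL`, writes one multi-page TIFF per fly plus a
#'   `truth.csv` ground-truth table into this directory; sequences are then
#'   streamed to disk one at a time instead of being kept in memory (a full
#'   two-channel sequence is large).
#' @return list with `sequences` (list of `frame_sequence`, or `NULL` when
#'   streaming to `out_dir`), `truths` (list of `fly_truth`) and `truth`
#'   (the ground-truth `data.frame`).
#' @export
render_population <- function(n, seed, cfg = render_config(), sex = "mixed",
                              out_dir = NULL) {
  stopifnot(n >= 1)
  sex <- match.arg(sex, c("mixed", "male", "female"))
  keep <- is.null(out_dir)
  if (!keep) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sequences <- if (keep) vector("list", n) else NULL
  truths <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    truth <- sample_fly(child_seed(seed, i),
                        sex = if (sex == "mixed") NULL else sex)
    cfg_i <- cfg
    cfg_i$seed <- child_seed(seed, 100000 + i)
    sq <- render_sequence(truth, cfg_i)
    if (keep) {
      sequences[[i]] <- sq
    } else {
      write_sequence(sq, file.path(out_dir, sprintf("fly_%03d.tif", i)))
      rm(sq)
    }
    truths[[i]] <- truth
    rows[[i]] <- truth_row(truth, fly_id = i)
  }
  truth_df <- do.call(rbind, rows)
  if (!keep) {
    utils::write.csv(truth_df, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  list(sequences = sequences, truths = truths, truth = truth_df)
}

truth_row <- function(truth, fly_id) {
  data.frame(fly_id = fly_id, sex = truth$sex,
             iod_px = truth$iod_px, sw_px = truth$sw_px,
             wl_px = truth$wl_px, ww_px = truth$ww_px, wa_px2 = truth$wa_px2,
             body_length_px = truth$body_length_px,
             sexcomb_present = truth$sexcomb_present,
             seed = truth$seed)
}
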