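# Shared low-level helpers: image containers are plain numeric matrices
# [row = y, col = x] with luminance in [0, 1] and pixel centers at integer
# coordinates (x = column index, y = row index).

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Quantize an image to 8-bit levels
#'
#' Rounds luminance to the 256 representable 8-bit levels. The renderer
#' quantizes every frame so that in-memory sequences are bit-identical to
#' sequences round-tripped through 8-bit TIFF/PNG files.
#'
#' @param img numeric matrix in \[0, 1\].
#' @return matrix with values on the grid k/255.
#' @export
quantize8 <- function(img) {
  round(clamp(img, 0, 1) * 255) / 255
}

# Evaluate f() under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, f) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  f()
}

# Derive a child seed from a parent seed and a stream index (kept < 2^31).
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2654435761 + k * 97) %% 2147483647)
}

# Bilinear sampling of img at real-valued coordinates (x, y); out-of-range
# samples return `fill`.
bilinear_sample <- function(img, x, y, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;  fy <- y - y0
  ok <- x0 >= 1 & x0 <= nc - 1 & y0 >= 1 & y0 <= nr - 1
  out <- rep(fill, length(x))
  if (any(ok)) {
    x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    i00 <- (x0k - 1) * nr + y0k
    v <- img[i00]       * (1 - fxk) * (1 - fyk) +
         img[i00 + nr]  * fxk       * (1 - fyk) +
         img[i00 + 1]   * (1 - fxk) * fyk +
         img[i00 + nr + 1] * fxk    * fyk
    out[ok] <- v
  }
  out
}

# Rigid warp: output pixel (x, y) takes the value of the input image at
# R(theta) * (p - out_center) + in_center, i.e. the output shows the input
# translated so that `in_center` lands on `out_center` and rotated by -theta
# about it. Used to align frames (rotate major axis to vertical).
warp_rigid <- function(img, theta, in_center, out_center = NULL, fill = 1) {
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(out_center)) out_center <- c((nc + 1) / 2, (nr + 1) / 2)
  xs <- rep(seq_len(nc), each = nr)
  ys <- rep(seq_len(nr), times = nc)
  dx <- xs - out_center[1]; dy <- ys - out_center[2]
  ct <- cos(theta); st <- sin(theta)
  xi <- ct * dx - st * dy + in_center[1]
  yi <- st * dx + ct * dy + in_center[2]
  matrix(bilinear_sample(img, xi, yi, fill = fill), nrow = nr, ncol = nc)
}

# Weighted image moments of a non-negative mass matrix.
# Returns centroid (x, y), orientation of the major axis (radians,
# angle from the +y image axis, in (-pi/2, pi/2]) and central moments.
mass_moments <- function(w) {
  m00 <- sum(w)
  if (m00 <= 0) return(NULL)
  nr <- nrow(w); nc <- ncol(w)
  cs <- colSums(w); rs <- rowSums(w)
  cx <- sum(cs * seq_len(nc)) / m00
  cy <- sum(rs * seq_len(nr)) / m00
  x <- rep(seq_len(nc), each = nr) - cx
  y <- rep(seq_len(nr), times = nc) - cy
  wv <- as.vector(w)
  mu20 <- sum(wv * x * x) / m00
  mu02 <- sum(wv * y * y) / m00
  mu11 <- sum(wv * x * y) / m00
  # major-axis angle relative to the +y (vertical) axis, in (-pi/2, pi/2]
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2), symmetric = TRUE)
  v <- ev$vectors[, 1]                      # major-axis direction (x, y)
  theta <- atan2(v[1], v[2])                # angle from +y axis
  if (theta > pi / 2) theta <- theta - pi
  if (theta <= -pi / 2) theta <- theta + pi
  list(m00 = m00, centroid = c(cx, cy), theta = theta,
       mu20 = mu20, mu02 = mu02, mu11 = mu11)
}

# Variance of the 4-neighbour Laplacian over a region of interest.
laplacian_variance <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3 || nc < 3) return(0)
  c0 <- img[2:(nr - 1), 2:(nc - 1)]
  lap <- img[1:(nr - 2), 2:(nc - 1)] + img[3:nr, 2:(nc - 1)] +
         img[2:(nr - 1), 1:(nc - 2)] + img[2:(nr - 1), 3:nc] - 4 * c0
  stats::var(as.vector(lap))
}

# Distance from points (x, y) to segment p1-p2 (each p a length-2 vector).
segment_distance <- function(x, y, p1, p2) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  l2 <- vx * vx + vy * vy
  if (l2 < 1e-12) return(sqrt((x - p1[1])^2 + (y - p1[2])^2))
  t <- clamp(((x - p1[1]) * vx + (y - p1[2]) * vy) / l2, 0, 1)
  sqrt((x - p1[1] - t * vx)^2 + (y - p1[2] - t * vy)^2)
}

# Minimum distance from points (x, y) to a polyline given as an n x 2 matrix.
polyline_distance <- function(x, y, pts) {
  d <- rep(Inf, length(x))
  for (i in seq_len(nrow(pts) - 1)) {
    d <- pmin(d, segment_distance(x, y, pts[i, ], pts[i + 1, ]))
  }
  d
}

# Even-odd point-in-polygon test, vectorized over query points.
point_in_polygon <- function(x, y, pts) {
  n <- nrow(pts)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- pts[i, 1]; yi <- pts[i, 2]
    xj <- pts[j, 1]; yj <- pts[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Shoelace area of a closed polygon (n x 2, not necessarily repeated first row).
shoelace_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Nearest-neighbour lookup: for each row of `query`, index of nearest row of
# `ref`, by brute force (point sets here are a few hundred points).
nearest_index <- function(query, ref) {
  d2 <- outer(query[, 1], ref[, 1], "-")^2 + outer(query[, 2], ref[, 2], "-")^2
  max.col(-d2, ties.method = "first")
}

# Region properties from a label matrix: area, centroid, second-moment
# ellipse (semi-axes, orientation) and eccentricity per label.
region_props <- function(labels) {
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids > 0]
  out <- lapply(ids, function(id) {
    w <- labels == id
    mm <- mass_moments(w * 1)
    ev <- eigen(matrix(c(mm$mu20, mm$mu11, mm$mu11, mm$mu02), 2),
                symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    semi_major <- 2 * sqrt(lam[1])
    semi_minor <- 2 * sqrt(lam[2])
    ecc <- if (lam[1] > 0) sqrt(1 - lam[2] / lam[1]) else 0
    list(id = id, area = mm$m00, centroid = mm$centroid,
         semi_major = semi_major, semi_minor = semi_minor,
         theta = mm$theta, eccentricity = ecc)
  })
  names(out) <- as.character(ids)
  out
}

# Convert between plain [y, x] matrices and EBImage's [x, y] Image layout.
as_ebimage <- function(m) EBImage::Image(t(m))
from_ebimage <- function(im) t(EBImage::imageData(im))
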