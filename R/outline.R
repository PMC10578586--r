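# Images are numeric matrices img[y, x] with intensities in [0, 1].

otsu_threshold <- function(vals) {
  vals <- vals[is.finite(vals)]
  EBImage::otsu(EBImage::Image(matrix(vals, ncol = 1)), range = range(0, 1))
}

# contour polygons of a matrix at a level, in (x, y) pixel coordinates
contour_polygons <- function(m, level) {
  cl <- suppressWarnings(
    grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                            z = m, levels = level))
  lapply(cl, function(ct) data.frame(x = ct$y, y = ct$x))
}

shoelace_area <- function(p) {
  x <- p$x; y <- p$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(p) {
  dx <- diff(c(p$x, p$x[1])); dy <- diff(c(p$y, p$y[1]))
  sum(sqrt(dx^2 + dy^2))
}

# algebraic (Kasa) least-squares circle fit
fit_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- stats::lm.fit(A, b)$coefficients
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(sol[3] + cx^2 + cy^2)
  resid <- sqrt(mean((sqrt((x - cx)^2 + (y - cy)^2) - r)^2))
  list(cx = unname(cx), cy = unname(cy), r = unname(r), residual = resid)
}

#' Detect the Petri dish in a grayscale image
#'
#' Otsu threshold, morphological closing, largest connected component,
#' circularity gate, and a least-squares circle fit to the component
#' boundary.
#'
#' @param img numeric matrix `img[y, x]`, intensities in `[0, 1]`.
#' @param min_area_frac minimal dish area as a fraction of the frame.
#' @param circularity_min minimal `4*pi*A/P^2` of the component boundary.
#' @param close_size diameter (px) of the closing brush.
#' @return list of class `dish_circle`: `cx`, `cy`, `radius`, `residual`,
#'   `truncated` (TRUE when the boundary touches the frame, raising the
#'   residual flag).
#' @export
detect_dish <- function(img, min_area_frac = 0.25, circularity_min = 0.8,
                        close_size = 5) {
  if (any(dim(img) < 64)) stop("image must be at least 64 x 64")
  component_of <- function(thr) {
    mask <- EBImage::Image(img > thr)
    mask <- EBImage::closing(mask, EBImage::makeBrush(close_size, "disc"))
    lab <- EBImage::bwlabel(mask)
    tab <- tabulate(as.integer(lab))
    if (length(tab) == 0) return(NULL)
    list(comp = as.matrix(lab) == which.max(tab), area = max(tab))
  }
  thr <- otsu_threshold(as.vector(img))
  cand <- component_of(thr)
  if (is.null(cand) || cand$area < min_area_frac * length(img)) {
    # a bright colony can dominate the first Otsu split; re-threshold the
    # darker pixels to separate the dish from the background instead
    lower <- img[img <= thr]
    if (length(unique(lower)) > 1) {
      cand <- component_of(otsu_threshold(lower))
    }
  }
  if (is.null(cand) || cand$area < min_area_frac * length(img))
    stop("dish not found")
  polys <- contour_polygons(cand$comp * 1, 0.5)
  if (length(polys) == 0) stop("dish not found")
  areas <- vapply(polys, function(p) abs(shoelace_area(p)), 0)
  p <- polys[[which.max(areas)]]
  A <- max(areas); P <- polygon_perimeter(p)
  truncated <- any(p$x < 3 | p$y < 3 |
                     p$x > ncol(img) - 2 | p$y > nrow(img) - 2)
  if (!truncated && 4 * pi * A / P^2 < circularity_min)
    stop("dish not found")
  fit <- fit_circle(p$x, p$y)
  if (fit$cx < 1 || fit$cx > ncol(img) || fit$cy < 1 || fit$cy > nrow(img))
    stop("dish not found")
  structure(list(cx = fit$cx, cy = fit$cy, radius = fit$r,
                 residual = fit$residual, truncated = truncated),
            class = "dish_circle")
}

resample_closed <- function(p, n_points) {
  x <- c(p$x, p$x[1]); y <- c(p$y, p$y[1])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  keep <- c(TRUE, seg > 1e-9)           # drop zero-length segments
  x <- x[keep]; y <- y[keep]
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  tgt <- seq(0, s[length(s)], length.out = n_points + 1)[-(n_points + 1)]
  data.frame(x = stats::approx(s, x, tgt)$y,
             y = stats::approx(s, y, tgt)$y)
}

#' Segment the colony within the dish
#'
#' Otsu threshold restricted to the dish interior (minus a margin), largest
#' connected component, marching-squares contour at the threshold level,
#' resampled to equally spaced points.
#'
#' @param img image matrix.
#' @param dish a [detect_dish()] result.
#' @param margin_frac fraction of the dish radius excluded at the rim.
#' @param n_points number of outline points (default 360).
#' @return object of class `outline`: data.frame `points` (x, y), per-point
#'   `shift` (0) and `converged` (NA), plus the segmentation threshold.
#' @export
segment_colony <- function(img, dish, margin_frac = 0.12, n_points = 360) {
  yy <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  xx <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  interior <- sqrt((xx - dish$cx)^2 + (yy - dish$cy)^2) <
    dish$radius * (1 - margin_frac)
  vals <- img[interior]
  if (diff(range(vals)) < 0.02) stop("colony not found")
  thr <- otsu_threshold(vals)
  mask <- interior & img > thr
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  tab <- tabulate(as.integer(lab))
  if (length(tab) == 0 || max(tab) < 16) stop("colony not found")
  if (sum(tab > 16) > 1)
    message(sprintf("segment_colony: %d candidate components, keeping the largest",
                    sum(tab > 16)))
  comp <- as.matrix(lab) == which.max(tab)
  # subpixel contour at the threshold level, restricted to the component
  zm <- img
  grown <- EBImage::dilate(EBImage::Image(comp), EBImage::makeBrush(5, "disc"))
  zm[!(as.matrix(grown) > 0)] <- min(img)
  polys <- contour_polygons(zm, thr)
  if (length(polys) == 0) stop("colony not found")
  areas <- vapply(polys, function(p) abs(shoelace_area(p)), 0)
  p <- resample_closed(polys[[which.max(areas)]], n_points)
  structure(list(points = p,
                 shift = rep(0, n_points),
                 converged = rep(NA, n_points),
                 threshold = thr),
            class = "outline")
}

#' Fit a sigmoid to an intensity profile
#'
#' Least-squares fit of `I(x) = a + b / (1 + exp(-(x - x0)/s))`. The
#' inflection `x0` is initialized at the position of maximal absolute
#' finite-difference gradient, `b` with the gradient's sign. Never throws:
#' non-convergence (or an unidentifiable profile) is reported via the
#' `converged` flag.
#'
#' @param profile sampled intensities (>= 7 values).
#' @param x sample positions (default signed index centered on the profile).
#' @return list of class `sigmoid_fit`: `a`, `b`, `x0`, `s`, `converged`,
#'   `residual`.
#' @export
fit_sigmoid <- function(profile, x = NULL) {
  n <- length(profile)
  if (n < 7) stop("need >= 7 profile samples")
  if (is.null(x)) x <- seq_along(profile) - (n + 1) / 2
  fail <- list(a = NA_real_, b = NA_real_, x0 = NA_real_, s = NA_real_,
               converged = FALSE, residual = NA_real_)
  class(fail) <- "sigmoid_fit"
  if (anyNA(profile) || stats::sd(profile) == 0) return(fail)
  grad <- diff(profile)
  i0 <- which.max(abs(grad))
  start <- list(a = min(profile),
                b = (max(profile) - min(profile)) * sign(grad[i0]),
                x0 = (x[i0] + x[i0 + 1]) / 2,
                s = (max(x) - min(x)) / 4)
  if (start$b < 0) start$a <- max(profile)
  dat <- data.frame(x = x, I = profile)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ a + b / (1 + exp(-(x - x0) / s)), data = dat,
                      start = start,
                      lower = c(-Inf, -Inf, min(x) - diff(range(x)),
                                1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  co <- stats::coef(fit)
  structure(list(a = co[["a"]], b = co[["b"]], x0 = co[["x0"]],
                 s = co[["s"]],
                 converged = fit$convInfo$isConv && co[["s"]] > 0,
                 residual = sqrt(mean(stats::resid(fit)^2))),
            class = "sigmoid_fit")
}

bilinear_sample <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  x <- pmin(pmax(x, 1), W); y <- pmin(pmax(y, 1), H)
  x0 <- pmin(floor(x), W - 1); y0 <- pmin(floor(y), H - 1)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
}

moving_median_circular <- function(v, window) {
  if (window <= 1) return(v)
  n <- length(v); half <- window %/% 2
  idx <- outer(seq_len(n), -half:half, "+")
  idx <- ((idx - 1) %% n) + 1
  apply(matrix(v[idx], n), 1, stats::median)
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_self_intersections <- function(p) {
  n <- nrow(p)
  P <- as.matrix(p)
  bad <- integer(0)
  for (i in seq_len(n)) {
    i2 <- i %% n + 1
    for (j in seq_len(n)) {
      if (j <= i + 1) next
      j2 <- j %% n + 1
      if (j2 == i) next
      if (segments_intersect(P[i, ], P[i2, ], P[j, ], P[j2, ]))
        bad <- c(bad, i, i2, j, j2)
    }
  }
  unique(bad)
}

#' Refine a colony outline to sigmoid inflection points
#'
#' For every outline point, intensities are sampled by bilinear interpolation
#' along the outward normal, a sigmoid is fitted, and the point is shifted to
#' the fitted inflection position when the fit converged and the shift is
#' within bounds. Shifts are optionally smoothed by a circular moving median,
#' and any point whose shift would make the polygon self-intersecting is
#' reverted.
#'
#' @param img image matrix.
#' @param outline a [segment_colony()] outline.
#' @param L profile half-length (px, >= 3).
#' @param max_shift maximal accepted |shift| (px).
#' @param step sampling step along the normal (px).
#' @param smooth_window circular moving-median window for shifts (default 5;
#'   1 disables smoothing).
#' @return refined `outline` with per-point `shift` and `converged` flags.
#' @export
refine_outline <- function(img, outline, L = 10, max_shift = 8, step = 0.5,
                           smooth_window = 5) {
  if (L < 3) stop("profile half-length L must be >= 3")
  p <- outline$points
  n <- nrow(p)
  cx <- mean(p$x); cy <- mean(p$y)
  ts <- seq(-L, L, by = step)
  shift <- numeric(n); conv <- logical(n)
  for (i in seq_len(n)) {
    prv <- p[if (i == 1) n else i - 1, ]
    nxt <- p[if (i == n) 1 else i + 1, ]
    tx <- nxt$x - prv$x; ty <- nxt$y - prv$y
    nrm <- c(ty, -tx)
    len <- sqrt(sum(nrm^2))
    if (len == 0) next
    nrm <- nrm / len
    if (sum(nrm * c(p$x[i] - cx, p$y[i] - cy)) < 0) nrm <- -nrm
    vals <- bilinear_sample(img, p$x[i] + ts * nrm[1], p$y[i] + ts * nrm[2])
    fit <- fit_sigmoid(vals, x = ts)
    if (isTRUE(fit$converged) && is.finite(fit$x0) &&
        abs(fit$x0) <= max_shift && abs(fit$x0) <= L) {
      shift[i] <- fit$x0
      conv[i] <- TRUE
    }
  }
  shift_s <- moving_median_circular(shift, smooth_window)
  shift_s[!conv] <- 0
  normals <- t(vapply(seq_len(n), function(i) {
    prv <- p[if (i == 1) n else i - 1, ]
    nxt <- p[if (i == n) 1 else i + 1, ]
    nrm <- c(nxt$y - prv$y, -(nxt$x - prv$x))
    len <- sqrt(sum(nrm^2)); if (len == 0) return(c(0, 0))
    nrm <- nrm / len
    if (sum(nrm * c(p$x[i] - cx, p$y[i] - cy)) < 0) nrm <- -nrm
    nrm
  }, numeric(2)))
  q <- data.frame(x = p$x + shift_s * normals[, 1],
                  y = p$y + shift_s * normals[, 2])
  for (tries in 1:10) {
    bad <- polygon_self_intersections(q)
    if (length(bad) == 0) break
    shift_s[bad] <- 0; conv[bad] <- FALSE
    q <- data.frame(x = p$x + shift_s * normals[, 1],
                    y = p$y + shift_s * normals[, 2])
  }
  structure(list(points = q, shift = shift_s, converged = conv,
                 threshold = outline$threshold),
            class = "outline")
}

#' Radius of a closed outline
#'
#' @param outline an `outline` (or data.frame of x, y points).
#' @param pixel_size_mm optional pixel size; when given, radii are also
#'   returned in mm.
#' @return list: `radius_px` (equivalent-area radius, `sqrt(A/pi)` with
#'   shoelace area), `centroid_radius_px` (mean centroid distance), and the
#'   mm equivalents when the pixel size is known.
#' @export
outline_radius <- function(outline, pixel_size_mm = NULL) {
  p <- if (inherits(outline, "outline")) outline$points else outline
  A <- abs(shoelace_area(p))
  if (A == 0) stop("degenerate polygon with zero area")
  r_eq <- sqrt(A / pi)
  cr <- mean(sqrt((p$x - mean(p$x))^2 + (p$y - mean(p$y))^2))
  out <- list(radius_px = r_eq, centroid_radius_px = cr)
  if (!is.null(pixel_size_mm)) {
    out$radius_mm <- r_eq * pixel_size_mm
    out$centroid_radius_mm <- cr * pixel_size_mm
  }
  out
}

read_gray_image <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Process a colony image time series
#'
#' Runs dish detection, colony segmentation, sigmoid refinement and radius
#' measurement on every image of a series; per-image failures are recorded
#' and do not stop the series. Manual corrections, if provided, replace
#' individual outline points after refinement.
#'
#' @param manifest data.frame with columns `path`, `time_h` and optionally
#'   `pixel_size_mm` (must be consistent across the series).
#' @param images optional list of in-memory image matrices overriding
#'   `manifest$path`.
#' @param corrections optional data.frame (`image`, `point_index`, `x`, `y`)
#'   of manual point edits keyed by image row number.
#' @param L,max_shift,smooth_window refinement parameters; see
#'   [refine_outline()].
#' @return data.frame: `time_h`, `radius_px`, `radius_mm` (NA without pixel
#'   size), `ok`, `note`; refined outlines attached as attribute `outlines`.
#' @export
process_series <- function(manifest, images = NULL, corrections = NULL,
                           L = 10, max_shift = 8, smooth_window = 5) {
  if (nrow(manifest) == 0)
    return(data.frame(time_h = numeric(0), radius_px = numeric(0),
                      radius_mm = numeric(0), ok = logical(0),
                      note = character(0)))
  px <- if ("pixel_size_mm" %in% names(manifest)) manifest$pixel_size_mm else
    rep(NA_real_, nrow(manifest))
  if (length(unique(stats::na.omit(px))) > 1)
    stop("inconsistent pixel size across series")
  outlines <- vector("list", nrow(manifest))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    res <- tryCatch({
      img <- if (!is.null(images)) images[[i]] else
        read_gray_image(manifest$path[i])
      dish <- detect_dish(img)
      ol <- segment_colony(img, dish)
      ol <- refine_outline(img, ol, L = L, max_shift = max_shift,
                           smooth_window = smooth_window)
      if (!is.null(corrections)) {
        cr <- corrections[corrections$image == i, , drop = FALSE]
        if (nrow(cr)) {
          ol$points$x[cr$point_index] <- cr$x
          ol$points$y[cr$point_index] <- cr$y
        }
      }
      outlines[[i]] <<- ol
      r <- outline_radius(ol, pixel_size_mm = if (is.na(px[i])) NULL else px[i])
      data.frame(time_h = manifest$time_h[i], radius_px = r$radius_px,
                 radius_mm = if (is.na(px[i])) NA_real_ else r$radius_mm,
                 ok = TRUE, note = "")
    }, error = function(e)
      data.frame(time_h = manifest$time_h[i], radius_px = NA_real_,
                 radius_mm = NA_real_, ok = FALSE,
                 note = conditionMessage(e)))
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "outlines") <- outlines
  out
}
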