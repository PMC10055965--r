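# Organelle quantification: connected-component segmentation and counting
# (mitochondria over time) and circular Hough detection with radius
# histograms (lipid droplets).

# 8-connected component labeling by breadth-first flood fill, vectorized one
# frontier wave at a time. (The installed labelers are 4-connected.)
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  todo <- which(mask)
  nextlab <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in todo) {
    if (labels[start] != 0L) next
    nextlab <- nextlab + 1L
    labels[start] <- nextlab
    frontier <- start
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nbr <- integer(0)
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs$dr[k]; cc <- c + offs$dc[k]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (any(ok)) nbr <- c(nbr, (cc[ok] - 1L) * nr + rr[ok])
      }
      nbr <- unique(nbr)
      nbr <- nbr[mask[nbr] & labels[nbr] == 0L]
      labels[nbr] <- nextlab
      frontier <- nbr
    }
  }
  labels
}

#' Segment bright objects by thresholding and 8-connected labeling
#'
#' Contrast-stretches the image to \[0, 1\], thresholds (Otsu by default),
#' removes components smaller than `min_area`, and labels the remaining
#' 8-connected components consecutively from 1. An all-background result is
#' valid (count 0), not an error.
#'
#' @param image Numeric matrix, or an [sr_image()].
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold Threshold on the stretched \[0, 1\] scale when
#'   `threshold_method = "fixed"`.
#' @param min_area Minimum component area in pixels (default 9).
#' @return An object of class `label_map`: `labels` (integer matrix,
#'   0 = background), `count`, and `areas` (pixels per object, a tibble).
#' @export
segment_objects <- function(image, threshold_method = c("otsu", "fixed"),
                            threshold = 0.5, min_area = 9) {
  if (inherits(image, "sr_image")) image <- image$pixels
  stopifnot(is.matrix(image), length(image) > 0)
  threshold_method <- match.arg(threshold_method)
  rng <- range(image)
  stretched <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  thr <- if (threshold_method == "otsu") {
    if (diff(rng) > 0)
      EBImage::otsu(EBImage::Image(stretched), range = c(0, 1))
    else Inf  # constant image: nothing to segment
  } else threshold
  mask <- stretched > thr
  labels <- label_components8(mask)
  if (max(labels) > 0) {
    areas <- tabulate(labels[labels > 0L], nbins = max(labels))
    keep <- which(areas >= min_area)
    relab <- integer(max(labels))
    relab[keep] <- seq_along(keep)
    labels[labels > 0L] <- relab[labels[labels > 0L]]
    areas <- areas[keep]
  } else {
    areas <- integer(0)
  }
  structure(
    list(labels = labels, count = length(areas),
         areas = tibble::tibble(label = seq_along(areas),
                                area_px = as.integer(areas))),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d object(s) in %d x %d\n", x$count,
              nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Per-frame object counts of an image sequence
#'
#' Runs [segment_objects()] on each frame and reports the count sequence and
#' its successive absolute differences — the change signal used to compare
#' fission/fusion activity between conditions.
#'
#' @param frames List of numeric matrices (>= 1 frame).
#' @param ... Passed to [segment_objects()].
#' @return A tibble with `frame`, `count` and `change` (absolute successive
#'   difference, `NA` for the first frame).
#' @export
count_timeseries <- function(frames, ...) {
  stopifnot(is.list(frames), length(frames) >= 1)
  counts <- vapply(frames, function(f) segment_objects(f, ...)$count,
                   integer(1))
  tibble::tibble(frame = seq_along(counts), count = counts,
                 change = c(NA_integer_, abs(diff(counts))))
}

#' Detect circular objects by gradient Hough voting
#'
#' Edge pixels (gradient magnitude above a fraction of its maximum) vote
#' along their gradient direction, both ways, at each candidate radius; the
#' per-radius accumulators are lightly smoothed, normalized by circumference,
#' and peaks above `sensitivity` are kept after non-maximum suppression.
#' Radii are then refined as the median distance of supporting edge pixels
#' to the detected center, and reported in nm.
#'
#' @param image Numeric matrix, or an [sr_image()].
#' @param r_min,r_max Radius search range in nm (`r_min < r_max`, both
#'   representable at the pixel size: `r_min >= 2` pixels).
#' @param pixel_size Pixel size in nm (taken from an `sr_image` when
#'   omitted).
#' @param sensitivity Detection threshold in (0, 1\]: the minimum fraction of
#'   circumference support. Default 0.3.
#' @param edge_frac Gradient-magnitude threshold as a fraction of the
#'   maximum. Default 0.2.
#' @return A tibble (class `droplet_set`) with `row`, `col` (center, pixels),
#'   `radius_nm`, `score` (circumference support) and `coverage` (fraction of
#'   angular sectors with edge support), strongest first.
#' @export
detect_circles <- function(image, r_min, r_max, pixel_size = NULL,
                           sensitivity = 0.3, edge_frac = 0.2) {
  if (inherits(image, "sr_image")) {
    if (is.null(pixel_size)) pixel_size <- image$pixel_size
    image <- image$pixels
  }
  if (is.null(pixel_size)) pixel_size <- 1
  if (!is.finite(r_min) || !is.finite(r_max) || r_min <= 0 ||
      r_min >= r_max)
    stop("invalid radius range: need 0 < r_min < r_max", call. = FALSE)
  rmin_px <- r_min / pixel_size
  rmax_px <- r_max / pixel_size
  if (rmin_px < 2)
    stop("r_min is not representable at this pixel size (< 2 pixels)",
         call. = FALSE)
  nr <- nrow(image); nc <- ncol(image)
  rng <- range(image)
  img <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0

  gy <- img * 0; gx <- img * 0
  gy[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  gx[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  mag <- sqrt(gy^2 + gx^2)
  if (max(mag) == 0)
    return(empty_droplets())
  edges <- which(mag > edge_frac * max(mag))
  er <- (edges - 1L) %% nr + 1L
  ec <- (edges - 1L) %/% nr + 1L
  uy <- gy[edges] / mag[edges]
  ux <- gx[edges] / mag[edges]

  radii_px <- seq(rmin_px, rmax_px, by = 0.5)
  cand <- list()
  box3 <- function(a) {  # 3x3 box smoothing to absorb vote rounding
    p <- rbind(a[1, ], a, a[nr, ])
    p <- cbind(p[, 1], p, p[, nc])
    (p[1:nr, 1:nc] + p[1:nr, 2:(nc + 1)] + p[1:nr, 3:(nc + 2)] +
       p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 2:(nc + 1)] +
       p[2:(nr + 1), 3:(nc + 2)] + p[3:(nr + 2), 1:nc] +
       p[3:(nr + 2), 2:(nc + 1)] + p[3:(nr + 2), 3:(nc + 2)]) / 9
  }
  for (r in radii_px) {
    vr <- round(c(er + r * uy, er - r * uy))
    vc <- round(c(ec + r * ux, ec - r * ux))
    ok <- vr >= 1 & vr <= nr & vc >= 1 & vc <= nc
    acc <- matrix(tabulate((vc[ok] - 1L) * nr + vr[ok], nbins = nr * nc),
                  nr, nc)
    acc <- box3(acc) * 9 / (2 * pi * r)   # circumference-normalized support
    hits <- which(acc > sensitivity)
    if (length(hits))
      cand[[length(cand) + 1]] <- data.frame(
        row = (hits - 1L) %% nr + 1L, col = (hits - 1L) %/% nr + 1L,
        r_px = r, score = acc[hits])
  }
  if (!length(cand)) return(empty_droplets())
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score), ]

  picked <- cand[0, ]
  while (nrow(cand)) {
    top <- cand[1, ]
    picked <- rbind(picked, top)
    # droplets do not nest: no second center can lie inside a detected circle
    d <- sqrt((cand$row - top$row)^2 + (cand$col - top$col)^2)
    cand <- cand[d > top$r_px + 2, ]
  }

  # verify each survivor on the refined circle: the radius is re-estimated
  # as the median edge distance near the voted radius, the score re-computed
  # as exact annulus support, and the angular coverage must be near-complete
  # (true circles have edge support in nearly every sector around the
  # center; coincidental vote peaks do not)
  nsect <- 24L
  verify <- function(top) {
    dist <- sqrt((er - top$row)^2 + (ec - top$col)^2)
    sel <- abs(dist - top$r_px) <= 2
    if (!any(sel)) return(c(NA_real_, 0, 0))
    r_ref <- stats::median(dist[sel])
    sel <- abs(dist - r_ref) <= 1.5
    if (!any(sel)) return(c(NA_real_, 0, 0))
    ang <- atan2(er[sel] - top$row, ec[sel] - top$col)
    sect <- pmin(floor((ang + pi) / (2 * pi) * nsect), nsect - 1)
    c(r_ref, sum(sel) / (2 * pi * r_ref), length(unique(sect)) / nsect)
  }
  v <- vapply(seq_len(nrow(picked)), function(i) verify(picked[i, ]),
              numeric(3))
  keep <- is.finite(v[1, ]) & v[1, ] >= rmin_px & v[1, ] <= rmax_px &
    v[2, ] >= 2 * sensitivity & v[3, ] >= 0.8
  out <- tibble::tibble(row = picked$row[keep], col = picked$col[keep],
                        radius_nm = v[1, keep] * pixel_size,
                        score = v[2, keep],
                        coverage = v[3, keep])
  out <- out[order(-out$score), ]
  class(out) <- c("droplet_set", class(out))
  out
}

empty_droplets <- function() {
  out <- tibble::tibble(row = numeric(0), col = numeric(0),
                        radius_nm = numeric(0), score = numeric(0),
                        coverage = numeric(0))
  class(out) <- c("droplet_set", class(out))
  out
}

#' Histogram of detected droplet radii
#'
#' Half-open bins `[edge_i, edge_(i+1))`; radii outside the edge span are
#' dropped. When the edges span all radii, the counts conserve the detection
#' total.
#'
#' @param droplets A [detect_circles()] result (or any data frame with a
#'   `radius_nm` column).
#' @param bin_edges Strictly increasing bin edges in nm.
#' @return A tibble with `bin_lo_nm`, `bin_hi_nm` and `count`.
#' @export
radius_histogram <- function(droplets, bin_edges) {
  stopifnot("radius_nm" %in% names(droplets))
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing", call. = FALSE)
  nbin <- length(bin_edges) - 1
  # findInterval is left-closed / right-open, matching the bin convention;
  # values below the first or at/above the last edge fall outside 1..nbin
  idx <- findInterval(droplets$radius_nm, bin_edges)
  idx <- idx[idx >= 1 & idx <= nbin]
  tibble::tibble(bin_lo_nm = bin_edges[-length(bin_edges)],
                 bin_hi_nm = bin_edges[-1],
                 count = tabulate(idx, nbins = nbin))
}
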