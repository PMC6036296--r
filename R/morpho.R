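# Convex-hull area-ratio morphometry on cell contours, as produced by
# real-time deformability cytometry: the ratio of convex-hull area to
# contour area (>= 1) is a sensitive, label-free surrogate of granulocyte
# shape change, elevated by membrane protrusions and blebs.

# Internal: 2-D cross product (o->a) x (o->b).
.cross2 <- function(ox, oy, ax, ay, bx, by)
  (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)

# Internal: TRUE if the closed polygon has a pair of non-adjacent edges
# that intersect (touching counts). O(n^2) pairwise segment test.
.self_intersects <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  idx <- which(outer(seq_len(n), seq_len(n),
                     function(i, j) j > i + 1L & !(i == 1L & j == n)),
               arr.ind = TRUE)
  if (!nrow(idx)) return(FALSE)
  i <- idx[, 1L]; j <- idx[, 2L]
  d1 <- .cross2(x[i], y[i], x2[i], y2[i], x[j], y[j])
  d2 <- .cross2(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
  d3 <- .cross2(x[j], y[j], x2[j], y2[j], x[i], y[i])
  d4 <- .cross2(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  if (any(proper)) return(TRUE)
  # collinear / endpoint-touching cases: a zero cross with overlapping boxes
  on_seg <- function(d, px, py, qx, qy, rx, ry)
    d == 0 & rx >= pmin(px, qx) & rx <= pmax(px, qx) &
      ry >= pmin(py, qy) & ry <= pmax(py, qy)
  touch <- on_seg(d1, x[i], y[i], x2[i], y2[i], x[j], y[j]) |
    on_seg(d2, x[i], y[i], x2[i], y2[i], x2[j], y2[j]) |
    on_seg(d3, x[j], y[j], x2[j], y2[j], x[i], y[i]) |
    on_seg(d4, x[j], y[j], x2[j], y2[j], x2[i], y2[i])
  any(touch)
}

#' Construct a cell contour
#'
#' A closed simple polygon in pixel coordinates (the last vertex connects
#' back to the first). Contours must have at least 3 distinct vertices and
#' no self-intersection; self-intersecting contours are rejected rather
#' than repaired, since silent repair would bias downstream area
#' statistics.
#'
#' @param x,y numeric vertex coordinates (equal length), or `x` a
#'   two-column matrix/data.frame.
#' @param validate check simplicity (default `TRUE`; skip for bulk input
#'   known to be valid).
#' @return object of class `"cell_contour"`: list with numeric `x`, `y`.
#' @export
cell_contour <- function(x, y = NULL, validate = TRUE) {
  if (is.null(y)) {
    m <- as.matrix(x)
    if (ncol(m) != 2L) stop("'x' must have two columns when 'y' is absent")
    y <- m[, 2L]; x <- m[, 1L]
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  # drop an explicitly repeated closing vertex
  n <- length(x)
  if (n > 1L && x[1L] == x[n] && y[1L] == y[n]) {
    x <- x[-n]; y <- y[-n]
  }
  if (nrow(unique(cbind(x, y))) < 3L)
    stop("a contour needs at least 3 distinct vertices")
  if (validate && .self_intersects(x, y))
    stop("contour is self-intersecting; rejected (not repaired)")
  structure(list(x = x, y = y), class = "cell_contour")
}

#' @export
print.cell_contour <- function(x, ...) {
  cat("cell_contour:", length(x$x), "vertices, area",
      signif(polygon_area(x), 5), "px^2\n")
  invisible(x)
}

#' Polygon area (shoelace)
#'
#' Absolute area of the closed polygon by the shoelace formula;
#' orientation-independent.
#'
#' @param contour a [cell_contour()].
#' @return area in px^2 (> 0; degenerate zero-area polygons are an error).
#' @export
polygon_area <- function(contour) {
  x <- contour$x; y <- contour$y
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  a <- abs(sum(x * y2 - x2 * y)) / 2
  if (a == 0) stop("degenerate contour: zero area")
  a
}

#' Convex hull of a contour (monotone chain)
#'
#' Andrew's monotone-chain construction: vertices are sorted
#' lexicographically and lower/upper chains built with strict right-turn
#' elimination, so collinear boundary points are dropped. The hull is
#' returned counter-clockwise.
#'
#' @param contour a [cell_contour()] (or any list with `x`, `y`).
#' @return the hull as a [cell_contour()].
#' @export
convex_hull <- function(contour) {
  pts <- unique(cbind(contour$x, contour$y))
  pts <- pts[order(pts[, 1L], pts[, 2L]), , drop = FALSE]
  n <- nrow(pts)
  if (n < 3L) stop("all points collinear: no hull")
  build <- function(ord) {
    h <- integer(0)
    for (i in ord) {
      while (length(h) >= 2L) {
        m <- length(h)
        if (.cross2(pts[h[m - 1L], 1L], pts[h[m - 1L], 2L],
                    pts[h[m], 1L], pts[h[m], 2L],
                    pts[i, 1L], pts[i, 2L]) <= 0)
          h <- h[-m]
        else break
      }
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(hull) < 3L) stop("all points collinear: no hull")
  cell_contour(pts[hull, 1L], pts[hull, 2L], validate = FALSE)
}

#' Hull-to-contour area ratio
#'
#' The area-ratio shape statistic: convex-hull area divided by contour
#' area. Equals 1 for convex contours and grows with protrusions; always
#' >= 1 for a simple polygon.
#'
#' @param contour a [cell_contour()].
#' @return list of class `"area_ratio_result"`: `contour_area`,
#'   `hull_area`, `area_ratio`.
#' @examples
#' notched <- cell_contour(c(0, 1, 1, 0.5, 0), c(0, 0, 1, 0.5, 1))
#' area_ratio(notched) # contour 0.75, hull 1, ratio 4/3
#' @export
area_ratio <- function(contour) {
  ca <- polygon_area(contour)
  ha <- polygon_area(convex_hull(contour))
  structure(list(contour_area = ca, hull_area = ha,
                 area_ratio = ha / ca),
            class = "area_ratio_result")
}

#' @export
print.area_ratio_result <- function(x, ...) {
  cat("area_ratio: contour", signif(x$contour_area, 6), "px^2, hull",
      signif(x$hull_area, 6), "px^2, ratio", signif(x$area_ratio, 6), "\n")
  invisible(x)
}

#' Population summary of area ratios
#'
#' Median and mean area ratio over a collection of contours (both are
#' reported because per-donor aggregation conventions differ), with an
#' under-collection flag when fewer than `min_events` events are available
#' (deformability-cytometry practice collects at least 5,000 events per
#' sample).
#'
#' @param contours list of [cell_contour()] objects.
#' @param min_events event-count threshold for the flag (default 5000).
#' @return list: `n`, `median_ratio`, `mean_ratio`, `below_threshold`.
#' @export
summarize_population <- function(contours, min_events = 5000L) {
  if (!length(contours)) stop("empty contour collection")
  ratios <- vapply(contours, function(ct) area_ratio(ct)$area_ratio,
                   numeric(1))
  list(n = length(ratios), median_ratio = median(ratios),
       mean_ratio = mean(ratios),
       below_threshold = length(ratios) < min_events)
}

#' Synthetic cell contours with tunable protrusions
#'
#' Radial polygons `r(theta) = R (1 + a sin(f theta + phase) + s(theta))`
#' sampled at `n_vertices` angles, where `s` is smooth low-order harmonic
#' noise. `amplitude = 0` gives (polygonized) circles with area ratio 1;
#' larger protrusion amplitudes raise the area ratio monotonically, so
#' "primed/activated-like" populations are produced by increasing
#' `amplitude`. Radial polygons are simple by construction.
#'
#' @param n number of cells.
#' @param radius mean radius R, px.
#' @param amplitude protrusion amplitude `a` (lobed-deviation fraction).
#' @param lobes protrusion frequency `f` (default 8).
#' @param noise_amp amplitude of the smooth harmonic noise (default 0.01).
#' @param n_vertices vertices per contour (default 64).
#' @param seed optional RNG seed.
#' @return list of [cell_contour()] objects.
#' @export
simulate_contours <- function(n, radius = 30, amplitude = 0, lobes = 8,
                              noise_amp = 0.01, n_vertices = 64L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  lapply(seq_len(n), function(i) {
    phase <- stats::runif(1, 0, 2 * pi)
    s <- rep(0, length(theta))
    if (noise_amp > 0)
      for (h in 2:4)
        s <- s + stats::rnorm(1, 0, noise_amp / 3) * sin(h * theta +
                                                  stats::runif(1, 0, 2 * pi))
    r <- radius * pmax(1 + amplitude * sin(lobes * theta + phase) + s, 0.05)
    cell_contour(r * cos(theta), r * sin(theta), validate = FALSE)
  })
}

#' Read / write contour tables
#'
#' Long-format delimited serialization of contour collections: columns
#' `event_id`, `vertex_index`, `x`, `y`.
#'
#' @param contours list of [cell_contour()] objects.
#' @param file path or connection.
#' @param validate re-validate contours on read (default `TRUE`).
#' @return `read_contour_table()`: list of contours;
#'   `write_contour_table()`: `file`, invisibly.
#' @export
write_contour_table <- function(contours, file) {
  rows <- lapply(seq_along(contours), function(i)
    data.frame(event_id = i, vertex_index = seq_along(contours[[i]]$x),
               x = contours[[i]]$x, y = contours[[i]]$y))
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' @rdname write_contour_table
#' @export
read_contour_table <- function(file, validate = TRUE) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("event_id", "vertex_index", "x", "y")
  if (!all(need %in% names(d)))
    stop("contour table needs columns: ", paste(need, collapse = ", "))
  lapply(split(d, d$event_id), function(e) {
    e <- e[order(e$vertex_index), , drop = FALSE]
    cell_contour(e$x, e$y, validate = validate)
  })
}
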