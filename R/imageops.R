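# Low-level binary-image operations shared by segmentation, radial profiling
# and cell detection. All masks are logical matrices; NA counts as background.

#' Label 8-connected components of a binary mask
#'
#' Run-based two-pass labeling with union-find. Two foreground pixels belong
#' to the same component if they touch horizontally, vertically or diagonally
#' (8-connectivity). Labels are assigned in raster-scan order of each
#' component's first run.
#'
#' @param mask Logical matrix (`NA` treated as `FALSE`).
#' @return Integer matrix of the same dimension; 0 = background.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  mask[is.na(mask)] <- FALSE
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (!any(mask)) return(labels)

  # collect runs per row: (row, col_start, col_end)
  runs_row <- integer(0); runs_start <- integer(0); runs_end <- integer(0)
  for (i in seq_len(nr)) {
    v <- mask[i, ]
    if (!any(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    fg <- which(r$values)
    runs_row <- c(runs_row, rep.int(i, length(fg)))
    runs_start <- c(runs_start, starts[fg])
    runs_end <- c(runs_end, ends[fg])
  }
  n_runs <- length(runs_row)
  parent <- seq_len(n_runs)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  # union runs on adjacent rows whose column spans touch (8-conn: +/- 1 overlap)
  prev_idx <- integer(0)
  row_of <- split(seq_len(n_runs), runs_row)
  rows_present <- as.integer(names(row_of))
  for (k in seq_along(rows_present)) {
    cur <- row_of[[k]]
    if (k > 1 && rows_present[k] - rows_present[k - 1] == 1L) {
      prev <- row_of[[k - 1]]
      for (a in cur) {
        for (b in prev) {
          if (runs_start[a] <= runs_end[b] + 1L && runs_end[a] >= runs_start[b] - 1L) union(a, b)
        }
      }
    }
  }
  roots <- vapply(seq_len(n_runs), find, integer(1))
  relabel <- match(roots, unique(roots))
  for (r in seq_len(n_runs)) {
    labels[runs_row[r], runs_start[r]:runs_end[r]] <- relabel[r]
  }
  labels
}

# Moore-neighbour boundary tracing with Jacob's stopping criterion.
# Returns an n x 2 matrix of (row, col) boundary pixel coordinates, ordered
# along the boundary, closed implicitly (last point adjacent to first).
trace_boundary <- function(mask) {
  stopifnot(is.matrix(mask))
  mask[is.na(mask)] <- FALSE
  idx <- which(mask)
  if (length(idx) == 0) abort("cannot trace the boundary of an empty mask.")
  nr <- nrow(mask)
  # first foreground pixel in column-major scan: its W neighbour is background
  start <- c((idx[1] - 1L) %% nr + 1L, (idx[1] - 1L) %/% nr + 1L)
  if (length(idx) == 1) return(matrix(start, 1, 2))
  # clockwise neighbour offsets starting at W
  dirs <- rbind(
    c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
    c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L)
  )
  inside <- function(p) {
    p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= ncol(mask) && mask[p[1], p[2]]
  }
  cur <- start
  bdir <- 1L  # direction of the backtrack (background) neighbour: W
  first_d <- NA_integer_
  pts <- vector("list", 64L)
  n_pts <- 0L
  repeat {
    found <- FALSE
    d <- bdir
    for (step in 1:8) {
      d <- d %% 8L + 1L  # clockwise, starting just after the backtrack pixel
      cand <- cur + dirs[d, ]
      if (inside(cand)) { found <- TRUE; break }
    }
    if (!found) {  # isolated pixel
      n_pts <- n_pts + 1L
      pts[[n_pts]] <- cur
      break
    }
    # stop on re-entering the start pixel with the same outgoing move
    if (!is.na(first_d) && all(cur == start) && d == first_d) break
    n_pts <- n_pts + 1L
    pts[[n_pts]] <- cur
    if (is.na(first_d)) first_d <- d
    if (n_pts > 8L * length(idx) + 8L) break  # safety net
    d_prev <- (d - 2L) %% 8L + 1L
    back <- cur + dirs[d_prev, ]  # checked just before cand, so background
    cur <- cand
    delta <- back - cur
    bdir <- which(dirs[, 1] == delta[1] & dirs[, 2] == delta[2])
  }
  do.call(rbind, pts[seq_len(n_pts)])
}

# Perimeter of a mask, in pixels: length of the closed polygon through the
# traced boundary pixel centres after a circular 5-point moving average.
# The smoothing removes the staircase overestimate of digitized smooth
# contours; tiny masks (< 8 boundary points) fall back to counting exposed
# pixel edges.
perimeter_px <- function(mask) {
  b <- trace_boundary(mask)
  n <- nrow(b)
  if (n < 8) {
    m <- mask
    m[is.na(m)] <- FALSE
    pad <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
    pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    edges <- 0L
    core <- pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)]
    edges <- sum(core & !pad[1:nrow(m), 2:(ncol(m) + 1)]) +
      sum(core & !pad[3:(nrow(m) + 2), 2:(ncol(m) + 1)]) +
      sum(core & !pad[2:(nrow(m) + 1), 1:ncol(m)]) +
      sum(core & !pad[2:(nrow(m) + 1), 3:(ncol(m) + 2)])
    return(as.numeric(edges))
  }
  w <- 5L
  k <- -(w %/% 2L):(w %/% 2L)
  sm <- matrix(0, n, 2)
  for (j in 1:2) {
    for (off in k) sm[, j] <- sm[, j] + b[((seq_len(n) - 1L + off) %% n) + 1L, j]
    sm[, j] <- sm[, j] / w
  }
  d <- sm[c(2:n, 1L), ] - sm
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

#' Otsu threshold of an intensity matrix
#'
#' Thin wrapper around `EBImage::otsu()` operating on the raw intensity range
#' of the input (values are rescaled to `[0, 1]` for the histogram and the
#' threshold mapped back).
#'
#' @param x Numeric matrix or array; `NA`s are ignored.
#' @param levels Number of histogram bins.
#' @return Threshold on the scale of `x`.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- x[!is.na(x)]
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  scaled <- (v - lo) / (hi - lo)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = levels)
  lo + thr * (hi - lo)
}

resolve_threshold <- function(x, threshold) {
  if (identical(threshold, "otsu")) otsu_threshold(x) else check_number(threshold, "threshold")
}

# Bilinear interpolation of img at continuous pixel coordinates.
# px = column coordinate, py = row coordinate; pixel (i, j) centre at
# (px, py) = (j - 0.5, i - 0.5). Coordinates outside the grid are clamped.
bilinear_sample <- function(img, px, py) {
  nr <- nrow(img); nc <- ncol(img)
  u <- pmin(pmax(px - 0.5, 0), nc - 1)  # 0-based col of left centre
  v <- pmin(pmax(py - 0.5, 0), nr - 1)
  j0 <- pmin(floor(u), nc - 1); i0 <- pmin(floor(v), nr - 1)
  j1 <- pmin(j0 + 1, nc - 1); i1 <- pmin(i0 + 1, nr - 1)
  fu <- u - j0; fv <- v - i0
  id <- function(i, j) i + 1 + nr * j  # (0-based i, j) -> linear index
  (1 - fu) * (1 - fv) * img[id(i0, j0)] +
    fu * (1 - fv) * img[id(i0, j1)] +
    (1 - fu) * fv * img[id(i1, j0)] +
    fu * fv * img[id(i1, j1)]
}
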