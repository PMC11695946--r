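# Internal numeric helpers shared across modules.

#' Evaluate an expression with a private RNG stream
#'
#' Saves and restores `.Random.seed` so that package functions that take a
#' `seed` argument do not perturb the caller's random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# mirror (reflect-without-repeat) index into 1..n for out-of-range i
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * (n - 1L))
  j <- ifelse(j < 0L, j + 2L * (n - 1L), j)
  as.integer(ifelse(j < n, j + 1L, 2L * n - 1L - j))
}

gauss_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) return(1)
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# convolve each column of a matrix with kernel k, mirror padding; large
# inputs are processed in column blocks to bound peak memory
conv_cols <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(m * k)
  n <- nrow(m)
  idx <- mirror_index((1L - r):(n + r), n)
  one_block <- function(mm) {
    out <- stats::filter(mm[idx, , drop = FALSE], k,
                         method = "convolution", sides = 2)
    out <- unclass(out) # drop the ts class before subsetting
    matrix(out[(r + 1L):(r + n), ], nrow = n)
  }
  nc <- ncol(m)
  if (as.double(n) * nc <= 2e7) return(one_block(m))
  block <- max(1L, as.integer(2e7 %/% n))
  for (a in seq(1L, nc, by = block)) {
    b <- min(a + block - 1L, nc)
    m[, a:b] <- one_block(m[, a:b, drop = FALSE])
  }
  m
}

# separable Gaussian blur of a 3D array (y, x, t); sigma length 3 in the
# same order, a zero entry skips that dimension.  Dimension attributes are
# rewritten in place and intermediates freed eagerly: multi-minute movies
# are hundreds of MB per copy.
gauss_blur_3d <- function(arr, sigma) {
  d <- dim(arr)
  stopifnot(length(d) == 3L, length(sigma) == 3L)
  for (ax in 1:3) {
    if (sigma[ax] <= 0 || d[ax] == 1L) next
    k <- gauss_kernel(sigma[ax])
    perm <- c(ax, setdiff(1:3, ax))
    if (ax != 1L) {
      arr <- aperm(arr, perm)
      gc(FALSE)
    }
    dm <- d[perm]
    dim(arr) <- c(dm[1], dm[2] * dm[3])
    arr <- conv_cols(arr, k)
    dim(arr) <- dm
    if (ax != 1L) {
      arr <- aperm(arr, order(perm))
      gc(FALSE)
    }
  }
  arr
}

gauss_blur_2d <- function(m, sigma) {
  if (length(sigma) == 1L) sigma <- c(sigma, sigma)
  a <- gauss_blur_3d(array(m, dim = c(dim(m), 1L)), c(sigma, 0))
  a[, , 1]
}

#' Robust standard deviation
#'
#' 1.4826 times the median absolute deviation, the normal-consistent scale
#' estimator used throughout the package wherever a threshold must not be
#' inflated by the very transients being detected.
#'
#' @param x numeric vector.
#' @return scalar robust SD estimate.
#' @export
robust_sd <- function(x) stats::mad(x, na.rm = TRUE)

# --- peak finding ----------------------------------------------------------

#' Find local maxima with topographic prominence
#'
#' Strict local maxima of `x` (plateaus contribute their first sample).  For
#' each peak the prominence is the peak height minus the higher of the two
#' minima found while extending left and right until a higher sample (or the
#' trace end) is met, the usual topographic definition.
#'
#' @param x numeric vector.
#' @return data.frame with columns `index`, `value`, `prominence`,
#'   `left_base`, `right_base` (indices of the bounding minima).
#' @export
find_peaks <- function(x) {
  n <- length(x)
  empty <- data.frame(index = integer(), value = numeric(),
                      prominence = numeric(), left_base = integer(),
                      right_base = integer())
  if (n < 3L) return(empty)
  dx_prev <- c(Inf, diff(x))
  dx_next <- c(diff(x), -Inf)
  cand <- which(dx_prev > 0 & dx_next <= 0)
  # drop interior plateau duplicates (keep first sample of each plateau)
  cand <- cand[cand > 1L & cand < n]
  if (!length(cand)) return(empty)
  prom <- numeric(length(cand))
  lb <- rb <- integer(length(cand))
  for (j in seq_along(cand)) {
    p <- cand[j]; v <- x[p]
    i <- p
    while (i > 1L && x[i - 1L] <= v) i <- i - 1L
    lseg <- x[i:p]; lb[j] <- i - 1L + which.min(lseg)
    i <- p
    while (i < n && x[i + 1L] <= v) i <- i + 1L
    rseg <- x[p:i]; rb[j] <- p - 1L + which.min(rseg)
    prom[j] <- v - max(x[lb[j]], x[rb[j]])
  }
  data.frame(index = cand, value = x[cand], prominence = prom,
             left_base = lb, right_base = rb)
}

# Full width of the excursion around peak index p at level `level`, with
# linear interpolation of the crossings.  Returns width in samples together
# with the crossing positions; widths that run into the trace boundary are
# flagged.
peak_width_at <- function(x, p, level) {
  n <- length(x)
  i <- p
  while (i > 1L && x[i - 1L] >= level) i <- i - 1L
  if (i == 1L && x[1L] >= level) {
    left <- 1; ltrunc <- TRUE
  } else {
    left <- (i - 1L) + (level - x[i - 1L]) / (x[i] - x[i - 1L]); ltrunc <- FALSE
  }
  i <- p
  while (i < n && x[i + 1L] >= level) i <- i + 1L
  if (i == n && x[n] >= level) {
    right <- n; rtrunc <- TRUE
  } else {
    right <- i + (level - x[i]) / (x[i + 1L] - x[i]); rtrunc <- FALSE
  }
  list(width = right - left, left = left, right = right,
       truncated = ltrunc || rtrunc)
}

# --- frame-index intervals -------------------------------------------------
# Intervals are half-open [start, end) in 1-based frame indices, stored as a
# 2-column matrix.

interval_matrix <- function(x) {
  if (is.null(x) || length(x) == 0L)
    return(matrix(numeric(), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  m <- matrix(as.numeric(unlist(x)), ncol = 2, byrow = is.list(x))
  colnames(m) <- c("start", "end")
  if (any(m[, 2] <= m[, 1])) stop("interval end must exceed start")
  m
}

# union of possibly overlapping half-open intervals; returns sorted disjoint set
merge_intervals <- function(m) {
  if (nrow(m) == 0L) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    k <- nrow(out)
    if (m[i, 1] <= out[k, 2]) out[k, 2] <- max(out[k, 2], m[i, 2])
    else out <- rbind(out, m[i, , drop = FALSE])
  }
  out
}

frames_in_intervals <- function(m, n_frames) {
  flag <- logical(n_frames)
  for (i in seq_len(nrow(m))) {
    a <- max(1L, ceiling(m[i, 1])); b <- min(n_frames, ceiling(m[i, 2]) - 1L)
    if (b >= a) flag[a:b] <- TRUE
  }
  flag
}

# --- connected components --------------------------------------------------

# 3D connected components of voxel coordinates (rows: y, x, t) under
# 26-connectivity (6-connectivity when conn = 6).  Returns an integer
# component label per row.
label_components_3d <- function(coords, dims, conn = 26) {
  n <- nrow(coords)
  if (n == 0L) return(integer())
  lin <- (coords[, 3] - 1) * (dims[1] * dims[2]) +
    (coords[, 2] - 1) * dims[1] + coords[, 1]
  ord <- order(lin)
  lin_sorted <- lin[ord]
  offs <- expand.grid(dy = -1:1, dx = -1:1, dt = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0 & offs$dt == 0), ]
  if (conn == 6) offs <- offs[abs(offs$dy) + abs(offs$dx) + abs(offs$dt) == 1, ]
  # only half the offsets are needed for an undirected edge list
  keep <- offs$dt > 0 | (offs$dt == 0 & (offs$dx > 0 | (offs$dx == 0 & offs$dy > 0)))
  offs <- offs[keep, ]
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    ny <- coords[, 1] + offs$dy[r]
    nx <- coords[, 2] + offs$dx[r]
    nt <- coords[, 3] + offs$dt[r]
    ok <- ny >= 1 & ny <= dims[1] & nx >= 1 & nx <= dims[2] &
      nt >= 1 & nt <= dims[3]
    nlin <- (nt - 1) * (dims[1] * dims[2]) + (nx - 1) * dims[1] + ny
    pos <- findInterval(nlin, lin_sorted)
    hit <- ok & pos > 0 & lin_sorted[pmax(pos, 1L)] == nlin
    if (any(hit))
      edges <- rbind(edges, cbind(which(hit), ord[pos[hit]]))
  }
  if (is.null(edges)) return(seq_len(n))
  g <- igraph::graph_from_edgelist(matrix(as.integer(edges), ncol = 2),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(n)]
}

# Otsu threshold of an arbitrary numeric vector/array, via EBImage on the
# rescaled value distribution.
otsu_threshold <- function(v, levels = 256L) {
  v <- as.numeric(v)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  v01 <- (v - rng[1]) / diff(rng)
  img <- EBImage::Image(v01, dim = c(length(v01), 1L))
  thr01 <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  rng[1] + thr01 * diff(rng)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- grayscale morphology --------------------------------------------------
# Disc-structured min/max filters with edge replication.  (The installed
# image toolkits only provide binary morphology, so the grayscale white
# top-hat used for punctum segmentation is built from these.)

disc_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2, ]
}

gray_filter_2d <- function(m, radius, fun = pmin) {
  offs <- disc_offsets(radius)
  ny <- nrow(m); nx <- ncol(m)
  out <- NULL
  for (k in seq_len(nrow(offs))) {
    ys <- pmin(pmax(seq_len(ny) + offs$dy[k], 1L), ny)
    xs <- pmin(pmax(seq_len(nx) + offs$dx[k], 1L), nx)
    shifted <- m[ys, xs, drop = FALSE]
    out <- if (is.null(out)) shifted else fun(out, shifted)
  }
  out
}

#' Grayscale white top-hat filter
#'
#' Image minus its grayscale opening (disc erosion followed by dilation),
#' which removes every structure wider than the disc and leaves bright
#' puncta on a flat background.
#'
#' @param m numeric matrix.
#' @param radius disc radius in pixels.
#' @return filtered matrix, same shape.
#' @export
white_tophat <- function(m, radius) {
  opened <- gray_filter_2d(gray_filter_2d(m, radius, pmin), radius, pmax)
  m - opened
}
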