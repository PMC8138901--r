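# Monte-Carlo cluster-extent thresholding on smooth Gaussian noise
# fields: the cluster-size threshold k_min that controls the family-wise
# false-positive rate at a given voxel-wise height threshold.

#' Describe the null noise field
#'
#' @param grid integer length 3, field dimensions in voxels.
#' @param voxel_size isotropic voxel size in mm.
#' @param fwhm full width at half maximum of the Gaussian spatial
#'   autocorrelation, mm; 0 means white noise.
#' @param sided `"two"` (threshold on |z|) or `"one"` (upper tail).
#' @param connectivity `"faces"` (6-neighborhood), `"edges"` (18) or
#'   `"corners"` (26).
#' @return A `noise_model` list.
#' @export
noise_model <- function(grid = c(32, 32, 32), voxel_size = 1.5, fwhm = 6,
                        sided = c("two", "one"),
                        connectivity = c("faces", "edges", "corners")) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 1L)) abort("'grid' must be 3 positive dims")
  check_number(voxel_size, "voxel_size", lower = 1e-9)
  check_number(fwhm, "fwhm", lower = 0)
  structure(list(grid = grid, voxel_size = voxel_size, fwhm = fwhm,
                 sided = match.arg(sided),
                 connectivity = match.arg(connectivity)),
            class = "noise_model")
}

#' Simulate a standardized smooth Gaussian field
#'
#' White Gaussian noise is convolved with a Gaussian kernel of the model's
#' FWHM under periodic boundaries (FFT convolution; periodicity keeps the
#' field stationary on small grids), then standardized to zero mean and
#' unit variance. The lag-d autocorrelation of the result is
#' `exp(-4 log(2) d^2 / fwhm^2)`.
#'
#' @param model a [noise_model()].
#' @param seed integer seed; fixed seed gives an identical field.
#' @return A 3-D numeric array with `mean 0`, `sd 1`.
#' @export
simulate_field <- function(model, seed = NULL) {
  stopifnot(inherits(model, "noise_model"))
  with_seed(seed, {
    x <- array(stats::rnorm(prod(model$grid)), dim = model$grid)
    if (model$fwhm > 0) {
      x <- smooth_periodic(x, model$fwhm / model$voxel_size)
    }
    (x - mean(x)) / stats::sd(x)
  })
}

# Periodic Gaussian smoothing by FFT. fwhm_vox is the target FWHM of the
# FIELD's autocorrelation, in voxel units: convolving white noise with a
# Gaussian kernel doubles the variance of the resulting ACF, so the
# kernel sigma is the target sigma divided by sqrt(2).
smooth_periodic <- function(x, fwhm_vox) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2))) / sqrt(2)
  dims <- dim(x)
  kern <- lapply(dims, function(n) {
    m <- n %/% 2
    d <- c(0:m, if (n - m - 1 >= 1) -((n - m - 1):1))  # circular distances
    g <- exp(-d^2 / (2 * sigma^2))
    g / sum(g)
  })
  # separable kernel as outer product, then circular convolution via FFT
  K <- outer(outer(kern[[1]], kern[[2]]), kern[[3]])
  dim(K) <- dims
  Re(stats::fft(stats::fft(x) * stats::fft(K), inverse = TRUE)) / prod(dims)
}

CONNECTIVITY_OFFSETS <- function(connectivity) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[rowSums(abs(off)) > 0, ]
  ord <- rowSums(abs(off))
  keep <- switch(connectivity,
                 faces = ord == 1,
                 edges = ord <= 2,
                 corners = ord <= 3)
  as.matrix(off[keep, , drop = FALSE])
}

#' Label connected clusters in a binary field
#'
#' Connected-component sizes of the `TRUE` voxels under the stated
#' connectivity (non-periodic adjacency). Components are found on the
#' voxel adjacency graph via [igraph::components()].
#'
#' @param field logical (or 0/1) 3-D array.
#' @param connectivity `"faces"`, `"edges"` or `"corners"`.
#' @return Integer vector of cluster sizes, descending; empty if no voxel
#'   is set.
#' @export
label_clusters <- function(field, connectivity = "faces") {
  if (is.numeric(field)) field <- field != 0
  dims <- dim(field)
  if (is.null(dims) || length(dims) != 3L) abort("'field' must be a 3-D array")
  idx <- which(field)
  if (!length(idx)) return(integer())
  coord <- arrayInd(idx, dims)
  lin <- function(co) (co[, 3] - 1) * dims[1] * dims[2] +
    (co[, 2] - 1) * dims[1] + co[, 1]
  inside <- function(co) co[, 1] >= 1 & co[, 1] <= dims[1] &
    co[, 2] >= 1 & co[, 2] <= dims[2] & co[, 3] >= 1 & co[, 3] <= dims[3]
  off <- CONNECTIVITY_OFFSETS(connectivity)
  # half the offsets suffice: each undirected edge found once
  off <- off[off[, 1] + 3 * off[, 2] + 9 * off[, 3] > 0, , drop = FALSE]
  in_set <- logical(prod(dims))
  in_set[idx] <- TRUE
  edges <- NULL
  for (r in seq_len(nrow(off))) {
    nb <- sweep(coord, 2, off[r, ], "+")
    ok <- inside(nb)
    nb_lin <- lin(nb[ok, , drop = FALSE])
    ok2 <- in_set[nb_lin]
    if (any(ok2)) {
      edges <- rbind(edges, cbind(idx[ok][ok2], nb_lin[ok2]))
    }
  }
  verts <- as.character(idx)
  g <- igraph::graph_from_data_frame(
    d = if (is.null(edges)) data.frame(from = character(), to = character())
        else data.frame(from = as.character(edges[, 1]),
                        to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = verts))
  comp <- igraph::components(g)
  sort(as.integer(comp$csize), decreasing = TRUE)
}

#' Monte-Carlo cluster-size threshold
#'
#' Simulates `n_iter` null fields, thresholds each at the voxel-wise height
#' threshold (`|z| > z_{1-p/2}` two-sided, `z > z_{1-p}` one-sided), records
#' the largest suprathreshold cluster, and returns the smallest cluster
#' size `k_min` whose exceedance probability is at most `alpha` -- i.e. the
#' cluster-extent threshold controlling the family-wise false-positive
#' rate at `alpha` for that height threshold.
#'
#' @param model a [noise_model()].
#' @param voxel_p voxel-wise height threshold (p, in (0, 1)).
#' @param alpha target family-wise rate.
#' @param n_iter Monte-Carlo iterations (>= 100).
#' @param seed integer seed.
#' @return List with `k_min`, `exceedance` (data.frame `k`, `p_exceed`),
#'   `max_sizes`, and the call parameters.
#' @export
cluster_threshold <- function(model, voxel_p = 0.005, alpha = 0.05,
                              n_iter = 1000, seed = 1L) {
  stopifnot(inherits(model, "noise_model"))
  check_number(voxel_p, "voxel_p", lower = 1e-12, upper = 1 - 1e-12)
  check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  if (n_iter < 100) abort("'n_iter' must be >= 100")
  z <- if (model$sided == "two") stats::qnorm(1 - voxel_p / 2)
       else stats::qnorm(1 - voxel_p)
  max_sizes <- integer(n_iter)
  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      f <- simulate_field(model)
      mask <- if (model$sided == "two") abs(f) > z else f > z
      sz <- label_clusters(mask, model$connectivity)
      max_sizes[i] <- if (length(sz)) sz[1] else 0L
    }
  })
  ks <- seq_len(max(max_sizes, 1L) + 1L)
  p_exceed <- vapply(ks, function(k) mean(max_sizes >= k), 1.0)
  hit <- which(p_exceed <= alpha)
  if (alpha < 1 / n_iter) {
    warning(sprintf(
      "alpha = %g is below the 1/%d simulation resolution; k_min is the simulation ceiling",
      alpha, n_iter))
  }
  k_min <- ks[hit[1]]
  list(k_min = k_min,
       exceedance = data.frame(k = ks, p_exceed = p_exceed),
       max_sizes = max_sizes,
       model = model, voxel_p = voxel_p, alpha = alpha, n_iter = n_iter)
}
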