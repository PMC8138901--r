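# Shared fixtures and independent oracles, all built in code.

# Minimal atlas with hand-set flags.
tiny_atlas <- function(left = 3, right = 3, cerebellum = TRUE) {
  regions <- data.frame(
    id = c(sprintf("L_%02d", seq_len(left)), sprintf("R_%02d", seq_len(right))),
    name = "r", hemisphere = rep(c("L", "R"), c(left, right)),
    supratentorial = TRUE, cerebellum = FALSE, stringsAsFactors = FALSE)
  if (cerebellum) {
    regions <- rbind(regions, data.frame(
      id = c("Cbe_L", "Cbe_R"), name = "cb", hemisphere = c("L", "R"),
      supratentorial = FALSE, cerebellum = TRUE, stringsAsFactors = FALSE))
  }
  structure(list(regions = regions), class = "gmv_atlas")
}

# Hand-built 4x4x4-style label volume: labels placed explicitly.
hand_volume_atlas <- function() {
  atlas <- tiny_atlas(left = 2, right = 1, cerebellum = FALSE)
  vol <- array(0L, dim = c(8, 8, 8))
  vol[2, 4, 4] <- 1L   # L_01
  vol[3, 6, 4] <- 2L   # L_02
  vol[6, 4, 4] <- 4L   # R_01 (row 4 of the region table)
  # affine: 2 mm voxels, 0-based voxel (0,0,0) at (-7,-7,-7) mm
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- -7
  atlas$volume <- vol
  atlas$affine <- aff
  atlas
}

# A gene_assoc-shaped table from a bare rho vector.
assoc_from_rho <- function(rho, genes = sprintf("G%05d", seq_along(rho))) {
  structure(data.frame(gene = genes, rho = rho, p = NA_real_, q = NA_real_,
                       stringsAsFactors = FALSE),
            class = c("gene_assoc", "data.frame"))
}

# Brute-force flood fill: independent oracle for label_clusters().
flood_fill_sizes <- function(field, connectivity = "faces") {
  dims <- dim(field)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[rowSums(abs(off)) > 0, ]
  ord <- rowSums(abs(off))
  off <- as.matrix(off[switch(connectivity, faces = ord == 1,
                              edges = ord <= 2, corners = ord <= 3), ])
  seen <- array(FALSE, dims)
  sizes <- integer()
  idx <- which(field, arr.ind = TRUE)
  for (s in seq_len(nrow(idx))) {
    start <- idx[s, ]
    if (seen[start[1], start[2], start[3]]) next
    stack <- list(start)
    seen[start[1], start[2], start[3]] <- TRUE
    size <- 0L
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (r in seq_len(nrow(off))) {
        w <- v + off[r, ]
        if (any(w < 1) || any(w > dims)) next
        if (field[w[1], w[2], w[3]] && !seen[w[1], w[2], w[3]]) {
          seen[w[1], w[2], w[3]] <- TRUE
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

# Exhaustive BH step-up oracle: largest i with p_(i) <= (i/n) q, then
# adjusted values by the step-up definition computed directly.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# All permutations of 1..n as a list (independent recursive enumeration).
perm_enum <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in perm_enum(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

# Exhaustive hypergeometric upper-tail oracle (direct sum of choose()).
hyper_tail_oracle <- function(k, K, N, n) {
  jj <- k:min(K, n)
  sum(choose(K, jj) * choose(N - K, n - jj)) / choose(N, n)
}
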