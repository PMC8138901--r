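regions6 <- sprintf("L_%02d", 1:6)
eff6 <- setNames(seq(0.1, 0.6, length.out = 6), regions6)

test_that("whitelist filtering defines the gene universe", {
  b <- gen_expression(expression_spec(n_genes = 10, n_causal = 0,
                                      n_donors = 1, seed = 1),
                      regions6, eff6)
  all_syms <- unique(b$probes$gene)
  expect_identical(suppressMessages(filter_probes(b, all_syms))$probes,
                   b$probes)
  wl <- all_syms[1:7]
  flt <- suppressMessages(filter_probes(b, wl))
  expect_identical(attr(flt, "n_genes_surviving"), 7L)
  expect_true(all(flt$probes$gene %in% wl))
  # the surviving count is reported in the run log
  expect_message(filter_probes(b, wl), "7 unique genes")
  expect_error(filter_probes(b, "NOT_A_GENE"), "whitelist")
  expect_error(filter_probes(b, character()), "whitelist")
})

test_that("probe collapsing averages probes of the same gene", {
  b <- structure(list(
    probes = data.frame(probe = c("p1", "p2", "p3"),
                        gene = c("g1", "g1", "g2"), stringsAsFactors = FALSE),
    expr = matrix(c(2, 4, 7), 3, 1, dimnames = list(c("p1", "p2", "p3"), "s1")),
    samples = data.frame(sample_id = "s1", donor = "D1")),
    class = "expr_bundle")
  out <- collapse_probes(b)
  expect_equal(out["g1", "s1"], 3)       # mean of {2, 4}
  expect_equal(out["g2", "s1"], 7)       # single probe passes through
  # random matrix vs an independent group-by mean
  set.seed(2)
  genes <- sample(c("a", "b", "c"), 6, replace = TRUE)
  m <- matrix(rnorm(6 * 4), 6, 4,
              dimnames = list(sprintf("p%d", 1:6), sprintf("s%d", 1:4)))
  b2 <- structure(list(probes = data.frame(probe = rownames(m), gene = genes,
                                           stringsAsFactors = FALSE),
                       expr = m), class = "expr_bundle")
  oracle <- apply(m, 2, function(col) tapply(col, genes, mean))
  expect_equal(collapse_probes(b2), oracle[sort(unique(genes)), ])
})

test_that("volume assignment: containing voxel, tolerance, bounds", {
  atlas <- hand_volume_atlas()
  # voxel (2,4,4) 1-based = 0-based (1,3,3) -> mm (-5, -1, -1)
  s <- data.frame(sample_id = c("a", "b", "c"),
                  donor = "D1",
                  x = c(-5, -5, -90), y = c(-1, -1 + 2.4, 0),
                  z = c(-1, -1, 0), stringsAsFactors = FALSE)
  out <- assign_samples(s[1, ], atlas)
  expect_identical(out$region, "L_01")
  # background 2.4 mm from L_01's voxel center: found at 3 mm, not at 1 mm
  expect_identical(assign_samples(s[2, ], atlas, max_dist_mm = 3)$region, "L_01")
  expect_identical(suppressWarnings(
    assign_samples(s[2, ], atlas, max_dist_mm = 1))$region, NA_character_)
  expect_warning(expect_warning(out3 <- assign_samples(s[3, ], atlas),
                                "bounds"), "unassigned")
  expect_identical(out3$region, NA_character_)
})

test_that("volume assignment matches an exhaustive nearest-voxel search", {
  atlas <- gen_atlas(n_per_hemisphere = 3, with_volume = TRUE,
                     grid = c(10, 10, 10), voxel_size = 6, seed = 3)
  set.seed(4)
  n <- 100
  s <- data.frame(sample_id = sprintf("s%03d", 1:n), donor = "D1",
                  x = runif(n, -28, 28), y = runif(n, -28, 28),
                  z = runif(n, -28, 28), stringsAsFactors = FALSE)
  max_dist <- 6
  got <- suppressWarnings(assign_samples(s, atlas, max_dist_mm = max_dist))
  lab_idx <- which(atlas$volume > 0, arr.ind = TRUE)
  lab_mm <- (lab_idx - 1) %*% t(atlas$affine[1:3, 1:3]) +
    matrix(atlas$affine[1:3, 4], nrow(lab_idx), 3, byrow = TRUE)
  oracle <- vapply(seq_len(n), function(i) {
    p <- c(s$x[i], s$y[i], s$z[i])
    vox <- round((p - atlas$affine[1:3, 4]) / atlas$affine[1, 1]) + 1
    if (any(vox < 1) || any(vox > dim(atlas$volume))) return(NA_character_)
    lab <- atlas$volume[vox[1], vox[2], vox[3]]
    if (lab == 0) {
      d <- sqrt(rowSums(sweep(lab_mm, 2, p, "-")^2))
      if (min(d) <= max_dist) lab <- atlas$volume[lab_idx[which.min(d), ,
                                                          drop = FALSE]]
    }
    if (lab > 0) atlas$regions$id[lab] else NA_character_
  }, "")
  expect_identical(got$region, oracle)
})

test_that("analysis-region rule: 45 left + merged right cerebellum = 46", {
  sel <- select_analysis_regions(gen_atlas())
  expect_identical(nrow(sel), 46L)
  expect_identical(sel$id[46], "cerebellum_R")
  expect_identical(attr(sel, "members")$cerebellum_R, "Cbe_R")
  # no cerebellum: 45 regions plus a warning
  expect_warning(sel2 <- select_analysis_regions(gen_atlas(cerebellum = FALSE)),
                 "cerebellum")
  expect_identical(nrow(sel2), 45L)
  # all-right-hemisphere atlas: error
  atl <- tiny_atlas(left = 0, right = 3, cerebellum = FALSE)
  expect_error(select_analysis_regions(atl), "left")
})

test_that("regionization takes per-region medians with scoping rules", {
  genes <- c("g1", "g2")
  m <- matrix(c(1, 2, 10, 5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(genes, c("s1", "s2", "s3")))
  sam <- data.frame(sample_id = c("s1", "s2", "s3"), donor = "D1",
                    region = c("rA", "rA", "rA"), stringsAsFactors = FALSE)
  out <- regionize(m, sam, "rA")
  expect_equal(out["g1", "rA"], 2)       # median robust to the 10
  # one sample per region -> identity
  sam2 <- data.frame(sample_id = c("s1", "s2", "s3"), donor = "D1",
                     region = c("rA", "rB", "rC"), stringsAsFactors = FALSE)
  out2 <- regionize(m, sam2, c("rA", "rB", "rC"))
  expect_equal(unname(out2["g1", ]), c(1, 2, 10))
  # brute-force group-by median oracle on a random bundle
  set.seed(5)
  m3 <- matrix(rnorm(4 * 12), 4, 12,
               dimnames = list(sprintf("g%d", 1:4), sprintf("s%02d", 1:12)))
  sam3 <- data.frame(sample_id = colnames(m3),
                     donor = sample(c("D1", "D2"), 12, replace = TRUE),
                     region = sample(c("rA", "rB"), 12, replace = TRUE),
                     stringsAsFactors = FALSE)
  out3 <- regionize(m3, sam3, c("rA", "rB"))
  for (g in rownames(m3)) for (r in c("rA", "rB")) {
    expect_equal(out3[g, r], median(m3[g, sam3$region == r]))
  }
  # column order invariance
  perm <- sample(12)
  out4 <- regionize(m3[, perm], sam3[perm, ], c("rA", "rB"))
  expect_equal(out3, out4, ignore_attr = TRUE)
  # single-donor scope equals pooled when there is one donor
  sam5 <- sam3; sam5$donor <- "D1"
  expect_equal(regionize(m3, sam5, c("rA", "rB")),
               regionize(m3, sam5, c("rA", "rB"), donor_scope = "D1"),
               ignore_attr = TRUE)
  # median robust to corrupting < 50% of samples by monotone outliers:
  # pushing the already-largest values further up cannot move the median
  rA_cols <- which(sam3$region == "rA")
  m6 <- m3
  m6[, rA_cols[1]] <- m6[, rA_cols[1]] + 1e6
  expect_equal(regionize(m6, sam3, c("rA", "rB"))[, "rB"], out3[, "rB"])
  vals <- m3["g1", rA_cols]
  n_corrupt <- floor((length(vals) - 1) / 2)
  m7 <- m3
  top_cols <- rA_cols[order(vals, decreasing = TRUE)[seq_len(n_corrupt)]]
  m7["g1", top_cols] <- m7["g1", top_cols] + 1e6
  expect_equal(regionize(m7, sam3, c("rA", "rB"))["g1", "rA"],
               out3["g1", "rA"])
  # dropped regions warn; dropping everything errors
  expect_warning(regionize(m3, sam3, c("rA", "rB", "rZ")), "rZ")
  sam8 <- sam3; sam8$region <- NA_character_
  expect_error(regionize(m3, sam8, c("rA", "rB")), "dropped")
})
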