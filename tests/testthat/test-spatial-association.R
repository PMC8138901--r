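test_that("t-map summaries: absolute vs signed, with a brute-force oracle", {
  tmap <- data.frame(region = c("rA", "rA", "rB", "rC", "rC", "rC"),
                     t = c(1, -1, 2.5, -1, -2, -3))
  memb <- tmap$region
  abs_map <- summarize_tmap(tmap, memb, mode = "absolute")
  sgn_map <- summarize_tmap(tmap, memb, mode = "signed")
  expect_equal(abs_map$value[abs_map$region == "rA"], 1)
  expect_equal(sgn_map$value[sgn_map$region == "rA"], 0)
  expect_equal(abs_map$value[abs_map$region == "rB"], 2.5)
  expect_equal(sgn_map$value[sgn_map$region == "rB"], 2.5)
  # brute-force per-region means
  for (r in unique(memb)) {
    expect_equal(abs_map$value[abs_map$region == r], mean(abs(tmap$t[memb == r])))
    expect_equal(sgn_map$value[sgn_map$region == r], mean(tmap$t[memb == r]))
  }
  # absolute map dominates |signed| elementwise
  expect_true(all(abs_map$value >= abs(sgn_map$value) - 1e-12))
  # region-level map passes through
  rl <- data.frame(region = c("rA", "rB"), t = c(-2, 3))
  expect_equal(summarize_tmap(rl, mode = "absolute")$value, c(2, 3))
  expect_equal(summarize_tmap(rl, mode = "signed")$value, c(-2, 3))
})

test_that("Spearman rho: closed form, extremes, ties, cross-check", {
  expect_equal(spearman_rho(1:10, 1:10)$rho, 1)
  expect_equal(spearman_rho(1:10, 10:1)$rho, -1)
  # tie-free closed form: 1 - 6 sum(d^2) / (n (n^2 - 1)), sum(d^2) = 4
  r <- spearman_rho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 0.8)
  # against the standard implementation (t approximation), with ties
  set.seed(6)
  x <- rnorm(30)
  y <- round(x + rnorm(30), 1)
  got <- spearman_rho(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(got$rho, unname(ref$estimate))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  # invariance under strictly monotone transforms
  expect_equal(spearman_rho(exp(x), y)$rho, got$rho)
  expect_equal(spearman_rho(x, qlogis(plogis(y)))$rho, got$rho)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:3, 1:4), "length")
})

test_that("exact permutation p agrees with the t approximation at small n", {
  set.seed(7)
  x <- rnorm(7)
  y <- rnorm(7)
  exact <- spearman_rho(x, y, exact = TRUE)
  approx <- spearman_rho(x, y)
  expect_equal(exact$rho, approx$rho)
  # permutation tail probability straddles the approximation loosely
  expect_lt(abs(exact$p - approx$p), 0.12)
  # perfect monotone data: exact p = 2 / n! (both orderings)
  expect_equal(spearman_rho(1:5, 1:5, exact = TRUE)$p, 2 / factorial(5))
  expect_error(spearman_rho(1:9, 9:1, exact = TRUE), "n <= 8")
})

test_that("BH adjustment matches hand and exhaustive step-up oracles", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p))
    # step-up property: rejection set at level a equals the largest set
    # with p_(i) <= (i/n) a
    for (a in c(0.05, 0.2)) {
      ps <- sort(p)
      thr <- which(ps <= seq_along(ps) / length(ps) * a)
      k <- if (length(thr)) max(thr) else 0L
      expect_identical(sum(q <= a), k)
    }
  }
})

test_that("gene-wise correlations identify a perfectly coupled gene", {
  set.seed(9)
  regions <- sprintf("r%02d", 1:20)
  diffmap <- structure(data.frame(region = regions, value = runif(20, 0.1, 3)),
                       mode = "absolute", class = c("gmv_diffmap", "data.frame"))
  E <- matrix(rnorm(50 * 20), 50, 20, dimnames = list(sprintf("g%02d", 1:50),
                                                      regions))
  E["g01", ] <- diffmap$value
  E["g07", ] <- 5  # constant gene: excluded
  assoc <- suppressMessages(gene_correlations(E, diffmap))
  expect_equal(assoc$rho[assoc$gene == "g01"], 1)
  expect_equal(min(assoc$p), assoc$p[assoc$gene == "g01"])
  expect_false("g07" %in% assoc$gene)
  expect_identical(attr(assoc, "excluded"), "g07")
  expect_message(gene_correlations(E, diffmap), "g07")
  bad <- diffmap
  bad$region[1] <- "elsewhere"
  E2 <- E[, -(2:19)]
  expect_error(gene_correlations(E2, diffmap), "mismatch")
})

test_that("null genes keep the FDR controlled across seeds", {
  n_seeds <- 400
  n_genes <- 100
  n_reg <- 12
  disc <- vapply(seq_len(n_seeds), function(s) {
    set.seed(s)
    y <- rnorm(n_reg)
    E <- matrix(rnorm(n_genes * n_reg), n_genes, n_reg,
                dimnames = list(sprintf("g%03d", 1:n_genes),
                                sprintf("r%02d", 1:n_reg)))
    dm <- structure(data.frame(region = colnames(E), value = y),
                    class = c("gmv_diffmap", "data.frame"))
    mean(gene_correlations(E, dm)$q < 0.05)
  }, 1.0)
  tol <- 3 * sd(disc) / sqrt(n_seeds)
  expect_lte(mean(disc), 0.05 + tol)
})

test_that("percentile thresholds follow the interpolated order statistics", {
  v <- as.numeric(1:100)
  thr <- percentile_thresholds(v)
  expect_gt(thr$rho_hi, 97)
  expect_lt(thr$rho_hi, 98)
  expect_lte(abs(thr$frac_above - 0.025), 1 / 100)
  expect_lte(abs(thr$frac_below - 0.025), 1 / 100)
  expect_error(percentile_thresholds(1:10), "40")
  # symmetric distribution: thresholds are mirror images on average
  set.seed(10)
  sums <- vapply(1:50, function(i) {
    r <- rnorm(500)
    t <- percentile_thresholds(r)
    t$rho_lo + t$rho_hi
  }, 1.0)
  expect_lt(abs(mean(sums)), 2 * sd(sums) / sqrt(50))
})

test_that("sensitivity variants rerun the affected stages faithfully", {
  atlas <- gen_atlas(n_per_hemisphere = 8)
  sel <- select_analysis_regions(atlas)
  eff <- setNames(seq(0, 0.8, length.out = nrow(sel)) *
                    rep_len(c(1, -1), nrow(sel)), sel$id)
  ds <- gen_cohort(cohort_spec(n_per_group = c(control = 20, persistent = 14,
                                               recovered = 8),
                               effect_map = eff, seed = 12), sel$id)
  label_eff <- setNames(eff[rep(sel$id, lengths(attr(sel, "members")))],
                        unlist(attr(sel, "members")))
  b <- gen_expression(expression_spec(n_genes = 40, n_causal = 4, n_donors = 2,
                                      seed = 13), names(label_eff), label_eff)
  state <- list(dataset = ds, bundle = b, whitelist = b$whitelist,
                atlas = atlas)
  primary <- suppressMessages(do.call(run_association, state))
  # identity variant: empty exclusion changes nothing
  v0 <- suppressMessages(
    sensitivity_suite(state, list(type = "exclude_regions",
                                  regions = character())))
  expect_equal(v0$assoc, primary$assoc, ignore_attr = TRUE)
  # excluding half the regions equals direct recomputation on the rest
  drop <- sel$id[seq(1, nrow(sel), by = 2)]
  v1 <- suppressMessages(
    sensitivity_suite(state, list(type = "exclude_regions", regions = drop)))
  keep <- setdiff(colnames(primary$expr), drop)
  dm_kept <- primary$diffmap[primary$diffmap$region %in% keep, ]
  class(dm_kept) <- c("gmv_diffmap", "data.frame")
  direct <- gene_correlations(primary$expr[, keep], dm_kept)
  expect_equal(v1$assoc$rho, direct$rho)
  # recovered-vs-control pair drops the persistent scans
  v2 <- suppressMessages(
    sensitivity_suite(state, list(type = "group_pair",
                                  groups = c("control", "recovered"))))
  expect_identical(attr(v2, "variant")$type, "group_pair")
  expect_equal(nrow(v2$assoc), nrow(primary$assoc))
  # male-only subset reruns on fewer scans
  v3 <- suppressMessages(
    sensitivity_suite(state, list(type = "subset_sex", sex = "M")))
  expect_lte(v3$fit$n_scans, primary$fit$n_scans)
  # per-donor emits one rho row per donor
  v4 <- suppressMessages(sensitivity_suite(state, list(type = "per_donor")))
  expect_identical(rownames(v4$per_donor), c("D1", "D2"))
  expect_identical(ncol(v4$per_donor), nrow(primary$assoc))
})

test_that("per-donor rho equals the pooled run when there is one donor", {
  atlas <- gen_atlas(n_per_hemisphere = 5, cerebellum = FALSE)
  sel <- suppressWarnings(select_analysis_regions(atlas))
  eff <- setNames(seq(0.1, 1, length.out = nrow(sel)), sel$id)
  ds <- gen_cohort(cohort_spec(n_per_group = c(control = 10, persistent = 8),
                               effect_map = eff, seed = 14), sel$id)
  b <- gen_expression(expression_spec(n_genes = 15, n_causal = 2, n_donors = 1,
                                      seed = 15), sel$id, eff)
  state <- list(dataset = ds, bundle = b, whitelist = b$whitelist,
                atlas = atlas)
  pooled <- suppressWarnings(suppressMessages(do.call(run_association, state)))
  pd <- suppressWarnings(suppressMessages(
    sensitivity_suite(state, list(type = "per_donor"))))
  expect_equal(unname(pd$per_donor["D1", pooled$assoc$gene]),
               pooled$assoc$rho)
})
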