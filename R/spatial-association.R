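# Gene-wise Spearman correlation between regional expression and the
# regional group-difference summary, with FDR control, percentile
# thresholds on the rho distribution, and the sensitivity variants.

#' Summarize a t-map into a regional difference map
#'
#' Absolute mode takes the mean of |t| per region (the magnitude of the
#' group difference regardless of direction); signed mode takes the mean t
#' (the directional post hoc variant). Region-level t-maps (one value per
#' region) pass through with |.| applied per mode; voxel-level maps are
#' aggregated by a region-membership vector.
#'
#' @param tmap a `gmv_tmap` (or data.frame with `region`, `t`).
#' @param membership optional character vector mapping each t entry to its
#'   analysis region (voxel mode); `NULL` means `tmap$region` already holds
#'   analysis regions, one row each.
#' @param mode `"absolute"` or `"signed"`.
#' @return A `gmv_diffmap`: data.frame `region`, `value`; attribute `mode`.
#' @export
summarize_tmap <- function(tmap, membership = NULL,
                           mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  t <- tmap$t
  reg <- if (is.null(membership)) tmap$region else membership
  if (anyNA(t)) abort("t-map contains NA t values")
  split_t <- split(if (mode == "absolute") abs(t) else t, reg)
  empty <- names(split_t)[!lengths(split_t)]
  if (length(empty)) abort(sprintf("empty region(s): %s", paste(empty, collapse = ", ")))
  val <- vapply(split_t, mean, 1.0)
  structure(data.frame(region = names(val), value = unname(val),
                       stringsAsFactors = FALSE, row.names = NULL),
            mode = mode, contrast = attr(tmap, "contrast"),
            class = c("gmv_diffmap", "data.frame"))
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks (average ranks on ties).
#' Two-sided p comes from `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom; with `exact = TRUE` (n <= 8) the p-value is the
#' exact permutation tail probability `P(|rho_perm| >= |rho|)`.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @param exact use the exact permutation null (all n! permutations).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_rho <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) abort("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3) abort("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("constant input: Spearman rho undefined")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8) abort("exact permutation p only supported for n <= 8")
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_(j >= i) p_(j) * n / j`, capped at
#' 1 and mapped back to input order (delegates to [stats::p.adjust()]).
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Gene-wise Spearman correlation with a regional difference map
#'
#' Correlates every gene's regional expression with the regional
#' group-difference summary over the shared analysis regions, and adjusts
#' the two-sided p-values by Benjamini-Hochberg FDR across all tested
#' genes. Genes with constant expression (rho undefined) are excluded and
#' reported.
#'
#' @param expr a `region_expr` matrix (genes x regions).
#' @param diff a `gmv_diffmap`.
#' @return A `gene_assoc` data.frame: `gene`, `rho`, `p`, `q`, sorted as
#'   input; attributes `n_regions`, `excluded`.
#' @export
gene_correlations <- function(expr, diff) {
  regions <- intersect(colnames(expr), diff$region)
  only_e <- setdiff(colnames(expr), diff$region)
  only_d <- setdiff(diff$region, colnames(expr))
  if (length(regions) < 3) {
    abort(sprintf(
      "region mismatch: %d shared; only in expression: %s; only in map: %s",
      length(regions),
      paste(only_e, collapse = ",") , paste(only_d, collapse = ",")))
  }
  y <- diff$value[match(regions, diff$region)]
  n <- length(regions)
  E <- expr[, regions, drop = FALSE]

  if (stats::sd(y) == 0) abort("difference map is constant: rho undefined")
  ry <- rank(y)
  RX <- t(apply(E, 1, rank))
  sdx <- apply(RX, 1, stats::sd)
  ok <- sdx > 0
  excluded <- rownames(E)[!ok]
  if (length(excluded)) {
    message("excluding constant gene(s): ", paste(excluded, collapse = ", "))
  }
  RXc <- RX[ok, , drop = FALSE] - rowMeans(RX[ok, , drop = FALSE])
  ryc <- ry - mean(ry)
  rho <- drop(RXc %*% ryc) / (sqrt(rowSums(RXc^2)) * sqrt(sum(ryc^2)))
  rho <- pmin(1, pmax(-1, rho))
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  p[abs(rho) >= 1] <- 0
  q <- bh_fdr(p)
  structure(data.frame(gene = rownames(E)[ok], rho = rho, p = p, q = q,
                       stringsAsFactors = FALSE, row.names = NULL),
            n_regions = n, excluded = excluded,
            class = c("gene_assoc", "data.frame"))
}

#' Percentile thresholds of the rho distribution
#'
#' Empirical percentiles (linear interpolation between order statistics,
#' the common statistical-software default) of the gene-wise rho
#' distribution; a randomly picked gene exceeds the upper threshold, or
#' falls below the lower one, with probability ~2.5% each.
#'
#' @param rho numeric vector of gene-wise correlations (>= 40 values).
#' @param lower,upper percentile levels (percent).
#' @return List `rho_lo`, `rho_hi`, `frac_below`, `frac_above`.
#' @export
percentile_thresholds <- function(rho, lower = 2.5, upper = 97.5) {
  if (length(rho) < 40) abort("need >= 40 rho values for stable percentiles")
  qs <- stats::quantile(rho, c(lower, upper) / 100, names = FALSE, type = 7)
  list(rho_lo = qs[1], rho_hi = qs[2],
       frac_below = mean(rho < qs[1]), frac_above = mean(rho > qs[2]))
}

#' Run the association pipeline from raw components
#'
#' One full pass of the association stages: whitelist probe filter ->
#' probe averaging -> sample assignment -> analysis-region selection ->
#' design/fit/contrast of the longitudinal GLM -> regional t summary ->
#' median regionization -> gene-wise Spearman with FDR. Used by
#' [run_pipeline()] and by [sensitivity_suite()] for variant reruns.
#'
#' @param dataset a `gmv_cohort`.
#' @param bundle an `expr_bundle`.
#' @param whitelist gene-symbol whitelist.
#' @param atlas a `gmv_atlas`.
#' @param groups control/case group labels for [build_design()].
#' @param mode t-summary mode, `"absolute"` or `"signed"`.
#' @param donor_scope `"pooled"` or a donor id for [regionize()].
#' @param exclude_regions analysis-region ids to drop before correlating.
#' @param subset_sex optional `"M"`/`"F"`: keep only subjects of that sex.
#' @param min_samples,max_dist_mm passed to [regionize()] /
#'   [assign_samples()].
#' @return List with `assoc` (`gene_assoc`), `diffmap`, `tmap`, `expr`
#'   (regionized matrix), `regions`, `fit`.
#' @export
run_association <- function(dataset, bundle, whitelist, atlas,
                            groups = c("control", "persistent"),
                            mode = "absolute", donor_scope = "pooled",
                            exclude_regions = character(),
                            subset_sex = NULL,
                            min_samples = 1L, max_dist_mm = 2) {
  if (!is.null(subset_sex)) {
    keep <- dataset$scans$sex == subset_sex
    dataset$scans <- dataset$scans[keep, , drop = FALSE]
    dataset$gmv <- dataset$gmv[keep, , drop = FALSE]
  }
  # single-sex subsets drop the (now constant) sex covariate
  design <- build_design(dataset, groups = groups,
                         include_sex = is.null(subset_sex))
  regions <- select_analysis_regions(atlas)
  if (length(exclude_regions)) {
    drop <- regions$id %in% exclude_regions
    members <- attr(regions, "members")[regions$id[!drop]]
    regions <- regions[!drop, , drop = FALSE]
    attr(regions, "members") <- members
    class(regions) <- c("gmv_regions", "data.frame")
  }
  if (nrow(regions) < 3) abort("variant leaves < 3 analysis regions")

  # GLM responses: per analysis region (cohort responses are regional)
  resp_regions <- intersect(regions$id, colnames(dataset$gmv))
  if (!length(resp_regions)) abort("cohort responses cover no analysis region")
  fit <- fit_swe(design, dataset$gmv[, resp_regions, drop = FALSE])
  tmap <- contrast_tmap(fit, "group")
  diffmap <- summarize_tmap(tmap, mode = mode)

  flt <- filter_probes(bundle, whitelist)
  gxs <- collapse_probes(flt)
  sam <- assign_samples(flt$samples, atlas, max_dist_mm = max_dist_mm)
  expr <- regionize(gxs, sam, regions, donor_scope = donor_scope,
                    min_samples = min_samples)
  assoc <- gene_correlations(expr, diffmap)
  list(assoc = assoc, diffmap = diffmap, tmap = tmap, expr = expr,
       regions = regions, fit = fit)
}

#' Sensitivity variants of the association analysis
#'
#' Reruns the affected stages of [run_association()] under one of the
#' study's sensitivity variants:
#' \describe{
#'   \item{`exclude_regions`}{drop the named analysis regions (e.g.
#'     cerebellum, basal ganglia, thalamus) and recorrelate.}
#'   \item{`subset_sex`}{keep only subjects of one sex (male-only check).}
#'   \item{`group_pair`}{refit the GLM on a different case group, e.g.
#'     recovered vs control.}
#'   \item{`per_donor`}{regionize each donor separately and emit a
#'     donor x gene rho table.}
#' }
#'
#' @param state named list of the pipeline inputs: `dataset`, `bundle`,
#'   `whitelist`, `atlas`, plus any [run_association()] parameters.
#' @param variant a list with `type` (one of the above) and its
#'   parameters (`regions`, `sex`, `groups`).
#' @return For `per_donor`, a list with `per_donor` (donor x gene rho
#'   matrix) and `donors`; otherwise the [run_association()] result,
#'   tagged with attribute `variant`.
#' @export
sensitivity_suite <- function(state, variant) {
  stopifnot(is.list(variant), !is.null(variant$type))
  base_args <- state[intersect(names(state),
                               names(formals(run_association)))]
  res <- switch(
    variant$type,
    exclude_regions = do.call(run_association,
                              utils::modifyList(base_args,
                                                list(exclude_regions = variant$regions %||% character()))),
    subset_sex = do.call(run_association,
                         utils::modifyList(base_args,
                                           list(subset_sex = variant$sex %||% "M"))),
    group_pair = do.call(run_association,
                         utils::modifyList(base_args,
                                           list(groups = variant$groups))),
    per_donor = {
      donors <- sort(unique(state$bundle$samples$donor))
      runs <- lapply(donors, function(d) {
        do.call(run_association,
                utils::modifyList(base_args, list(donor_scope = d)))
      })
      genes <- sort(Reduce(union, lapply(runs, function(r) r$assoc$gene)))
      tab <- matrix(NA_real_, length(donors), length(genes),
                    dimnames = list(donors, genes))
      for (i in seq_along(runs)) {
        tab[i, runs[[i]]$assoc$gene] <- runs[[i]]$assoc$rho
      }
      list(per_donor = tab, donors = donors, runs = runs)
    },
    abort(sprintf("unknown variant type '%s'", variant$type))
  )
  attr(res, "variant") <- variant
  res
}
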