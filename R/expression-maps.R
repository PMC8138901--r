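# From donor expression bundle to gene x region matrix: symbol-whitelist
# probe filtering, probe-to-gene averaging, sample-to-region assignment,
# analysis-region selection, per-region median regionization.

#' Filter probes by a gene-symbol whitelist
#'
#' Removes probes whose gene symbol is not in the whitelist (emulating the
#' exclusion of symbols that cannot be resolved in a nomenclature
#' database); the surviving unique symbols form the gene universe.
#'
#' @param bundle an `expr_bundle`.
#' @param whitelist nonempty character vector of accepted symbols.
#' @return The filtered bundle; its `n_genes_surviving` attribute records
#'   the size of the surviving gene universe (also reported via `message`).
#' @export
filter_probes <- function(bundle, whitelist) {
  stopifnot(inherits(bundle, "expr_bundle"))
  if (!length(whitelist)) abort("'whitelist' must be nonempty")
  keep <- bundle$probes$gene %in% whitelist
  if (!any(keep)) abort("no probes survive the whitelist filter")
  bundle$probes <- bundle$probes[keep, , drop = FALSE]
  bundle$expr <- bundle$expr[keep, , drop = FALSE]
  n_genes <- length(unique(bundle$probes$gene))
  message(sprintf("whitelist filter: %d probes retained, %d unique genes",
                  sum(keep), n_genes))
  attr(bundle, "n_genes_surviving") <- n_genes
  bundle
}

#' Average probes of the same gene
#'
#' Per (gene, sample), the arithmetic mean over that gene's probes.
#'
#' @param bundle an `expr_bundle` (typically after [filter_probes()]).
#' @return Numeric gene x sample matrix, genes in sorted order.
#' @export
collapse_probes <- function(bundle) {
  stopifnot(inherits(bundle, "expr_bundle"))
  gene <- factor(bundle$probes$gene)
  out <- rowsum(bundle$expr, gene) / as.vector(table(gene))
  rownames(out) <- levels(gene)
  out
}

#' Assign expression samples to atlas regions
#'
#' Label-volume mode: each sample's MNI coordinate is mapped to the voxel
#' containing it (0-based indices via the inverse affine); if that voxel is
#' background, the nearest labeled voxel within `max_dist_mm` is used, else
#' the sample stays unassigned. Table mode (no volume in the atlas): the
#' samples' own `region` column is passed through.
#'
#' @param samples data.frame with `sample_id`, `x`, `y`, `z` (mm) and, for
#'   table mode, a `region` column.
#' @param atlas a `gmv_atlas`; volume mode requires `volume` + `affine`.
#' @param max_dist_mm search radius for background coordinates.
#' @return The samples data.frame with a `region` column (`NA` =
#'   unassigned, with a warning naming the count).
#' @export
assign_samples <- function(samples, atlas, max_dist_mm = 2) {
  stopifnot(inherits(atlas, "gmv_atlas"))
  if (is.null(atlas$volume)) {
    if (is.null(samples$region)) {
      abort("table-mode assignment needs a 'region' column in 'samples'")
    }
    bad <- !is.na(samples$region) & !samples$region %in% atlas$regions$id
    if (any(bad)) {
      abort(sprintf("sample regions not in the atlas: %s",
                    paste(unique(samples$region[bad]), collapse = ", ")))
    }
    return(samples)
  }
  dims <- dim(atlas$volume)
  inv <- solve(atlas$affine)
  mm <- cbind(samples$x, samples$y, samples$z, 1)
  vox0 <- mm %*% t(inv)  # 0-based continuous voxel coordinates
  vox <- round(vox0[, 1:3, drop = FALSE]) + 1  # containing voxel, 1-based
  region <- rep(NA_character_, nrow(samples))

  labeled <- which(atlas$volume > 0, arr.ind = TRUE)
  lab_mm <- (labeled - 1) %*% t(atlas$affine[1:3, 1:3]) +
    matrix(atlas$affine[1:3, 4], nrow(labeled), 3, byrow = TRUE)
  lab_val <- atlas$volume[labeled]

  outside <- 0L
  for (i in seq_len(nrow(samples))) {
    v <- vox[i, ]
    if (any(v < 1) || any(v > dims)) {
      outside <- outside + 1L
      next
    }
    lab <- atlas$volume[v[1], v[2], v[3]]
    if (lab == 0L) {
      d2 <- rowSums(sweep(lab_mm, 2, mm[i, 1:3], "-")^2)
      j <- which.min(d2)
      if (sqrt(d2[j]) <= max_dist_mm) lab <- lab_val[j]
    }
    if (lab > 0L) region[i] <- atlas$regions$id[lab]
  }
  if (outside > 0L) {
    warning(sprintf("%d sample(s) fall outside the label volume bounds", outside))
  }
  n_un <- sum(is.na(region))
  if (n_un > 0L) {
    warning(sprintf("%d sample(s) unassigned (background beyond %g mm)",
                    n_un, max_dist_mm))
  }
  samples$region <- region
  samples
}

#' Select the analysis regions
#'
#' Applies the hemispheric selection rule: keep all left-hemisphere
#' supratentorial regions, plus the right cerebellum merged into a single
#' analysis region (its strong anatomical connection to the left cerebral
#' hemisphere motivates including it on this side of the analysis). Order
#' is deterministic by region id, the merged cerebellum last.
#'
#' @param atlas a `gmv_atlas` with populated `hemisphere`,
#'   `supratentorial`, `cerebellum` flags.
#' @return A `gmv_regions` data.frame (`id`, `name`, `n_members`) whose
#'   `members` attribute maps each analysis region id to its constituent
#'   atlas label ids.
#' @export
select_analysis_regions <- function(atlas) {
  stopifnot(inherits(atlas, "gmv_atlas"))
  rt <- atlas$regions
  left <- rt[rt$hemisphere %in% "L" & rt$supratentorial & !rt$cerebellum, ,
             drop = FALSE]
  if (nrow(left) == 0L) abort("no left-hemisphere supratentorial regions in the atlas")
  left <- left[order(left$id), , drop = FALSE]
  members <- as.list(stats::setNames(left$id, left$id))
  out <- data.frame(id = left$id, name = left$name,
                    n_members = 1L, stringsAsFactors = FALSE)
  cbr <- rt[rt$cerebellum & rt$hemisphere %in% "R", , drop = FALSE]
  if (nrow(cbr) > 0L) {
    out <- rbind(out, data.frame(id = "cerebellum_R", name = "right cerebellum",
                                 n_members = nrow(cbr), stringsAsFactors = FALSE))
    members$cerebellum_R <- cbr$id
  } else {
    warning("atlas has no right-cerebellum label; proceeding without it")
  }
  structure(out, members = members, class = c("gmv_regions", "data.frame"))
}

#' Regionize a gene x sample matrix
#'
#' Represents each analysis region by the median over its assigned samples
#' (the median is robust to outlying samples). Pooled scope takes the
#' median over all donors' samples; single-donor scope restricts to one
#' donor's samples, supporting the per-donor variability analysis.
#'
#' @param gene_by_sample numeric matrix (genes x samples) from
#'   [collapse_probes()].
#' @param samples data.frame with `sample_id`, `donor` and assigned
#'   `region` (atlas label ids; `NA` = unassigned, ignored).
#' @param regions a `gmv_regions` from [select_analysis_regions()] (or a
#'   character vector of region ids mapped one-to-one).
#' @param donor_scope `"pooled"` or a donor id.
#' @param min_samples minimum contributing samples per retained region;
#'   regions below it are dropped with a warning.
#' @return A `region_expr` matrix (genes x retained regions) with
#'   attributes `scope`, `n_samples` (per region) and `dropped`.
#' @export
regionize <- function(gene_by_sample, samples, regions,
                      donor_scope = "pooled", min_samples = 1L) {
  if (is.character(regions)) {
    regions <- structure(
      data.frame(id = regions, name = regions, n_members = 1L,
                 stringsAsFactors = FALSE),
      members = as.list(stats::setNames(regions, regions)),
      class = c("gmv_regions", "data.frame"))
  }
  members <- attr(regions, "members")
  sam <- samples[!is.na(samples$region), , drop = FALSE]
  if (!identical(donor_scope, "pooled")) {
    sam <- sam[sam$donor == donor_scope, , drop = FALSE]
  }
  mat <- gene_by_sample[, sam$sample_id, drop = FALSE]
  out <- matrix(NA_real_, nrow(gene_by_sample), nrow(regions),
                dimnames = list(rownames(gene_by_sample), regions$id))
  n_samples <- stats::setNames(integer(nrow(regions)), regions$id)
  for (r in regions$id) {
    cols <- sam$region %in% members[[r]]
    n_samples[r] <- sum(cols)
    if (n_samples[r] >= 1L) {
      block <- mat[, cols, drop = FALSE]
      out[, r] <- if (ncol(block) == 1L) block[, 1] else
        apply(block, 1, stats::median)
    }
  }
  drop <- n_samples < max(1L, min_samples)
  if (all(drop)) abort("all regions dropped: no region meets 'min_samples'")
  if (any(drop)) {
    warning(sprintf("dropping region(s) with < %d samples: %s", min_samples,
                    paste(regions$id[drop], collapse = ", ")))
  }
  structure(out[, !drop, drop = FALSE], scope = donor_scope,
            n_samples = n_samples[!drop], dropped = regions$id[drop],
            class = c("region_expr", class(out)))
}
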