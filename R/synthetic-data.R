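# Synthetic-data generators with known ground truth: longitudinal GMV
# cohorts, an AAL-like atlas, donor expression bundles, and gene-set
# catalogs. Every downstream stage of the pipeline is testable against
# the planted truth without any external download.

#' Specify a synthetic longitudinal cohort
#'
#' Describes a longitudinal voxel-based-morphometry-style cohort: subjects in
#' named groups (`control`, `persistent`, optionally `recovered`), each with
#' one or more annual scans, per-scan covariates (sex, IQ, brain size,
#' socioeconomic status, stuttering severity for the stuttering groups), and
#' a regional gray-matter-volume (GMV) response generated as
#'
#' \deqn{y_{ijr} = \mu_r + u_i + \delta_r g_i + \gamma_r g_i (a_{ij}-\bar a)
#'       + x_{ij}^\top \beta + \varepsilon_{ijr}}
#'
#' with subject random intercept \eqn{u_i \sim N(0, \code{subject_sd}^2)} and
#' residual \eqn{\varepsilon \sim N(0, \code{noise_sd}^2)}. `effect_map`
#' (\eqn{\delta_r}) holds the true group difference the GLM must recover.
#'
#' @param n_per_group named integer vector of subjects per group; names are
#'   group labels, `"control"` required. Default mirrors a cohort of 44
#'   controls and 26 children with persistent stuttering.
#' @param visits_per_subject integer or length-2 range of scans per subject
#'   (inter-visit spacing is fixed at 1 year).
#' @param age_range numeric length 2, years; age at first visit is uniform.
#' @param effect_map named numeric, region -> group effect (GMV units) for
#'   the `persistent` group; regions not named get 0.
#' @param age_slope_map named numeric, region -> group-by-age interaction.
#' @param covariate_effects named numeric coefficients applied to centered
#'   covariates (`sex`, `iq`, `brain_size`, `ses`, `severity`); default all 0.
#' @param noise_sd,subject_sd residual and random-intercept SDs (GMV units).
#' @param baseline region baseline GMV (single value or named per-region).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return An object of class `cohort_spec`.
#' @seealso [gen_cohort()]
#' @export
cohort_spec <- function(n_per_group = c(control = 44, persistent = 26),
                        visits_per_subject = c(1, 5),
                        age_range = c(3, 10),
                        effect_map = NULL,
                        age_slope_map = NULL,
                        covariate_effects = NULL,
                        noise_sd = 0.5,
                        subject_sd = 0.5,
                        baseline = 10,
                        seed = 1L) {
  if (is.null(names(n_per_group)) || !"control" %in% names(n_per_group)) {
    abort("'n_per_group' must be a named vector including a 'control' group")
  }
  if (any(n_per_group < 2)) {
    abort("'n_per_group' must be >= 2 for every group")
  }
  if (any(visits_per_subject < 1)) {
    abort("'visits_per_subject' must be >= 1")
  }
  check_number(noise_sd, "noise_sd", lower = 1e-12)
  check_number(subject_sd, "subject_sd", lower = 0)
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    abort("'age_range' must be an increasing length-2 numeric")
  }
  structure(list(
    n_per_group = n_per_group,
    visits_per_subject = visits_per_subject,
    age_range = age_range,
    effect_map = effect_map,
    age_slope_map = age_slope_map,
    covariate_effects = covariate_effects,
    noise_sd = noise_sd,
    subject_sd = subject_sd,
    baseline = baseline,
    seed = seed
  ), class = "cohort_spec")
}

map_over_regions <- function(map, regions, what) {
  out <- stats::setNames(rep(0, length(regions)), regions)
  if (!is.null(map)) {
    bad <- setdiff(names(map), regions)
    if (length(bad)) {
      abort(sprintf("'%s' names unknown regions: %s", what,
                    paste(bad, collapse = ", ")))
    }
    out[names(map)] <- map
  }
  out
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a [cohort_spec()] cohort over the given regions. Covariates use
#' printed-plausible population values: IQ ~ N(110, 13), brain size ~
#' N(1100, 100) cm^3, SES ~ N(50, 10), sex Bernoulli(0.5); stuttering
#' severity (an SSI-4-like score, ~N(20, 6) truncated at 0) is drawn only
#' for non-control groups and is `NA` for controls -- the design builder
#' codes it zero there.
#'
#' @param spec a [cohort_spec()].
#' @param regions character vector of region ids (response columns).
#' @return A `gmv_cohort`: list with `scans` (one row per scan: `scan_id`,
#'   `subject`, `group`, `age`, `sex`, `iq`, `brain_size`, `ses`,
#'   `severity`), `gmv` (scan x region matrix), `regions`, and a `truth`
#'   attribute recording the planted effects.
#' @export
gen_cohort <- function(spec, regions) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (length(regions) < 1L) abort("'regions' must be nonempty")
  regions <- as.character(regions)
  effect <- map_over_regions(spec$effect_map, regions, "effect_map")
  slope <- map_over_regions(spec$age_slope_map, regions, "age_slope_map")
  base <- if (length(spec$baseline) == 1L) {
    stats::setNames(rep(spec$baseline, length(regions)), regions)
  } else {
    map_over_regions(spec$baseline, regions, "baseline")
  }
  ce <- spec$covariate_effects %||% numeric()

  with_seed(spec$seed, {
    groups <- rep(names(spec$n_per_group), spec$n_per_group)
    n_subj <- length(groups)
    subject <- sprintf("S%03d", seq_len(n_subj))
    visits <- draw_count(spec$visits_per_subject, n_subj)
    u <- stats::rnorm(n_subj, 0, spec$subject_sd)
    age0 <- stats::runif(n_subj, spec$age_range[1], spec$age_range[2])
    sex <- sample(c("M", "F"), n_subj, replace = TRUE)
    iq <- stats::rnorm(n_subj, 110, 13)
    brain <- stats::rnorm(n_subj, 1100, 100)
    ses <- stats::rnorm(n_subj, 50, 10)
    sev <- ifelse(groups == "control", NA_real_,
                  pmax(0, stats::rnorm(n_subj, 20, 6)))

    idx <- rep(seq_len(n_subj), visits)
    scans <- data.frame(
      scan_id = sprintf("%s_v%d", subject[idx],
                        sequence(visits)),
      subject = subject[idx],
      group = groups[idx],
      age = age0[idx] + (sequence(visits) - 1),
      sex = sex[idx],
      iq = iq[idx],
      brain_size = brain[idx],
      ses = ses[idx],
      severity = sev[idx],
      stringsAsFactors = FALSE
    )
    abar <- mean(scans$age)
    g <- as.numeric(scans$group == "persistent")
    # centered covariate contributions; severity enters as 0 for controls
    covmat <- cbind(
      sex = as.numeric(scans$sex == "F") - 0.5,
      iq = scans$iq - 110,
      brain_size = scans$brain_size - 1100,
      ses = scans$ses - 50,
      severity = ifelse(is.na(scans$severity), 0, scans$severity - 20)
    )
    covterm <- if (length(ce)) {
      drop(covmat[, names(ce), drop = FALSE] %*% ce)
    } else 0

    n_scan <- nrow(scans)
    eps <- matrix(stats::rnorm(n_scan * length(regions), 0, spec$noise_sd),
                  n_scan, length(regions))
    gmv <- matrix(base, n_scan, length(regions), byrow = TRUE) +
      u[idx] + covterm +
      outer(g, effect) + outer(g * (scans$age - abar), slope) + eps
    dimnames(gmv) <- list(scans$scan_id, regions)

    structure(list(scans = scans, gmv = gmv, regions = regions),
              truth = list(effect_map = effect, age_slope_map = slope,
                           baseline = base, age_mean = abar),
              class = "gmv_cohort")
  })
}

#' @export
print.gmv_cohort <- function(x, ...) {
  cat(sprintf("<gmv_cohort> %d scans, %d subjects (%s), %d regions\n",
              nrow(x$scans), length(unique(x$scans$subject)),
              paste(sprintf("%s=%d", names(table(x$scans$group[!duplicated(x$scans$subject)])),
                            table(x$scans$group[!duplicated(x$scans$subject)])),
                    collapse = ", "),
              length(x$regions)))
  invisible(x)
}

#' Generate an AAL-like atlas
#'
#' Builds a region table emulating an automated-anatomical-labeling
#' parcellation: `n_per_hemisphere` supratentorial regions in each
#' hemisphere plus one cerebellar region per hemisphere. Optionally also
#' builds a label volume: region centroids are placed in a brain-shaped
#' bounding box (left regions at x < 0) and every in-box voxel is labeled
#' by its nearest centroid, giving a Voronoi parcellation usable by
#' [assign_samples()].
#'
#' @param n_per_hemisphere supratentorial regions per hemisphere (45 for the
#'   standard 90-region parcellation).
#' @param cerebellum include cerebellar regions (flagged, infratentorial).
#' @param with_volume also generate a label volume.
#' @param grid,voxel_size label-volume dimensions (voxels) and isotropic
#'   voxel size in mm; the volume is centered on the origin so MNI-style
#'   x < 0 is the left hemisphere.
#' @param seed integer seed for centroid placement.
#' @return A `gmv_atlas`: list with `regions` (columns `id`, `name`,
#'   `hemisphere`, `supratentorial`, `cerebellum`), and if requested
#'   `volume` (integer 3-D array of region indices, 0 = background),
#'   `affine` (voxel -> mm, 0-based indices) and `centroids` (mm).
#' @export
gen_atlas <- function(n_per_hemisphere = 45, cerebellum = TRUE,
                      with_volume = FALSE, grid = c(24, 28, 24),
                      voxel_size = 6, seed = 1L) {
  ids <- c(sprintf("L_%02d", seq_len(n_per_hemisphere)),
           sprintf("R_%02d", seq_len(n_per_hemisphere)))
  regions <- data.frame(
    id = ids,
    name = paste0("region_", ids),
    hemisphere = rep(c("L", "R"), each = n_per_hemisphere),
    supratentorial = TRUE,
    cerebellum = FALSE,
    stringsAsFactors = FALSE
  )
  if (cerebellum) {
    regions <- rbind(regions, data.frame(
      id = c("Cbe_L", "Cbe_R"),
      name = c("cerebellum_left", "cerebellum_right"),
      hemisphere = c("L", "R"),
      supratentorial = FALSE,
      cerebellum = TRUE,
      stringsAsFactors = FALSE
    ))
  }
  atlas <- structure(list(regions = regions), class = "gmv_atlas")
  if (!with_volume) return(atlas)

  with_seed(seed, {
    ext <- grid * voxel_size
    # affine: 0-based voxel index -> mm, volume centered at the origin
    affine <- diag(c(rep(voxel_size, 3), 1))
    affine[1:3, 4] <- -(grid - 1) / 2 * voxel_size
    n_reg <- nrow(regions)
    # supratentorial centroids in the upper 3/4 of z; cerebellum low posterior
    cz <- ifelse(regions$cerebellum,
                 stats::runif(n_reg, -ext[3] / 2 + voxel_size, -ext[3] / 4),
                 stats::runif(n_reg, -ext[3] / 8, ext[3] / 2 - voxel_size))
    cy <- ifelse(regions$cerebellum,
                 stats::runif(n_reg, -ext[2] / 2 + voxel_size, -ext[2] / 4),
                 stats::runif(n_reg, -ext[2] / 2 + voxel_size,
                              ext[2] / 2 - voxel_size))
    half <- ext[1] / 2 - voxel_size
    cx <- ifelse(regions$hemisphere == "L",
                 stats::runif(n_reg, -half, -voxel_size / 2),
                 stats::runif(n_reg, voxel_size / 2, half))
    centroids <- cbind(x = cx, y = cy, z = cz)
    rownames(centroids) <- regions$id

    vx <- expand.grid(i = seq_len(grid[1]) - 1, j = seq_len(grid[2]) - 1,
                      k = seq_len(grid[3]) - 1)
    mm <- as.matrix(vx) * voxel_size +
      matrix(affine[1:3, 4], nrow(vx), 3, byrow = TRUE)
    # nearest centroid, hemisphere-respecting (no label crosses the midline)
    d2 <- outer(rowSums(mm^2), rep(1, n_reg)) - 2 * mm %*% t(centroids) +
      outer(rep(1, nrow(mm)), rowSums(centroids^2))
    left_vox <- mm[, 1] < 0
    left_reg <- regions$hemisphere == "L"
    d2[left_vox, !left_reg] <- Inf
    d2[!left_vox, left_reg] <- Inf
    lab <- max.col(-d2, ties.method = "first")
    # carve a background shell so out-of-brain coordinates exist
    r2 <- (mm[, 1] / (ext[1] / 2))^2 + (mm[, 2] / (ext[2] / 2))^2 +
      (mm[, 3] / (ext[3] / 2))^2
    lab[r2 > 1] <- 0L
    atlas$volume <- array(as.integer(lab), dim = grid)
    atlas$affine <- affine
    atlas$centroids <- centroids
    atlas
  })
}

#' Specify a synthetic donor expression bundle
#'
#' Describes a microarray-style expression resource emulating a multi-donor
#' brain-wide sampling: `n_genes` genes measured by `probes_per_gene` probes
#' in `samples_per_region` samples per region *per donor*. A subset of
#' `n_causal` "causal" genes have regional expression that tracks the rank
#' of the absolute regional group effect with strength `coupling`: the
#' gene-level regional signal is
#' \deqn{s_r = c \, z(\mathrm{rank}|\delta_r|) + \sqrt{1 - c^2}\, \eta_r}
#' with \eqn{z} standardization and \eqn{\eta_r \sim N(0,1)} independent per
#' gene, so `coupling` = 1 gives a perfect monotone link in rank space and
#' `coupling` = 0 gives spatial independence. Non-causal genes get
#' independent regional profiles.
#'
#' @param n_genes,n_causal gene universe size and number of causal genes.
#' @param probes_per_gene,samples_per_region integer or range.
#' @param n_donors number of donors (the emulated resource has six).
#' @param coupling monotone link strength in \[0, 1\].
#' @param expr_noise_sd sample-level measurement noise SD (log-intensity).
#' @param whitelist_frac fraction of gene symbols covered by the generated
#'   symbol whitelist (causal genes are always covered).
#' @param seed integer seed.
#' @return An object of class `expression_spec`.
#' @export
expression_spec <- function(n_genes = 500, n_causal = 10,
                            probes_per_gene = 2, samples_per_region = 3,
                            n_donors = 6, coupling = 1,
                            expr_noise_sd = 0.5, whitelist_frac = 1,
                            seed = 1L) {
  if (n_causal > n_genes) abort("'n_causal' must be <= 'n_genes'")
  if (n_donors < 1) abort("'n_donors' must be >= 1")
  check_number(coupling, "coupling", lower = 0, upper = 1)
  check_number(expr_noise_sd, "expr_noise_sd", lower = 0)
  check_number(whitelist_frac, "whitelist_frac", lower = 0, upper = 1)
  structure(list(
    n_genes = n_genes, n_causal = n_causal,
    probes_per_gene = probes_per_gene,
    samples_per_region = samples_per_region,
    n_donors = n_donors, coupling = coupling,
    expr_noise_sd = expr_noise_sd, whitelist_frac = whitelist_frac,
    seed = seed
  ), class = "expression_spec")
}

#' Generate a synthetic donor expression bundle
#'
#' @param spec an [expression_spec()].
#' @param regions character vector of region ids samples are drawn from
#'   (typically atlas label ids).
#' @param effect_map named numeric covering every region; its absolute value
#'   drives the causal genes' regional signal.
#' @param atlas optional `gmv_atlas` with a label volume; if supplied,
#'   sample MNI coordinates are drawn uniformly within each region's
#'   labeled voxels (plus sub-voxel jitter), so volume-based assignment
#'   recovers the true region. Without an atlas, coordinates are synthetic
#'   points around per-region centroids.
#' @return An `expr_bundle`: list with `probes` (probe -> gene), `samples`
#'   (`sample_id`, `donor`, `x`, `y`, `z`, `region` truth column), `expr`
#'   (probe x sample matrix of log-intensities), `whitelist` (character),
#'   and a `truth` attribute (`causal_genes`, gene x region signal matrix).
#' @export
gen_expression <- function(spec, regions, effect_map, atlas = NULL) {
  stopifnot(inherits(spec, "expression_spec"))
  regions <- as.character(regions)
  if (!all(regions %in% names(effect_map))) {
    abort("'effect_map' must cover all regions")
  }
  eff <- abs(effect_map[regions])

  with_seed(spec$seed, {
    genes <- sprintf("GENE%04d", seq_len(spec$n_genes))
    causal <- if (spec$n_causal > 0) genes[seq_len(spec$n_causal)] else character()
    n_reg <- length(regions)

    # gene-level regional signal in rank space (standardized rank of |effect|)
    zr <- as.numeric(scale(rank(eff)))
    noise <- matrix(stats::rnorm(spec$n_genes * n_reg), spec$n_genes, n_reg)
    signal <- noise
    if (length(causal)) {
      c2 <- spec$coupling
      signal[seq_along(causal), ] <-
        c2 * matrix(zr, length(causal), n_reg, byrow = TRUE) +
        sqrt(1 - c2^2) * noise[seq_along(causal), , drop = FALSE]
    }
    dimnames(signal) <- list(genes, regions)
    gene_mean <- stats::rnorm(spec$n_genes, 7, 1)

    # probes
    npp <- draw_count(spec$probes_per_gene, spec$n_genes)
    probes <- data.frame(
      probe = sprintf("P%05d", seq_len(sum(npp))),
      gene = rep(genes, npp),
      stringsAsFactors = FALSE
    )
    probe_offset <- stats::rnorm(nrow(probes), 0, 0.3)

    # samples: per region, per donor
    donors <- sprintf("D%d", seq_len(spec$n_donors))
    nspr <- draw_count(spec$samples_per_region, n_reg * spec$n_donors)
    samples <- data.frame(
      donor = rep(rep(donors, each = n_reg), nspr),
      region = rep(rep(regions, spec$n_donors), nspr),
      stringsAsFactors = FALSE
    )
    samples$sample_id <- sprintf("SMP%05d", seq_len(nrow(samples)))
    xyz <- sample_coordinates(samples$region, regions, atlas)
    samples <- cbind(samples[c("sample_id", "donor")], xyz,
                     region = samples$region, stringsAsFactors = FALSE)

    # expression: gene signal + probe offset + measurement noise
    gidx <- match(probes$gene, genes)
    ridx <- match(samples$region, regions)
    expr <- gene_mean[gidx] + signal[cbind(rep(gidx, nrow(samples)),
                                           rep(ridx, each = nrow(probes)))]
    expr <- matrix(expr, nrow(probes), nrow(samples)) + probe_offset +
      stats::rnorm(nrow(probes) * nrow(samples), 0, spec$expr_noise_sd)
    dimnames(expr) <- list(probes$probe, samples$sample_id)

    n_wl <- max(floor(spec$whitelist_frac * spec$n_genes), length(causal))
    whitelist <- sort(union(causal, sample(setdiff(genes, causal),
                                           max(0, n_wl - length(causal)))))

    structure(list(probes = probes, samples = samples, expr = expr,
                   whitelist = whitelist),
              truth = list(causal_genes = causal, signal = signal),
              class = "expr_bundle")
  })
}

# Draw one MNI coordinate per sample. With a label volume, pick a uniform
# voxel among the region's voxels plus jitter; otherwise scatter around a
# synthetic per-region centroid (left-hemisphere-style x < 0).
sample_coordinates <- function(sample_region, regions, atlas) {
  n <- length(sample_region)
  if (!is.null(atlas) && !is.null(atlas$volume)) {
    vs <- atlas$affine[1, 1]
    out <- matrix(NA_real_, n, 3)
    reg_index <- match(regions, atlas$regions$id)
    for (r in seq_along(regions)) {
      sel <- which(sample_region == regions[r])
      if (!length(sel)) next
      vox <- which(atlas$volume == reg_index[r], arr.ind = TRUE)
      if (nrow(vox) == 0L) {
        abort(sprintf("region '%s' has no voxels in the atlas volume", regions[r]))
      }
      pick <- vox[sample.int(nrow(vox), length(sel), replace = TRUE), ,
                  drop = FALSE]
      mm <- (pick - 1) %*% t(atlas$affine[1:3, 1:3]) +
        matrix(atlas$affine[1:3, 4], length(sel), 3, byrow = TRUE)
      out[sel, ] <- mm + matrix(stats::runif(3 * length(sel), -vs / 4, vs / 4),
                                length(sel), 3)
    }
    colnames(out) <- c("x", "y", "z")
    return(as.data.frame(out))
  }
  cent <- cbind(x = stats::runif(length(regions), -60, -5),
                y = stats::runif(length(regions), -80, 60),
                z = stats::runif(length(regions), -40, 60))
  ridx <- match(sample_region, regions)
  out <- cent[ridx, , drop = FALSE] + matrix(stats::rnorm(3 * n, 0, 2), n, 3)
  as.data.frame(out)
}

#' @export
print.expr_bundle <- function(x, ...) {
  cat(sprintf(
    "<expr_bundle> %d probes / %d genes x %d samples, %d donors, %d whitelisted symbols\n",
    nrow(x$probes), length(unique(x$probes$gene)), nrow(x$samples),
    length(unique(x$samples$donor)), length(x$whitelist)))
  invisible(x)
}

#' Specify a synthetic gene-set catalog
#'
#' @param n_categories number of gene sets.
#' @param category_size_range length-2 integer range of member counts.
#' @param causal_enriched_categories number of categories planted to draw at
#'   least 80% of their members from the causal genes.
#' @param seed integer seed.
#' @return An object of class `catalog_spec`.
#' @export
catalog_spec <- function(n_categories = 20, category_size_range = c(10, 50),
                         causal_enriched_categories = 2, seed = 1L) {
  if (any(category_size_range < 1)) abort("category sizes must be >= 1")
  if (causal_enriched_categories > n_categories) {
    abort("'causal_enriched_categories' must be <= 'n_categories'")
  }
  structure(list(n_categories = n_categories,
                 category_size_range = category_size_range,
                 causal_enriched_categories = causal_enriched_categories,
                 seed = seed), class = "catalog_spec")
}

#' Generate a synthetic gene-set catalog
#'
#' Random categories drawn from the gene universe; the designated enriched
#' categories take at least 80% of their members from `causal_genes` (their
#' size is capped so that is feasible).
#'
#' @param spec a [catalog_spec()].
#' @param genes gene universe (character).
#' @param causal_genes subset of `genes` to enrich for.
#' @return A `gene_catalog`: list of categories, each `list(id, name,
#'   genes)`, with a `truth` attribute naming the enriched category ids.
#' @export
gen_catalog <- function(spec, genes, causal_genes = character()) {
  stopifnot(inherits(spec, "catalog_spec"))
  if (!all(causal_genes %in% genes)) {
    abort("'causal_genes' must be a subset of 'genes'")
  }
  with_seed(spec$seed, {
    sizes <- draw_count(spec$category_size_range, spec$n_categories)
    enriched <- seq_len(spec$causal_enriched_categories)
    cats <- vector("list", spec$n_categories)
    for (i in seq_len(spec$n_categories)) {
      if (i %in% enriched && length(causal_genes)) {
        size <- min(sizes[i], max(1L, floor(length(causal_genes) / 0.8)))
        n_causal <- ceiling(0.8 * size)
        members <- c(sample(causal_genes, min(n_causal, length(causal_genes))),
                     sample(setdiff(genes, causal_genes), size - n_causal))
      } else {
        members <- sample(genes, sizes[i])
      }
      cats[[i]] <- list(id = sprintf("CAT%03d", i),
                        name = if (i %in% enriched && length(causal_genes))
                          "planted_enriched" else "random_category",
                        genes = sort(members))
    }
    structure(cats,
              truth = list(enriched_ids = sprintf("CAT%03d", enriched)),
              class = "gene_catalog")
  })
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("<gene_catalog> %d categories, sizes %s\n", length(x),
              paste(range(vapply(x, function(c) length(c$genes), 1L)),
                    collapse = "-")))
  invisible(x)
}
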