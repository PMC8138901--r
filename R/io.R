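# File formats: scan table CSV + GMV TSV, probe/sample/expression tables,
# whitelist TXT, atlas region CSV + optional NIfTI label volume, GMT
# catalogs, YAML pipeline configuration. Writers and readers round-trip.

fmt_num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

write_tsv_matrix <- function(mat, path, id_col) {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_matrix <- function(path, id_col) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != id_col) {
    abort(sprintf("%s: expected first column '%s', found '%s'", path, id_col,
                  names(df)[1]))
  }
  ids <- df[[1]]
  df <- df[, -1, drop = FALSE]
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1]
      abort(sprintf("%s: non-numeric value in column '%s', row %d (%s)",
                    path, names(df)[j], bad, df[[j]][bad]))
    }
  }
  mat <- as.matrix(df)
  rownames(mat) <- ids
  mat
}

#' Write / read a longitudinal cohort
#'
#' The cohort is stored as a scan table CSV (one row per scan, named
#' covariate columns; severity empty for controls) plus a scan x region
#' GMV response TSV.
#'
#' @param cohort a `gmv_cohort`.
#' @param scans_path,gmv_path file paths.
#' @return `read_cohort()` returns a validated `gmv_cohort`.
#' @export
write_cohort <- function(cohort, scans_path, gmv_path) {
  utils::write.csv(cohort$scans, scans_path, row.names = FALSE, quote = FALSE,
                   na = "")
  write_tsv_matrix(cohort$gmv, gmv_path, "scan_id")
  invisible(c(scans_path, gmv_path))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(scans_path, gmv_path) {
  scans <- utils::read.csv(scans_path, stringsAsFactors = FALSE)
  gmv <- read_tsv_matrix(gmv_path, "scan_id")
  need <- c("scan_id", "subject", "group", "age", "sex", "iq", "brain_size",
            "ses", "severity")
  miss <- setdiff(need, names(scans))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s) %s", scans_path,
                  paste(miss, collapse = ", ")))
  }
  if (!setequal(scans$scan_id, rownames(gmv))) {
    abort("scan table and GMV matrix disagree on scan ids")
  }
  gmv <- gmv[scans$scan_id, , drop = FALSE]
  if (any(!is.finite(gmv))) abort("GMV matrix contains non-finite values")
  # severity present iff group is a stuttering group
  bad <- scans$scan_id[scans$group != "control" & !is.finite(scans$severity)]
  if (length(bad)) {
    abort(sprintf("stuttering-group scans missing severity: %s",
                  paste(bad, collapse = ", ")))
  }
  structure(list(scans = scans, gmv = gmv, regions = colnames(gmv)),
            class = "gmv_cohort")
}

#' Write / read a donor expression bundle
#'
#' Stored as probes TSV (`probe`, `gene`), samples CSV (`sample_id`,
#' `donor`, `x`, `y`, `z`, optional `region`), probe x sample expression
#' TSV and a one-symbol-per-line whitelist.
#'
#' @param bundle an `expr_bundle`.
#' @param dir directory (created if needed); files `probes.tsv`,
#'   `samples.csv`, `expr.tsv`, `whitelist.txt`.
#' @return `read_bundle()` returns a validated `expr_bundle`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(bundle$probes, file.path(dir, "probes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(bundle$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE, quote = FALSE)
  write_tsv_matrix(bundle$expr, file.path(dir, "expr.tsv"), "probe")
  writeLines(bundle$whitelist, file.path(dir, "whitelist.txt"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  probes <- utils::read.delim(file.path(dir, "probes.tsv"),
                              stringsAsFactors = FALSE)
  samples <- utils::read.csv(file.path(dir, "samples.csv"),
                             stringsAsFactors = FALSE)
  expr <- read_tsv_matrix(file.path(dir, "expr.tsv"), "probe")
  whitelist <- readLines(file.path(dir, "whitelist.txt"))
  if (!identical(rownames(expr), probes$probe)) {
    abort("expression rows do not match the probe table")
  }
  if (!identical(colnames(expr), samples$sample_id)) {
    abort("expression columns do not match the sample table")
  }
  if (any(!is.finite(as.matrix(samples[c("x", "y", "z")])))) {
    abort("sample coordinates must be finite")
  }
  structure(list(probes = probes, samples = samples, expr = expr,
                 whitelist = whitelist), class = "expr_bundle")
}

#' Write / read an atlas
#'
#' Region metadata CSV (`id`, `name`, `hemisphere`, `supratentorial`,
#' `cerebellum`) plus an optional NIfTI label volume whose voxel values
#' index the region table rows (0 = background); the NIfTI sform carries
#' the voxel-to-mm affine.
#'
#' @param atlas a `gmv_atlas`.
#' @param regions_path region table CSV path.
#' @param volume_path optional `.nii`/`.nii.gz` path for the label volume.
#' @return `read_atlas()` returns a `gmv_atlas`.
#' @export
write_atlas <- function(atlas, regions_path, volume_path = NULL) {
  utils::write.csv(atlas$regions, regions_path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(volume_path)) {
    if (is.null(atlas$volume)) abort("atlas has no label volume to write")
    img <- RNifti::asNifti(atlas$volume)
    img <- RNifti::`sform<-`(img, structure(atlas$affine, code = 2L))
    RNifti::writeNifti(img, volume_path)
  }
  invisible(regions_path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(regions_path, volume_path = NULL) {
  regions <- utils::read.csv(regions_path, stringsAsFactors = FALSE)
  need <- c("id", "name", "hemisphere", "supratentorial", "cerebellum")
  miss <- setdiff(need, names(regions))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s) %s", regions_path,
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(regions$id)) abort("atlas region ids must be unique")
  atlas <- structure(list(regions = regions), class = "gmv_atlas")
  if (!is.null(volume_path)) {
    img <- RNifti::readNifti(volume_path)
    vol <- array(as.integer(round(as.array(img))), dim = dim(img))
    if (max(vol) > nrow(regions)) {
      abort("label volume contains values beyond the region table")
    }
    atlas$volume <- vol
    aff <- RNifti::xform(img)
    attributes(aff) <- list(dim = dim(aff))
    atlas$affine <- aff
  }
  atlas
}

#' Read / write gene-set catalogs in GMT format
#'
#' One category per line: id, description, then member gene symbols, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @param catalog a `gene_catalog`.
#' @return `read_gmt()` returns a `gene_catalog`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cats <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(sprintf("%s: line %d has fewer than 3 fields", path, i))
    }
    list(id = f[1], name = f[2], genes = unique(f[-(1:2)]))
  })
  structure(cats, class = "gene_catalog")
}

#' @rdname read_gmt
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(catalog, function(cat) {
    paste(c(cat$id, cat$name, cat$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' A single YAML-serializable document naming every input path and stage
#' parameter. [read_config()] / [write_config()] round-trip it;
#' [validate_config()] checks paths and parameter ranges.
#'
#' @param paths named list: `scans`, `gmv`, `bundle_dir`, `atlas_regions`,
#'   `catalog`, optional `atlas_volume`.
#' @param params named list of stage parameters; defaults:
#'   `groups = c("control", "persistent")`, `mode = "absolute"`,
#'   `fraction = 0.025`, `percentiles = c(2.5, 97.5)`, `min_samples = 1`,
#'   `min_category = 3`, `max_dist_mm = 2`, `variants = list()`.
#' @param cluster_sim optional list for the cluster-extent stage (`grid`,
#'   `voxel_size`, `fwhm`, `voxel_p`, `alpha`, `n_iter`).
#' @param seed root integer seed; stage substreams are derived from it.
#' @param out_dir output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(paths, params = list(), cluster_sim = NULL,
                            seed = 1L, out_dir = "results") {
  defaults <- list(groups = c("control", "persistent"), mode = "absolute",
                   fraction = 0.025, percentiles = c(2.5, 97.5),
                   min_samples = 1L, min_category = 3L, max_dist_mm = 2,
                   variants = list())
  params <- utils::modifyList(defaults, params)
  structure(list(paths = paths, params = params, cluster_sim = cluster_sim,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(paths = raw$paths, params = raw$params %||% list(),
                         cluster_sim = raw$cluster_sim,
                         seed = raw$seed %||% 1L,
                         out_dir = raw$out_dir %||% "results")
  cfg$params$groups <- as.character(cfg$params$groups)
  cfg$params$percentiles <- as.numeric(cfg$params$percentiles)
  cfg
}

#' @rdname pipeline_config
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  need <- c("scans", "gmv", "bundle_dir", "atlas_regions", "catalog")
  miss <- setdiff(need, names(config$paths))
  if (length(miss)) {
    abort(sprintf("config paths missing: %s", paste(miss, collapse = ", ")))
  }
  for (nm in names(config$paths)) {
    p <- config$paths[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("config path '%s' does not exist: %s", nm, p))
    }
  }
  with(config$params, {
    check_number(fraction, "fraction", lower = 1e-9, upper = 1)
    check_number(max_dist_mm, "max_dist_mm", lower = 0)
    if (length(percentiles) != 2 || percentiles[1] >= percentiles[2]) {
      abort("'percentiles' must be increasing length 2")
    }
  })
  invisible(config)
}

#' Write a complete synthetic input set
#'
#' Generates a cohort, atlas, expression bundle and catalog from the given
#' specs, writes them in the package's file formats, and returns a
#' [pipeline_config()] pointing at them -- a self-contained study with
#' known ground truth exercising the full I/O path.
#'
#' @param dir target directory.
#' @param cohort,expression,catalog spec objects (see [cohort_spec()],
#'   [expression_spec()], [catalog_spec()]); defaults are the package's
#'   reference study conditions.
#' @param atlas a `gmv_atlas` (default [gen_atlas()] without volume).
#' @param effect_map planted regional group effects; default plants
#'   moderate effects in a handful of regions.
#' @param seed root seed; spec seeds are derived from it.
#' @return The validated `pipeline_config` (also written to
#'   `config.yaml`); ground truth is written to `truth.json`.
#' @export
write_synthetic_inputs <- function(dir, cohort = NULL, expression = NULL,
                                   catalog = NULL, atlas = NULL,
                                   effect_map = NULL, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atlas <- atlas %||% gen_atlas()
  regions <- select_analysis_regions(atlas)
  analysis_ids <- regions$id
  if (is.null(effect_map)) {
    # graded regional effect profile: magnitudes span 0..0.8 GMV units with
    # alternating signs, the way a real group-difference map varies smoothly
    # in magnitude across regions (both increases and decreases)
    n <- length(analysis_ids)
    effect_map <- stats::setNames(
      seq(0, 0.8, length.out = n) * rep_len(c(1, -1), n), analysis_ids)
  }
  cohort <- cohort %||% cohort_spec(effect_map = effect_map,
                                    seed = substream_seed(seed, "cohort"))
  # a supplied cohort spec without an effect map inherits the study's map,
  # so cohort and expression always share the same planted truth
  if (is.null(cohort$effect_map)) cohort$effect_map <- effect_map
  expression <- expression %||%
    expression_spec(seed = substream_seed(seed, "expression"))
  catalog <- catalog %||% catalog_spec(seed = substream_seed(seed, "catalog"))

  ds <- gen_cohort(cohort, analysis_ids)
  # expression samples live in atlas label space; the analysis regions'
  # member labels carry the same effect as their analysis region
  members <- attr(regions, "members")
  label_ids <- unlist(members, use.names = FALSE)
  label_eff <- stats::setNames(
    rep(effect_map[rep(analysis_ids, lengths(members))], 1), label_ids)
  bundle <- gen_expression(expression, label_ids, label_eff, atlas = atlas)
  genes <- sort(unique(bundle$probes$gene))
  causal <- attr(bundle, "truth")$causal_genes
  cat_obj <- gen_catalog(catalog, genes, causal)

  write_cohort(ds, file.path(dir, "scans.csv"), file.path(dir, "gmv.tsv"))
  write_bundle(bundle, file.path(dir, "bundle"))
  vol_path <- if (!is.null(atlas$volume)) file.path(dir, "atlas.nii.gz")
  write_atlas(atlas, file.path(dir, "atlas_regions.csv"), vol_path)
  write_gmt(cat_obj, file.path(dir, "catalog.gmt"))
  jsonlite::write_json(
    list(effect_map = as.list(effect_map), causal_genes = causal,
         enriched_categories = attr(cat_obj, "truth")$enriched_ids),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)

  cfg <- pipeline_config(
    paths = list(scans = file.path(dir, "scans.csv"),
                 gmv = file.path(dir, "gmv.tsv"),
                 bundle_dir = file.path(dir, "bundle"),
                 atlas_regions = file.path(dir, "atlas_regions.csv"),
                 atlas_volume = vol_path,
                 catalog = file.path(dir, "catalog.gmt")),
    seed = seed, out_dir = file.path(dir, "results"))
  write_config(cfg, file.path(dir, "config.yaml"))
  validate_config(cfg)
}
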