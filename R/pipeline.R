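# End-to-end orchestration: load and validate all inputs, run the
# association stages, percentile thresholds, both enrichment tails, the
# configured sensitivity variants and (optionally) the cluster-extent
# simulation, and write every result table to the output directory.

#' Load and validate all pipeline inputs
#'
#' Reads every path in the configuration through the package's readers,
#' checks the loaded objects' invariants, and logs a manifest of counts.
#'
#' @param config a validated [pipeline_config()].
#' @return List with `dataset`, `bundle`, `whitelist`, `atlas`, `catalog`.
#' @export
load_inputs <- function(config) {
  validate_config(config)
  dataset <- read_cohort(config$paths$scans, config$paths$gmv)
  bundle <- read_bundle(config$paths$bundle_dir)
  atlas <- read_atlas(config$paths$atlas_regions, config$paths$atlas_volume)
  catalog <- read_gmt(config$paths$catalog)
  message(sprintf(
    "loaded: %d scans x %d regions; %d probes x %d samples; %d atlas regions; %d categories",
    nrow(dataset$scans), length(dataset$regions), nrow(bundle$probes),
    nrow(bundle$samples), nrow(atlas$regions), length(catalog)))
  list(dataset = dataset, bundle = bundle, whitelist = bundle$whitelist,
       atlas = atlas, catalog = catalog)
}

variant_tag <- function(variant) {
  switch(variant$type,
         exclude_regions = paste0("exclude_",
                                  if (length(variant$regions %||% character()))
                                    length(variant$regions) else "none"),
         subset_sex = paste0("sex_", variant$sex %||% "M"),
         group_pair = paste0("pair_", paste(variant$groups, collapse = "_")),
         per_donor = "per_donor",
         variant$type)
}

write_assoc <- function(assoc, path) {
  df <- assoc
  df$rho <- fmt_num(df$rho)
  df$p <- fmt_num(df$p)
  df$q <- fmt_num(df$q)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full association pipeline
#'
#' Executes the configured analysis end to end and writes, under
#' `config$out_dir`: the regional t-map and difference map, the gene
#' association table, the percentile thresholds (JSON), both enrichment
#' tails, one subdirectory per sensitivity variant, a run log with a
#' parameter echo, and (if `cluster_sim` is configured) the Monte-Carlo
#' cluster-size threshold. Deterministic: the same configuration and seed
#' give byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the in-memory result list (`assoc`, `thresholds`,
#'   `enrichment`, `variants`, `cluster_sim`, `paths`).
#' @export
run_pipeline <- function(config) {
  inputs <- load_inputs(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  pp <- config$params

  state <- list(dataset = inputs$dataset, bundle = inputs$bundle,
                whitelist = inputs$whitelist, atlas = inputs$atlas,
                groups = pp$groups, mode = pp$mode,
                min_samples = pp$min_samples, max_dist_mm = pp$max_dist_mm)
  primary <- run_association(inputs$dataset, inputs$bundle, inputs$whitelist,
                             inputs$atlas, groups = pp$groups, mode = pp$mode,
                             min_samples = pp$min_samples,
                             max_dist_mm = pp$max_dist_mm)

  utils::write.table(
    transform(primary$tmap, t = fmt_num(t), p = fmt_num(p)),
    file.path(out, "tmap.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    transform(primary$diffmap, value = fmt_num(value)),
    file.path(out, "diffmap.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_assoc(primary$assoc, file.path(out, "gene_association.tsv"))

  thr <- percentile_thresholds(primary$assoc$rho, pp$percentiles[1],
                               pp$percentiles[2])
  jsonlite::write_json(thr, file.path(out, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA)

  background <- primary$assoc$gene
  enr <- list()
  for (tail in c("positive", "negative")) {
    sel <- select_top_genes(primary$assoc, pp$fraction, tail)
    writeLines(sel, file.path(out, sprintf("top_genes_%s.txt", tail)))
    res <- fisher_enrichment(sel, inputs$catalog, background,
                             min_category = pp$min_category)
    df <- res
    df$factor <- fmt_num(df$factor)
    df$p <- fmt_num(df$p)
    df$q <- fmt_num(df$q)
    utils::write.table(df, file.path(out, sprintf("enrichment_%s.tsv", tail)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    enr[[tail]] <- res
  }

  variants <- list()
  for (variant in pp$variants) {
    tag <- variant_tag(variant)
    vdir <- file.path(out, "variants", tag)
    dir.create(vdir, showWarnings = FALSE, recursive = TRUE)
    vres <- sensitivity_suite(state, variant)
    if (identical(variant$type, "per_donor")) {
      write_tsv_matrix(vres$per_donor, file.path(vdir, "per_donor_rho.tsv"),
                       "donor")
    } else {
      write_assoc(vres$assoc, file.path(vdir, "gene_association.tsv"))
    }
    variants[[tag]] <- vres
  }

  csim <- NULL
  if (!is.null(config$cluster_sim)) {
    cs <- config$cluster_sim
    model <- noise_model(grid = cs$grid %||% c(32, 32, 32),
                         voxel_size = cs$voxel_size %||% 1.5,
                         fwhm = cs$fwhm %||% 6)
    csim <- cluster_threshold(model, voxel_p = cs$voxel_p %||% 0.005,
                              alpha = cs$alpha %||% 0.05,
                              n_iter = cs$n_iter %||% 1000,
                              seed = substream_seed(config$seed, "clustersim"))
    jsonlite::write_json(
      list(k_min = csim$k_min, voxel_p = csim$voxel_p, alpha = csim$alpha,
           n_iter = csim$n_iter, exceedance = csim$exceedance),
      file.path(out, "cluster_sim.json"), auto_unbox = TRUE, digits = NA)
  }

  log_lines <- c(
    "gmvexpr run log",
    sprintf("seed: %d", config$seed),
    sprintf("config hash: %s", config_hash(config)),
    sprintf("groups: %s", paste(pp$groups, collapse = " vs ")),
    sprintf("summary mode: %s", pp$mode),
    sprintf("genes surviving whitelist: %d", nrow(primary$assoc) +
              length(attr(primary$assoc, "excluded"))),
    sprintf("genes tested: %d", nrow(primary$assoc)),
    sprintf("analysis regions: %d", nrow(primary$regions)),
    sprintf("selection fraction: %g (top set size %d)", pp$fraction,
            floor(pp$fraction * nrow(primary$assoc))),
    sprintf("rho percentile thresholds: [%0.6g, %0.6g]", thr$rho_lo,
            thr$rho_hi),
    sprintf("variants: %s",
            if (length(pp$variants))
              paste(vapply(pp$variants, variant_tag, ""), collapse = ", ")
            else "none"))
  writeLines(log_lines, file.path(out, "run_log.txt"))

  invisible(list(assoc = primary$assoc, diffmap = primary$diffmap,
                 tmap = primary$tmap, regions = primary$regions,
                 thresholds = thr, enrichment = enr, variants = variants,
                 cluster_sim = csim, out_dir = out))
}

# Small stable fingerprint of the configuration for the run log.
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            4294967291)
}
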