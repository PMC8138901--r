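# Fisher's-exact over-representation of the top-ranked genes against a
# gene-set catalog with an explicit background universe.

#' Select the top fraction of ranked genes
#'
#' Takes the `floor(fraction * n_genes)` genes with the largest
#' (`tail = "positive"`) or smallest (`tail = "negative"`) Spearman rho.
#' Boundary ties are broken deterministically by gene-id lexicographic
#' order (and logged), so the same input always yields the same set.
#'
#' @param assoc a `gene_assoc` from [gene_correlations()].
#' @param fraction selection fraction in (0, 1\].
#' @param tail `"positive"` or `"negative"`.
#' @return Character vector of selected gene ids.
#' @export
select_top_genes <- function(assoc, fraction = 0.025,
                             tail = c("positive", "negative")) {
  tail <- match.arg(tail)
  if (!(fraction > 0 && fraction <= 1)) abort("'fraction' must be in (0, 1]")
  n_sel <- floor(fraction * nrow(assoc))
  if (n_sel < 1) abort("empty selection: fraction too small for the universe")
  ord <- if (tail == "positive") {
    order(-assoc$rho, assoc$gene)
  } else {
    order(assoc$rho, assoc$gene)
  }
  sel <- assoc$gene[ord[seq_len(n_sel)]]
  if (n_sel < nrow(assoc) &&
      assoc$rho[ord[n_sel]] == assoc$rho[ord[n_sel + 1]]) {
    message(sprintf("boundary tie at rho = %.6g broken lexicographically",
                    assoc$rho[ord[n_sel]]))
  }
  sel
}

#' Fisher's-exact over-representation analysis
#'
#' For each category, the one-sided (over-representation) hypergeometric
#' test of the overlap `k` between the selected set (size `n`) and the
#' category restricted to the background (size `K`) in a background
#' universe of size `N`; enrichment factor = `(k/n) / (K/N)`. p-values are
#' the hypergeometric upper tail (via [stats::phyper()]) and q-values are
#' Benjamini-Hochberg across the tested categories.
#'
#' @param selected character vector of selected genes, subset of
#'   `background`.
#' @param catalog a `gene_catalog` (see [gen_catalog()], [read_gmt()]).
#' @param background character vector: the gene universe actually tested.
#' @param min_category minimum in-background category size to test.
#' @return An `enrichment_result` data.frame sorted by p: `category`,
#'   `name`, `k`, `n`, `K`, `N`, `factor`, `p`, `q`; attribute `skipped`
#'   lists categories below `min_category`.
#' @export
fisher_enrichment <- function(selected, catalog, background,
                              min_category = 3L) {
  offenders <- setdiff(selected, background)
  if (length(offenders)) {
    abort(sprintf("selected genes not in the background: %s",
                  paste(offenders, collapse = ", ")))
  }
  N <- length(unique(background))
  n <- length(unique(selected))
  rows <- lapply(catalog, function(cat) {
    memb <- intersect(cat$genes, background)
    K <- length(memb)
    if (K < min_category) return(NULL)
    k <- length(intersect(selected, memb))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cat$id, name = cat$name, k = k, n = n, K = K,
               N = N, factor = (k / n) / (K / N), p = p,
               stringsAsFactors = FALSE)
  })
  skipped <- vapply(catalog, function(cat) {
    length(intersect(cat$genes, background)) < min_category
  }, TRUE)
  out <- do.call(rbind, rows)
  if (is.null(out)) abort("no category meets 'min_category' within the background")
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$category), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, skipped = vapply(catalog[skipped], `[[`, "", "id"),
            class = c("enrichment_result", "data.frame"))
}
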