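# Marginal longitudinal model for repeated GMV measures with
# cluster-robust (sandwich) variance, per region (or per voxel).

DESIGN_COLUMNS <- c("(Intercept)", "group", "age", "age2", "group_age",
                    "sex", "iq", "brain_size", "ses", "severity")

#' Build the longitudinal group-difference design matrix
#'
#' Assembles the 10-column design used throughout the pipeline: intercept,
#' group indicator (case = 1, control = 0), centered age, centered age
#' squared (demeaned after squaring), group-by-centered-age interaction,
#' and the nuisance covariates sex, IQ, brain size, socioeconomic status
#' and stuttering severity. Age is centered at the grand mean over all
#' retained scans before squaring and interacting. Every covariate column
#' except severity is demeaned over all scans; severity is coded 0 on
#' control rows and group-mean-centered over case rows, so it absorbs
#' severity-related variance without shifting the group estimate.
#'
#' @param dataset a `gmv_cohort` (see [gen_cohort()]).
#' @param groups length-2 character: `c(control_label, case_label)`; scans
#'   of other groups are dropped. The group contrast is case minus control.
#' @param include_sex keep the sex covariate column. Single-sex analyses
#'   (e.g. the male-only sensitivity variant) must drop it, since a
#'   constant column is unidentifiable.
#' @return A `gmv_design`: list with `X` (n x 10 matrix), `scan_id`,
#'   `cluster` (subject per row), `contrasts` (named list of length-10
#'   vectors, `"group"` predefined), `groups`, `rank`.
#' @export
build_design <- function(dataset, groups = c("control", "persistent"),
                         include_sex = TRUE) {
  stopifnot(inherits(dataset, "gmv_cohort"))
  if (length(groups) != 2L) abort("'groups' must name a control and a case group")
  sc <- dataset$scans[dataset$scans$group %in% groups, , drop = FALSE]
  if (nrow(sc) == 0L) abort("no scans in the requested groups")
  for (gl in groups) {
    if (length(unique(sc$subject[sc$group == gl])) < 2L) {
      abort(sprintf("need >= 2 subjects in group '%s'", gl))
    }
  }
  for (v in c("age", "iq", "brain_size", "ses")) {
    bad <- sc$scan_id[!is.finite(sc[[v]])]
    if (length(bad)) {
      abort(sprintf("missing '%s' for scans: %s", v, paste(bad, collapse = ", ")))
    }
  }
  bad <- sc$scan_id[!sc$sex %in% c("M", "F")]
  if (length(bad)) {
    abort(sprintf("missing 'sex' for scans: %s", paste(bad, collapse = ", ")))
  }
  case <- sc$group == groups[2]
  bad_sev <- sc$scan_id[case & !is.finite(sc$severity)]
  if (length(bad_sev)) {
    abort(sprintf("missing 'severity' for case scans: %s",
                  paste(bad_sev, collapse = ", ")))
  }

  a <- sc$age - mean(sc$age)
  g <- as.numeric(case)
  sev <- ifelse(case, sc$severity, 0)
  sev[case] <- sev[case] - mean(sev[case])
  X <- cbind(
    1, g, a, a^2 - mean(a^2), g * a,
    as.numeric(sc$sex == "F") - mean(sc$sex == "F"),
    sc$iq - mean(sc$iq),
    sc$brain_size - mean(sc$brain_size),
    sc$ses - mean(sc$ses),
    sev
  )
  colnames(X) <- DESIGN_COLUMNS
  if (!include_sex) X <- X[, colnames(X) != "sex", drop = FALSE]

  # zero-variance columns make the model unidentifiable; name the offender
  sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
  if (any(sds < 1e-12)) {
    abort(sprintf("rank-deficient design: constant column(s) %s",
                  paste(names(sds)[sds < 1e-12], collapse = ", ")))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient design: collinear columns (flagged)")
  }

  contrasts <- list(group = stats::setNames(as.numeric(colnames(X) == "group"),
                                            colnames(X)))
  structure(list(X = X, scan_id = sc$scan_id, cluster = sc$subject,
                 contrasts = contrasts, groups = groups, rank = qrX$rank,
                 rank_deficient = qrX$rank < ncol(X)),
            class = "gmv_design")
}

#' Fit the sandwich-estimator GLM
#'
#' Ordinary least squares per response column with a cluster-robust
#' covariance aggregated over subject residual blocks:
#' \deqn{V = (X^\top X)^{-1} \Big(\sum_s X_s^\top \tilde e_s \tilde e_s^\top
#'       X_s\Big) (X^\top X)^{-1}}
#' where \eqn{\tilde e_s} is subject \eqn{s}'s (optionally
#' leverage-adjusted) residual block. The t reference distribution uses
#' the conservative cluster-count degrees of freedom
#' `n_subjects - rank(X)`.
#'
#' `adjust` selects the small-sample treatment of the residual blocks:
#' `"CR2"` (default) premultiplies each block by
#' \eqn{(I - H_{ss})^{-1/2}}, the Bell-McCaffrey bias adjustment, which
#' keeps the group-contrast test close to its nominal level at this
#' study's cluster counts; `"CR1"` scales the meat by
#' \eqn{G/(G-1)\cdot(N-1)/(N-p)}; `"none"` is the raw estimator, which
#' with one scan per subject reduces exactly to the HC0
#' heteroskedasticity-robust covariance (and CR2 to HC2).
#'
#' @param design a `gmv_design` from [build_design()].
#' @param responses numeric matrix, one row per scan (rownames = scan ids,
#'   matched against the design) and one column per region or voxel.
#' @param adjust small-sample adjustment: `"CR2"`, `"CR1"` or `"none"`.
#' @return A `gmv_swe`: list with `beta` (coefficient x region), `meat`
#'   (p^2 x region matrix of stacked meat matrices), `bread` ((X'X)^-1),
#'   `residuals` (unadjusted), `df`, `n_subjects`, `n_scans`,
#'   `zero_variance` (logical per region, t undefined there), `adjust`.
#' @export
fit_swe <- function(design, responses, adjust = c("CR2", "CR1", "none")) {
  stopifnot(inherits(design, "gmv_design"))
  adjust <- match.arg(adjust)
  if (is.null(dim(responses))) responses <- cbind(response = responses)
  if (!is.null(rownames(responses))) {
    if (!all(design$scan_id %in% rownames(responses))) {
      abort("responses are missing rows for some design scans")
    }
    responses <- responses[design$scan_id, , drop = FALSE]
  } else if (nrow(responses) != nrow(design$X)) {
    abort("responses must align with the design rows")
  }
  X <- design$X
  p <- ncol(X)
  XtX <- crossprod(X)
  bread <- tryCatch(solve(XtX), error = function(e) abort("singular X'X"))
  beta <- bread %*% crossprod(X, responses)
  E <- responses - X %*% beta

  # meat: sum over subjects of (X_s' e~_s)(X_s' e~_s)', stacked p^2 x R
  ii <- rep(seq_len(p), p)
  jj <- rep(seq_len(p), each = p)
  meat <- matrix(0, p * p, ncol(responses))
  for (s in unique(design$cluster)) {
    rows <- design$cluster == s
    Xs <- X[rows, , drop = FALSE]
    Es <- E[rows, , drop = FALSE]
    if (adjust == "CR2") {
      # (I - H_ss)^(-1/2): inverse symmetric square root of the
      # within-cluster annihilator (eigenvalues floored for safety)
      M <- diag(nrow(Xs)) - Xs %*% bread %*% t(Xs)
      ei <- eigen(M, symmetric = TRUE)
      w <- ifelse(ei$values > 1e-8, 1 / sqrt(ei$values), 0)  # pseudo-inverse
      Es <- ei$vectors %*% (t(ei$vectors) %*% Es * w)
    }
    A <- crossprod(Xs, Es)  # p x R
    meat <- meat + A[ii, , drop = FALSE] * A[jj, , drop = FALSE]
  }
  n_subjects <- length(unique(design$cluster))
  if (adjust == "CR1") {
    meat <- meat * (n_subjects / (n_subjects - 1)) *
      ((nrow(X) - 1) / (nrow(X) - p))
  }
  zero_var <- apply(responses, 2, function(y) stats::var(y) < 1e-24)
  df <- n_subjects - design$rank
  if (df <= 0) abort("non-positive degrees of freedom: too few subjects")

  structure(list(beta = beta, meat = meat, bread = bread, residuals = E,
                 df = df, n_subjects = n_subjects, n_scans = nrow(X),
                 zero_variance = zero_var, contrasts = design$contrasts,
                 regions = colnames(responses), adjust = adjust),
            class = "gmv_swe")
}

#' Sandwich covariance matrix for one region
#'
#' @param result a `gmv_swe`.
#' @param region region id or column index.
#' @return The p x p cluster-robust covariance of the coefficients.
#' @export
swe_vcov <- function(result, region = 1L) {
  stopifnot(inherits(result, "gmv_swe"))
  if (is.character(region)) region <- match(region, result$regions)
  p <- ncol(result$bread)
  M <- matrix(result$meat[, region], p, p)
  result$bread %*% M %*% result$bread
}

#' Contrast t-map over regions
#'
#' Computes `t = c'beta / sqrt(c' V c)` per region for a named contrast,
#' with two-sided p from a Student t on `n_subjects - rank(X)` degrees of
#' freedom. Positive t means case group larger than control. Regions with
#' zero response variance are flagged and excluded from the map.
#'
#' @param result a `gmv_swe` from [fit_swe()].
#' @param contrast contrast name (`"group"` by default) or a length-p
#'   numeric contrast vector.
#' @return A `gmv_tmap`: data.frame with `region`, `t`, `p`; attributes
#'   `contrast`, `df`, `excluded` (flagged region ids).
#' @export
contrast_tmap <- function(result, contrast = "group") {
  stopifnot(inherits(result, "gmv_swe"))
  if (is.character(contrast)) {
    if (!contrast %in% names(result$contrasts)) {
      abort(sprintf("unknown contrast '%s'; available: %s", contrast,
                    paste(names(result$contrasts), collapse = ", ")))
    }
    cname <- contrast
    cvec <- result$contrasts[[contrast]]
  } else {
    cname <- "custom"
    cvec <- contrast
  }
  p <- ncol(result$bread)
  if (length(cvec) != p) abort("contrast length must match coefficient count")
  u <- drop(result$bread %*% cvec)
  uu <- as.numeric(outer(u, u))
  num <- drop(crossprod(cvec, result$beta))
  den <- sqrt(pmax(colSums(result$meat * uu), 0))
  t <- num / den
  t[result$zero_variance | den == 0] <- NA_real_
  pval <- 2 * stats::pt(-abs(t), result$df)
  keep <- !is.na(t)
  excluded <- result$regions[!keep]
  if (length(excluded)) {
    message("excluding zero-variance region(s): ", paste(excluded, collapse = ", "))
  }
  structure(
    data.frame(region = result$regions[keep], t = t[keep], p = pval[keep],
               stringsAsFactors = FALSE, row.names = NULL),
    contrast = cname, df = result$df, excluded = excluded,
    class = c("gmv_tmap", "data.frame"))
}

#' @export
print.gmv_swe <- function(x, ...) {
  cat(sprintf("<gmv_swe> %d scans / %d subjects, %d coefficients x %d regions, df = %d\n",
              x$n_scans, x$n_subjects, nrow(x$beta), ncol(x$beta), x$df))
  invisible(x)
}
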