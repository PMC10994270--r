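#' Aggregate image-level records to well level
#'
#' Collapses the image fields of each well to a single record with the given
#' statistic (default: median, matching the well-level median convention for
#' high-content screens). Missing field values are ignored. Metadata must be
#' constant within a well.
#'
#' @param tab Image-level feature table.
#' @param statistic `"median"` or `"mean"`.
#' @return Well-level feature table (one row per plate x well), with the
#'   aggregation statistic recorded in attribute `"aggregated_by"`; the
#'   `field` column holds the number of fields aggregated.
#' @export
aggregate_to_well <- function(tab, statistic = c("median", "mean")) {
  assert_feature_table(tab)
  statistic <- match.arg(statistic)
  fc <- feature_cols(tab)
  dt <- data.table::as.data.table(tab)
  meta_nonfield <- setdiff(META_COLS, "field")
  chk <- dt[, .(n_meta = data.table::uniqueN(.SD)),
            by = c("plate_id", "well"), .SDcols = meta_nonfield]
  if (any(chk$n_meta != 1L)) {
    bad <- chk[chk$n_meta != 1L]
    stop("inconsistent metadata within well(s): ",
         paste(paste(bad$plate_id, bad$well), collapse = ", "))
  }
  # literal median/mean calls keep data.table's grouped (GForce) fast path
  feats <- if (statistic == "median")
    dt[, lapply(.SD, median, na.rm = TRUE), by = c("plate_id", "well"),
       .SDcols = fc]
  else
    dt[, lapply(.SD, mean, na.rm = TRUE), by = c("plate_id", "well"),
       .SDcols = fc]
  meta <- dt[, .(subclone_id = subclone_id[1], genotype = genotype[1],
                 treatment = treatment[1],
                 concentration_nM = concentration_nM[1], field = .N),
             by = c("plate_id", "well")]
  agg <- merge(meta, feats, by = c("plate_id", "well"), sort = FALSE)
  out <- as.data.frame(agg)[, c(META_COLS, fc)]
  attr(out, "aggregated_by") <- statistic
  out
}

#' Normalise features to in-plate control wells
#'
#' Robust z-scoring per plate and feature against an anchor control class:
#' `x -> (x - median_anchor) / (1.4826 * MAD_anchor)`, computed from the
#' anchor wells of the same plate. By default the anchor is the knock-out
#' vehicle (negative control) wells, so normalised values read as signed
#' displacement from the mutant baseline and reversion towards wild-type has
#' a consistent direction; `anchor = "wt_vehicle"` is available. Features
#' whose anchor MAD is zero on any plate are flagged degenerate and centred
#' but not scaled.
#'
#' @param tab Well-level feature table.
#' @param anchor `"ko_vehicle"` (default) or `"wt_vehicle"`.
#' @return Normalised table; attributes `"norm_params"` (per-plate center and
#'   scale vectors, reusable via [apply_normalization()]) and
#'   `"degenerate_features"`.
#' @export
normalize_to_controls <- function(tab, anchor = c("ko_vehicle", "wt_vehicle")) {
  assert_feature_table(tab)
  anchor <- match.arg(anchor)
  fc <- feature_cols(tab)
  is_anchor <- if (anchor == "ko_vehicle")
    tab$genotype == "KO" & tab$treatment == "VEHICLE"
  else tab$genotype == "WT" & tab$treatment == "VEHICLE"

  plates <- unique(tab$plate_id)
  params <- list()
  for (pl in plates) {
    sel <- is_anchor & tab$plate_id == pl
    if (sum(sel) < 4)
      stop("plate ", pl, " has fewer than 4 ", anchor,
           " wells; cannot anchor normalisation")
    m <- feature_matrix(tab[sel, , drop = FALSE])
    center <- apply(m, 2, median)
    scale <- apply(m, 2, mad)  # mad() already includes the 1.4826 constant
    params[[pl]] <- list(center = center, scale = scale)
  }
  degenerate <- sort(unique(unlist(lapply(params, function(p)
    names(p$center)[p$scale == 0]))))
  out <- apply_normalization(tab, params, degenerate)
  attr(out, "norm_params") <- params
  attr(out, "degenerate_features") <- degenerate
  attr(out, "anchor") <- anchor
  out
}

#' Apply stored per-plate normalisation parameters to a feature table
#'
#' Used to carry the well-level normalisation onto image-level records with
#' the same plates (e.g. before image-level classification), so that no new
#' parameters are estimated.
#'
#' @param tab Feature table (well- or image-level).
#' @param params Per-plate list of `center`/`scale` vectors from
#'   [normalize_to_controls()].
#' @param degenerate Feature names to centre but not scale.
#' @export
apply_normalization <- function(tab, params, degenerate = character(0)) {
  assert_feature_table(tab)
  fc <- feature_cols(tab)
  out <- as.data.frame(tab)
  m <- feature_matrix(out)
  for (pl in unique(out$plate_id)) {
    if (is.null(params[[pl]])) stop("no normalisation parameters for plate ", pl)
    rows <- out$plate_id == pl
    ctr <- params[[pl]]$center[fc]
    scl <- params[[pl]]$scale[fc]
    scl[fc %in% degenerate | scl == 0] <- 1
    m[rows, ] <- sweep(sweep(m[rows, , drop = FALSE], 2, ctr), 2, scl, "/")
  }
  out[, fc] <- m
  out
}

#' Drop degenerate (singular) feature columns
#'
#' Removes zero-variance columns, then scans the remaining columns in order
#' and removes any column linearly dependent (within `rank_tol`, relative to
#' its norm) on the columns retained so far — the variables that would make
#' the feature matrix singular.
#'
#' @param tab Well-level feature table.
#' @param rank_tol Relative tolerance on the residual norm below which a
#'   column counts as linearly dependent.
#' @return list with `table` (pruned) and `dropped` (named list with
#'   `zero_variance` and `collinear` character vectors).
#' @export
drop_degenerate <- function(tab, rank_tol = 1e-8) {
  assert_feature_table(tab)
  fc <- feature_cols(tab)
  m <- feature_matrix(tab)
  v <- apply(m, 2, stats::var)
  zero_var <- fc[v == 0 | !is.finite(v)]
  keep <- setdiff(fc, zero_var)
  collinear <- character(0)
  if (length(keep) > 1) {
    x <- scale(m[, keep, drop = FALSE], center = TRUE, scale = FALSE)
    nrm <- sqrt(colSums(x^2))
    x <- sweep(x, 2, nrm, "/")
    g <- crossprod(x)  # Gram matrix of unit-norm centred columns
    # left-to-right Cholesky sweep: column j is kept iff its residual after
    # projection on previously kept columns exceeds rank_tol
    p <- length(keep)
    L <- matrix(0, p, p)
    kept_idx <- integer(0)
    for (j in seq_len(p)) {
      k <- length(kept_idx)
      if (k == 0) {
        r2 <- g[j, j]
        w <- numeric(0)
      } else {
        w <- forwardsolve(L[seq_len(k), seq_len(k), drop = FALSE],
                          g[kept_idx, j])
        r2 <- g[j, j] - sum(w^2)
      }
      if (sqrt(max(r2, 0)) > rank_tol) {
        kept_idx <- c(kept_idx, j)
        L[k + 1L, seq_len(k)] <- w
        L[k + 1L, k + 1L] <- sqrt(max(r2, 0))
      } else {
        collinear <- c(collinear, keep[j])
      }
    }
    keep <- keep[kept_idx]
  }
  if (!length(keep)) warning("all feature columns dropped as degenerate")
  out <- as.data.frame(tab)[, c(META_COLS, keep), drop = FALSE]
  list(table = out, dropped = list(zero_variance = zero_var,
                                   collinear = collinear))
}

#' Drop redundant (highly correlated) features
#'
#' Iteratively removes one member of each feature pair whose absolute Pearson
#' correlation meets `r_threshold`: the member with the larger mean absolute
#' correlation to all other remaining features is dropped (ties broken by
#' dropping the lexicographically later name), until no pair exceeds the
#' threshold.
#'
#' @param tab Well-level feature table with degenerate columns already removed.
#' @param r_threshold Absolute-correlation threshold (default 0.95).
#' @return list with `table` and `dropped` (character vector, in drop order).
#' @export
drop_redundant <- function(tab, r_threshold = 0.95) {
  assert_feature_table(tab)
  fc <- feature_cols(tab)
  m <- feature_matrix(tab)
  r <- abs(cor(m))
  diag(r) <- 0
  alive <- rep(TRUE, length(fc))
  dropped <- character(0)
  repeat {
    ra <- r[alive, alive, drop = FALSE]
    if (!length(ra) || max(ra) < r_threshold) break
    idx <- which(alive)
    top <- which(ra == max(ra), arr.ind = TRUE)[1, ]
    i <- idx[top[1]]; j <- idx[top[2]]
    mean_i <- mean(r[i, alive & seq_along(alive) != i])
    mean_j <- mean(r[j, alive & seq_along(alive) != j])
    victim <- if (mean_i > mean_j) i
      else if (mean_j > mean_i) j
      else if (fc[i] > fc[j]) i else j
    alive[victim] <- FALSE
    dropped <- c(dropped, fc[victim])
  }
  keep <- fc[alive]
  out <- as.data.frame(tab)[, c(META_COLS, keep), drop = FALSE]
  list(table = out, dropped = dropped)
}

# Vectorised one-way ANOVA across feature columns: returns F and p per column.
# Equivalent to per-feature anova(lm(feature ~ group)); verified against
# stats::aov in the test suite.
row_anova <- function(m, group) {
  group <- as.factor(group)
  n <- nrow(m)
  k <- nlevels(group)
  G <- model.matrix(~ group - 1)
  ng <- colSums(G)
  gm <- crossprod(G, m) / ng               # group means (k x p)
  grand <- colMeans(m)
  ss_between <- colSums(ng * (sweep(gm, 2, grand))^2)
  ss_total <- colSums(sweep(m, 2, grand)^2)
  ss_within <- ss_total - ss_between
  df1 <- k - 1
  df2 <- n - k
  f <- (ss_between / df1) / (ss_within / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  list(f = f, p = p, df1 = df1, df2 = df2)
}

#' Per-feature one-way ANOVA filter with Benjamini-Hochberg correction
#'
#' Tests each feature for mean differences across the given group labels
#' (e.g. the screening control classes), adjusts p-values by the
#' Benjamini-Hochberg step-up procedure and reports the set significant at
#' `q < alpha`. Features constant across all observations are flagged
#' untestable and excluded from testing.
#'
#' @param tab Well-level feature table.
#' @param group_labels Factor-like vector, one label per row of `tab`.
#' @param alpha FDR level (default 0.05).
#' @return A `qc_report` list: per-feature `f`, `p`, `q`, the significant
#'   feature names, untestable features, and counts.
#' @export
anova_filter <- function(tab, group_labels, alpha = 0.05) {
  assert_feature_table(tab)
  group_labels <- as.factor(as.character(group_labels))
  if (length(group_labels) != nrow(tab))
    stop("group_labels must have one entry per row")
  cnt <- table(group_labels)
  if (length(cnt) < 2) stop("need at least 2 groups")
  if (any(cnt < 2))
    stop("group(s) with fewer than 2 observations: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  fc <- feature_cols(tab)
  m <- feature_matrix(tab)
  const <- apply(m, 2, function(x) max(x) == min(x))
  untestable <- fc[const]
  test_cols <- fc[!const]
  res <- row_anova(m[, test_cols, drop = FALSE], group_labels)
  q <- p.adjust(res$p, method = "BH")
  sig <- test_cols[q < alpha]
  structure(list(feature = test_cols, f = unname(res$f), p = unname(res$p),
                 q = unname(q), df = c(res$df1, res$df2),
                 significant = sig, untestable = untestable,
                 alpha = alpha,
                 n_tested = length(test_cols), n_significant = length(sig)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d features tested, %d significant at BH q < %g (%d untestable)\n",
              x$n_tested, x$n_significant, x$alpha, length(x$untestable)))
  invisible(x)
}

#' Run the full feature-QC pipeline on an image-level table
#'
#' Fixed stage order: aggregate to well level, normalise to in-plate controls,
#' drop degenerate columns, drop redundant columns, then the per-feature
#' ANOVA+BH report across the control classes (wild-type vehicle, knock-out
#' vehicle, knock-out untreated). Returns everything needed to apply the same
#' normalisation and feature selection to image-level records.
#'
#' @param tab Image-level feature table.
#' @param statistic Well aggregation statistic.
#' @param anchor Normalisation anchor class.
#' @param rank_tol,r_threshold,alpha Stage parameters (see the stage functions).
#' @return A `feature_qc` list: `wells` (QC'd well-level table), `report`
#'   (the [anova_filter()] output), `retained` feature names, `dropped`
#'   lists, `norm_params`, `degenerate_features`, and the parameters used.
#' @export
run_feature_qc <- function(tab, statistic = "median",
                           anchor = "ko_vehicle",
                           rank_tol = 1e-8, r_threshold = 0.95,
                           alpha = 0.05) {
  wells <- aggregate_to_well(tab, statistic)
  norm <- normalize_to_controls(wells, anchor)
  norm_params <- attr(norm, "norm_params")
  degen_flag <- attr(norm, "degenerate_features")
  deg <- drop_degenerate(norm, rank_tol)
  red <- drop_redundant(deg$table, r_threshold)
  wells_qc <- red$table
  ctrl <- wells_qc$treatment %in% c("VEHICLE", "UNTREATED")
  grp <- paste(wells_qc$genotype[ctrl], wells_qc$treatment[ctrl], sep = "_")
  report <- anova_filter(wells_qc[ctrl, , drop = FALSE], grp, alpha)
  list(wells = wells_qc,
       report = report,
       retained = feature_cols(wells_qc),
       dropped = list(degenerate = unique(c(degen_flag,
                                            deg$dropped$zero_variance,
                                            deg$dropped$collinear)),
                      redundant = red$dropped),
       norm_params = norm_params,
       degenerate_features = degen_flag,
       params = list(statistic = statistic, anchor = anchor,
                     rank_tol = rank_tol, r_threshold = r_threshold,
                     alpha = alpha))
}

#' Project image-level records through a fitted feature-QC
#'
#' Applies the stored per-plate normalisation and feature selection (no new
#' estimation) so image-level records live in the same feature space as the
#' QC'd well-level table.
#'
#' @param qc A `feature_qc` object from [run_feature_qc()].
#' @param tab Image-level feature table from the same plates.
#' @export
apply_feature_qc <- function(qc, tab) {
  norm <- apply_normalization(tab, qc$norm_params, qc$degenerate_features)
  norm[, c(META_COLS, qc$retained), drop = FALSE]
}
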