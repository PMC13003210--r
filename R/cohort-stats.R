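# Cohort-level statistics: per-time-point aggregation, paired
# signed-rank tests, rank-sum tests with Benjamini-Hochberg correction
# across the two control comparisons, and the standardized 2-D PCA.

#' Aggregate per-recording feature time series into a cohort table
#'
#' Each recording's windowed feature series is collapsed to its mean,
#' yielding one row per (participant, time point). Raw-impedance
#' magnitude features (not comparable across participants because of
#' electrode placement and thorax-size differences) are never part of
#' the 13-feature set and are therefore excluded by construction.
#'
#' @param series_list named list of feature time series (one per
#'   recording id).
#' @param manifest data frame with `id`, `participant_id`, `group`,
#'   `time_point` for every recording.
#' @return `cohort_table` data frame: `participant_id`, `group`,
#'   `time_point` plus the 13 aggregated features.
#' @export
aggregate_cohort <- function(series_list, manifest) {
  stopifnot(all(c("id", "participant_id", "group", "time_point") %in%
                  names(manifest)))
  key <- paste(manifest$participant_id, manifest$time_point)
  if (anyDuplicated(key))
    stop("duplicate (participant, time point) rows in manifest")
  feats <- multimodal_feature_names()
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$id[i]
    s <- series_list[[id]]
    if (is.null(s) || nrow(s) == 0)
      stop(sprintf("no feature series for recording %s", id))
    v <- colMeans(s[, intersect(feats, names(s)), drop = FALSE],
                  na.rm = TRUE)
    cbind(manifest[i, c("participant_id", "group", "time_point")],
          as.data.frame(as.list(v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired signed-rank tests across time points
#'
#' Two-sided Wilcoxon signed-rank test of T1 versus T2 for every feature
#' over participants with both time points; W is the positive-rank sum
#' of the T1 - T2 differences (exact distribution when no ties/zeros and
#' n <= 25, normal approximation otherwise; zero differences dropped).
#'
#' @param table a `cohort_table` from [aggregate_cohort()].
#' @param features feature names (default: the 13 multimodal features).
#' @param tp pair of time-point labels.
#' @return data frame of `stat_result` rows: feature, comparison, `n`,
#'   `W`, `p`, and per-group median/IQR.
#' @export
paired_wilcoxon <- function(table, features = multimodal_feature_names(),
                            tp = c("T1", "T2")) {
  a <- table[table$time_point == tp[1], ]
  b <- table[table$time_point == tp[2], ]
  common <- intersect(a$participant_id, b$participant_id)
  if (length(common) < 1)
    stop("no participants with both time points available")
  a <- a[match(common, a$participant_id), ]
  b <- b[match(common, b$participant_id), ]
  rows <- lapply(features, function(f) {
    d <- a[[f]] - b[[f]]
    if (all(d == 0)) {
      w <- 0; p <- 1
    } else {
      ht <- suppressWarnings(stats::wilcox.test(a[[f]], b[[f]],
                                                paired = TRUE,
                                                exact = NULL))
      w <- unname(ht$statistic); p <- ht$p.value
    }
    data.frame(feature = f,
               comparison = paste(tp, collapse = "-"), n = length(d),
               W = w, p = p,
               median_1 = stats::median(a[[f]]),
               iqr_1 = stats::IQR(a[[f]]),
               median_2 = stats::median(b[[f]]),
               iqr_2 = stats::IQR(b[[f]]))
  })
  do.call(rbind, rows)
}

#' Group comparisons against control with Benjamini-Hochberg correction
#'
#' Two-sided Wilcoxon rank-sum tests of each patient time point against
#' the control group, per feature; the two raw p-values of a feature
#' (T1-control, T2-control) are adjusted jointly by Benjamini-Hochberg
#' with m = 2. W is the rank sum of the first-named (patient) group.
#'
#' @param table a `cohort_table`.
#' @param features feature names.
#' @param time_points patient time points to compare against control.
#' @param control_label `time_point` label of the control rows.
#' @return data frame with `W`, raw `p` and `p_adj` per (feature,
#'   comparison), plus group medians/IQRs.
#' @export
group_wilcoxon_bh <- function(table,
                              features = multimodal_feature_names(),
                              time_points = c("T1", "T2"),
                              control_label = "single") {
  ctrl <- table[table$time_point == control_label, ]
  if (nrow(ctrl) == 0) stop("control group is empty")
  rows <- list()
  for (f in features) {
    res <- lapply(time_points, function(tp) {
      g <- table[table$time_point == tp, ]
      if (nrow(g) == 0) {
        message(sprintf("no rows for time point %s; comparison skipped", tp))
        return(NULL)
      }
      ht <- suppressWarnings(stats::wilcox.test(g[[f]], ctrl[[f]],
                                                exact = NULL))
      n1 <- nrow(g)
      # rank sum of the first-named group = U + n1 (n1 + 1) / 2
      w <- unname(ht$statistic) + n1 * (n1 + 1) / 2
      data.frame(feature = f,
                 comparison = sprintf("%s-control", tp),
                 n1 = n1, n2 = nrow(ctrl), W = w, p = ht$p.value,
                 median_1 = stats::median(g[[f]]), iqr_1 = stats::IQR(g[[f]]),
                 median_2 = stats::median(ctrl[[f]]),
                 iqr_2 = stats::IQR(ctrl[[f]]))
    })
    res <- do.call(rbind, res)
    if (is.null(res)) next
    res$p_adj <- stats::p.adjust(res$p, method = "BH")
    rows[[f]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standardized principal component analysis of the cohort table
#'
#' Features are z-scored over the pooled rows (scales differ by orders
#' of magnitude between timing and SI features), zero-variance features
#' dropped with a warning, and the correlation-structure
#' eigendecomposition taken. Components are oriented so that each one's
#' largest-magnitude loading is positive; PC1 loadings are additionally
#' ranked by absolute value.
#'
#' @param table a `cohort_table`.
#' @param features feature names.
#' @param ncomp number of components to report scores for.
#' @return list of class `pca_result`: `loadings` (features x
#'   components), `explained` (variance fractions, all components),
#'   `scores` (rows x ncomp, with participant/time-point columns),
#'   `pc1_ranking` (features ordered by |PC1 loading|).
#' @export
run_pca <- function(table, features = multimodal_feature_names(),
                    ncomp = 2) {
  x <- as.matrix(table[, features, drop = FALSE])
  if (nrow(x) < 3) stop("PCA needs at least 3 rows")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropping zero-variance feature(s): %s",
                    paste(colnames(x)[v == 0], collapse = ", ")))
    x <- x[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  load <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(load))) {
    s <- sign(load[which.max(abs(load[, j])), j])
    if (s < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ncomp <- min(ncomp, ncol(scores))
  sc <- cbind(table[, c("participant_id", "group", "time_point")],
              as.data.frame(scores[, seq_len(ncomp), drop = FALSE]))
  structure(list(
    loadings = load,
    explained = expl,
    scores = sc,
    pc1_ranking = rownames(load)[order(abs(load[, 1]),
                                       decreasing = TRUE)]),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d features, PC1 %.1f%% / PC2 %.1f%% variance\n",
              nrow(x$loadings), 100 * x$explained[1],
              100 * x$explained[2]))
  cat("PC1 ranking:", paste(utils::head(x$pc1_ranking, 5), collapse = ", "),
      "...\n")
  invisible(x)
}

#' Compare aggregated PC1 scores between groups
#'
#' Rank-sum tests of the first principal component score, patient time
#' points versus control, with Benjamini-Hochberg correction over the
#' two comparisons.
#'
#' @param pca a `pca_result` from [run_pca()].
#' @param time_points patient time points; `control_label` the control
#'   `time_point` label.
#' @return data frame as in [group_wilcoxon_bh()].
#' @export
compare_pc1_groups <- function(pca, time_points = c("T1", "T2"),
                               control_label = "single") {
  sc <- pca$scores
  sc$PC1_score <- sc$PC1
  group_wilcoxon_bh(sc, features = "PC1_score",
                    time_points = time_points,
                    control_label = control_label)
}
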