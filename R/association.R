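# Disease-group comparisons of per-cluster CPM and Spearman correlations
# between baiE abundance and the secondary/primary bile-acid ratio.
# The two-group test is a two-sided Mann-Whitney U (the star notation on
# skewed CPM data never names its test in the source material; U is the
# standard nonparametric choice and is documented as an assumption):
# exact enumeration when n_a + n_b <= 12 and no ties, otherwise the
# normal approximation with tie and continuity correction. No
# multiple-testing correction by default; Benjamini-Hochberg behind a
# flag.

#' Secondary-to-primary bile-acid ratio
#'
#' `(DCA + LCA) / (CA + CDCA)` per sample. Samples missing any
#' concentration, or with a zero denominator, yield `NA` (excluded
#' pairwise downstream, with a log entry).
#'
#' @param meta metadata data frame with columns `CA`, `CDCA`, `DCA`,
#'   `LCA`.
#' @return numeric vector named by `sample_id`.
#' @export
ba_ratio <- function(meta) {
  need <- c("CA", "CDCA", "DCA", "LCA")
  if (!all(need %in% names(meta)))
    stop("metadata lacks bile-acid columns: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  den <- meta$CA + meta$CDCA
  ratio <- (meta$DCA + meta$LCA) / den
  bad <- !is.na(den) & den == 0
  if (any(bad)) {
    log_msg("ba_ratio: excluding %d sample(s) with zero primary-BA total",
            sum(bad))
    ratio[bad] <- NA_real_
  }
  setNames(ratio, meta$sample_id)
}

stars_for <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Compare per-cluster abundance between disease groups and healthy
#'
#' Two-sided Mann-Whitney U on the CPM values of `cluster_id`, each
#' disease group against the reference group. Significance stars follow
#' the conventional mapping (* p<0.05, ** p<0.01, *** p<0.001).
#'
#' @param profiles long abundance table (rows from [normalize_cpm()]).
#' @param metadata sample metadata with `sample_id` and `group`.
#' @param cluster_id cluster to test.
#' @param reference reference group label (default `"healthy"`).
#' @param p_adjust apply Benjamini-Hochberg across the returned
#'   comparisons.
#' @return data frame with one row per disease group: `cluster_id`,
#'   `group_a` (reference), `group_b`, `n_a`, `n_b`, `u_statistic`,
#'   `p_value`, `direction` (`a>b`, `b>a` or `none`, from the median
#'   difference), `stars`.
#' @export
compare_groups <- function(profiles, metadata, cluster_id,
                           reference = "healthy", p_adjust = FALSE) {
  x <- profiles[profiles$cluster_id == cluster_id, c("sample_id", "cpm")]
  x$group <- metadata$group[match(x$sample_id, metadata$sample_id)]
  if (!reference %in% x$group) stop("reference group absent: ", reference)
  groups <- setdiff(unique(x$group[!is.na(x$group)]), reference)
  rows <- list()
  for (g in groups) {
    a <- x$cpm[x$group == reference]
    b <- x$cpm[x$group == g]
    if (length(a) < 3 || length(b) < 3) {
      warning("skipping group ", g, ": fewer than 3 samples per arm")
      next
    }
    exact <- (length(a) + length(b) <= 12) &&
      !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided", exact = exact,
                  correct = TRUE))
    md <- stats::median(a) - stats::median(b)
    rows[[g]] <- data.frame(
      cluster_id = cluster_id, group_a = reference, group_b = g,
      n_a = length(a), n_b = length(b),
      u_statistic = unname(wt$statistic), p_value = wt$p.value,
      direction = if (md > 0) "a>b" else if (md < 0) "b>a" else "none",
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(invisible(NULL))
  out <- do.call(rbind, rows)
  if (p_adjust) out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$stars <- stars_for(out$p_value)
  rownames(out) <- NULL
  out
}

#' Spearman correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of midranks; the p-value comes from
#' the t approximation with n - 2 degrees of freedom. Pairs with a
#' missing value in either vector are excluded.
#'
#' @param abundance,ratio equal-length numeric vectors (n >= 3 complete
#'   pairs).
#' @param label label stored in the result (a cluster id or `"all"`).
#' @return one-row data frame `cluster_id`, `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(abundance, ratio, label = "all") {
  if (length(abundance) != length(ratio)) stop("length mismatch")
  ok <- !is.na(abundance) & !is.na(ratio)
  x <- abundance[ok]; y <- ratio[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; rho undefined")
    return(data.frame(cluster_id = label, rho = NA_real_,
                      p_value = NA_real_, n = n, stringsAsFactors = FALSE))
  }
  rho <- cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  data.frame(cluster_id = label, rho = rho, p_value = p, n = n,
             stringsAsFactors = FALSE)
}

#' Abundance-vs-bile-acid-ratio correlations per cluster and pooled
#'
#' @param profiles long abundance table (rows from [normalize_cpm()]).
#' @param metadata metadata with bile-acid concentrations.
#' @param clusters cluster ids to test; defaults to all present.
#' @return data frame of [spearman_cor()] rows: each cluster plus a
#'   pooled `"all"` row (total CPM across clusters).
#' @export
correlate_ba <- function(profiles, metadata, clusters = NULL) {
  ratio <- ba_ratio(metadata)
  clusters <- clusters %||% sort(unique(profiles$cluster_id))
  rows <- lapply(clusters, function(cl) {
    p <- profiles[profiles$cluster_id == cl, ]
    spearman_cor(p$cpm[match(metadata$sample_id, p$sample_id)],
                 unname(ratio), label = cl)
  })
  tot <- tapply(profiles$cpm, profiles$sample_id, sum)
  rows[[length(rows) + 1L]] <- spearman_cor(
    as.numeric(tot[metadata$sample_id]), unname(ratio), label = "all")
  do.call(rbind, rows)
}
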