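# RPPA differential filter and ranking.

#' Filter and rank differentially expressed RPPA proteins
#'
#' Per protein: mean log2 difference (treated minus control) and a
#' two-sided two-sample Student t-test p-value (unadjusted by default).
#' The differential set keeps proteins with |log2FC| >= log2(fc_min) and
#' p < alpha; the ranked list is the `top_n` proteins by |log2FC| among
#' those passing, padded in score order (and flagged) if fewer pass.
#'
#' @param table list as from [generate_rppa_table()]: `values`
#'   (proteins x samples log2 matrix) and `groups` (sample labels).
#' @param control_group label of the control group.
#' @param treated_group label of the treated group; defaults to the single
#'   non-control group.
#' @param fc_min minimum fold change (linear scale, default 2).
#' @param alpha p-value cutoff (default 0.05).
#' @param top_n length of the ranked list (default 100).
#' @param adjust apply Benjamini-Hochberg correction before filtering
#'   (off by default: the filter is a raw p < alpha rule).
#' @return list with `stats` (per-protein log2fc, fold_change, p),
#'   `differential` (protein ids passing both filters) and `ranked`
#'   (data frame `protein`, `score` = |log2fc|, `log2fc`, `fold_change`,
#'   `p_value`, `passed`; ordered score desc, id asc).
#' @export
rppa_filter_rank <- function(table, control_group = "control",
                             treated_group = NULL, fc_min = 2, alpha = 0.05,
                             top_n = 100, adjust = FALSE) {
  vals <- table$values; groups <- table$groups
  assert_that(control_group %in% groups, "control group absent")
  if (is.null(treated_group)) {
    others <- setdiff(unique(groups), control_group)
    assert_that(length(others) == 1,
                "specify treated_group when more than two groups are present")
    treated_group <- others
  }
  ctrl <- vals[, groups == control_group, drop = FALSE]
  trt <- vals[, groups == treated_group, drop = FALSE]
  assert_that(ncol(ctrl) >= 2 && ncol(trt) >= 2,
              "each group needs >= 2 samples (variance undefined otherwise)")
  log2fc <- rowMeans(trt) - rowMeans(ctrl)
  p <- vapply(seq_len(nrow(vals)), function(i) {
    stats::t.test(trt[i, ], ctrl[i, ], var.equal = TRUE)$p.value
  }, numeric(1))
  if (adjust) p <- stats::p.adjust(p, method = "BH")
  prot <- rownames(vals)
  stats_df <- data.frame(protein = prot, log2fc = log2fc,
                         fold_change = 2^log2fc, p_value = p)
  pass <- abs(log2fc) >= log2(fc_min) & p < alpha
  differential <- prot[pass]
  ord <- order(-abs(stats_df$log2fc), stats_df$protein)
  ranked_all <- stats_df[ord, ]
  ranked_all$score <- abs(ranked_all$log2fc)
  ranked_all$passed <- pass[ord]
  ranked <- rbind(ranked_all[ranked_all$passed, ],
                  ranked_all[!ranked_all$passed, ])
  ranked <- head(ranked, top_n)
  rownames(ranked) <- NULL
  if (any(!ranked$passed)) {
    attr(ranked, "padded") <- sum(!ranked$passed)
  }
  list(stats = stats_df, differential = differential,
       ranked = ranked[, c("protein", "score", "log2fc", "fold_change",
                           "p_value", "passed")])
}

#' Standard group comparisons used in the reporting layer
#'
#' Thin wrapper over the classical tests: two-sample Student t,
#' Wilcoxon rank-sum (Mann-Whitney), one-way ANOVA and Kruskal-Wallis.
#'
#' @param values_by_group named list of numeric vectors (>= 2 groups,
#'   >= 2 values each).
#' @param test one of `"t"`, `"rank-sum"`, `"anova"`, `"rank-multi"`.
#' @return list `test`, `statistic`, `p_value`, `means`, and for two
#'   groups `percent_change` of the means (second vs first).
#' @export
compare_groups <- function(values_by_group, test = "rank-sum") {
  assert_that(length(values_by_group) >= 2, "need >= 2 groups")
  assert_that(all(vapply(values_by_group, length, 1L) >= 2),
              "need >= 2 values per group")
  g2 <- length(values_by_group) == 2
  x <- values_by_group[[1]]; y <- values_by_group[[2]]
  res <- switch(test,
    "t" = {
      assert_that(g2, "test 't' needs exactly 2 groups")
      stats::t.test(x, y)
    },
    "rank-sum" = {
      assert_that(g2, "test 'rank-sum' needs exactly 2 groups")
      suppressWarnings(stats::wilcox.test(x, y))
    },
    "anova" = {
      v <- unlist(values_by_group, use.names = FALSE)
      f <- factor(rep(seq_along(values_by_group),
                      vapply(values_by_group, length, 1L)))
      a <- summary(stats::aov(v ~ f))[[1]]
      list(statistic = a[["F value"]][1], p.value = a[["Pr(>F)"]][1])
    },
    "rank-multi" = stats::kruskal.test(values_by_group),
    stop("unknown test '", test, "'; valid: t, rank-sum, anova, rank-multi",
         call. = FALSE)
  )
  means <- vapply(values_by_group, mean, numeric(1))
  out <- list(test = test,
              statistic = unname(res$statistic[1]),
              p_value = unname(res$p.value),
              means = means)
  if (g2 && means[1] != 0) {
    out$percent_change <- unname(100 * (means[2] - means[1]) / means[1])
  }
  out
}
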