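# Relative expression by the delta-delta-CT method.
#
# dCT  = CT(target) - CT(reference) per biological sample (run), after
#        averaging technical replicates;
# ddCT = dCT - mean dCT of the calibrator condition;
# FC   = 2^(-ddCT).
#
# The condition-level fold is reported as 2^(-mean ddCT) — the geometric
# mean of the per-sample folds — so the calibrator condition is exactly 1
# by construction; the SE shown is the arithmetic standard error of the
# per-sample folds (the error bar a bar chart of fold changes would carry).

#' Relative expression by the delta-delta-CT method
#'
#' @param table CT table as from [generate_ct_table()] or [read_tsv()]:
#'   columns `condition`, `gene`, `run`, `ct` (and optionally
#'   `sample_id`, `replicate`).
#' @param target_gene gene to quantify.
#' @param reference_gene internal-control gene (e.g. GAPDH).
#' @param calibrator condition the fold changes are relative to.
#' @return data frame with one row per condition: `gene`, `condition`,
#'   `fold` (geometric-mean 2^-ddCT), `se` (SE of per-sample folds), `n`
#'   (biological samples). Attribute `"samples"` carries the per-sample
#'   dCT/ddCT/fold detail.
#' @export
ddct <- function(table, target_gene, reference_gene, calibrator) {
  need <- c("condition", "gene", "run", "ct")
  assert_that(all(need %in% names(table)),
              paste("CT table must have columns:", paste(need, collapse = ", ")))
  assert_that(calibrator %in% table$condition, "calibrator condition absent from table")
  for (g in c(target_gene, reference_gene)) {
    assert_that(g %in% table$gene, paste0("gene '", g, "' absent from table"))
  }
  # average technical replicates per biological sample (condition x run)
  avg <- aggregate(ct ~ condition + run + gene, data = table, FUN = mean)
  samples <- unique(avg[, c("condition", "run")])
  wide <- merge(
    setNames(avg[avg$gene == target_gene, c("condition", "run", "ct")],
             c("condition", "run", "ct_target")),
    setNames(avg[avg$gene == reference_gene, c("condition", "run", "ct")],
             c("condition", "run", "ct_ref")),
    by = c("condition", "run"), all.x = TRUE, all.y = TRUE
  )
  bad <- wide[is.na(wide$ct_ref), ]
  if (nrow(bad)) {
    stop("reference gene '", reference_gene, "' missing for sample(s): ",
         paste(paste(bad$condition, bad$run, sep = "_run"), collapse = ", "),
         call. = FALSE)
  }
  wide <- wide[!is.na(wide$ct_target), ]
  wide$dct <- wide$ct_target - wide$ct_ref
  cal_mean <- mean(wide$dct[wide$condition == calibrator])
  wide$ddct <- wide$dct - cal_mean
  wide$fold <- 2^(-wide$ddct)
  out <- do.call(rbind, lapply(split(wide, wide$condition), function(d) {
    data.frame(gene = target_gene, condition = d$condition[1],
               fold = 2^(-mean(d$ddct)),
               se = if (nrow(d) > 1) sd(d$fold) / sqrt(nrow(d)) else NA_real_,
               n = nrow(d))
  }))
  rownames(out) <- NULL
  attr(out, "samples") <- wide
  out
}

#' Percent change between two fold values
#'
#' The arithmetic behind every "reduced by X%" statement:
#' `100 * (fold_alt - fold_ref) / fold_ref`.
#'
#' @param fold_alt,fold_ref positive fold values (reference > 0).
#' @export
percent_change <- function(fold_alt, fold_ref) {
  assert_that(is.numeric(fold_ref) && all(fold_ref > 0),
              "fold_ref must be positive")
  100 * (fold_alt - fold_ref) / fold_ref
}
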