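# Per-cell morphometrics.
#
# Shape metrics (eccentricity_ratio, solidity, area, displacement) follow
# the conventions of the imaging experiments this package emulates:
# eccentricity is the ratio of minor to major moment-ellipse axis length
# (1 = round), solidity is region area over convex-hull area, and nuclear
# displacement is the Euclidean distance between the nuclear centroid and
# the centroid of the whole cell segment (which contains the nucleus).

#' Measure every non-border cell in a segmented image
#'
#' @param image list of channel matrices with at least `protein`; as
#'   produced by [generate_cell_image()] (`$image`) or [read_cell_image()].
#' @param nuclei nucleus label mask (see [segment_nuclei()]).
#' @param cells cell label mask (see [segment_cells()]).
#' @param fibers binary stress-fiber mask, or `NULL` for no fiber metrics.
#' @param fiber_length_min fiber components shorter than this (major-axis
#'   length, pixels, after clipping to the cell) are excluded from the
#'   fiber count and length list; clipped fragments are not fibers. The
#'   fiber-area percentage uses the full mask.
#' @return data frame with one row per measurable cell:
#'   `cell_id`, `nucleus_id`, `nuclear_area`, `cell_area`,
#'   `eccentricity_ratio` and `solidity` (of the nuclear region),
#'   `nc_area_ratio`, `nuclear_displacement` (pixels), `pct_fiber_area`,
#'   `n_fibers`, `mean_fiber_length`, `mean_nuc_intensity`,
#'   `mean_cyto_intensity` (protein channel, a.u.), `flag`
#'   (`"ok"` or `"empty_cytoplasm"`), and a `fiber_lengths` list column
#'   (end-to-end length, pixels, of each fiber component in the cell).
#'   Border-touching cells are excluded; a nucleus spanning two cells
#'   drops the affected cells with a warning.
#' @export
measure_cells <- function(image, nuclei, cells, fibers = NULL,
                          fiber_length_min = 10) {
  nuclei <- as_label_matrix(nuclei)
  cells <- as_label_matrix(cells)
  assert_that(all(dim(nuclei) == dim(cells)), "mask shapes differ")
  protein <- image$protein
  assert_that(!is.null(protein) && all(dim(protein) == dim(cells)),
              "protein channel missing or mis-shaped")
  if (is.null(fibers)) fibers <- matrix(FALSE, nrow(cells), ncol(cells))
  fibers <- fibers > 0

  cell_props <- region_props(cells)
  nuc_props <- region_props(nuclei)
  if (nrow(cell_props) == 0) return(empty_cell_records())

  # map each nucleus to the cell holding the majority of its pixels, and
  # detect nuclei materially spanning two cells (>20% of pixels elsewhere)
  nz <- nuclei > 0
  nuc_to_cell <- rep(NA_integer_, max(nuclei))
  spanning <- integer(0)
  for (k in nuc_props$label) {
    under <- cells[nz & nuclei == k]
    tab <- table(under[under > 0])
    if (length(tab) == 0) next
    best <- as.integer(names(tab)[which.max(tab)])
    if (length(tab) > 1 && (sum(tab) - max(tab)) / sum(tab) > 0.2) {
      spanning <- c(spanning, as.integer(names(tab)))
      next
    }
    nuc_to_cell[k] <- best
  }
  if (length(spanning)) {
    warning("nucleus spanning two cells; skipping cell(s) ",
            paste(unique(spanning), collapse = ", "))
  }

  rows <- list()
  for (i in seq_len(nrow(cell_props))) {
    cid <- cell_props$label[i]
    if (cell_props$touches_border[i] || cid %in% spanning) next
    nuc_ids <- which(nuc_to_cell == cid)
    if (length(nuc_ids) != 1) next   # no (or ambiguous) nucleus
    nid <- nuc_ids
    np <- nuc_props[nuc_props$label == nid, ]
    in_cell <- cells == cid
    in_nuc <- nuclei == nid & in_cell
    cyto <- in_cell & !in_nuc
    a_n <- sum(in_nuc); a_c <- sum(in_cell)
    if (a_n == 0) next
    d <- sqrt((np$centroid_r - cell_props$centroid_r[i])^2 +
              (np$centroid_c - cell_props$centroid_c[i])^2)
    fib_cell <- fibers & in_cell
    fl <- fiber_lengths_in(fib_cell, fiber_length_min)
    flag <- if (sum(cyto) == 0) "empty_cytoplasm" else "ok"
    rows[[length(rows) + 1]] <- data.frame(
      cell_id = cid, nucleus_id = nid,
      nuclear_area = a_n, cell_area = a_c,
      eccentricity_ratio = np$eccentricity_ratio,
      solidity = np$solidity,
      nc_area_ratio = a_n / a_c,
      nuclear_displacement = d,
      pct_fiber_area = 100 * sum(fib_cell) / a_c,
      n_fibers = length(fl),
      mean_fiber_length = if (length(fl)) mean(fl) else NA_real_,
      mean_nuc_intensity = mean(protein[in_nuc]),
      mean_cyto_intensity = if (flag == "ok") mean(protein[cyto]) else NA_real_,
      flag = flag
    )
    rows[[length(rows)]]$fiber_lengths <- I(list(fl))
  }
  if (length(rows) == 0) return(empty_cell_records())
  do.call(rbind, rows)
}

fiber_lengths_in <- function(mask, length_min = 10) {
  if (!any(mask)) return(numeric(0))
  lens <- component_lengths(label8(mask))
  unname(lens[lens >= length_min])
}

empty_cell_records <- function() {
  df <- data.frame(
    cell_id = integer(), nucleus_id = integer(), nuclear_area = numeric(),
    cell_area = numeric(), eccentricity_ratio = numeric(),
    solidity = numeric(), nc_area_ratio = numeric(),
    nuclear_displacement = numeric(), pct_fiber_area = numeric(),
    n_fibers = integer(), mean_fiber_length = numeric(),
    mean_nuc_intensity = numeric(), mean_cyto_intensity = numeric(),
    flag = character()
  )
  df$fiber_lengths <- I(list())
  df
}

cell_metric_names <- function() {
  c("nuclear_area", "cell_area", "eccentricity_ratio", "solidity",
    "nc_area_ratio", "nuclear_displacement", "pct_fiber_area", "n_fibers",
    "mean_fiber_length", "mean_nuc_intensity", "mean_cyto_intensity")
}

#' Condition-level effect on a per-cell metric
#'
#' Percent change of group means plus a rank-based two-sided p-value:
#' Wilcoxon rank-sum (Mann-Whitney) for two groups. For more than two
#' groups use [compare_groups()] with the Kruskal-Wallis test.
#'
#' @param records_ref,records_alt data frames from [measure_cells()]
#'   (reference and alternative condition); rows flagged other than
#'   `"ok"` are dropped, except that `mean_nuc_intensity` tolerates
#'   `empty_cytoplasm` rows.
#' @param metric one of the per-cell metric columns.
#' @param test `"rank-sum-2"` (default).
#' @return list with `metric`, `mean_ref`, `mean_alt`, `percent_change`,
#'   `p_value`, `test`, `n_ref`, `n_alt`.
#' @export
estimate_effect <- function(records_ref, records_alt, metric,
                            test = "rank-sum-2") {
  valid <- cell_metric_names()
  if (!metric %in% valid) {
    stop("unknown metric '", metric, "'; valid metrics: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  assert_that(test %in% c("rank-sum-2"),
              "estimate_effect supports test = 'rank-sum-2'; use compare_groups() for multi-group tests")
  pull <- function(rec) {
    if (!is.null(rec$flag) && metric != "mean_nuc_intensity") {
      rec <- rec[rec$flag == "ok", , drop = FALSE]
    }
    v <- rec[[metric]]
    v[is.finite(v)]
  }
  x <- pull(records_ref); y <- pull(records_alt)
  assert_that(length(x) >= 2 && length(y) >= 2,
              "need >= 2 measurable cells per group")
  m0 <- mean(x); m1 <- mean(y)
  pc <- if (m0 != 0) 100 * (m1 - m0) / m0 else NA_real_
  p <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL)$p.value)
  list(metric = metric, mean_ref = m0, mean_alt = m1,
       percent_change = pc, p_value = p, test = test,
       n_ref = length(x), n_alt = length(y))
}
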