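# Classical segmentation backends: median-filter + Otsu + watershed for
# nuclei, marker-controlled watershed (seeded region growing) for cell
# bodies, multiscale Hessian ridge filtering for actin stress fibers.
# The contracts are backend-agnostic (instance masks in, metrics out), so a
# learned segmenter can replace any stage without touching the measurements.

norm01 <- function(x) {
  r <- range(x)
  if (diff(r) <= .Machine$double.eps) return(NULL)
  (x - r[1]) / diff(r)
}

#' Segment nuclei from the DNA channel
#'
#' Median filter, global Otsu threshold, 8-connectivity components,
#' small-object removal, then a distance-transform watershed to split
#' touching nuclei.
#'
#' @param image list of channel matrices with `dna`.
#' @param min_area discard components smaller than this (pixels^2).
#' @param median_radius median-filter window radius (pixels).
#' @param min_separation minimum seed separation for the watershed split
#'   (pixels); controls the local-maximum neighbourhood.
#' @return integer label matrix, labels 1..K.
#' @export
segment_nuclei <- function(image, min_area = 50, median_radius = 2,
                           min_separation = 10) {
  dna <- image$dna
  assert_that(!is.null(dna), "dna channel missing")
  x <- norm01(dna)
  if (is.null(x)) {
    stop("degenerate input: dna channel is constant, Otsu threshold undefined",
         call. = FALSE)
  }
  xf <- EBImage::medianFilter(x, median_radius)
  th <- EBImage::otsu(EBImage::Image(xf), range = c(0, 1))
  bw <- xf > th
  lab <- label8(bw)
  lab <- drop_small(lab, min_area)
  if (max(lab) == 0) return(lab)
  # split touching nuclei: watershed on the distance transform
  dm <- EBImage::distmap(lab > 0)
  ws <- EBImage::watershed(dm, tolerance = 1,
                           ext = max(1L, as.integer(min_separation / 2)))
  out <- drop_small(as_label_matrix(ws), min_area)
  relabel(out)
}

drop_small <- function(lab, min_area) {
  lab <- as_label_matrix(lab)
  if (max(lab) == 0) return(lab)
  sizes <- tabulate(lab[lab > 0], max(lab))
  kill <- which(sizes < min_area)
  if (length(kill)) lab[lab %in% kill] <- 0L
  relabel(lab)
}

#' Segment cell bodies with nuclei as markers
#'
#' Foreground is the Otsu threshold of a smoothed actin+protein composite,
#' morphologically closed and hole-filled; instances are grown from the
#' nucleus markers by seeded propagation (marker-controlled watershed), so
#' each cell label contains exactly its seed nucleus.
#'
#' @param image list of channel matrices with `actin` and `protein`.
#' @param nuclei nucleus label matrix from [segment_nuclei()].
#' @param sigma Gaussian smoothing sd for the composite (pixels).
#' @return integer label matrix; cell label k is grown from nucleus k.
#'   Border-touching cells are kept in the mask and excluded later by
#'   [measure_cells()].
#' @export
segment_cells <- function(image, nuclei, sigma = 2) {
  nuclei <- as_label_matrix(nuclei)
  assert_that(max(nuclei) > 0, "no nuclei to seed cell segmentation")
  comp <- image$actin + image$protein
  x <- norm01(comp)
  if (is.null(x)) stop("degenerate input: actin+protein composite is constant",
                       call. = FALSE)
  # edge-preserving denoising for the foreground decision (a Gaussian blur
  # would shift the cell boundary); the smoothed composite is still used as
  # the propagation landscape
  xm <- EBImage::medianFilter(x, 2)
  th <- EBImage::otsu(EBImage::Image(xm), range = c(0, 1))
  fg <- xm > th
  xs <- EBImage::gblur(x, sigma = sigma)
  fg <- EBImage::closing(fg, EBImage::makeBrush(5, "disc"))
  fg <- EBImage::fillHull(fg)
  fg <- fg | nuclei > 0
  cells <- EBImage::propagate(EBImage::Image(xs), seeds = nuclei, mask = fg)
  as_label_matrix(cells)
}

#' Segment actin stress fibers with a multiscale ridge filter
#'
#' Bright curvilinear structures are enhanced by the most negative Hessian
#' eigenvalue of the Gaussian-smoothed actin channel (scale-normalised,
#' maximum over `ridge_sigmas`), thresholded by Otsu within the cell
#' foreground, and filtered by component major-axis length. The cell
#' foreground is eroded by ~2x the largest sigma first so the step edge at
#' the cell boundary cannot masquerade as a fiber.
#'
#' @param image list of channel matrices with `actin`.
#' @param cells cell label matrix.
#' @param ridge_sigmas Gaussian scales (pixels).
#' @param length_min discard components with end-to-end (max Feret) length
#'   below this (pixels).
#' @return logical matrix; `TRUE` on fiber pixels (possibly empty).
#' @export
segment_stress_fibers <- function(image, cells, ridge_sigmas = c(1, 2),
                                  length_min = 10) {
  actin <- image$actin
  assert_that(!is.null(actin), "actin channel missing")
  cells <- as_label_matrix(cells)
  empty <- matrix(FALSE, nrow(actin), ncol(actin))
  x <- norm01(actin)
  if (is.null(x) || max(cells) == 0) return(empty)

  # fill the background with the median within-cell intensity so the step
  # edge at the cell boundary produces no ridge response of its own
  xf <- x
  xf[cells == 0] <- stats::median(x[cells > 0])
  ridge <- matrix(0, nrow(x), ncol(x))
  for (s in ridge_sigmas) {
    ridge <- pmax(ridge, s^2 * ridge_response(xf, s))
  }
  margin <- ceiling(max(ridge_sigmas))
  fg <- EBImage::erode(cells > 0, EBImage::makeBrush(2 * margin + 1, "disc"))
  vals <- ridge[fg]
  if (!length(vals) || diff(range(vals)) < 1e-6 || max(vals) < 1e-4) {
    return(empty)
  }
  th <- otsu_vector(vals)
  mask <- ridge > th & fg
  if (!any(mask)) return(empty)
  # object refinement: the ridge response spreads ~sigma sideways and
  # decays at fiber endpoints, so the final objects are the bright
  # within-cell components (actin above Otsu of the cell foreground) that
  # carry ridge support; this mirrors the two-stage pixel/object
  # classification the classical backend replaces
  cell_vals <- x[cells > 0]
  if (diff(range(cell_vals)) > 1e-6) {
    th_int <- otsu_vector(cell_vals)
    cand <- (x > th_int) & fg
    if (any(cand)) {
      clab <- label8(cand)
      supported <- setdiff(unique(clab[mask & cand]), 0L)
      if (length(supported)) {
        mask <- matrix(clab %in% supported, nrow(clab), ncol(clab))
      }
    }
  }
  lab <- label8(mask)
  lens <- component_lengths(lab)
  keep <- as.integer(names(lens)[lens >= length_min])
  mask & matrix(lab %in% keep, nrow(lab), ncol(lab))
}

# Negated smaller Hessian eigenvalue (bright-ridge response >= 0) at one
# Gaussian scale, via separable Gaussian-derivative kernels.
ridge_response <- function(x, sigma) {
  half <- max(2L, ceiling(3 * sigma))
  t <- seq(-half, half)
  g <- exp(-t^2 / (2 * sigma^2)); g <- g / sum(g)
  g1 <- -t / sigma^2 * g
  g2 <- (t^2 / sigma^2 - 1) / sigma^2 * g
  conv_sep <- function(im, kr, kc) {
    k <- outer(kr, kc)
    EBImage::filter2(im, k, boundary = "replicate")
  }
  ixx <- conv_sep(x, g2, g)
  iyy <- conv_sep(x, g, g2)
  ixy <- conv_sep(x, g1, g1)
  tr <- ixx + iyy
  dd <- sqrt(pmax(0, (ixx - iyy)^2 + 4 * ixy^2))
  lmin <- (tr - dd) / 2
  pmax(0, -lmin)
}

#' IoU matching of predicted instances against ground-truth instances
#'
#' Each truth label is matched to the predicted label with maximal
#' intersection; returns the per-truth-instance intersection-over-union.
#'
#' @param pred,truth label matrices of equal shape.
#' @return data frame `truth_label`, `pred_label`, `iou`.
#' @export
match_instances <- function(pred, truth) {
  pred <- as_label_matrix(pred); truth <- as_label_matrix(truth)
  ids <- sort(unique(truth[truth > 0]))
  out <- lapply(ids, function(k) {
    tmask <- truth == k
    under <- pred[tmask]
    tab <- table(under[under > 0])
    if (!length(tab)) {
      return(data.frame(truth_label = k, pred_label = NA_integer_, iou = 0))
    }
    pbest <- as.integer(names(tab)[which.max(tab)])
    inter <- max(tab)
    uni <- sum(tmask) + sum(pred == pbest) - inter
    data.frame(truth_label = k, pred_label = pbest, iou = inter / uni)
  })
  do.call(rbind, out)
}
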