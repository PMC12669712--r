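# Region properties of labelled masks.
#
# The shape descriptors follow the moment-ellipse convention: axis lengths
# are 4*sqrt(eigenvalues) of the pixel-coordinate covariance matrix, and the
# axis ratio reported as `eccentricity_ratio` is minor/major (1 = perfectly
# round), NOT the conic-section eccentricity. Solidity is region area over
# the area of the rasterised convex hull of the region's pixels.

#' Geometric properties of every instance in a label mask
#'
#' @param labels integer matrix; 0 = background, k > 0 = instance k.
#' @return data frame with one row per label: `label`, `area` (pixels),
#'   `centroid_r`, `centroid_c` (0-based pixel coordinates),
#'   `major_axis`, `minor_axis` (pixels), `eccentricity_ratio`
#'   (minor/major, in (0,1]), `solidity` (in (0,1]), `touches_border`.
#' @export
region_props <- function(labels) {
  labels <- as_label_matrix(labels)
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) {
    return(data.frame(label = integer(), area = numeric(),
                      centroid_r = numeric(), centroid_c = numeric(),
                      major_axis = numeric(), minor_axis = numeric(),
                      eccentricity_ratio = numeric(), solidity = numeric(),
                      touches_border = logical()))
  }
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- which(labels > 0)
  lab <- labels[idx]
  rr <- (idx - 1L) %% nr   # 0-based row
  cc <- (idx - 1L) %/% nr  # 0-based col
  out <- lapply(ids, function(k) {
    sel <- lab == k
    r <- rr[sel]; c <- cc[sel]
    n <- length(r)
    cr <- mean(r); cc0 <- mean(c)
    mu20 <- mean((r - cr)^2)
    mu02 <- mean((c - cc0)^2)
    mu11 <- mean((r - cr) * (c - cc0))
    tr <- mu20 + mu02
    det2 <- sqrt(max(0, (mu20 - mu02)^2 / 4 + mu11^2))
    l1 <- tr / 2 + det2
    l2 <- max(0, tr / 2 - det2)
    major <- 4 * sqrt(l1)
    minor <- 4 * sqrt(l2)
    ecc <- if (major > 0) minor / major else 1
    data.frame(
      label = k, area = n, centroid_r = cr, centroid_c = cc0,
      major_axis = major, minor_axis = minor,
      eccentricity_ratio = ecc,
      solidity = region_solidity(r, c),
      touches_border = any(r == 0 | c == 0 | r == nr - 1L | c == nc - 1L)
    )
  })
  do.call(rbind, out)
}

# Solidity = n / (# lattice points inside the convex hull of the pixel
# centres, boundary inclusive). For digitally convex regions (digitisations
# of convex sets, e.g. the generator's ellipses) this is exactly 1.
region_solidity <- function(r, c) {
  n <- length(r)
  if (n <= 3) return(1)
  pts <- cbind(c, r)  # chull expects x, y
  h <- grDevices::chull(pts)
  if (length(h) < 3) return(1)  # collinear region: hull degenerates
  hx <- pts[h, 1]; hy <- pts[h, 2]
  # candidate lattice points: bounding box
  gx <- seq(min(c), max(c)); gy <- seq(min(r), max(r))
  gr <- expand.grid(x = gx, y = gy)
  inside <- rep(TRUE, nrow(gr))
  m <- length(h)
  eps <- 1e-9
  # chull returns vertices clockwise (in x right / y up convention);
  # test sign of cross product against every edge, boundary inclusive
  crosses <- matrix(0, nrow(gr), m)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    crosses[, i] <- ex * (gr$y - hy[i]) - ey * (gr$x - hx[i])
  }
  inside <- apply(crosses, 1, function(v) all(v <= eps) || all(v >= -eps))
  hull_area <- sum(inside)
  if (hull_area < n) hull_area <- n
  n / hull_area
}

# End-to-end (max Feret) length of every component in a label matrix,
# +1 px for pixel extent. The moment-ellipse major axis overestimates the
# length of thin straight objects by ~15%, so fibers are measured this way.
component_lengths <- function(labels) {
  labels <- as_label_matrix(labels)
  ids <- sort(unique(labels[labels > 0]))
  nr <- nrow(labels)
  out <- vapply(ids, function(k) {
    idx <- which(labels == k)
    r <- (idx - 1L) %% nr; c <- (idx - 1L) %/% nr
    if (length(r) == 1) return(1)
    h <- grDevices::chull(cbind(c, r))
    hr <- r[h]; hc <- c[h]
    max(sqrt(outer(hr, hr, "-")^2 + outer(hc, hc, "-")^2)) + 1
  }, numeric(1))
  setNames(out, ids)
}

# Coerce EBImage Image or matrix to an integer label matrix.
as_label_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  storage.mode(x) <- "integer"
  x
}

# 8-connectivity connected-component labelling. EBImage::bwlabel is
# 4-connective; diagonal-touching fragments are merged with a union-find
# pass over the two diagonal shift directions.
label8 <- function(mask) {
  m <- as_label_matrix(mask > 0)
  lab <- as_label_matrix(EBImage::bwlabel(m))
  k <- max(lab)
  if (k <= 1) return(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # \ diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # / diagonal
  for (p in list(cbind(a1[a1 > 0 & b1 > 0], b1[a1 > 0 & b1 > 0]),
                 cbind(a2[a2 > 0 & b2 > 0], b2[a2 > 0 & b2 > 0]))) {
    if (nrow(p)) {
      p <- unique(p[p[, 1] != p[, 2], , drop = FALSE])
      for (i in seq_len(nrow(p))) union(p[i, 1], p[i, 2])
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

# Relabel a mask to consecutive 1..K preserving order of first appearance
# of the sorted original labels.
relabel <- function(labels) {
  labels <- as_label_matrix(labels)
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) return(labels)
  out <- labels
  out[labels > 0] <- match(labels[labels > 0], ids)
  out
}
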