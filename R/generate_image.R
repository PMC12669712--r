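# Synthetic three-channel fluorescence images with recorded ground truth.
#
# Cells are rendered as convex (circular) bodies with one elliptical nucleus
# each; convexity keeps the truth morphometrics closed-form, which makes the
# generator a usable oracle for the segmentation pipeline. The protein
# channel is piecewise-constant (background / cytoplasm / nucleus) before
# noise, so with noise_sd = 0 it has exactly three intensity levels.

DNA_LEVEL <- 200     # a.u., nuclear DNA stain
ACTIN_BODY <- 70     # a.u., diffuse actin over the cell body
ACTIN_FIBER <- 170   # a.u., stress fibers

#' Generate one synthetic three-channel cell image with ground truth
#'
#' Renders `profile$cells_per_image` non-overlapping circular cells, each
#' with an elliptical nucleus whose centroid is offset from the cell centroid
#' by `nucleus_displacement_frac_mean` times the cell radius along a random
#' direction. Channels: `dna` bright in nuclei, `actin` covering the cell
#' body plus line-segment stress fibers, `protein` equal to
#' `yap_nuclear_mean` in nuclei and `yap_cyto_mean` in the cytoplasm.
#' Additive Gaussian noise (sd `noise_sd`) is applied on top of
#' `background_level`. The same seed always yields the identical image.
#'
#' @param profile an [effect_profile()].
#' @param image_shape integer vector `c(rows, cols)`, each >= 128.
#' @param seed integer seed.
#' @return list with `image` (list of `dna`, `actin`, `protein` matrices),
#'   and `truth`: `nuclei_mask`, `cell_mask` (label matrices),
#'   `fiber_mask` (binary), `cells` (noise-free per-cell records, see
#'   [measure_cells()]), and `params` (the per-cell generative parameters).
#' @export
generate_cell_image <- function(profile, image_shape = c(512, 512), seed = 1) {
  validate_profile(profile)
  assert_that(length(image_shape) == 2 && all(image_shape >= 128),
              "image_shape must be at least 128 x 128")
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  withr::with_seed(seed, {
    n <- profile$cells_per_image
    # nucleus geometry: semi-axes a >= b with geometric-mean radius r and
    # minor/major ratio q, so a = r/sqrt(q), b = r*sqrt(q)
    r_nuc <- pmax(4, rnorm(n, profile$nucleus_radius_mean,
                           profile$nucleus_radius_sd))
    q <- rep(profile$nucleus_axis_ratio_mean, n)
    a_nuc <- r_nuc / sqrt(q)
    b_nuc <- r_nuc * sqrt(q)
    theta <- runif(n, 0, pi)
    frac <- profile$nucleus_displacement_frac_mean
    # circular cell radius: nucleus plus displacement plus margin must fit,
    # with enough cytoplasm to host fibers of the profile's length scale
    r_cell <- pmax((a_nuc + 5) / (1 - frac), 2.2 * r_nuc)
    d <- frac * r_cell
    phi <- runif(n, 0, 2 * pi)

    # integer cell centres make zero-displacement fixtures exactly
    # symmetric (centroid, moments) on the pixel grid
    centers <- round(place_centers(n, nr, nc, r_cell))

    row_g <- matrix(rep(seq_len(nr) - 1, nc), nr, nc)
    col_g <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
    cell_mask <- matrix(0L, nr, nc)
    nuc_mask <- matrix(0L, nr, nc)
    fiber_mask <- matrix(FALSE, nr, nc)
    params <- vector("list", n)
    for (i in seq_len(n)) {
      cr <- centers[i, 1]; cc <- centers[i, 2]
      in_cell <- (row_g - cr)^2 + (col_g - cc)^2 <= r_cell[i]^2
      cell_mask[in_cell] <- i
      # nucleus centre offset along phi
      ncr <- cr + d[i] * cos(phi[i])
      ncc <- cc + d[i] * sin(phi[i])
      dr <- row_g - ncr; dc <- col_g - ncc
      u <- dr * cos(theta[i]) + dc * sin(theta[i])
      v <- -dr * sin(theta[i]) + dc * cos(theta[i])
      in_nuc <- (u / a_nuc[i])^2 + (v / b_nuc[i])^2 <= 1
      nuc_mask[in_nuc] <- i
      # stress fibers: straight segments of sampled length inside the cell
      k_fib <- rpois(1, profile$fiber_count_mean)
      fib_len <- numeric(0)
      if (k_fib > 0) {
        for (f in seq_len(k_fib)) {
          len <- max(4, rnorm(1, profile$fiber_length_mean,
                              profile$fiber_length_sd))
          ang <- runif(1, 0, pi)
          # fibers stay clear of the cell boundary so the ridge filter can
          # recover them without confounding from the body's step edge
          rad0 <- sqrt(runif(1)) * (r_cell[i] - 7)
          ang0 <- runif(1, 0, 2 * pi)
          fr <- cr + rad0 * cos(ang0); fc <- cc + rad0 * sin(ang0)
          seg <- draw_segment(fr, fc, ang, len, nr, nc)
          seg_r <- (seg - 1L) %% nr; seg_c <- (seg - 1L) %/% nr
          keep <- (seg_r - cr)^2 + (seg_c - cc)^2 <= (r_cell[i] - 6)^2
          seg <- seg[keep]
          if (length(seg)) {
            fiber_mask[seg] <- TRUE
            fib_len <- c(fib_len, len)
          }
        }
      }
      params[[i]] <- data.frame(
        cell_id = i, cell_row = cr, cell_col = cc, cell_radius = r_cell[i],
        nucleus_row = ncr, nucleus_col = ncc,
        nucleus_major_semiaxis = a_nuc[i], nucleus_minor_semiaxis = b_nuc[i],
        nucleus_axis_ratio = q[i], nucleus_displacement = d[i],
        n_fibers = length(fib_len)
      )
    }
    bg <- profile$background_level
    dna <- matrix(bg, nr, nc);     dna[nuc_mask > 0] <- bg + DNA_LEVEL
    actin <- matrix(bg, nr, nc);   actin[cell_mask > 0] <- ACTIN_BODY
    actin[fiber_mask] <- ACTIN_FIBER
    protein <- matrix(bg, nr, nc)
    protein[cell_mask > 0] <- profile$yap_cyto_mean
    protein[nuc_mask > 0] <- profile$yap_nuclear_mean

    clean <- list(dna = dna, actin = actin, protein = protein)
    truth_cells <- measure_cells(clean, nuc_mask, cell_mask, fiber_mask)
    truth_cells$condition <- profile$condition_name

    if (profile$noise_sd > 0) {
      img <- lapply(clean, function(ch) {
        ch <- ch + matrix(rnorm(nr * nc, 0, profile$noise_sd), nr, nc)
        ch[ch < 0] <- 0
        ch
      })
    } else img <- clean

    list(
      image = img,
      truth = list(nuclei_mask = nuc_mask, cell_mask = cell_mask,
                   fiber_mask = fiber_mask, cells = truth_cells,
                   params = do.call(rbind, params)),
      condition = profile$condition_name,
      seed = seed
    )
  })
}

# Rejection-sample non-overlapping cell centres with a border margin.
place_centers <- function(n, nr, nc, r_cell) {
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(4000)) {
      m <- r_cell[i] + 3
      if (nr - 2 * m <= 1 || nc - 2 * m <= 1) break
      cr <- runif(1, m, nr - 1 - m)
      cc <- runif(1, m, nc - 1 - m)
      if (i == 1 || all(sqrt((centers[seq_len(i - 1), 1] - cr)^2 +
                             (centers[seq_len(i - 1), 2] - cc)^2) >=
                        r_cell[seq_len(i - 1)] + r_cell[i] + 3)) {
        centers[i, ] <- c(cr, cc)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("image shape ", nr, "x", nc, " too small to place ", n,
           " non-overlapping cells of radius ~", round(max(r_cell)),
           " px; enlarge image_shape or reduce cells_per_image",
           call. = FALSE)
    }
  }
  centers
}

# Rasterise a straight segment of given length centred at (r0, c0), ~2 px
# wide; returns linear indices into an nr x nc matrix.
draw_segment <- function(r0, c0, angle, len, nr, nc) {
  t <- seq(-len / 2, len / 2, by = 0.25)
  pr <- r0 + t * cos(angle)
  pc <- c0 + t * sin(angle)
  # thicken by one pixel perpendicular to the segment
  pr <- c(pr, pr - sin(angle)); pc <- c(pc, pc + cos(angle))
  ir <- round(pr) + 1; ic <- round(pc) + 1
  ok <- ir >= 1 & ir <= nr & ic >= 1 & ic <= nc
  unique((ic[ok] - 1L) * nr + ir[ok])
}

#' Generate a multi-condition set of synthetic images
#'
#' With the packaged default profiles (9 cells per 512x512 image) and
#' `n_images = 12` this yields >= 100 cells per condition, matching the
#' pooling depth of the imaging experiments the generator emulates.
#'
#' @param profiles list of [effect_profile()] objects (one per condition).
#' @param n_images images per condition (>= 1).
#' @param image_shape passed to [generate_cell_image()].
#' @param seed integer; each image gets a deterministic child seed.
#' @return list of per-image results as from [generate_cell_image()], with
#'   `condition` set; attribute `conditions` lists the condition names.
#' @export
generate_condition_set <- function(profiles, n_images = 12,
                                   image_shape = c(512, 512), seed = 1) {
  assert_that(n_images >= 1, "n_images must be >= 1")
  if (inherits(profiles, "hq_profile")) profiles <- list(profiles)
  out <- list()
  for (ci in seq_along(profiles)) {
    for (ii in seq_len(n_images)) {
      s <- child_seed(seed, "images", ci * 1000L + ii)
      out[[length(out) + 1]] <-
        generate_cell_image(profiles[[ci]], image_shape, seed = s)
    }
  }
  attr(out, "conditions") <- vapply(profiles, `[[`, "", "condition_name")
  out
}

#' Write a generated image as a multi-page TIFF with a ground-truth sidecar
#'
#' One 32-bit float page per channel (dna, actin, protein), plus
#' `<stem>_truth.json` holding the label masks (run-length free, plain
#' integer arrays) and the noise-free per-cell records.
#'
#' @param gen result of [generate_cell_image()].
#' @param stem output path without extension.
#' @return the TIFF path, invisibly.
#' @export
write_cell_image <- function(gen, stem) {
  pages <- lapply(gen$image, function(ch) ch / max(ch, 1))
  tiff::writeTIFF(pages, paste0(stem, ".tiff"), bits.per.sample = 32L)
  truth <- list(
    condition = gen$condition, seed = gen$seed,
    channel_max = lapply(gen$image, function(ch) max(ch, 1)),
    nuclei_mask = as.integer(gen$truth$nuclei_mask),
    cell_mask = as.integer(gen$truth$cell_mask),
    fiber_mask = as.integer(gen$truth$fiber_mask),
    shape = dim(gen$truth$cell_mask),
    cells = gen$truth$cells[, !vapply(gen$truth$cells, is.list, TRUE)]
  )
  jsonlite::write_json(truth, paste0(stem, "_truth.json"), digits = NA)
  invisible(paste0(stem, ".tiff"))
}

#' Read a multi-page TIFF written by [write_cell_image()]
#'
#' @param path TIFF path; `<stem>_truth.json` is read when present to
#'   restore intensity scaling and ground truth.
#' @export
read_cell_image <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  names(pages) <- c("dna", "actin", "protein")[seq_along(pages)]
  sidecar <- sub("\\.tiff?$", "_truth.json", path)
  truth <- NULL
  if (file.exists(sidecar)) {
    tr <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (ch in names(pages)) {
      pages[[ch]] <- pages[[ch]] * tr$channel_max[[ch]]
    }
    shp <- tr$shape
    truth <- list(
      nuclei_mask = matrix(tr$nuclei_mask, shp[1], shp[2]),
      cell_mask = matrix(tr$cell_mask, shp[1], shp[2]),
      fiber_mask = matrix(tr$fiber_mask, shp[1], shp[2]) > 0,
      cells = tr$cells
    )
  }
  list(image = pages, truth = truth)
}
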