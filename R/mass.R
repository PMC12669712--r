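# Mass photometry: contrast-to-mass calibration, Gaussian-mixture peak
# fitting on raw landing-event masses (EM, k selected by BIC), and
# higher-order complex detection in a mixed sample.

#' Construct a mass-photometry sample design
#'
#' @param species data frame or list of lists with `name`, `mass` (kDa)
#'   and `fraction`; fractions must sum to 1.
#' @param n_events number of landing events.
#' @param mass_sd per-event Gaussian mass spread (kDa).
#' @param contrast_slope,contrast_intercept calibration `mass = a*contrast + b`
#'   (slope non-zero).
#' @export
mass_design <- function(species, n_events = 5000, mass_sd = 8,
                        contrast_slope = 1000, contrast_intercept = 0) {
  if (!is.data.frame(species)) {
    species <- do.call(rbind, lapply(species, as.data.frame))
  }
  assert_that(all(c("name", "mass", "fraction") %in% names(species)),
              "species needs columns name, mass, fraction")
  assert_that(all(species$mass > 0), "masses must be positive")
  assert_that(abs(sum(species$fraction) - 1) < 1e-8, "fractions must sum to 1")
  assert_that(contrast_slope != 0, "contrast_slope must be non-zero")
  d <- list(species = species, n_events = as.integer(n_events),
            mass_sd = mass_sd, contrast_slope = contrast_slope,
            contrast_intercept = contrast_intercept)
  class(d) <- "hq_mass_design"
  d
}

#' Generate single-molecule landing events from a mixture design
#'
#' Masses are drawn from the Gaussian mixture defined by the design;
#' contrasts are back-computed through the calibration; event order is
#' shuffled. Deterministic per seed.
#'
#' @param design a [mass_design()].
#' @param seed integer seed.
#' @return list `events` (data frame `mass_kda`, `contrast`,
#'   `species_true`), `calibration` (`slope`, `intercept`), `design`.
#' @export
generate_mass_events <- function(design, seed = 1) {
  stopifnot(inherits(design, "hq_mass_design"))
  withr::with_seed(seed, {
    sp <- design$species
    comp <- sample(seq_len(nrow(sp)), design$n_events, replace = TRUE,
                   prob = sp$fraction)
    mass <- rnorm(design$n_events, sp$mass[comp], design$mass_sd)
    ord <- sample(design$n_events)
    events <- data.frame(
      mass_kda = mass[ord],
      contrast = (mass[ord] - design$contrast_intercept) / design$contrast_slope,
      species_true = sp$name[comp][ord]
    )
    list(events = events,
         calibration = list(slope = design$contrast_slope,
                            intercept = design$contrast_intercept),
         design = design)
  })
}

#' Fit Gaussian peaks to a mass distribution
#'
#' Univariate Gaussian-mixture fit by expectation-maximisation on the raw
#' masses (not on histogram bins) for k = 1..`k_max`; k chosen by BIC.
#' Initialisation is k-means++-style from a fixed seed, so the fit is
#' deterministic. A 5-kDa histogram is attached for reporting only.
#'
#' @param events numeric vector of masses (kDa), a data frame with a
#'   `mass_kda` or `contrast` column, or the list from
#'   [generate_mass_events()]. Contrast-unit input requires `calibration`.
#' @param k_max maximum number of peaks (default 4).
#' @param bin_width reporting histogram bin width (kDa).
#' @param seed seed for the initialisation.
#' @param calibration list `slope`, `intercept` when events are contrasts.
#' @return object of class `hq_peaks`: `peaks` (data frame `center`,
#'   `width`, `weight`, centers ascending, weights summing to 1), `k`,
#'   `loglik`, `bic` (per k), `n`, `histogram`, `degenerate`.
#' @export
fit_mass_peaks <- function(events, k_max = 4, bin_width = 5, seed = 1,
                           calibration = NULL) {
  x <- extract_masses(events, calibration)
  n <- length(x)
  assert_that(n >= 1, "no events")
  if (k_max >= 2 && n < 50) {
    stop("too few events (", n, ") for a multi-component fit; need >= 50",
         call. = FALSE)
  }
  if (diff(range(x)) <= .Machine$double.eps) {
    peaks <- data.frame(center = x[1], width = 0, weight = 1)
    return(structure(list(peaks = peaks, k = 1L, loglik = NA_real_,
                          bic = NA_real_, n = n,
                          histogram = mass_histogram(x, bin_width),
                          degenerate = TRUE),
                     class = "hq_peaks"))
  }
  fits <- lapply(seq_len(k_max), function(k) {
    # several seeded k-means++ restarts guard against local optima, which
    # otherwise bias BIC toward overfitted k
    cand <- lapply(0:2, function(r) em_gmm(x, k, seed + k + 1000L * r))
    cand[[which.max(vapply(cand, `[[`, 0, "loglik"))]]
  })
  bic <- vapply(seq_len(k_max), function(k) {
    -2 * fits[[k]]$loglik + (3 * k - 1) * log(n)
  }, numeric(1))
  kbest <- which.min(bic)
  fit <- fits[[kbest]]
  ord <- order(fit$mu)
  peaks <- data.frame(center = fit$mu[ord], width = fit$sigma[ord],
                      weight = fit$w[ord])
  structure(list(peaks = peaks, k = kbest, loglik = fit$loglik,
                 bic = setNames(bic, paste0("k", seq_len(k_max))), n = n,
                 histogram = mass_histogram(x, bin_width),
                 degenerate = FALSE),
            class = "hq_peaks")
}

extract_masses <- function(events, calibration = NULL) {
  if (is.list(events) && !is.data.frame(events) && !is.null(events$events)) {
    calibration <- calibration %||% events$calibration
    events <- events$events
  }
  if (is.data.frame(events)) {
    if (!is.null(events$mass_kda)) return(as.numeric(events$mass_kda))
    if (!is.null(events$contrast)) {
      assert_that(!is.null(calibration),
                  "contrast-unit events need a calibration (slope, intercept)")
      return(calibration$slope * as.numeric(events$contrast) +
               calibration$intercept)
    }
    stop("event table needs a mass_kda or contrast column", call. = FALSE)
  }
  as.numeric(events)
}

mass_histogram <- function(x, bin_width) {
  br <- seq(floor(min(x) / bin_width) * bin_width,
            ceiling(max(x) / bin_width) * bin_width + bin_width, bin_width)
  h <- hist(x, breaks = br, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}

# Univariate Gaussian-mixture EM with k-means++-style seeding.
em_gmm <- function(x, k, seed, max_iter = 300, tol = 1e-8) {
  n <- length(x)
  withr::with_seed(seed, {
    mu <- kmeanspp_centers(x, k)
    sigma <- rep(max(sd(x) / k, 1e-3), k)
    w <- rep(1 / k, k)
    ll_old <- -Inf
    sigma_floor <- max(1e-6, 1e-3 * sd(x))
    for (iter in seq_len(max_iter)) {
      logd <- vapply(seq_len(k), function(j)
        log(w[j]) + stats::dnorm(x, mu[j], sigma[j], log = TRUE),
        numeric(n))
      m <- apply(logd, 1, max)
      lse <- m + log(rowSums(exp(logd - m)))
      ll <- sum(lse)
      r <- exp(logd - lse)
      nk <- colSums(r)
      nk <- pmax(nk, 1e-12)
      w <- nk / n
      mu <- colSums(r * x) / nk
      sigma <- sqrt(pmax(colSums(r * (x - rep(mu, each = n))^2) / nk,
                         sigma_floor^2))
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
      ll_old <- ll
    }
    list(mu = mu, sigma = sigma, w = w, loglik = ll)
  })
}

kmeanspp_centers <- function(x, k) {
  centers <- x[sample.int(length(x), 1)]
  while (length(centers) < k) {
    d2 <- vapply(x, function(v) min((v - centers)^2), numeric(1))
    if (sum(d2) <= 0) {
      centers <- c(centers, x[sample.int(length(x), k - length(centers))])
      break
    }
    centers <- c(centers, x[sample.int(length(x), 1, prob = d2)])
  }
  centers[seq_len(k)]
}

#' Detect a higher-order complex in a mixed sample
#'
#' Positive iff the mixture's peak set contains a peak of weight at least
#' `weight_min` whose center exceeds every peak center of sample A and of
#' sample B by more than `mass_tol`. Also reports whether that center is
#' within `mass_tol` of the sum of the dominant A and B centers (the mass
#' a 1:1 complex would have).
#'
#' @param peaks_a,peaks_b,peaks_mix `hq_peaks` objects for the individual
#'   samples and the mixture.
#' @param mass_tol kDa; default 2x the pooled peak width of A and B.
#' @param weight_min minimum mixture fraction of the candidate peak.
#' @return list `positive`, `complex_peak` (row of the mixture peak table
#'   or `NULL`), `sum_consistent`, `expected_complex_mass`, `mass_tol`.
#' @export
detect_complex <- function(peaks_a, peaks_b, peaks_mix, mass_tol = NULL,
                           weight_min = 0.1) {
  pa <- peaks_a$peaks; pb <- peaks_b$peaks; pm <- peaks_mix$peaks
  if (is.null(mass_tol)) {
    ws <- c(pa$width, pb$width); wt <- c(pa$weight, pb$weight)
    mass_tol <- 2 * sqrt(sum(wt * ws^2) / sum(wt))
  }
  ceiling_ab <- max(pa$center, pb$center)
  top_a <- pa$center[which.max(pa$weight)]
  top_b <- pb$center[which.max(pb$weight)]
  expected <- top_a + top_b
  cand <- pm[pm$weight >= weight_min & pm$center > ceiling_ab + mass_tol, ,
             drop = FALSE]
  if (nrow(cand) == 0) {
    return(list(positive = FALSE, complex_peak = NULL,
                sum_consistent = FALSE, expected_complex_mass = expected,
                mass_tol = mass_tol))
  }
  best <- cand[which.max(cand$weight), ]
  list(positive = TRUE, complex_peak = best,
       sum_consistent = abs(best$center - expected) <= mass_tol,
       expected_complex_mass = expected, mass_tol = mass_tol)
}
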