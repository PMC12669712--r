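# End-to-end driver: simulate -> quantify images -> qPCR -> RPPA ->
# network routes -> mass photometry, with one user seed fanned out to
# per-stage child seeds and byte-identical TSV outputs per (config, seed).

#' Default pipeline configuration
#'
#' A desk-scale run of the whole synthetic experiment suite. Override
#' any block by passing a modified copy to [run_pipeline()].
#'
#' @param seed global seed (fanned out to fixed per-stage child seeds).
#' @param out_dir output directory.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("hq_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    images = list(
      enabled = TRUE,
      profiles = c("wt", "ksr1_null"),
      n_images = 2,
      image_shape = c(384, 384)
    ),
    qpcr = list(
      enabled = TRUE,
      fixtures = c("mef_ko_cyr61", "mef_ko_ctgf", "mef_oe_yap",
                   "mef_ko_yap", "mcf7_kd_yap")
    ),
    rppa = list(
      enabled = TRUE,
      n_proteins = 50, n_per_group = 3, noise_sd = 0.1,
      planted = c(STK4 = 2.5, LATS1 = -2.2, CCN1 = 2.1, CCN2 = -2.4,
                  AMOT = 2.2, TP53BP1 = -2.6, PXN = 2.3, RHOA = 2.05,
                  CTNNB1 = -2.1, MAPK1 = 2.15),
      fc_min = 2, alpha = 0.05, top_n = 100
    ),
    routes = list(
      enabled = TRUE,
      network = "toy_signor.tsv",
      source = "KSR1", target = "YAP1", max_len = 4, top_k = 5
    ),
    mass = list(
      enabled = TRUE,
      mass_a = 102, mass_b = 120, complex_fraction = 0.3,
      n_events = 3000, mass_sd = 8
    )
  )
}

valid_config_keys <- function() {
  list(
    top = c("seed", "out_dir", "images", "qpcr", "rppa", "routes", "mass"),
    images = c("enabled", "profiles", "n_images", "image_shape"),
    qpcr = c("enabled", "fixtures"),
    rppa = c("enabled", "n_proteins", "n_per_group", "noise_sd", "planted",
             "fc_min", "alpha", "top_n"),
    routes = c("enabled", "network", "source", "target", "max_len", "top_k"),
    mass = c("enabled", "mass_a", "mass_b", "complex_fraction", "n_events",
             "mass_sd")
  )
}

validate_config <- function(config) {
  keys <- valid_config_keys()
  unknown <- setdiff(names(config), keys$top)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  assert_that(is.numeric(config$seed %||% NA), "config$seed must be numeric")
  assert_that(is.character(config$out_dir %||% NA), "config$out_dir must be a path")
  for (blk in c("images", "qpcr", "rppa", "routes", "mass")) {
    if (is.null(config[[blk]])) next
    unknown <- setdiff(names(config[[blk]]), keys[[blk]])
    if (length(unknown)) {
      stop("unknown config key(s) in '", blk, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  invisible(config)
}

#' Run the full synthetic experiment pipeline
#'
#' Executes the enabled stages against synthetic inputs generated from the
#' packaged fixtures, writes per-stage TSVs plus a consolidated
#' `summary.tsv` and a `run_metadata.json` recording the seed, and returns
#' the summary invisibly. Identical (config, seed) pairs produce
#' byte-identical outputs. Config validation happens before any stage runs
#' and before any file is written.
#'
#' @param config configuration list as from [default_config()]; unknown
#'   keys are rejected.
#' @return invisibly, a list with per-stage results and the summary table.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  seed <- as.integer(config$seed)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  summary_rows <- list()
  res <- list()
  add <- function(stage, quantity, value) {
    summary_rows[[length(summary_rows) + 1]] <<-
      data.frame(stage = stage, quantity = quantity, value = value)
  }

  if (isTRUE(config$images$enabled)) {
    profs <- lapply(config$images$profiles, function(p)
      read_profile(hq_fixture("profiles", paste0(p, ".yaml"))))
    set <- generate_condition_set(profs, n_images = config$images$n_images,
                                  image_shape = config$images$image_shape,
                                  seed = child_seed(seed, "images"))
    cells <- quantify_condition_set(set)
    write_tsv(cells, file.path(out, "cells.tsv"))
    conds <- attr(set, "conditions")
    ref <- cells[cells$condition == conds[1], ]
    effects <- list()
    for (alt in conds[-1]) {
      for (m in c("mean_nuc_intensity", "nuclear_area",
                  "eccentricity_ratio", "nuclear_displacement")) {
        e <- estimate_effect(ref, cells[cells$condition == alt, ], m)
        effects[[length(effects) + 1]] <- data.frame(
          condition_ref = conds[1], condition_alt = alt, metric = m,
          mean_ref = e$mean_ref, mean_alt = e$mean_alt,
          percent_change = e$percent_change, p_value = e$p_value,
          test = e$test, n_ref = e$n_ref, n_alt = e$n_alt)
        add("images", paste0(alt, ":", m, ":percent_change"),
            e$percent_change)
      }
    }
    effects <- do.call(rbind, effects)
    write_tsv(effects, file.path(out, "image_effects.tsv"))
    res$images <- list(cells = cells, effects = effects)
  }

  if (isTRUE(config$qpcr$enabled)) {
    qrows <- list()
    for (fx in config$qpcr$fixtures) {
      des <- read_ct_design(hq_fixture("qpcr", paste0(fx, ".yaml")))
      tab <- generate_ct_table(des, seed = child_seed(seed, "qpcr",
                                                      match(fx, config$qpcr$fixtures)))
      target <- setdiff(des$genes, des$reference_gene)[1]
      rel <- ddct(tab, target, des$reference_gene, des$calibrator_condition)
      rel$fixture <- fx
      qrows[[fx]] <- rel
      alt <- setdiff(des$conditions, des$calibrator_condition)[1]
      add("qpcr", paste0(fx, ":fold"), rel$fold[rel$condition == alt])
    }
    qpcr <- do.call(rbind, qrows); rownames(qpcr) <- NULL
    write_tsv(qpcr, file.path(out, "qpcr_fold.tsv"))
    res$qpcr <- qpcr
  }

  if (isTRUE(config$rppa$enabled)) {
    rt <- generate_rppa_table(config$rppa$n_proteins, config$rppa$n_per_group,
                              planted = config$rppa$planted,
                              noise_sd = config$rppa$noise_sd,
                              seed = child_seed(seed, "rppa"))
    rr <- rppa_filter_rank(rt, fc_min = config$rppa$fc_min,
                           alpha = config$rppa$alpha,
                           top_n = config$rppa$top_n)
    write_tsv(rr$ranked, file.path(out, "rppa_ranked.tsv"))
    add("rppa", "n_differential", length(rr$differential))
    res$rppa <- rr
  }

  if (isTRUE(config$routes$enabled)) {
    g <- read_signor(hq_fixture("network", config$routes$network))
    routes <- enumerate_routes(g, config$routes$source, config$routes$target,
                               max_len = config$routes$max_len)
    ranked_universe <- if (!is.null(res$rppa)) res$rppa$ranked$protein else character(0)
    # the toy network names real pathway members; include them in the
    # scoring universe alongside whatever RPPA ranked
    ranked_universe <- unique(c(ranked_universe,
                                setdiff(igraph::V(g)$name,
                                        c(config$routes$source,
                                          config$routes$target))))
    scores <- lapply(routes, score_route, graph = g,
                     ranked = ranked_universe)
    rk <- rank_routes_identify_hub(routes, scores,
                                   top_k = config$routes$top_k)
    write_tsv(rk$ranked, file.path(out, "routes.tsv"))
    add("routes", "n_routes", length(routes))
    add("routes", "top_route_total", rk$ranked$total[1])
    res$routes <- c(rk, list(routes = routes, scores = scores))
  }

  if (isTRUE(config$mass$enabled)) {
    ms <- config$mass
    s_mass <- child_seed(seed, "mass")
    des_a <- mass_design(data.frame(name = "A", mass = ms$mass_a, fraction = 1),
                         n_events = ms$n_events, mass_sd = ms$mass_sd)
    des_b <- mass_design(data.frame(name = "B", mass = ms$mass_b, fraction = 1),
                         n_events = ms$n_events, mass_sd = ms$mass_sd)
    fr <- ms$complex_fraction
    des_mix <- mass_design(data.frame(
      name = c("A", "B", "A:B"),
      mass = c(ms$mass_a, ms$mass_b, ms$mass_a + ms$mass_b),
      fraction = c((1 - fr) / 2, (1 - fr) / 2, fr)),
      n_events = ms$n_events, mass_sd = ms$mass_sd)
    pa <- fit_mass_peaks(generate_mass_events(des_a, s_mass), seed = s_mass)
    pb <- fit_mass_peaks(generate_mass_events(des_b, s_mass + 1), seed = s_mass)
    pm <- fit_mass_peaks(generate_mass_events(des_mix, s_mass + 2), seed = s_mass)
    call <- detect_complex(pa, pb, pm)
    peaks <- rbind(cbind(sample = "A", pa$peaks),
                   cbind(sample = "B", pb$peaks),
                   cbind(sample = "mix", pm$peaks))
    write_tsv(peaks, file.path(out, "mass_peaks.tsv"))
    add("mass", "complex_detected", as.numeric(call$positive))
    add("mass", "complex_mass",
        if (call$positive) call$complex_peak$center else NA_real_)
    res$mass <- list(peaks = peaks, call = call)
  }

  summary <- if (length(summary_rows)) do.call(rbind, summary_rows) else
    data.frame(stage = character(), quantity = character(), value = numeric())
  write_tsv(summary, file.path(out, "summary.tsv"))
  jsonlite::write_json(
    list(seed = seed, package_version = as.character(utils::packageVersion("hippoquant")),
         stages_run = names(res)),
    file.path(out, "run_metadata.json"), auto_unbox = TRUE, digits = NA)
  res$summary <- summary
  invisible(res)
}

#' Segment and measure every image of a condition set
#'
#' Full image pipeline (nuclei, cells, fibers, per-cell records) over the
#' output of [generate_condition_set()], pooling cells across images
#' within each condition.
#'
#' @param set list from [generate_condition_set()].
#' @param min_area,median_radius passed to [segment_nuclei()].
#' @return data frame of per-cell records with `condition` and `image`
#'   columns.
#' @export
quantify_condition_set <- function(set, min_area = 50, median_radius = 2) {
  rows <- list()
  for (i in seq_along(set)) {
    gen <- set[[i]]
    nuc <- segment_nuclei(gen$image, min_area = min_area,
                          median_radius = median_radius)
    if (max(nuc) == 0) next
    cells <- segment_cells(gen$image, nuc)
    fibers <- segment_stress_fibers(gen$image, cells)
    rec <- measure_cells(gen$image, nuc, cells, fibers)
    if (nrow(rec) == 0) next
    rec$condition <- gen$condition
    rec$image <- i
    rows[[length(rows) + 1]] <- rec
  }
  if (!length(rows)) return(cbind(empty_cell_records(),
                                  condition = character(), image = integer()))
  do.call(rbind, rows)
}
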