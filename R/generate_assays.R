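# Synthetic qPCR cycle-threshold tables and RPPA expression tables with
# known ground truth.

#' Construct a qPCR experiment design
#'
#' @param genes character vector of assayed genes, including the reference.
#' @param reference_gene internal-control gene (fold change 1 everywhere).
#' @param conditions condition labels.
#' @param calibrator_condition condition all fold changes are relative to.
#' @param true_fold_change named list `gene -> condition -> positive fold`.
#' @param reference_ct_mean baseline CT (cycles).
#' @param replicates technical replicates per run (wells).
#' @param runs independent biological runs.
#' @param ct_noise_sd per-well Gaussian CT noise (cycles).
#' @export
ct_design <- function(genes, reference_gene, conditions,
                      calibrator_condition, true_fold_change,
                      reference_ct_mean = 20, replicates = 3, runs = 3,
                      ct_noise_sd = 0.15) {
  d <- list(genes = as.character(genes),
            reference_gene = as.character(reference_gene),
            conditions = as.character(conditions),
            calibrator_condition = as.character(calibrator_condition),
            true_fold_change = true_fold_change,
            reference_ct_mean = reference_ct_mean,
            replicates = as.integer(replicates), runs = as.integer(runs),
            ct_noise_sd = ct_noise_sd)
  assert_that(d$reference_gene %in% d$genes, "reference gene not in genes")
  assert_that(d$calibrator_condition %in% d$conditions,
              "calibrator_condition not in conditions")
  assert_that(d$ct_noise_sd >= 0, "ct_noise_sd must be >= 0")
  assert_that(d$replicates >= 1 && d$runs >= 1, "replicates and runs must be >= 1")
  for (g in d$genes) {
    for (cn in d$conditions) {
      fc <- d$true_fold_change[[g]][[cn]]
      assert_that(is.numeric(fc) && fc > 0,
                  paste0("non-positive or missing fold change for ", g, "/", cn))
      if (g == d$reference_gene) {
        assert_that(fc == 1, "reference gene must have fold change 1 in all conditions")
      }
    }
  }
  class(d) <- "hq_ct_design"
  d
}

#' Read a qPCR design fixture from YAML
#' @param path YAML file with the fields of [ct_design()].
#' @export
read_ct_design <- function(path) {
  y <- yaml::read_yaml(path)
  ct_design(genes = y$genes, reference_gene = y$reference_gene,
            conditions = y$conditions,
            calibrator_condition = y$calibrator_condition,
            true_fold_change = y$true_fold_change,
            reference_ct_mean = y$reference_ct_mean,
            replicates = y$replicates, runs = y$runs,
            ct_noise_sd = y$ct_noise_sd)
}

#' Generate a cycle-threshold table from a design
#'
#' CT for gene g in condition c is
#' `reference_ct_mean - log2(true_fold_change[g, c])` plus per-well
#' Gaussian noise; the reference gene's CT is condition-independent. Each
#' (gene, condition) contributes `replicates x runs` wells.
#'
#' @param design a [ct_design()].
#' @param seed integer seed.
#' @return data frame `sample_id`, `condition`, `gene`, `replicate`,
#'   `run`, `ct`.
#' @export
generate_ct_table <- function(design, seed = 1) {
  stopifnot(inherits(design, "hq_ct_design"))
  withr::with_seed(seed, {
    rows <- expand.grid(replicate = seq_len(design$replicates),
                        run = seq_len(design$runs),
                        gene = design$genes,
                        condition = design$conditions,
                        stringsAsFactors = FALSE)
    fc <- mapply(function(g, cn) design$true_fold_change[[g]][[cn]],
                 rows$gene, rows$condition)
    rows$ct <- design$reference_ct_mean - log2(fc) +
      rnorm(nrow(rows), 0, design$ct_noise_sd)
    rows$sample_id <- paste(rows$condition, rows$run, sep = "_run")
    rows[, c("sample_id", "condition", "gene", "replicate", "run", "ct")]
  })
}

#' Generate a synthetic RPPA log2-expression table
#'
#' Control samples are N(0, noise_sd) per protein; treated samples are
#' shifted by the planted log2 effects. Unplanted proteins share the null
#' distribution across groups.
#'
#' @param n_proteins number of proteins.
#' @param n_per_group samples per group (>= 2).
#' @param planted named numeric vector, protein -> log2 effect. Names not
#'   of the form `P###` are assigned to the first proteins in order.
#' @param noise_sd per-sample Gaussian sd (log2 units).
#' @param seed integer seed.
#' @return list `values` (proteins x samples matrix of log2 expression),
#'   `groups` (per-sample labels `control`/`treated`), `planted`.
#' @export
generate_rppa_table <- function(n_proteins = 50, n_per_group = 3,
                                planted = c(), noise_sd = 0.1, seed = 1) {
  assert_that(n_per_group >= 2, "n_per_group must be >= 2")
  withr::with_seed(seed, {
    prot <- sprintf("P%03d", seq_len(n_proteins))
    if (length(planted)) {
      nm <- names(planted)
      if (is.null(nm) || any(!nzchar(nm))) {
        names(planted) <- prot[seq_along(planted)]
      } else {
        missing <- setdiff(nm, prot)
        # allow arbitrary protein names: substitute them into the roster
        if (length(missing)) prot[seq_along(missing)] <- missing
      }
      assert_that(all(names(planted) %in% prot), "planted names exceed n_proteins")
    }
    groups <- rep(c("control", "treated"), each = n_per_group)
    vals <- matrix(rnorm(n_proteins * length(groups), 0, noise_sd),
                   n_proteins, length(groups),
                   dimnames = list(prot, paste0(groups, seq_along(groups))))
    if (length(planted)) {
      vals[names(planted), groups == "treated"] <-
        vals[names(planted), groups == "treated"] + planted
    }
    list(values = vals, groups = groups, planted = planted)
  })
}
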