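#' Run the full comparative-diversity pipeline
#'
#' Orchestrates all stages over a list of species datasets: degeneracy
#' classification, per-species diversity estimation (pi_4D, pi_0D,
#' within-individual pi, F_IT), heterozygosity-dispersion classification,
#' the cross-species DFE-shape regression, the sweep-rate fit, Pagel's
#' lambda on ln(pi_4D), the family ANOVA and trait correlations. The run
#' is a pure function of its inputs and seed: the same call returns an
#' identical report.
#'
#' @param species A named list, one entry per species, each a list with
#'   elements `geno` (genotype tibble: `cds_id`, `pos`, `gt_a`, `gt_b`)
#'   and `classes` (site classification), e.g. from
#'   [sim_pair_genotypes()] or [read_genotype_vcf()] +
#'   [classify_fasta()].
#' @param traits Tibble with one row per species: `species`, `body_size`,
#'   `nc`, and optionally `family` plus further trait columns. Required
#'   columns are checked by name and a missing one is reported explicitly.
#' @param tree Optional `phylo` with tips matching the species names; when
#'   supplied, Pagel's lambda of `ln(pi_4D)` is computed.
#' @param constants List of model constants: `mu` (default 2.9e-9), `J`
#'   (default 1e-5), `UT` (default 0).
#' @param window_length Callable sites per dispersion window (default
#'   1000); species with fewer than 30 windows get `NA` classification.
#' @param seed Seed for all stochastic stages (bootstraps, optimizer
#'   starts).
#' @param out_dir Optional directory: writes `species_report.tsv`,
#'   `cross_species.json` and `run_config.json` there.
#'
#' @return List with `species_report` (per-species tibble), `cross_species`
#'   (list: `dfe`, `sweep`, `lambda`, `anova`, `correlations`), and
#'   `log` (excluded-record counts per species).
#' @export
run_pipeline <- function(species, traits, tree = NULL,
                         constants = list(mu = 2.9e-9, J = 1e-5, UT = 0),
                         window_length = 1000, seed = 1, out_dir = NULL) {
  stopifnot(is.list(species), length(species) >= 3, !is.null(names(species)))
  need <- c("species", "body_size", "nc")
  miss <- setdiff(need, names(traits))
  if (length(miss) > 0) {
    stop("trait table is missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  mu <- constants$mu %||% 2.9e-9
  J <- constants$J %||% 1e-5
  UT <- constants$UT %||% 0

  per_species <- purrr::imap(species, function(sp, name) {
    est <- tryCatch(
      estimate_diversity(sp$geno, sp$classes),
      error = function(e) {
        stop("diversity stage failed for species '", name, "': ",
          conditionMessage(e),
          call. = FALSE
        )
      }
    )
    row4 <- est[est$class == "4D", ]
    row0 <- est[est$class == "0D", ]
    disp <- tryCatch(
      {
        prof <- window_counts(
          dplyr::rename(sp$geno, gt = "gt_a"),
          classes = sp$classes, window_length = window_length
        )
        if (nrow(prof) >= 30) {
          dispersion_class(prof, seed = seed)$classification
        } else {
          NA_character_
        }
      },
      error = function(e) NA_character_
    )
    tibble::tibble(
      species = name,
      pi_4d = row4$pi_b, pi_0d = row0$pi_b,
      ratio_0d_4d = row0$pi_b / row4$pi_b,
      pi_within_a = row4$pi_within_a, pi_within_b = row4$pi_within_b,
      f_it = attr(est, "f_it"),
      dispersion = disp,
      dropped = sum(attr(est, "dropped"))
    )
  })
  report <- purrr::list_rbind(per_species)
  report <- dplyr::left_join(report, traits, by = "species")

  dfe <- tryCatch(
    beta_slope(report, seed = seed),
    error = function(e) {
      stop("dfe stage failed: ", conditionMessage(e), call. = FALSE)
    }
  )
  sweep <- tryCatch(
    fit_sweep_rate(report, mu = mu, J = J, UT = UT, seed = seed),
    error = function(e) {
      stop("linked-selection stage failed: ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  lambda <- NULL
  if (!is.null(tree)) {
    lambda <- pagel_lambda(tree, stats::setNames(
      log(report$pi_4d),
      report$species
    ))
  }
  anova <- if ("family" %in% names(report) &&
    length(unique(report$family)) >= 2) {
    anova_oneway(
      dplyr::mutate(report, ln_pi4 = log(.data$pi_4d)),
      "ln_pi4", "family"
    )
  } else {
    NULL
  }
  correlations <- list(
    fit_vs_body = if (nrow(report) >= 3) {
      pearson_cor(report, "f_it", "body_size")
    } else {
      NULL
    }
  )
  out <- list(
    species_report = report,
    cross_species = list(
      dfe = dfe, sweep = sweep, lambda = lambda,
      anova = anova, correlations = correlations
    ),
    log = purrr::map(species, function(sp) {
      attr(count_site_classes(sp$geno, sp$classes), "dropped")
    })
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report, file.path(out_dir, "species_report.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    jsonlite::write_json(
      list(
        dfe = glance(dfe),
        sweep = glance(sweep),
        lambda = if (!is.null(lambda)) glance(lambda) else NULL,
        anova = anova,
        correlations = correlations
      ),
      file.path(out_dir, "cross_species.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
    jsonlite::write_json(
      list(
        constants = list(mu = mu, J = J, UT = UT),
        window_length = window_length, seed = seed,
        n_species = length(species)
      ),
      file.path(out_dir, "run_config.json"),
      auto_unbox = TRUE
    )
  }
  out
}
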