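#' Tally genotype configurations of a diploid pair by site class
#'
#' Given diploid genotype calls for two individuals (A and B) at variant
#' sites and a per-position site classification, counts for each class the
#' heterozygous sites unique to A (`n_a`), unique to B (`n_b`), shared
#' (`n_ab`), the fixed homozygous differences (`n_fix`), and the number of
#' callable sites (`n_tot`). Classified positions absent from `geno` are
#' taken to be invariant and callable in both individuals; positions with a
#' missing call (`"./."` or `NA`) in either individual are removed from
#' `n_tot` and all counts; multi-allelic records are dropped and counted in
#' the `"dropped"` attribute.
#'
#' @param geno Tibble of variant sites with columns `pos`, `gt_a`, `gt_b`
#'   (strings like `"0/1"`; `|` separators accepted) and, if `classes` has
#'   one, `cds_id`. Only biallelic SNPs should be encoded; any genotype
#'   containing an allele index > 1 is treated as multi-allelic and dropped.
#' @param classes Site classification tibble (`cds_id`, `pos`, `class`)
#'   from [classify_cds()], defining the callable universe.
#'
#' @return A tibble with one row per class (`4D`, `0D`, `other`) and
#'   columns `class`, `n_a`, `n_b`, `n_ab`, `n_fix`, `n_tot`. Attribute
#'   `"dropped"` holds a named count of excluded records by reason.
#' @export
count_site_classes <- function(geno, classes) {
  keys <- intersect(c("cds_id", "pos"), intersect(names(geno), names(classes)))
  stopifnot("pos" %in% keys)
  geno <- dplyr::mutate(geno,
    conf_a = gt_config(.data$gt_a),
    conf_b = gt_config(.data$gt_b)
  )
  dropped <- c(
    multiallelic = sum(geno$conf_a == "multi" | geno$conf_b == "multi",
      na.rm = TRUE
    ),
    missing_call = sum(geno$conf_a == "miss" | geno$conf_b == "miss")
  )
  multi <- dplyr::filter(geno, .data$conf_a == "multi" | .data$conf_b == "multi")
  miss <- dplyr::filter(geno, .data$conf_a == "miss" | .data$conf_b == "miss")
  ok <- dplyr::filter(
    geno,
    !.data$conf_a %in% c("multi", "miss"),
    !.data$conf_b %in% c("multi", "miss")
  )
  cls <- dplyr::left_join(classes, ok, by = keys)
  # sites dropped for missing/multi-allelic calls leave the callable universe
  bad <- dplyr::bind_rows(multi, miss)
  if (nrow(bad) > 0) {
    cls <- dplyr::anti_join(cls, bad, by = keys)
  }
  cls <- dplyr::mutate(cls,
    conf_a = dplyr::coalesce(.data$conf_a, "hom_ref"),
    conf_b = dplyr::coalesce(.data$conf_b, "hom_ref")
  )
  out <- cls |>
    dplyr::filter(.data$class %in% c("4D", "0D", "other")) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n_a = sum(.data$conf_a == "het" & .data$conf_b != "het"),
      n_b = sum(.data$conf_b == "het" & .data$conf_a != "het"),
      n_ab = sum(.data$conf_a == "het" & .data$conf_b == "het"),
      n_fix = sum((.data$conf_a == "hom_ref" & .data$conf_b == "hom_alt") |
        (.data$conf_a == "hom_alt" & .data$conf_b == "hom_ref")),
      n_tot = dplyr::n(),
      .groups = "drop"
    )
  out <- dplyr::left_join(
    tibble::tibble(class = c("4D", "0D", "other")),
    out,
    by = "class"
  ) |>
    dplyr::mutate(dplyr::across(
      dplyr::where(is.numeric),
      ~ dplyr::coalesce(.x, 0L)
    ))
  attr(out, "dropped") <- dropped
  out
}

# classify a diploid GT string
gt_config <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- dplyr::case_when(
    is.na(gt) | gt %in% c("./.", ".") ~ "miss",
    gt %in% c("0/0") ~ "hom_ref",
    gt %in% c("0/1", "1/0") ~ "het",
    gt %in% c("1/1") ~ "hom_alt",
    TRUE ~ "multi"
  )
  out
}

#' Between-individual nucleotide diversity
#'
#' For two diploid individuals A and B, the diversity between them averages
#' the four inter-individual haplotype comparisons:
#' \deqn{\pi_b = \frac{(n_A + n_B + n_{AB})/2 + n_{fix}}{n_{tot}}}
#' where heterozygous sites private to one individual or shared contribute
#' one half and fixed homozygous differences contribute one.
#'
#' @param counts Tibble with columns `n_a`, `n_b`, `n_ab`, `n_fix`,
#'   `n_tot`, e.g. from [count_site_classes()].
#' @return `counts` with an appended `pi_b` column. Rows with `n_tot == 0`
#'   get `NA` and a warning: diversity is undefined there, not zero.
#' @export
pi_b <- function(counts) {
  stopifnot(all(c("n_a", "n_b", "n_ab", "n_fix", "n_tot") %in% names(counts)))
  if (any(counts$n_tot == 0)) {
    warning("pi_b undefined where n_tot = 0; returning NA", call. = FALSE)
  }
  dplyr::mutate(counts,
    pi_b = ifelse(.data$n_tot > 0,
      ((.data$n_a + .data$n_b + .data$n_ab) / 2 + .data$n_fix) / .data$n_tot,
      NA_real_
    )
  )
}

#' Within-individual heterozygosity
#'
#' @param het_count Number of heterozygous sites in the individual.
#' @param n_tot Number of callable sites (must be positive; 0 gives `NA`
#'   with a warning).
#' @return `het_count / n_tot`, vectorized.
#' @export
pi_within <- function(het_count, n_tot) {
  if (any(n_tot == 0)) {
    warning("pi_within undefined where n_tot = 0; returning NA", call. = FALSE)
  }
  ifelse(n_tot > 0, het_count / n_tot, NA_real_)
}

#' Individual-vs-total differentiation F_IT
#'
#' Measures departure from random mating of two diploid individuals as
#' `1 - mean(H_obs) / mean(H_exp)` over polymorphic callable sites, where
#' `H_obs` is the fraction of the two individuals that are heterozygous at
#' the site and `H_exp` is the unbiased expected heterozygosity from the
#' pooled allele frequency `p` of the four haplotypes,
#' `(n/(n-1)) * 2 p (1 - p)` with `n = 4`. The small-sample correction
#' makes the estimator unbiased around zero under random mating; positive
#' values indicate heterozygote deficit (structure or inbreeding),
#' negative values heterozygote excess.
#'
#' @param geno Tibble with `gt_a`, `gt_b` diploid genotype strings; missing
#'   and multi-allelic calls are dropped.
#' @return A single number; `NA` (with a warning) when no polymorphic site
#'   remains.
#' @export
f_it <- function(geno) {
  conf_a <- gt_config(geno$gt_a)
  conf_b <- gt_config(geno$gt_b)
  keep <- !conf_a %in% c("miss", "multi") & !conf_b %in% c("miss", "multi")
  conf_a <- conf_a[keep]
  conf_b <- conf_b[keep]
  alt <- function(conf) c(hom_ref = 0, het = 1, hom_alt = 2)[conf]
  p <- (alt(conf_a) + alt(conf_b)) / 4
  poly <- p > 0 & p < 1
  if (!any(poly)) {
    warning("F_IT undefined without polymorphic sites; returning NA",
      call. = FALSE
    )
    return(NA_real_)
  }
  h_obs <- ((conf_a == "het") + (conf_b == "het")) / 2
  h_exp <- (4 / 3) * 2 * p * (1 - p)
  1 - mean(h_obs[poly]) / mean(h_exp[poly])
}

#' Mean pairwise diversity of aligned haplotypes
#'
#' Average proportion of differing positions over all haplotype pairs,
#' skipping positions where either member of a pair carries a gap, `N` or
#' other ambiguity code. Used for loci without degeneracy structure, e.g.
#' a mitochondrial barcode alignment.
#'
#' @param haps Character vector of >= 2 equal-length aligned sequences.
#' @return Mean per-site pairwise difference; `NA` with a warning if no
#'   pair has comparable sites.
#' @export
pairwise_pi <- function(haps) {
  stopifnot(length(haps) >= 2)
  haps <- toupper(haps)
  lens <- unique(nchar(haps))
  stopifnot(length(lens) == 1)
  mat <- do.call(rbind, strsplit(haps, ""))
  okbase <- matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))
  pairs <- utils::combn(length(haps), 2)
  pis <- apply(pairs, 2, function(ij) {
    comp <- okbase[ij[1], ] & okbase[ij[2], ]
    if (!any(comp)) {
      return(NA_real_)
    }
    mean(mat[ij[1], comp] != mat[ij[2], comp])
  })
  if (all(is.na(pis))) {
    warning("no comparable sites in any haplotype pair; returning NA",
      call. = FALSE
    )
    return(NA_real_)
  }
  mean(pis, na.rm = TRUE)
}

#' Per-species diversity summary
#'
#' Convenience wrapper running [count_site_classes()], [pi_b()],
#' [pi_within()] and [f_it()] for one species.
#'
#' @inheritParams count_site_classes
#' @return One-row-per-class tibble with `pi_b`, `pi_within_a`,
#'   `pi_within_b` and, as attributes, the overall `f_it` and the dropped
#'   record log.
#' @export
estimate_diversity <- function(geno, classes) {
  counts <- count_site_classes(geno, classes)
  out <- pi_b(counts)
  # per-individual het counts by class over the same callable universe
  keys <- intersect(c("cds_id", "pos"), intersect(names(geno), names(classes)))
  cls <- dplyr::inner_join(classes, geno, by = keys) |>
    dplyr::mutate(conf_a = gt_config(.data$gt_a), conf_b = gt_config(.data$gt_b)) |>
    dplyr::filter(
      !.data$conf_a %in% c("miss", "multi"),
      !.data$conf_b %in% c("miss", "multi")
    ) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      het_a = sum(.data$conf_a == "het"),
      het_b = sum(.data$conf_b == "het"),
      .groups = "drop"
    )
  out <- dplyr::left_join(out, cls, by = "class") |>
    dplyr::mutate(
      het_a = dplyr::coalesce(.data$het_a, 0L),
      het_b = dplyr::coalesce(.data$het_b, 0L),
      pi_within_a = ifelse(.data$n_tot > 0, .data$het_a / .data$n_tot, NA_real_),
      pi_within_b = ifelse(.data$n_tot > 0, .data$het_b / .data$n_tot, NA_real_)
    ) |>
    dplyr::select(-"het_a", -"het_b")
  attr(out, "f_it") <- suppressWarnings(f_it(geno))
  attr(out, "dropped") <- attr(counts, "dropped")
  out
}
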