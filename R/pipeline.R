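# End-to-end orchestration: QC -> domain proportions -> overlap -> core ->
# pan-microbiome -> diversity -> factor tests, written as a plain-text
# report directory.

#' Run the full microbiome analysis pipeline
#'
#' Takes a profile (either a `taxon_profile` list or the three TSV paths),
#' applies QC filtering, and runs every downstream analysis in order:
#' per-sample domain proportions, per-dataset genus overlap, core
#' microbiota (per dataset, pooled, and shared), the pan-microbiome
#' accumulation curve with Heaps fit and extrapolation, Shannon diversity,
#' PERMANOVA for every usable metadata factor (dataset, sex, age group,
#' sampling site, tissue source), divergence-to-median heterogeneity with
#' rank-sum comparisons for the binary factors, and separating
#' coefficients for sampling site and tissue source.
#'
#' All outputs are written to `out_dir` as TSV/JSON, and `run.log` records
#' every parameter and seed, so any number in the report can be recomputed.
#'
#' @param profile A `taxon_profile`, or `NULL` if paths are given.
#' @param counts_path,taxonomy_path,metadata_path TSV paths, used when
#'   `profile` is `NULL`.
#' @param out_dir Report directory (created).
#' @param min_reads QC threshold on total reads per sample (default 100).
#' @param detection,prevalence Core-microbiota thresholds (defaults 0.002
#'   and 0.20).
#' @param n_reps Accumulation-curve replicates (default 1000).
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param top_n Taxa kept in the collapsed phylum table (default 10).
#' @param n_extrapolate Extrapolation point for the pan estimate; defaults
#'   to four times the post-QC sample count.
#' @param seed Integer seed driving all randomised steps.
#' @return Invisibly, a list with every intermediate result (`qc`,
#'   `domain`, `overlap`, `core`, `accumulation`, `heaps`, `pan`,
#'   `diversity`, `permanova`, `divergence`, `coefficients`).
#' @export
run_pipeline <- function(profile = NULL,
                         counts_path = NULL, taxonomy_path = NULL,
                         metadata_path = NULL,
                         out_dir,
                         min_reads = 100,
                         detection = 0.002,
                         prevalence = 0.20,
                         n_reps = 1000,
                         n_permutations = 999,
                         top_n = 10,
                         n_extrapolate = NULL,
                         seed) {
  if (is.null(profile)) {
    if (is.null(counts_path) || is.null(taxonomy_path) ||
        is.null(metadata_path)) {
      stop("supply either a profile or all three TSV paths", call. = FALSE)
    }
    profile <- read_profile(counts_path, taxonomy_path, metadata_path)
  }
  if (missing(seed)) stop("seed is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("panmicro run ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("seed = ", seed),
    paste0("min_reads = ", min_reads),
    paste0("detection = ", detection),
    paste0("prevalence = ", prevalence),
    paste0("n_reps = ", n_reps),
    paste0("n_permutations = ", n_permutations),
    paste0("top_n = ", top_n)
  )

  # --- QC -------------------------------------------------------------
  qc <- qc_filter(profile$counts, min_reads = min_reads)
  readr::write_tsv(tidy(qc), file.path(out_dir, "qc_report.tsv"))
  counts <- qc$kept
  meta <- dplyr::filter(profile$metadata,
                        .data$sample_id %in% names(counts)[-1])
  log_lines <- c(log_lines,
                 paste0("samples_in = ", nrow(profile$metadata)),
                 paste0("samples_kept = ", nrow(meta)),
                 paste0("zero_read = ", length(qc$zero_read)),
                 paste0("low_read = ", length(qc$low_read)))

  rel <- to_relative_abundance(counts)

  # --- domain proportions --------------------------------------------
  domain <- domain_proportions(counts, profile$taxonomy, meta)
  readr::write_tsv(domain, file.path(out_dir, "domain_proportions.tsv"))

  # --- per-dataset overlap -------------------------------------------
  m <- profile_matrix(counts)
  ds <- align_samples(stats::setNames(meta$dataset, meta$sample_id),
                      colnames(m))
  genus_sets <- lapply(split(colnames(m), ds), function(ids) {
    rownames(m)[rowSums(m[, ids, drop = FALSE]) > 0]
  })
  overlap <- if (length(genus_sets) >= 2) overlap_sets(genus_sets) else NULL
  if (!is.null(overlap)) {
    jsonlite::write_json(list(
      regions = overlap$regions, intersection = overlap$intersection,
      shared_fraction = overlap$shared_fraction,
      union_size = overlap$union_size
    ), file.path(out_dir, "overlap.json"), auto_unbox = TRUE, digits = NA)
  }

  # --- core microbiota ------------------------------------------------
  core <- core_taxa_by_dataset(rel, ds, detection = detection,
                               prevalence = prevalence)
  core_tbl <- dplyr::bind_rows(c(
    unname(purrr::imap(core$per_dataset, ~ tibble::tibble(
      scope = .y, genus = .x))),
    list(tibble::tibble(scope = "pooled", genus = core$pooled),
         tibble::tibble(scope = "shared", genus = core$shared))
  ))
  readr::write_tsv(core_tbl, file.path(out_dir, "core_taxa.tsv"))

  # --- accumulation + pan --------------------------------------------
  acc <- accumulation_curve(counts, n_reps = n_reps, seed = seed)
  heaps <- fit_heaps(acc)
  if (is.null(n_extrapolate)) n_extrapolate <- 4 * nrow(acc$summary)
  pan <- pan_estimate(heaps, n_extrapolate)
  acc_tbl <- dplyr::mutate(acc$summary, fitted = heaps$fitted$fitted)
  readr::write_tsv(acc_tbl, file.path(out_dir, "accumulation.tsv"))
  jsonlite::write_json(list(
    kappa = heaps$kappa, gamma = heaps$gamma, r_squared = heaps$r_squared,
    union_richness = acc$union_richness,
    n_extrapolate = pan$n_extrapolate,
    pan_estimate = pan$predicted_richness,
    open = pan$open
  ), file.path(out_dir, "pan.json"), auto_unbox = TRUE, digits = NA)
  log_lines <- c(log_lines, paste0("n_extrapolate = ", n_extrapolate))

  # --- diversity ------------------------------------------------------
  div <- alpha_diversity(rel) |>
    dplyr::left_join(sample_richness(counts), by = "sample_id") |>
    dplyr::left_join(meta, by = "sample_id")
  readr::write_tsv(div, file.path(out_dir, "diversity.tsv"))

  # --- factor tests ---------------------------------------------------
  d <- bray_curtis(rel)
  dm <- as_distance_matrix(d)
  factors <- list(
    dataset = stats::setNames(meta$dataset, meta$sample_id),
    sex = stats::setNames(meta$sex, meta$sample_id),
    age_group = stats::setNames(
      ifelse(meta$age > 65, "old", "young"), meta$sample_id),
    sampling_site = stats::setNames(meta$sampling_site, meta$sample_id),
    tissue_source = stats::setNames(meta$tissue_source, meta$sample_id)
  )
  perm_rows <- list()
  div_rows <- list()
  for (fac in names(factors)) {
    lab <- factors[[fac]][rownames(dm)]
    ok <- !is.na(lab)
    sizes <- table(lab[ok])
    sizes <- sizes[sizes >= 2]
    if (length(sizes) < 2) next
    use <- ok & lab %in% names(sizes)
    fit <- permanova(dm[use, use], lab[use],
                     n_permutations = n_permutations, seed = seed)
    perm_rows[[fac]] <- dplyr::mutate(glance(fit), factor = fac,
                                      groups = paste(names(sizes),
                                                     collapse = "|"),
                                      .before = 1)
    usable_ids <- rownames(dm)[use]
    lab_use <- lab[use]
    rel_sub <- dplyr::select(rel, 1, dplyr::all_of(usable_ids))
    attr(rel_sub, "zero_samples") <- character(0)
    dv <- divergence_to_median(rel_sub, stats::setNames(lab_use, usable_ids))
    div_rows[[fac]] <- dplyr::mutate(dv, factor = fac, .before = 1)
  }
  permanova_tbl <- dplyr::bind_rows(perm_rows)
  readr::write_tsv(permanova_tbl, file.path(out_dir, "permanova.tsv"))
  divergence_tbl <- dplyr::bind_rows(div_rows)
  readr::write_tsv(divergence_tbl, file.path(out_dir, "divergence.tsv"))

  # --- separating coefficients for the binary design factors ---------
  coef_rows <- list()
  for (fac in c("sampling_site", "tissue_source")) {
    lab <- factors[[fac]][colnames(profile_matrix(rel))]
    lev <- names(which(table(lab) >= 2))
    lev <- setdiff(lev, "bulk")
    if (length(lev) != 2) lev <- names(sort(table(lab), decreasing = TRUE))[1:2]
    if (sum(!is.na(lev)) < 2) next
    lab2 <- ifelse(lab %in% lev, lab, NA)
    if (length(unique(stats::na.omit(lab2))) != 2) next
    co <- separating_coefficients(rel, lab2)
    coef_rows[[fac]] <- dplyr::mutate(top_coefficients(co, 20),
                                      factor = fac, .before = 1)
  }
  coefficients_tbl <- dplyr::bind_rows(coef_rows)
  readr::write_tsv(coefficients_tbl, file.path(out_dir, "coefficients.tsv"))

  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(
    qc = qc, domain = domain, overlap = overlap, core = core,
    accumulation = acc, heaps = heaps, pan = pan, diversity = div,
    permanova = permanova_tbl, divergence = divergence_tbl,
    coefficients = coefficients_tbl
  ))
}
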