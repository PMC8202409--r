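# Data model and I/O for genus-level count tables, taxonomy and sample
# metadata, plus abundance transforms, taxonomic aggregation and QC
# filtering. All tables are tibbles: the count table has a `genus` first
# column and one column per sample; taxonomy has columns genus/phylum/domain;
# metadata has one row per sample.

DOMAIN_LEVELS <- c("bacteria", "virus", "archaea", "fungi")
SEX_LEVELS <- c("male", "female")
SITE_LEVELS <- c("stroma", "epithelium", "bulk")
SOURCE_LEVELS <- c("human_tissue", "pdx")
PHYLUM_NONE <- "None"

#' Read a genus-level microbial profile from TSV files
#'
#' Loads the three tab-separated tables that together describe a cohort:
#' a genus x sample count matrix (first column `genus`, one integer column
#' per sample), a taxonomy map (`genus`, `phylum`, `domain`; an empty phylum
#' means no phylum-level assignment and is recoded to `"None"`), and sample
#' metadata (`sample_id`, `dataset`, `sex`, `age`, `sampling_site`,
#' `tissue_source`; empty cells are missing).
#'
#' Genera present in the counts but absent from the taxonomy are admitted
#' with `phylum = "None"` only when `default_domain` is supplied; otherwise
#' their domain is unresolvable and an error is raised. Samples present in
#' the counts but absent from the metadata are an error.
#'
#' @param counts_path,taxonomy_path,metadata_path Paths to the three TSVs.
#' @param default_domain Optional domain (`"bacteria"`, `"virus"`,
#'   `"archaea"`, `"fungi"`) assigned to genera missing from the taxonomy.
#' @return A list of class `taxon_profile` with elements `counts`,
#'   `taxonomy` and `metadata`, each a tibble.
#' @export
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' prof <- generate_profiles(synthetic_config(
#'   n_samples = c(a = 4, b = 4), pool_size = 100, n_effect_taxa = 5,
#'   zero_read_count = 1, low_read_count = 1, seed = 1))
#' write_profile(prof, dir)
#' back <- read_profile(file.path(dir, "counts.tsv"),
#'                      file.path(dir, "taxonomy.tsv"),
#'                      file.path(dir, "metadata.tsv"))
#' dim(back$counts)
read_profile <- function(counts_path, taxonomy_path, metadata_path,
                         default_domain = NULL) {
  counts <- readr::read_tsv(counts_path, col_types = readr::cols(
    genus = readr::col_character(), .default = readr::col_double()
  ), na = character(), progress = FALSE)
  problems <- readr::problems(counts)
  if (nrow(problems) > 0) {
    stop("malformed counts TSV at line ", problems$row[1], ": ",
         problems$expected[1], " but got ", problems$actual[1], call. = FALSE)
  }
  if (names(counts)[1] != "genus") {
    stop("counts TSV must have 'genus' as its first column", call. = FALSE)
  }
  m <- validate_counts(counts)
  if (any(m != round(m))) {
    stop("counts: non-integer entries are not allowed", call. = FALSE)
  }

  taxonomy <- readr::read_tsv(taxonomy_path, col_types = readr::cols(
    genus = readr::col_character(), phylum = readr::col_character(),
    domain = readr::col_character()
  ), na = character(), progress = FALSE)
  taxonomy <- dplyr::mutate(
    taxonomy,
    phylum = dplyr::if_else(.data$phylum == "" | is.na(.data$phylum),
                            PHYLUM_NONE, .data$phylum)
  )
  if (anyDuplicated(taxonomy$genus)) {
    stop("taxonomy: duplicate genus labels", call. = FALSE)
  }
  bad <- setdiff(unique(taxonomy$domain), DOMAIN_LEVELS)
  if (length(bad) > 0) {
    stop("taxonomy: unknown domain value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  missing_tax <- setdiff(counts$genus, taxonomy$genus)
  if (length(missing_tax) > 0) {
    if (is.null(default_domain)) {
      stop("genera without taxonomy and no default_domain given: ",
           paste(head(missing_tax, 5), collapse = ", "),
           if (length(missing_tax) > 5) ", ...", call. = FALSE)
    }
    default_domain <- match.arg(default_domain, DOMAIN_LEVELS)
    taxonomy <- dplyr::bind_rows(taxonomy, tibble::tibble(
      genus = missing_tax, phylum = PHYLUM_NONE, domain = default_domain
    ))
  }

  metadata <- readr::read_tsv(metadata_path, col_types = readr::cols(
    sample_id = readr::col_character(), dataset = readr::col_character(),
    sex = readr::col_character(), age = readr::col_double(),
    sampling_site = readr::col_character(),
    tissue_source = readr::col_character()
  ), na = "", progress = FALSE)
  validate_metadata(metadata)
  orphan <- setdiff(colnames(counts)[-1], metadata$sample_id)
  if (length(orphan) > 0) {
    stop("samples present in counts but absent from metadata: ",
         paste(head(orphan, 5), collapse = ", "), call. = FALSE)
  }

  new_taxon_profile(counts, taxonomy, metadata)
}

validate_metadata <- function(metadata) {
  required <- c("sample_id", "dataset", "sex", "age", "sampling_site",
                "tissue_source")
  miss <- setdiff(required, names(metadata))
  if (length(miss) > 0) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("metadata: duplicate sample_id", call. = FALSE)
  }
  if (any(metadata$age < 0, na.rm = TRUE)) {
    stop("metadata: age must be non-negative", call. = FALSE)
  }
  check_enum <- function(x, levels, what) {
    bad <- setdiff(unique(x[!is.na(x)]), levels)
    if (length(bad) > 0) {
      stop("metadata: invalid ", what, " value(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  check_enum(metadata$sex, SEX_LEVELS, "sex")
  check_enum(metadata$sampling_site, SITE_LEVELS, "sampling_site")
  check_enum(metadata$tissue_source, SOURCE_LEVELS, "tissue_source")
  invisible(metadata)
}

new_taxon_profile <- function(counts, taxonomy, metadata) {
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "taxon_profile")
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat("<taxon_profile> ", nrow(x$counts), " genera x ",
      ncol(x$counts) - 1, " samples\n", sep = "")
  invisible(x)
}

#' Write a profile to a directory of TSV files
#'
#' Inverse of [read_profile()]: writes `counts.tsv`, `taxonomy.tsv` and
#' `metadata.tsv` so that reading them back reproduces the tables exactly.
#'
#' @param profile A `taxon_profile` (or a list with `counts`, `taxonomy`,
#'   `metadata` tibbles).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_profile <- function(profile, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(profile$counts, file.path(dir, "counts.tsv"))
  tax <- dplyr::mutate(profile$taxonomy,
    phylum = dplyr::if_else(.data$phylum == PHYLUM_NONE, "", .data$phylum))
  readr::write_tsv(tax, file.path(dir, "taxonomy.tsv"))
  readr::write_tsv(profile$metadata, file.path(dir, "metadata.tsv"), na = "")
  if (!is.null(profile$ground_truth)) {
    jsonlite::write_json(profile$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Convert counts to relative abundances
#'
#' Divides each sample column by its total read count. Samples whose total
#' is zero cannot be normalised; their columns are left all-zero and the
#' sample ids are recorded in the `zero_samples` attribute (retrieve with
#' [zero_samples()]).
#'
#' @param counts Count profile tibble (first column `genus`).
#' @return A tibble of the same shape with columns summing to 1 (or 0 for
#'   flagged samples), carrying a `zero_samples` character attribute.
#' @export
#' @examples
#' tab <- tibble::tibble(genus = c("A", "B", "C"), s1 = c(2, 1, 1))
#' to_relative_abundance(tab)
to_relative_abundance <- function(counts) {
  m <- validate_counts(counts)
  totals <- colSums(m)
  zero <- colnames(m)[totals == 0]
  scale <- ifelse(totals == 0, 1, totals)
  rel <- sweep(m, 2, scale, "/")
  out <- matrix_profile(rel)
  attr(out, "zero_samples") <- zero
  out
}

#' Samples flagged as having zero total reads
#'
#' @param rel_table A relative-abundance tibble from
#'   [to_relative_abundance()].
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
zero_samples <- function(rel_table) {
  z <- attr(rel_table, "zero_samples")
  if (is.null(z)) character(0) else z
}

#' Aggregate a genus-level table to phylum or domain level
#'
#' Sums counts over genera sharing the same label at the requested rank.
#' Genera lacking a phylum assignment are retained under the `"None"`
#' category at phylum level; a genus with no resolvable domain is an error
#' at domain level.
#'
#' @param counts Count (or relative-abundance) profile tibble.
#' @param taxonomy Taxonomy tibble (`genus`, `phylum`, `domain`).
#' @param level `"phylum"` or `"domain"`.
#' @return A profile tibble whose first column is named after `level`.
#' @export
aggregate_taxa <- function(counts, taxonomy, level = c("phylum", "domain")) {
  level <- match.arg(level)
  m <- profile_matrix(counts)
  key <- taxonomy[[level]][match(rownames(m), taxonomy$genus)]
  if (level == "phylum") key[is.na(key)] <- PHYLUM_NONE
  if (anyNA(key) || any(!nzchar(key))) {
    stop("genus with unresolvable ", level, ": ",
         paste(head(rownames(m)[is.na(key) | !nzchar(key)], 5),
               collapse = ", "), call. = FALSE)
  }
  agg <- rowsum(m, group = key)
  out <- matrix_profile(agg, label_col = level)
  dplyr::arrange(out, .data[[level]])
}

#' Per-sample domain composition of microbial reads
#'
#' For every sample with at least one microbial read, computes the fraction
#' of reads assigned to each domain (bacteria, virus, archaea, and fungi if
#' present). Zero-read samples are excluded with a warning.
#'
#' @inheritParams aggregate_taxa
#' @param metadata Optional metadata tibble; when given, the `dataset`
#'   column is joined onto the result so per-dataset summaries chain
#'   naturally with dplyr.
#' @return A long tibble with columns `sample_id`, `domain`, `proportion`
#'   (and `dataset` when metadata is supplied).
#' @export
domain_proportions <- function(counts, taxonomy, metadata = NULL) {
  dom <- aggregate_taxa(counts, taxonomy, level = "domain")
  m <- profile_matrix(dom)
  totals <- colSums(m)
  if (all(totals == 0)) {
    stop("no sample has microbial reads", call. = FALSE)
  }
  if (any(totals == 0)) {
    warning("excluding ", sum(totals == 0),
            " zero-read sample(s) from domain proportions", call. = FALSE)
    m <- m[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  prop <- sweep(m, 2, totals, "/")
  out <- matrix_profile(prop, label_col = "domain") |>
    tidyr::pivot_longer(-"domain", names_to = "sample_id",
                        values_to = "proportion") |>
    dplyr::select("sample_id", "domain", "proportion") |>
    dplyr::arrange(.data$sample_id, .data$domain)
  if (!is.null(metadata)) {
    out <- dplyr::left_join(
      out, dplyr::select(metadata, "sample_id", "dataset"), by = "sample_id")
  }
  out
}

#' Summarise domain proportions by dataset
#'
#' @param props Output of [domain_proportions()] including a `dataset`
#'   column.
#' @return Tibble with mean and standard deviation of each domain's
#'   proportion per dataset.
#' @export
summarise_domain_proportions <- function(props) {
  stopifnot("dataset" %in% names(props))
  props |>
    dplyr::group_by(.data$dataset, .data$domain) |>
    dplyr::summarise(mean = mean(.data$proportion),
                     sd = stats::sd(.data$proportion),
                     n = dplyr::n(), .groups = "drop")
}

#' Remove samples with too few microbial reads
#'
#' Samples whose total read count is strictly below `min_reads` are dropped
#' from the kept table; the function also reports which samples had no
#' microbial reads at all and which fell below the threshold.
#'
#' @param counts Count profile tibble.
#' @param min_reads Minimum total reads a sample must have to be kept
#'   (default 100).
#' @return A list of class `qc_result`: `kept` (filtered tibble),
#'   `zero_read` and `low_read` (character vectors of sample ids; zero-read
#'   samples are included in `low_read` whenever `min_reads > 0`), and
#'   `totals` (a tibble of per-sample totals).
#' @export
qc_filter <- function(counts, min_reads = 100) {
  stopifnot(is.numeric(min_reads), length(min_reads) == 1, min_reads >= 0)
  m <- validate_counts(counts)
  totals <- colSums(m)
  zero <- colnames(m)[totals == 0]
  low <- colnames(m)[totals < min_reads]
  kept_ids <- colnames(m)[totals >= min_reads]
  kept <- dplyr::select(counts, 1, dplyr::all_of(kept_ids))
  structure(list(
    kept = kept,
    zero_read = zero,
    low_read = low,
    min_reads = min_reads,
    totals = tibble::tibble(sample_id = colnames(m), total_reads = totals,
                            kept = colnames(m) %in% kept_ids)
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> min_reads=", x$min_reads, ": kept ",
      ncol(x$kept) - 1, "/", nrow(x$totals), " samples (",
      length(x$zero_read), " zero-read, ", length(x$low_read),
      " below threshold)\n", sep = "")
  invisible(x)
}

#' @method tidy qc_result
#' @export
tidy.qc_result <- function(x, ...) x$totals

#' Collapse a table to its top-n taxa plus an "Other" row
#'
#' Taxa are ranked by mean relative abundance across all samples (ties
#' broken alphabetically); everything outside the top `n` is summed into a
#' single row so stacked-bar figures stay readable. Column sums are
#' preserved exactly.
#'
#' @param rel_table Relative-abundance (or count) profile tibble.
#' @param n Number of taxa to keep (>= 1).
#' @param other_label Label of the aggregate row (default `"Other"`).
#' @return Profile tibble with `min(n, taxa) + 1` rows, the aggregate last.
#' @export
top_n_collapse <- function(rel_table, n, other_label = "Other") {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive integer", call. = FALSE)
  }
  m <- profile_matrix(rel_table)
  if (other_label %in% rownames(m)) {
    stop("other_label clashes with an existing taxon label", call. = FALSE)
  }
  ord <- order(-rowMeans(m), rownames(m))
  keep <- rownames(m)[ord][seq_len(min(n, nrow(m)))]
  rest <- setdiff(rownames(m), keep)
  other <- if (length(rest) > 0) {
    colSums(m[rest, , drop = FALSE])
  } else {
    rep(0, ncol(m))
  }
  out <- rbind(m[keep, , drop = FALSE],
               matrix(other, nrow = 1, dimnames = list(other_label, NULL)))
  label_col <- names(rel_table)[1]
  matrix_profile(out, label_col = label_col)
}

#' Per-sample genus richness
#'
#' Number of genera with at least one read in each sample.
#'
#' @param counts Count profile tibble.
#' @return Tibble with `sample_id` and `richness`.
#' @export
sample_richness <- function(counts) {
  m <- profile_matrix(counts)
  tibble::tibble(sample_id = colnames(m), richness = colSums(m > 0))
}
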