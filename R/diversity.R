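# Alpha diversity, Bray-Curtis dissimilarity, divergence-to-median
# heterogeneity and two-sample rank testing.

#' Shannon diversity of a relative-abundance vector
#'
#' \eqn{H = -\sum_{p_i > 0} p_i \log p_i}, in nats by default. An all-zero
#' vector (a zero-read sample) has undefined diversity and returns `NA`.
#'
#' @param p Numeric vector of relative abundances summing to 1 (or counts:
#'   the vector is renormalised).
#' @param base Logarithm base; `exp(1)` (nats) by default.
#' @return A single non-negative number, at most `log(length(p), base)`.
#' @export
#' @examples
#' shannon(c(0.5, 0.5))   # log(2)
shannon <- function(p, base = exp(1)) {
  stopifnot(is.numeric(p), all(p >= 0))
  tot <- sum(p)
  if (tot == 0) return(NA_real_)
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Shannon diversity for every sample of a table
#'
#' @param rel_table Relative-abundance profile tibble (zero-total samples
#'   yield `NA`).
#' @param base Logarithm base passed to [shannon()].
#' @return Tibble with `sample_id` and `shannon`.
#' @export
alpha_diversity <- function(rel_table, base = exp(1)) {
  m <- profile_matrix(rel_table)
  tibble::tibble(
    sample_id = colnames(m),
    shannon = apply(m, 2, shannon, base = base)
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarities
#' \eqn{d_{ij} = \sum_t |x_{ti} - x_{tj}| / \sum_t (x_{ti} + x_{tj})}
#' between sample columns, computed with `vegan::vegdist`. Samples flagged
#' as zero-total (see [to_relative_abundance()]) are dropped first; fewer
#' than two usable samples is an error.
#'
#' @param rel_table Relative-abundance profile tibble.
#' @return A `dist` object labelled by sample id.
#' @export
bray_curtis <- function(rel_table) {
  m <- profile_matrix(rel_table)
  usable <- setdiff(colnames(m), zero_samples(rel_table))
  usable <- usable[colSums(m[, usable, drop = FALSE]) > 0]
  if (length(usable) < 2) {
    stop("need at least 2 samples with nonzero totals", call. = FALSE)
  }
  vegan::vegdist(t(m[, usable, drop = FALSE]), method = "bray")
}

#' Write a distance matrix as a square TSV
#'
#' @param d A `dist` object or symmetric matrix.
#' @param path Output path; header row and first column carry sample ids.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  m <- as_distance_matrix(d)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                          tibble::as_tibble(m, .name_repair = "minimal"))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Divergence of each sample from its group's median profile
#'
#' For every group, the reference profile is the per-taxon median of the
#' member columns (not renormalised); each member's divergence is its
#' Bray-Curtis dissimilarity to that reference. Group means of the
#' divergence measure community heterogeneity: a group can share its
#' central composition with another yet be far more dispersed around it.
#'
#' @param rel_table Relative-abundance profile tibble.
#' @param group_labels Group label per sample (named by sample id, or in
#'   table column order). Samples with `NA` labels are dropped.
#' @return Tibble of class `divergence_result` with `sample_id`, `group`,
#'   `divergence` (in `[0, 1]`).
#' @export
divergence_to_median <- function(rel_table, group_labels) {
  m <- profile_matrix(rel_table)
  m <- m[, setdiff(colnames(m), zero_samples(rel_table)), drop = FALSE]
  labels <- align_samples(group_labels, colnames(m), "group_labels")
  keep <- !is.na(labels)
  m <- m[, keep, drop = FALSE]
  labels <- labels[keep]
  if (ncol(m) == 0 || length(unique(labels)) == 0) {
    stop("no usable samples with group labels", call. = FALSE)
  }
  res <- lapply(split(colnames(m), labels), function(ids) {
    x <- m[, ids, drop = FALSE]
    ref <- apply(x, 1, stats::median)
    num <- colSums(abs(x - ref))
    den <- colSums(x + ref)
    d <- ifelse(den == 0, 0, num / den)
    tibble::tibble(sample_id = ids, divergence = unname(d))
  })
  out <- dplyr::bind_rows(res, .id = "group") |>
    dplyr::select("sample_id", "group", "divergence")
  class(out) <- c("divergence_result", class(out))
  out
}

#' Wilcoxon-Mann-Whitney rank-sum test for two independent groups
#'
#' Wraps `stats::wilcox.test` with an explicit exactness policy: the exact
#' null distribution is used when both groups are at most `exact_cap`
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity correction is used.
#'
#' @param values_a,values_b Numeric observations for the two groups.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact_cap Largest per-group size for which exact enumeration is
#'   attempted (default 12).
#' @return Tibble with `statistic` (Mann-Whitney U for group a), `p_value`,
#'   `method`, `n_a`, `n_b`.
#' @export
rank_sum_test <- function(values_a, values_b,
                          alternative = c("two.sided", "less", "greater"),
                          exact_cap = 12) {
  alternative <- match.arg(alternative)
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  has_ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- !has_ties && length(values_a) <= exact_cap &&
    length(values_b) <= exact_cap
  ht <- suppressWarnings(stats::wilcox.test(
    values_a, values_b, alternative = alternative,
    exact = exact, correct = TRUE
  ))
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    method = if (exact) "exact" else "normal approximation",
    n_a = length(values_a),
    n_b = length(values_b)
  )
}
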