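# One-factor PERMANOVA from first principles, pairwise tests,
# group-separating taxon coefficients, fold changes and age-threshold
# scanning.

# Sums of squares from a squared-distance matrix and a label vector.
# SS_T = (1/N) sum_{i<j} d_ij^2 ; SS_W = sum_g (1/n_g) sum_{i<j in g} d_ij^2.
permanova_ss <- function(d2, labels) {
  n <- nrow(d2)
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (idx in split(seq_len(n), labels)) {
    sub <- d2[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  c(ss_t = ss_t, ss_w = ss_w)
}

permanova_f <- function(d2, labels, a, n) {
  ss <- permanova_ss(d2, labels)
  ss_a <- ss[["ss_t"]] - ss[["ss_w"]]
  (ss_a / (a - 1)) / (ss[["ss_w"]] / (n - a))
}

# All distinct arrangements of a label multiset, as a list of vectors.
# Used for exact enumeration on small designs; the caller bounds the count.
multiset_permutations <- function(labels) {
  labels <- as.character(labels)
  rec <- function(pool) {
    if (length(pool) == 0) return(list(character(0)))
    out <- list()
    for (v in unique(pool)) {
      rest <- pool[-match(v, pool)]
      for (tail in rec(rest)) out[[length(out) + 1]] <- c(v, tail)
    }
    out
  }
  rec(sort(labels))
}

# Number of distinct arrangements of a label multiset.
n_label_arrangements <- function(labels) {
  tab <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(tab + 1)))
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the total sum of squared dissimilarities into among-group and
#' within-group components and tests the pseudo-F ratio
#' \deqn{F = \frac{SS_A / (a - 1)}{SS_W / (N - a)}}
#' by permuting group labels. With
#' \eqn{SS_T = \frac{1}{N}\sum_{i<j} d_{ij}^2} and
#' \eqn{SS_W = \sum_g \frac{1}{n_g} \sum_{i<j \in g} d_{ij}^2},
#' \eqn{SS_A = SS_T - SS_W} and \eqn{R^2 = SS_A / SS_T}.
#'
#' When the number of distinct label arrangements is at most
#' `n_permutations`, the full permutation distribution is enumerated and
#' the p-value is exact: the fraction of arrangements (including the
#' observed one) with \eqn{F \ge F_{obs}}. Otherwise `n_permutations`
#' random label shuffles are drawn and
#' \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})}, so the
#' smallest attainable p is \eqn{1/(n_{perm}+1)}.
#'
#' @param dist A `dist` object or symmetric dissimilarity matrix.
#' @param labels Group label per sample (named by sample id or aligned with
#'   the distance-matrix order); at least two groups, each of size >= 2.
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Integer seed for the permutation stream (required for the
#'   Monte-Carlo branch, logged either way).
#' @param exact `NULL` (default) applies the enumeration rule above;
#'   `TRUE` forces full enumeration, `FALSE` forces random permutations.
#' @return Object of class `permanova_test` with fields `pseudo_f`, `r2`,
#'   `p_value`, `n_permutations` (permutations actually evaluated), `exact`,
#'   `seed`, `group_sizes`, `ss` (SS_A, SS_W, SS_T) and `df`.
#' @export
#' @examples
#' d <- dist(c(a1 = 0, a2 = 1, b1 = 10, b2 = 11))
#' permanova(d, c("a", "a", "b", "b"), seed = 1)
permanova <- function(dist, labels, n_permutations = 999, seed = NULL,
                      exact = NULL) {
  m <- as_distance_matrix(dist)
  n <- nrow(m)
  labels <- as.character(align_samples(labels, rownames(m), "labels"))
  sizes <- table(labels)
  if (length(sizes) < 2) {
    stop("need at least two groups", call. = FALSE)
  }
  if (any(sizes < 2)) {
    stop("every group must have at least 2 samples", call. = FALSE)
  }
  a <- length(sizes)
  d2 <- m^2
  ss <- permanova_ss(d2, labels)
  ss_a <- ss[["ss_t"]] - ss[["ss_w"]]
  f_obs <- (ss_a / (a - 1)) / (ss[["ss_w"]] / (n - a))
  r2 <- ss_a / ss[["ss_t"]]

  m_arr <- n_label_arrangements(labels)
  if (is.null(exact)) {
    exact <- is.finite(m_arr) && m_arr <= n_permutations
  } else if (isTRUE(exact) && (!is.finite(m_arr) || m_arr > 1e6)) {
    stop("too many label arrangements to enumerate", call. = FALSE)
  }
  if (exact) {
    perms <- multiset_permutations(labels)
    f_perm <- vapply(perms, function(lab) permanova_f(d2, lab, a, n),
                     numeric(1))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- length(perms)
  } else {
    if (is.null(seed)) {
      stop("seed is required for Monte-Carlo permutations", call. = FALSE)
    }
    f_perm <- withr::with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        permanova_f(d2, sample(labels), a, n)
      }, numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)
    n_used <- n_permutations
  }

  structure(list(
    pseudo_f = f_obs,
    r2 = r2,
    p_value = p,
    n_permutations = n_used,
    exact = exact,
    seed = if (is.null(seed)) NA_integer_ else seed,
    group_sizes = c(sizes),
    ss = c(ss_a = ss_a, ss_w = ss[["ss_w"]], ss_t = ss[["ss_t"]]),
    df = c(among = a - 1, within = n - a),
    f_perm = f_perm
  ), class = "permanova_test")
}

#' @export
print.permanova_test <- function(x, ...) {
  cat("<permanova_test> pseudo-F = ", signif(x$pseudo_f, 5),
      ", R2 = ", signif(x$r2, 4), ", p = ", signif(x$p_value, 4),
      if (x$exact) " (exact, " else " (", x$n_permutations,
      " permutations)\n", sep = "")
  invisible(x)
}

#' @method tidy permanova_test
#' @export
tidy.permanova_test <- function(x, ...) {
  tibble::tibble(
    term = c("among groups", "within groups", "total"),
    df = c(x$df[["among"]], x$df[["within"]], sum(x$df)),
    sum_sq = c(x$ss[["ss_a"]], x$ss[["ss_w"]], x$ss[["ss_t"]]),
    statistic = c(x$pseudo_f, NA, NA),
    p_value = c(x$p_value, NA, NA)
  )
}

#' @method glance permanova_test
#' @export
glance.permanova_test <- function(x, ...) {
  tibble::tibble(
    pseudo_f = x$pseudo_f, r2 = x$r2, p_value = x$p_value,
    n_permutations = x$n_permutations, exact = x$exact, seed = x$seed
  )
}

#' Pairwise PERMANOVA over all group pairs
#'
#' Runs [permanova()] on the sample subset of every pair of groups.
#' Pairs in which a group has fewer than 2 samples are reported as
#' not testable rather than erroring.
#'
#' @inheritParams permanova
#' @return Tibble with one row per pair: `group1`, `group2`, `n1`, `n2`,
#'   `pseudo_f`, `r2`, `p_value`, `n_permutations`, `exact`, `testable`.
#' @export
pairwise_permanova <- function(dist, labels, n_permutations = 999,
                               seed = NULL) {
  m <- as_distance_matrix(dist)
  labels <- as.character(align_samples(labels, rownames(m), "labels"))
  groups <- sort(unique(labels[!is.na(labels)]))
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    idx <- which(labels %in% pr)
    sizes <- table(labels[idx])
    base <- tibble::tibble(group1 = pr[1], group2 = pr[2],
                           n1 = sum(labels == pr[1], na.rm = TRUE),
                           n2 = sum(labels == pr[2], na.rm = TRUE))
    if (length(sizes) < 2 || any(sizes < 2)) {
      return(dplyr::mutate(base, pseudo_f = NA_real_, r2 = NA_real_,
                           p_value = NA_real_, n_permutations = NA_integer_,
                           exact = NA, testable = FALSE))
    }
    fit <- permanova(m[idx, idx], labels[idx],
                     n_permutations = n_permutations, seed = seed)
    dplyr::mutate(base, pseudo_f = fit$pseudo_f, r2 = fit$r2,
                  p_value = fit$p_value,
                  n_permutations = as.integer(fit$n_permutations),
                  exact = fit$exact, testable = TRUE)
  })
}

#' Taxon coefficients separating two groups
#'
#' For a binary grouping, the coefficient of each taxon is the difference of
#' its group mean relative abundances (reference group minus the other);
#' positive values mean the taxon is more abundant in the reference group.
#' This equals the regression coefficient of a per-taxon linear model on a
#' 0/1 group code.
#'
#' @param rel_table Relative-abundance profile tibble.
#' @param binary_labels Two-level group label per sample (named or in
#'   column order; `NA` samples dropped).
#' @param reference Group treated as positive direction; defaults to the
#'   first level in sorted order.
#' @return Tibble of class `separating_coefficients` with `genus`,
#'   `coefficient`, `mean_ref`, `mean_other`, `rank` (by absolute
#'   coefficient, descending).
#' @export
separating_coefficients <- function(rel_table, binary_labels,
                                    reference = NULL) {
  m <- profile_matrix(rel_table)
  labels <- align_samples(binary_labels, colnames(m), "binary_labels")
  keep <- !is.na(labels)
  m <- m[, keep, drop = FALSE]
  labels <- as.character(labels[keep])
  lev <- sort(unique(labels))
  if (length(lev) != 2) {
    stop("binary_labels must have exactly two groups, got ", length(lev),
         call. = FALSE)
  }
  if (is.null(reference)) reference <- lev[1]
  if (!reference %in% lev) stop("reference not among the labels", call. = FALSE)
  other <- setdiff(lev, reference)
  mean_ref <- rowMeans(m[, labels == reference, drop = FALSE])
  mean_other <- rowMeans(m[, labels == other, drop = FALSE])
  out <- tibble::tibble(
    genus = rownames(m),
    coefficient = unname(mean_ref - mean_other),
    mean_ref = unname(mean_ref),
    mean_other = unname(mean_other)
  ) |>
    dplyr::arrange(dplyr::desc(abs(.data$coefficient)), .data$genus) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "reference") <- reference
  attr(out, "other") <- other
  class(out) <- c("separating_coefficients", class(out))
  out
}

#' Top-k separating taxa
#' @param coefs Output of [separating_coefficients()].
#' @param k Number of taxa.
#' @return The first `k` rows by absolute coefficient.
#' @export
top_coefficients <- function(coefs, k = 20) {
  dplyr::slice_head(coefs, n = k)
}

#' Fold change of a taxon's mean relative abundance between two groups
#'
#' Ratio of the group-1 mean over the group-2 mean. When the denominator
#' mean is zero, a pseudo-abundance equal to half the smallest nonzero
#' relative abundance in the table is added to both means and the result is
#' flagged; the reciprocal identity `fold_change(A,B) = 1/fold_change(B,A)`
#' holds whenever no pseudo-count triggered.
#'
#' @param rel_table Relative-abundance profile tibble.
#' @param group_labels Group label per sample.
#' @param taxon Genus to compare (must be present in the table).
#' @param group1,group2 Labels of numerator and denominator groups;
#'   default to the first two sorted levels.
#' @return Tibble with `taxon`, `group1`, `group2`, `mean1`, `mean2`,
#'   `fold_change`, `pseudo_count_used`.
#' @export
fold_change <- function(rel_table, group_labels, taxon,
                        group1 = NULL, group2 = NULL) {
  m <- profile_matrix(rel_table)
  if (!taxon %in% rownames(m)) {
    stop("taxon not present in table: ", taxon, call. = FALSE)
  }
  labels <- align_samples(group_labels, colnames(m), "group_labels")
  lev <- sort(unique(as.character(labels[!is.na(labels)])))
  if (is.null(group1)) group1 <- lev[1]
  if (is.null(group2)) group2 <- lev[2]
  stopifnot(group1 %in% lev, group2 %in% lev)
  mean1 <- mean(m[taxon, which(labels == group1)])
  mean2 <- mean(m[taxon, which(labels == group2)])
  pseudo <- 0
  used <- FALSE
  if (mean2 == 0) {
    nz <- m[m > 0]
    pseudo <- if (length(nz) > 0) min(nz) / 2 else 1e-6
    used <- TRUE
  }
  tibble::tibble(
    taxon = taxon, group1 = group1, group2 = group2,
    mean1 = mean1, mean2 = mean2,
    fold_change = (mean1 + pseudo) / (mean2 + pseudo),
    pseudo_count_used = used
  )
}

#' PERMANOVA scan over age thresholds
#'
#' For every threshold tau, samples are split into `<= tau` and `> tau`
#' groups and a PERMANOVA is run; thresholds leaving fewer than 2 samples
#' on either side are reported as not testable. Mirrors the practice of
#' checking that an age effect is absent robustly across cutoffs rather
#' than at one arbitrary dichotomy.
#'
#' @inheritParams permanova
#' @param ages Age per sample (named or aligned with the distance matrix);
#'   samples with `NA` age are dropped.
#' @param thresholds Numeric vector of cutoffs (default `seq(45, 70, 5)`).
#' @return Tibble with one row per threshold: `threshold`, `n_young`,
#'   `n_old`, `pseudo_f`, `r2`, `p_value`, `testable`.
#' @export
age_threshold_scan <- function(dist, ages, thresholds = seq(45, 70, by = 5),
                               n_permutations = 999, seed = NULL) {
  m <- as_distance_matrix(dist)
  ages <- align_samples(ages, rownames(m), "ages")
  keep <- which(!is.na(ages))
  if (length(keep) < 4) stop("too few samples with ages", call. = FALSE)
  m <- m[keep, keep, drop = FALSE]
  ages <- ages[keep]
  res <- purrr::map_dfr(thresholds, function(tau) {
    grp <- ifelse(ages <= tau, "young", "old")
    sizes <- table(grp)
    base <- tibble::tibble(threshold = tau,
                           n_young = sum(grp == "young"),
                           n_old = sum(grp == "old"))
    if (length(sizes) < 2 || any(sizes < 2)) {
      return(dplyr::mutate(base, pseudo_f = NA_real_, r2 = NA_real_,
                           p_value = NA_real_, testable = FALSE))
    }
    fit <- permanova(m, grp, n_permutations = n_permutations, seed = seed)
    dplyr::mutate(base, pseudo_f = fit$pseudo_f, r2 = fit$r2,
                  p_value = fit$p_value, testable = TRUE)
  })
  if (!any(res$testable)) {
    stop("no threshold yields two groups of size >= 2", call. = FALSE)
  }
  res
}
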