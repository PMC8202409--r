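# Core-microbiota detection, cross-dataset overlap partitions, and
# pan-microbiome accumulation with Heaps-law fitting and extrapolation.

#' Core microbiota by detection and prevalence thresholds
#'
#' A genus is detected in a sample when its relative abundance exceeds the
#' positivity detection threshold `detection` (strict `>` by default); its
#' prevalence is the fraction of samples in which it is detected. The core
#' set is every genus whose prevalence is at least `prevalence` (`>=` by
#' default). Defaults are a 0.2% detection rate and 20% prevalence.
#'
#' @param rel_table Relative-abundance profile tibble.
#' @param detection Relative-abundance detection threshold in `[0, 1)`
#'   (default 0.002).
#' @param prevalence Prevalence threshold in `(0, 1]` (default 0.20).
#' @param detection_strict,prevalence_strict Comparison conventions:
#'   detection uses `>` and prevalence `>=` by default.
#' @return Object of class `core_taxa_result`: `core` (character vector of
#'   core genera), `prevalence` (tibble of per-genus prevalence), and the
#'   thresholds used.
#' @export
core_taxa <- function(rel_table, detection = 0.002, prevalence = 0.20,
                      detection_strict = TRUE, prevalence_strict = FALSE) {
  stopifnot(detection >= 0, detection < 1, prevalence > 0, prevalence <= 1)
  if (nrow(rel_table) == 0 || ncol(rel_table) < 2) {
    stop("empty table", call. = FALSE)
  }
  m <- profile_matrix(rel_table)
  detected <- if (detection_strict) m > detection else m >= detection
  prev <- rowMeans(detected)
  is_core <- if (prevalence_strict) prev > prevalence else prev >= prevalence
  structure(list(
    core = rownames(m)[is_core],
    prevalence = tibble::tibble(genus = rownames(m), prevalence = unname(prev),
                                core = unname(is_core)) |>
      dplyr::arrange(dplyr::desc(.data$prevalence), .data$genus),
    detection = detection,
    prevalence_threshold = prevalence
  ), class = "core_taxa_result")
}

#' @export
print.core_taxa_result <- function(x, ...) {
  cat("<core_taxa_result> ", length(x$core), " core genera (detection > ",
      x$detection, ", prevalence >= ", x$prevalence_threshold, ")\n", sep = "")
  invisible(x)
}

#' @method tidy core_taxa_result
#' @export
tidy.core_taxa_result <- function(x, ...) x$prevalence

#' Per-dataset core sets and their shared intersection
#'
#' Computes [core_taxa()] within each dataset's sample subset, plus on the
#' pooled collection, and intersects the per-dataset cores.
#'
#' @param rel_table Relative-abundance profile tibble.
#' @param datasets Dataset label per sample.
#' @inheritParams core_taxa
#' @return List with `per_dataset` (named list of core sets), `pooled`
#'   (core set over all samples) and `shared` (intersection of the
#'   per-dataset cores).
#' @export
core_taxa_by_dataset <- function(rel_table, datasets, detection = 0.002,
                                 prevalence = 0.20) {
  m <- profile_matrix(rel_table)
  datasets <- align_samples(datasets, colnames(m), "datasets")
  label_col <- names(rel_table)[1]
  per <- lapply(split(colnames(m), datasets), function(ids) {
    sub <- dplyr::select(rel_table, dplyr::all_of(c(label_col, ids)))
    core_taxa(sub, detection, prevalence)$core
  })
  pooled <- core_taxa(rel_table, detection, prevalence)$core
  shared <- Reduce(intersect, per)
  list(per_dataset = per, pooled = pooled, shared = shared)
}

#' Overlap partition of several named sets
#'
#' Given named sets (e.g. the genera observed per dataset), partitions
#' their union into the \eqn{2^k - 1} membership regions of a Venn diagram
#' and reports the k-way intersection and each set's shared fraction
#' (intersection size over set size).
#'
#' @param sets Named list of >= 2 character vectors.
#' @return List with `regions` (tibble: `membership` pattern string,
#'   `sets` involved, `size`), `intersection` (character vector),
#'   `shared_fraction` (tibble per set), and `union_size`.
#' @export
overlap_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) {
    stop("need a named list of at least two sets", call. = FALSE)
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named", call. = FALSE)
  }
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  k <- length(sets)
  all_patterns <- apply(
    as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE], 1,
    paste, collapse = "")
  all_patterns <- setdiff(all_patterns, strrep("0", k))
  counts <- table(factor(pattern, levels = all_patterns))
  regions <- tibble::tibble(
    membership = names(counts),
    sets = vapply(names(counts), function(p) {
      paste(names(sets)[strsplit(p, "")[[1]] == "1"], collapse = "&")
    }, character(1)),
    size = as.integer(counts)
  )
  inter <- universe[rowSums(member) == k]
  sizes <- unname(vapply(sets, length, integer(1)))
  shared_fraction <- tibble::tibble(
    set = names(sets),
    size = sizes,
    shared = length(inter),
    fraction = length(inter) / sizes
  )
  list(regions = regions, intersection = inter,
       shared_fraction = shared_fraction, union_size = length(universe))
}

#' Pan-microbiome accumulation curve
#'
#' For each replicate, samples are taken one at a time in a seeded uniform
#' random order and the cumulative number of distinct genera observed
#' (count > 0, or above `detection` if given) is recorded, until all
#' samples are used. The replicate curves and their mean form the
#' collector's curve of the cohort.
#'
#' @param counts Count profile tibble.
#' @param n_reps Number of random sample orderings (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param detection Presence threshold on counts (default 0: any read).
#' @return Object of class `accumulation_curve`: `curves` (n_reps x N
#'   integer matrix), `summary` (tibble: `n_samples`, `mean`, `sd`),
#'   `union_richness`, `n_reps`, `seed`.
#' @export
accumulation_curve <- function(counts, n_reps = 1000, seed, detection = 0) {
  stopifnot(n_reps >= 1)
  m <- profile_matrix(counts)
  if (ncol(m) < 1) stop("need at least one sample", call. = FALSE)
  pres <- (m > detection) * 1
  pres <- pres[rowSums(pres) > 0, , drop = FALSE]
  n <- ncol(m)
  curves <- withr::with_seed(seed, {
    t(vapply(seq_len(n_reps), function(r) {
      perm <- sample.int(n)
      if (nrow(pres) == 0) return(integer(n))
      # first position (in permuted order) at which each genus appears
      first <- max.col(pres[, perm, drop = FALSE], ties.method = "first")
      cumsum(tabulate(first, nbins = n))
    }, integer(n)))
  })
  structure(list(
    curves = curves,
    summary = tibble::tibble(
      n_samples = seq_len(n),
      mean = colMeans(curves),
      sd = apply(curves, 2, stats::sd)
    ),
    union_richness = nrow(pres),
    n_reps = n_reps,
    seed = seed
  ), class = "accumulation_curve")
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat("<accumulation_curve> ", x$n_reps, " replicates over ",
      nrow(x$summary), " samples; union richness ", x$union_richness,
      "\n", sep = "")
  invisible(x)
}

#' @method tidy accumulation_curve
#' @export
tidy.accumulation_curve <- function(x, ...) x$summary

#' Fit Heaps' law to a mean accumulation curve
#'
#' Fits the power law \eqn{P(n) = \kappa n^\gamma} to the mean collector's
#' curve. The default fit is ordinary least squares on the log-log scale
#' (\eqn{\ln P = \ln\kappa + \gamma \ln n}) with \eqn{R^2} reported on that
#' scale; `method = "nls"` refits on the raw scale by nonlinear least
#' squares started from the log-log estimates.
#'
#' @param mean_curve Numeric vector of strictly positive cumulative
#'   richness values at n = 1..N, an `accumulation_curve` object, or its
#'   `summary` tibble.
#' @param method `"loglog"` (default) or `"nls"`.
#' @return Object of class `heaps_fit`: `kappa`, `gamma`, `r_squared`,
#'   `n_obs`, `method`, and `fitted` (tibble of n, observed, fitted).
#' @export
fit_heaps <- function(mean_curve, method = c("loglog", "nls")) {
  method <- match.arg(method)
  if (inherits(mean_curve, "accumulation_curve")) {
    mean_curve <- mean_curve$summary$mean
  } else if (is.data.frame(mean_curve)) {
    mean_curve <- mean_curve$mean
  }
  y <- as.numeric(mean_curve)
  n <- seq_along(y)
  if (length(y) < 3) stop("curve must have length >= 3", call. = FALSE)
  if (any(y <= 0)) stop("curve values must be strictly positive", call. = FALSE)
  fit <- stats::lm(log(y) ~ log(n))
  kappa <- exp(unname(coef(fit)[1]))
  gamma <- unname(coef(fit)[2])
  ly <- log(y)
  tss <- sum((ly - mean(ly))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  if (method == "nls") {
    # a zero-residual start makes nls fail to converge; keep the log-log
    # estimates in that case
    nl <- tryCatch(
      stats::nls(y ~ k * n^g, start = list(k = kappa, g = gamma)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      kappa <- unname(coef(nl)[["k"]])
      gamma <- unname(coef(nl)[["g"]])
      raw_tss <- sum((y - mean(y))^2)
      r2 <- if (raw_tss == 0) 1 else 1 - sum(stats::residuals(nl)^2) / raw_tss
    }
  }
  structure(list(
    kappa = kappa, gamma = gamma, r_squared = r2,
    n_obs = length(y), method = method,
    fitted = tibble::tibble(n = n, observed = y, fitted = kappa * n^gamma)
  ), class = "heaps_fit")
}

#' Predict cumulative richness from a Heaps fit
#' @param object A `heaps_fit`.
#' @param n Sample counts at which to predict.
#' @param ... Unused.
#' @return Numeric vector \eqn{\kappa n^\gamma}.
#' @export
predict.heaps_fit <- function(object, n, ...) {
  object$kappa * n^object$gamma
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat("<heaps_fit> P(n) = ", signif(x$kappa, 5), " * n^",
      signif(x$gamma, 5), "  (R2 = ", signif(x$r_squared, 6), ", ",
      x$method, ")\n", sep = "")
  invisible(x)
}

#' @method tidy heaps_fit
#' @export
tidy.heaps_fit <- function(x, ...) {
  tibble::tibble(term = c("kappa", "gamma"),
                 estimate = c(x$kappa, x$gamma))
}

#' @method glance heaps_fit
#' @export
glance.heaps_fit <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, gamma = x$gamma,
                 r_squared = x$r_squared, n_obs = x$n_obs, method = x$method)
}

#' Extrapolate the pan-microbiome size and classify openness
#'
#' Evaluates the fitted Heaps law at `n_extrapolate` samples and classifies
#' the pan-microbiome as open when the fitted exponent exceeds
#' `open_margin` (richness still growing with sample count) and closed
#' otherwise. The extrapolation point must be stated explicitly and be at
#' least the observed sample count.
#'
#' @param fit A `heaps_fit`.
#' @param n_extrapolate Number of samples at which to predict (>= the
#'   fitted curve length).
#' @param open_margin Openness margin on gamma (default 0.02).
#' @return Tibble with `n_extrapolate`, `predicted_richness`, `gamma`,
#'   `open`, `open_margin`.
#' @export
pan_estimate <- function(fit, n_extrapolate, open_margin = 0.02) {
  stopifnot(inherits(fit, "heaps_fit"))
  if (n_extrapolate < fit$n_obs) {
    stop("n_extrapolate must be at least the observed sample count (",
         fit$n_obs, ")", call. = FALSE)
  }
  tibble::tibble(
    n_extrapolate = n_extrapolate,
    predicted_richness = predict(fit, n_extrapolate),
    gamma = fit$gamma,
    open = fit$gamma > open_margin,
    open_margin = open_margin
  )
}
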