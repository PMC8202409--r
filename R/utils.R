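# Internal helpers shared across modules: conversion between the tidy
# profile tibble (first column = genus label, remaining columns = samples)
# and a plain numeric matrix, plus input validation.

#' Convert a profile tibble to a genus x sample numeric matrix
#'
#' @param profile A tibble whose first column holds genus labels and whose
#'   remaining columns are per-sample numeric values.
#' @return Numeric matrix with genus rownames and sample colnames.
#' @keywords internal
#' @noRd
profile_matrix <- function(profile) {
  stopifnot(is.data.frame(profile), ncol(profile) >= 2)
  m <- as.matrix(profile[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    stop("profile columns after the first must be numeric", call. = FALSE)
  }
  rownames(m) <- as.character(profile[[1]])
  m
}

#' Rebuild a profile tibble from a matrix
#' @keywords internal
#' @noRd
matrix_profile <- function(m, label_col = "genus") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(!!label_col := rownames(m)), out)
}

#' Validate a count profile tibble
#'
#' Checks non-negativity, integer-valued counts, and unique genus and
#' sample labels.
#' @keywords internal
#' @noRd
validate_counts <- function(counts, what = "counts") {
  m <- profile_matrix(counts)
  if (anyNA(m)) {
    stop(what, ": missing values are not allowed", call. = FALSE)
  }
  if (any(m < 0)) {
    stop(what, ": negative entries are not allowed", call. = FALSE)
  }
  g <- rownames(m)
  if (anyDuplicated(g)) {
    stop(what, ": duplicate genus labels: ",
         paste(unique(g[duplicated(g)]), collapse = ", "), call. = FALSE)
  }
  s <- colnames(m)
  if (anyDuplicated(s)) {
    stop(what, ": duplicate sample labels: ",
         paste(unique(s[duplicated(s)]), collapse = ", "), call. = FALSE)
  }
  invisible(m)
}

# Align a per-sample vector (named or positional) with a set of sample ids.
align_samples <- function(x, sample_ids, what = "labels") {
  if (!is.null(names(x)) && all(sample_ids %in% names(x))) {
    return(x[sample_ids])
  }
  if (length(x) != length(sample_ids)) {
    stop(what, " must be named by sample or have length ", length(sample_ids),
         call. = FALSE)
  }
  stats::setNames(x, sample_ids)
}

# Distance-matrix coercion: accepts `dist` or a symmetric matrix.
as_distance_matrix <- function(d) {
  if (inherits(d, "dist")) {
    m <- as.matrix(d)
  } else if (is.matrix(d)) {
    m <- d
  } else {
    stop("expected a 'dist' object or a symmetric matrix", call. = FALSE)
  }
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(m) != 0)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("s", seq_len(nrow(m)))
  }
  m
}
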