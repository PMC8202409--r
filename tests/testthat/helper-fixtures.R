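# Fixtures built in code: tiny profile tables, TSV trios on disk, and
# independent brute-force oracles used across test files.

tiny_counts <- function() {
  tibble::tibble(
    genus = c("Acinetobacter", "Bacillus", "Cutibacterium"),
    s1 = c(2, 1, 1),
    s2 = c(0, 5, 0)
  )
}

tiny_taxonomy <- function() {
  tibble::tibble(
    genus = c("Acinetobacter", "Bacillus", "Cutibacterium"),
    phylum = c("Proteobacteria", "Firmicutes", "None"),
    domain = c("bacteria", "bacteria", "bacteria")
  )
}

tiny_metadata <- function(sample_ids = c("s1", "s2")) {
  tibble::tibble(
    sample_id = sample_ids,
    dataset = "dsA",
    sex = NA_character_,
    age = NA_real_,
    sampling_site = "bulk",
    tissue_source = "human_tissue"
  )
}

# Write a counts/taxonomy/metadata TSV trio; returns the directory.
write_tsv_trio <- function(counts = tiny_counts(),
                           taxonomy = tiny_taxonomy(),
                           metadata = tiny_metadata(),
                           dir = withr::local_tempdir(.local_envir = parent.frame())) {
  readr::write_tsv(counts, file.path(dir, "counts.tsv"))
  tax <- dplyr::mutate(taxonomy,
    phylum = dplyr::if_else(phylum == "None", "", phylum))
  readr::write_tsv(tax, file.path(dir, "taxonomy.tsv"))
  readr::write_tsv(metadata, file.path(dir, "metadata.tsv"), na = "")
  dir
}

read_trio <- function(dir, ...) {
  read_profile(file.path(dir, "counts.tsv"),
               file.path(dir, "taxonomy.tsv"),
               file.path(dir, "metadata.tsv"), ...)
}

# Random relative-abundance table (columns sum to 1).
random_rel_table <- function(n_taxa, n_samples, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::rexp(n_taxa * n_samples), nrow = n_taxa,
                dimnames = list(sprintf("t%03d", seq_len(n_taxa)),
                                sprintf("s%03d", seq_len(n_samples))))
    m <- sweep(m, 2, colSums(m), "/")
    dplyr::bind_cols(tibble::tibble(genus = rownames(m)),
                     tibble::as_tibble(as.data.frame(m)))
  })
}

# Naive double-loop Bray-Curtis oracle.
oracle_bray_curtis <- function(m) {
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- 0; den <- 0
      for (t in seq_len(nrow(m))) {
        num <- num + abs(m[t, i] - m[t, j])
        den <- den + (m[t, i] + m[t, j])
      }
      d[i, j] <- if (den == 0) 0 else num / den
    }
  }
  d
}

# Brute-force PERMANOVA pseudo-F with explicit double loops over pairs.
oracle_permanova_f <- function(dmat, labels) {
  n <- nrow(dmat)
  groups <- unique(labels)
  a <- length(groups)
  ss_t <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) ss_t <- ss_t + dmat[i, j]^2
  }
  ss_t <- ss_t / n
  ss_w <- 0
  for (g in groups) {
    idx <- which(labels == g)
    acc <- 0
    if (length(idx) > 1) {
      for (ii in seq_len(length(idx) - 1)) {
        for (jj in (ii + 1):length(idx)) {
          acc <- acc + dmat[idx[ii], idx[jj]]^2
        }
      }
    }
    ss_w <- ss_w + acc / length(idx)
  }
  ss_a <- ss_t - ss_w
  (ss_a / (a - 1)) / (ss_w / (n - a))
}

# Brute-force core-taxa oracle: explicit loops over genera and samples.
oracle_core_taxa <- function(m, detection, prevalence) {
  core <- character(0)
  for (g in rownames(m)) {
    hits <- 0
    for (s in colnames(m)) {
      if (m[g, s] > detection) hits <- hits + 1
    }
    if (hits / ncol(m) >= prevalence) core <- c(core, g)
  }
  core
}

# Small null-calibration config reused by acceptance tests.
null_config <- function(seed = 1) {
  synthetic_config(pool_size = 150, n_effect_taxa = 5,
                   n_samples = c(a = 20), zero_read_count = 0,
                   low_read_count = 0, reads_meanlog = log(5000),
                   reads_sdlog = 0.3, dispersion_ratio = 1,
                   site_effect = 1, source_effect = 1, seed = seed)
}
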