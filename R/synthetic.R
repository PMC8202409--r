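# Dirichlet-multinomial cohort simulator. Emulates the statistical
# structure the downstream analyses assume: several datasets with
# dataset-dominated compositional variation, an open genus pool with
# power-law occurrence (so richness accumulates sublinearly), a
# bacteria/virus/archaea domain mix, binary factors with configurable
# location effects and group-specific overdispersion, and a tail of
# zero-read / low-read samples.

#' Configuration of the synthetic cohort generator
#'
#' The generative model: each dataset d receives a base composition
#' \eqn{\theta_d \sim Dirichlet(c_d \cdot p)} over a pool of `pool_size`
#' genera with power-law occurrence probabilities
#' \eqn{p_g \propto g^{-\alpha}}; each sample then draws its own
#' composition \eqn{\pi_s \sim Dirichlet(c_s \cdot \theta_d \cdot e_s)}
#' where \eqn{e_s} multiplies designated effect taxa for samples in the
#' affected factor level, and \eqn{c_s} is the per-sample concentration,
#' divided by `dispersion_ratio` for the heterogeneity groups (male sex,
#' age above 65); counts are \eqn{Multinomial(R_s, \pi_s)} with log-normal
#' read depths \eqn{R_s}. A configured number of samples is overridden to
#' zero or fewer than 100 reads, mimicking failed libraries.
#'
#' Default cohort: four datasets of 214, 191, 30 and 147 samples. The
#' first dataset carries a stroma/epithelium/bulk sampling-site split, the
#' second and third contain patient-derived-xenograft (PDX) samples, the
#' third and fourth are sex-labelled and the fourth carries ages, so every
#' factor analysis has a natural subset to run on.
#'
#' @param pool_size Number of genera in the open pool (default 2500).
#' @param rank_exponent Power-law exponent of occurrence probabilities
#'   (default 1).
#' @param n_samples Named integer vector of samples per dataset
#'   (default `c(ds1 = 214, ds2 = 191, ds3 = 30, ds4 = 147)`).
#' @param dataset_concentration Total Dirichlet concentration of the
#'   dataset base compositions; smaller values make between-dataset
#'   variation dominate (default 1000).
#' @param sample_concentration Total Dirichlet concentration of per-sample
#'   compositions; controls within-dataset dispersion and, with read
#'   depth, per-sample richness (default 200; about three hundred genera
#'   per sample at default depths).
#' @param reads_meanlog,reads_sdlog Log-normal read-depth parameters
#'   (defaults `log(3e4)` and 0.7).
#' @param zero_read_count,low_read_count Number of samples overridden to 0
#'   reads and (additionally) to 1-99 reads (defaults 9 and 33).
#' @param site_effect,source_effect Multiplicative shifts applied to the
#'   designated effect taxa in epithelium and PDX samples respectively;
#'   1 disables the effect (defaults 4 and 6).
#' @param sex_effect,age_effect As above for male and old samples
#'   (defaults 1: no location effect, as observed for these factors).
#' @param n_effect_taxa Number of designated taxa per planted effect
#'   (default 20).
#' @param dispersion_ratio Factor by which the sample concentration is
#'   divided for male and old samples, planting extra heterogeneity
#'   without a location shift (default 1.5; 1 disables).
#' @param domain_mixture Named probabilities of genus domain assignment
#'   (default bacteria 0.85, virus 0.14, archaea 0.01).
#' @param phylum_none_fraction Fraction of genera with no phylum-level
#'   assignment (default 0.05).
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(pool_size = 2500,
                             rank_exponent = 1,
                             n_samples = c(ds1 = 214, ds2 = 191,
                                           ds3 = 30, ds4 = 147),
                             dataset_concentration = 1000,
                             sample_concentration = 200,
                             reads_meanlog = log(3e4),
                             reads_sdlog = 0.7,
                             zero_read_count = 9,
                             low_read_count = 33,
                             site_effect = 4,
                             source_effect = 6,
                             sex_effect = 1,
                             age_effect = 1,
                             n_effect_taxa = 20,
                             dispersion_ratio = 1.5,
                             domain_mixture = c(bacteria = 0.85,
                                                virus = 0.14,
                                                archaea = 0.01),
                             phylum_none_fraction = 0.05,
                             seed) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("seed is mandatory", call. = FALSE)
  }
  if (is.null(names(n_samples))) {
    names(n_samples) <- paste0("ds", seq_along(n_samples))
  }
  cfg <- list(
    pool_size = as.integer(pool_size),
    rank_exponent = rank_exponent,
    n_samples = n_samples,
    dataset_concentration = dataset_concentration,
    sample_concentration = sample_concentration,
    reads_meanlog = reads_meanlog,
    reads_sdlog = reads_sdlog,
    zero_read_count = as.integer(zero_read_count),
    low_read_count = as.integer(low_read_count),
    site_effect = site_effect,
    source_effect = source_effect,
    sex_effect = sex_effect,
    age_effect = age_effect,
    n_effect_taxa = as.integer(n_effect_taxa),
    dispersion_ratio = dispersion_ratio,
    domain_mixture = domain_mixture,
    phylum_none_fraction = phylum_none_fraction,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$pool_size >= 2, cfg$rank_exponent > 0,
            all(cfg$n_samples >= 1),
            cfg$dataset_concentration > 0, cfg$sample_concentration > 0,
            cfg$site_effect > 0, cfg$source_effect > 0,
            cfg$sex_effect > 0, cfg$age_effect > 0,
            cfg$n_effect_taxa >= 1, cfg$dispersion_ratio >= 1,
            all(cfg$domain_mixture >= 0), sum(cfg$domain_mixture) > 0,
            cfg$phylum_none_fraction >= 0, cfg$phylum_none_fraction <= 1)
  total <- sum(cfg$n_samples)
  if (cfg$zero_read_count + cfg$low_read_count > total) {
    stop("more zero/low-read samples than samples in the cohort",
         call. = FALSE)
  }
  if (4 * cfg$n_effect_taxa > min(cfg$pool_size, 150) - 4) {
    stop("n_effect_taxa too large for the pool", call. = FALSE)
  }
  invisible(cfg)
}

# Power-law occurrence probabilities over the pool.
pool_probs <- function(cfg) {
  p <- seq_len(cfg$pool_size)^(-cfg$rank_exponent)
  p / sum(p)
}

rdirichlet_one <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  s <- sum(x)
  if (s == 0 || !is.finite(s)) {
    # extreme underflow: fall back to the normalized concentration
    x <- alpha
    s <- sum(x)
  }
  x / s
}

synthetic_metadata <- function(cfg) {
  ds_names <- names(cfg$n_samples)
  k <- length(ds_names)
  rows <- purrr::imap(as.list(cfg$n_samples), function(n, ds) {
    i <- match(ds, ds_names)
    site <- rep("bulk", n)
    if (i == 1 && k >= 2 && n >= 6) {
      n_str <- round(0.60 * n); n_epi <- round(0.33 * n)
      site <- rep(c("stroma", "epithelium", "bulk"),
                  c(n_str, n_epi, n - n_str - n_epi))
    }
    source <- rep("human_tissue", n)
    if (k >= 3 && i == 3) source <- rep("pdx", n)
    if (k >= 2 && i == 2 && n >= 10) {
      source[seq_len(round(0.15 * n))] <- "pdx"
    }
    sex <- rep(NA_character_, n)
    if (i >= k - 1) {
      sex <- sample(rep(c("male", "female"),
                        c(ceiling(0.53 * n), n - ceiling(0.53 * n))))
    }
    age <- rep(NA_real_, n)
    if (i == k) age <- round(stats::runif(n, 35, 85))
    tibble::tibble(dataset = ds, sex = sex, age = age,
                   sampling_site = sample(site),
                   tissue_source = sample(source))
  })
  meta <- dplyr::bind_rows(rows)
  meta$sample_id <- sprintf("s%04d", seq_len(nrow(meta)))
  dplyr::select(meta, "sample_id", "dataset", "sex", "age",
                "sampling_site", "tissue_source")
}

synthetic_taxonomy <- function(cfg, genus_ids) {
  g <- length(genus_ids)
  mix <- cfg$domain_mixture / sum(cfg$domain_mixture)
  domain <- sample(names(mix), g, replace = TRUE, prob = mix)
  n_phy <- c(bacteria = 14, virus = 7, archaea = 3, fungi = 4)
  phylum <- vapply(domain, function(d) {
    k <- n_phy[[d]]
    w <- seq_len(k)^-1
    paste0(toupper(substr(d, 1, 1)), "phy",
           sample.int(k, 1, prob = w / sum(w)))
  }, character(1))
  none <- stats::runif(g) < cfg$phylum_none_fraction
  phylum[none] <- PHYLUM_NONE
  tibble::tibble(genus = genus_ids, phylum = unname(phylum),
                 domain = unname(domain))
}

#' Generate a synthetic cohort
#'
#' Draws a full genus x sample count table, taxonomy and metadata from the
#' generative model described in [synthetic_config()], along with a ground
#' truth record of every planted structure.
#'
#' @param config A `synthetic_config`.
#' @return A list of class `taxon_profile` with `counts`, `taxonomy`,
#'   `metadata` and `ground_truth` (the config, dataset base compositions,
#'   designated effect taxa per factor, and the overridden zero/low-read
#'   sample ids).
#' @export
#' @examples
#' cfg <- synthetic_config(pool_size = 200, n_effect_taxa = 10,
#'                         n_samples = c(a = 10, b = 10),
#'                         zero_read_count = 1, low_read_count = 2,
#'                         seed = 42)
#' prof <- generate_profiles(cfg)
#' prof$counts[1:3, 1:4]
generate_profiles <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    g <- cfg$pool_size
    genus_ids <- sprintf("g%04d", seq_len(g))
    p <- pool_probs(cfg)
    meta <- synthetic_metadata(cfg)
    tax <- synthetic_taxonomy(cfg, genus_ids)
    n_total <- nrow(meta)

    theta <- vapply(names(cfg$n_samples), function(ds) {
      rdirichlet_one(cfg$dataset_concentration * p)
    }, numeric(g))

    # designated effect taxa: moderately abundant ranks so the planted
    # shifts are visible against the power-law background
    eligible <- seq(5, min(g, 150))
    site_taxa <- sort(sample(eligible, cfg$n_effect_taxa))
    source_taxa <- sort(sample(setdiff(eligible, site_taxa),
                               cfg$n_effect_taxa))
    sex_taxa <- sort(sample(setdiff(eligible, c(site_taxa, source_taxa)),
                            cfg$n_effect_taxa))
    age_taxa <- sort(sample(
      setdiff(eligible, c(site_taxa, source_taxa, sex_taxa)),
      cfg$n_effect_taxa))

    reads <- round(stats::rlnorm(n_total, cfg$reads_meanlog, cfg$reads_sdlog))
    override <- sample.int(n_total, cfg$zero_read_count + cfg$low_read_count)
    zero_ids <- override[seq_len(cfg$zero_read_count)]
    low_ids <- setdiff(override, zero_ids)
    reads[zero_ids] <- 0
    if (length(low_ids) > 0) {
      reads[low_ids] <- sample.int(99, length(low_ids), replace = TRUE)
    }

    counts <- matrix(0L, nrow = g, ncol = n_total,
                     dimnames = list(genus_ids, meta$sample_id))
    for (s in seq_len(n_total)) {
      alpha <- cfg$sample_concentration * theta[, match(meta$dataset[s],
                                                        colnames(theta))]
      if (identical(meta$sampling_site[s], "epithelium")) {
        alpha[site_taxa] <- alpha[site_taxa] * cfg$site_effect
      }
      if (identical(meta$tissue_source[s], "pdx")) {
        alpha[source_taxa] <- alpha[source_taxa] * cfg$source_effect
      }
      hetero <- identical(meta$sex[s], "male") ||
        (!is.na(meta$age[s]) && meta$age[s] > 65)
      if (identical(meta$sex[s], "male")) {
        alpha[sex_taxa] <- alpha[sex_taxa] * cfg$sex_effect
      }
      if (!is.na(meta$age[s]) && meta$age[s] > 65) {
        alpha[age_taxa] <- alpha[age_taxa] * cfg$age_effect
      }
      if (hetero) alpha <- alpha / cfg$dispersion_ratio
      pi_s <- rdirichlet_one(alpha)
      if (reads[s] > 0) {
        counts[, s] <- stats::rmultinom(1, size = reads[s], prob = pi_s)
      }
    }

    out <- new_taxon_profile(
      matrix_profile(counts), tax, meta
    )
    out$ground_truth <- list(
      config = unclass(cfg),
      theta = theta,
      site_taxa = genus_ids[site_taxa],
      source_taxa = genus_ids[source_taxa],
      sex_taxa = genus_ids[sex_taxa],
      age_taxa = genus_ids[age_taxa],
      zero_read_samples = meta$sample_id[zero_ids],
      low_read_samples = meta$sample_id[low_ids]
    )
    class(out) <- c("synthetic_profile", class(out))
    out
  })
}

#' Generate a null pair: two labelled groups from one population
#'
#' Draws `2 * n_per_group` exchangeable samples from a single dataset base
#' composition (no planted effects, no extra dispersion) and assigns group
#' labels independently of composition. The workhorse of type-I-error
#' calibration for [permanova()] and [rank_sum_test()].
#'
#' @param config A `synthetic_config` (pool size, concentrations and read
#'   depths are taken from it; effects and overrides are ignored).
#' @param n_per_group Samples per group (default 10).
#' @param seed Seed for this draw (defaults to `config$seed`).
#' @return List with `counts` (profile tibble), `rel` (relative
#'   abundances) and `labels` (character vector named by sample).
#' @export
generate_null_pair <- function(config, n_per_group = 10,
                               seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"), n_per_group >= 1)
  cfg <- config
  withr::with_seed(seed, {
    g <- cfg$pool_size
    genus_ids <- sprintf("g%04d", seq_len(g))
    p <- pool_probs(cfg)
    theta <- rdirichlet_one(cfg$dataset_concentration * p)
    n <- 2L * n_per_group
    reads <- pmax(1, round(stats::rlnorm(n, cfg$reads_meanlog,
                                         cfg$reads_sdlog)))
    counts <- matrix(0L, nrow = g, ncol = n,
                     dimnames = list(genus_ids, sprintf("s%03d", seq_len(n))))
    for (s in seq_len(n)) {
      pi_s <- rdirichlet_one(cfg$sample_concentration * theta)
      counts[, s] <- stats::rmultinom(1, size = reads[s], prob = pi_s)
    }
    labels <- stats::setNames(
      sample(rep(c("grp1", "grp2"), each = n_per_group)), colnames(counts))
    counts_tbl <- matrix_profile(counts)
    list(counts = counts_tbl,
         rel = to_relative_abundance(counts_tbl),
         labels = labels)
  })
}
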