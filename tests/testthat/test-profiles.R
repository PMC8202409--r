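test_that("TSV round-trip reproduces counts, taxonomy and metadata exactly", {
  dir <- write_tsv_trio()
  prof <- read_trio(dir)
  expect_equal(prof$counts, tiny_counts())
  expect_equal(prof$taxonomy, tiny_taxonomy())
  expect_equal(prof$metadata, tiny_metadata())

  dir2 <- withr::local_tempdir()
  write_profile(prof, dir2)
  back <- read_trio(dir2)
  expect_equal(back$counts, prof$counts)
  expect_equal(back$taxonomy, prof$taxonomy)
  expect_equal(back$metadata, prof$metadata)
})

test_that("read_profile enforces its contracts", {
  # sample present in counts but missing from metadata
  dir <- write_tsv_trio(metadata = tiny_metadata("s1"))
  expect_error(read_trio(dir), "absent from metadata")

  # negative count
  bad <- tiny_counts(); bad$s1[2] <- -4
  dir <- write_tsv_trio(counts = bad)
  expect_error(read_trio(dir), "negative")

  # duplicate genus label
  dup <- tiny_counts(); dup$genus[2] <- dup$genus[1]
  dir <- write_tsv_trio(counts = dup)
  expect_error(read_trio(dir), "duplicate genus")

  # genus missing from taxonomy: error unless a default domain is given
  dir <- write_tsv_trio(taxonomy = tiny_taxonomy()[-1, ])
  expect_error(read_trio(dir), "without taxonomy")
  prof <- read_trio(dir, default_domain = "bacteria")
  tax_row <- dplyr::filter(prof$taxonomy, genus == "Acinetobacter")
  expect_equal(tax_row$phylum, "None")
  expect_equal(tax_row$domain, "bacteria")

  # invalid metadata enumeration
  md <- tiny_metadata(); md$sex[1] <- "unknown"
  dir <- write_tsv_trio(metadata = md)
  expect_error(read_trio(dir), "invalid sex")
})

test_that("to_relative_abundance normalises columns and flags zero totals", {
  tab <- tibble::tibble(genus = c("A", "B", "C"),
                        s1 = c(2, 1, 1), s2 = c(0, 0, 0), s3 = c(5, 0, 0))
  rel <- to_relative_abundance(tab)
  expect_equal(rel$s1, c(0.5, 0.25, 0.25))
  expect_equal(rel$s2, c(0, 0, 0))
  expect_equal(rel$s3, c(1, 0, 0))
  expect_equal(zero_samples(rel), "s2")

  # property: nonzero columns sum to 1 within 1e-9
  withr::with_seed(5, {
    m <- matrix(rpois(200, 3), nrow = 10,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  })
  rel2 <- to_relative_abundance(dplyr::bind_cols(
    tibble::tibble(genus = rownames(m)), tibble::as_tibble(as.data.frame(m))))
  sums <- colSums(panmicro:::profile_matrix(rel2))
  nz <- setdiff(colnames(m), zero_samples(rel2))
  expect_true(all(abs(sums[nz] - 1) < 1e-9))
})

test_that("aggregate_taxa sums counts at the requested rank and keeps None", {
  counts <- tibble::tibble(genus = c("A", "B", "C"), s1 = c(1, 2, 3))
  tax <- tibble::tibble(genus = c("A", "B", "C"),
                        phylum = c("P", "P", "None"),
                        domain = c("bacteria", "bacteria", "bacteria"))
  phy <- aggregate_taxa(counts, tax, "phylum")
  expect_equal(phy$s1[match(c("P", "None"), phy$phylum)], c(3, 3))

  dom <- aggregate_taxa(counts, tax, "domain")
  expect_equal(dom$s1, 6)
  expect_equal(dom$domain, "bacteria")

  # conservation of per-sample totals at every level, on a random table
  cfg <- synthetic_config(pool_size = 120, n_effect_taxa = 5,
                          n_samples = c(a = 6), zero_read_count = 0,
                          low_read_count = 0, seed = 11)
  prof <- generate_profiles(cfg)
  tot <- colSums(panmicro:::profile_matrix(prof$counts))
  for (lvl in c("phylum", "domain")) {
    agg <- aggregate_taxa(prof$counts, prof$taxonomy, lvl)
    expect_equal(colSums(panmicro:::profile_matrix(agg)), tot)
  }
})

test_that("domain_proportions divides reads by the sample total", {
  counts <- tibble::tibble(genus = c("b1", "v1", "a1"),
                           s1 = c(80, 20, 0), s2 = c(0, 0, 7))
  tax <- tibble::tibble(genus = c("b1", "v1", "a1"),
                        phylum = c("P1", "P2", "P3"),
                        domain = c("bacteria", "virus", "archaea"))
  props <- domain_proportions(counts, tax)
  get <- function(s, d) props$proportion[props$sample_id == s & props$domain == d]
  expect_equal(get("s1", "bacteria"), 0.8)
  expect_equal(get("s1", "virus"), 0.2)
  expect_equal(get("s1", "archaea"), 0)
  expect_equal(get("s2", "archaea"), 1)

  # dataset means via the summary helper
  counts2 <- tibble::tibble(genus = c("b1", "v1", "a1"),
                            s1 = c(80, 20, 0), s2 = c(60, 40, 0))
  props2 <- domain_proportions(counts2, tax, tiny_metadata(c("s1", "s2")))
  means <- summarise_domain_proportions(props2)
  expect_equal(means$mean[means$domain == "bacteria"], 0.7)
  expect_equal(means$mean[means$domain == "virus"], 0.3)

  # zero-read samples are excluded with a warning
  counts3 <- tibble::tibble(genus = c("b1", "v1", "a1"),
                            s1 = c(1, 0, 0), s2 = c(0, 0, 0))
  expect_warning(p3 <- domain_proportions(counts3, tax), "zero-read")
  expect_false("s2" %in% p3$sample_id)
})

test_that("qc_filter removes samples strictly below the read threshold", {
  counts <- tibble::tibble(genus = c("A", "B"),
                           s1 = c(0, 0), s2 = c(25, 25), s3 = c(500, 500))
  qc <- qc_filter(counts, min_reads = 100)
  expect_equal(names(qc$kept)[-1], "s3")
  expect_equal(qc$zero_read, "s1")
  expect_equal(sort(qc$low_read), c("s1", "s2"))
  # kept + removed partitions the input
  expect_equal(sort(c(names(qc$kept)[-1],
                      qc$totals$sample_id[!qc$totals$kept])),
               c("s1", "s2", "s3"))

  # boundary: a sample with exactly min_reads reads is kept
  counts2 <- tibble::tibble(genus = "A", s1 = 99, s2 = 100)
  qc2 <- qc_filter(counts2, min_reads = 100)
  expect_equal(names(qc2$kept)[-1], "s2")
  expect_equal(qc2$low_read, "s1")

  # min_reads = 0 keeps everything; filtering is idempotent
  expect_equal(ncol(qc_filter(counts, min_reads = 0)$kept), 4)
  again <- qc_filter(qc$kept, min_reads = 100)
  expect_equal(again$kept, qc$kept)
})

test_that("top_n_collapse ranks by mean abundance and preserves column sums", {
  rel <- tibble::tibble(genus = c("A", "B", "C"),
                        s1 = c(0.5, 0.3, 0.2), s2 = c(0.6, 0.25, 0.15))
  out <- top_n_collapse(rel, 2)
  expect_equal(out$genus, c("A", "B", "Other"))
  expect_equal(out$s1, c(0.5, 0.3, 0.2))

  # n >= taxa keeps everything with an all-zero Other row
  out2 <- top_n_collapse(rel, 10)
  expect_equal(nrow(out2), 4)
  expect_equal(out2$s1[out2$genus == "Other"], 0)

  # column sums preserved on a random table
  r <- random_rel_table(30, 8, seed = 3)
  collapsed <- top_n_collapse(r, 5)
  expect_equal(colSums(panmicro:::profile_matrix(collapsed)),
               colSums(panmicro:::profile_matrix(r)))
  expect_error(top_n_collapse(rel, 0), "positive")
})
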