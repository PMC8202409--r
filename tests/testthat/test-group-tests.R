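test_that("permanova reproduces the hand-worked two-group instance", {
  # 1-D points A = {0, 1}, B = {10, 11}, Euclidean distances:
  # SS_T = 404/4 = 101, SS_W = 1, SS_A = 100, F = (100/1)/(1/2) = 200;
  # full enumeration of the 6 label arrangements gives p = 2/6 = 1/3
  d <- stats::dist(c(a1 = 0, a2 = 1, b1 = 10, b2 = 11))
  fit <- permanova(d, c("A", "A", "B", "B"), seed = 1)
  expect_equal(fit$pseudo_f, 200, tolerance = 1e-12)
  expect_equal(fit$p_value, 1 / 3, tolerance = 1e-12)
  expect_true(fit$exact)
  expect_equal(fit$r2, 100 / 101, tolerance = 1e-12)
  expect_equal(unname(fit$ss), c(100, 1, 101), tolerance = 1e-12)

  # invariance to swapping group names
  fit2 <- permanova(d, c("B", "B", "A", "A"), seed = 1)
  expect_equal(fit2$pseudo_f, fit$pseudo_f)
  expect_equal(fit2$p_value, fit$p_value)
})

test_that("permanova pseudo-F agrees with the brute-force oracle", {
  for (seed in 1:50) {
    withr::with_seed(seed, {
      x <- matrix(stats::rnorm(12 * 5), nrow = 12)
      labels <- sample(rep(c("a", "b", "c"), c(4, 4, 4)))
    })
    dmat <- as.matrix(stats::dist(x))
    fit <- permanova(dmat, labels, n_permutations = 9, seed = seed)
    expect_equal(fit$pseudo_f, oracle_permanova_f(dmat, labels),
                 tolerance = 1e-10)
  }
})

test_that("permanova pseudo-F matches vegan::adonis2 on a random instance", {
  withr::with_seed(31, {
    x <- matrix(abs(stats::rnorm(16 * 8)), nrow = 16)
    labels <- rep(c("u", "v"), each = 8)
  })
  d <- vegan::vegdist(x, method = "bray")
  fit <- permanova(d, labels, n_permutations = 99, seed = 2)
  ref <- vegan::adonis2(d ~ g, data = data.frame(g = labels),
                        permutations = 99)
  expect_equal(fit$pseudo_f, ref$F[1], tolerance = 1e-10)
  expect_equal(fit$r2, ref$R2[1], tolerance = 1e-10)
})

test_that("exact enumeration matches long-run Monte-Carlo permutation p", {
  withr::with_seed(12, {
    x <- stats::rnorm(8)
    labels <- rep(c("a", "b"), each = 4)
  })
  dmat <- as.matrix(stats::dist(x))
  exact_fit <- permanova(dmat, labels, n_permutations = 100, seed = 1)
  expect_true(exact_fit$exact)
  expect_equal(exact_fit$n_permutations, 70)  # 8! / (4! 4!)
  mc_fit <- permanova(dmat, labels, n_permutations = 20000, seed = 5,
                      exact = FALSE)
  expect_false(mc_fit$exact)
  expect_equal(mc_fit$p_value, exact_fit$p_value, tolerance = 0.02)
  # +1 correction: Monte-Carlo p can never be 0 or exceed 1
  expect_gte(mc_fit$p_value, 1 / 20001)
  expect_lte(mc_fit$p_value, 1)
})

test_that("permanova validates its inputs", {
  d <- stats::dist(1:6)
  expect_error(permanova(d, rep("a", 6), seed = 1), "two groups")
  expect_error(permanova(d, c("a", rep("b", 5)), seed = 1), "at least 2")
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(permanova(bad, c("a", "b"), seed = 1), "symmetric")
})

test_that("pairwise_permanova reports every pair and matches subset calls", {
  withr::with_seed(3, {
    x <- matrix(stats::rnorm(12 * 4), nrow = 12)
  })
  labels <- rep(c("a", "b", "c"), each = 4)
  dmat <- as.matrix(stats::dist(x))
  rownames(dmat) <- colnames(dmat) <- paste0("s", 1:12)
  pw <- pairwise_permanova(dmat, labels, n_permutations = 99, seed = 4)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$testable))

  idx <- labels %in% c("a", "b")
  direct <- permanova(dmat[idx, idx], labels[idx], n_permutations = 99,
                      seed = 4)
  row_ab <- dplyr::filter(pw, group1 == "a", group2 == "b")
  expect_equal(row_ab$pseudo_f, direct$pseudo_f)
  expect_equal(row_ab$p_value, direct$p_value)

  # a singleton group is reported as not testable, not an error
  labels2 <- c(rep("a", 4), rep("b", 7), "c")
  pw2 <- pairwise_permanova(dmat, labels2, n_permutations = 99, seed = 4)
  expect_false(pw2$testable[pw2$group2 == "c"][1])
  expect_true(all(is.na(pw2$p_value[!pw2$testable])))
})

test_that("separating_coefficients are group mean differences", {
  rel <- tibble::tibble(genus = c("A", "B", "C"),
                        s1 = c(0.6, 0.3, 0.1), s2 = c(0.4, 0.5, 0.1),
                        s3 = c(0.1, 0.8, 0.1), s4 = c(0.3, 0.6, 0.1))
  labels <- c(s1 = "g1", s2 = "g1", s3 = "g2", s4 = "g2")
  co <- separating_coefficients(rel, labels)
  expect_equal(co$coefficient[co$genus == "A"], 0.5 - 0.2)
  expect_equal(co$coefficient[co$genus == "B"], 0.4 - 0.7)
  expect_equal(co$coefficient[co$genus == "C"], 0)
  expect_equal(co$genus[1:2], c("A", "B"))  # ranked by |coefficient|

  # swapping the reference negates every coefficient
  co_swap <- separating_coefficients(rel, labels, reference = "g2")
  expect_equal(co_swap$coefficient[match(co$genus, co_swap$genus)],
               -co$coefficient)

  expect_error(separating_coefficients(rel, c(s1 = "a", s2 = "b", s3 = "c",
                                              s4 = "c")), "two groups")
  expect_equal(nrow(top_coefficients(co, 2)), 2)
})

test_that("fold_change handles zero denominators with a pseudo-count", {
  rel <- tibble::tibble(genus = c("Gammaretrovirus", "Other1"),
                        s1 = c(0.376, 0.624), s2 = c(0.376, 0.624),
                        s3 = c(0.001, 0.999), s4 = c(0.001, 0.999))
  labels <- c(s1 = "pdx", s2 = "pdx", s3 = "human", s4 = "human")
  fc <- fold_change(rel, labels, "Gammaretrovirus",
                    group1 = "pdx", group2 = "human")
  expect_equal(fc$fold_change, 376)
  expect_false(fc$pseudo_count_used)

  # reciprocal identity when both means are positive
  fc_rev <- fold_change(rel, labels, "Gammaretrovirus",
                        group1 = "human", group2 = "pdx")
  expect_equal(fc$fold_change, 1 / fc_rev$fold_change)

  # equal means give 1
  fc_eq <- fold_change(rel, labels, "Other1",
                       group1 = "pdx", group2 = "pdx")
  expect_equal(fc_eq$fold_change, 1)

  # zero denominator triggers the pseudo-count and the flag
  rel0 <- tibble::tibble(genus = c("X", "Y"),
                         s1 = c(0.5, 0.5), s2 = c(0.5, 0.5),
                         s3 = c(0, 1), s4 = c(0, 1))
  fc0 <- fold_change(rel0, labels, "X", group1 = "pdx", group2 = "human")
  expect_true(fc0$pseudo_count_used)
  expect_true(is.finite(fc0$fold_change))

  expect_error(fold_change(rel, labels, "NotThere"), "not present")
})

test_that("age_threshold_scan partitions samples per threshold", {
  withr::with_seed(8, {
    x <- matrix(stats::rnorm(12 * 6), nrow = 12)
  })
  dmat <- as.matrix(stats::dist(x))
  rownames(dmat) <- colnames(dmat) <- paste0("s", 1:12)
  ages <- stats::setNames(c(40, 42, 50, 52, 58, 60, 62, 66, 68, 70, 72, 75),
                          rownames(dmat))
  scan <- age_threshold_scan(dmat, ages, thresholds = c(30, 55, 65),
                             n_permutations = 99, seed = 6)
  expect_equal(nrow(scan), 3)
  # below the minimum age: everyone is old, not testable
  expect_false(scan$testable[scan$threshold == 30])
  row55 <- dplyr::filter(scan, threshold == 55)
  expect_equal(row55$n_young, 4)
  expect_equal(row55$n_old, 8)
  expect_true(row55$testable)
  expect_error(age_threshold_scan(dmat, ages, thresholds = 10,
                                  n_permutations = 99, seed = 1),
               "no threshold")
})
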