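toy_table <- function(mat, contaminant = FALSE, reverse = FALSE,
                      only_by_site = FALSE) {
  n <- nrow(mat)
  intensity_table(mat, data.frame(
    contaminant = rep_len(contaminant, n),
    reverse = rep_len(reverse, n),
    only_by_site = rep_len(only_by_site, n)
  ))
}

test_that("flagged rows are removed once, with counts logged", {
  mat <- matrix(2^rnorm(80, 25), 10, 8,
                dimnames = list(paste0("p", 1:10), paste0("s", 1:8)))
  x <- intensity_table(mat, data.frame(
    contaminant = c(TRUE, TRUE, rep(FALSE, 8)),
    reverse = c(TRUE, FALSE, TRUE, rep(FALSE, 7)),
    only_by_site = rep(FALSE, 10)
  ))
  out <- filter_rows(x)
  expect_equal(nrow(out$intensities), 7L) # row 1 doubly flagged, removed once
  expect_equal(attr(out, "removed")[["total"]], 3L)

  clean <- toy_table(mat)
  expect_identical(filter_rows(clean)$intensities, mat)
})

test_that("log2 transform maps values elementwise and keeps missingness", {
  mat <- matrix(c(8, 1, NA, 1024), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
  out <- log2_transform(toy_table(mat))
  expect_equal(out$intensities[1, 1], 3)
  expect_equal(out$intensities[2, 1], 0)
  expect_true(is.na(out$intensities[1, 2]))
  expect_equal(out$intensities[2, 2], 10)
  bad <- toy_table(matrix(c(-1, 2, 3, 4), 2, 2))
  expect_error(log2_transform(bad), "non-positive")
})

test_that("validity filter keeps rows fully observed in one group", {
  groups <- rep(c("target", "control"), each = 4)
  mat <- rbind(
    full_a = c(1:4, NA, NA, NA, NA),        # 4/4 in target -> kept
    partial = c(1:3, NA, 1:3, NA),          # 3/4 in both -> removed
    full_both = c(1:4, 1:4),                # kept
    full_b = c(NA, NA, NA, NA, 1:4)         # 4/4 in control -> kept
  )
  colnames(mat) <- paste0("s", 1:8)
  out <- validity_filter(toy_table(mat), groups)
  expect_setequal(rownames(out$intensities),
                  c("full_a", "full_both", "full_b"))
  relaxed <- validity_filter(toy_table(mat), groups, min_valid = 3)
  expect_equal(nrow(relaxed$intensities), 4L)
})

test_that("imputation is seeded, column-wise downshifted normal", {
  set.seed(1)
  n <- 4000
  obs <- rnorm(n, 25, 2)
  mat <- cbind(col1 = c(obs, rep(NA_real_, 10000)),
               col2 = rnorm(n + 10000, 25, 2))
  rownames(mat) <- paste0("p", seq_len(nrow(mat)))
  x <- toy_table(mat)
  out1 <- impute(x, width = 0.3, downshift = 1.8, seed = 42)
  out2 <- impute(x, width = 0.3, downshift = 1.8, seed = 42)
  expect_identical(out1$intensities, out2$intensities)

  imp <- out1$intensities[is.na(mat[, 1]), 1]
  mu_exp <- mean(obs) - 1.8 * sd(obs)
  expect_equal(mean(imp), mu_exp, tolerance = 0.02)
  expect_equal(sd(imp), 0.3 * sd(obs), tolerance = 0.02)

  # no missing values: identity
  complete <- toy_table(matrix(rnorm(40, 25), 10, 4))
  expect_identical(impute(complete, seed = 1)$intensities,
                   complete$intensities)
  # too few observed values to estimate the distribution
  thin <- toy_table(matrix(c(25, rep(NA, 5)), 3, 2))
  expect_error(impute(thin, seed = 1), "fewer than 2 observed")
})

test_that("PCA separates shifted groups and returns orthogonal components", {
  base <- rnorm(100, 25, 2)
  mat <- sapply(1:8, function(j) base)
  mat[1:50, 1:4] <- mat[1:50, 1:4] + 4 # constant shift on half the proteins
  mat <- mat + matrix(rnorm(800, 0, 0.1), 100, 8)
  colnames(mat) <- paste0("s", 1:8)
  p <- sample_pca(toy_table(mat))
  pc1 <- p$coordinates[, 1]
  expect_true(all(sign(pc1[1:4]) != sign(pc1[5:8])))
  expect_gt(p$explained_variance[1], 0.9)
  rot <- p$coordinates
  cross <- as.numeric(crossprod(rot[, 1], rot[, 2]))
  expect_equal(cross / nrow(rot), 0, tolerance = 1e-8)

  # identical samples: zero variance, defined output
  flat <- sapply(1:4, function(j) rep(25, 10))
  colnames(flat) <- paste0("f", 1:4)
  pf <- sample_pca(toy_table(flat))
  expect_equal(sum(pf$explained_variance), 0)
  expect_error(sample_pca(toy_table(matrix(1:4, 4, 1))), "two samples")
})

test_that("s0 statistic reduces to the classical t and is monotone in s0", {
  set.seed(33)
  groups <- factor(rep(c("t", "c"), each = 4), levels = c("t", "c"))
  mat <- matrix(rnorm(160, 25, 1), 20, 8)
  rownames(mat) <- paste0("p", 1:20)
  d0 <- s0_test(mat, groups, s0 = 0)$d
  tref <- apply(mat, 1, function(x) {
    t.test(x[1:4], x[5:8], var.equal = TRUE)$statistic
  })
  expect_equal(unname(d0), unname(tref), tolerance = 1e-12)

  # equal group means give d = 0 for any s0
  same <- rbind(c(1, 2, 3, 4, 1, 2, 3, 4))
  expect_equal(s0_test(same, groups, s0 = 0)$d, 0)
  expect_equal(s0_test(same, groups, s0 = 2)$d, 0)

  # |d| strictly decreases as s0 grows (for nonzero differences)
  d1 <- abs(s0_test(mat, groups, s0 = 1)$d)
  d2 <- abs(s0_test(mat, groups, s0 = 2)$d)
  nonzero <- abs(d0) > 0
  expect_true(all(d2[nonzero] < d1[nonzero]))

  # antisymmetry under group swap
  swapped <- factor(rep(c("t", "c"), each = 4), levels = c("c", "t"))
  expect_equal(s0_test(mat, swapped, s0 = 2)$d,
               -s0_test(mat, groups, s0 = 2)$d)

  # zero variance with s0 = 0 flags infinity
  const <- rbind(c(2, 2, 2, 2, 1, 1, 1, 1))
  expect_true(is.infinite(s0_test(const, groups, s0 = 0)$d))
})

test_that("balanced 4v4 designs enumerate 35 complement-invariant relabelings", {
  groups <- factor(rep(c("t", "c"), each = 4), levels = c("t", "c"))
  perms <- prodomainevo:::balanced_permutations(groups)
  expect_equal(ncol(perms$sets), 35L)
  expect_true(all(perms$sets[1, ] == 1L))
  set.seed(2)
  mat <- matrix(rnorm(800, 25, 1), 100, 8)
  rownames(mat) <- paste0("p", 1:100)
  res <- permutation_fdr(mat, groups, s0 = 2, fdr = 0.01, seed = 1)
  expect_equal(res$n_permutations, 34L) # observed labelling excluded
})

test_that("permutation FDR recovers strong spikes and is consistent end-to-end", {
  sim <- simulate_lfq(lfq_sim_config(n_proteins = 400, n_enriched = 20,
                                     seed = 77))
  res <- enrich_pipeline(sim$table, sim$groups, s0 = 2, fdr = 0.01,
                         seed = 77)
  called <- res$results$protein_id[res$results$significant &
                                     res$results$direction == "target"]
  spiked <- sim$truth$protein_id[sim$truth$enriched]
  expect_gte(sum(spiked %in% called) / length(spiked), 0.95)
  expect_equal(res$n_enriched, sum(res$results$significant &
                                     res$results$direction == "target"))

  # fdr = 1 limit: every nonzero |d| is callable
  res_all <- permutation_fdr(res2mat <- {
    m <- matrix(rnorm(160, 25, 1), 20, 8)
    m[1, 1:4] <- m[1, 1:4] + 5
    rownames(m) <- paste0("p", 1:20); colnames(m) <- paste0("s", 1:8)
    m
  }, factor(rep(c("t", "c"), each = 4), levels = c("t", "c")),
  s0 = 2, fdr = 1, seed = 1)
  expect_true(all(res_all$significant[abs(res_all$d) > 0]))

  # volcano export round-trips and flags exactly the significant set
  path <- withr::local_tempfile(fileext = ".tsv")
  exported <- volcano_export(res, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$protein_id, exported$protein_id)
  expect_equal(back$significant, exported$significant)
  expect_equal(back$difference, exported$difference, tolerance = 1e-9)
  expect_setequal(exported$protein_id[exported$significant],
                  res$results$protein_id[res$results$significant])
})

test_that("pipeline is deterministic given config and seed", {
  sim <- simulate_lfq(lfq_sim_config(n_proteins = 200, n_enriched = 10,
                                     seed = 5))
  r1 <- enrich_pipeline(sim$table, sim$groups, seed = 9)
  r2 <- enrich_pipeline(sim$table, sim$groups, seed = 9)
  expect_identical(r1$results, r2$results)
  expect_identical(r1$summary$threshold, r2$summary$threshold)
})

test_that("proteinGroups dialect round-trips through the reader", {
  sim <- simulate_lfq(lfq_sim_config(n_proteins = 50, n_enriched = 5,
                                     seed = 3),
                      path = withr::local_tempfile(fileext = ".tsv"))
  back <- read_proteingroups(sim$path)
  expect_equal(dim(back$intensities), dim(sim$table$intensities))
  expect_equal(back$flags$contaminant, sim$table$flags$contaminant)
  # zeros in the file come back as missing
  expect_equal(is.na(back$intensities), is.na(sim$table$intensities))
  expect_equal(back$intensities[!is.na(back$intensities)],
               sim$table$intensities[!is.na(sim$table$intensities)],
               tolerance = 1e-6)
  # all-empty flag columns (read as logical NA) must not poison the filter
  expect_equal(nrow(filter_rows(back)$intensities), 50L)
})
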