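test_that("rank-correlation matrix matches a hand oracle and flags constants", {
  tab <- data.frame(x = c(3, 1, 4, 1, 5), y = c(2, 7, 1, 8, 3),
                    z = c(1, 2, 3, 4, 5))
  cm <- correlation_matrix(tab)
  expect_equal(unname(diag(cm)), c(1, 1, 1))
  expect_equal(cm, t(cm))
  expect_true(all(cm >= -1 & cm <= 1))
  expect_equal(cm["x", "y"], oracle_spearman(tab$x, tab$y))
  expect_equal(cm["x", "z"], oracle_spearman(tab$x, tab$z))
  # a column against itself and against its negation
  tab2 <- data.frame(a = c(1, 2, 3, 4), b = -c(1, 2, 3, 4))
  cm2 <- correlation_matrix(tab2)
  expect_equal(unname(cm2["a", "b"]), -1)
  # constant column -> flagged NA entries
  cm3 <- correlation_matrix(data.frame(a = 1:5, b = rep(2, 5)))
  expect_true(is.na(cm3["a", "b"]))
  expect_gt(nrow(attr(cm3, "undefined")), 0)
})

test_that("Mann-Whitney neighbour tests: identical, separated and gradient groups", {
  # identical groups: no evidence
  x <- rep(c(1, 2, 3, 4, 5), 2)
  gr <- rep(c("I", "II"), each = 5)
  res <- neighbouring_group_tests(x, factor(gr, levels = c("I", "II")))
  expect_gte(res$p, 0.99)

  # completely separated groups of 5 vs 5: exact p = 2/252
  y <- c(1:5, 11:15)
  res2 <- neighbouring_group_tests(y, factor(gr, levels = c("I", "II")))
  expect_equal(res2$p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_true(res2$significant)

  # 7-group synthetic gradient of simulated inbreeding
  set.seed(91)
  p <- runif(3000, 0.2, 0.8)
  fr <- provided_frequencies(p)
  fs <- seq(0.12, 0, length.out = 7)
  vals <- c(); grp <- c()
  for (k in 1:7) {
    vals <- c(vals, replicate(12, as.numeric(
      f_plink(sim_inbred_genotypes(p, fs[k]), fr))))
    grp <- c(grp, rep(paste0("G", k), 12))
  }
  grp <- factor(grp, levels = paste0("G", 1:7))
  meds <- tapply(vals, grp, median)
  expect_true(all(diff(meds) < 0))   # monotone decreasing medians
  res3 <- neighbouring_group_tests(vals, grp)
  expect_equal(nrow(res3), 6)
  expect_true(all(res3$n_a == 12 & res3$n_b == 12))

  # empty group is skipped with a note
  res4 <- neighbouring_group_tests(c(1, 2, 3), factor(c("A", "A", "A"),
                                   levels = c("A", "B")))
  expect_match(res4$note, "skipped")
})

test_that("sibling-pair Wilcoxon test handles ties, extremes and degenerate input", {
  est <- setNames(c(1, 1, 2, 2, 3, 3), paste0("s", 1:6))
  pairs <- cbind(c("s1", "s3", "s5"), c("s2", "s4", "s6"))
  res <- sibling_pair_test(est, pairs)
  expect_equal(res$p, 1)
  expect_match(res$note, "zero")

  est2 <- setNames(c(5, 1, 6, 2, 7, 3, 8, 4, 9, 5, 10, 6),
                   paste0("t", 1:12))
  pairs2 <- cbind(paste0("t", seq(1, 12, 2)), paste0("t", seq(2, 12, 2)))
  res2 <- sibling_pair_test(est2, pairs2)
  expect_lt(res2$p, 0.05)     # member A always exceeds B: minimal p for n = 6
  expect_equal(res2$n_pairs_used, 6)
})

test_that("simulated sibling pairs show no systematic estimator difference", {
  # sibs from a first-cousin mating share expected F; estimates differ only
  # by noise, so the within-pair signed-rank test is typically null
  map <- make_sim_map(n_markers = 1200, n_chromosomes = 6, seed = 97)
  fr <- provided_frequencies(map$freq_a1)
  ped <- build_cousin_pedigree(1)
  plan <- hbdkit:::meiosis_plan(map)
  set.seed(101)
  n_pairs <- 20
  va <- vb <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    ga <- assign_genotypes(gene_drop(ped, map, plan), map)
    gb <- assign_genotypes(gene_drop(ped, map, plan), map)  # same pedigree: sibs
    va[k] <- as.numeric(f_plink(ga, fr))
    vb[k] <- as.numeric(f_plink(gb, fr))
  }
  est <- setNames(c(va, vb), c(paste0("a", 1:n_pairs), paste0("b", 1:n_pairs)))
  res <- sibling_pair_test(est, cbind(paste0("a", 1:n_pairs),
                                      paste0("b", 1:n_pairs)))
  expect_gt(res$p, 0.05)
})

test_that("conditional correlation drops the uninformative subset", {
  set.seed(103)
  n <- 60
  truth <- c(rep(0, 30), runif(30, 0.01, 0.1))
  est1 <- truth + rnorm(n, 0, 0.01)
  est2 <- truth + rnorm(n, 0, 0.01)
  tab <- data.frame(A = est1, B = est2, cond = truth)
  full <- cor(tab$A, tab$B, method = "spearman")
  cc <- conditional_correlation(tab, "A", "B", "cond", 0)
  expect_equal(cc$n_used, 30)
  expect_gte(cc$rho, -1); expect_lte(cc$rho, 1)
  # nothing removed -> equals the unconditional value
  cc_all <- conditional_correlation(tab, "A", "B", "cond", -1)
  expect_equal(cc_all$rho, full)
  # too-small subset -> undefined
  cc_small <- conditional_correlation(tab, "A", "B", "cond", 0.099)
  expect_true(is.na(cc_small$rho))
})

test_that("the simulation study is reproducible and applies truncation as configured", {
  map <- make_sim_map(n_markers = 400, n_chromosomes = 4, seed = 107)
  st1 <- run_simulation_study(degrees = 1, n_replicates = 10, map = map,
                              methods = c("MLH", "F_PLINK", "FEstimSPT"),
                              seed = 11)
  st2 <- run_simulation_study(degrees = 1, n_replicates = 10, map = map,
                              methods = c("MLH", "F_PLINK", "FEstimSPT"),
                              seed = 11)
  expect_identical(st1$degrees[["1"]]$table, st2$degrees[["1"]]$table)
  expect_true(all(st1$degrees[["1"]]$table$F_PLINK >= 0))   # truncated

  raw <- run_simulation_study(degrees = 1, n_replicates = 10, map = map,
                              methods = "F_PLINK", truncate = FALSE, seed = 11)
  expect_identical(truncate_negative(raw$degrees[["1"]]$table$F_PLINK),
                   st1$degrees[["1"]]$table$F_PLINK)
  # summary carries mean and empirical 95% bounds for every column
  s <- st1$degrees[["1"]]$summary
  expect_setequal(s$estimator, c("true_hbd", "MLH", "F_PLINK", "FEstimSPT"))
  expect_true(all(s$q2.5 <= s$mean & s$mean <= s$q97.5))
})

test_that("estimate_inbreeding returns the long per-individual table", {
  map <- make_sim_map(n_markers = 300, n_chromosomes = 3, seed = 109)
  s <- simulate_replicates(1, 3, map, seed = 13)
  gmat <- do.call(rbind, lapply(s$replicates, `[[`, "genotypes"))
  rownames(gmat) <- paste0("id", 1:3)
  ds <- hbd_dataset(gmat, map)
  tab <- estimate_inbreeding(ds, freqs = map$freq_a1,
                             methods = c("MLH", "F_ADC", "FEstim"))
  expect_identical(dim(tab), c(9L, 4L))
  expect_setequal(unique(tab$method), c("MLH", "F_ADC", "FEstim"))
  expect_true(all(tab$n_markers_used == 300))
  expect_true(all(tab$value[tab$method == "FEstim"] >= 0 &
                  tab$value[tab$method == "FEstim"] <= 1))
})
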