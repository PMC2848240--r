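test_that("transition matrix has the exponential-distance form", {
  pr <- hmm_params(f = 0.0625, a = 0.063)
  expect_equal(transition_matrix(pr, 0), diag(2), ignore_attr = TRUE)
  # large distance: both rows reach the stationary distribution
  Tinf <- transition_matrix(pr, 1e6)
  expect_equal(unname(Tinf[1, ]), c(0.0625, 0.9375), tolerance = 1e-12)
  expect_equal(unname(Tinf[2, ]), c(0.0625, 0.9375), tolerance = 1e-12)
  # direct evaluation against the formula at d = 0.008
  T8 <- transition_matrix(pr, 0.008)
  expect_equal(unname(T8["nonHBD", "HBD"]), 0.0625 * (1 - exp(-0.063 * 0.008)))
  expect_equal(unname(rowSums(T8)), c(1, 1))
  # stationarity: pi T = pi
  pi0 <- c(0.0625, 0.9375)
  expect_equal(unname(pi0 %*% T8)[1, ], pi0)
})

make_small_fixture <- function(L = 10, n_chrom = 1, seed = 23, f_gen = 0.3) {
  set.seed(seed)
  map <- make_sim_map(n_markers = L, spacing_morgans = 0.05,
                      n_chromosomes = n_chrom,
                      freq_sampler = function(n) runif(n, 0.2, 0.8))
  g <- sim_inbred_genotypes(map$freq_a1, f_gen)
  list(map = map, g = g, fr = provided_frequencies(map$freq_a1))
}

test_that("forward log-likelihood equals the exhaustive hidden-path sum", {
  fx <- make_small_fixture(L = 10)
  pr <- hmm_params(f = 0.12, a = 2)
  ll <- forward_loglik(fx$g, fx$map, fx$fr, pr)
  em <- oracle_emissions(fx$g, fx$map$freq_a1)
  dist <- c(0, diff(fx$map$pos_m))
  oracle <- oracle_hmm_exhaustive(em$hbd, em$non, dist, 0.12, 2)
  expect_equal(ll, oracle$loglik, tolerance = 1e-10)

  # two chromosomes: likelihoods multiply (logs add)
  fx2 <- make_small_fixture(L = 12, n_chrom = 2, seed = 29)
  ll2 <- forward_loglik(fx2$g, fx2$map, fx2$fr, pr)
  em2 <- oracle_emissions(fx2$g, fx2$map$freq_a1)
  ora <- 0
  for (ch in 1:2) {
    i <- fx2$map$chrom == ch
    ora <- ora + oracle_hmm_exhaustive(em2$hbd[i], em2$non[i],
                                       c(0, diff(fx2$map$pos_m[i])),
                                       0.12, 2)$loglik
  }
  expect_equal(ll2, ora, tolerance = 1e-10)
})

test_that("single marker and the a -> Inf limit reduce to the single-point likelihood", {
  fr1 <- provided_frequencies(0.3)
  pr <- hmm_params(f = 0.2, a = 1)
  ll <- forward_loglik(2L, data.frame(marker_id = "m", chrom = 1L, pos_m = 0),
                       fr1, pr)
  expect_equal(ll, log(0.2 * 0.3 + 0.8 * 0.09), tolerance = 1e-12)

  fx <- make_small_fixture(L = 200, n_chrom = 4, seed = 31)
  f <- 0.07
  ll_hmm <- forward_loglik(fx$g, fx$map, fx$fr, hmm_params(f = f, a = 1e6))
  spt <- festim_spt(fx$g, fx$fr)
  em <- oracle_emissions(fx$g, fx$map$freq_a1)
  ll_spt_at_f <- sum(log(f * em$hbd + (1 - f) * em$non))
  expect_equal(ll_hmm, ll_spt_at_f, tolerance = 1e-6)
})

test_that("likelihood is invariant to chromosome order and within-chromosome reversal", {
  fx <- make_small_fixture(L = 60, n_chrom = 3, seed = 37)
  pr <- hmm_params(f = 0.1, a = 3)
  ll <- forward_loglik(fx$g, fx$map, fx$fr, pr)

  # swap chromosome blocks
  o <- order(match(fx$map$chrom, c(2, 3, 1)), fx$map$pos_m)
  map_sw <- fx$map[o, ]
  map_sw$chrom <- rep(1:3, table(fx$map$chrom)[c(2, 3, 1)])
  expect_equal(forward_loglik(fx$g[o], map_sw, provided_frequencies(fx$map$freq_a1[o]), pr),
               ll, tolerance = 1e-10)

  # reverse marker order within each chromosome (mirror the positions)
  o_rev <- unlist(lapply(split(seq_len(nrow(fx$map)), fx$map$chrom), rev),
                  use.names = FALSE)
  map_rev <- fx$map[o_rev, ]
  map_rev$pos_m <- stats::ave(map_rev$pos_m, map_rev$chrom,
                              FUN = function(x) max(x) - x)
  expect_equal(forward_loglik(fx$g[o_rev], map_rev,
                              provided_frequencies(fx$map$freq_a1[o_rev]), pr),
               ll, tolerance = 1e-10)
})

test_that("HBD posterior matches the exhaustive oracle and respects hard zeros", {
  fx <- make_small_fixture(L = 10, seed = 41)
  pr <- hmm_params(f = 0.15, a = 1.5)
  post <- hbd_posterior(fx$g, fx$map, fx$fr, pr)
  em <- oracle_emissions(fx$g, fx$map$freq_a1)
  oracle <- oracle_hmm_exhaustive(em$hbd, em$non, c(0, diff(fx$map$pos_m)),
                                  0.15, 1.5)
  expect_equal(post$p_hbd, oracle$posterior, tolerance = 1e-10)
  expect_true(all(post$p_hbd >= 0 & post$p_hbd <= 1))
  # f = 0 -> posterior identically 0
  post0 <- hbd_posterior(fx$g, fx$map, fx$fr, hmm_params(f = 0, a = 1))
  expect_true(all(post0$p_hbd == 0))
  # heterozygous marker with epsilon = 0 is an impossible HBD emission
  het <- which(fx$g == 1L)
  expect_true(all(post$p_hbd[het] == 0))
})

test_that("MLE finds boundary zero on outbred data and a known long stretch", {
  set.seed(43)
  map <- make_sim_map(n_markers = 2000, spacing_morgans = 0.0008,
                      n_chromosomes = 1, seed = 47,
                      freq_sampler = function(n) runif(n, 0.3, 0.7))
  fr <- provided_frequencies(map$freq_a1)
  g_out <- sim_inbred_genotypes(map$freq_a1, 0)
  fit0 <- festim_mle(g_out, map, fr)
  expect_lt(fit0$f, 0.01)

  # one 200-marker homozygous stretch in the middle: f ~ 0.1, and the MLE
  # must beat a coarse (f, a) grid search
  g <- sim_inbred_genotypes(map$freq_a1, 0)
  idx <- 901:1100
  g[idx] <- 2L * rbinom(200, 1, map$freq_a1[idx])
  fit <- festim_mle(g, map, fr)
  expect_lt(abs(fit$f - 0.1), 0.03)
  em <- oracle_emissions(g, map$freq_a1)
  dist <- c(0, diff(map$pos_m))
  newchrom <- c(TRUE, rep(FALSE, 1999))
  grid_ll <- -Inf
  for (fg in seq(0.02, 0.3, by = 0.01)) for (ag in c(0.5, 1, 2, 4, 8)) {
    v <- hbdkit:::hmm_forward_loglik_cpp(em$hbd, em$non, dist, newchrom, fg, ag)
    if (v > grid_ll) { grid_ll <- v; grid_f <- fg }
  }
  expect_gte(fit$loglik, grid_ll - 1e-6)
  expect_lt(abs(fit$f - grid_f), 0.02)
})

test_that("mean HBD posterior at the MLE approximates f-hat (stationarity)", {
  map <- make_sim_map(n_markers = 1500, n_chromosomes = 6, seed = 53)
  fr <- provided_frequencies(map$freq_a1)
  set.seed(54)
  sim <- sim_hmm_individual(map, f = 0.0625, a = 6.4)
  fit <- festim_mle(sim$genotypes, map, fr)
  post <- hbd_posterior(sim$genotypes, map, fr,
                        hmm_params(f = fit$f, a = fit$a))
  expect_lt(abs(mean(post$p_hbd) - fit$f), 0.02)
})
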