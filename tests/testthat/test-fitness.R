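test_that("enrichment ratios follow the log2 frequency fold-change", {
  expect_equal(enrichment_ratio(100, 100, 1e6, 1e6), 0)
  expect_equal(enrichment_ratio(100, 400, 1e6, 2e6), 1)
  expect_equal(enrichment_ratio(200, 25, 1e6, 1e6), -3)
  # invariance to proportional scaling of both totals
  expect_equal(enrichment_ratio(30, 70, 1e5, 2e5),
               enrichment_ratio(30, 70, 5e5, 1e6))
  expect_true(is.na(enrichment_ratio(0, 10, 1e6, 1e6)))
  # zero post count takes the configurable floor
  expect_equal(enrichment_ratio(10, 0, 1e6, 1e6, zero_post_floor = 0.5),
               log2(0.05))
})

test_that("fitness metric normalizes against wild type and doublings", {
  expect_equal(fitness_metric(3.2, 3.2, 8), 0)
  expect_equal(fitness_metric(-4.79, 3.21, 8), -1)
  # an epsilon gap of 1.2 at g_p = 8 sits exactly at the beneficial threshold
  expect_equal(fitness_metric(3.21 + 1.2, 3.21, 8), 0.15)
  expect_error(fitness_metric(1, 0, 0), "g_p")
})

test_that("lower-bound fitness reproduces the printed detection limits", {
  lb <- lower_bound_fitness(49, 1.86, 10, 8, 3.21)
  expect_equal(lb$zeta_lb, -0.80, tolerance = 5e-4)
  expect_equal(lower_bound_fitness(63, 2.97, 10, 8, 0)$epsilon_lb,
               log2(10 / 187.11), tolerance = 1e-6)
  # floor equal to the normalized half-median: eps_LB = 0
  lb0 <- lower_bound_fitness(5, 2, 10, 8, 3.2)
  expect_equal(lb0$epsilon_lb, 0)
  expect_equal(lb0$zeta_lb, -3.2 / 8)
  expect_error(lower_bound_fitness(49, 1.86, 0, 8, 3.2), "floor_reads")
})

test_that("lower bound moves down as coverage or expansion grows", {
  z <- function(hm, ratio) lower_bound_fitness(hm, ratio, 10, 8, 3)$zeta_lb
  expect_lt(z(100, 2), z(50, 2))
  expect_lt(z(50, 4), z(50, 2))
})

test_that("a variant at the floor with half-median pre reads sits exactly at zeta_LB", {
  cnt <- toy_count_table(pre = c(WT = 5000, A = 100, B = 200, C = 100),
                         post = c(WT = 21000, A = 10, B = 440, C = 150))
  # pre half-median over observed members: 0.5 * median(5000,100,200,100)
  fit <- compute_fitness(cnt, g_p = 8, floor_reads = 10)
  expect_equal(attr(fit, "pre_half_median"), 75)
  # rebuild the member at exactly half-median pre reads and floor post reads
  cnt2 <- toy_count_table(pre = c(WT = 5000, A = 75, B = 200, C = 100),
                          post = c(WT = 21000, A = 10, B = 440, C = 150))
  fit2 <- compute_fitness(cnt2, g_p = 8, floor_reads = 10)
  expect_equal(attr(fit2, "pre_half_median"), 75)
  expect_equal(fit2$zeta[fit2$variant == "S1A"], attr(fit2, "zeta_lb"),
               tolerance = 1e-12)
})

test_that("wild-type fitness is exactly zero and scaling leaves zeta unchanged", {
  cnt <- toy_count_table()
  fit <- compute_fitness(cnt, g_p = 8)
  expect_identical(fit$zeta[fit$variant == "WT"], 0)
  cnt10 <- cnt
  cnt10$pre_count <- cnt10$pre_count * 10L
  cnt10$post_count <- cnt10$post_count * 7L
  fit10 <- compute_fitness(cnt10, g_p = 8)
  expect_equal(fit$zeta, fit10$zeta, tolerance = 1e-12)
})

test_that("replicates combine by read summation and reduce error", {
  one <- toy_count_table()
  expect_equal(combine_replicates(list(one))$pre_count, one$pre_count)
  two <- one
  two$pre_count <- c(7000, 300, 100, 150)
  two$post_count <- c(15000, 100, 75, 50)
  two$replicate <- 2L
  comb <- combine_replicates(rbind(one, two))
  expect_equal(comb$pre_count, one$pre_count + two$pre_count)
  expect_equal(comb$post_count, one$post_count + two$post_count)
  bad <- two
  bad$variant[2] <- "S9W"
  expect_error(combine_replicates(list(one, bad)), "offending")

  st <- sim_study(L = 30, depth = 2e5, replicates = 2, seed_lib = 40,
                  seed_dfe = 41, seed_sel = 42)
  ez <- expected_zeta(st$truth$r, st$g_wt, st$g_p)
  mse <- function(cnt) {
    fit <- compute_fitness(cnt, g_p = st$g_p)
    ok <- !fit$below_lower_bound & fit$variant != "WT"
    e <- fit$zeta[ok] - ez[match(fit$variant[ok], st$truth$variant)]
    mean(e[is.finite(e)]^2)
  }
  reps <- split(st$counts, st$counts$replicate)
  expect_lt(mse(combine_replicates(st$counts)),
            min(mse(reps[[1]]), mse(reps[[2]])))
})

test_that("replicate correlation behaves like a correlation and improves above bounds", {
  f1 <- mock_fit(paste0("S", 1:10, "A"), seq(-1, 1, length.out = 10), "X")
  f2 <- f1
  expect_equal(replicate_correlation(f1, f2, exclude_below = FALSE)$r, 1)
  f3 <- f1
  f3$zeta <- -f1$zeta
  expect_equal(replicate_correlation(f1, f3, exclude_below = FALSE)$r, -1)
  expect_error(replicate_correlation(f1[1:2, ], f2[1:2, ]), "insufficient")

  # regime where the above-bound signal is well resolved: there, the noisy
  # censored measurements below the detection limit only dilute agreement
  st <- sim_study(L = 40, depth = 2e6, replicates = 2, seed_lib = 50,
                  seed_dfe = 51, seed_sel = 52,
                  dfe = list(lethal_fraction = 0.35, neutral_sd = 0.12,
                             beneficial_fraction = 0.05))
  reps <- split(st$counts, st$counts$replicate)
  fa <- compute_fitness(reps[[1]], g_p = 8)
  fb <- compute_fitness(reps[[2]], g_p = 8)
  with_all <- replicate_correlation(fa, fb, exclude_below = FALSE)
  above <- replicate_correlation(fa, fb, exclude_below = TRUE)
  expect_gt(above$r, with_all$r)
  expect_lt(above$n, with_all$n)
  expect_lt(above$p, 0.001)
})

test_that("synonymous records average by read-count weights", {
  one <- synonymous_weighted_mean(0.4, 7)
  expect_equal(one$mean, 0.4)
  expect_equal(one$sd, 0)
  expect_equal(synonymous_weighted_mean(c(0.1, 0.3), c(1, 3))$mean, 0.25)
  expect_equal(synonymous_weighted_mean(c(0.1, 0.5, 0.3), c(2, 2, 2))$mean,
               mean(c(0.1, 0.5, 0.3)))
  expect_error(synonymous_weighted_mean(c(0.1, 0.2), c(0, 0)), "weights")
})

test_that("codon-level records aggregate to protein level", {
  spec <- library_spec(4, codons_per_variant = 2, sequencing_depth_pre = 1e5,
                       sequencing_depth_post = 1e5)
  lib <- make_library(spec, seed = 60)
  truth <- sample_true_dfe(lib, true_dfe_spec(seed = 61))
  cnt <- simulate_selection(lib, truth, selection_scenario(), seed = 62)
  fit <- compute_fitness(cnt, g_p = 8)
  agg <- aggregate_synonymous(fit)
  expect_equal(sort(unique(fit$variant)), sort(agg$variant))
  expect_true(all(agg$n_codons[agg$variant != "WT"] == 2))
  v <- agg$variant[agg$variant != "WT"][1]
  rows <- fit[fit$variant == v, ]
  w <- rows$pre_count + rows$post_count
  expect_equal(agg$zeta[agg$variant == v], sum(w * rows$zeta) / sum(w))
})

test_that("theoretical error tracks Poisson counting noise", {
  expect_equal(theoretical_error(100, 100, 1e9, 1e9, 8),
               sqrt(0.02) / log(2) / 8, tolerance = 1e-6)
  # decreases monotonically with every count
  base <- theoretical_error(100, 100, 1000, 1000, 8)
  expect_lt(theoretical_error(200, 100, 1000, 1000, 8), base)
  expect_lt(theoretical_error(100, 200, 1000, 1000, 8), base)
  expect_lt(theoretical_error(100, 100, 2000, 1000, 8), base)
  expect_identical(theoretical_error(0, 10, 10, 10, 8), Inf)

  # coverage: ~95% of truly neutral variants within 2 theoretical s.d. of 0
  lib <- make_library(library_spec(10, sequencing_depth_pre = 1e6,
                                   sequencing_depth_post = 1e6), seed = 63)
  truth <- sample_true_dfe(lib, true_dfe_spec(lethal_fraction = 0,
                                              neutral_sd = 0,
                                              beneficial_fraction = 0,
                                              cterm_window = 10, seed = 64))
  cnt <- simulate_selection(lib, truth, selection_scenario(), seed = 65)
  fit <- compute_fitness(cnt, g_p = 8)
  v <- fit$variant != "WT"
  cover <- mean(abs(fit$zeta[v]) <= 2 * fit$theoretical_sd[v])
  expect_gt(cover, 0.90)
  expect_lte(cover, 1)
})

test_that("the beneficial call is a strict threshold", {
  expect_true(classify_beneficial(0.16))
  expect_false(classify_beneficial(0.15))
  expect_true(classify_beneficial(0.33))  # an ACT-beneficial exemplar
  expect_equal(classify_beneficial(c(-1, 0.2), threshold = 0.1),
               c(FALSE, TRUE))
})

test_that("fitness recovery is quantitative above the detection limit", {
  st <- sim_study(L = 50, depth = 1e6, seed_lib = 70, seed_dfe = 71,
                  seed_sel = 72)
  fit <- compute_fitness(st$counts, g_p = 8)
  ez <- expected_zeta(st$truth$r, st$g_wt, st$g_p)
  m <- match(fit$variant, st$truth$variant)
  ok <- !fit$below_lower_bound & fit$variant != "WT" & is.finite(ez[m])
  slope <- coef(lm(fit$zeta[ok] ~ ez[m][ok]))[[2]]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
  expect_gt(cor(fit$zeta[ok], ez[m][ok]), 0.95)
})
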