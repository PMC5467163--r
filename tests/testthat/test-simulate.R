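test_that("degenerate DFE specs produce the trivial growth-rate fields", {
  lib <- make_library(library_spec(20), seed = 1)
  all_lethal <- sample_true_dfe(lib, true_dfe_spec(lethal_fraction = 1,
                                                   beneficial_fraction = 0,
                                                   seed = 1))
  expect_true(all(all_lethal$r[all_lethal$type != "wt"] == 0))
  all_neutral <- sample_true_dfe(lib, true_dfe_spec(lethal_fraction = 0,
                                                    neutral_sd = 0,
                                                    beneficial_fraction = 0,
                                                    cterm_window = 20,
                                                    seed = 1))
  expect_true(all(all_neutral$r == 1))
  expect_equal(all_neutral$r[all_neutral$type == "wt"], 1)
})

test_that("class fractions summing above one are rejected", {
  expect_error(true_dfe_spec(lethal_fraction = 0.7, beneficial_fraction = 0.4,
                             seed = 1), "fractions")
})

test_that("beneficial growth-rate advantages are exponential with the stated mean", {
  lib <- make_library(library_spec(500), seed = 3)  # 10,000 variants
  truth <- sample_true_dfe(lib, true_dfe_spec(beneficial_fraction = 0.05,
                                              beneficial_rate = 7, seed = 4))
  adv <- truth$r[truth$class == "beneficial"] - 1
  se <- (1 / 7) / sqrt(length(adv))
  expect_gt(length(adv), 300)
  expect_lt(abs(mean(adv) - 1 / 7), 3 * se)
})

test_that("nonsense variants are lethal except in the C-terminal window", {
  lib <- make_library(library_spec(100), seed = 5)
  truth <- sample_true_dfe(lib, true_dfe_spec(cterm_window = 19, seed = 6))
  ns <- truth[truth$type == "nonsense", ]
  expect_true(all(ns$r[ns$position <= 100 - 19] == 0))
  expect_true(any(ns$r[ns$position > 100 - 19] > 0))
})

test_that("sampling is reproducible under a fixed seed", {
  lib <- make_library(library_spec(10), seed = 7)
  t1 <- sample_true_dfe(lib, true_dfe_spec(seed = 8))
  t2 <- sample_true_dfe(lib, true_dfe_spec(seed = 8))
  expect_identical(t1$r, t2$r)
  sc <- selection_scenario()
  c1 <- simulate_selection(lib, t1, sc, seed = 9)
  c2 <- simulate_selection(lib, t1, sc, seed = 9)
  expect_identical(c1$post_count, c2$post_count)
})

test_that("neutral competition leaves expected frequencies unchanged", {
  lib <- make_library(library_spec(5), seed = 10)
  truth <- sample_true_dfe(lib, true_dfe_spec(lethal_fraction = 0,
                                              neutral_sd = 0,
                                              beneficial_fraction = 0,
                                              cterm_window = 5, seed = 1))
  cnt <- simulate_selection(lib, truth, selection_scenario(), seed = 11,
                            depth_pre = 1e5, depth_post = 1e5)
  # deterministic post-selection frequencies equal the pre frequencies
  ab <- lib$abundance
  wt <- lib$type == "wt"
  ab[wt] <- sum(ab[!wt]) * 0.3 / 0.7
  expect_equal(attr(cnt, "true_post_freq"), ab / sum(ab), tolerance = 1e-10)
  expect_equal(attr(cnt, "g_wt"), 8, tolerance = 1e-8)
})

test_that("two-lineage knockout competition matches the closed form", {
  # wild type vs non-grower at 50/50: knockout final frequency 2^(-g_p - 1)
  # (up to the -1 correction from the knockout's constant biomass)
  g_p <- 4.145
  lib <- make_library(library_spec(1, include_stop = FALSE), seed = 12)
  lib <- lib[1:2, ]  # WT + one variant
  lib$abundance <- c(0.5, 0.5)
  truth <- sample_true_dfe(lib, true_dfe_spec(seed = 1))
  truth <- truth[truth$variant %in% lib$variant, ]
  truth$r[truth$type != "wt"] <- 0
  sc <- selection_scenario(g_p = g_p, passage_doublings = g_p,
                           wt_fraction_initial = 0.5)
  cnt <- simulate_selection(lib, truth, sc, seed = 13,
                            depth_pre = 1e6, depth_post = 1e6)
  ko_freq <- attr(cnt, "true_post_freq")[cnt$type != "wt"]
  expect_equal(unname(ko_freq), 0.5 / 2^g_p, tolerance = 1e-6)
  # realized wild-type doublings solve 0.5*2^tau + 0.5 = 2^g_p
  expect_equal(attr(cnt, "g_wt"), log2(2^(g_p + 1) - 1), tolerance = 1e-8)
  # a non-growing lineage never increases in absolute number (no cheating)
  expect_lte(ko_freq * 2^g_p, 0.5 + 1e-12)
})

test_that("cheat_leak rescues part of a non-grower's deficit", {
  lib <- make_library(library_spec(1, include_stop = FALSE), seed = 12)
  lib <- lib[1:2, ]
  lib$abundance <- c(0.5, 0.5)
  truth <- sample_true_dfe(lib, true_dfe_spec(seed = 1))
  truth$r[truth$type != "wt"] <- 0
  freq_at <- function(leak) {
    sc <- selection_scenario(g_p = 4, passage_doublings = 4,
                             wt_fraction_initial = 0.5, cheat_leak = leak)
    cnt <- simulate_selection(lib, truth, sc, seed = 13,
                              depth_pre = 1e5, depth_post = 1e5)
    unname(attr(cnt, "true_post_freq")[cnt$type != "wt"])
  }
  expect_gt(freq_at(0.5), freq_at(0))
  expect_equal(freq_at(1), 0.5)  # full rescue: neutral competition
})

test_that("expected fitness metric follows (r - 1) * g_wt / g_p", {
  expect_equal(expected_zeta(1, 10, 8), 0)
  expect_equal(expected_zeta(1.1, 12, 8), 0.15)  # ~10% growth advantage
  expect_equal(expected_zeta(1.2, 8, 8), 0.2)
  expect_identical(expected_zeta(0, 8, 8), -Inf)
  expect_error(expected_zeta(1, 0, 8), "> 0")
})

test_that("simulated read frequencies conserve mass", {
  st <- sim_study(L = 10, depth = 1e5)
  expect_equal(sum(st$counts$pre_count), 1e5)
  expect_equal(sum(st$counts$post_count), 1e5)
  expect_equal(sum(attr(st$counts, "true_post_freq")), 1, tolerance = 1e-12)
})

test_that("recovered fitness is centered, monotone in r and depth-invariant", {
  # one position, 19 variants with pinned growth rates on a grid
  lib <- make_library(library_spec(1, include_stop = FALSE), seed = 20)
  truth <- sample_true_dfe(lib, true_dfe_spec(seed = 21))
  grid <- rep(c(0.8, 0.9, 1.0, 1.1, 1.2), length.out = 19)
  truth$r[truth$type != "wt"] <- grid
  sc <- selection_scenario()
  recover <- function(depth, seed) {
    cnt <- simulate_selection(lib, truth, sc, seed = seed,
                              depth_pre = depth, depth_post = depth)
    fit <- compute_fitness(cnt, g_p = 8)
    fit$zeta[match(truth$variant[truth$type != "wt"], fit$variant)]
  }
  z1 <- recover(1e6, 22)
  means <- tapply(z1, grid, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) > 0))
  # doubling depth leaves the recovered values in place (variance only)
  z2 <- recover(2e6, 23)
  expect_equal(mean(z1 - z2), 0, tolerance = 0.02)

  # neutral null: with all r = 1 the recovered metrics center at 0
  truth$r[truth$type != "wt"] <- 1
  zn <- unlist(lapply(24:26, function(s) recover(1e6, s)))
  expect_lt(abs(mean(zn)), 3 * sd(zn) / sqrt(length(zn)))
})

test_that("pre-selection counts do not bias recovered fitness", {
  st <- sim_study(L = 50, depth = 1e6, seed_lib = 30, seed_dfe = 31,
                  seed_sel = 32)
  fit <- compute_fitness(combine_replicates(st$counts), g_p = 8)
  ok <- !fit$below_lower_bound & fit$variant != "WT"
  r <- cor(fit$pre_count[ok], fit$zeta[ok])
  expect_lt(abs(r), 0.1)
})

test_that("zero sequencing depth is rejected", {
  st <- sim_study(L = 5)
  expect_error(simulate_selection(st$lib, st$truth, selection_scenario(),
                                  seed = 1, depth_pre = 0, depth_post = 100),
               "depth")
})
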