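dn <- function(r, c) list(paste0("s", seq_len(r)), paste0("t", seq_len(c)))

test_that("sampling respects Bernoulli boundaries and the mask", {
  withr::local_seed(1)
  P1 <- matrix(1, 5, 5, dimnames = dn(5, 5))
  expect_true(all(sample_am(P1) == 1))
  P0 <- matrix(0, 5, 5, dimnames = dn(5, 5))
  expect_true(all(sample_am(P0) == 0))
  # a zeroed (masked) cell never produces a 1 across many draws
  P <- matrix(0.5, 4, 4, dimnames = dn(4, 4))
  P[2, 3] <- 0
  hits <- sum(vapply(1:1000, function(i) sample_am(P)[2, 3], numeric(1)))
  expect_equal(hits, 0)
})

test_that("uniform crossover mixes cells only from its two parents", {
  withr::local_seed(2)
  a <- matrix(rbinom(36, 1, 0.5), 6, 6, dimnames = dn(6, 6))
  expect_equal(uniform_crossover(a, a), a)
  b <- 1 - a  # complementary
  mix <- uniform_crossover(a, b)
  expect_true(all(mix == a | mix == b))
  expect_error(uniform_crossover(a, matrix(0, 2, 2)), "shape")
})

test_that("competition keeps the incumbent on ties", {
  fit <- function(M) sum(M)
  a <- matrix(1, 2, 2); b <- matrix(0, 2, 2)
  expect_equal(compete(a, b, fit), a)
  expect_equal(compete(b, a, fit), a)
  expect_identical(compete(a, a + 0, fit), a + 0)  # tie -> second argument
  # winner's fitness is the max of the two
  withr::local_seed(3)
  for (rep in 1:10) {
    x <- matrix(rbinom(9, 1, 0.5), 3, 3)
    y <- matrix(rbinom(9, 1, 0.5), 3, 3)
    expect_equal(fit(compete(x, y, fit)), max(fit(x), fit(y)))
  }
})

test_that("probability updates step toward the elite and clamp at the bounds", {
  P <- matrix(0.5, 2, 2)
  elite <- matrix(c(1, 0, 0, 1), 2, 2)
  up <- update_pm_toward_elite(P, elite, 0.01)
  expect_equal(up, matrix(c(0.51, 0.49, 0.49, 0.51), 2, 2))
  # clamping at 0 and 1
  expect_equal(update_pm_toward_elite(matrix(0, 1, 1), matrix(0, 1, 1), 0.01),
               matrix(0, 1, 1))
  expect_equal(update_pm_toward_elite(matrix(1, 1, 1), matrix(1, 1, 1), 0.01),
               matrix(1, 1, 1))
  # repeated updates converge to the elite pattern
  for (i in 1:200) P <- update_pm_toward_elite(P, elite, 0.01)
  expect_equal(P, elite)
  # masked cells stay pinned at zero
  mask <- matrix(c(1, 1, 0, 1), 2, 2)
  P2 <- update_pm_toward_elite(matrix(0.5, 2, 2), elite, 0.01, mask)
  expect_equal(P2[1, 2], 0)
})

test_that("negative-anchor decay zeroes the anchor cell and dampens consistent neighbors", {
  fx <- fig2_fixture()
  P <- matrix(0.5, 3, 3, dimnames = list(fx$o1$entities$id,
                                         fx$o2$entities$id))
  sims <- matrix(0.5, 3, 3, dimnames = dimnames(P))
  sims["a1", "b1"] <- 0.1  # negative anchor when selected by the elite
  elite <- matrix(0, 3, 3, dimnames = dimnames(P))
  elite["a1", "b1"] <- 1

  out <- apply_na_decay(P, elite, sims, na_threshold = 0.2, step = 0.01,
                        fx$o1, fx$o2)
  expect_equal(unname(out["a1", "b1"]), 0)
  # oracle: recompute decay targets from the definitions
  expected <- P
  expected["a1", "b1"] <- 0
  nb <- neighbor_correspondences(c("a1", "b1"), fx$o1, fx$o2, radius = 1)
  for (k in seq_len(nrow(nb))) {
    if (!contradicts(c(nb$e1[k], nb$e2[k]),
                     list(e1 = "a1", e2 = "b1"), fx$o1, fx$o2)) {
      expected[nb$e1[k], nb$e2[k]] <- expected[nb$e1[k], nb$e2[k]] - 0.01
    }
  }
  expect_equal(out, expected)
  # the two contradicting cells must not have been decayed
  expect_equal(unname(out["a2", "b3"]), 0.5)
  expect_equal(unname(out["a3", "b2"]), 0.5)

  # nothing below the threshold: no change
  sims2 <- matrix(0.5, 3, 3, dimnames = dimnames(P))
  expect_equal(apply_na_decay(P, elite, sims2, 0.2, 0.01, fx$o1, fx$o2), P)
})

test_that("probability-matrix distance is a symmetric element-wise sum or mean", {
  a <- matrix(0.5, 3, 3)
  expect_equal(pm_distance(a, a), 0)
  b <- a; b[2, 2] <- 0.8
  expect_equal(pm_distance(a, b, "sum"), 0.3)
  expect_equal(pm_distance(a, b, "mean"), 0.3 / 9)
  withr::local_seed(4)
  for (rep in 1:5) {
    x <- matrix(runif(9), 3, 3); y <- matrix(runif(9), 3, 3)
    expect_equal(pm_distance(x, y), pm_distance(y, x))
  }
  expect_error(pm_distance(a, matrix(0, 2, 2)), "shape")
})

test_that("synthesized probability matrices explore away from the existing ones", {
  withr::local_seed(5)
  zeros <- matrix(0, 3, 3)
  expect_equal(synthesize_new_pm(list(zeros, zeros)), zeros)
  ones <- matrix(1, 3, 3)
  expect_equal(synthesize_new_pm(list(ones, ones)), ones)

  # a cell whose maximum over PMs is m < 0.5 lands in [m, 1]
  low <- matrix(0.3, 3, 3)
  draws <- replicate(500, synthesize_new_pm(list(low))[1, 1])
  expect_true(all(draws >= 0.3 & draws <= 1))
  # mirrored: minimum n > 0.5 lands in [0, n]
  high <- matrix(0.8, 3, 3)
  draws <- replicate(500, synthesize_new_pm(list(high))[2, 2])
  expect_true(all(draws >= 0 & draws <= 0.8))
  # straddling 0.5 lands exactly in the middle
  both <- synthesize_new_pm(list(matrix(0.8, 2, 2), matrix(0.2, 2, 2)))
  expect_true(all(both == 0.5))
  # mask keeps forbidden cells at zero
  mask <- matrix(c(1, 0, 1, 1), 2, 2)
  expect_equal(synthesize_new_pm(list(matrix(0.3, 2, 2)), mask)[2, 1], 0)
})

test_that("PM maintenance removes overlapping matrices and grows on stagnation", {
  fx <- identical_toy_pair(5)
  th <- thesaurus()
  sims <- similarity_matrix(fx$o1, fx$o2, t = th)
  cfg <- acea_config(max_gen = 0, pm_num_init = 2, seed = 10, delta = 5)
  state <- withr::with_seed(10, acea_init(fx$o1, fx$o2, sims, cfg))

  # identical PMs with distinct elites: the worse elite's PM is dropped
  state$pms[[2]]$P <- state$pms[[1]]$P
  better <- which.max(vapply(state$pms, `[[`, numeric(1), "elite_fit"))
  kept_fit <- max(vapply(state$pms, `[[`, numeric(1), "elite_fit"))
  state2 <- maintain_pms(state)
  expect_length(state2$pms, 1L)
  expect_equal(state2$pms[[1]]$elite_fit, kept_fit)

  # distant PMs, no stagnation: untouched
  state$pms[[2]]$P <- 1 - state$pms[[1]]$P
  state3 <- maintain_pms(state)
  expect_length(state3$pms, 2L)

  # reaching the stagnation threshold adds exactly one PM and resets the count
  state3$stagnation <- cfg$delta
  state4 <- withr::with_seed(11, maintain_pms(state3))
  expect_length(state4$pms, 3L)
  expect_equal(state4$stagnation, 0L)
})

test_that("a full run recovers the identity alignment of an identical pair", {
  fx <- identical_toy_pair(6)
  res <- acea_run(fx$o1, fx$o2,
                  config = acea_config(max_gen = 400, seed = 3),
                  thesaurus = thesaurus())
  m <- evaluate_against_reference(res$alignment, fx$reference)
  expect_equal(m$f_measure, 1)
  # the global best fitness never decreases along the trace
  expect_true(all(diff(res$trace$best_fitness) >= 0))
  expect_true(all(res$trace$pm_count >= 1))
})

test_that("a zero-generation budget returns the best initial elite", {
  fx <- identical_toy_pair(4)
  res <- acea_run(fx$o1, fx$o2, config = acea_config(max_gen = 0, seed = 9),
                  thesaurus = thesaurus())
  expect_equal(nrow(res$trace), 1L)
  expect_equal(res$trace$generation, 0L)
  expect_gte(res$fitness, 0)
})

test_that("runs are deterministic given the seed", {
  fx <- generate_fixture_pair(fixture_spec(n_concepts = 8, seed = 2))
  th <- fixture_thesaurus()
  r1 <- acea_run(fx$o1, fx$o2, config = acea_config(max_gen = 60, seed = 5),
                 thesaurus = th)
  r2 <- acea_run(fx$o1, fx$o2, config = acea_config(max_gen = 60, seed = 5),
                 thesaurus = th)
  expect_identical(as.data.frame(r1$alignment), as.data.frame(r2$alignment))
  expect_identical(r1$trace, r2$trace)
})

test_that("empty ontologies yield an empty alignment with a warning", {
  o0 <- new_ontology(NULL, name = "empty")
  o1 <- identical_toy_pair(3)$o1
  expect_warning(res <- acea_run(o0, o1, config = acea_config(max_gen = 5)),
                 "empty")
  expect_equal(nrow(res$alignment), 0L)
  expect_equal(res$fitness, 0)
})

test_that("the compact-EA reduction disables reasoning and adaptivity", {
  cfg <- cea_config(max_gen = 10, seed = 1)
  expect_equal(cfg$pm_num_init, 1L)
  expect_false(cfg$use_mask)
  expect_false(cfg$use_na_decay)
  expect_false(cfg$adaptive)
  fx <- identical_toy_pair(4)
  res <- acea_run(fx$o1, fx$o2, config = cfg, thesaurus = thesaurus())
  expect_true(all(res$trace$pm_count == 1))
})

test_that("configuration arguments are validated", {
  expect_error(acea_config(step = 0), "step")
  expect_error(acea_config(step = 1), "step")
  expect_error(acea_config(delta = 0), "delta")
  expect_error(acea_config(pm_num_init = 0), "pm_num_init")
  expect_error(acea_config(max_gen = -1), "max_gen")
})
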