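# Kinetic Monte-Carlo engine: transition sets, the Gillespie step, initial
# states, trajectories and ensemble reproducibility.

test_that("transition sets enumerate single-bit flips with the right rates", {
  toy <- toy_model(escape = 10)
  # [ABC] = [001]: A can activate (rate 1), C can inactivate (escape rate 10)
  ts <- transitions(toy$model, c(A = 0, B = 0, C = 1), toy$params)
  expect_equal(ts$node, c(1L, 3L))
  expect_equal(ts$rate, c(1, 10))
  expect_equal(ts$target, c(5, 0))   # [101] and [000]
  expect_equal(ts$total_rate, 11)
  # the fixed point [000] is absorbing
  ts0 <- transitions(toy$model, c(A = 0, B = 0, C = 0), toy$params)
  expect_length(ts0$rate, 0)
  expect_equal(ts0$total_rate, 0)
  # 1-node model with rate_up = 2 when off
  m1 <- one_node_model(up = "2.0")
  ts1 <- transitions(m1, 0)
  expect_equal(ts1$rate, 2)
  expect_equal(ts1$target, 1)
  # each target differs from the source in exactly one bit
  for (s in 0:7) {
    ts <- transitions(toy$model, s, toy$params)
    for (tg in ts$target) {
      expect_equal(sum(state_bits(s, 3) != state_bits(tg, 3)), 1)
    }
  }
})

test_that("the Gillespie step follows the closed-form time and cumulative-rate rules", {
  toy <- toy_model(escape = 10)
  ts <- transitions(toy$model, c(A = 0, B = 0, C = 1), toy$params)  # rates (1, 10)
  # holding time: u = exp(-rho_tot) gives dt = 1 exactly
  st <- gillespie_step(ts, u = exp(-11), u2 = 0.5)
  expect_equal(st$dt, 1)
  # u2 * rho_tot = 5.5 lies in (1, 11]: the second candidate is selected
  expect_equal(st$state, 0)
  # boundary rule: u2 * rho_tot equal to the first cumulative sum selects the first
  st1 <- gillespie_step(ts, u = 0.5, u2 = 1 / 11)
  expect_equal(st1$state, 5)
  st2 <- gillespie_step(ts, u = 0.5, u2 = 1 / 11 + 1e-12)
  expect_equal(st2$state, 0)
  # errors
  ts0 <- transitions(toy$model, 0, toy$params)
  expect_error(gillespie_step(ts0, 0.5, 0.5), "absorbing")
  expect_error(gillespie_step(ts, 0, 0.5), "\\(0, 1\\]")
})

test_that("initial states fix input nodes and draw the rest uniformly", {
  toy <- toy_model()
  # all nodes fixed: deterministic
  fixed <- setNames(c(1, 0, 1), c("A", "B", "C"))
  expect_true(all(replicate(10, sample_initial_state(toy$model, fixed)) == 5))
  # no input nodes: all 8 states equiprobable (chi-square)
  set.seed(1)
  draws <- replicate(40000, sample_initial_state(toy$model))
  tab <- tabulate(draws + 1, nbins = 8)
  expect_gt(chisq.test(tab)$p.value, 1e-4)
  # one input fixed at 1, two free: 4 equiprobable states, fixed bit always set
  mixed <- setNames(c(1, NA, NA), c("A", "B", "C"))
  d2 <- replicate(20000, sample_initial_state(toy$model, mixed))
  expect_true(all(state_bits(d2, 3)[, 1] == 1))
  tab2 <- table(d2)
  expect_equal(sort(as.numeric(names(tab2))), c(1, 3, 5, 7))
  expect_gt(chisq.test(as.numeric(tab2))$p.value, 1e-4)
})

test_that("jump times from a single-transition state are exponential", {
  # off -> on at rate 2, on absorbing
  m <- one_node_model(up = "2.0", down = "0.0")
  cfg <- quick_config(m, timetick = 1, max_time = 50, sample_count = 4000,
                      statdist_traj_count = 0, istate = c(X = 0))
  ens <- run_ensemble(m, cfg)
  jumps <- vapply(ens, function(tr) if (length(tr$times) > 1) tr$times[2] else NA_real_, 0)
  expect_lt(mean(is.na(jumps)), 0.01)
  ks <- suppressWarnings(stats::ks.test(jumps[!is.na(jumps)], "pexp", rate = 2))
  expect_gt(ks$p.value, 1e-4)
  # empirical mean holding time ~ 1/rho_tot
  expect_equal(mean(jumps, na.rm = TRUE), 0.5, tolerance = 0.1)
})

test_that("trajectories respect the horizon, bit-flip and absorbing contracts", {
  # a model in which every state is absorbing holds its initial state
  m0 <- one_node_model(up = "0.0", down = "0.0")
  cfg0 <- quick_config(m0, timetick = 1, max_time = 5, sample_count = 1,
                       statdist_traj_count = 0)
  tr0 <- simulate_trajectory(m0, cfg0, seed = 1)
  expect_equal(tr0$times, 0)
  expect_equal(tr0$horizon, 5)
  # property over random models: strictly increasing times within the horizon,
  # consecutive states differing in exactly one bit
  for (sd in 1:3) {
    fx <- make_fixture("random", n = 5, seed = sd)
    m <- parse_bnd(fx$bnd)
    cfg <- quick_config(m, timetick = 0.25, max_time = 2, sample_count = 40,
                        statdist_traj_count = 0, seed = sd)
    for (tr in run_ensemble(m, cfg)) {
      expect_true(all(diff(tr$times) > 0))
      expect_true(all(tr$times <= tr$horizon))
      if (length(tr$states) > 1) {
        flips <- vapply(seq_len(length(tr$states) - 1), function(k) {
          sum(state_bits(tr$states[k], 5) != state_bits(tr$states[k + 1], 5))
        }, 0L)
        expect_true(all(flips == 1L))
      }
    }
  }
})

test_that("ensembles are reproducible from the seed and invariant to parallel_degree", {
  toy <- toy_model()
  m <- toy$model
  base <- quick_config(m, timetick = 0.1, max_time = 2, sample_count = 30,
                       statdist_traj_count = 0, seed = 42, parameters = toy$params)
  e1 <- run_ensemble(m, base)
  e2 <- run_ensemble(m, base)
  expect_identical(lapply(e1, `[[`, "states"), lapply(e2, `[[`, "states"))
  expect_identical(lapply(e1, `[[`, "times"), lapply(e2, `[[`, "times"))
  par4 <- base
  par4$parallel_degree <- 4L
  e3 <- run_ensemble(m, par4)
  expect_identical(lapply(e1, `[[`, "times"), lapply(e3, `[[`, "times"))
  other <- base
  other$seed <- 43L
  e4 <- run_ensemble(m, other)
  expect_false(identical(lapply(e1, `[[`, "times"), lapply(e4, `[[`, "times")))
  # sample_count = 1 gives a singleton ensemble
  expect_length(run_ensemble(m, base, sample_count = 1), 1L)
})

test_that("with equal rates the embedded jump chain picks targets uniformly (1/gamma)", {
  fx <- make_fixture("random", n = 4, seed = 5, rates = "unit")
  m <- parse_bnd(fx$bnd)
  # find a state with at least 2 outgoing transitions
  st <- NULL
  for (s in 0:15) {
    ts <- transitions(m, s)
    if (length(ts$rate) >= 2) { st <- s; break }
  }
  expect_false(is.null(st))
  ts <- transitions(m, st)
  gamma <- length(ts$rate)
  set.seed(7)
  picks <- replicate(3000, gillespie_step(ts, runif(1), runif(1))$state)
  tab <- table(factor(picks, levels = ts$target))
  expect_gt(chisq.test(as.numeric(tab))$p.value, 1e-4)
  expect_equal(max(abs(as.numeric(tab) / 3000 - 1 / gamma)), 0, tolerance = 0.05)
})

test_that("simulate() on a model is a thin wrapper over the ensemble engine", {
  toy <- toy_model()
  cfg <- quick_config(toy$model, timetick = 0.1, max_time = 1, sample_count = 5,
                      statdist_traj_count = 0, seed = 3, parameters = toy$params)
  tr <- simulate(toy$model, nsim = 5, config = cfg)
  expect_length(tr, 5L)
  expect_s3_class(tr[[1]], "bkmc_trajectory")
})
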