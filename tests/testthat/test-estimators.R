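# Windowed estimators: occupancy arithmetic, entropies, Hamming distances,
# marginalization, and their error conventions.

test_that("entropy follows the plug-in formula with 0 log 0 = 0", {
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("window occupancy fractions follow the trajectory exactly", {
  toy <- toy_model()
  # constant in [101] over one window of width 1
  ws <- window_probabilities(list(mk_traj(0, 5, 1)), 1, toy$model, toy$params)
  expect_equal(ws$prob[1, ], 1)
  expect_equal(ws$labels, "A -- C")
  # [101] for dt/2, then [001]: occupancies 0.5 / 0.5
  ws2 <- window_probabilities(list(mk_traj(c(0, 0.5), c(5, 4), 1)), 1,
                              toy$model, toy$params)
  expect_equal(as.numeric(ws2$prob[1, order(ws2$states)]), c(0.5, 0.5))
  # multi-window: jump at t = 1.25 with dt = 0.5 splits the third window 1:1
  ws3 <- window_probabilities(list(mk_traj(c(0, 1.25), c(5, 4), 2)), 0.5,
                              toy$model, toy$params)
  expect_equal(ws3$prob[3, match(c(4, 5), ws3$states)], c(0.5, 0.5))
  expect_equal(ws3$prob[4, match(4, ws3$states)], 1)
})

test_that("per-window distributions sum to one and errors need >= 2 trajectories", {
  toy <- toy_model()
  cfg <- quick_config(toy$model, timetick = 0.1, max_time = 2, sample_count = 40,
                      statdist_traj_count = 0, seed = 2, parameters = toy$params)
  ens <- run_ensemble(toy$model, cfg)
  ws <- window_probabilities(ens, 0.1, toy$model, toy$params)
  expect_true(all(abs(rowSums(ws$prob) - 1) < 1e-9))
  expect_true(all(ws$prob >= 0 & ws$prob <= 1))
  expect_true(all(is.finite(ws$prob_err)))
  one <- window_probabilities(ens[1], 0.1, toy$model, toy$params)
  expect_true(all(is.na(one$prob_err)))
  expect_error(window_probabilities(list(), 0.1, toy$model), "empty trajectory")
})

test_that("a trailing partial window is discarded with a warning", {
  toy <- toy_model()
  tr <- mk_traj(0, 5, 1.05)
  expect_warning(ws <- window_probabilities(list(tr), 0.1, toy$model, toy$params),
                 "partial window")
  expect_equal(ws$K, 10L)
})

test_that("declaring a node internal marginalizes exactly over its bit", {
  fx <- make_fixture("random", n = 4, seed = 9)
  m <- parse_bnd(fx$bnd)
  cfg <- quick_config(m, timetick = 0.25, max_time = 2, sample_count = 60,
                      statdist_traj_count = 0, seed = 4)
  ens <- run_ensemble(m, cfg)
  full <- window_probabilities(ens, 0.25, m)
  marg <- window_probabilities(ens, 0.25, m, internal = "B")
  keep <- m$node_names != "B"
  proj <- ctboolnet:::project_state(full$states, 4, keep)
  for (j in seq_along(marg$states)) {
    expect_equal(marg$prob[, j],
                 rowSums(full$prob[, proj == marg$states[j], drop = FALSE]),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(rowSums(marg$prob) - 1) < 1e-9))
})

test_that("jump-chain probabilities normalize rates and respect internal nodes", {
  toy <- toy_model(escape = 10)
  # single candidate: probability 1
  p <- transition_probabilities(toy$model, c(A = 1, B = 1, C = 1), toy$params)
  expect_equal(as.numeric(p), 1)
  # absorbing: empty map
  expect_length(transition_probabilities(toy$model, 0, toy$params), 0)
  # two candidates with very unequal rates
  m2 <- parse_bnd(paste("node A { rate_up = 1.0; rate_down = 0.0; }",
                        "node B { rate_up = $eps; rate_down = 0.0; }", sep = "\n"))
  p2 <- transition_probabilities(m2, 0, c(eps = 1e-5))
  expect_equal(as.numeric(p2), c(1, 1e-5) / (1 + 1e-5))
  # internal-node rule: only output-flipping candidates enter the normalization
  p3 <- transition_probabilities(m2, 0, c(eps = 1e-5), internal = "A")
  expect_equal(as.numeric(p3), 1)
  expect_equal(names(p3), "2")
  # ... and the map is empty when all candidates flip internal nodes
  m1 <- one_node_model(up = "1.0", down = "1.0", name = "A")
  msrc <- paste(format_model(m1), "node B { rate_up = 0.0; rate_down = 0.0; }", sep = "\n")
  m3 <- parse_bnd(msrc)
  expect_length(transition_probabilities(m3, 0, internal = "A"), 0)
  expect_equal(transition_entropy_state(m3, 0, internal = "A"), 0)
})

test_that("the state transition entropy matches direct evaluation", {
  toy <- toy_model(escape = 10)
  expect_equal(transition_entropy_state(toy$model, 0, toy$params), 0)  # fixed point
  # two equal-rate candidates: 1 bit
  m <- parse_bnd(paste("node A { rate_up = 1.0; rate_down = 0.0; }",
                       "node B { rate_up = 1.0; rate_down = 0.0; }", sep = "\n"))
  expect_equal(transition_entropy_state(m, 0), 1)
  # rates (1, 1e-5): tiny but non-zero entropy, computed independently
  m2 <- parse_bnd(paste("node A { rate_up = 1.0; rate_down = 0.0; }",
                        "node B { rate_up = $eps; rate_down = 0.0; }", sep = "\n"))
  pp <- c(1, 1e-5) / (1 + 1e-5)
  expected <- -sum(pp * log2(pp))
  expect_equal(transition_entropy_state(m2, 0, c(eps = 1e-5)), expected)
  expect_equal(expected, 1.81e-4, tolerance = 0.01)
})

test_that("windowed transition entropy averages TH over occupancy", {
  toy <- toy_model(escape = 10)
  # constant at the fixed point: zero in every window
  ws0 <- transition_entropy_window(list(mk_traj(0, 0, 2)), 0.5, toy$model, toy$params)
  expect_equal(ws0$th, rep(0, 4))
  # whole window spent in [001]: TH(tau) = TH([001])
  th001 <- transition_entropy_state(toy$model, 4, toy$params)
  ws1 <- transition_entropy_window(list(mk_traj(0, 4, 1)), 1, toy$model, toy$params)
  expect_equal(ws1$th, th001)
  expect_gt(th001, 0.4)  # rates (1, 10) mix
  # half window in [001], half in the fixed point
  ws2 <- transition_entropy_window(list(mk_traj(c(0, 0.5), c(4, 0), 1)), 1,
                                   toy$model, toy$params)
  expect_equal(ws2$th, th001 / 2)
})

test_that("Hamming-distance distributions count reference-node disagreements", {
  toy <- toy_model()
  ref <- setNames(c(1, 0, 1), c("A", "B", "C"))   # reference state [101]
  # HD([000], [101]) = 2 with all three nodes as reference
  ws <- hamming_distribution(list(mk_traj(0, 0, 1)), 1, toy$model,
                             refstate = ref, params = toy$params)
  expect_equal(as.numeric(ws$hd[1, ]), c(0, 0, 1, 0))
  # trajectory constant at the reference state: point mass at HD = 0 everywhere
  ws2 <- hamming_distribution(list(mk_traj(0, 5, 2)), 0.5, toy$model,
                              refstate = ref, params = toy$params)
  expect_true(all(ws2$hd[, 1] == 1))
  expect_true(all(abs(rowSums(ws2$hd) - 1) < 1e-9))
  # reference over a node subset
  ws3 <- hamming_distribution(list(mk_traj(0, 0, 1)), 1, toy$model,
                              refstate = setNames(c(1, NA, NA), c("A", "B", "C")),
                              params = toy$params)
  expect_equal(as.numeric(ws3$hd[1, ]), c(0, 1))
  expect_error(hamming_distribution(list(mk_traj(0, 0, 1)), 1, toy$model,
                                    refstate = NULL), "no reference nodes")
})

test_that("H vanishes exactly when one projected state has full occupancy", {
  toy <- toy_model()
  ws <- window_probabilities(list(mk_traj(0, 0, 1), mk_traj(0, 0, 1)), 1,
                             toy$model, toy$params)
  expect_equal(ws$H, 0)
  ws2 <- window_probabilities(list(mk_traj(0, 0, 1), mk_traj(0, 5, 1)), 1,
                              toy$model, toy$params)
  expect_gt(ws2$H, 0)
})

test_that("the toy model shows the fixed-point signature at a long horizon", {
  toy <- toy_model(escape = 10)
  cfg <- quick_config(toy$model, timetick = 0.5, max_time = 20, sample_count = 1500,
                      statdist_traj_count = 0, seed = 11, parameters = toy$params)
  ens <- run_ensemble(toy$model, cfg)
  ws <- window_probabilities(ens, 0.5, toy$model, toy$params)
  last <- ws$K
  expect_equal(ws$prob[last, match(0, ws$states)], 1, tolerance = 0.01)
  expect_lt(ws$H[last], 0.02)
  expect_lt(ws$th[last], 0.005)
})
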