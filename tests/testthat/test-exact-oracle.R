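# Exact master-equation oracle: generator structure, matrix exponentials,
# stationary analysis, spectra, transition graphs — and the oracle-vs-engine
# cross-check.

test_that("the generator has the prescribed structure", {
  # 1-node relaxation: [[-lambda, lambda], [mu, -mu]]
  m <- one_node_model(up = "1.5", down = "0.75")
  Q <- as.matrix(build_generator(m))
  expect_equal(unname(Q), matrix(c(-1.5, 0.75, 1.5, -0.75), 2))
  # toy model: 8x8, absorbing row [000] identically zero
  toy <- toy_model()
  Qt <- build_generator(toy$model, toy$params)
  expect_equal(dim(Qt), c(8L, 8L))
  expect_true(all(Qt[1, ] == 0))
  # rows sum to zero, off-diagonals non-negative (random models)
  for (sd in 1:3) {
    mr <- parse_bnd(make_fixture("random", n = 5, seed = sd)$bnd)
    Qr <- build_generator(mr)
    expect_true(all(abs(Matrix::rowSums(Qr)) < 1e-12))
    A <- as.matrix(Qr)
    diag(A) <- 0
    expect_true(all(A >= 0))
  }
  expect_error(build_generator(parse_bnd(make_fixture("random", n = 6, seed = 1)$bnd),
                               limit = 5), "limited to 5")
})

test_that("the master equation matches the two-state closed form and conserves probability", {
  lambda <- 2
  mu <- 0.5
  m <- one_node_model(up = "2.0", down = "0.5")
  Q <- build_generator(m)
  p0 <- c(0.9, 0.1)
  times <- c(0, 0.3, 1, 3, 10)
  sol <- solve_master(Q, p0, times)
  expect_equal(unname(sol[1, ]), p0)   # t = 0 is the identity case
  pinf <- lambda / (lambda + mu)
  expect_equal(unname(sol[, 2]), pinf + (p0[2] - pinf) * exp(-(lambda + mu) * times),
               tolerance = 1e-8)
  # conservation and non-negativity on a random model
  mr <- parse_bnd(make_fixture("random", n = 4, seed = 3)$bnd)
  Qr <- build_generator(mr)
  solr <- solve_master(Qr, rep(1 / 16, 16), c(0.1, 0.5, 2, 8))
  expect_true(all(abs(rowSums(solr) - 1) < 1e-9))
  expect_true(all(solr >= 0))
  # toy fast escape: the fixed point absorbs everything at large t
  toy <- toy_model(10)
  Qt <- build_generator(toy$model, toy$params)
  solt <- solve_master(Qt, rep(1 / 8, 8), 60)
  expect_equal(unname(solt[1, 1]), 1, tolerance = 1e-6)
})

test_that("exact window averages agree with a fine-grained quadrature", {
  toy <- toy_model(10)
  Q <- build_generator(toy$model, toy$params)
  p0 <- rep(1 / 8, 8)
  avg <- master_window_average(Q, p0, 0.5, 4)
  tt <- seq(0, 2, by = 1 / 512)
  sol <- solve_master(Q, p0, tt)
  for (tau in 1:4) {
    rows <- which(tt >= (tau - 1) * 0.5 & tt <= tau * 0.5)
    riemann <- colMeans(sol[rows, ])
    expect_lt(max(abs(avg[tau, ] - riemann)), 1e-3)
  }
})

test_that("stationary analysis identifies terminal components and their distributions", {
  toy <- toy_model(10)
  sa <- stationary_analysis(build_generator(toy$model, toy$params))
  expect_length(sa, 1L)
  expect_equal(sa[[1]]$states, 0)
  expect_equal(sa[[1]]$p, 1)
  # 1-node frozen model: two disconnected absorbing states, two point masses
  m0 <- one_node_model(up = "0.0", down = "0.0")
  sa0 <- stationary_analysis(build_generator(m0))
  expect_length(sa0, 2L)
  expect_true(all(vapply(sa0, function(s) length(s$states), 0L) == 1L))
  # pure 4-cycle with equal rates: uniform over the four states
  sa4 <- stationary_analysis(build_generator(four_cycle_model()))
  expect_length(sa4, 1L)
  expect_equal(sort(sa4[[1]]$states), 0:3)
  expect_equal(sa4[[1]]$p, rep(0.25, 4))
})

test_that("spectral reality and the dominant-decaying-mode diagnostic behave as designed", {
  # 1-node generator: always real
  ev1 <- damped_oscillation_check(build_generator(one_node_model("1.0", "2.0")))
  expect_false(ev1$has_nonreal)
  # pure cycle: rotation mode, non-real pair
  ev4 <- damped_oscillation_check(build_generator(four_cycle_model()))
  expect_true(ev4$has_nonreal)
  # toy: with either escape rate a non-real pair exists, but only the slow
  # regime has a complex *dominant decaying* mode (visible oscillation)
  toy_f <- toy_model(10)
  evf <- damped_oscillation_check(build_generator(toy_f$model, toy_f$params))
  expect_false(evf$dominant_is_complex)
  expect_equal(Re(evf$dominant_decaying), -0.5427, tolerance = 1e-3)
  toy_s <- toy_model(1e-5)
  evs <- damped_oscillation_check(build_generator(toy_s$model, toy_s$params))
  expect_true(evs$has_nonreal)
  expect_true(evs$dominant_is_complex)
  expect_equal(abs(Im(evs$dominant_decaying)), 1, tolerance = 1e-3)
})

test_that("the transition graph annotates fixed points, cycles and gamma", {
  toy <- toy_model(10)
  tg <- transition_graph(toy$model, toy$params)
  expect_equal(tg$fixed_points, 0)
  expect_length(tg$cycles, 1L)
  expect_equal(sort(tg$cycles[[1]]), c(4, 5, 6, 7))  # {[001],[101],[011],[111]}
  # out-degree equals the number of outgoing candidates
  mr <- parse_bnd(make_fixture("random", n = 4, seed = 6)$bnd)
  tgr <- transition_graph(mr)
  for (s in 0:15) {
    expect_equal(unname(tgr$gamma[as.character(s)]),
                 length(transitions(mr, s)$rate))
  }
  # frozen model: every state is an isolated fixed point
  mf <- parse_bnd(paste("node A { rate_up = 0.0; rate_down = 0.0; }",
                        "node B { rate_up = 0.0; rate_down = 0.0; }", sep = "\n"))
  tgf <- transition_graph(mf)
  expect_equal(sort(tgf$fixed_points), 0:3)
  expect_length(tgf$cycles, 0L)
})

test_that("graph exports are readable by external tools", {
  toy <- toy_model(10)
  tg <- transition_graph(toy$model, toy$params)
  gml <- tempfile(fileext = ".graphml")
  export_transition_graph(tg, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 8)
  expect_equal(igraph::ecount(back), igraph::ecount(tg$graph))
  dot <- tempfile(fileext = ".dot")
  export_transition_graph(tg, dot, "dot")
  expect_gt(file.size(dot), 0)
})

test_that("normalized generator rows reproduce the 1/gamma jump chain at equal rates", {
  for (sd in c(2, 8)) {
    mu <- parse_bnd(make_fixture("random", n = 5, seed = sd, rates = "unit")$bnd)
    Q <- as.matrix(build_generator(mu))
    diag(Q) <- 0
    for (s in seq_len(nrow(Q))) {
      out <- Q[s, Q[s, ] > 0]
      if (length(out)) {
        expect_equal(unname(out / sum(out)), rep(1 / length(out), length(out)))
      }
    }
  }
})

test_that("engine window estimates agree with the exact oracle on random models", {
  # light version of the equivalence property (heavier sweep in acceptance)
  agree <- 0
  total <- 0
  for (sd in c(4, 12, 23)) {
    mr <- parse_bnd(make_fixture("random", n = 5, seed = sd)$bnd)
    cfg <- quick_config(mr, timetick = 0.25, max_time = 2, sample_count = 800,
                        statdist_traj_count = 0, seed = sd)
    ens <- run_ensemble(mr, cfg)
    ws <- window_probabilities(ens, 0.25, mr)
    Q <- build_generator(mr)
    exact <- master_window_average(Q, rep(1 / 32, 32), 0.25, 8)
    est <- matrix(0, 8, 32)
    se <- matrix(0, 8, 32)
    est[, ws$states + 1] <- ws$prob
    se[, ws$states + 1] <- ws$prob_err
    floor_se <- sqrt(exact * (1 - exact) / 800)
    tol <- 4 * pmax(se, floor_se, 1e-8)
    agree <- agree + sum(abs(est - exact) <= tol)
    total <- total + length(exact)
  }
  expect_gt(agree / total, 0.95)
})
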