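test_that("fixation kernel satisfies its algebraic identities", {
  expect_equal(fixation_factor(0), 1)
  S <- c(-50, -10, -2, -0.3, 1e-9, 0.3, 2, 10, 50)
  # g(S)/g(-S) = exp(S)
  expect_equal(fixation_factor(S) / fixation_factor(-S), exp(S),
               tolerance = 1e-12)
  expect_equal(fixation_factor(10), 10 / (1 - exp(-10)), tolerance = 1e-12)
  expect_true(all(fixation_factor(c(-1e4, -300, 300, 1e4)) >= 0))
})

test_that("substitution rates are neutral on a flat landscape and satisfy detailed balance", {
  flat <- draw_landscape(landscape_spec("flat"))
  r <- substitution_rates(flat, "A", rate_model(1))
  expect_equal(r[["A"]], 0)
  expect_equal(unname(r[names(r) != "A"]), rep(1 / 19, 19))
  expect_equal(sum(r), 1)

  set.seed(5)
  logf <- rnorm(20)
  pi <- stationary_distribution(logf)
  for (i in c(1, 7, 20)) {
    ri <- substitution_rates(logf, i)
    for (j in c(2, 13)) {
      if (i == j) next
      rj <- substitution_rates(logf, j)
      expect_equal(pi[i] * ri[[j]], pi[j] * rj[[i]], tolerance = 1e-12)
    }
  }
})

test_that("long-run occupancy on a reduced static chain matches the matrix-exponential oracle", {
  skip_if_not_installed("pracma")
  # 3 effective alleles; the other 17 are essentially lethal
  logf <- c(1, 0.3, -0.5, rep(-60, 17))
  # oracle: continuous-time chain with our rate kernel, P(t) = expm(Q t)
  Q <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) if (i != j)
    Q[i, j] <- (1 / 19) * fixation_factor(logf[j] - logf[i])
  diag(Q) <- -rowSums(Q)
  P <- pracma::expm(Q * 200)
  pi_oracle <- P[1, ]
  expect_equal(pi_oracle, stationary_distribution(logf[1:3]),
               tolerance = 1e-5, ignore_attr = TRUE)

  # ergodic occupancy of a long simulated lineage
  set.seed(6)
  t_max <- 3e5
  tr <- lineage_tree(t_max)
  occ <- c(0, 0, 0)
  for (rep in 1:2) {
    h <- simulate_site(tr, landscape_spec("gamma", alpha = 1),
                       change_process("static"), logf0 = logf)
    tl <- h$events[h$events$type == "substitution", ]
    times <- c(0, tl$offset, t_max)
    states <- c(match(h$root_state, AMINO_ACIDS), match(tl$to, AMINO_ACIDS))
    dur <- diff(times)
    for (s in 1:3) occ[s] <- occ[s] + sum(dur[states == s])
  }
  occ <- occ / sum(occ)
  expect_lt(max(abs(occ - pi_oracle)), 0.01)
})

test_that("neutral simulation produces one substitution per dS and exact replay", {
  set.seed(7)
  tr <- fix_tree()
  L <- sum(tr$edge.length)
  counts <- replicate(40, {
    h <- simulate_site(tr, landscape_spec("flat"), change_process("static"))
    sum(h$events$type == "substitution")
  })
  expect_lt(abs(mean(counts) - L), 4 * sqrt(L / 40))

  h <- simulate_site(tr, landscape_spec("gamma", alpha = 1),
                     change_process("allele_linear", k = -30))
  expect_identical(replay_history(h), h$node_state)
  h2 <- simulate_site(tr, landscape_spec("rugged"),
                      change_process("random", lambda = 2))
  expect_identical(replay_history(h2), h2$node_state)
})

test_that("a static rugged landscape keeps the peak allele resident", {
  set.seed(8)
  tr <- lineage_tree(500)
  h <- simulate_site(tr, landscape_spec("rugged", peak_height = 10),
                     change_process("static"))
  peak <- AMINO_ACIDS[which.max(h$logf0)]
  tl <- h$events[h$events$type == "substitution", ]
  times <- c(0, tl$offset, 500)
  states <- c(h$root_state, tl$to)
  occ_peak <- sum(diff(times)[states == peak]) / 500
  expect_gt(occ_peak, 0.9)
})

test_that("fitness drift shapes the overall substitution count", {
  # senescence accelerates and entrenchment slows substitution relative to
  # the static landscape of the same shape
  set.seed(9)
  tr <- fix_tree()
  count_for <- function(k, n = 40) {
    proc <- if (k == 0) change_process("static") else
      change_process("allele_linear", k = k)
    sum(replicate(n, {
      h <- simulate_site(tr, landscape_spec("gamma", alpha = 1), proc)
      sum(h$events$type == "substitution")
    }))
  }
  n_neg <- count_for(-50); n_zero <- count_for(0); n_pos <- count_for(50)
  expect_gt(n_neg, n_zero)
  expect_gt(n_zero, n_pos)

  # moderate senescence on a strongly peaked landscape stays below the
  # neutral rate: the allele declines but remains the preferred one
  n_rug <- sum(replicate(40, {
    h <- simulate_site(tr, landscape_spec("rugged", peak_height = 10),
                       change_process("allele_linear", k = -5))
    sum(h$events$type == "substitution")
  }))
  expect_lt(n_rug / 40, sum(tr$edge.length))
})

test_that("ancestral fitness and survival under random landscape changes", {
  set.seed(10)
  grid <- c(0.5, 2)
  traj_at <- function(lambda, spec, n = 150) {
    tr <- lineage_tree(3)
    proc <- if (lambda == 0) change_process("static") else
      change_process("random", lambda = lambda)
    hs <- replicate(n, simulate_site(tr, spec, proc), simplify = FALSE)
    list(traj = fitness_trajectory(hs, grid),
         surv = ancestral_survival(hs, grid))
  }
  rug <- landscape_spec("rugged", peak_height = 10)
  r0 <- traj_at(0, rug); r1 <- traj_at(1, rug); r5 <- traj_at(5, rug)
  # static: resident fitness constant; random: decays, faster with lambda
  expect_equal(r0$traj$mean_logf[1], r0$traj$mean_logf[2], tolerance = 1e-9)
  expect_gt(r1$traj$mean_logf[2], r5$traj$mean_logf[2])
  expect_gt(r0$traj$mean_logf[2], r1$traj$mean_logf[2])
  # decays toward the across-allele mean (0.5 for the rugged vector)
  expect_gt(r0$traj$mean_logf[2], 5)
  expect_lt(abs(r5$traj$mean_logf[2] - 0.5), 1.5)
  # survival decays faster with lambda on a rugged landscape
  expect_gt(r0$surv$surviving[2], r5$surv$surviving[2])

  # flat: survival is independent of lambda and matches the symmetric
  # 20-state chain, P(resident) = 1/20 + (19/20) exp(-(20/19) t)
  flat <- landscape_spec("flat")
  f0 <- traj_at(0, flat, 200); f5 <- traj_at(5, flat, 200)
  expect_identical(unique(f0$traj$mean_logf), 0)
  oracle <- 1 / 20 + (19 / 20) * exp(-(20 / 19) * grid)
  for (f in list(f0, f5))
    expect_lt(max(abs(f$surv$surviving - oracle)), 0.1)
  expect_lt(abs(f0$surv$surviving[2] - f5$surv$surviving[2]), 0.12)
})

test_that("alignments are reproducible and internally consistent", {
  tr <- toy_tree()
  a1 <- simulate_alignment(tr, 5, landscape_spec("gamma", alpha = 1),
                           change_process("static"), seed = 99)
  a2 <- simulate_alignment(tr, 5, landscape_spec("gamma", alpha = 1),
                           change_process("static"), seed = 99)
  expect_identical(a1$states, a2$states)
  expect_equal(dim(a1$states), c(7, 5))
  for (h in a1$histories)
    expect_identical(replay_history(h), h$node_state)
})
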