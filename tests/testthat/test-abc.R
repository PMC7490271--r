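test_that("reference simulation is deterministic and respects the cap", {
  pooled <- fix_subtrees()
  small <- pool_subtrees(list())
  expect_error(simulate_reference(small, prior_spec("two_param"), 5),
               "empty")
  r1 <- simulate_reference(pooled, prior_spec("two_param"), n_sims = 15,
                           seed = 31)
  r2 <- simulate_reference(pooled, prior_spec("two_param"), n_sims = 15,
                           seed = 31)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_error(simulate_subtree_branches(pooled, 1, 0, cap = 0), "cap")
  capped <- simulate_subtree_branches(pooled, alpha = 1, k = 0, cap = 10)
  # at most 10 subtrees' worth of branches
  max_size <- max(vapply(unclass(pooled), function(e) length(e$shape$len), 0))
  expect_lte(nrow(capped), 10 * max_size)
})

test_that("strong senescence raises the age coefficient of the summary statistics", {
  set.seed(32)
  pooled <- fix_subtrees()
  bs <- replicate(5, summary_regression(
    simulate_subtree_branches(pooled, alpha = 1, k = -80, fraction = 1))$b)
  expect_true(all(bs > 0))
})

test_that("a static two-parameter draw matches a zero-fraction three-parameter draw", {
  set.seed(33)
  pooled <- fix_subtrees()
  two <- replicate(20, summary_regression(
    simulate_subtree_branches(pooled, alpha = 1, k = 0, fraction = 1))$b)
  three <- replicate(20, summary_regression(
    simulate_subtree_branches(pooled, alpha = 1, k = -60, fraction = 0))$b)
  expect_gt(stats::t.test(two, three)$p.value, 0.001)
})

test_that("rejection accepts exactly ceiling(tolerance * n) rows, invariant to statistic rescaling", {
  ref <- fix_ref("two_param")
  fit <- abc_fit(c(a = 0.5, b = 0), ref, tolerance = 0.013, adjust = "none")
  expect_equal(nrow(fit$samples), ceiling(0.013 * nrow(ref)))

  # rescaling one summary statistic (and the observation) by an arbitrary
  # factor leaves the accepted set unchanged thanks to MAD normalization
  ref2 <- ref
  ref2$b <- ref2$b * 37
  attr(ref2, "prior") <- attr(ref, "prior")
  class(ref2) <- class(ref)
  f1 <- abc_fit(c(a = 0.5, b = 0.02), ref, 0.01, adjust = "none")
  f2 <- abc_fit(c(a = 0.5, b = 0.02 * 37), ref2, 0.01, adjust = "none")
  expect_equal(f1$samples$k, f2$samples$k)

  expect_error(abc_fit(c(a = 0, b = 0), ref, tolerance = 1e-5), "accepted")
})

test_that("posterior is self-consistent at a reference row", {
  ref <- fix_ref("two_param")
  i <- which.min(abs(ref$k - 40))
  fit <- abc_fit(c(a = ref$a[i], b = ref$b[i]), ref, tolerance = 0.01)
  expect_lt(abs(fit$estimates["k", "median"] - ref$k[i]), 30)
  expect_equal(sign(fit$estimates["k", "median"]), sign(ref$k[i]))
})

test_that("parameter recovery: the sign and rough size of k are inferred", {
  set.seed(34)
  pooled <- fix_subtrees()
  ref <- fix_ref("two_param")
  for (k_true in c(-50, 50)) {
    obs <- summary_regression(
      simulate_subtree_branches(pooled, alpha = 1, k = k_true, fraction = 1))
    fit <- abc_fit(obs, ref, tolerance = 0.01)
    ci <- fit$estimates["k", c("lo", "hi")]
    expect_equal(sign(fit$estimates["k", "median"]), sign(k_true))
    if (k_true > 0) expect_gt(ci$lo, 0) else expect_lt(ci$hi, 0)
  }
  # three-parameter model: negative k at fraction 0.5 keeps a negative median
  ref3 <- fix_ref("three_param")
  obs <- summary_regression(
    simulate_subtree_branches(pooled, alpha = 1, k = -50, fraction = 0.5))
  fit3 <- abc_fit(obs, ref3, tolerance = 0.01)
  expect_lt(fit3$estimates["k", "median"], 0)
  expect_true(all(c("alpha", "k", "fraction") %in% names(coef(fit3))))
})

test_that("three-parameter posteriors nest the two-parameter model at fraction 1", {
  set.seed(35)
  pooled <- fix_subtrees()
  obs <- summary_regression(
    simulate_subtree_branches(pooled, alpha = 1, k = 60, fraction = 1))
  f2 <- abc_fit(obs, fix_ref("two_param"), 0.01)
  f3 <- abc_fit(obs, fix_ref("three_param"), 0.01)
  expect_equal(sign(f2$estimates["k", "median"]),
               sign(f3$estimates["k", "median"]))
  # with all alleles affected, the three-parameter fit infers a high fraction
  expect_gt(f3$estimates["fraction", "median"], 0.5)
})

test_that("cross-validation error is near zero for perfectly informative statistics and grows with tolerance", {
  set.seed(36)
  # synthetic reference where the statistics reveal the parameters exactly
  n <- 2000
  syn <- data.frame(alpha = 10^runif(n, -1.5, 1), k = runif(n, -100, 100))
  syn$fraction <- 1
  syn$a <- log10(syn$alpha)
  syn$b <- syn$k / 100
  syn$c <- 0
  attr(syn, "prior") <- prior_spec("two_param")
  class(syn) <- c("abc_reference", "data.frame")
  set.seed(37)
  cv <- cross_validate(syn, n_test = 30, tolerance = 0.01)
  expect_true(all(cv$error < 0.05))
  errs <- vapply(c(0.005, 0.01, 0.05), function(tol) {
    set.seed(38)
    sum(cross_validate(syn, n_test = 30, tolerance = tol,
                       adjust = "none")$error)
  }, 0)
  expect_true(all(diff(errs) >= 0))
})

test_that("confusion matrix transposes under a sign flip of the test set", {
  ref <- fix_ref("two_param")
  test <- ref[sample.int(nrow(ref), 40), ]
  set.seed(39)
  cm <- abc_confusion(ref, test = test, min_abs_k = 1)
  flipped <- test
  flipped$k <- -flipped$k
  est_sign <- ifelse(cm$details$est_k > 0, "entrenched", "senescing")
  true_flip <- ifelse(flipped$k[abs(flipped$k) >= 1] > 0,
                      "entrenched", "senescing")
  lev <- c("senescing", "entrenched")
  tab_flip <- table(factor(true_flip, lev), factor(est_sign, lev))
  expect_equal(unname(tab_flip[1, ]), unname(cm$table[2, ]))
  expect_equal(unname(tab_flip[2, ]), unname(cm$table[1, ]))
})
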