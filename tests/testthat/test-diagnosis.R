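# Naive Bayes with genetic-algorithm feature selection.

test_that("fitness sigmoid matches its printed and conventional orientations", {
  expect_equal(fitness_sigmoid(0), 0.5)
  expect_equal(fitness_sigmoid(1), 1 / (1 + exp(1)), tolerance = 1e-12)
  expect_equal(fitness_sigmoid(1), 0.26894, tolerance = 1e-5)
  expect_lt(fitness_sigmoid(100), 1e-10)            # printed form decreases
  expect_gt(fitness_sigmoid(100, printed = FALSE), 1 - 1e-10)
})

test_that("expected copy numbers are rounded proportional allocations", {
  expect_equal(expected_copies(c(1, 1, 1, 1), 4), c(1L, 1L, 1L, 1L))
  expect_equal(expected_copies(c(3, 1), 4), c(3L, 1L))
  ec <- expected_copies(c(1, 1, 1), 4)
  expect_equal(sum(ec), 4L)
  set.seed(14)
  for (i in 1:20) {
    f <- runif(sample(2:8, 1))
    N <- sample(3:30, 1)
    cc <- expected_copies(f, N)
    expect_equal(sum(cc), N)                        # largest-remainder sums
    expect_true(all(abs(cc - N * f / sum(f)) < 1))
  }
  expect_error(expected_copies(c(0, 0), 4), class = "echoasd_config_error")
})

test_that("joint probability factorizes and Bayes posteriors normalize", {
  expect_equal(joint_probability(0.3, 0.5), 0.15)
  set.seed(15)
  for (i in 1:20) {
    joint <- matrix(runif(4), 2)
    joint <- joint / sum(joint)                     # random joint table
    pm <- rowSums(joint)
    # P(M and N) = P(N | M) P(M)
    expect_equal(joint_probability(joint[1, 1] / pm[1], pm[1]), joint[1, 1],
                 tolerance = 1e-12)
  }
  # independent events factorize into the product of marginals
  pm <- 0.4; pn <- 0.7
  expect_equal(joint_probability(pn, pm), pn * pm, tolerance = 1e-15)
  post <- bayes_posterior(c(0.9, 0.1), c(0.5, 0.5))
  expect_equal(post, c(0.9, 0.1), tolerance = 1e-12)
  expect_equal(bayes_posterior(c(0.3, 0.3), c(0.2, 0.8)), c(0.2, 0.8))
  expect_equal(sum(bayes_posterior(runif(5), rep(0.2, 5))), 1,
               tolerance = 1e-12)
})

test_that("naive Bayes fits hand-computed smoothed frequencies", {
  tab <- data.frame(f1 = c("a", "a", "b", "b"),
                    f2 = c("x", "y", "x", "x"),
                    class = c("pos", "pos", "neg", "neg"))
  m <- nb_fit(tab, smoothing = 1)
  expect_equal(unname(m$priors), c(0.5, 0.5))
  # P(f1 = a | pos) = (2 + 1) / (2 + 2) = 0.75
  expect_equal(m$conditionals$f1["pos", "a"], 0.75)
  expect_equal(m$conditionals$f1["neg", "a"], 0.25)
  # P(f2 = x | neg) = (2 + 1) / (2 + 2) = 0.75
  expect_equal(m$conditionals$f2["neg", "x"], 0.75)
  for (f in names(m$conditionals))
    expect_equal(unname(rowSums(m$conditionals[[f]])), c(1, 1),
                 tolerance = 1e-12)
  single <- nb_fit(data.frame(f1 = c("a", "b"), class = c("p", "p")))
  expect_equal(unname(single$priors), 1)
})

test_that("posteriors normalize and symmetric data gives 50/50", {
  tab <- data.frame(f1 = c("a", "b"), class = c("c1", "c2"))
  m <- nb_fit(tab)
  pred <- nb_predict(m, list(f1 = "a"))
  expect_equal(sum(pred$posteriors), 1, tolerance = 1e-12)
  sym <- data.frame(f1 = c("a", "a", "b", "b"), class = c("c1", "c2", "c1", "c2"))
  ps <- nb_predict(nb_fit(sym), list(f1 = "a"))$posteriors
  expect_equal(unname(ps), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("NB equals the exhaustive joint classifier when independence holds", {
  # build counts so the empirical joint exactly factorizes per class
  probs <- list(pos = c(f1 = 0.5, f2 = 0.25, f3 = 0.75),
                neg = c(f1 = 0.25, f2 = 0.75, f3 = 0.5))
  rows <- list()
  for (cl in names(probs)) {
    p <- probs[[cl]]
    for (b1 in 0:1) for (b2 in 0:1) for (b3 in 0:1) {
      cnt <- 64 * prod(ifelse(c(b1, b2, b3) == 1, p, 1 - p))
      stopifnot(cnt == round(cnt))
      if (cnt > 0)
        rows[[length(rows) + 1]] <-
          data.frame(f1 = b1, f2 = b2, f3 = b3, class = cl)[rep(1, cnt), ]
    }
  }
  tab <- do.call(rbind, rows)
  tab[1:3] <- lapply(tab[1:3], factor)
  m <- nb_fit(tab, smoothing = 0)
  joint_counts <- table(tab$class, interaction(tab$f1, tab$f2, tab$f3))
  for (b1 in 0:1) for (b2 in 0:1) for (b3 in 0:1) {
    rec <- list(f1 = b1, f2 = b2, f3 = b3)
    nb_class <- nb_predict(m, rec)$class
    key <- paste(b1, b2, b3, sep = ".")
    joint_class <- rownames(joint_counts)[which.max(joint_counts[, key])]
    expect_equal(nb_class, joint_class)
  }
})

test_that("fitted conditionals recover the generating model within 0.05", {
  priors <- c(sick = 0.4, healthy = 0.6)
  cond <- list(
    a = rbind(sick = c(`0` = 0.2, `1` = 0.8), healthy = c(`0` = 0.7, `1` = 0.3)),
    b = rbind(sick = c(`0` = 0.5, `1` = 0.5), healthy = c(`0` = 0.9, `1` = 0.1)),
    c = rbind(sick = c(`0` = 0.3, `1` = 0.7), healthy = c(`0` = 0.4, `1` = 0.6)),
    d = rbind(sick = c(`0` = 0.6, `1` = 0.4), healthy = c(`0` = 0.2, `1` = 0.8)))
  tab <- synth_records(2000, priors, cond, seed = 16)
  m <- nb_fit(tab)
  for (f in names(cond)) {
    fitted <- m$conditionals[[f]][rownames(cond[[f]]), colnames(cond[[f]])]
    expect_lt(max(abs(fitted - cond[[f]])), 0.05)
  }
  expect_lt(max(abs(m$priors[names(priors)] - priors)), 0.05)
})

test_that("GA selects the informative feature and elitism is monotone", {
  priors <- c(sick = 0.5, healthy = 0.5)
  cond <- list(
    signal = rbind(sick = c(`0` = 0.1, `1` = 0.9),
                   healthy = c(`0` = 0.9, `1` = 0.1)),
    n1 = rbind(sick = c(`0` = 0.5, `1` = 0.5), healthy = c(`0` = 0.5, `1` = 0.5)),
    n2 = rbind(sick = c(`0` = 0.5, `1` = 0.5), healthy = c(`0` = 0.5, `1` = 0.5)),
    n3 = rbind(sick = c(`0` = 0.5, `1` = 0.5), healthy = c(`0` = 0.5, `1` = 0.5)))
  tab <- synth_records(300, priors, cond, seed = 17)
  res <- ga_select_features(tab, pop_size = 16, generations = 12,
                            folds = 3, seed = 18)
  expect_true("signal" %in% res$features)
  expect_true(all(diff(res$trace) >= 0))            # elitism invariant
  res2 <- ga_select_features(tab, pop_size = 16, generations = 12,
                             folds = 3, seed = 18)
  expect_identical(res$mask, res2$mask)             # same seed, same mask
})
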