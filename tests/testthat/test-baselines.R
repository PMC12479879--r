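test_that("templates are scalogram means with the mean-of-one identity", {
  wf1 <- fish_waveforms(make_fish(1, 0.6), 1, seed = 1)
  tpl <- build_templates(list(A = wf1), fs = 50000)
  expect_equal(tpl$templates$A, morse_scalogram(wf1[1, ])$coeffs,
               tolerance = 1e-12)
  # two identical EODs: the mean is either one
  tpl2 <- build_templates(list(A = rbind(wf1, wf1)), fs = 50000)
  expect_equal(tpl2$templates$A, tpl$templates$A, tolerance = 1e-12)
  expect_error(build_templates(list()), "no fish")
})

test_that("a noisy fish's mean scalogram converges to the clean template", {
  m <- make_fish(5, 0.7)
  noisy <- fish_waveforms(m, 100, noise_sd = 0.05, seed = 5)
  clean <- fish_waveforms(m, 1, noise_sd = 0, seed = 1)
  tpl <- build_templates(list(A = noisy), fs = 50000)
  r <- cor(as.numeric(tpl$templates$A),
           as.numeric(morse_scalogram(clean[1, ])$coeffs))
  expect_gt(r, 0.99)
})

test_that("correlation classification is exact on its own template", {
  wa <- fish_waveforms(make_fish(1, 0.9), 1, seed = 1)
  wb <- fish_waveforms(make_fish(2, 0.9), 1, seed = 2)
  tpl <- build_templates(list(A = wa, B = wb), fs = 50000)
  lab <- correlate_classify(wa, tpl)
  expect_equal(as.character(lab), "A")
})

test_that("correlation separates an easy dyad and degrades to ties", {
  ma <- make_fish(11, 0.9); mb <- make_fish(12, 0.9)
  tpl <- build_templates(list(A = fish_waveforms(ma, 40, seed = 1),
                              B = fish_waveforms(mb, 40, seed = 2)),
                         fs = 50000)
  test_wf <- rbind(fish_waveforms(ma, 50, seed = 3),
                   fish_waveforms(mb, 50, seed = 4))
  truth <- rep(c("A", "B"), each = 50)
  lab <- correlate_classify(test_wf, tpl)
  expect_gte(mean(lab == truth), 0.95)

  # identical templates for both fish: every decision is a tie -> fish A
  tpl_same <- tpl; tpl_same$templates$B <- tpl_same$templates$A
  lab2 <- suppressMessages(correlate_classify(test_wf, tpl_same))
  expect_true(all(lab2 == "A"))
  expect_equal(attr(lab2, "n_ties"), 100)
  expect_equal(mean(lab2 == truth), 0.5)
})

test_that("the SVM learns separable classes and trains deterministically", {
  set.seed(1)
  fa <- list(features = matrix(rnorm(60 * 5, mean = 0), ncol = 5),
             peak_amp_V = runif(60, 0.01, 0.03))
  fb <- list(features = matrix(rnorm(60 * 5, mean = 4), ncol = 5),
             peak_amp_V = runif(60, 0.01, 0.03))
  cfg <- svm_config(n_train_per_fish = 50, cv_folds = 10, search_budget = 10,
                    seed = 3)
  expect_warning(
    svm_train(list(A = list(features = fa$features[1:20, ]), B = fb),
              svm_config(n_train_per_fish = 30, seed = 1)),
    "using all")
  m1 <- svm_train(list(A = fa, B = fb), cfg)
  m2 <- svm_train(list(A = fa, B = fb), cfg)
  expect_gte(m1$cv_acc, 0.99)
  expect_identical(c(m1$C, m1$gamma), c(m2$C, m2$gamma))
  # self-classification is consistent with the CV estimate
  self_acc <- mean(svm_classify(m1, rbind(fa$features, fb$features)) ==
                     rep(c("A", "B"), each = 60))
  expect_gte(self_acc, m1$cv_acc - 0.05)
  expect_error(svm_train(list(A = fa), cfg), "two fish")
})

test_that("SVM prediction is row-wise and robust to degenerate rows", {
  set.seed(2)
  fa <- list(features = matrix(rnorm(40 * 4, 0), ncol = 4))
  fb <- list(features = matrix(rnorm(40 * 4, 3), ncol = 4))
  m <- svm_train(list(A = fa, B = fb),
                 svm_config(n_train_per_fish = 40, cv_folds = 5,
                            search_budget = 4, seed = 1))
  X <- rbind(fa$features[1:5, ], fb$features[1:5, ])
  lab <- svm_classify(m, X)
  perm <- sample(10)
  expect_equal(svm_classify(m, X[perm, ]), lab[perm])
  z <- svm_classify(m, matrix(0, 1, 4))
  expect_true(z %in% c("A", "B"))
  expect_error(svm_classify(m, matrix(0, 1, 7)), "dimension")
})

test_that("SVM beats correlation within-session; both degrade across sessions", {
  accs <- replicate(3, NULL, simplify = FALSE)
  for (s in 1:3) {
    ma <- make_fish(s * 100 + 1, 0.6); mb <- make_fish(s * 100 + 2, 0.6)
    train_a <- fish_waveforms(ma, 60, noise_sd = 0.05, seed = s * 10 + 1)
    train_b <- fish_waveforms(mb, 60, noise_sd = 0.05, seed = s * 10 + 2)
    test_same <- rbind(fish_waveforms(ma, 60, noise_sd = 0.05, seed = s * 10 + 3),
                       fish_waveforms(mb, 60, noise_sd = 0.05, seed = s * 10 + 4))
    # a later session: the waveforms themselves drift
    ma2 <- perturb_fish(ma, 0.12, seed = s + 50)
    mb2 <- perturb_fish(mb, 0.12, seed = s + 60)
    test_drift <- rbind(fish_waveforms(ma2, 60, noise_sd = 0.05, seed = s * 10 + 5),
                        fish_waveforms(mb2, 60, noise_sd = 0.05, seed = s * 10 + 6))
    truth <- rep(c("A", "B"), each = 60)

    tpl <- build_templates(list(A = train_a, B = train_b), fs = 50000)
    fa <- list(features = feature_matrix(train_a, "timefreq", fs = 50000))
    fb <- list(features = feature_matrix(train_b, "timefreq", fs = 50000))
    svm <- svm_train(list(A = fa, B = fb),
                     svm_config(n_train_per_fish = 60, cv_folds = 5,
                                search_budget = 9, seed = s))
    acc <- function(wf, clf) {
      if (clf == "corr") mean(correlate_classify(wf, tpl) == truth)
      else mean(svm_classify(svm, feature_matrix(wf, "timefreq",
                                                 fs = 50000)) == truth)
    }
    accs[[s]] <- c(corr_same = acc(test_same, "corr"),
                   svm_same = acc(test_same, "svm"),
                   corr_drift = acc(test_drift, "corr"),
                   svm_drift = acc(test_drift, "svm"))
  }
  a <- do.call(rbind, accs)
  # supervised ordering within-session, in the median
  expect_gte(median(a[, "svm_same"]), median(a[, "corr_same"]))
  # session drift hurts the supervised classifiers, in the median
  expect_lt(median(pmin(a[, "svm_drift"], a[, "corr_drift"])),
            median(pmin(a[, "svm_same"], a[, "corr_same"])))
})
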