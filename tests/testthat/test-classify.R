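test_that("both classifiers are perfect on separable features", {
  withr::with_seed(3, {
    n <- 20
    X <- rbind(cbind(rnorm(n, 3), rnorm(n)), cbind(rnorm(n, -3), rnorm(n)))
    y <- c(rep("P300", n), rep("NONP300", n))
  })
  sw <- swlda_train(X, y)
  expect_equal(predict(sw, X), y)
  mm <- margin_train(X, y)
  expect_equal(predict(mm, X), y)
})

test_that("swlda held-out accuracy is chance-level on label-free features", {
  withr::with_seed(11, {
    Xtr <- matrix(rnorm(60 * 5), 60)
    ytr <- rep(c("P300", "NONP300"), 30)
    Xte <- matrix(rnorm(200 * 5), 200)
    yte <- rep(c("P300", "NONP300"), 100)
  })
  sw <- swlda_train(Xtr, ytr)
  cc <- confusion_counts(yte, predict(sw, Xte))
  expect_lt(abs(accuracy(cc) - 0.5), 0.15)
})

test_that("a duplicated informative column is retained only once", {
  withr::with_seed(23, {
    z <- rnorm(60)
    X <- cbind(z, z, matrix(rnorm(60 * 2), 60))
    y <- ifelse(z + rnorm(60, sd = 0.4) > 0, "P300", "NONP300")
  })
  sw <- swlda_train(X, y)
  expect_equal(sum(sw$mask[1:2]), 1)
})

test_that("the leave-one-out margin protocol returns 2U models and a seeded pick", {
  withr::with_seed(9, {
    U <- 20
    X <- rbind(cbind(rnorm(U, 2), rnorm(U)), cbind(rnorm(U, -2), rnorm(U)))
    y <- c(rep("P300", U), rep("NONP300", U))
  })
  loo <- margin_train_loo(X, y, seed = 5)
  expect_length(loo$models, 2 * U)
  loo2 <- margin_train_loo(X, y, seed = 5)
  expect_equal(loo$selected, loo2$selected)
  expect_equal(predict(loo$model, X), predict(loo2$model, X))
})

test_that("accuracy follows the confusion-count arithmetic and its symmetry", {
  expect_equal(accuracy(list(TP = 10, TN = 10, FP = 0, FN = 0)), 1.0)
  expect_equal(accuracy(list(TP = 9, TN = 8, FP = 2, FN = 1)), 0.85)
  expect_equal(accuracy(list(TP = 0, TN = 0, FP = 5, FN = 5)), 0.0)
  expect_error(accuracy(list(TP = 0, TN = 0, FP = 0, FN = 0)), "positive")
  # invariance under swapping the positive/negative roles
  withr::with_seed(2, {
    for (i in 1:20) {
      cc <- as.list(sample(0:20, 4, replace = TRUE))
      names(cc) <- c("TP", "TN", "FP", "FN")
      if (sum(unlist(cc)) == 0) next
      sw <- list(TP = cc$TN, TN = cc$TP, FP = cc$FN, FN = cc$FP)
      expect_equal(accuracy(cc), accuracy(sw))
    }
  })
})

test_that("validation builds floor(P'/K) balanced pairs and ranks electrodes", {
  tr <- make_epochs(nP = 60, nN = 120, C = 2, T = 40, amp = c(6, 0),
                    noise_sd = 1, seed = 4, electrodes = c("Cz", "P3"))
  pr <- calibrate(tr, calibration_params(S = 6, A = 15, K = 3, O = 2,
                                         max_folds = 8, master_seed = 2))
  # validation pool sized like the reference protocol: P' = 150, K = 15
  va <- make_epochs(nP = 150, nN = 750, C = 2, T = 40, amp = c(6, 0),
                    noise_sd = 1, seed = 5, electrodes = c("Cz", "P3"))
  rep <- validate_profile(pr, va, K = 15, seed = 8)
  expect_equal(attr(rep, "D"), 10)
  expect_equal(rep$TP + rep$FN, rep(10L, nrow(rep)))
  expect_equal(rep$TN + rep$FP, rep(10L, nrow(rep)))
  expect_equal(rep$rank, seq_len(nrow(rep)))
  expect_true(all(diff(rep$accuracy) <= 0))

  # at the profile's own optimum K the signal electrode beats chance clearly
  # (single-trial chains at this small scale are noisy; near-perfect
  # separation is exercised at full scale in the acceptance suite)
  rep2 <- validate_profile(pr, va, seed = 8)
  expect_gte(rep2$accuracy[rep2$electrode == "Cz"], 0.75)

  expect_error(validate_profile(pr, va, K = 200), "fewer than")
})

test_that("zero-signal validation stays at chance level", {
  tr <- make_epochs(nP = 60, nN = 120, C = 2, T = 40, amp = c(6, 0),
                    noise_sd = 1, seed = 4, electrodes = c("Cz", "P3"))
  pr <- calibrate(tr, calibration_params(S = 6, A = 15, K = 3, O = 2,
                                         max_folds = 8, master_seed = 2))
  va0 <- make_epochs(nP = 60, nN = 60, C = 2, T = 40, amp = c(0, 0),
                     noise_sd = 1, seed = 31, electrodes = c("Cz", "P3"))
  rep0 <- validate_profile(pr, va0, K = 2, seed = 9)
  expect_true(all(abs(rep0$accuracy - 0.5) <= 0.2))
})

test_that("concatenated-electrode validation returns a single pooled row", {
  tr <- make_epochs(nP = 40, nN = 80, C = 2, T = 40, amp = c(6, 5),
                    noise_sd = 1, seed = 14, electrodes = c("Cz", "Pz"))
  pr <- calibrate(tr, calibration_params(S = 6, A = 10, K = 3, O = 2,
                                         max_folds = 6, master_seed = 6))
  va <- make_epochs(nP = 30, nN = 30, C = 2, T = 40, amp = c(6, 5),
                    noise_sd = 1, seed = 15, electrodes = c("Cz", "Pz"))
  rep <- validate_profile(pr, va, K = 3, seed = 2,
                          electrode_mode = "concatenated")
  expect_equal(nrow(rep), 1)
  expect_equal(rep$electrode, "all")
  expect_gte(rep$accuracy, 0.8)
})

test_that("svm-backed validation runs the same protocol", {
  tr <- make_epochs(nP = 40, nN = 80, C = 1, T = 40, amp = 6,
                    noise_sd = 1, seed = 24, electrodes = "Cz")
  pr <- calibrate(tr, calibration_params(S = 6, A = 10, K = 3, O = 2,
                                         max_folds = 6, master_seed = 4))
  va <- make_epochs(nP = 30, nN = 30, C = 1, T = 40, amp = 6,
                    noise_sd = 1, seed = 25, electrodes = "Cz")
  rep <- validate_profile(pr, va, K = 3, seed = 3, classifier = "svm")
  expect_gte(rep$accuracy[1], 0.8)
})
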