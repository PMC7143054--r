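test_that("criteria match their closed forms and hand values", {
  expect_equal(aic(1, 10, 10), 2)
  expect_equal(aicc(1, 10, 10), 2.5)
  expect_equal(bic(1, 10, 10), log(10))

  set.seed(6)
  for (i in 1:50) {
    k <- sample(1:10, 1); n <- k + 1 + sample(1:100, 1); r <- runif(1, 0.01, 10)
    expect_equal(aicc(k, n, r) - aic(k, n, r),
                 (2 * k^2 + 2 * k) / (n - k - 1), tolerance = 1e-12)
    expect_equal(bic(k, n, r) - aic(k, n, r), k * (log(n) - 2),
                 tolerance = 1e-12)
  }
})

test_that("criteria penalize parameters and AICc converges to AIC", {
  for (crit in list(aic, aicc, bic)) {
    v <- vapply(1:5, function(k) crit(k, 100, 1), 0)
    expect_true(all(diff(v) > 0))
  }
  k <- 3
  expect_lt(aicc(k, 1e8 * k, 1) - aic(k, 1e8 * k, 1), 1e-6)
  expect_error(aic(1, 10, 0), "RSS")
  expect_error(aicc(5, 6, 1), "n > k")
})

fake_result <- function(model = "m1", rss = 1, loss = 2, k_total = 18,
                        n = 51) {
  structure(list(model = model, objective = "abs_diff", rss = rss,
                 loss = loss, k_total = k_total, n = n),
            class = "optimization_result")
}

test_that("score_model averages RSS before computing criteria", {
  sc <- score_model(list(fake_result(rss = 1), fake_result(rss = 3)))
  expect_equal(sc$mean_rss, 2)
  expect_equal(sc$aicc, aicc(18, 51, 2))
  expect_equal(sc$k, 18)
  expect_equal(sc$n, 51)

  single <- score_model(list(fake_result(rss = 0.5)))
  expect_equal(single$aic, aic(18, 51, 0.5))

  expect_error(score_model(list()), "no results")
  expect_error(score_model(list(fake_result("a"), fake_result("b"))),
               "share one model")
})

test_that("fitted expert model yields the documented counting", {
  fix <- expert_fixture()
  m <- udp_glcnac_expert_model()
  sc <- score_model(fit_repeated(m, fix$dataset, "abs_diff",
                                 saga_config(500), repeats = 2))
  expect_equal(sc$n, 3 * 17)   # capacity 16 -> 17 entries per profile
  expect_equal(sc$k, 18)       # 6 parameters per time point
})

test_that("split scoring pools additively and matches combined counting", {
  per_tp <- lapply(1:3, function(t)
    list(fake_result(rss = 0.1, loss = 0.2, k_total = 6, n = 17)))
  sc <- combine_split_scores(per_tp)
  expect_equal(sc$mean_rss, 0.3, tolerance = 1e-12)
  expect_equal(sc$n, 51)
  expect_equal(sc$k, 18)
  expect_equal(sc$aicc, aicc(18, 51, 0.3))

  # single time point reduces to score_model
  one <- combine_split_scores(list(list(fake_result(rss = 0.1, k_total = 6,
                                                    n = 17))))
  direct <- score_model(list(fake_result(rss = 0.1, k_total = 6, n = 17)))
  expect_equal(one$aicc, direct$aicc)

  expect_error(combine_split_scores(list(
    list(fake_result("a")), list(fake_result("b")))), "different models")
})

test_that("split fits of each time point match combined-mode counting", {
  fix <- expert_fixture(noise_sd = 0.01)
  m <- udp_glcnac_expert_model()
  per_tp <- lapply(seq_along(fix$dataset$profiles), function(t) {
    sub <- fix$dataset
    sub$profiles <- sub$profiles[t]
    fit_repeated(m, sub, "abs_diff", saga_config(1000), repeats = 2,
                 base_seed = t * 10)
  })
  sc <- combine_split_scores(per_tp)
  combined <- score_model(fit_repeated(m, fix$dataset, "abs_diff",
                                       saga_config(1000), repeats = 2))
  expect_equal(sc$n, combined$n)
  expect_equal(sc$k, combined$k)
})

test_that("select_model ranks ascending with deterministic tie-breaks", {
  mk <- function(model, aicc_val) {
    s <- list(model = model, k = 18, n = 51, mean_loss = 1, mean_rss = 1,
              aic = aicc_val - 1, aicc = aicc_val, bic = aicc_val + 1)
    class(s) <- "model_score"
    s
  }
  rep_ <- select_model(list(mk("b", -384.31), mk("a", -401.76),
                            mk("c", -226.73)), "AICc")
  expect_equal(rep_$selected, "a")
  expect_equal(rep_$table$rank, 1:3)
  expect_equal(rep_$table$model, c("a", "b", "c"))

  expect_equal(select_model(list(mk("only", 1)))$table$rank, 1)

  # ranking is invariant under adding a constant
  shifted <- select_model(list(mk("b", -384.31 + 100), mk("a", -401.76 + 100),
                               mk("c", -226.73 + 100)), "AICc")
  expect_equal(shifted$table$model, rep_$table$model)

  expect_warning(sel <- select_model(list(mk("z", 5), mk("y", 5))), "tie")
  expect_equal(sel$selected, "y")
})
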