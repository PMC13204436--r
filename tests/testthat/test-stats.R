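test_that("identical arms are never called different", {
  set.seed(101)
  x <- rnorm(20, 70, 4)
  cmp <- compare_groups(x, x, sample_id = "S", day = 2, parameter = "alpha1")
  expect_gt(cmp$p_value, 0.99)
  expect_equal(cmp$direction, "none")
})

test_that("small-sample Mann-Whitney matches the exact reference", {
  set.seed(202)
  for (n1 in 3:6) for (n2 in 3:6) {
    for (rep in 1:3) {
      x <- rnorm(n1); y <- rnorm(n2) + rep - 2
      ours <- mann_whitney_u(x, y)
      ref <- wilcox.test(y, x, exact = TRUE)$p.value
      expect_true(ours$exact)
      expect_equal(ours$p_value, ref, tolerance = 1e-12)
    }
  }
})

test_that("tied small samples are handled by enumeration", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  res <- mann_whitney_u(x, y)
  expect_true(res$exact)
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
  # enumeration must be permutation-consistent: identical pooled data -> p 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
})

test_that("the normality gate routes to the right test", {
  set.seed(303)
  norm_a <- rnorm(35, 70, 4); norm_b <- rnorm(35, 73, 4)
  cmp <- compare_groups(norm_a, norm_b)
  expect_equal(cmp$test_used, "student_t")
  skewed <- exp(rnorm(35, 0, 1))
  cmp2 <- compare_groups(skewed, skewed * 1.1 + rnorm(35, 0, 0.01))
  expect_equal(cmp2$test_used, "mann_whitney")
})

test_that("degenerate and undersized arms are rejected or flagged", {
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "insufficient")
  expect_warning(cmp <- compare_groups(rep(5, 5), c(5.1, 5.2, 5.3, 5.0, 4.9)),
                 "constant")
  expect_equal(cmp$test_used, "mann_whitney")
})

test_that("type-I error stays near nominal under the null", {
  rejections <- vapply(1:300, function(i) {
    set.seed(4000 + i)
    compare_groups(rnorm(35, 70, 4), rnorm(35, 70, 4))$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.09)
})

test_that("rejection rate grows monotonically with the true effect", {
  effects <- seq(0, 4, length.out = 5)
  rates <- vapply(seq_along(effects), function(k) {
    mean(vapply(1:200, function(i) {
      set.seed(5000 + 300 * k + i)
      compare_groups(rnorm(35, 69.1, 4.7),
                     rnorm(35, 69.1 + effects[k], 4.7))$p_value <= 0.05
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(rates) >= -0.05))
  expect_gt(rates[5], rates[1] + 0.5)
})

test_that("alpha1 power at the M5 day-2 printed effect matches theory", {
  # analytic oracle for the t-test under the reconstructed SDs
  d <- (72.2 - 69.1) / sqrt((0.8^2 + 0.7^2) / 2 * 35)
  analytic <- power.t.test(n = 35, delta = d, sd = 1, sig.level = 0.05)$power
  emp <- mean(vapply(1:500, function(i) {
    set.seed(6000 + i)
    compare_groups(rnorm(35, 69.1, 0.8 * sqrt(35)),
                   rnorm(35, 72.2, 0.7 * sqrt(35)))$p_value <= 0.05
  }, logical(1)))
  expect_lt(abs(emp - analytic), 0.07)
})

test_that("response classification follows the alpha1/tau2 increase rule", {
  mk <- function(par, p, dir, cm = 70, tm = 71) {
    data.frame(sample_id = "S", day = 7, parameter = par, control_mean = cm,
               control_sem = 0.7, treated_mean = tm, treated_sem = 0.7,
               n_control = 35, n_treated = 35, test_used = "student_t",
               p_value = p, direction = dir)
  }
  # alpha1 up only -> response
  call <- classify_flim_response(rbind(mk("alpha1", 0.001, "increase"),
                                       mk("tau2", 0.4, "none")))
  expect_equal(call$call, "response")
  # both decreased -> no_response
  call <- classify_flim_response(rbind(mk("alpha1", 0.01, "decrease", 73, 70),
                                       mk("tau2", 0.001, "decrease", 3.6, 3.1)))
  expect_equal(call$call, "no_response")
  # mixed increase + decrease -> the increase wins (response)
  call <- classify_flim_response(rbind(mk("alpha1", 0.01, "increase"),
                                       mk("tau2", 0.01, "decrease", 3.6, 3.1)))
  expect_equal(call$call, "response")
  # no changes -> indeterminate
  call <- classify_flim_response(rbind(mk("alpha1", 0.5, "none"),
                                       mk("tau2", 0.7, "none")))
  expect_equal(call$call, "indeterminate")
  expect_error(classify_flim_response(mk("alpha1", 0.5, "none")), "tau2")
})

test_that("the high-baseline rescue upgrades only high flat samples", {
  mk <- function(par, cm, tm) {
    data.frame(sample_id = "P17", day = 7, parameter = par, control_mean = cm,
               control_sem = 0.5, treated_mean = tm, treated_sem = 0.6,
               n_control = 35, n_treated = 35, test_used = "student_t",
               p_value = 0.9, direction = "none")
  }
  thr <- c(alpha1 = 71.5, tau2 = 3.4)
  high <- rbind(mk("alpha1", 73.6, 73.6), mk("tau2", 3.84, 3.86))
  call <- classify_flim_response(high, rescue = TRUE, rescue_thresholds = thr)
  expect_equal(call$call, "response")
  expect_true(call$rescue_applied)
  low <- rbind(mk("alpha1", 70.9, 71.0), mk("tau2", 3.3, 3.3))
  call2 <- classify_flim_response(low, rescue = TRUE, rescue_thresholds = thr)
  expect_equal(call2$call, "indeterminate")
  expect_false(call2$rescue_applied)
  # rescue off: never applied
  call3 <- classify_flim_response(high)
  expect_equal(call3$call, "indeterminate")
})

test_that("classification is label-symmetric", {
  set.seed(707)
  ctrl <- rnorm(35, 69.1, 4); trt <- rnorm(35, 73.5, 4)
  fwd <- compare_groups(ctrl, trt, parameter = "alpha1")
  rev <- compare_groups(trt, ctrl, parameter = "alpha1")
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$direction, "increase")
  expect_equal(rev$direction, "decrease")
  t2n <- compare_groups(rnorm(35, 3.3, 0.3), rnorm(35, 3.31, 0.3),
                        parameter = "tau2")
  t2n$sample_id <- fwd$sample_id <- rev$sample_id <- "S"
  call_fwd <- classify_flim_response(rbind(fwd, t2n))
  call_rev <- classify_flim_response(rbind(rev, t2n))
  expect_equal(call_fwd$call, "response")
  expect_equal(call_rev$call, "no_response")
})

test_that("the day-7 call decides the timecourse", {
  calls <- data.frame(sample_id = "S", day = c(2L, 7L),
                      call = c("indeterminate", "response"),
                      rescue_applied = FALSE)
  expect_equal(classify_timecourse(calls)$call, "response")
  expect_equal(classify_timecourse(calls[1, , drop = FALSE])$call,
               "indeterminate")
  d214 <- data.frame(sample_id = "S", day = c(2L, 14L),
                     call = c("indeterminate", "no_response"),
                     rescue_applied = FALSE)
  expect_equal(classify_timecourse(d214)$day, 14L)
  expect_error(classify_timecourse(calls[0, ]), "no per-day")
})
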