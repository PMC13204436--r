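flow_row <- function(condition, subset, marker, parent, positive, rep = 1,
                     sid = "M1") {
  data.frame(sample_id = sid, condition = condition, day = 14,
             parent_subset = subset, marker = marker,
             parent_events = parent, positive_events = positive,
             replicate = rep)
}

test_that("simulated gating respects subset nesting and determinism", {
  s1 <- simulate_flow_summary("M1", "treated", "up", seed = 11)
  s2 <- simulate_flow_summary("M1", "treated", "up", seed = 11)
  expect_identical(s1, s2)
  expect_true(all(s1$positive_events <= s1$parent_events))
  expect_true(all(s1$positive_events >= 0))
  expect_equal(nrow(s1), 2 * 2 * 3)  # subsets x markers x replicates
})

test_that("identical pooled proportions are non-significant", {
  ctrl <- rbind(flow_row("control", "CD8", "CD25", 2000, 200),
                flow_row("control", "CD8", "CD69", 2000, 240))
  trt <- rbind(flow_row("treated", "CD8", "CD25", 2000, 200),
               flow_row("treated", "CD8", "CD69", 2000, 240))
  cmp <- compare_activation(ctrl, trt)
  expect_true(all(cmp$p_value > 0.9))
  expect_true(all(cmp$direction == "none"))
})

test_that("a large activation shift is detected as a significant increase", {
  ctrl <- rbind(flow_row("control", "CD8", "CD25", 2000, 200),
                flow_row("control", "CD8", "CD69", 2000, 240))
  trt <- rbind(flow_row("treated", "CD8", "CD25", 2000, 600),
               flow_row("treated", "CD8", "CD69", 2000, 700))
  cmp <- compare_activation(ctrl, trt)
  expect_true(all(cmp$p_value < 1e-6))
  expect_true(all(cmp$direction == "increase"))
  call <- classify_activation_response(cmp)
  expect_equal(call$call, "activation_response")
})

test_that("small-count Fisher p-values match hypergeometric enumeration", {
  cases <- list(c(8, 12, 3, 17), c(5, 5, 9, 1), c(2, 18, 7, 13))
  for (cs in cases) {
    ctrl <- rbind(flow_row("control", "CD8", "CD25", cs[3] + cs[4], cs[3]),
                  flow_row("control", "CD8", "CD69", cs[3] + cs[4], cs[3]))
    trt <- rbind(flow_row("treated", "CD8", "CD25", cs[1] + cs[2], cs[1]),
                 flow_row("treated", "CD8", "CD69", cs[1] + cs[2], cs[1]))
    cmp <- compare_activation(ctrl, trt)
    expect_equal(cmp$p_value[cmp$marker == "CD25"],
                 oracle_fisher_p(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-9)
  }
})

test_that("the activation call needs both CD8 markers up", {
  base <- rbind(flow_row("x", "CD8", "CD25", 1, 1), flow_row("x", "CD8", "CD69", 1, 1))
  cmp <- data.frame(sample_id = "M1",
                    parent_subset = c("CD8", "CD8", "CD4convFoxP3neg"),
                    marker = c("CD25", "CD69", "CD25"),
                    control_frac = 0.1, treated_frac = 0.2,
                    control_events = 6000, treated_events = 6000,
                    test_used = "fisher_exact", p_value = c(0.001, 0.2, 0.001),
                    direction = c("increase", "none", "increase"))
  expect_equal(classify_activation_response(cmp)$call, "no_activation_response")
  expect_equal(classify_activation_response(cmp, require = "any")$call,
               "activation_response")
  cmp$direction[1] <- "decrease"
  expect_equal(classify_activation_response(cmp)$call, "no_activation_response")
  expect_error(classify_activation_response(cmp[cmp$marker == "CD25", ]),
               "CD69")
})

test_that("null flow comparisons reject near the nominal rate", {
  rej <- vapply(1:400, function(i) {
    ctrl <- simulate_flow_summary("S", "control", "none",
                                  seed = 9000 + 2 * i)
    trt <- simulate_flow_summary("S", "treated", "none",
                                 seed = 9001 + 2 * i)
    cmp <- compare_activation(ctrl, trt)
    cmp$p_value[cmp$parent_subset == "CD8" & cmp$marker == "CD25"] <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.025)
  expect_lte(mean(rej), 0.075)
})

test_that("calls are stable under uniform count scaling at large counts", {
  ctrl <- rbind(flow_row("control", "CD8", "CD25", 4000, 400),
                flow_row("control", "CD8", "CD69", 4000, 480))
  trt <- rbind(flow_row("treated", "CD8", "CD25", 4000, 1200),
               flow_row("treated", "CD8", "CD69", 4000, 1400))
  call1 <- classify_activation_response(compare_activation(ctrl, trt))
  ctrl2 <- ctrl; trt2 <- trt
  ctrl2$parent_events <- ctrl$parent_events * 2L
  ctrl2$positive_events <- ctrl$positive_events * 2L
  trt2$parent_events <- trt$parent_events * 2L
  trt2$positive_events <- trt$positive_events * 2L
  call2 <- classify_activation_response(compare_activation(ctrl2, trt2))
  expect_equal(call1$call, call2$call)
})

test_that("the mouse fixture yields the expected activation responders", {
  cohort <- make_study_cohort("mouse", seed = 1)
  res <- run_flow_cohort(cohort)
  expect_equal(nrow(res$calls), 15)
  responders <- res$calls$sample_id[res$calls$call == "activation_response"]
  expect_setequal(responders,
                  c("M2", "M3", "M4", "M5", "M8", "M9", "M14", "M15"))
})
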