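test_that("paired t matches the textbook formula and handles degenerate input", {
  set.seed(41)
  pre <- rnorm(12, 5); post <- pre + rnorm(12, 0.3)
  res <- paired_t(pre, post)
  d <- pre - post
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(12)))
  expect_equal(res$df, 11)
  expect_equal(res$p, 2 * pt(abs(res$statistic), 11, lower.tail = FALSE))

  # identical conditions: t = 0, p = 1 by convention
  same <- paired_t(pre, pre)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # constant nonzero difference: undefined statistic
  expect_error(paired_t(c(1, 2, 3, 4), c(2, 3, 4, 5)), "zero variance")
  expect_error(paired_t(1:2, 2:3), "at least 3")
})

test_that("interaction F equals the squared difference-score t and aov", {
  set.seed(42)
  rec <- make_records(n1 = 10, n2 = 8, effect1 = -1, effect2 = 1)
  res <- rm_anova_interaction(rec)

  # difference-score identity
  wide <- reshape(rec, direction = "wide", idvar = c("subject_id", "group"),
                  timevar = "condition")
  d <- wide$value.sleep_deprived - wide$value.routine
  tt <- t.test(d ~ factor(wide$group, c("patient", "control")),
               var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$df2, 16)

  # full repeated-measures aov oracle
  rec$subject_id <- factor(rec$subject_id)
  rec$group <- factor(rec$group)
  rec$condition <- factor(rec$condition)
  fit <- summary(aov(value ~ group * condition + Error(subject_id / condition),
                     data = rec))
  tab <- fit[["Error: subject_id:condition"]][[1]]
  expect_equal(res$statistic, tab["group:condition", "F value"],
               tolerance = 1e-8)
  expect_equal(res$p, tab["group:condition", "Pr(>F)"], tolerance = 1e-8)
})

test_that("a parallel condition shift produces a near-zero interaction", {
  set.seed(43)
  rec <- make_records(n1 = 30, n2 = 30, effect1 = 2, effect2 = 2)
  res <- rm_anova_interaction(rec)
  expect_gt(res$p, 0.05)

  # exactly parallel shift: F identically 0
  ids <- sprintf("s%02d", 1:8)
  rec0 <- rbind(
    data.frame(subject_id = ids, group = rep(c("patient", "control"), 4),
               condition = "routine", value = rnorm(8)),
    data.frame(subject_id = ids, group = rep(c("patient", "control"), 4),
               condition = "sleep_deprived", value = NA))
  rec0$value[9:16] <- rec0$value[1:8] + 3
  expect_equal(rm_anova_interaction(rec0)$statistic, 0)
})

test_that("missing conditions and tiny groups are rejected", {
  rec <- make_records(4, 4)
  expect_error(rm_anova_interaction(rec[-1, ]), "both conditions")
  one <- make_records(4, 4)
  one <- one[one$group == "patient" | one$subject_id == "C01", ]
  expect_error(rm_anova_interaction(one), "2 subjects per group")
})

test_that("permuted group labels reject at the nominal rate", {
  set.seed(44)
  rec <- make_records(n1 = 21, n2 = 17)  # null: no group difference
  wide <- reshape(rec, direction = "wide", idvar = c("subject_id", "group"),
                  timevar = "condition")
  d <- wide$value.sleep_deprived - wide$value.routine
  n <- length(d)
  hits <- replicate(1000, {
    g <- sample(rep(c("patient", "control"), c(21, 17)))
    d1 <- d[g == "patient"]; d2 <- d[g == "control"]
    sp2 <- ((20) * var(d1) + (16) * var(d2)) / (n - 2)
    f <- ((mean(d1) - mean(d2))^2) / (sp2 * (1 / 21 + 1 / 17))
    pf(f, 1, n - 2, lower.tail = FALSE) < 0.05
  })
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})

test_that("Benjamini-Hochberg flags follow the step-up rule per band", {
  res <- data.frame(band = "alpha", p = c(0.001, 0.8, 0.9, 0.95),
                    measure = letters[1:4])
  out <- fdr_correct(res)
  expect_equal(out$fdr_significant, c(TRUE, FALSE, FALSE, FALSE))

  res1 <- data.frame(band = "alpha", p = rep(1, 4))
  expect_false(any(fdr_correct(res1)$fdr_significant))

  res2 <- data.frame(band = "alpha", p = rep(0.01, 4))
  expect_true(all(fdr_correct(res2)$fdr_significant))

  # families are separate per band
  res3 <- data.frame(band = c(rep("alpha", 4), rep("beta", 2)),
                     p = c(0.04, 0.04, 0.04, 0.04, 0.04, 0.9))
  out3 <- fdr_correct(res3)
  expect_true(all(out3$fdr_significant[1:4]))
  expect_false(out3$fdr_significant[5])  # 0.04 > 0.05 * 1/2 in its family
})

test_that("BH flags are monotone in p within a family", {
  set.seed(45)
  for (rep in 1:20) {
    res <- data.frame(band = "alpha", p = runif(8))
    out <- fdr_correct(res)
    o <- order(out$p)
    flags <- out$fdr_significant[o]
    expect_true(all(diff(as.integer(flags)) <= 0))
  }
})

test_that("report tables carry the full schema on both cohort scopes", {
  set.seed(46)
  meas <- list()
  for (m in c("path_length", "clustering_coefficient", "diameter",
              "leaf_number")) {
    for (b in c("alpha", "beta")) {
      r <- make_records(6, 6, effect1 = ifelse(m == "leaf_number", -2, 0),
                        effect2 = ifelse(m == "leaf_number", 2, 0))
      r$band <- b; r$measure <- m
      meas[[paste(m, b)]] <- r
    }
  }
  meas <- do.call(rbind, meas)
  meas$added_value <- meas$group == "patient" &
    meas$subject_id %in% c("P01", "P02", "P03", "P04")
  tabs <- build_tables(meas)
  expect_named(tabs, c("paired_patients", "paired_controls", "interaction"))
  expect_equal(nrow(tabs$paired_patients), 8L)  # 4 measures x 2 bands
  expect_equal(nrow(tabs$interaction), 16L)     # x 2 scopes
  expect_setequal(unique(tabs$interaction$scope), c("all", "added_value"))
  expect_true(all(c("statistic", "p", "p_adj", "fdr_significant") %in%
                    names(tabs$interaction)))

  # no added-value patients: subset scope omitted with a warning
  meas$added_value <- FALSE
  expect_warning(tabs0 <- build_tables(meas), "no added-value")
  expect_setequal(unique(tabs0$interaction$scope), "all")
})
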