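test_that("median regression recovers a planted slope and scales coefficients", {
  set.seed(27)
  n <- 200
  axes <- matrix(c(rnorm(n), rnorm(n), rnorm(n)), n,
                 dimnames = list(paste0("S", 1:n), paste0("PCo", 1:3)))
  age <- rnorm(n, 35, 8)
  md <- data.frame(age = age,
                   y = 1 + 2 * axes[, 1] + 0 * age + rnorm(n),
                   row.names = rownames(axes))
  qa <- quantileAssoc(md, axes, "y", nAxes = 3)
  b1 <- qa[qa$axis == "PCo1", ]
  expect_gte(b1$beta, 1.8); expect_lte(b1$beta, 2.2)
  expect_lte(b1$p, 0.001)
  # RC scalings are exact arithmetic on the axis summaries
  expect_equal(b1$rc_range, b1$beta * diff(range(axes[, 1])))
  expect_equal(b1$rc_sd, b1$beta * sd(axes[, 1]))
  expect_true(all(sign(qa$rc_range) == sign(qa$beta), na.rm = TRUE))
  expect_true(all(qa$p_adj >= qa$p - 1e-12, na.rm = TRUE))
  # constant outcome: zero slope, p ~ 1
  md$flat <- 5
  qf <- quantileAssoc(md, axes, "flat", nAxes = 1)
  expect_equal(qf$beta, 0)
  expect_equal(qf$p, 1)
})

test_that("RC scalings are invariant to axis rescaling", {
  set.seed(28)
  n <- 120
  axes <- matrix(rnorm(n), n, 1, dimnames = list(paste0("S", 1:n), "PCo1"))
  md <- data.frame(age = rnorm(n, 35, 8), row.names = rownames(axes))
  md$y <- 3 * axes[, 1] + rnorm(n)
  q1 <- quantileAssoc(md, axes, "y", nAxes = 1)
  q2 <- quantileAssoc(md, axes * 10, "y", nAxes = 1)
  expect_equal(q1$rc_range, q2$rc_range, tolerance = 1e-4)
  expect_equal(q1$rc_sd, q2$rc_sd, tolerance = 1e-4)
  expect_equal(q1$beta, 10 * q2$beta, tolerance = 1e-4)
})

test_that("rank-score null calibration is near nominal", {
  set.seed(29)
  rej <- 0; B <- 60; n <- 100
  for (i in seq_len(B)) {
    axes <- matrix(rnorm(n), n, 1, dimnames = list(paste0("S", 1:n), "PCo1"))
    md <- data.frame(age = rnorm(n, 35, 8), row.names = rownames(axes))
    md$y <- 17 + 0.05 * md$age + rnorm(n, 0, 3)
    qa <- quantileAssoc(md, axes, "y", nAxes = 1)
    if (qa$p <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / B, 0.0)
  expect_lte(rej / B, 0.15)
})

test_that("Fisher 2xk matches enumeration, degenerates on zero margins", {
  tab <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  res <- fisher2xk(tab)
  expect_equal(res$p, fisherEnum2x2(tab), tolerance = 1e-9)
  expect_equal(res$method, "exact")
  zr <- matrix(c(0, 0, 5, 7), 2, byrow = TRUE)
  expect_equal(fisher2xk(zr)$p, 1)
  expect_error(fisher2xk(matrix(c(1.5, 1, 1, 1), 2)), "integers")
  # 2x2 agreement with the hypergeometric closed form on random tables
  set.seed(30)
  for (i in 1:30) {
    t2 <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisher2xk(t2)$p, fisherEnum2x2(t2), tolerance = 1e-8)
  }
})

test_that("Cramér's V matches closed forms and the printed worked example", {
  expect_equal(cramersV(matrix(c(28, 0, 35, 37), 2)), 0.478, tolerance = 1e-3)
  ind <- outer(c(10, 20), c(3, 7)) / 10
  expect_equal(cramersV(ind), 0, tolerance = 1e-12)
  expect_equal(cramersV(diag(c(9, 13))), 1)
  # equals |phi| for 2x2
  set.seed(31)
  t2 <- matrix(rpois(4, 8) + 1, 2)
  phi <- suppressWarnings(sqrt(chisq.test(t2, correct = FALSE)$statistic / sum(t2)))
  expect_equal(cramersV(t2), unname(phi))
  expect_warning(v0 <- cramersV(matrix(c(0, 0, 1, 2), 2)), "zero margin")
  expect_true(is.na(v0))
})

test_that("clinical indices follow the HOMA-IR and Matsuda definitions", {
  md <- data.frame(fasting_glucose = c(81, 101.25, 90, -1),
                   fasting_insulin = c(3.7, 10, 2.5, 4),
                   glucose_mean = c(NA, NA, 100, NA),
                   insulin_mean = c(NA, NA, 10000 / (90 * 2.5 * 100), NA))
  expect_warning(out <- clinicalIndices(md), "non-positive")
  expect_equal(round(out$homa_ir[1], 2), 0.74)
  expect_equal(out$homa_ir[2], 2.5)
  expect_false(out$insulin_resistant[2])   # strict > 2.5
  expect_true(out$insulin_resistant[out$homa_ir > 2.5][1] %in% TRUE ||
                all(out$homa_ir <= 2.5, na.rm = TRUE))
  expect_true(is.na(out$homa_ir[4]))
  # Matsuda: product of the four terms 1e8 gives exactly 1
  expect_equal(out$matsuda[3], 10000 / sqrt(90 * 2.5 * 100 *
                                              (10000 / (90 * 2.5 * 100))))
  # AUC fallback converts to means by duration
  md2 <- data.frame(fasting_glucose = 90, fasting_insulin = 10,
                    glucose_auc = 12000, insulin_auc = 6000)
  out2 <- clinicalIndices(md2, ogttMinutes = 120)
  expect_equal(out2$matsuda, 10000 / sqrt(90 * 10 * 100 * 50))
})

test_that("YFAS stratification applies the three printed rules to OB only", {
  md <- data.frame(weight_group = factor(c("OB", "OB", "OB", "NW"),
                                         levels = c("NW", "OB")),
                   yfas_symptoms = c(3, 3, 2, 5),
                   yfas_diagnosis = c(TRUE, FALSE, FALSE, FALSE),
                   row.names = paste0("S", 1:4))
  g <- yfasStratify(md)
  expect_equal(as.character(g[1:3]), c("O_DHA", "O_HA", "O_LA"))
  expect_true(is.na(g[4]))
  bad <- md; bad$yfas_diagnosis[3] <- TRUE   # diagnosis with 2 symptoms
  expect_error(yfasStratify(bad), "violates")
})
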