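test_that("time bins are half-open and out-of-range samples are dropped", {
  s <- data.frame(patient_id = "A", time_h = c(8.0, 23.9, 24.0, 7.999, 200),
                  mediator = "IL-6", value = 1:5,
                  censored = FALSE)
  expect_message(b <- assign_time_bins(s, time_grid()), "dropped 1")
  expect_equal(attr(b, "n_dropped"), 1)
  # 8.0 -> [8,16) bin (nominal 12); 23.9 -> [16,24); 24.0 -> [24,60);
  # 7.999 -> [0,8)
  expect_equal(b$time_h[match(c(1, 2, 3, 4), b$value)], c(12, 20, 48, 4))
})

test_that("duplicate draws within a bin are averaged", {
  s <- data.frame(patient_id = "A", time_h = c(10, 14),
                  mediator = "IL-6", value = c(100, 200), censored = FALSE)
  b <- assign_time_bins(s, time_grid())
  expect_equal(nrow(b), 1)
  expect_equal(b$value, 150)
  expect_equal(b$time_h, 12)
})

test_that("time grid validation catches malformed grids", {
  expect_error(time_grid(times = c(4, 2)), "increasing")
  expect_error(time_grid(times = c(4, 12), edges = c(0, 8, 16, 24)), "edges")
  expect_error(time_grid(times = c(10, 12), edges = c(0, 8, 16)), "bin")
})

test_that("cell means and SEM follow the group summary rules", {
  b <- data.frame(patient_id = c("A", "B", "C"), mediator = "IL-6",
                  time_h = c(4, 4, 12), value = c(10, 30, 7))
  g <- factor(c(A = "BD_LT", B = "BD_LT", C = "BD_LT"),
              levels = c("BD_LT", "BD_GE"))
  m <- group_time_means(b, g)
  c4 <- m[m$time_h == 4, ]
  expect_equal(c4$n, 2L)
  expect_equal(c4$mean, 20)
  expect_equal(c4$sem, sd(c(10, 30)) / sqrt(2))
  c12 <- m[m$time_h == 12, ]
  expect_equal(c12$mean, 7)   # single observation: mean = value
  expect_true(is.na(c12$sem)) # ... and SEM missing
})

test_that("noiseless cohort cell means equal the configured 10^mean", {
  cfg <- simulation_config(n_per_group = c(4, 4), log_sd = 0,
                           missing_prob = 0, lod = 0, seed = 20)
  co <- generate_cohort(cfg)
  g <- stratify_by_bd(co$patients)
  m <- group_time_means(assign_time_bins(co$samples), g)
  for (i in c(1, 100, 300)) {
    expect_equal(m$mean[i],
                 10^cfg$group_log_means[m$mediator[i], m$group[i],
                                        as.character(m$time_h[i])])
  }
})

test_that("balanced two-way ANOVA equals the textbook decomposition", {
  vals <- c(1, 3, 2, 4, 3, 5, 4, 6)
  grp <- factor(rep(c("g1", "g2"), each = 4))
  tim <- factor(rep(rep(c("t1", "t2"), each = 2), 2))
  a <- two_way_anova(vals, grp, tim, transform = "raw")
  expect_equal(a$ss, c(8, 2, 0, 8))                     # hand-computed
  expect_equal(a$df, c(1, 1, 1, 4))
  expect_equal(a$F[1], (8 / 1) / (8 / 4))
  expect_equal(a$p[1], pf(4, 1, 4, lower.tail = FALSE))
  # balanced case: effects + residual = total SS
  expect_equal(sum(a$ss), sum((vals - mean(vals))^2))
})

test_that("ANOVA guards reject degenerate inputs", {
  grp <- factor(rep(c("a", "b"), each = 4))
  tim <- factor(rep(c("t1", "t2"), 4))
  expect_error(two_way_anova(rep(5, 8), grp, tim), "zero variance")
  expect_error(two_way_anova(c(-1, 1, 2, 3, 4, 5, 6, 7), grp, tim),
               "positive")
  # empty cell is named
  expect_error(
    two_way_anova(1:6, factor(c("a", "a", "a", "a", "b", "b")),
                  factor(c("t1", "t2", "t1", "t2", "t1", "t1"))),
    "b/t2")
  expect_error(two_way_anova(1:4, factor(c("a", "a", "b", "b")),
                             factor(c("t1", "t2", "t1", "t2"))),
               "degrees of freedom")
})

test_that("Type III ANOVA handles unbalanced cells", {
  set.seed(21)
  n <- c(5, 9, 7, 12, 6, 8)
  grp <- factor(rep(rep(c("g1", "g2"), each = 3), times = n))
  tim <- factor(rep(rep(c("t1", "t2", "t3"), 2), times = n))
  y <- rnorm(sum(n), mean = ifelse(grp == "g2", 1, 0))
  a <- two_way_anova(y, grp, tim, transform = "raw")
  expect_true(all(a$ss >= 0))
  expect_true(all(a$p[1:3] >= 0 & a$p[1:3] <= 1))
  expect_equal(a$df, c(1, 2, 2, sum(n) - 6))
})

test_that("trapezoidal AUC follows the quadrature rules", {
  # constant mean over a spanned interval
  expect_equal(auc_trapezoid(c(0, 6, 24), c(5, 5, 5), c(0, 24)), 120)
  # triangle
  expect_equal(auc_trapezoid(c(0, 10), c(0, 10), c(0, 10)), 50)
  # missing interior point: trapezoid spans the gap
  expect_equal(auc_trapezoid(c(0, 12, 24), c(2, NA, 4), c(0, 24)), 72)
  # random piecewise-linear series equals a fine-grid Riemann sum
  set.seed(22)
  for (i in 1:5) {
    t <- sort(sample(0:200, 8))
    v <- runif(8, 0, 50)
    expect_equal(auc_trapezoid(t, v), riemann_auc(t, v), tolerance = 1e-9)
  }
  expect_error(auc_trapezoid(c(0, 10), c(NA, 3), c(0, 10)), "2 nonmissing")
})

test_that("AUC is additive over abutting intervals and scale-equivariant", {
  t <- c(4, 12, 20)
  v <- c(10, 40, 25)
  expect_equal(auc_trapezoid(t, v, c(0, 12)) + auc_trapezoid(t, v, c(12, 24)),
               auc_trapezoid(t, v, c(0, 24)))
  expect_equal(auc_trapezoid(t, 3 * v, c(0, 24)),
               3 * auc_trapezoid(t, v, c(0, 24)))
})

test_that("fold-change ranking filters, sorts, and breaks ties by name", {
  tbl <- data.frame(mediator = c("M1", "M2", "M3", "M4", "M5"),
                    auc_bd_ge = c(20, 30, 10, 40, 15),
                    auc_bd_lt = c(10, 10, 10, 40, 5),
                    p_group = c(0.01, 0.01, 0.2, 0.001, 0.01))
  r <- fold_change_ranking(tbl, alpha = 0.05)
  expect_equal(r$mediator, c("M2", "M5", "M1", "M4"))  # 3, 3, 2, 1
  expect_equal(r$fold_change, c(3, 3, 2, 1))
  expect_false("M3" %in% r$mediator)    # non-significant mediators excluded
  expect_error(fold_change_ranking(transform(tbl, auc_bd_lt = 0)),
               "denominator")
})

test_that("multiplying concentrations leaves fold changes unchanged", {
  co <- generate_cohort(small_config(seed = 23))
  g <- stratify_by_bd(co$patients)
  m1 <- group_time_means(assign_time_bins(co$samples), g)
  co$samples$value <- co$samples$value * 7
  m2 <- group_time_means(assign_time_bins(co$samples), g)
  a1 <- auc_by_group(m1, c(0, 24))
  a2 <- auc_by_group(m2, c(0, 24))
  expect_equal(a2$auc, 7 * a1$auc)
  f1 <- a1$auc[a1$group == "BD_GE"] / a1$auc[a1$group == "BD_LT"]
  f2 <- a2$auc[a2$group == "BD_GE"] / a2$auc[a2$group == "BD_LT"]
  expect_equal(f1, f2)
})

test_that("a planted 3-fold group effect is detected reliably", {
  # CV = 0.5 on the natural scale -> log10 SD = sqrt(log(1.25))/log(10)
  sd10 <- sqrt(log(1.25)) / log(10)
  lm_arr <- function(times) {
    arr <- array(1.5, dim = c(1, 2, length(times)),
                 dimnames = list("IL-6", c("BD_LT", "BD_GE"),
                                 as.character(times)))
    arr[1, "BD_GE", ] <- 1.5 + log10(3)
    arr
  }
  times <- c(4, 12, 20)
  rejected <- logical(10)
  for (i in seq_along(rejected)) {
    cfg <- simulation_config(n_per_group = c(70, 84), mediators = "IL-6",
                             sampling_times_h = times,
                             group_log_means = lm_arr(times),
                             log_sd = sd10, planted_blocks = list(),
                             missing_prob = 0, lod = 0, seed = 100 + i)
    co <- generate_cohort(cfg)
    g <- stratify_by_bd(co$patients)
    a <- two_way_anova(co$samples$value, g[co$samples$patient_id],
                       co$samples$time_h)
    rejected[i] <- a$p[1] < 0.05
  }
  expect_gt(mean(rejected), 0.9)
})
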