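# build a correlation matrix with given off-diagonal entries
corr_from_edges <- function(nodes, edges, r = 0.9) {
  C <- diag(length(nodes))
  dimnames(C) <- list(nodes, nodes)
  for (e in edges) {
    C[e[1], e[2]] <- r
    C[e[2], e[1]] <- r
  }
  C
}

test_that("window matrices hold per-patient window means on log10 scale", {
  s <- data.frame(patient_id = c("A", "A", "B"),
                  time_h = c(9, 15, 4),
                  mediator = "IL-6",
                  value = c(100, 1000, 50), censored = FALSE)
  w <- analysis_window(8, 16)
  m <- window_patient_matrix(s, w, min_pairs = 1)
  # B has no draw in [8,16) and is absent; A's two draws average on log10
  expect_equal(rownames(m), "A")
  expect_equal(unname(m["A", "IL-6"]), 2.5)
  # a patient with draws only at 4 h is absent from [8,16)
  expect_false("B" %in% rownames(m))
})

test_that("window matrix row count equals patients drawn in-window", {
  co <- generate_cohort(small_config(seed = 24))
  m <- window_patient_matrix(co$samples, analysis_window(0, 8), min_pairs = 2)
  with_4h <- unique(co$samples$patient_id[co$samples$time_h == 4])
  expect_equal(sort(rownames(m)), sort(with_4h))
  expect_equal(ncol(m), 22)
  expect_error(window_patient_matrix(co$samples, analysis_window(300, 308)),
               "insufficient data")
})

test_that("correlation matrix matches brute-force covariance computation", {
  set.seed(25)
  mat <- matrix(rnorm(20 * 6), 20, 6,
                dimnames = list(NULL, paste0("m", 1:6)))
  C <- correlation_matrix(mat, min_pairs = 2)
  expect_equal(unname(diag(C)), rep(1, 6))
  expect_equal(C, t(C))
  for (pair in list(c(1, 2), c(3, 6))) {
    x <- mat[, pair[1]]; y <- mat[, pair[2]]
    brute <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(unname(C[pair[1], pair[2]]), brute, tolerance = 1e-12)
  }
  # exact linear and monotone relations
  mat2 <- cbind(x = 1:15, lin = 2 * (1:15) + 1, cub = (1:15)^3)
  expect_equal(unname(correlation_matrix(mat2, min_pairs = 2)["x", "lin"]), 1)
  expect_equal(
    unname(correlation_matrix(mat2, method = "spearman",
                              min_pairs = 2)["x", "cub"]), 1)
})

test_that("zero-variance columns and thin pairs never form edges", {
  set.seed(26)
  mat <- cbind(matrix(rnorm(40), 20, 2), flat = 5)
  colnames(mat) <- c("a", "b", "flat")
  expect_warning(C <- correlation_matrix(mat, min_pairs = 2), "flat")
  expect_true(all(is.na(C["flat", c("a", "b")])))
  # fewer than min_pairs complete pairs -> NA
  mat2 <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  mat2[1:15, 1] <- NA
  C2 <- correlation_matrix(mat2, min_pairs = 8)
  expect_true(is.na(C2["a", "b"]))
  net <- build_network(C2, threshold = 0.01)
  expect_equal(nrow(net$edges), 0)
})

test_that("edge thresholding is >= and matches an exhaustive double loop", {
  nodes <- paste0("m", 1:4)
  C69 <- corr_from_edges(nodes, list(c(1, 2), c(2, 3)), r = 0.69)
  expect_equal(nrow(build_network(C69)$edges), 0)   # 0.69 < 0.70
  C70 <- corr_from_edges(nodes, list(c(1, 2)), r = 0.70)
  expect_equal(nrow(build_network(C70)$edges), 1)   # boundary is inclusive
  set.seed(27)
  for (i in 1:10) {
    p <- sample(4:10, 1)
    Z <- matrix(rnorm(p * 15), 15, p, dimnames = list(NULL, paste0("m", 1:p)))
    C <- cor(Z)
    for (th in c(0.2, 0.5)) {
      net <- build_network(C, threshold = th)
      expect_equal(sort(paste(net$edges$from, net$edges$to, sep = "|")),
                   edges_double_loop(C, th))
      neta <- build_network(C, threshold = th, mode = "absolute")
      expect_equal(sort(paste(neta$edges$from, neta$edges$to, sep = "|")),
                   edges_double_loop(C, th, absolute = TRUE))
    }
  }
  expect_error(build_network(C69, threshold = 0), "threshold")
  expect_error(build_network(C69, threshold = 1.2), "threshold")
})

test_that("density follows the edge-times-node formula", {
  nodes <- paste0("m", 1:10)
  complete <- corr_from_edges(nodes, combn(10, 2, simplify = FALSE), r = 0.9)
  d <- network_density(build_network(complete))
  expect_equal(d$E, 45)
  expect_equal(d$density, 10)   # complete graphs score N
  # path on 4 nodes: 3 * 4 / 6 = 2
  path4 <- corr_from_edges(paste0("m", 1:4),
                           list(c(1, 2), c(2, 3), c(3, 4)), r = 0.8)
  expect_equal(network_density(build_network(path4))$density, 2)
  # empty network
  empty <- network_density(build_network(corr_from_edges(paste0("m", 1:3),
                                                          list())))
  expect_equal(empty$density, 0)
  # node_rule = "all" counts unconnected mediators too
  one_edge <- corr_from_edges(nodes, list(c(1, 2)), r = 0.9)
  net <- build_network(one_edge)
  expect_equal(network_density(net, "connected")$N, 2)
  expect_equal(network_density(net, "all")$N, 10)
  expect_equal(network_density(net, "all")$density, 1 * 10 / 45)
})

test_that("density is permutation-invariant and monotone in threshold", {
  set.seed(28)
  Z <- matrix(rnorm(12 * 30), 30, 12, dimnames = list(NULL, paste0("m", 1:12)))
  C <- cor(Z)
  net <- build_network(C, threshold = 0.2)
  perm <- sample(12)
  Cp <- C[perm, perm]
  netp <- build_network(Cp, threshold = 0.2)
  for (rule in c("connected", "all")) {
    expect_equal(network_density(netp, rule)$density,
                 network_density(net, rule)$density)
  }
  # raising the threshold never adds an edge
  e_prev <- Inf
  for (th in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    e <- nrow(build_network(C, threshold = th)$edges)
    expect_lte(e, e_prev)
    e_prev <- e
  }
})

test_that("network comparison computes shared, unique, and Jaccard", {
  nodes <- paste0("m", 1:5)
  A <- build_network(corr_from_edges(nodes, list(c(1, 2), c(2, 3))))
  B <- build_network(corr_from_edges(nodes, list(c(2, 3), c(4, 5))))
  cmp <- compare_networks(A, B)
  expect_equal(cmp$shared, "m2|m3")
  expect_equal(cmp$only_a, "m1|m2")
  expect_equal(cmp$only_b, "m4|m5")
  expect_equal(cmp$jaccard, 1 / 3)
  expect_equal(compare_networks(A, A)$jaccard, 1)
  disjointB <- build_network(corr_from_edges(nodes, list(c(3, 4))))
  expect_equal(compare_networks(A, disjointB)$jaccard, 0)
  emptyN <- build_network(corr_from_edges(nodes, list()))
  expect_equal(compare_networks(emptyN, emptyN)$jaccard, 0)  # by convention
  other <- build_network(corr_from_edges(paste0("x", 1:5), list(c(1, 2))))
  expect_error(compare_networks(A, other), "universes")
})

test_that("dyna_run is deterministic and recovers planted structure", {
  cfg <- simulation_config(n_per_group = c(20, 24), missing_prob = 0,
                           seed = 29)
  co <- generate_cohort(cfg)
  g <- stratify_by_bd(co$patients)
  r1 <- dyna_run(co$samples, g)
  r2 <- dyna_run(co$samples, g)
  expect_identical(r1$density, r2$density)
  expect_equal(nrow(r1$density), 6)  # 2 groups x 3 windows
  d <- r1$density
  ge <- d[d$group == "BD_GE", ]
  lt <- d[d$group == "BD_LT", ]
  # the default rho = 0.85 block lives in BD_GE windows [0,8) and [8,16)
  expect_gt(ge$density[ge$window == "0-8 h"], lt$density[lt$window == "0-8 h"])
  expect_gt(ge$density[ge$window == "8-16 h"],
            lt$density[lt$window == "8-16 h"])
})
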