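test_that("simple Mantel statistic and p behave at the boundaries", {
  dx <- random_dist(8, 1)
  r <- mantel_test(dx, dx, n_perm = 99, seed = 1)
  expect_equal(r$r, 1)
  expect_equal(r$p, 1 / 100)                 # (0 + 1)/(99 + 1)
  # affine invariance: dy = a + b dx, b > 0
  dy <- unclass(dx) * 2.5; dy[dy > 0] <- dy[dy > 0] + 1; diag(dy) <- 0
  expect_equal(mantel_test(dx, dist_matrix(dy), n_perm = 9, seed = 1)$r, 1)
  # constant distances rejected
  ids5 <- paste0("s", 1:5)
  cm <- matrix(1, 5, 5, dimnames = list(ids5, ids5))
  diag(cm) <- 0
  expect_error(mantel_test(dist_matrix(cm), random_dist(5, 2)), "constant")
  expect_error(mantel_test(random_dist(3, 1), random_dist(3, 1)), ">= 4")
})

test_that("Mantel r equals an independent flat-vector Pearson oracle", {
  for (s in 1:6) {
    dx <- random_dist(7, s); dy <- random_dist(7, s + 100)
    xv <- unclass(dx)[lower.tri(unclass(dx))]
    yv <- unclass(dy)[lower.tri(unclass(dy))]
    # explicit sum-formula Pearson, no cor()
    n <- length(xv)
    num <- sum(xv * yv) - n * mean(xv) * mean(yv)
    den <- sqrt((sum(xv^2) - n * mean(xv)^2) * (sum(yv^2) - n * mean(yv)^2))
    expect_equal(mantel_test(dx, dy, n_perm = 0)$r, num / den,
                 tolerance = 1e-12)
    # vegan agreement (independent implementation)
    v <- suppressWarnings(suppressMessages(
      vegan::mantel(as.dist(unclass(dx)), as.dist(unclass(dy)),
                    permutations = 0)))
    expect_equal(mantel_test(dx, dy, n_perm = 0)$r, unname(v$statistic),
                 tolerance = 1e-10)
  }
})

test_that("Mantel results are invariant to input row order", {
  dx <- random_dist(9, 3); dy <- random_dist(9, 103)
  r1 <- mantel_test(dx, dy, n_perm = 199, seed = 11)
  perm <- sample(9)
  dy_shuf <- dist_matrix(unclass(dy)[perm, perm])
  r2 <- mantel_test(dx, dy_shuf, n_perm = 199, seed = 11)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_equal(r1$p, r2$p)
})

test_that("partial Mantel matches the residual-regression oracle", {
  for (s in 1:10) {
    n <- sample(6:10, 1)
    dx <- random_dist(n, s); dy <- random_dist(n, s + 50)
    dz <- random_dist(n, s + 90)
    pr <- partial_mantel(dx, dy, dz, n_perm = 0)$partial_r
    lt <- lower.tri(unclass(dx))
    xv <- unclass(dx)[lt]; yv <- unclass(dy)[lt]; zv <- unclass(dz)[lt]
    oracle <- cor(resid(lm(xv ~ zv)), resid(lm(yv ~ zv)))
    expect_equal(pr, oracle, tolerance = 1e-10)
  }
})

test_that("partial Mantel limiting cases", {
  dx <- random_dist(8, 7)
  # dz = tiny independent noise, dy = dx -> reduces to simple Mantel (r ~ 1)
  set.seed(1)
  noise <- matrix(rnorm(16), 8, 2,
                  dimnames = list(rownames(unclass(dx)), NULL))
  dz <- dist_matrix(dist(noise))
  r <- partial_mantel(dx, dx, dz, n_perm = 99, seed = 1)
  expect_gt(r$partial_r, 0.99)
  expect_equal(r$p, 1 / 100)
  # constructed orthogonality: r_xy = r_xz * r_yz = 0 -> partial_r exactly 0
  base <- matrix(2, 4, 4); diag(base) <- 0
  ids <- letters[1:4]
  mk <- function(v) {
    m <- base; m[lower.tri(m)] <- 2 + v; m <- t(m); m[lower.tri(m)] <- 2 + v
    dimnames(m) <- list(ids, ids); dist_matrix(m)
  }
  # u orthogonal to v, w orthogonal to v, u correlated with w:
  # r_xy = 0 = r_xz * r_yz with r_xz != 0
  u <- c(2, 1, -1, -2, 0, 0); w <- c(1, 1, -1, -1, 0, 0)
  v <- c(0, 0, 0, 0, 1, -1)
  expect_equal(partial_mantel(mk(u), mk(v), mk(w), n_perm = 0)$partial_r, 0,
               tolerance = 1e-12)
  # collinear covariate rejected
  expect_error(partial_mantel(dx, random_dist(8, 8), dx, n_perm = 0),
               "collinear")
})

test_that("classifier covers all significance patterns exactly", {
  fake <- function(p) structure(list(r = 0.5, p = p, n_perm = 999,
                                     kind = "partial", partial_r = 0.4,
                                     n_samples = 10),
                                class = "mantel_result")
  pat <- expand.grid(es = c(0.01, 0.4), se = c(0.02, 0.7))
  labels <- mapply(function(es, se) {
    classify_metacommunity(fake(0.01), fake(0.01), fake(es), fake(se))$label
  }, pat$es, pat$se)
  expect_equal(labels, c("SS+ME", "NM/PD", "SS", "UD"))
  # alpha boundary: p == alpha counts as significant
  expect_equal(classify_metacommunity(fake(0.5), fake(0.5), fake(0.05),
                                      fake(0.5))$label, "SS")
  # NF propagates
  expect_equal(classify_metacommunity(nf_marker("x"), fake(0.5), fake(0.5),
                                      fake(0.5))$label, "NF")
  # mismatched sample sets rejected
  bad <- fake(0.01); bad$n_samples <- 12
  expect_error(classify_metacommunity(fake(0.1), fake(0.1), fake(0.1), bad),
               "mismatched")
})

test_that("battery enumerates the month x group grid and applies NF rules", {
  sim <- simulate_metacommunity(scenario_config(
    n_otus = 80, depth = 400, n_stations = 5,
    months = default_months()[1:3], seed = 5))
  b <- mantel_battery(sim$otu, sim$metadata, n_perm = 49, seed = 1,
                      min_samples = 4)
  expect_equal(nrow(b$manifest), (1 + 3) * (1 + 7))
  expect_equal(sum(b$manifest$month != "All" & b$manifest$group != "All"),
               3 * 7)
  expect_true(all(b$results$label[b$manifest$status == "NF"] == "NF"))
  # all x all cell is computable and classified
  allcell <- b$results[b$results$month == "All" & b$results$group == "All", ]
  expect_true(allcell$label %in% c("SS", "SS+ME", "NM/PD", "UD"))
  expect_true(all(na.omit(c(abs(b$results$r_E), abs(b$results$r_S))) <= 1))
  # a month with < min_samples samples emits NF
  sim2 <- simulate_metacommunity(scenario_config(
    n_otus = 40, depth = 300, n_stations = 3,
    months = default_months()[1:2], seed = 6))
  b2 <- mantel_battery(sim2$otu, sim2$metadata, n_perm = 19, seed = 1,
                       min_samples = 4)
  mcells <- b2$manifest[b2$manifest$month != "All" &
                          b2$manifest$group == "All", ]
  expect_true(all(mcells$status == "NF"))
})
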