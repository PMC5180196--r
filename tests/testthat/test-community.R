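test_that("rarefy keeps depth exactly, drops shallow samples, is seeded", {
  t <- toy_table()  # row sums 10, 10, 10
  r <- rarefy(t, 10, seed = 7)
  expect_identical(r$counts, t$counts)  # subsample of all reads
  r5 <- rarefy(t, 5, seed = 7)
  expect_true(all(rowSums(r5$counts) == 5))
  expect_identical(rarefy(t, 5, seed = 7)$counts, r5$counts)  # bit-identical
  expect_false(identical(rarefy(t, 5, seed = 8)$counts, r5$counts))
  # sample below depth is dropped with a message
  cnt <- toy_counts(); cnt["s2", ] <- c(1L, 0L, 0L, 1L)
  expect_message(r2 <- rarefy(otu_table(cnt), 5, seed = 1), "s2")
  expect_false("s2" %in% sample_ids(r2))
  expect_error(rarefy(otu_table(cnt), 1000, seed = 1), "no samples survive")
})

test_that("rarefaction subsampling is hypergeometric", {
  # one sample {A:6, B:4}, depth 5: support of A is {1..5},
  # E[A] = 5 * 6/10 = 3
  cnt <- matrix(c(6L, 4L), 1, 2, dimnames = list("s", c("A", "B")))
  draws <- vapply(seq_len(10000), function(s) {
    rarefy(otu_table(cnt), 5, seed = s)$counts[1, "A"]
  }, integer(1))
  expect_true(all(draws >= 1 & draws <= 5))
  expect_equal(mean(draws), 3, tolerance = 0.05 / 3)
  # single-OTU sample: {A:10, B:0} at depth 5 -> A = 5, B pruned
  cnt2 <- matrix(c(10L, 0L), 1, 2, dimnames = list("s", c("A", "B")))
  r <- rarefy(otu_table(cnt2), 5, seed = 1)
  expect_identical(r$counts, matrix(5L, 1, 1, dimnames = list("s", "A")))
})

test_that("relative abundance rows sum to one", {
  cnt <- matrix(c(1L, 1L, 2L, 2500L, 0L, 0L), 2, 3, byrow = TRUE,
                dimnames = list(c("a", "b"), c("x", "y", "z")))
  ra <- relative_abundance(otu_table(cnt))
  expect_equal(ra["a", ], c(x = 0.25, y = 0.25, z = 0.5))
  expect_equal(ra["b", ], c(x = 1, y = 0, z = 0))
  expect_equal(unname(rowSums(ra)), c(1, 1), tolerance = 1e-12)
  cnt[2, ] <- 0L
  expect_error(relative_abundance(otu_table(cnt)), "zero-sum")
  # per-OTU mean relative abundance matches hand computation
  m <- matrix(c(2L, 2L, 0L, 1L, 1L, 2L, 0L, 3L, 3L), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("x", "y", "z")))
  expect_equal(unname(100 * colMeans(relative_abundance(otu_table(m)))),
               100 * c(mean(c(2/4, 1/4, 0/6)), mean(c(2/4, 1/4, 3/6)),
                       mean(c(0/4, 2/4, 3/6))))
})

test_that("taxon subsetting partitions the table and flags absent labels", {
  t <- toy_table()
  cy <- subset_by_taxon(t, "Cyanobacteria")
  expect_equal(otu_ids(cy), c("otu1", "otu3"))
  expect_true(is_nf(subset_by_taxon(t, "Euryarchaeota")))
  # the 7 groups + Unclassified cover a simulated table exactly once
  sim <- simulate_metacommunity(scenario_config(n_otus = 60, depth = 300,
                                                n_stations = 4,
                                                months = default_months()[1:2],
                                                seed = 3))
  hits <- lapply(c(default_taxon_groups(), "Unclassified"), function(g) {
    s <- subset_by_taxon(sim$otu, g)
    if (is_nf(s)) character(0) else otu_ids(s)
  })
  expect_setequal(unlist(hits), otu_ids(sim$otu))
  expect_equal(sum(lengths(hits)), length(otu_ids(sim$otu)))
})

test_that("Bray-Curtis matches the formula and a brute-force oracle", {
  m <- matrix(c(1L, 2L, 3L, 3L, 2L, 1L, 1L, 2L, 3L), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("x", "y", "z")))
  d <- bray_curtis(otu_table(m))
  expect_equal(d["a", "b"], 1 / 3)         # (2+0+2)/12
  expect_equal(d["a", "c"], 0)             # identical rows
  disj <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
                 dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(bray_curtis(otu_table(disj))["a", "b"], 1)
  # random tables vs the double-loop oracle; bounds; reorder invariance
  for (s in 1:5) {
    set.seed(s)
    rm_ <- matrix(rpois(60, 4), 6, 10,
                  dimnames = list(paste0("s", 1:6), paste0("o", 1:10)))
    rm_[1, ] <- rm_[1, ] + 1L  # guard against all-zero rows
    storage.mode(rm_) <- "integer"
    d1 <- bray_curtis(otu_table(rm_))
    expect_equal(unclass(d1), bray_oracle(rm_), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(d1 >= 0 & d1 <= 1))
    perm <- sample(6)
    d2 <- bray_curtis(otu_table(rm_[perm, , drop = FALSE]))
    expect_equal(unclass(d2[rownames(d1), rownames(d1)]), unclass(d1),
                 tolerance = 1e-12)
  }
  two_zero <- matrix(c(0L, 0L, 1L, 0L, 0L, 2L), 3, 2,
                     dimnames = list(c("a", "b", "c"), c("x", "y")))
  expect_error(bray_curtis(otu_table(two_zero)), "all-zero")
})

test_that("environmental distance z-scores variables and checks variance", {
  md <- toy_metadata(4)
  # hand-computed: z-score then Euclidean over two variables
  x <- cbind(md$salinity, md$temperature)
  z <- apply(x, 2, function(v) (v - mean(v)) / sd(v))
  expect_d <- sqrt(sum((z[1, ] - z[3, ])^2))
  d <- env_distance(md, c("salinity", "temperature"))
  expect_equal(d["s01", "s03"], expect_d, tolerance = 1e-12)
  # identical samples -> 0 (duplicate a row via zero variance trick avoided)
  df <- as.data.frame(md); df[2, -1] <- df[1, -1]; df$month <- "May"
  md2 <- sample_metadata(df, env_variables(md))
  expect_equal(env_distance(md2)["s01", "s02"], 0)
  # unstandardized single variable: |0 - 3| = 3
  df3 <- as.data.frame(md)[1:2, ]; df3$salinity <- c(0, 3)
  md3 <- sample_metadata(df3, env_variables(md))
  expect_equal(env_distance(md3, "salinity", standardize = FALSE)[1, 2], 3)
  # zero-variance variable named in error
  df4 <- as.data.frame(md); df4$po4 <- 1
  expect_error(env_distance(sample_metadata(df4, env_variables(md))), "po4")
})

test_that("spatial distance supports flat-degrees and great-circle modes", {
  df <- toy_metadata(2)
  df$latitude <- c(0, 3); df$longitude <- c(0, 4)
  md <- sample_metadata(as.data.frame(df), env_variables(df))
  expect_equal(spatial_distance(md)["s01", "s02"], 5)
  df$latitude <- c(0, 0); df$longitude <- c(0, 90)
  md2 <- sample_metadata(as.data.frame(df), env_variables(df))
  expect_equal(spatial_distance(md2, "great-circle")["s01", "s02"],
               6371 * pi / 2, tolerance = 1e-9)
  expect_equal(spatial_distance(md2)["s01", "s01"], 0)
})

test_that("occupancy is the detected-sample fraction", {
  t <- toy_table()
  expect_equal(unname(occupancy(t)), c(1, 2 / 3, 2 / 3, 1))
  expect_equal(round(100 * 31 / 63, 1), 49.2)  # reporting convention
})
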