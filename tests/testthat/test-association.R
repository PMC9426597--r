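test_that("bile-acid ratio follows its definition and homogeneity", {
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     CA = c(1, 2, 0), CDCA = c(1, 2, 0),
                     DCA = c(1, 1, 1), LCA = c(1, 1, 1))
  r <- suppressMessages(ba_ratio(meta))
  expect_equal(unname(r[1:2]), c(1, 0.5))
  expect_true(is.na(r[3])) # zero denominator excluded

  scaled <- meta
  scaled[, c("CA", "CDCA", "DCA", "LCA")] <-
    meta[, c("CA", "CDCA", "DCA", "LCA")] * 7
  expect_equal(suppressMessages(ba_ratio(scaled))[1:2], r[1:2])

  expect_error(ba_ratio(meta[, 1:3]), "lacks bile-acid")
})

test_that("group comparison matches exact enumeration and is scale-free", {
  prof <- data.frame(sample_id = sprintf("s%d", 1:6),
                     cluster_id = "1",
                     cpm = c(10, 11, 12, 1, 2, 3))
  meta <- data.frame(sample_id = sprintf("s%d", 1:6),
                     group = rep(c("healthy", "CD"), each = 3))
  cmp <- compare_groups(prof, meta, "1")
  expect_equal(cmp$p_value, 0.1) # all-greater 3v3, two-sided exact
  expect_equal(cmp$direction, "a>b")
  expect_equal(cmp$stars, "")
  expect_equal(cmp$n_a, 3)

  prof2 <- prof; prof2$cpm <- prof$cpm * 1e4
  cmp2 <- compare_groups(prof2, meta, "1")
  expect_equal(cmp2$p_value, cmp$p_value)
  expect_equal(cmp2$u_statistic, cmp$u_statistic)

  # planted location shift: strong, correctly signed evidence
  set.seed(12)
  n <- 50
  prof3 <- data.frame(sample_id = sprintf("t%03d", 1:(2 * n)),
                      cluster_id = "1",
                      cpm = exp(c(rnorm(n, 2), rnorm(n, 1))))
  meta3 <- data.frame(sample_id = prof3$sample_id,
                      group = rep(c("healthy", "LC"), each = n))
  cmp3 <- compare_groups(prof3, meta3, "1")
  expect_lt(cmp3$p_value, 0.001)
  expect_equal(cmp3$stars, "***")
  expect_equal(cmp3$direction, "a>b")

  expect_error(compare_groups(prof, meta[meta$group != "healthy", ], "1"),
               "reference group absent")
  expect_warning(compare_groups(prof[-1, ], meta, "1"), "fewer than 3")
})

test_that("group test holds its nominal size under the null", {
  set.seed(20)
  n_rep <- 500
  rej <- vapply(seq_len(n_rep), function(i) {
    prof <- data.frame(sample_id = sprintf("u%02d", 1:30),
                       cluster_id = "1", cpm = exp(rnorm(30)))
    meta <- data.frame(sample_id = prof$sample_id,
                       group = sample(rep(c("healthy", "CD"), each = 15)))
    compare_groups(prof, meta, "1")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("spearman matches the rank-definition oracle and cor.test", {
  mono <- spearman_cor(1:10, (1:10)^3)
  expect_equal(mono$rho, 1)
  expect_equal(mono$p_value, 0)
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 2, 1))$rho, -1)

  set.seed(30)
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(8)
    got <- spearman_cor(x, y, label = "c")
    expect_equal(got$rho, brute_spearman(x, y))
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    expect_equal(got$rho, unname(ct$estimate))
  }

  # invariance under strictly monotone transforms
  x <- rexp(20); y <- rnorm(20)
  expect_equal(spearman_cor(exp(x), y)$rho, spearman_cor(x, y)$rho)
  expect_equal(spearman_cor(x, y^3)$rho,
               spearman_cor(x, sign(y) * abs(y)^3)$rho)

  expect_warning(z <- spearman_cor(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(is.na(z$rho))
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("correlation table reports per-cluster and pooled results", {
  set.seed(40)
  n <- 30
  sim <- simulate_metadata(exp(rnorm(n, 3)), rho_target = 0.9, seed = 41)
  prof <- data.frame(sample_id = rep(sim$metadata$sample_id, 2),
                     cluster_id = rep(c("1", "2"), each = n),
                     cpm = c(unname(sim$abundance), exp(rnorm(n))))
  tab <- correlate_ba(prof, sim$metadata)
  expect_setequal(tab$cluster_id, c("1", "2", "all"))
  expect_gt(tab$rho[tab$cluster_id == "1"], 0.6)
  expect_equal(tab$n, rep(n, 3))
})

test_that("association plots return well-formed ggplot objects", {
  set.seed(50)
  n <- 20
  sim <- simulate_metadata(exp(rnorm(n, 3)), rho_target = 0.5, seed = 51)
  prof <- data.frame(sample_id = sim$metadata$sample_id,
                     cluster_id = "1", cpm = unname(sim$abundance))
  bx <- plot_abundance_box(prof, sim$metadata, "1")
  expect_s3_class(bx, "ggplot")
  sc <- plot_ba_scatter(setNames(prof$cpm, prof$sample_id), sim$metadata, "1")
  expect_s3_class(sc, "ggplot")
  # both render without error
  tf <- withr::local_tempfile(fileext = ".png")
  suppressMessages(ggplot2::ggsave(tf, bx, width = 4, height = 3, dpi = 72))
  expect_true(file.exists(tf))
})
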