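test_that("the marginal-product null probability follows its closed form", {
  expect_equal(expected_link_probability(10, 10, 10), 1)
  expect_equal(expected_link_probability(0, 5, 10), 0)
  # marginal inputs at the scale of the motivating synthesis
  expect_equal(expected_link_probability(177, 734, 2636),
               (177 / 2636) * (734 / 2636), tolerance = 1e-15)
  expect_error(expected_link_probability(1, 1, 0),
               class = "moalink_validation_error")
  expect_error(expected_link_probability(11, 5, 10),
               class = "moalink_validation_error")
})

test_that("the exact upper tail matches direct summation", {
  expect_equal(binom_upper_tail(0, 50, 0.1), 1)
  expect_equal(binom_upper_tail(1, 1, 0.5), 0.5)
  expect_equal(binom_upper_tail(5, 20, 0.1), bf_binom_upper(5, 20, 0.1),
               tolerance = 1e-12)
  expect_error(binom_upper_tail(5, 4, 0.1),
               class = "moalink_validation_error")
  expect_error(binom_upper_tail(1, 4, 1.5),
               class = "moalink_validation_error")
})

test_that("the upper tail is nonincreasing in k and exact on a small grid", {
  for (p0 in c(0.01, 0.2, 0.5, 0.9)) {
    for (n in c(1, 7, 25)) {
      p <- binom_upper_tail(0:n, n, p0)
      expect_true(all(diff(p) <= 1e-15))
      oracle <- vapply(0:n, bf_binom_upper, numeric(1), n = n, p = p0)
      expect_equal(p, oracle, tolerance = 1e-12)
    }
  }
})

test_that("test_links computes one result per nonzero cell from its own marginals", {
  # degenerate saturation: the only link is certain under its own null
  fit <- test_links(toy_links("a1", "1.1", "14"))
  expect_equal(fit$results$p0, 1)
  expect_equal(fit$results$p, 1)
  expect_false(fit$results$significant)

  # two independent cells: p0 = 1/4 each, p = 1 - (3/4)^2
  fit <- test_links(toy_links("a1", c("1.1", "1.2"), c("14", "4")))
  expect_equal(fit$results$p0, c(0.25, 0.25))
  expect_equal(fit$results$p, c(0.4375, 0.4375))
  expect_equal(fit$results$expected_count, fit$results$p0 * fit$n_total)

  # empty input -> empty result set
  fit0 <- test_links(toy_links(character(), character(), character()))
  expect_equal(nrow(fit0$results), 0L)
})

test_that("results are invariant to statement order", {
  set.seed(5)
  links <- random_links(n_statements = 30)
  fit1 <- tidy(test_links(links))
  shuffled <- links[sample(nrow(links)), ]
  fit2 <- tidy(test_links(shuffled))
  expect_equal(dplyr::arrange(fit1, bct_code, moa_id),
               dplyr::arrange(fit2, bct_code, moa_id))
})

test_that("a strongly planted link is flagged significant", {
  grid <- uniform_grid(6, 4)
  prop <- plant_links(grid$codes, grid$ids,
                      tibble::tibble(bct_code = grid$codes[2], moa_id = "3",
                                     multiplier = 5))
  sim <- simulate_corpus(n_articles = 150, mean_links = 5, sd_links = 4,
                         bct_weights = grid$bct_weights,
                         moa_weights = grid$moa_weights,
                         propensity = prop, other_rate = 0, seed = 404)
  fit <- test_links(sim$corpus)
  planted <- fit$results[fit$results$bct_code == grid$codes[2] &
                           fit$results$moa_id == "3", ]
  expect_gte(planted$expected_count, 20)
  expect_true(planted$significant)
})

test_that("grouping significant results by BCT and by MoA yields identical link sets", {
  sim <- simulate_corpus(n_articles = 60, seed = 2024)
  fit <- test_links(sim$corpus)
  t1 <- table1_view(fit)
  t2 <- table2_view(fit)
  key <- function(v) sort(paste(v$bct_code, v$moa_id))
  expect_equal(key(t1), key(t2))
  expect_equal(nrow(t1), sum(fit$results$significant))
  # label columns come from the registries
  expect_false(anyNA(t1$bct_label))
  expect_false(anyNA(t1$moa_label))
  # table1 sorted by code then p; table2 by id then p
  expect_true(!is.unsorted(t1$bct_code))
  expect_true(!is.unsorted(t2$moa_id))
})

test_that("the BH adjustment flags a subset of the raw criterion", {
  sim <- simulate_corpus(n_articles = 80, seed = 77)
  raw <- test_links(sim$corpus, adjust = "none")
  bh <- test_links(sim$corpus, adjust = "BH")
  raw_set <- with(raw$results, paste(bct_code, moa_id)[significant])
  bh_set <- with(bh$results, paste(bct_code, moa_id)[significant])
  expect_true(all(bh_set %in% raw_set))
  expect_true(all(bh$results$p_adjusted >= bh$results$p - 1e-15))
})

test_that("summarize_significant reduces a link set to its headline statistics", {
  rows <- tibble::tibble(
    bct_code = c("1.1", "1.1", "2.2", "3.1"),
    moa_id = c(1L, 4L, 4L, 4L))
  s <- summarize_significant(rows)
  expect_equal(s$n_links, 4L)
  expect_equal(s$n_bcts, 3L)
  expect_equal(s$n_moas, 2L)
  expect_equal(s$mean_moas_per_bct, 1.33)
  expect_equal(s$max_moas_per_bct, 2L)
  expect_equal(s$mean_bcts_per_moa, 2)
  expect_equal(s$max_bcts_per_moa, 3L)

  s0 <- summarize_significant(rows[0, ])
  expect_equal(s0$n_links, 0L)
  expect_equal(s0$pct_bct_coverage, 0)
})

test_that("tidy, glance and the CSV export expose the fitted object", {
  sim <- simulate_corpus(n_articles = 40, seed = 15)
  fit <- test_links(sim$corpus)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("bct_code", "moa_id", "k", "p0", "expected_count", "p",
                    "significant") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_tested, nrow(td))
  expect_equal(gl$n_significant, sum(td$significant))
  expect_equal(gl$alpha, 0.05)

  f <- withr::local_tempfile(fileext = ".csv")
  write_test_results(fit, f, view = "all")
  out <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(out), nrow(td))
  expect_true(all(c("bct_label", "moa_label") %in% names(out)))
})
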