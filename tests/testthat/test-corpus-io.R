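write_tables <- function(dir, source_rows, bct_rows, link_rows) {
  source_path <- file.path(dir, "source.csv")
  bct_path <- file.path(dir, "bct.csv")
  link_path <- file.path(dir, "link.csv")
  writeLines(c("article_id,year,behavior,article_type,theory_status",
               source_rows), source_path)
  writeLines(c("article_id,bct_code", bct_rows), bct_path)
  writeLines(c(paste0("article_id,bct_code,moa_label_raw,moa_category,",
                      "explicitness,grouping,empirical_status"),
               link_rows), link_path)
  list(source = source_path, bct = bct_path, link = link_path)
}

test_that("reading the three-table schema preserves rows and handles emptiness", {
  dir <- withr::local_tempdir()
  p <- write_tables(dir, character(), character(), character())
  empty <- read_corpus(p$source, p$bct, p$link)
  expect_equal(nrow(empty$articles), 0L)
  expect_equal(nrow(empty$links), 0L)

  p <- write_tables(dir,
    c("A1,2001,smoking cessation,outcome evaluation,applied",
      "A2,2010,diet,development/protocol,none-mentioned"),
    c("A1,1.1", "A1,5.1", "A2,1.2"),
    c("A1,1.1,self-regulation,14,2,1,1",
      "A1,5.1,knowledge,1,1,2,1",
      "A2,1.2,self-efficacy,,2,1,3"))
  corpus <- read_corpus(p$source, p$bct, p$link)
  expect_equal(nrow(corpus$articles), 2L)
  expect_equal(nrow(corpus$links), 3L)
  expect_equal(corpus$links$moa_category[3], "UNRESOLVED")

  resolved <- resolve_corpus_moas(corpus)
  expect_equal(resolved$links$moa_category[3], "4")
  expect_equal(resolved$links$moa_category[1:2], c("14", "1"))
})

test_that("schema and integrity violations are reported with their cause", {
  dir <- withr::local_tempdir()
  p <- write_tables(dir,
    "A1,2001,smoking cessation,outcome evaluation,applied",
    "A1,1.1", "A9,1.1,x,14,2,1,1")
  expect_error(read_corpus(p$source, p$bct, p$link),
               "A9", class = "moalink_integrity_error")

  p <- write_tables(dir,
    "A1,2001,smoking cessation,outcome evaluation,applied",
    "A1,77.7", "A1,77.7,x,14,2,1,1")
  expect_error(read_corpus(p$source, p$bct, p$link),
               "77.7", class = "moalink_validation_error")

  # missing column in the link table
  writeLines(c("article_id,bct_code,explicitness,grouping,empirical_status",
               "A1,1.1,2,1,1"), file.path(dir, "badlink.csv"))
  expect_error(read_corpus(p$source, p$bct, file.path(dir, "badlink.csv")),
               "moa_label_raw", class = "moalink_schema_error")
})

test_that("write_corpus/read_corpus round-trips the logical content", {
  sim <- simulate_corpus(n_articles = 15, seed = 99)
  dir <- withr::local_tempdir()
  paths <- write_corpus(sim$corpus, dir)
  back <- read_corpus(paths[["source"]], paths[["bct"]], paths[["link"]])
  expect_equal(back$articles, sim$corpus$articles)
  expect_equal(back$bct_codings, sim$corpus$bct_codings)
  expect_equal(back$links, sim$corpus$links)
})

test_that("validate_corpus reports without throwing", {
  links <- toy_links(c("a1", "a1", "a1"), c("1.1", "1.1", "1.2"),
                     c("14", "14", "4"))
  corpus <- toy_corpus(links)
  report <- validate_corpus(corpus)
  expect_equal(sum(report$level == "error"), 0L)
  expect_equal(sum(report$level == "warning"), 1L)  # duplicate statement

  bad <- corpus
  bad$links$explicitness[1] <- 3L
  report <- validate_corpus(bad)
  expect_true(any(report$check == "flag_range" & report$level == "error"))

  orphan <- corpus
  orphan$links$article_id[2] <- "a9"
  report <- validate_corpus(orphan)
  expect_true(any(report$check == "orphan_links" & report$level == "error"))

  clean <- toy_corpus(toy_links("a1", "1.1", "14"))
  expect_equal(nrow(validate_corpus(clean)), 0L)
})

test_that("percent agreement and PABAK follow the closed form", {
  expect_equal(coding_agreement(100, 100)$pabak, 1)
  expect_equal(coding_agreement(100, 50)$pabak, 0)
  res <- coding_agreement(100, 95)
  expect_equal(res$percent_agreement, 0.95)
  expect_equal(res$pabak, 0.90)
  expect_error(coding_agreement(0, 0), class = "moalink_validation_error")
  expect_error(coding_agreement(10, 11), class = "moalink_validation_error")
  # identity and range over a sweep
  for (a in 0:20) {
    r <- coding_agreement(20, a)
    expect_equal(r$pabak, 2 * r$percent_agreement - 1)
    expect_true(r$pabak >= -1 && r$pabak <= 1)
  }
})

test_that("the significant-links fixture reconciles to the printed link set", {
  sig <- read_significant_links()
  expect_equal(nrow(sig), 87L)
  expect_equal(dplyr::n_distinct(sig$bct_code, sig$moa_id), 87L)
  bac <- moa_registry()$id[moa_registry()$label == "Beliefs about Capabilities"]
  expect_equal(sig$frequency[sig$bct_code == "8.7" & sig$moa_id == bac], 28L)
  expect_true(all(sig$p_value > 0 & sig$p_value <= 0.05))

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("source_table,bct_code,moa_id,frequency,p_display", f)
  expect_error(read_significant_links(f), class = "moalink_fixture_error")

  # a row above the criterion is fixture corruption
  writeLines(c("source_table,bct_code,moa_id,frequency,p_display",
               "1,1.1,14,3,.060"), f)
  expect_error(read_significant_links(f), class = "moalink_fixture_error")

  # disagreeing table views are fixture corruption
  writeLines(c("source_table,bct_code,moa_id,frequency,p_display",
               "1,1.1,14,3,.003", "2,1.1,14,4,.003"), f)
  expect_error(read_significant_links(f), class = "moalink_fixture_error")
})

test_that("censored p-value strings parse and re-format consistently", {
  parsed <- parse_p_display(c(".008", "<.001", "0.013", "<.050"))
  expect_equal(parsed$p_value, c(0.008, 0.001, 0.013, 0.05))
  expect_equal(parsed$censored, c(FALSE, TRUE, FALSE, TRUE))
  expect_error(parse_p_display("n.s."), class = "moalink_parse_error")
  expect_equal(format_p(c(0.0004, 0.008, 0.0432)),
               c("<.001", ".008", ".043"))
})
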