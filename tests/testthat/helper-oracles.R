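# Independent oracles and fixture builders used across the suite.

# Direct-summation binomial upper tail: P(X >= k), X ~ Binomial(n, p).
# Written independently of the package's survival-function route.
bf_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  i <- k:n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# Brute-force nested-loop article count per (bct, moa) cell.
bf_cell_counts <- function(links) {
  out <- list()
  for (b in unique(links$bct_code)) {
    for (m in unique(links$moa_category)) {
      arts <- unique(links$article_id[links$bct_code == b &
                                        links$moa_category == m])
      if (length(arts) > 0) {
        out[[length(out) + 1]] <- data.frame(bct_code = b, moa_id = m,
                                             k = length(arts))
      }
    }
  }
  do.call(rbind, out)
}

# A minimal links tibble with sensible defaults.
toy_links <- function(article_id, bct_code, moa_category,
                      explicitness = 2L, grouping = 1L,
                      empirical_status = 1L) {
  tibble::tibble(
    article_id = article_id, bct_code = bct_code,
    moa_label_raw = "construct", moa_definition_raw = NA_character_,
    moa_category = as.character(moa_category),
    explicitness = as.integer(explicitness),
    grouping = as.integer(grouping),
    empirical_status = as.integer(empirical_status))
}

# Wrap a links tibble into a consistent corpus.
toy_corpus <- function(links) {
  ids <- unique(links$article_id)
  articles <- tibble::tibble(
    article_id = ids, year = 2015L, behavior = "physical activity",
    article_type = "outcome evaluation", theory_status = "applied")
  codings <- dplyr::distinct(links, article_id, bct_code)
  moalink:::new_moa_corpus(articles, codings, links)
}

# Random small links tibble for property tests (uses real taxonomy codes).
random_links <- function(n_articles = 6, n_statements = 25,
                         codes = c("1.1", "1.2", "2.3", "5.1", "8.7"),
                         moas = c("1", "4", "14", "OTHER")) {
  toy_links(
    article_id = sample(sprintf("a%d", seq_len(n_articles)), n_statements,
                        replace = TRUE),
    bct_code = sample(codes, n_statements, replace = TRUE),
    moa_category = sample(moas, n_statements, replace = TRUE),
    explicitness = sample(1:2, n_statements, replace = TRUE),
    grouping = sample(1:2, n_statements, replace = TRUE),
    empirical_status = sample(1:3, n_statements, replace = TRUE))
}

# Write a corpus to CSVs in a temp dir and return the three paths.
toy_corpus_files <- function(corpus, dir = withr::local_tempdir(
                               .local_envir = parent.frame())) {
  write_corpus(corpus, dir)
}

# Reduced simulation grid used by the calibration and power suites:
# uniform weights so every expected cell count is N / (cells).
uniform_grid <- function(n_bct = 6, n_moa = 4) {
  codes <- bct_registry()$code[seq_len(n_bct)]
  ids <- as.character(seq_len(n_moa))
  list(codes = codes, ids = ids,
       bct_weights = stats::setNames(rep(1, n_bct), codes),
       moa_weights = stats::setNames(rep(1, n_moa), ids))
}
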