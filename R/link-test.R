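#' Expected link probability under the marginal-product null
#'
#' In the absence of an agreed expected frequency for any given BCT-MoA
#' link, the null probability of a link falling in cell (B, M) is the
#' product of the probability that the link involves BCT B and the
#' probability that it involves MoA M, both estimated from the marginals:
#' \deqn{p_0 = (m_B / N) (m_M / N)}
#' where \eqn{m_B} and \eqn{m_M} are the total link counts of the BCT and
#' the MoA and \eqn{N} the corpus-wide link total.
#'
#' @param m_b,m_m Marginal link counts (vectors recycle).
#' @param n Total number of links (scalar, > 0).
#' @return Numeric vector of null cell probabilities.
#' @examples
#' expected_link_probability(177, 734, 2636)
#' @export
expected_link_probability <- function(m_b, m_m, n) {
  if (length(n) != 1 || is.na(n) || n <= 0) {
    abort("The null is undefined for a link total N <= 0.",
          class = "moalink_validation_error")
  }
  if (any(m_b < 0) || any(m_m < 0) || any(m_b > n) || any(m_m > n)) {
    abort("Marginals must lie in [0, N].",
          class = "moalink_validation_error")
  }
  (m_b / n) * (m_m / n)
}

#' One-tailed exact binomial upper-tail probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim Binomial(N, p_0)}, computed exactly via
#' the survival-function formulation (numerically stable at large N; no
#' normal approximation). The upper tail is used because the aim is to
#' identify links described more often than the null predicts.
#'
#' @param k Observed count(s), `0 <= k <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability in `[0, 1]`.
#' @return Numeric vector of upper-tail probabilities; `k = 0` gives 1.
#' @examples
#' binom_upper_tail(5, 20, 0.1)
#' @export
binom_upper_tail <- function(k, n, p0) {
  if (any(k < 0) || any(k > n)) {
    abort("k must lie in [0, n].", class = "moalink_validation_error")
  }
  if (any(p0 < 0) || any(p0 > 1)) {
    abort("p0 must lie in [0, 1].", class = "moalink_validation_error")
  }
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Test every described link against the marginal-product null
#'
#' The core inference of the pipeline. For each nonzero cell of the
#' link-frequency table, the observed article count \eqn{k} is compared
#' with its expectation under independence of BCT use and MoA targeting:
#' a one-tailed exact binomial test of \eqn{k} successes in \eqn{N} trials
#' at null probability \eqn{p_0 = (m_B/N)(m_M/N)}. Cells never described
#' (k = 0) are not tested. The raw `p < alpha` criterion mirrors the
#' arbitrary minimum criterion of the source synthesis; an optional
#' Benjamini-Hochberg adjustment is available as an extension.
#'
#' @param x A `moa_freq_table`, `moa_corpus`, or link tibble (the latter
#'   two are tabulated first with the given `scope`).
#' @param alpha Significance threshold in (0, 1); default .05.
#' @param scope Frequency-table scope used when `x` is not already a
#'   table; the null marginals and N are computed on this same scope.
#' @param adjust `"none"` (default, the source criterion) or `"BH"` for a
#'   Benjamini-Hochberg false-discovery-rate adjustment; significance is
#'   then judged on the adjusted p-value.
#' @return An object of class `moa_link_test` with elements `results` (a
#'   tibble: `bct_code`, `moa_id`, `k`, `m_b`, `m_m`, `p0`,
#'   `expected_count`, `p`, `p_adjusted`, `significant`), `alpha`,
#'   `scope`, `adjust` and `n_total`. [tidy()] returns the results,
#'   [glance()] a one-row summary, [autoplot()] the clustered heat map.
#' @examples
#' links <- tibble::tibble(
#'   article_id = c("a1", "a2", "a1"), bct_code = c("1.1", "1.1", "1.2"),
#'   moa_label_raw = "x", moa_category = c("14", "14", "4"),
#'   explicitness = 2L, grouping = 1L, empirical_status = 1L)
#' tidy(test_links(links))
#' @export
test_links <- function(x, alpha = 0.05, scope = c("categorized", "all"),
                       adjust = c("none", "BH")) {
  scope <- match.arg(scope)
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("alpha must be a single value in (0, 1).",
          class = "moalink_validation_error")
  }
  if (!inherits(x, "moa_freq_table")) {
    x <- link_frequency_table(x, scope = scope)
  } else if (x$scope != scope && !missing(scope)) {
    abort(sprintf("Frequency table scope '%s' does not match requested scope '%s'.",
                  x$scope, scope),
          class = "moalink_validation_error")
  }
  cells <- x$cells
  n <- x$n_total
  if (nrow(cells) == 0) {
    results <- tibble::tibble(
      bct_code = character(), moa_id = character(), k = integer(),
      m_b = numeric(), m_m = numeric(), p0 = numeric(),
      expected_count = numeric(), p = numeric(), p_adjusted = numeric(),
      significant = logical())
  } else {
    m_b <- x$bct_marginals[cells$bct_code]
    m_m <- x$moa_marginals[cells$moa_id]
    p0 <- expected_link_probability(m_b, m_m, n)
    p <- binom_upper_tail(cells$k, n, p0)
    p_adjusted <- if (adjust == "BH") p.adjust(p, method = "BH") else p
    results <- tibble::tibble(
      bct_code = cells$bct_code, moa_id = cells$moa_id, k = cells$k,
      m_b = unname(m_b), m_m = unname(m_m), p0 = unname(p0),
      expected_count = n * unname(p0), p = unname(p),
      p_adjusted = unname(p_adjusted),
      significant = unname(p_adjusted) < alpha)
  }
  structure(list(results = results, alpha = alpha, scope = x$scope,
                 adjust = adjust, n_total = n),
            class = "moa_link_test")
}

#' @export
print.moa_link_test <- function(x, ...) {
  cat(sprintf(
    "<moa_link_test> %d tested links (N = %d, %s scope), %d significant at alpha = %g%s\n",
    nrow(x$results), x$n_total, x$scope, sum(x$results$significant),
    x$alpha, if (x$adjust == "BH") " (BH-adjusted)" else ""))
  invisible(x)
}

#' @rdname test_links
#' @param x,object A `moa_link_test`.
#' @param ... Unused.
#' @export
tidy.moa_link_test <- function(x, ...) x$results

#' @rdname test_links
#' @export
glance.moa_link_test <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x$results),
    n_significant = sum(x$results$significant),
    n_total_links = x$n_total,
    alpha = x$alpha,
    scope = x$scope,
    adjust = x$adjust)
}

#' Significant results arranged in the two published layouts
#'
#' `table1_view()` groups by technique (sorted by code, then ascending p);
#' `table2_view()` groups by mechanism (sorted by id, then ascending p).
#' Both carry the same underlying link set, with registry labels and the
#' censored p display attached.
#'
#' @param x A `moa_link_test` (its significant rows are used) or a tibble
#'   of significant links with columns `bct_code`, `moa_id` and either `p`
#'   or `p_value`, e.g. from [read_significant_links()].
#' @param bct,moa Registries used to attach labels.
#' @return A tibble with `bct_code`, `bct_label`, `moa_id`, `moa_label`,
#'   `frequency`, `p` and `p_display`, sorted for the requested view.
#' @export
table1_view <- function(x, bct = bct_registry(), moa = moa_registry()) {
  rows <- significant_rows(x)
  rows <- dplyr::arrange(rows, .data$bct_code, .data$p)
  attach_labels(rows, bct, moa)
}

#' @rdname table1_view
#' @export
table2_view <- function(x, bct = bct_registry(), moa = moa_registry()) {
  rows <- significant_rows(x)
  rows <- dplyr::arrange(rows, as.integer(.data$moa_id), .data$p)
  attach_labels(rows, bct, moa)
}

significant_rows <- function(x) {
  if (inherits(x, "moa_link_test")) {
    rows <- x$results[x$results$significant, ]
    rows$frequency <- rows$k
    rows$p_display <- format_p(rows$p)
  } else {
    rows <- tibble::as_tibble(x)
    if (!"p" %in% names(rows) && "p_value" %in% names(rows)) {
      rows$p <- rows$p_value
    }
    if (!"frequency" %in% names(rows) && "k" %in% names(rows)) {
      rows$frequency <- rows$k
    }
    if (!"p_display" %in% names(rows)) rows$p_display <- format_p(rows$p)
  }
  rows
}

attach_labels <- function(rows, bct, moa) {
  tibble::tibble(
    bct_code = rows$bct_code,
    bct_label = bct$label[match(rows$bct_code, bct$code)],
    moa_id = as.integer(rows$moa_id),
    moa_label = moa$label[match(as.integer(rows$moa_id), moa$id)],
    frequency = rows$frequency,
    p = rows$p,
    p_display = rows$p_display)
}

#' Summarise a set of significant links
#'
#' Reduces a significant-link set to the headline descriptive statistics
#' of the synthesis: distinct links, techniques and mechanisms involved,
#' mean and maximum mechanisms per technique (and vice versa), and
#' coverage of the 93-technique taxonomy and the 26-mechanism set. Means
#' are rounded to two decimals and coverages to whole percent, rounding
#' half up, matching the printed reporting convention.
#'
#' @param x A `moa_link_test` (significant rows are used) or a tibble of
#'   significant links with columns `bct_code` and `moa_id`.
#' @param n_bcts_universe,n_moas_universe Denominators for the coverage
#'   percentages (taxonomy sizes; defaults 93 and 26).
#' @return A one-row tibble: `n_links`, `n_bcts`, `n_moas`,
#'   `mean_moas_per_bct`, `max_moas_per_bct`, `mean_bcts_per_moa`,
#'   `max_bcts_per_moa`, `pct_bct_coverage`, `pct_moa_coverage`.
#' @examples
#' summarize_significant(read_significant_links())
#' @export
summarize_significant <- function(x, n_bcts_universe = 93,
                                  n_moas_universe = 26) {
  rows <- if (inherits(x, "moa_link_test")) {
    x$results[x$results$significant, ]
  } else {
    tibble::as_tibble(x)
  }
  rows <- dplyr::distinct(rows, .data$bct_code, .data$moa_id)
  if (nrow(rows) == 0) {
    return(tibble::tibble(
      n_links = 0L, n_bcts = 0L, n_moas = 0L,
      mean_moas_per_bct = NA_real_, max_moas_per_bct = 0L,
      mean_bcts_per_moa = NA_real_, max_bcts_per_moa = 0L,
      pct_bct_coverage = 0, pct_moa_coverage = 0))
  }
  per_bct <- dplyr::count(rows, .data$bct_code)$n
  per_moa <- dplyr::count(rows, .data$moa_id)$n
  n_links <- nrow(rows)
  n_bcts <- length(per_bct)
  n_moas <- length(per_moa)
  tibble::tibble(
    n_links = n_links, n_bcts = n_bcts, n_moas = n_moas,
    mean_moas_per_bct = round_half_up(n_links / n_bcts, 2),
    max_moas_per_bct = max(per_bct),
    mean_bcts_per_moa = round_half_up(n_links / n_moas, 2),
    max_bcts_per_moa = max(per_moa),
    pct_bct_coverage = round_half_up(100 * n_bcts / n_bcts_universe),
    pct_moa_coverage = round_half_up(100 * n_moas / n_moas_universe))
}

#' Export test results as CSV in either published layout
#'
#' @param x A `moa_link_test`.
#' @param path Output CSV path.
#' @param view `"table1"` (grouped by technique), `"table2"` (grouped by
#'   mechanism) or `"all"` (every tested cell, unsorted views do not
#'   apply).
#' @param bct,moa Registries used for labels.
#' @return Invisibly, `path`.
#' @export
write_test_results <- function(x, path, view = c("all", "table1", "table2"),
                               bct = bct_registry(), moa = moa_registry()) {
  stopifnot(inherits(x, "moa_link_test"))
  view <- match.arg(view)
  out <- switch(view,
    all = {
      res <- x$results
      tibble::tibble(
        bct_code = res$bct_code,
        bct_label = bct$label[match(res$bct_code, bct$code)],
        moa_id = res$moa_id,
        moa_label = moa$label[match(suppressWarnings(as.integer(res$moa_id)),
                                    moa$id)],
        k = res$k, p0 = res$p0, expected_count = res$expected_count,
        p = res$p, significant = res$significant)
    },
    table1 = table1_view(x, bct, moa),
    table2 = table2_view(x, bct, moa))
  readr::write_csv(out, path)
  invisible(path)
}
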