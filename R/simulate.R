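#' Default skewed usage weights
#'
#' The synthesis corpus the generator emulates is highly concentrated: a
#' handful of techniques and mechanisms absorb a large share of all links
#' (one mechanism alone accounted for more than a quarter of them). The
#' default weights are therefore Zipf-like, \eqn{w_r = 1/r} over a fixed
#' rank order: for mechanisms the mass is put first on Beliefs about
#' Capabilities, then Intention, then the remaining ids in registry
#' order. These defaults are documented illustrative constants, not
#' estimates of the published marginals (which are unreported).
#'
#' @param registry The corresponding registry tibble.
#' @return A named numeric weight vector over codes (BCTs) or ids (MoAs).
#' @export
default_bct_weights <- function(registry = bct_registry()) {
  setNames(1 / seq_len(nrow(registry)), registry$code)
}

#' @rdname default_bct_weights
#' @export
default_moa_weights <- function(registry = moa_registry()) {
  rank_order <- c(4L, 8L, setdiff(registry$id, c(4L, 8L)))
  w <- 1 / seq_along(rank_order)
  setNames(w[match(registry$id, rank_order)], registry$id)
}

#' Generate a synthetic coded corpus with known ground truth
#'
#' Emulates the statistical structure the analysis assumes: a set of
#' articles each contributing an overdispersed number of link statements,
#' links falling on (BCT, MoA) cells with probability proportional to
#' `bct_weights * moa_weights * propensity`, deduplicated within article
#' (sampling without replacement mirrors the once-per-article extraction
#' rule). A `propensity` multiplier of 1 everywhere is the independence
#' null; cells with multiplier > 1 are "planted" links recorded in the
#' ground truth. Defaults reproduce the emulation targets: 277 articles,
#' links per article following a zero-truncated negative binomial with
#' mean 9.56 and SD 13.80, 33% of statements needing inference, 12%
#' one-to-one statements and 0.9% empirically tested links.
#'
#' @param n_articles Number of articles.
#' @param mean_links,sd_links Mean and SD of the links-per-article
#'   distribution (negative binomial, zero-truncated since every included
#'   article describes at least one link). `sd_links` must exceed
#'   `sqrt(mean_links)`; overdispersion is the observed regime.
#' @param bct_weights,moa_weights Named nonnegative usage weights over
#'   taxonomy codes / registry ids; restricting the names restricts the
#'   simulated cell grid. Defaults: [default_bct_weights()],
#'   [default_moa_weights()].
#' @param propensity Optional multiplier matrix over cells
#'   (`dimnames = list(bct codes, moa ids)`), 1 = independence.
#' @param other_rate Probability a statement's mechanism is
#'   uncategorizable (category `"OTHER"`); default 0.05.
#' @param p_inference,p_one_to_one,p_tested,p_measured Flag-distribution
#'   parameters: P(explicitness = 1), P(grouping = 1),
#'   P(empirical_status = 3), P(empirical_status = 2).
#' @param extra_coding_rate Expected number of coded-but-unlinked BCTs
#'   per article (BCTs are routinely coded even when no mechanism is
#'   stated for them).
#' @param seed Integer seed for the single root generator; `NULL` uses
#'   (and advances) the session RNG.
#' @return A list with elements `corpus` (a `moa_corpus`) and
#'   `ground_truth` (list: `planted` tibble of cells with multiplier > 1,
#'   and the full `propensity` matrix).
#' @examples
#' sim <- simulate_corpus(n_articles = 20, seed = 1)
#' sim$corpus
#' @export
simulate_corpus <- function(n_articles = 277,
                            mean_links = 9.56, sd_links = 13.80,
                            bct_weights = default_bct_weights(),
                            moa_weights = default_moa_weights(),
                            propensity = NULL,
                            other_rate = 0.05,
                            p_inference = 0.33, p_one_to_one = 0.12,
                            p_tested = 0.009, p_measured = 0.05,
                            extra_coding_rate = 0.5,
                            seed = NULL) {
  stopifnot(n_articles >= 0, mean_links > 0,
            other_rate >= 0, other_rate < 1,
            all(bct_weights >= 0), all(moa_weights >= 0),
            sum(bct_weights) > 0, sum(moa_weights) > 0)
  if (sd_links^2 <= mean_links) {
    abort("sd_links^2 must exceed mean_links (negative binomial is overdispersed).",
          class = "moalink_config_error")
  }
  bct_codes <- names(bct_weights)
  moa_ids <- names(moa_weights)
  if (is.null(bct_codes) || is.null(moa_ids)) {
    abort("bct_weights and moa_weights must be named vectors.",
          class = "moalink_config_error")
  }
  n_cells <- length(bct_codes) * length(moa_ids)
  if (mean_links > n_cells) {
    abort("Configured mean links per article exceeds the number of distinct cells.",
          class = "moalink_config_error")
  }
  if (is.null(propensity)) {
    propensity <- matrix(1, length(bct_codes), length(moa_ids),
                         dimnames = list(bct_codes, moa_ids))
  } else {
    stopifnot(identical(rownames(propensity), bct_codes),
              identical(colnames(propensity), moa_ids),
              all(propensity >= 0))
  }
  planted_idx <- which(propensity > 1, arr.ind = TRUE)
  planted <- tibble::tibble(
    bct_code = bct_codes[planted_idx[, 1]],
    moa_id = moa_ids[planted_idx[, 2]],
    multiplier = propensity[planted_idx])
  ground_truth <- list(planted = planted, propensity = propensity)

  if (n_articles == 0) {
    empty_articles <- tibble::tibble(
      article_id = character(), year = integer(), behavior = character(),
      article_type = character(), theory_status = character())
    empty_bct <- tibble::tibble(article_id = character(),
                                bct_code = character())
    empty_links <- tibble::tibble(
      article_id = character(), bct_code = character(),
      moa_label_raw = character(), moa_definition_raw = character(),
      moa_category = character(), explicitness = integer(),
      grouping = integer(), empirical_status = integer())
    return(list(corpus = new_moa_corpus(empty_articles, empty_bct,
                                        empty_links),
                ground_truth = ground_truth))
  }

  moa_reg <- moa_registry()
  nb <- zt_nbinom_params(mean_links, sd_links)
  cell_prob <- as.vector(outer(bct_weights, moa_weights) * propensity)
  cell_bct <- rep(bct_codes, times = length(moa_ids))
  cell_moa <- rep(moa_ids, each = length(bct_codes))

  with_local_seed(seed, {
    ids <- sprintf("A%04d", seq_len(n_articles))
    # zero-truncated negative binomial links-per-article
    n_links <- rnbinom(n_articles, size = nb$size, mu = nb$mu)
    while (any(n_links == 0)) {
      redo <- n_links == 0
      n_links[redo] <- rnbinom(sum(redo), size = nb$size, mu = nb$mu)
    }
    n_links <- pmin(n_links, n_cells)

    articles <- tibble::tibble(
      article_id = ids,
      year = ifelse(runif(n_articles) < 0.49,
                    sample(2010:2016, n_articles, replace = TRUE),
                    sample(1982:2009, n_articles, replace = TRUE)),
      behavior = sample(c("physical activity", "diet", "alcohol reduction",
                          "smoking cessation", "other"),
                        n_articles, replace = TRUE,
                        prob = c(0.40, 0.18, 0.10, 0.06, 0.26)),
      article_type = sample(c("outcome evaluation", "development/protocol"),
                            n_articles, replace = TRUE,
                            prob = c(0.78, 0.22)),
      theory_status = sample(c("none-mentioned", "mentioned-unspecified",
                               "applied"),
                             n_articles, replace = TRUE,
                             prob = c(0.14, 0.13, 0.73)))

    links <- purrr::map2_dfr(ids, n_links, function(id, l) {
      cells <- sample.int(n_cells, l, replace = FALSE, prob = cell_prob)
      tibble::tibble(article_id = id,
                     bct_code = cell_bct[cells],
                     moa_id = cell_moa[cells])
    })
    is_other <- runif(nrow(links)) < other_rate
    reg_label <- moa_reg$label[match(as.integer(links$moa_id), moa_reg$id)]
    links <- tibble::tibble(
      article_id = links$article_id,
      bct_code = links$bct_code,
      moa_label_raw = ifelse(is_other, "idiosyncratic construct", reg_label),
      moa_definition_raw = NA_character_,
      moa_category = ifelse(is_other, MOA_OTHER, links$moa_id),
      explicitness = ifelse(runif(nrow(links)) < p_inference, 1L, 2L),
      grouping = ifelse(runif(nrow(links)) < p_one_to_one, 1L, 2L),
      empirical_status = sample(1:3, nrow(links), replace = TRUE,
                                prob = c(1 - p_measured - p_tested,
                                         p_measured, p_tested)))

    bct_codings <- dplyr::distinct(links, .data$article_id, .data$bct_code)
    n_extra <- stats::rpois(n_articles, extra_coding_rate)
    extra <- purrr::map2_dfr(ids, n_extra, function(id, k) {
      if (k == 0) return(NULL)
      tibble::tibble(article_id = id,
                     bct_code = sample(bct_codes, min(k, length(bct_codes)),
                                       prob = bct_weights))
    })
    bct_codings <- dplyr::distinct(
      dplyr::bind_rows(bct_codings, extra), .data$article_id,
      .data$bct_code)
    bct_codings <- dplyr::arrange(bct_codings, .data$article_id,
                                  .data$bct_code)

    list(corpus = new_moa_corpus(articles, bct_codings, links),
         ground_truth = ground_truth)
  })
}

#' Zero-truncated negative binomial calibration
#'
#' Finds the underlying negative binomial (size, mu) whose zero-truncated
#' distribution has the requested mean and standard deviation, so that the
#' links-per-article distribution matches the configured moments after
#' the at-least-one-link inclusion rule. Solved numerically; the fit is
#' deterministic.
#'
#' @param mean,sd Target moments of the truncated distribution.
#' @return A list with elements `size` and `mu`.
#' @keywords internal
zt_nbinom_params <- function(mean, sd) {
  target_var <- sd^2
  moments <- function(par) {
    r <- exp(par[1]); m <- exp(par[2])
    p0 <- (r / (r + m))^r
    mt <- m / (1 - p0)
    vt <- (m + m^2 * (1 + 1 / r)) / (1 - p0) - mt^2
    c(mt, vt)
  }
  obj <- function(par) {
    mv <- moments(par)
    if (!all(is.finite(mv)) || mv[2] <= 0) return(1e6)
    (mv[1] / mean - 1)^2 + (mv[2] / target_var - 1)^2
  }
  start <- c(log(mean^2 / max(target_var - mean, mean / 10)), log(mean))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (fit$value > 1e-4) {
    abort("Cannot match the requested links-per-article mean/SD with a zero-truncated negative binomial.",
          class = "moalink_config_error")
  }
  list(size = exp(fit$par[1]), mu = exp(fit$par[2]))
}

#' Plant enriched links into a propensity matrix
#'
#' Convenience constructor for the generator's ground-truth structure: an
#' all-ones (independence) matrix over the given cells with selected
#' cells multiplied up.
#'
#' @param bct_codes,moa_ids Axis names of the grid (must match the
#'   weights later passed to [simulate_corpus()]).
#' @param cells A tibble/data.frame with columns `bct_code`, `moa_id` and
#'   optionally `multiplier` (default 2).
#' @return A propensity matrix.
#' @export
plant_links <- function(bct_codes, moa_ids, cells) {
  m <- matrix(1, length(bct_codes), length(moa_ids),
              dimnames = list(bct_codes, as.character(moa_ids)))
  cells <- tibble::as_tibble(cells)
  if (!"multiplier" %in% names(cells)) cells$multiplier <- 2
  m[cbind(match(cells$bct_code, bct_codes),
          match(as.character(cells$moa_id), as.character(moa_ids)))] <-
    cells$multiplier
  m
}

#' Recovery of planted links by the enrichment test
#'
#' Compares the links flagged significant against the generator's ground
#' truth: sensitivity is the share of planted cells flagged, and the
#' false-flag rate is the share of tested non-planted cells flagged.
#'
#' @param test A `moa_link_test` run on the generated corpus.
#' @param ground_truth The `ground_truth` element returned by
#'   [simulate_corpus()].
#' @param alpha Threshold used for flagging; defaults to the test's own.
#' @return A one-row tibble: `n_planted`, `n_flagged`, `sensitivity`
#'   (`NA` when nothing was planted), `false_flag_rate`.
#' @export
recovery_metrics <- function(test, ground_truth, alpha = test$alpha) {
  stopifnot(inherits(test, "moa_link_test"))
  res <- test$results
  flagged <- res$p_adjusted < alpha
  planted_key <- paste(ground_truth$planted$bct_code,
                       ground_truth$planted$moa_id)
  cell_key <- paste(res$bct_code, res$moa_id)
  is_planted <- cell_key %in% planted_key
  n_planted <- length(planted_key)
  sensitivity <- if (n_planted == 0) NA_real_ else {
    sum(planted_key %in% cell_key[flagged]) / n_planted
  }
  n_nonplanted_tested <- sum(!is_planted)
  false_flag_rate <- if (n_nonplanted_tested == 0) NA_real_ else {
    sum(flagged & !is_planted) / n_nonplanted_tested
  }
  tibble::tibble(n_planted = n_planted, n_flagged = sum(flagged),
                 sensitivity = sensitivity,
                 false_flag_rate = false_flag_rate)
}

#' Write a generator's ground truth as JSON
#'
#' @param ground_truth The `ground_truth` element of [simulate_corpus()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(list(
    planted = ground_truth$planted,
    bct_codes = rownames(ground_truth$propensity),
    moa_ids = colnames(ground_truth$propensity),
    propensity = apply(ground_truth$propensity, 1, identity,
                       simplify = FALSE)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
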