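#' Deduplicate link statements to one per article
#'
#' Each link is counted at most once per article: among duplicated
#' (`article_id`, `bct_code`, `moa_category`) statements the most explicit
#' survives (highest `explicitness`, ties broken by highest
#' `empirical_status`, then first occurrence). The operation is idempotent.
#'
#' @param links A link tibble (the `links` table of a corpus) or a
#'   `moa_corpus`, in which case its link table is deduplicated in place.
#' @return An object of the same kind with at most one statement per
#'   (article, BCT, MoA).
#' @export
deduplicate_links <- function(links) {
  if (inherits(links, "moa_corpus")) {
    links$links <- deduplicate_links(links$links)
    return(links)
  }
  links <- tibble::as_tibble(links)
  if (nrow(links) == 0) return(links)
  ord <- order(links$article_id, links$bct_code, links$moa_category,
               -links$explicitness, -links$empirical_status)
  out <- links[ord, ]
  out <- out[!duplicated(out[, c("article_id", "bct_code", "moa_category")]), ]
  out[order(match(do.call(paste, out[, c("article_id", "bct_code",
                                         "moa_category")]),
                  do.call(paste, links[, c("article_id", "bct_code",
                                           "moa_category")]))), ]
}

is_categorized <- function(moa_category) {
  grepl("^[0-9]+$", moa_category)
}

#' Build the BCT-by-MoA link-frequency table
#'
#' Counts, for every (BCT, MoA) cell, the number of distinct articles in
#' which that link was described (statements are deduplicated per article
#' first), together with the row and column marginals and the corpus-wide
#' link total N. With `scope = "categorized"` (the default, and the scope
#' on which enrichment tests run) statements whose MoA could not be
#' categorized (`"OTHER"`/`"UNRESOLVED"`) are excluded from the cells, the
#' marginals and N alike, so the conservation identity
#' \eqn{\sum_B m_B = \sum_M m_M = N} always holds.
#'
#' @param links A link tibble or `moa_corpus`.
#' @param scope `"categorized"` or `"all"`. Under `"all"`, uncategorized
#'   statements are retained as pseudo-categories so they contribute to N
#'   and the BCT marginals.
#' @return An object of class `moa_freq_table`: a list with tibble `cells`
#'   (`bct_code`, `moa_id` as character, `k`), named numeric vectors
#'   `bct_marginals`, `moa_marginals`, integer `n_total`, and `scope`.
#' @examples
#' links <- tibble::tibble(
#'   article_id = c("a1", "a2"), bct_code = "1.1",
#'   moa_label_raw = "behavioral regulation", moa_category = "14",
#'   explicitness = 2L, grouping = 1L, empirical_status = 1L)
#' link_frequency_table(links)$cells
#' @export
link_frequency_table <- function(links, scope = c("categorized", "all")) {
  scope <- match.arg(scope)
  if (inherits(links, "moa_corpus")) links <- links$links
  links <- deduplicate_links(links)
  if (scope == "categorized") {
    links <- links[is_categorized(links$moa_category), ]
  }
  cells <- dplyr::count(links, .data$bct_code,
                        moa_id = .data$moa_category, name = "k")
  cells <- dplyr::arrange(cells, .data$bct_code, .data$moa_id)
  bct_marginals <- tapply(cells$k, cells$bct_code, sum)
  moa_marginals <- tapply(cells$k, cells$moa_id, sum)
  structure(list(
    cells = cells,
    bct_marginals = setNames(as.numeric(bct_marginals),
                             names(bct_marginals)),
    moa_marginals = setNames(as.numeric(moa_marginals),
                             names(moa_marginals)),
    n_total = sum(cells$k),
    scope = scope
  ), class = "moa_freq_table")
}

#' @export
print.moa_freq_table <- function(x, ...) {
  cat(sprintf("<moa_freq_table> %d cells, %d BCTs x %d MoAs, N = %d (%s scope)\n",
              nrow(x$cells), length(x$bct_marginals),
              length(x$moa_marginals), x$n_total, x$scope))
  invisible(x)
}

#' @export
tidy.moa_freq_table <- function(x, ...) x$cells

#' Export a frequency table as CSV plus a JSON sidecar
#'
#' Writes the cells in long format (`bct_code,moa_id,k`) and a JSON file
#' carrying the marginals, N and the scope.
#'
#' @param x A `moa_freq_table`.
#' @param csv_path,json_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_frequency_table <- function(x, csv_path, json_path) {
  stopifnot(inherits(x, "moa_freq_table"))
  readr::write_csv(x$cells, csv_path)
  jsonlite::write_json(
    list(n_total = x$n_total, scope = x$scope,
         bct_marginals = as.list(x$bct_marginals),
         moa_marginals = as.list(x$moa_marginals)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}

#' Corpus-level descriptive statistics
#'
#' Summarises a coded corpus after per-article deduplication: article and
#' link totals, the links-per-article distribution (over articles
#' contributing at least one link, matching the inclusion criterion that
#' every included article describes a link), flag proportions, and
#' coverage of the taxonomy and the mechanism set.
#'
#' @param corpus A `moa_corpus`.
#' @return A one-row tibble: `n_articles`, `n_links_total`,
#'   `mean_links_per_article`, `sd_links_per_article`,
#'   `pct_inference_needed`, `pct_group_statements`,
#'   `pct_empirically_tested`, `n_bcts_coded`, `n_bcts_linked`,
#'   `n_moas_linked`.
#' @export
corpus_summary <- function(corpus) {
  stopifnot(inherits(corpus, "moa_corpus"))
  links <- deduplicate_links(corpus$links)
  if (nrow(links) == 0) {
    return(tibble::tibble(
      n_articles = nrow(corpus$articles), n_links_total = 0L,
      mean_links_per_article = NA_real_, sd_links_per_article = NA_real_,
      pct_inference_needed = NA_real_, pct_group_statements = NA_real_,
      pct_empirically_tested = NA_real_,
      n_bcts_coded = length(unique(corpus$bct_codings$bct_code)),
      n_bcts_linked = 0L, n_moas_linked = 0L))
  }
  per_article <- dplyr::count(links, .data$article_id)$n
  tibble::tibble(
    n_articles = nrow(corpus$articles),
    n_links_total = nrow(links),
    mean_links_per_article = mean(per_article),
    sd_links_per_article = if (length(per_article) > 1) sd(per_article) else 0,
    pct_inference_needed = 100 * mean(links$explicitness == 1),
    pct_group_statements = 100 * mean(links$grouping == 2),
    pct_empirically_tested = 100 * mean(links$empirical_status == 3),
    n_bcts_coded = length(unique(corpus$bct_codings$bct_code)),
    n_bcts_linked = length(unique(links$bct_code)),
    n_moas_linked = length(unique(links$moa_category[
      is_categorized(links$moa_category)]))
  )
}
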