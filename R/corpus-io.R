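#' @title Coded link corpora: the three-table schema
#' @description
#' A coded corpus is held in three connected tables, joined on
#' `article_id`:
#'
#' * `articles` — one row per included article: `article_id`, `year`,
#'   `behavior`, `article_type`, `theory_status` (one of
#'   `"none-mentioned"`, `"mentioned-unspecified"`, `"applied"`).
#' * `bct_codings` — one row per BCT coded in an article (whether or not it
#'   was linked to a mechanism): `article_id`, `bct_code`.
#' * `links` — one row per author-described BCT-MoA link statement:
#'   `article_id`, `bct_code`, `moa_label_raw`, `moa_definition_raw`,
#'   `moa_category` (registry id as character, `"OTHER"` or
#'   `"UNRESOLVED"`), `explicitness` (1 = some inference needed, 2 = no
#'   inference needed), `grouping` (1 = one-to-one statement, 2 = group
#'   statement), `empirical_status` (1 = MoA not measured, 2 = measured but
#'   link not tested, 3 = link tested).
#' @name moa_corpus
NULL

new_moa_corpus <- function(articles, bct_codings, links) {
  structure(list(articles = tibble::as_tibble(articles),
                 bct_codings = tibble::as_tibble(bct_codings),
                 links = tibble::as_tibble(links)),
            class = "moa_corpus")
}

REQUIRED_SOURCE_COLS <- c("article_id", "year", "behavior", "article_type",
                          "theory_status")
REQUIRED_BCT_COLS <- c("article_id", "bct_code")
REQUIRED_LINK_COLS <- c("article_id", "bct_code", "moa_label_raw",
                        "explicitness", "grouping", "empirical_status")

check_columns <- function(df, required, file_role) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s table is missing required column(s): %s",
                  file_role, paste(missing, collapse = ", ")),
          class = "moalink_schema_error")
  }
  invisible(df)
}

#' Read a coded corpus from its three CSV tables
#'
#' Reads the source (article), BCT-coding and link tables, checks the
#' schema, and enforces referential integrity: every link must cite a known
#' article, a taxonomy BCT code, and a BCT coded in that article. Link rows
#' without a `moa_category` column (or with missing values in it) are
#' marked `"UNRESOLVED"`; use [resolve_corpus_moas()] to categorize them.
#'
#' @param source_path,bct_path,link_path Paths to the three CSV files.
#' @param registry BCT registry used to validate codes.
#' @return A `moa_corpus` object (list of tibbles `articles`,
#'   `bct_codings`, `links`).
#' @seealso [write_corpus()], [validate_corpus()]
#' @export
read_corpus <- function(source_path, bct_path, link_path,
                        registry = bct_registry()) {
  articles <- readr::read_csv(source_path, col_types = readr::cols(
    article_id = readr::col_character(),
    year = readr::col_integer(),
    .default = readr::col_character()
  ))
  check_columns(articles, REQUIRED_SOURCE_COLS, "Source")

  bct_codings <- readr::read_csv(bct_path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  check_columns(bct_codings, REQUIRED_BCT_COLS, "BCT")

  links <- readr::read_csv(link_path, col_types = readr::cols(
    article_id = readr::col_character(),
    bct_code = readr::col_character(),
    explicitness = readr::col_integer(),
    grouping = readr::col_integer(),
    empirical_status = readr::col_integer(),
    .default = readr::col_character()
  ))
  check_columns(links, REQUIRED_LINK_COLS, "Link")
  if (!"moa_definition_raw" %in% names(links)) {
    links$moa_definition_raw <- NA_character_
  }
  if (!"moa_category" %in% names(links)) {
    links$moa_category <- MOA_UNRESOLVED
  }
  links$moa_category[is.na(links$moa_category)] <- MOA_UNRESOLVED

  if (anyDuplicated(articles$article_id)) {
    abort("Duplicate article_id in source table.",
          class = "moalink_validation_error")
  }
  bad_codes <- unique(c(setdiff(links$bct_code, registry$code),
                        setdiff(bct_codings$bct_code, registry$code)))
  if (length(bad_codes) > 0) {
    rows <- which(links$bct_code %in% bad_codes)
    abort(sprintf("Unknown BCT code(s) %s (link rows: %s)",
                  paste(bad_codes, collapse = ", "),
                  paste(head(rows, 10), collapse = ", ")),
          class = "moalink_validation_error")
  }
  orphans <- unique(c(setdiff(links$article_id, articles$article_id),
                      setdiff(bct_codings$article_id, articles$article_id)))
  if (length(orphans) > 0) {
    abort(sprintf("Link/BCT rows cite article id(s) absent from the source table: %s",
                  paste(orphans, collapse = ", ")),
          class = "moalink_integrity_error")
  }
  coded <- paste(bct_codings$article_id, bct_codings$bct_code)
  unlisted <- !(paste(links$article_id, links$bct_code) %in% coded)
  if (any(unlisted)) {
    abort(sprintf("Link rows cite BCTs not coded for their article (rows: %s)",
                  paste(head(which(unlisted), 10), collapse = ", ")),
          class = "moalink_integrity_error")
  }
  new_moa_corpus(articles, bct_codings, links)
}

#' Write a corpus back to its three CSV tables
#'
#' @param corpus A `moa_corpus`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix; files are `<prefix>source.csv`,
#'   `<prefix>bct.csv`, `<prefix>link.csv`.
#' @return Invisibly, a named character vector of the three paths.
#' @export
write_corpus <- function(corpus, dir, prefix = "") {
  stopifnot(inherits(corpus, "moa_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    source = file.path(dir, paste0(prefix, "source.csv")),
    bct = file.path(dir, paste0(prefix, "bct.csv")),
    link = file.path(dir, paste0(prefix, "link.csv"))
  )
  readr::write_csv(corpus$articles, paths[["source"]], na = "")
  readr::write_csv(corpus$bct_codings, paths[["bct"]], na = "")
  readr::write_csv(corpus$links, paths[["link"]], na = "")
  invisible(paths)
}

#' Resolve the unresolved MoA labels in a corpus
#'
#' Applies [resolve_moa_label()] to every link whose `moa_category` is
#' `"UNRESOLVED"`, leaving already-categorized rows untouched.
#'
#' @param corpus A `moa_corpus`.
#' @param synonyms Synonym map passed to [resolve_moa_label()].
#' @return The corpus with `links$moa_category` filled in.
#' @export
resolve_corpus_moas <- function(corpus, synonyms = moa_synonym_map()) {
  stopifnot(inherits(corpus, "moa_corpus"))
  links <- corpus$links
  todo <- links$moa_category == MOA_UNRESOLVED
  if (any(todo)) {
    links$moa_category[todo] <- resolve_moa_label(links$moa_label_raw[todo],
                                                  synonyms = synonyms)
  }
  corpus$links <- links
  corpus
}

#' @export
print.moa_corpus <- function(x, ...) {
  cat(sprintf("<moa_corpus> %d articles, %d BCT codings, %d link statements\n",
              nrow(x$articles), nrow(x$bct_codings), nrow(x$links)))
  invisible(x)
}

#' Validate a corpus and report problems
#'
#' A reporting operation: it never throws. Checks flag enumerations,
#' duplicate (pre-deduplication) link statements, referential integrity and
#' unresolved MoA labels.
#'
#' @param corpus A `moa_corpus`.
#' @return A tibble with columns `level` (`"error"`, `"warning"`, `"info"`),
#'   `check` and `message`; zero `error` rows means the corpus is valid.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "moa_corpus"))
  links <- corpus$links
  report <- list()
  add <- function(level, check, message) {
    report[[length(report) + 1]] <<- tibble::tibble(
      level = level, check = check, message = message)
  }

  if (anyDuplicated(corpus$articles$article_id)) {
    add("error", "unique_articles", "Duplicate article_id in source table.")
  }
  orphans <- setdiff(links$article_id, corpus$articles$article_id)
  if (length(orphans) > 0) {
    add("error", "orphan_links",
        sprintf("%d link row(s) cite unknown article id(s): %s",
                sum(links$article_id %in% orphans),
                paste(orphans, collapse = ", ")))
  }
  coded <- paste(corpus$bct_codings$article_id, corpus$bct_codings$bct_code)
  uncoded <- !(paste(links$article_id, links$bct_code) %in% coded)
  if (any(uncoded)) {
    add("error", "uncoded_bcts",
        sprintf("%d link row(s) cite a BCT not coded for their article.",
                sum(uncoded)))
  }
  bad_flag <- function(x, allowed) !is.na(x) & !(x %in% allowed)
  n_flag <- sum(bad_flag(links$explicitness, 1:2)) +
    sum(bad_flag(links$grouping, 1:2)) +
    sum(bad_flag(links$empirical_status, 1:3))
  if (n_flag > 0) {
    add("error", "flag_range",
        sprintf("%d flag value(s) outside their enumerations.", n_flag))
  }
  valid_cat <- c(as.character(1:26), MOA_OTHER, MOA_UNRESOLVED)
  n_cat <- sum(!links$moa_category %in% valid_cat)
  if (n_cat > 0) {
    add("error", "moa_category",
        sprintf("%d link row(s) with invalid moa_category.", n_cat))
  }
  dup <- duplicated(links[, c("article_id", "bct_code", "moa_category")])
  if (any(dup)) {
    add("warning", "duplicate_statements",
        sprintf("%d duplicated (article, BCT, MoA) statement(s); deduplicate_links() will keep one per article.",
                sum(dup)))
  }
  n_unres <- sum(links$moa_category == MOA_UNRESOLVED)
  if (n_unres > 0) {
    add("info", "unresolved_moas",
        sprintf("%d link row(s) with UNRESOLVED MoA labels.", n_unres))
  }
  if (length(report) == 0) {
    return(tibble::tibble(level = character(), check = character(),
                          message = character()))
  }
  dplyr::bind_rows(report)
}

#' Inter-coder agreement: percent agreement and PABAK
#'
#' For double-coded extraction decisions, computes observed percent
#' agreement \eqn{p_o} and the Prevalence and Bias Adjusted Kappa,
#' \eqn{PABAK = 2 p_o - 1}, the chance-corrected agreement statistic of
#' choice when negative agreement is highly prevalent.
#'
#' @param n_items Number of decisions compared (> 0).
#' @param n_agreements Number of decisions on which both coders agree.
#' @return A one-row tibble: `n_items`, `n_agreements`,
#'   `percent_agreement`, `pabak`.
#' @examples
#' coding_agreement(100, 95)  # pabak 0.90
#' @export
coding_agreement <- function(n_items, n_agreements) {
  if (length(n_items) != 1 || is.na(n_items) || n_items <= 0) {
    abort("n_items must be a single positive count.",
          class = "moalink_validation_error")
  }
  if (n_agreements < 0 || n_agreements > n_items) {
    abort("n_agreements must lie in [0, n_items].",
          class = "moalink_validation_error")
  }
  p_o <- n_agreements / n_items
  tibble::tibble(n_items = n_items, n_agreements = n_agreements,
                 percent_agreement = p_o, pabak = 2 * p_o - 1)
}

#' Read the packaged table of enrichment-significant links
#'
#' The package ships a transcription of the published summary tables of
#' links meeting the p < .05 relative-frequency criterion, once grouped by
#' technique and once grouped by mechanism. Both transcriptions are read,
#' checked against each other row by row, and reconciled into a single link
#' set; any disagreement between the two views is treated as fixture
#' corruption.
#'
#' @param path Optional path to an alternative fixture CSV with columns
#'   `source_table,bct_code,moa_id,frequency,p_display`.
#' @param alpha Significance bound every row must satisfy (default .05).
#' @return A tibble with columns `bct_code`, `moa_id`, `frequency`,
#'   `p_display`, `p_value` (the printed value or censoring bound) and
#'   `censored`, one row per distinct significant link.
#' @examples
#' sig <- read_significant_links()
#' nrow(sig)  # 87
#' @export
read_significant_links <- function(path = NULL, alpha = 0.05) {
  path <- path %||% moalink_extdata("significant_links.csv")
  raw <- readr::read_csv(path, col_types = readr::cols(
    source_table = readr::col_integer(),
    bct_code = readr::col_character(),
    moa_id = readr::col_integer(),
    frequency = readr::col_integer(),
    p_display = readr::col_character()
  ))
  if (nrow(raw) == 0) {
    abort("Significant-links fixture is empty.",
          class = "moalink_fixture_error")
  }
  views <- split(raw[, c("bct_code", "moa_id", "frequency", "p_display")],
                 raw$source_table)
  if (length(views) == 2) {
    key <- function(v) do.call(paste, c(v[order(v$bct_code, v$moa_id), ],
                                        sep = "\r"))
    if (!identical(sort(key(views[[1]])), sort(key(views[[2]])))) {
      abort("Fixture corruption: the two table views disagree on the link set.",
            class = "moalink_fixture_error")
    }
  }
  links <- dplyr::distinct(raw, .data$bct_code, .data$moa_id,
                           .keep_all = TRUE)
  links$source_table <- NULL
  parsed <- parse_p_display(links$p_display)
  links$p_value <- parsed$p_value
  links$censored <- parsed$censored
  if (any(links$p_value <= 0 | links$p_value > alpha)) {
    abort("Fixture corruption: p-value display outside (0, alpha].",
          class = "moalink_fixture_error")
  }
  if (any(links$frequency < 1)) {
    abort("Fixture corruption: link frequency below 1.",
          class = "moalink_fixture_error")
  }
  tibble::as_tibble(links)
}
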