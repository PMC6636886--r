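#' Load the BCT taxonomy registry
#'
#' Reads the packaged transcription of the 93-technique Behavior Change
#' Technique Taxonomy (BCTTv1). Each technique carries a hierarchical code
#' (e.g. `"8.7"`) whose leading integer is the higher-order cluster.
#'
#' @param path Optional path to an alternative registry CSV with columns
#'   `code,label`. Defaults to the file shipped with the package.
#' @return A tibble with columns `code` (character), `label` (character) and
#'   `group_number` (integer cluster index parsed from the code).
#' @examples
#' reg <- bct_registry()
#' nrow(reg)  # 93
#' reg$label[reg$code == "1.1"]
#' @export
bct_registry <- function(path = NULL) {
  path <- path %||% moalink_extdata("bct_taxonomy.csv")
  reg <- readr::read_csv(path, col_types = readr::cols(
    code = readr::col_character(),
    label = readr::col_character()
  ))
  if (!all(c("code", "label") %in% names(reg))) {
    abort("BCT registry must have columns 'code' and 'label'.",
          class = "moalink_config_error")
  }
  if (anyDuplicated(reg$code)) {
    abort("BCT registry contains duplicate codes.",
          class = "moalink_config_error")
  }
  if (!all(grepl("^[0-9]+\\.[0-9]+$", reg$code))) {
    abort("BCT codes must match the pattern <digits>.<digits>.",
          class = "moalink_config_error")
  }
  if (any(is.na(reg$label) | !nzchar(reg$label))) {
    abort("BCT registry labels must be nonempty.",
          class = "moalink_config_error")
  }
  if (nrow(reg) != 93L) {
    abort(sprintf("BCT registry must contain exactly 93 techniques, found %d.",
                  nrow(reg)),
          class = "moalink_config_error")
  }
  dplyr::mutate(reg,
                group_number = as.integer(sub("\\..*$", "", .data$code)))
}

#' Look up BCT labels by code
#'
#' @param code Character vector of taxonomy codes (e.g. `"5.1"`).
#' @param registry A BCT registry tibble, by default [bct_registry()].
#' @return Character vector of labels.
#' @examples
#' bct_label("8.7")
#' @export
bct_label <- function(code, registry = bct_registry()) {
  idx <- match(code, registry$code)
  if (anyNA(idx)) {
    abort(paste0("Unknown BCT code(s): ",
                 paste(unique(code[is.na(idx)]), collapse = ", ")),
          class = "moalink_lookup_error")
  }
  registry$label[idx]
}

#' Load the mechanism-of-action registry
#'
#' Reads the packaged set of 26 mechanism-of-action constructs: the 14
#' domains of the Theoretical Domains Framework plus 12 constructs frequent
#' across theories of behavior change, each with its working definition.
#'
#' @param path Optional path to an alternative registry CSV with columns
#'   `id,label,definition,source`.
#' @return A tibble with columns `id` (integer 1-26), `label`, `definition`
#'   and `source` (one of `"TDF-domain"`, `"theory-derived"`).
#' @examples
#' moa <- moa_registry()
#' table(moa$source)
#' @export
moa_registry <- function(path = NULL) {
  path <- path %||% moalink_extdata("moa_constructs.csv")
  reg <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_integer(),
    label = readr::col_character(),
    definition = readr::col_character(),
    source = readr::col_character()
  ))
  needed <- c("id", "label", "definition", "source")
  if (!all(needed %in% names(reg))) {
    abort("MoA registry must have columns id, label, definition, source.",
          class = "moalink_config_error")
  }
  if (nrow(reg) != 26L || anyDuplicated(reg$id) || anyDuplicated(reg$label)) {
    abort("MoA registry must contain 26 uniquely identified constructs.",
          class = "moalink_config_error")
  }
  if (!setequal(reg$id, 1:26)) {
    abort("MoA ids must be the integers 1 through 26.",
          class = "moalink_config_error")
  }
  if (any(is.na(reg$definition) | !nzchar(reg$definition))) {
    abort("Every MoA construct must carry a definition.",
          class = "moalink_config_error")
  }
  if (!all(reg$source %in% c("TDF-domain", "theory-derived"))) {
    abort("MoA source must be 'TDF-domain' or 'theory-derived'.",
          class = "moalink_config_error")
  }
  if (sum(reg$source == "TDF-domain") != 14L) {
    abort("Exactly 14 MoA constructs must be TDF domains.",
          class = "moalink_config_error")
  }
  reg
}

#' Load the MoA synonym map
#'
#' The packaged seed maps a small set of free-text author labels (for
#' example "self-efficacy", conceptually identical to Beliefs about
#' Capabilities) onto registry ids. Canonical registry labels always
#' resolve without an entry here. The map is intentionally minimal and
#' user-extensible via `extra`; coder judgment on idiosyncratic labels
#' cannot be automated, so unmatched labels resolve to `"OTHER"`.
#'
#' @param path Optional path to a CSV with columns `synonym,moa_id`.
#' @param extra Optional tibble/data.frame with columns `synonym,moa_id`
#'   appended to (and overriding) the packaged seed.
#' @param registry MoA registry used to check referential integrity.
#' @return A tibble with columns `synonym` (normalized) and `moa_id`.
#' @export
moa_synonym_map <- function(path = NULL, extra = NULL,
                            registry = moa_registry()) {
  path <- path %||% moalink_extdata("moa_synonyms.csv")
  map <- readr::read_csv(path, col_types = readr::cols(
    synonym = readr::col_character(),
    moa_id = readr::col_integer()
  ))
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    stopifnot(all(c("synonym", "moa_id") %in% names(extra)))
    map <- dplyr::bind_rows(extra, map)
  }
  map <- dplyr::mutate(map, synonym = normalize_label(.data$synonym))
  map <- dplyr::distinct(map, .data$synonym, .keep_all = TRUE)
  if (!all(map$moa_id %in% registry$id)) {
    abort("Synonym map references MoA ids absent from the registry.",
          class = "moalink_config_error")
  }
  map
}

#' Resolve free-text MoA labels to registry categories
#'
#' Labels are normalized (case, whitespace, quotes) and matched first
#' against the canonical registry labels, then against the synonym map.
#' Labels that match neither resolve to the sentinel `"OTHER"`.
#'
#' @param raw_label Character vector of author labels; must be nonempty.
#' @param synonyms Synonym map, by default [moa_synonym_map()].
#' @param registry MoA registry, by default [moa_registry()].
#' @return Character vector: a registry id (`"1"`..`"26"`) or `"OTHER"`.
#' @examples
#' resolve_moa_label(c("Beliefs about Capabilities", "self-efficacy"))
#' @export
resolve_moa_label <- function(raw_label, synonyms = moa_synonym_map(),
                              registry = moa_registry()) {
  raw_label <- as.character(raw_label)
  if (length(raw_label) == 0) return(character(0))
  if (any(is.na(raw_label) | !nzchar(trimws(raw_label)))) {
    abort("MoA labels must be nonempty.", class = "moalink_validation_error")
  }
  norm <- normalize_label(raw_label)
  canonical <- match(norm, normalize_label(registry$label))
  out <- as.character(registry$id[canonical])
  syn <- match(norm, synonyms$synonym)
  out[is.na(out)] <- as.character(synonyms$moa_id[syn[is.na(out)]])
  out[is.na(out)] <- MOA_OTHER
  out
}
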