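#' Normalize a free-text construct label
#'
#' Lowercases, trims, collapses internal whitespace, and strips straight and
#' typographic quote characters, so that transcription variants of the same
#' label compare equal.
#'
#' @param x Character vector of labels.
#' @return Character vector of normalized labels.
#' @examples
#' normalize_label(c("  Beliefs about   Capabilities ", "“Norms”"))
#' @export
normalize_label <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[\"'‘’“”]", "", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Round half away from zero (commercial rounding); base round() ties to even.
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format p-values in the censored display convention
#'
#' Values below .001 are printed as "<.001", all others with three decimals
#' and no leading zero (e.g. ".008").
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Character vector.
#' @examples
#' format_p(c(0.0004, 0.008, 0.0432))
#' @export
format_p <- function(p) {
  stopifnot(is.numeric(p))
  out <- ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.3f", p)))
  out[is.na(p)] <- NA_character_
  out
}

#' Parse censored p-value display strings
#'
#' Accepts strings such as ".008", "0.013", "<.001" or "<.050" and returns
#' the numeric value (for censored strings, the printed bound) together with
#' a flag marking censoring.
#'
#' @param x Character vector of display strings.
#' @return A tibble with columns `p_display`, `p_value`, `censored`.
#' @examples
#' parse_p_display(c(".008", "<.001"))
#' @export
parse_p_display <- function(x) {
  x <- trimws(as.character(x))
  censored <- startsWith(x, "<")
  num <- suppressWarnings(as.numeric(sub("^<", "", x)))
  if (anyNA(num[!is.na(x)])) {
    bad <- x[is.na(num) & !is.na(x)]
    abort(paste0("Unparseable p-value display string(s): ",
                 paste(unique(bad), collapse = ", ")),
          class = "moalink_parse_error")
  }
  tibble::tibble(p_display = x, p_value = num, censored = censored)
}

# Run an expression with a locally seeded RNG, restoring (or removing) the
# global .Random.seed afterwards so package functions leave no global state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

moalink_extdata <- function(file) {
  path <- system.file("extdata", file, package = "moalink")
  if (!nzchar(path)) {
    abort(paste0("Packaged data file not found: ", file),
          class = "moalink_config_error")
  }
  path
}
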