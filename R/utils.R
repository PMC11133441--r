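#' Round-half-up percentage of a count over a denominator
#'
#' FAERS summary tables print percentages rounded half-up (so 0.55 at one
#' decimal becomes 0.6, never 0.5 as banker's rounding would give). The
#' computation is done in exact integer arithmetic to avoid binary floating
#' point landing an exact .5 on the wrong side.
#'
#' @param count Nonnegative integer count (vectorised).
#' @param denominator Positive integer denominator.
#' @param digits Number of decimal places to keep (default 1).
#' @return Numeric vector: `100 * count / denominator` rounded half-up.
#' @examples
#' percent(1568, 17894, 2) # 8.76
#' percent(1436, 2595, 1)  # 55.3
#' @export
percent <- function(count, denominator, digits = 1) {
  if (any(!is.finite(denominator)) || any(denominator <= 0)) {
    stop("percent(): denominator must be a positive integer", call. = FALSE)
  }
  if (any(!is.finite(count)) || any(count < 0)) {
    stop("percent(): count must be nonnegative", call. = FALSE)
  }
  # exact: all operands integers representable in doubles (< 2^53)
  scaled <- count * 100 * 10^digits
  q <- scaled %/% denominator
  r <- scaled - q * denominator
  (q + as.numeric(2 * r >= denominator)) / 10^digits
}

#' Normalize a MedDRA preferred-term string for matching
#'
#' Trims, collapses internal whitespace and case-folds. Used for every join
#' between reaction rows, PT->SOC map keys and planted-signal names, so the
#' same verbatim term in different casings counts as one PT.
#'
#' @param x Character vector of verbatim PT strings.
#' @return Character vector of normalized keys.
#' @export
normalize_pt <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

# modal verbatim casing per normalized key; ties broken alphabetically
.display_casing <- function(verbatim, key = normalize_pt(verbatim)) {
  verbatim <- trimws(gsub("[[:space:]]+", " ", verbatim))
  tab <- table(key, verbatim)
  pick <- apply(tab, 1L, function(row) names(row)[which.max(row)])
  setNames(as.character(pick), rownames(tab))
}

# user-facing (as opposed to internal) error, used by the CLI to set exit code 1
abort_user <- function(msg) {
  stop(structure(
    class = c("faersignal_user_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
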