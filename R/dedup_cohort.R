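# FDA-recommended case deduplication and target-drug cohort construction.
# All downstream counting (descriptive tables and 2x2 cells) runs off the
# event list built here: one row per distinct (report, PT) pair, flagged by
# cohort membership.

#' Deduplicate DEMO records by case
#'
#' Applies the FDA-recommended rule: among report versions sharing a
#' `case_id`, keep the one with the largest `fda_dt`; among those, the largest
#' `primary_id` (compared numerically when every id in the table parses as a
#' number, lexicographically otherwise). Output order is deterministic
#' (sorted by `case_id`), so the result is independent of input order.
#'
#' @param records DEMO tibble from [parse_faers_table()].
#' @return List of class `dedup_result` with elements `kept` (one record per
#'   case), `removed_count` and `input_count`.
#' @export
deduplicate_demo <- function(records) {
  stopifnot(all(c("case_id", "primary_id", "fda_dt") %in% names(records)))
  n_in <- nrow(records)
  pid_num <- suppressWarnings(as.numeric(records$primary_id))
  pid_key <- if (n_in > 0L && !anyNA(pid_num)) pid_num
             else xtfrm(records$primary_id)
  ord <- order(records$case_id, -records$fda_dt, -pid_key)
  ranked <- records[ord, , drop = FALSE]
  kept <- ranked[!duplicated(ranked$case_id), , drop = FALSE]
  structure(
    list(kept = kept, removed_count = n_in - nrow(kept), input_count = n_in),
    class = "dedup_result"
  )
}

#' @export
print.dedup_result <- function(x, ...) {
  cat(sprintf("FAERS deduplication: %d report versions -> %d cases (%d removed)\n",
              x$input_count, nrow(x$kept), x$removed_count))
  invisible(x)
}

#' Match drug rows against a list of search names
#'
#' A row matches when any search string occurs case-insensitively as a
#' substring of either the verbatim drug name or the active-ingredient field.
#' Substring (not exact) matching is used because FAERS verbatim names carry
#' doses, salts and brand decorations ("XPOVIO 80MG").
#'
#' @param drugs DRUG tibble (columns `drug_name`, `active_ingredient`).
#' @param names Non-empty character vector of search strings, e.g.
#'   `c("selinexor", "xpovio")`.
#' @return Logical vector, one element per drug row.
#' @export
match_drug_name <- function(drugs, names) {
  if (length(names) == 0L || all(!nzchar(names))) {
    stop("match_drug_name(): 'names' must be a non-empty character vector",
         call. = FALSE)
  }
  hay1 <- tolower(drugs$drug_name)
  hay2 <- tolower(drugs$active_ingredient)
  hit <- rep(FALSE, nrow(drugs))
  for (nm in tolower(names)) {
    hit <- hit |
      (!is.na(hay1) & grepl(nm, hay1, fixed = TRUE)) |
      (!is.na(hay2) & grepl(nm, hay2, fixed = TRUE))
  }
  hit
}

#' Build the target-drug cohort and the case-PT event list
#'
#' The cohort is the set of deduplicated reports carrying at least one drug
#' row that matches the search names with the requested role code (default
#' primary suspect). The event list holds one row per distinct
#' (`primary_id`, normalized PT) pair for every kept report, flagged
#' `is_target_drug` by cohort membership; reports from all other drugs form
#' the background used for the c/d cells of the 2x2 tables. A PT repeated
#' within one report counts once. PTs are reported in their most frequent
#' verbatim casing.
#'
#' @param dedup `dedup_result` from [deduplicate_demo()].
#' @param drugs DRUG tibble.
#' @param reactions REAC tibble.
#' @param names Drug search strings (see [match_drug_name()]).
#' @param role Role code required for cohort membership (default `"PS"`).
#' @return List of class `faers_cohort`: `cohort_ids` (sorted primary ids),
#'   `events` (tibble: primary_id, case_id, pt, is_target_drug),
#'   `n_unmatched_reactions` (reaction rows referencing a primary_id absent
#'   from the kept DEMO records, excluded from events).
#' @export
build_cohort <- function(dedup, drugs, reactions, names, role = "PS") {
  stopifnot(inherits(dedup, "dedup_result"))
  role <- match.arg(toupper(role), .ROLE_CODES)
  kept <- dedup$kept

  drugs_k <- drugs[drugs$primary_id %in% kept$primary_id, , drop = FALSE]
  hit <- match_drug_name(drugs_k, names) & drugs_k$role_code == role
  cohort_ids <- sort(unique(drugs_k$primary_id[hit]))

  known <- reactions$primary_id %in% kept$primary_id
  n_unmatched <- sum(!known)
  reac <- reactions[known, , drop = FALSE]

  key <- normalize_pt(reac$pt)
  ok <- nzchar(key)
  reac <- reac[ok, , drop = FALSE]
  key <- key[ok]

  display <- if (nrow(reac) > 0L) .display_casing(reac$pt, key)
             else setNames(character(0), character(0))

  ev <- tibble(primary_id = reac$primary_id, pt_key = key)
  ev <- ev[!duplicated(ev), , drop = FALSE]
  case_lookup <- setNames(kept$case_id, kept$primary_id)
  events <- tibble(
    primary_id = ev$primary_id,
    case_id = unname(case_lookup[ev$primary_id]),
    pt = unname(display[ev$pt_key]),
    is_target_drug = ev$primary_id %in% cohort_ids
  )
  events <- events[order(events$primary_id, events$pt), , drop = FALSE]

  structure(
    list(cohort_ids = cohort_ids, events = events,
         n_unmatched_reactions = n_unmatched),
    class = "faers_cohort"
  )
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat(sprintf(
    "FAERS cohort: %d target reports; %d target events, %d background events\n",
    length(x$cohort_ids), sum(x$events$is_target_drug),
    sum(!x$events$is_target_drug)))
  if (x$n_unmatched_reactions > 0L) {
    cat(sprintf("  (%d reaction rows referenced unknown reports and were dropped)\n",
                x$n_unmatched_reactions))
  }
  invisible(x)
}
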