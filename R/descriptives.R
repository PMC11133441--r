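# Descriptive summaries of a deduplicated cohort: demographics, severe
# outcomes, PT/SOC frequency tables, annual report counts and grouped PT
# sums. Every table carries (category, n, percent) with percent computed
# half-up over an explicit denominator.

.freq_tbl <- function(category, n, denominator, digits) {
  tibble(category = category, n = as.integer(n),
         percent = percent(n, denominator, digits))
}

# age in years from (value, unit); YR/MON/DY supported, others missing
.age_years <- function(age_value, age_unit) {
  unit <- toupper(age_unit)
  ifelse(is.na(age_value), NA_real_,
    ifelse(is.na(unit) | unit %in% c("YR", "YRS"), age_value,
      ifelse(unit == "MON", age_value / 12,
        ifelse(unit == "DY", age_value / 365.25, NA_real_))))
}

.OCCP_LABELS <- c(CN = "Consumer", MD = "Physician", HP = "Health-profession",
                  PH = "Pharmacist", OT = "Other health-profession")

#' Clinical-characteristics tables for a cohort
#'
#' Reproduces the layout of a FAERS demographics table: gender
#' (Male/Female/N/A), age bands in years (18-64, >=65, N/A), weight bands in
#' kilograms (<80, 80-100 closed, >100, N/A), reporter occupation and the
#' top-k reporting countries. All denominators equal the cohort size. Ages
#' under 18 have no band of their own and are placed in N/A with a warning
#' rather than silently dropped. Occupation codes outside the labelled set
#' (e.g. LW) fall under "Unknown" together with missing values.
#'
#' @param demo Deduplicated DEMO records restricted to the cohort.
#' @param digits Decimal places for percentages (default 1).
#' @param top_countries Number of country rows (default 5).
#' @return Named list of tibbles (`gender`, `age`, `weight`, `reporter`,
#'   `country`), each with columns category/n/percent; attribute
#'   `denominator` = cohort size.
#' @export
demographic_table <- function(demo, digits = 1, top_countries = 5) {
  n <- nrow(demo)
  if (n == 0L) stop("demographic_table(): empty cohort", call. = FALSE)

  gender <- .freq_tbl(
    c("Male", "Female", "N/A"),
    c(sum(demo$sex == "M", na.rm = TRUE),
      sum(demo$sex == "F", na.rm = TRUE),
      sum(is.na(demo$sex))),
    n, digits)

  age <- .age_years(demo$age_value, demo$age_unit)
  under18 <- sum(!is.na(age) & age < 18)
  if (under18 > 0L) {
    warning(sprintf("%d record(s) with age < 18 placed in the N/A band",
                    under18), call. = FALSE)
  }
  age_tbl <- .freq_tbl(
    c("18-64", ">=65", "N/A"),
    c(sum(!is.na(age) & age >= 18 & age < 65),
      sum(!is.na(age) & age >= 65),
      sum(is.na(age)) + under18),
    n, digits)

  wt <- demo$weight_kg
  weight_tbl <- .freq_tbl(
    c("<80", "80-100", ">100", "N/A"),
    c(sum(!is.na(wt) & wt < 80),
      sum(!is.na(wt) & wt >= 80 & wt <= 100),
      sum(!is.na(wt) & wt > 100),
      sum(is.na(wt))),
    n, digits)

  occ <- demo$reporter_occupation
  occ_lab <- unname(.OCCP_LABELS[occ])
  occ_lab[is.na(occ_lab)] <- "Unknown"
  occ_counts <- vapply(c(.OCCP_LABELS, "Unknown"),
                       function(l) sum(occ_lab == l), integer(1))
  reporter <- .freq_tbl(names(occ_counts), occ_counts, n, digits)

  ctry <- demo$reporter_country[!is.na(demo$reporter_country)]
  country <- if (length(ctry) == 0L) {
    tibble(category = character(0), n = integer(0), percent = numeric(0))
  } else {
    tab <- sort(table(ctry), decreasing = TRUE)
    top <- head(tab, top_countries)
    .freq_tbl(names(top), as.integer(top), n, digits)
  }

  structure(
    list(gender = gender, age = age_tbl, weight = weight_tbl,
         reporter = reporter, country = country),
    denominator = n, class = "faers_demographics")
}

.OUTCOME_LABELS <- c(
  HO = "Hospitalized", DE = "Death", LT = "Life-threatening",
  DS = "Disability", RI = "Resulted in permanent impairment/disability",
  CA = "Congenital anomaly", OT = "Other")

#' Severe-outcome distribution
#'
#' Counts one instance per distinct (report, outcome code) pair over the
#' cohort's OUTC rows; the denominator is the total number of severe-outcome
#' instances (all seven FAERS codes count as severe, including "Other").
#'
#' @param outcomes OUTC tibble restricted to the cohort.
#' @param digits Decimal places for percentages (default 1).
#' @return Tibble (category, n, percent) over the seven outcome labels, with
#'   attribute `denominator` (total instances). Percentages are NA when there
#'   are no instances.
#' @export
outcome_table <- function(outcomes, digits = 1) {
  inst <- unique(outcomes[c("primary_id", "outcome_code")])
  counts <- unname(vapply(names(.OUTCOME_LABELS),
                          function(code) sum(inst$outcome_code == code),
                          integer(1)))
  denom <- sum(counts)
  pct <- if (denom > 0) percent(counts, denom, digits)
         else rep(NA_real_, length(counts))
  out <- tibble(category = unname(.OUTCOME_LABELS), n = as.integer(counts),
                percent = pct)
  attr(out, "denominator") <- denom
  out
}

#' Preferred-term frequency table for target-drug events
#'
#' Counts per PT over events flagged `is_target_drug`, sorted by descending
#' count with alphabetical tie-break; the percentage denominator is the total
#' number of target events (not only the displayed rows).
#'
#' @param events Event tibble from [build_cohort()].
#' @param top_n Number of rows to keep (default all).
#' @param digits Decimal places (default 2).
#' @return Tibble (pt, n, percent) with attribute `denominator`.
#' @export
pt_frequency <- function(events, top_n = Inf, digits = 2) {
  tev <- events[events$is_target_drug, , drop = FALSE]
  total <- nrow(tev)
  if (total == 0L) {
    out <- tibble(pt = character(0), n = integer(0), percent = numeric(0))
    attr(out, "denominator") <- 0L
    return(out)
  }
  tab <- table(tev$pt)
  out <- tibble(pt = names(tab), n = as.integer(tab))
  out <- out[order(-out$n, out$pt), , drop = FALSE]
  out$percent <- percent(out$n, total, digits)
  if (is.finite(top_n)) out <- head(out, top_n)
  attr(out, "denominator") <- total
  out
}

#' System-organ-class frequency table
#'
#' Maps target events to SOCs via a user-supplied PT->SOC map. Events whose
#' PT is absent from the map are collected under the `unmapped_n` attribute
#' and excluded from the SOC denominator, so the SOC total is smaller than the
#' PT total whenever the map is incomplete.
#'
#' @param events Event tibble from [build_cohort()].
#' @param map `pt_soc_map` from [load_pt_soc_map()].
#' @param top_n Number of rows to keep (default all).
#' @param digits Decimal places (default 2).
#' @return Tibble (soc, n, percent), attributes `denominator` (mapped events)
#'   and `unmapped_n`.
#' @export
soc_frequency <- function(events, map, top_n = Inf, digits = 2) {
  tev <- events[events$is_target_drug, , drop = FALSE]
  soc <- unname(unclass(map)[normalize_pt(tev$pt)])
  unmapped <- sum(is.na(soc))
  soc <- soc[!is.na(soc)]
  denom <- length(soc)
  out <- if (denom == 0L) {
    tibble(soc = character(0), n = integer(0), percent = numeric(0))
  } else {
    tab <- table(soc)
    o <- tibble(soc = names(tab), n = as.integer(tab))
    o <- o[order(-o$n, o$soc), , drop = FALSE]
    o$percent <- percent(o$n, denom, digits)
    if (is.finite(top_n)) o <- head(o, top_n)
    o
  }
  attr(out, "denominator") <- denom
  attr(out, "unmapped_n") <- unmapped
  out
}

#' Annual distribution of cohort reports
#'
#' One count per calendar year of the FDA receipt date; years with zero
#' reports inside the observed range are emitted explicitly with count 0.
#'
#' @param demo Deduplicated DEMO records restricted to the cohort.
#' @return Tibble (year, n).
#' @export
annual_distribution <- function(demo) {
  yrs <- demo$event_year[!is.na(demo$event_year)]
  if (length(yrs) == 0L) return(tibble(year = integer(0), n = integer(0)))
  rng <- seq(min(yrs), max(yrs))
  tibble(year = as.integer(rng),
         n = vapply(rng, function(y) sum(yrs == y), integer(1)))
}

#' Grouped PT counts
#'
#' Sums target-event counts over named groups of PTs (e.g. a gastrointestinal
#' group of nausea/anorexia/diarrhea/vomiting/constipation), with percentages
#' over the total number of target events. Groups may overlap; overlaps are
#' reported with a warning.
#'
#' @param events Event tibble from [build_cohort()].
#' @param groups Named list of character vectors of PT names.
#' @param digits Decimal places (default 2).
#' @return Tibble (group, n, percent) with attribute `denominator`.
#' @export
group_pt_counts <- function(events, groups, digits = 2) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  tev <- events[events$is_target_drug, , drop = FALSE]
  total <- nrow(tev)
  if (total == 0L) stop("group_pt_counts(): no target events", call. = FALSE)
  key <- normalize_pt(tev$pt)

  members <- lapply(groups, normalize_pt)
  all_members <- unlist(members, use.names = FALSE)
  overlap <- unique(all_members[duplicated(all_members)])
  if (length(overlap) > 0L) {
    warning(sprintf("PT(s) present in more than one group: %s",
                    paste(overlap, collapse = ", ")), call. = FALSE)
  }
  n <- vapply(members, function(m) sum(key %in% m), integer(1))
  out <- tibble(group = names(groups), n = as.integer(n),
                percent = percent(n, total, digits))
  attr(out, "denominator") <- total
  out
}
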