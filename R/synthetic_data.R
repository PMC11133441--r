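# FAERS-like synthetic data. The generator emulates the structural features
# the pipeline depends on -- duplicate report versions sharing a case id,
# role-coded drug mentions, multi-PT reaction lists drawn from a background
# multinomial with optional planted drug-event signals, outcome codes and
# heavy demographic missingness -- with one root seed and per-table derived
# streams so the tables are individually stable.

.TARGET_NAME_VARIANTS <- c("XPOVIO", "SELINEXOR", "XPOVIO 80MG", "XPOVIO 100MG")
.OTHER_DRUGS <- c(
  "LENALIDOMIDE", "BORTEZOMIB", "DEXAMETHASONE", "POMALIDOMIDE",
  "DARATUMUMAB", "CARFILZOMIB", "RITUXIMAB", "CYCLOPHOSPHAMIDE",
  "IBUPROFEN", "METFORMIN", "ATORVASTATIN", "OMEPRAZOLE", "ASPIRIN",
  "LISINOPRIL", "AMLODIPINE", "GABAPENTIN", "LEVOTHYROXINE", "WARFARIN",
  "PREDNISONE", "FUROSEMIDE")
.COUNTRIES <- c("US", "CN", "CA", "IL", "AU", "GB", "DE", "FR", "JP", "IN")
.COUNTRY_W <- c(0.748, 0.040, 0.031, 0.027, 0.026, 0.035, 0.030, 0.025,
                0.020, 0.018)
.INDICATIONS_TARGET <- c("Multiple myeloma", "Plasma cell myeloma",
                         "Diffuse large B-cell lymphoma")
.INDICATIONS_OTHER <- c("Product used for unknown indication",
                        "Multiple myeloma", "Hypertension", "Pain",
                        "Type 2 diabetes mellitus")
.RPSR_CODES <- c("FGN", "SDY", "HP", "CSM", "OTH")

#' Default background PT vocabulary
#'
#' The 15 most frequent selinexor adverse events (with their published report
#' counts as multinomial weights) plus 85 generic background terms sharing the
#' remaining weight, so the default vocabulary reproduces a realistic
#' head-heavy PT frequency profile.
#'
#' @return Tibble with columns `pt`, `weight`.
#' @export
default_pt_vocabulary <- function() {
  top <- c("Nausea" = 1568, "Fatigue" = 1151,
           "Anorexia or loss of appetite" = 919, "Diarrhea" = 774,
           "Vomiting" = 605, "Thrombocytopenia" = 525, "Death" = 466,
           "Lethargy" = 463, "Weight Loss" = 432,
           "Decreased platelet count" = 399, "Anemia" = 305,
           "Constipation" = 262, "Dizziness" = 261,
           "Infectious pneumonia" = 233, "Dehydration" = 203)
  filler_total <- 17894 - sum(top)
  filler <- setNames(rep(filler_total / 85, 85),
                     sprintf("Background PT %03d", seq_len(85)))
  tibble(pt = c(names(top), names(filler)),
         weight = unname(c(top, filler)))
}

#' Configuration for the synthetic FAERS generator
#'
#' Defaults mirror the reporting structure of the published selinexor cohort
#' where it is stated: ~4.07 events per report, a duplicate-version share such
#' that deduplication removes ~20.9% of DEMO rows, Table-2 missingness rates
#' (sex 69.7%, age 98%, weight 87.1%, occupation 1.2%) and Table-3 outcome
#' weights; the reporting window is July 2019 - June 2023. Scale parameters
#' the source does not state (number of cases, target-drug share) default to a
#' simulation-friendly 5000 cases with 5% target share.
#'
#' @param n_cases Number of distinct cases to simulate.
#' @param target_drug_prob Probability a case's primary-suspect drug is the
#'   target drug.
#' @param pt_vocabulary Tibble (pt, weight): background multinomial.
#' @param planted_signals Named numeric vector `c("Some PT" = rho, ...)`;
#'   within target-drug cases the named PTs' weights are multiplied by rho.
#' @param events_per_case Mean number of distinct PTs per case; the count is
#'   drawn as `1 + Poisson(events_per_case - 1)`.
#' @param duplicate_prob Probability a case also emits one earlier report
#'   version (same case id, smaller fda_dt/primary_id, identical content).
#' @param outcome_weights Named nonnegative weights over the seven outcome
#'   codes plus `"none"`.
#' @param missing_rates Named probabilities for masking `sex`, `age`,
#'   `weight`, `country`, `occupation`.
#' @param date_range Integer `c(start, end)` as YYYYMMDD.
#' @param seed Root seed; per-table streams are derived from it.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 5000,
                             target_drug_prob = 0.05,
                             pt_vocabulary = default_pt_vocabulary(),
                             planted_signals = NULL,
                             events_per_case = 4.07,
                             duplicate_prob = 0.26,
                             outcome_weights = c(HO = 1436, DE = 750, LT = 60,
                                                 DS = 20, RI = 1, CA = 0,
                                                 OT = 328, none = 1797),
                             missing_rates = c(sex = 0.697, age = 0.98,
                                               weight = 0.871, country = 0.05,
                                               occupation = 0.012),
                             date_range = c(20190701L, 20230630L),
                             seed = 1L) {
  bad <- function(field, why) {
    stop(sprintf("synthetic_config(): invalid '%s': %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(n_cases) || length(n_cases) != 1L || n_cases < 0 ||
      n_cases != floor(n_cases)) bad("n_cases", "nonnegative integer required")
  for (p in c("target_drug_prob", "duplicate_prob")) {
    v <- get(p)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      bad(p, "probability in [0,1] required")
  }
  if (!is.data.frame(pt_vocabulary) ||
      !all(c("pt", "weight") %in% names(pt_vocabulary)) ||
      nrow(pt_vocabulary) == 0L)
    bad("pt_vocabulary", "tibble with pt and weight columns required")
  if (any(pt_vocabulary$weight < 0) || all(pt_vocabulary$weight == 0))
    bad("pt_vocabulary", "weights must be nonnegative and not all zero")
  if (anyDuplicated(normalize_pt(pt_vocabulary$pt)))
    bad("pt_vocabulary", "duplicated PT")
  if (!is.null(planted_signals)) {
    if (!is.numeric(planted_signals) || is.null(names(planted_signals)))
      bad("planted_signals", "named numeric vector required")
    if (any(planted_signals <= 0))
      bad("planted_signals", "rate ratios must be > 0")
    unknown <- setdiff(normalize_pt(names(planted_signals)),
                       normalize_pt(pt_vocabulary$pt))
    if (length(unknown) > 0L)
      bad("planted_signals",
          paste("PT not in vocabulary:", paste(unknown, collapse = ", ")))
  }
  if (!is.numeric(events_per_case) || events_per_case < 1)
    bad("events_per_case", "mean of at least 1 required")
  req_out <- c(.OUTCOME_CODES, "none")
  if (!all(req_out %in% names(outcome_weights)))
    bad("outcome_weights",
        paste("weights required for", paste(req_out, collapse = ", ")))
  if (any(outcome_weights < 0) || all(outcome_weights == 0))
    bad("outcome_weights", "nonnegative, not all zero")
  req_miss <- c("sex", "age", "weight", "country", "occupation")
  if (!all(req_miss %in% names(missing_rates)))
    bad("missing_rates",
        paste("rates required for", paste(req_miss, collapse = ", ")))
  if (any(missing_rates < 0 | missing_rates > 1))
    bad("missing_rates", "probabilities in [0,1] required")
  if (length(date_range) != 2L || !all(.valid_yyyymmdd(as.character(date_range))) ||
      date_range[1] > date_range[2])
    bad("date_range", "two valid YYYYMMDD integers, start <= end")
  if (!is.numeric(seed) || length(seed) != 1L || seed != floor(seed))
    bad("seed", "integer required")

  structure(list(
    n_cases = as.integer(n_cases), target_drug_prob = target_drug_prob,
    pt_vocabulary = as_tibble(pt_vocabulary[c("pt", "weight")]),
    planted_signals = planted_signals, events_per_case = events_per_case,
    duplicate_prob = duplicate_prob, outcome_weights = outcome_weights,
    missing_rates = missing_rates, date_range = as.integer(date_range),
    seed = as.integer(seed)), class = "synthetic_config")
}

.empty_tables <- function() {
  kinds <- .FAERS_KINDS
  out <- lapply(kinds, function(k) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    # build a zero-row typed tibble by writing/parsing an empty table
    sc <- .faers_schema[[k]]
    writeLines(paste(unname(sc$cols), collapse = "$"), tmp)
    parse_faers_table(tmp, k)
  })
  setNames(out, kinds)
}

# target-case PT weights: background weights with planted PTs scaled by rho
.planted_weights <- function(config) {
  w <- config$pt_vocabulary$weight
  if (!is.null(config$planted_signals)) {
    idx <- match(normalize_pt(names(config$planted_signals)),
                 normalize_pt(config$pt_vocabulary$pt))
    w[idx] <- w[idx] * config$planted_signals
  }
  w
}

#' Generate a synthetic FAERS-like dataset
#'
#' Draws `n_cases` cases: a primary-suspect drug (target with probability
#' `target_drug_prob`, otherwise a background drug, plus occasional
#' concomitant rows and occasional non-PS target-drug mentions to exercise
#' role filtering), `1 + Poisson(events_per_case - 1)` distinct PTs sampled
#' without replacement from the vocabulary (planted PTs re-weighted by rho in
#' target cases), demographics masked by the configured missingness, at most
#' one outcome code per case, and -- with probability `duplicate_prob` -- an
#' additional earlier report version differing only in `fda_dt`/`primary_id`.
#' Output is reproducible: the same config and seed yield identical tables.
#'
#' @param config A [synthetic_config()].
#' @return Named list of seven typed tibbles (`DEMO`, `DRUG`, `REAC`, `OUTC`,
#'   `INDI`, `THER`, `RPSR`) in the same form [parse_faers_table()] returns.
#' @export
generate_faers <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_cases
  if (n == 0L) return(.empty_tables())

  days <- seq(as.Date(as.character(config$date_range[1]), "%Y%m%d"),
              as.Date(as.character(config$date_range[2]), "%Y%m%d"), by = "day")
  as_int_date <- function(d) as.integer(format(d, "%Y%m%d"))

  # case frame stream
  set.seed(config$seed)
  case_id <- as.character(30000000L + seq_len(n))
  is_target <- runif(n) < config$target_drug_prob
  final_date <- sample(days, n, replace = TRUE)
  has_dup <- runif(n) < config$duplicate_prob
  dup_lag <- sample(0:180, n, replace = TRUE)
  primary_id <- paste0(case_id, ifelse(has_dup, "2", "1"))

  # demographics stream
  set.seed(config$seed + 1L)
  mr <- config$missing_rates
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.557, 0.443))
  sex[runif(n) < mr[["sex"]]] <- NA_character_
  age <- round(pmin(pmax(rnorm(n, 62, 12), 18), 90))
  age_unit <- sample(c("YR", "MON", "DY"), n, replace = TRUE,
                     prob = c(0.95, 0.03, 0.02))
  age_value <- ifelse(age_unit == "YR", age,
                      ifelse(age_unit == "MON", age * 12, round(age * 365.25)))
  miss_age <- runif(n) < mr[["age"]]
  age_value[miss_age] <- NA_real_
  age_unit[miss_age] <- NA_character_
  weight_kg <- round(pmin(pmax(rnorm(n, 75, 18), 40), 140), 1)
  weight_kg[runif(n) < mr[["weight"]]] <- NA_real_
  occp <- sample(c("CN", "MD", "HP", "PH", "OT"), n, replace = TRUE,
                 prob = c(0.629, 0.220, 0.120, 0.010, 0.008))
  occp[runif(n) < mr[["occupation"]]] <- NA_character_
  country <- sample(.COUNTRIES, n, replace = TRUE, prob = .COUNTRY_W)
  country[runif(n) < mr[["country"]]] <- NA_character_

  fda_dt <- as_int_date(final_date)
  demo <- tibble(
    primary_id = primary_id, case_id = case_id, fda_dt = fda_dt,
    sex = sex, age_value = age_value, age_unit = age_unit,
    weight_kg = weight_kg, reporter_occupation = occp,
    reporter_country = country, event_year = fda_dt %/% 10000L)
  if (any(has_dup)) {
    dup_date <- final_date[has_dup] - dup_lag[has_dup]
    dup <- demo[has_dup, , drop = FALSE]
    dup$primary_id <- paste0(dup$case_id, "1")
    dup$fda_dt <- as_int_date(dup_date)
    dup$event_year <- dup$fda_dt %/% 10000L
    demo <- bind_rows(demo, dup)
  }
  demo <- demo[order(demo$case_id, demo$primary_id), , drop = FALSE]

  # drug stream
  set.seed(config$seed + 2L)
  ps_name <- ifelse(is_target,
                    sample(.TARGET_NAME_VARIANTS, n, replace = TRUE),
                    sample(.OTHER_DRUGS, n, replace = TRUE))
  ps_ai <- ifelse(is_target, "SELINEXOR", ps_name)
  n_conc <- pmin(rpois(n, 0.7), 3L)
  conc_case <- rep(seq_len(n), n_conc)
  conc <- if (length(conc_case) > 0L) {
    tibble(
      primary_id = primary_id[conc_case],
      drug_seq = unlist(lapply(n_conc[n_conc > 0], function(k) 1L + seq_len(k))),
      role_code = "C",
      drug_name = sample(.OTHER_DRUGS, length(conc_case), replace = TRUE),
      active_ingredient = NA_character_)
  } else NULL
  if (length(conc_case) > 0L) conc$active_ingredient <- conc$drug_name
  # occasional non-PS target mentions in background cases (role filtering)
  nonps <- which(!is_target & runif(n) < 0.02)
  nonps_rows <- if (length(nonps) > 0L) {
    tibble(primary_id = primary_id[nonps],
           drug_seq = 9L,
           role_code = sample(c("SS", "C"), length(nonps), replace = TRUE),
           drug_name = sample(.TARGET_NAME_VARIANTS, length(nonps),
                              replace = TRUE),
           active_ingredient = "SELINEXOR")
  } else NULL
  drug <- bind_rows(
    tibble(primary_id = primary_id, drug_seq = 1L, role_code = "PS",
           drug_name = ps_name, active_ingredient = ps_ai),
    conc, nonps_rows)
  drug <- drug[order(drug$primary_id, drug$drug_seq), , drop = FALSE]

  # reaction stream: distinct PTs per case, weighted without replacement
  set.seed(config$seed + 3L)
  vocab <- config$pt_vocabulary$pt
  v <- length(vocab)
  w_bg <- config$pt_vocabulary$weight
  w_tg <- .planted_weights(config)
  k <- pmin(1L + rpois(n, config$events_per_case - 1), v)
  idx_t <- which(is_target)
  idx_b <- which(!is_target)
  pt_idx <- vector("list", n)
  for (i in idx_t) pt_idx[[i]] <- sample.int(v, k[i], prob = w_tg)
  for (i in idx_b) pt_idx[[i]] <- sample.int(v, k[i], prob = w_bg)
  reac <- tibble(primary_id = rep(primary_id, k),
                 pt = vocab[unlist(pt_idx)])
  reac <- reac[order(reac$primary_id, reac$pt), , drop = FALSE]

  # outcome stream
  set.seed(config$seed + 4L)
  ow <- config$outcome_weights
  code <- sample(names(ow), n, replace = TRUE, prob = ow / sum(ow))
  with_out <- code != "none"
  outc <- tibble(primary_id = primary_id[with_out],
                 outcome_code = code[with_out])
  outc <- outc[order(outc$primary_id), , drop = FALSE]

  # remaining tables
  set.seed(config$seed + 5L)
  indi_pt <- ifelse(is_target,
                    sample(.INDICATIONS_TARGET, n, replace = TRUE),
                    sample(.INDICATIONS_OTHER, n, replace = TRUE))
  indi <- tibble(primary_id = primary_id, drug_seq = 1L,
                 indication_pt = indi_pt)
  start <- final_date - sample(7:400, n, replace = TRUE)
  ther <- tibble(primary_id = primary_id, drug_seq = 1L,
                 start_dt = as_int_date(start))
  has_rpsr <- runif(n) < 0.25
  rpsr <- tibble(primary_id = primary_id[has_rpsr],
                 source_code = sample(.RPSR_CODES, sum(has_rpsr),
                                      replace = TRUE))

  finalize <- function(x, kind) {
    attr(x, "table_kind") <- kind
    attr(x, "parse_report") <- tibble(line = integer(0), table = character(0),
                                      reason = character(0))
    x
  }
  list(DEMO = finalize(demo, "DEMO"), DRUG = finalize(drug, "DRUG"),
       REAC = finalize(reac, "REAC"), OUTC = finalize(outc, "OUTC"),
       INDI = finalize(indi, "INDI"), THER = finalize(ther, "THER"),
       RPSR = finalize(rpsr, "RPSR"))
}

#' Write a generated dataset to a directory
#'
#' Emits the seven FAERS ASCII files (`DEMO.txt` ... `RPSR.txt`) via
#' [write_faers_table()] plus a `manifest.json` recording the generating
#' configuration and seed.
#'
#' @param tables List from [generate_faers()].
#' @param dir Output directory (created if needed).
#' @param config Optional [synthetic_config()] recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(tables, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (kind in .FAERS_KINDS) {
    write_faers_table(tables[[kind]], file.path(dir, paste0(kind, ".txt")),
                      table_kind = kind)
  }
  if (!is.null(config)) {
    manifest <- unclass(config)
    manifest$planted_signals <- as.list(manifest$planted_signals)
    manifest$outcome_weights <- as.list(manifest$outcome_weights)
    manifest$missing_rates <- as.list(manifest$missing_rates)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Expected 2x2 cell counts under the generator's sampling model
#'
#' First-order (rare-event) approximation: with `q = target_drug_prob`,
#' `E[K] = events_per_case` and per-draw PT probabilities `p` (background) and
#' `p_t` (target, after rho re-weighting), the expected cells are
#' `E[a] = n q E[K] p_t`, `E[b] = n q E[K] (1 - p_t)`,
#' `E[c] = n (1-q) E[K] p`, `E[d] = n (1-q) E[K] (1 - p)`. The approximation
#' ignores the within-case without-replacement exclusion, so it is accurate
#' for PTs whose per-draw probability is small; it is exact in the null
#' (rho = 1) sense that the implied odds ratio is then exactly 1.
#'
#' @param config A [synthetic_config()].
#' @param pt PT name (must be in the vocabulary).
#' @return Named numeric vector `c(a, b, c, d)` of expected counts.
#' @export
expected_contingency <- function(config, pt) {
  stopifnot(inherits(config, "synthetic_config"))
  key <- normalize_pt(config$pt_vocabulary$pt)
  i <- match(normalize_pt(pt), key)
  if (is.na(i)) {
    stop(sprintf("expected_contingency(): PT not in vocabulary: %s", pt),
         call. = FALSE)
  }
  w_bg <- config$pt_vocabulary$weight
  w_tg <- .planted_weights(config)
  p_bg <- w_bg[i] / sum(w_bg)
  p_tg <- w_tg[i] / sum(w_tg)
  n <- config$n_cases
  q <- config$target_drug_prob
  ek <- config$events_per_case
  c(a = n * q * ek * p_tg,
    b = n * q * ek * (1 - p_tg),
    c = n * (1 - q) * ek * p_bg,
    d = n * (1 - q) * ek * (1 - p_bg))
}
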