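# Fixtures are built in code: small hand-written FAERS ASCII files and typed
# record tibbles; nothing is read from disk beyond what a test writes itself.

write_tmp_lines <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# minimal typed DEMO tibble (same shape parse_faers_table returns)
demo_tbl <- function(primary_id, case_id, fda_dt,
                     sex = NA_character_, age_value = NA_real_,
                     age_unit = NA_character_, weight_kg = NA_real_,
                     reporter_occupation = NA_character_,
                     reporter_country = NA_character_) {
  out <- tibble::tibble(
    primary_id = as.character(primary_id),
    case_id = as.character(case_id),
    fda_dt = as.integer(fda_dt),
    sex = sex, age_value = age_value, age_unit = age_unit,
    weight_kg = weight_kg, reporter_occupation = reporter_occupation,
    reporter_country = reporter_country,
    event_year = as.integer(fda_dt) %/% 10000L)
  attr(out, "table_kind") <- "DEMO"
  out
}

drug_tbl <- function(primary_id, role_code, drug_name,
                     active_ingredient = NA_character_, drug_seq = 1L) {
  tibble::tibble(primary_id = as.character(primary_id),
                 drug_seq = as.integer(drug_seq), role_code = role_code,
                 drug_name = drug_name, active_ingredient = active_ingredient)
}

reac_tbl <- function(primary_id, pt) {
  tibble::tibble(primary_id = as.character(primary_id), pt = pt)
}

# events tibble with given per-PT counts, all target or all background
events_from_counts <- function(counts, is_target = TRUE, id_offset = 0L) {
  pts <- rep(names(counts), counts)
  tibble::tibble(
    primary_id = as.character(seq_along(pts) + id_offset),
    case_id = as.character(seq_along(pts) + id_offset),
    pt = pts, is_target_drug = is_target)
}

# compare typed record tibbles ignoring parse-report attributes
expect_same_records <- function(x, y) {
  expect_equal(as.data.frame(x), as.data.frame(y), ignore_attr = TRUE)
}

# generator config with one rare planted signal: base weight 6.7 out of
# ~17900 gives per-draw probability ~3.7e-4, so the rare-event expectation
# is accurate; rho = 10 yields expected a ~ 15 at 20,000 cases, 5% target.
planted_rare_config <- function(n_cases = 20000, seed = 1, rho = 10,
                                pt = "Acute kidney injury") {
  vocab <- default_pt_vocabulary()
  vocab <- rbind(vocab, tibble::tibble(pt = pt, weight = 6.7))
  synthetic_config(n_cases = n_cases, seed = seed, pt_vocabulary = vocab,
                   planted_signals = stats::setNames(rho, pt))
}
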