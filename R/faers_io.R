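# FAERS quarterly ASCII tables: dollar-delimited, one header line, no quoting.
# Each table kind is parsed into a typed tibble with standardized column names;
# rows that fail validation are skipped and collected into a parse report
# (line, table, reason) attached as an attribute.

.FAERS_KINDS <- c("DEMO", "DRUG", "REAC", "OUTC", "INDI", "THER", "RPSR")

.ROLE_CODES <- c("PS", "SS", "C", "I")
.OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
.OCCP_CODES <- c("MD", "PH", "HP", "CN", "OT", "LW")

# internal field name -> column name in the FAERS ASCII file
.faers_schema <- list(
  DEMO = list(
    cols = c(primary_id = "primaryid", case_id = "caseid", fda_dt = "fda_dt",
             sex = "sex", age_value = "age", age_unit = "age_cod",
             weight = "wt", weight_unit = "wt_cod",
             reporter_occupation = "occp_cod",
             reporter_country = "reporter_country"),
    required = c("primaryid", "caseid", "fda_dt")
  ),
  DRUG = list(
    cols = c(primary_id = "primaryid", drug_seq = "drug_seq",
             role_code = "role_cod", drug_name = "drugname",
             active_ingredient = "prod_ai"),
    required = c("primaryid", "drug_seq", "role_cod", "drugname")
  ),
  REAC = list(
    cols = c(primary_id = "primaryid", pt = "pt"),
    required = c("primaryid", "pt")
  ),
  OUTC = list(
    cols = c(primary_id = "primaryid", outcome_code = "outc_cod"),
    required = c("primaryid", "outc_cod")
  ),
  INDI = list(
    cols = c(primary_id = "primaryid", drug_seq = "indi_drug_seq",
             indication_pt = "indi_pt"),
    required = c("primaryid")
  ),
  THER = list(
    cols = c(primary_id = "primaryid", drug_seq = "dsg_drug_seq",
             start_dt = "start_dt"),
    required = c("primaryid")
  ),
  RPSR = list(
    cols = c(primary_id = "primaryid", source_code = "rpsr_cod"),
    required = c("primaryid")
  )
)

# split a $-delimited line preserving trailing empty fields (strsplit drops them)
.split_dollar <- function(lines) {
  parts <- strsplit(paste0(lines, "$\x01"), "$", fixed = TRUE)
  lapply(parts, function(p) p[-length(p)])
}

.is_missing_field <- function(x) {
  x <- trimws(x)
  is.na(x) | x == "" | toupper(x) == "NULL"
}

.as_clean <- function(x) {
  x <- trimws(x)
  x[.is_missing_field(x)] <- NA_character_
  x
}

.valid_yyyymmdd <- function(x) {
  ok <- !is.na(x) & grepl("^[0-9]{8}$", x)
  ok[ok] <- !is.na(as.Date(x[ok], format = "%Y%m%d"))
  ok
}

#' Parse one FAERS quarterly ASCII table
#'
#' Reads a dollar-delimited FAERS table (Latin-1 encoded, header line naming
#' the columns) into a typed tibble. Columns are located by header name, not
#' position, so layout revisions that add columns are tolerated. Rows with the
#' wrong field count or failing per-field validation (malformed date/number,
#' unknown role or outcome code, empty PT) are skipped and reported with their
#' line numbers in the `parse_report` attribute.
#'
#' @param path Path to the table file.
#' @param table_kind One of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`, `"INDI"`,
#'   `"THER"`, `"RPSR"`.
#' @return A tibble of typed records (see Details) with attributes
#'   `table_kind` and `parse_report` (tibble with columns line, table, reason).
#' @details Standardized columns by kind:
#'   * DEMO: `primary_id`, `case_id`, `fda_dt` (integer YYYYMMDD), `sex`
#'     (`"M"`/`"F"`/NA), `age_value`, `age_unit`, `weight_kg` (LBS converted at
#'     0.453592, GMS at 1/1000; other units set missing), `reporter_occupation`,
#'     `reporter_country`, `event_year`.
#'   * DRUG: `primary_id`, `drug_seq`, `role_code` (PS/SS/C/I only),
#'     `drug_name`, `active_ingredient`.
#'   * REAC: `primary_id`, `pt` (non-empty).
#'   * OUTC: `primary_id`, `outcome_code` (DE/LT/HO/DS/CA/RI/OT only).
#'   * INDI/THER/RPSR: identifier plus pass-through fields.
#'
#' Empty fields, literal `NULL` and whitespace-only fields are missing (NA).
#' @export
parse_faers_table <- function(path, table_kind) {
  table_kind <- match.arg(toupper(table_kind), .FAERS_KINDS)
  if (!file.exists(path)) {
    stop(sprintf("cannot read %s table: file not found: %s", table_kind, path),
         call. = FALSE)
  }
  con <- file(path, encoding = "latin1")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) {
    stop(sprintf("%s file is empty (no header line): %s", table_kind, path),
         call. = FALSE)
  }
  sc <- .faers_schema[[table_kind]]
  header <- tolower(trimws(.split_dollar(lines[1])[[1]]))
  missing_req <- setdiff(sc$required, header)
  if (length(missing_req) > 0L) {
    stop(sprintf("%s header is missing required column(s): %s",
                 table_kind, paste(missing_req, collapse = ", ")),
         call. = FALSE)
  }

  body <- lines[-1]
  keep <- nzchar(trimws(body))
  line_no <- which(keep) + 1L   # 1-based file line numbers
  body <- body[keep]

  bad_line <- integer(0)
  bad_reason <- character(0)
  note_bad <- function(lines, reason) {
    bad_line <<- c(bad_line, lines)
    bad_reason <<- c(bad_reason, rep(reason, length(lines)))
  }

  fields <- .split_dollar(body)
  nf <- lengths(fields)
  wrong <- nf != length(header)
  if (any(wrong)) note_bad(line_no[wrong], "wrong field count")
  fields <- fields[!wrong]
  line_no <- line_no[!wrong]

  get_col <- function(file_col) {
    j <- match(file_col, header)
    if (is.na(j)) rep(NA_character_, length(fields))
    else .as_clean(vapply(fields, `[[`, "", j))
  }
  raw <- lapply(sc$cols, get_col)
  names(raw) <- names(sc$cols)

  drop <- rep(FALSE, length(fields))
  invalidate <- function(bad, reason) {
    new <- bad & !drop
    if (any(new)) note_bad(line_no[new], reason)
    drop <<- drop | bad
  }

  out <- switch(table_kind,
    DEMO = {
      invalidate(is.na(raw$primary_id), "missing primaryid")
      invalidate(!.valid_yyyymmdd(raw$fda_dt), "invalid fda_dt")
      age <- suppressWarnings(as.numeric(raw$age_value))
      invalidate(!is.na(raw$age_value) & (is.na(age) | age < 0), "invalid age")
      wt <- suppressWarnings(as.numeric(raw$weight))
      invalidate(!is.na(raw$weight) & (is.na(wt) | wt < 0), "invalid weight")
      sex <- toupper(raw$sex)
      sex[!sex %in% c("M", "F")] <- NA_character_
      wt_unit <- toupper(raw$weight_unit)
      weight_kg <- ifelse(is.na(wt), NA_real_,
        ifelse(is.na(wt_unit) | wt_unit %in% c("KG", "KGS"), wt,
          ifelse(wt_unit == "LBS", wt * 0.453592,
            ifelse(wt_unit == "GMS", wt / 1000, NA_real_))))
      occp <- toupper(raw$reporter_occupation)
      occp[!occp %in% .OCCP_CODES] <- NA_character_
      fda_dt <- as.integer(raw$fda_dt)
      tibble(
        primary_id = raw$primary_id,
        case_id = raw$case_id,
        fda_dt = fda_dt,
        sex = sex,
        age_value = age,
        age_unit = toupper(raw$age_unit),
        weight_kg = weight_kg,
        reporter_occupation = occp,
        reporter_country = raw$reporter_country,
        event_year = fda_dt %/% 10000L
      )
    },
    DRUG = {
      invalidate(is.na(raw$primary_id), "missing primaryid")
      role <- toupper(raw$role_code)
      invalidate(!role %in% .ROLE_CODES, "unknown role code")
      seq <- suppressWarnings(as.integer(raw$drug_seq))
      invalidate(!is.na(raw$drug_seq) & is.na(seq), "invalid drug_seq")
      tibble(
        primary_id = raw$primary_id,
        drug_seq = seq,
        role_code = role,
        drug_name = raw$drug_name,
        active_ingredient = raw$active_ingredient
      )
    },
    REAC = {
      invalidate(is.na(raw$primary_id), "missing primaryid")
      invalidate(.is_missing_field(raw$pt), "empty pt")
      tibble(primary_id = raw$primary_id, pt = raw$pt)
    },
    OUTC = {
      invalidate(is.na(raw$primary_id), "missing primaryid")
      code <- toupper(raw$outcome_code)
      invalidate(!code %in% .OUTCOME_CODES, "unknown outcome code")
      tibble(primary_id = raw$primary_id, outcome_code = code)
    },
    INDI = {
      invalidate(is.na(raw$primary_id), "missing primaryid")
      tibble(primary_id = raw$primary_id,
             drug_seq = suppressWarnings(as.integer(raw$drug_seq)),
             indication_pt = raw$indication_pt)
    },
    THER = {
      invalidate(is.na(raw$primary_id), "missing primaryid")
      start <- raw$start_dt
      start[!.valid_yyyymmdd(start)] <- NA_character_
      tibble(primary_id = raw$primary_id,
             drug_seq = suppressWarnings(as.integer(raw$drug_seq)),
             start_dt = as.integer(start))
    },
    RPSR = {
      invalidate(is.na(raw$primary_id), "missing primaryid")
      tibble(primary_id = raw$primary_id, source_code = raw$source_code)
    }
  )
  out <- out[!drop, , drop = FALSE]

  report <- tibble(line = bad_line, table = rep(table_kind, length(bad_line)),
                   reason = bad_reason)
  report <- report[order(report$line), , drop = FALSE]
  attr(out, "table_kind") <- table_kind
  attr(out, "parse_report") <- report
  out
}

#' Write records back to the FAERS ASCII dialect
#'
#' Emits the same dollar-delimited, header-first dialect [parse_faers_table()]
#' reads, so `parse_faers_table(write_faers_table(x))` reproduces `x`
#' field-for-field. The dialect has no quoting: a `$` inside a field is
#' rejected with an error rather than written ambiguously.
#'
#' @param records Typed tibble as returned by [parse_faers_table()] (or built
#'   with the same columns).
#' @param path Output file path.
#' @param table_kind Table kind; defaults to the `table_kind` attribute.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(records, path,
                              table_kind = attr(records, "table_kind")) {
  if (is.null(table_kind)) {
    stop("table_kind is required (records carry no table_kind attribute)",
         call. = FALSE)
  }
  table_kind <- match.arg(toupper(table_kind), .FAERS_KINDS)
  sc <- .faers_schema[[table_kind]]

  fields <- names(sc$cols)
  # DEMO round-trips weight in kilograms; derived event_year is not written
  if (table_kind == "DEMO") {
    fields <- setdiff(fields, c("weight", "weight_unit"))
    cols <- c(sc$cols[setdiff(names(sc$cols), c("weight", "weight_unit"))],
              weight_kg = "wt", weight_unit_out = "wt_cod")
  } else {
    cols <- sc$cols
  }

  fmt <- function(v) {
    out <- ifelse(is.na(v), "", as.character(v))
    if (any(grepl("$", out, fixed = TRUE))) {
      stop(sprintf(
        "cannot write %s table: field value contains the '$' delimiter",
        table_kind), call. = FALSE)
    }
    out
  }

  n <- nrow(records)
  col_text <- lapply(names(cols), function(f) {
    if (f == "weight_unit_out") {
      if (n == 0L) character(0)
      else ifelse(is.na(records$weight_kg), "", "KG")
    } else if (!f %in% names(records)) {
      rep("", n)
    } else {
      fmt(records[[f]])
    }
  })
  header <- paste(unname(cols), collapse = "$")
  body <- if (n == 0L) character(0) else do.call(paste, c(col_text, sep = "$"))
  con <- file(path, open = "w", encoding = "latin1")
  on.exit(close(con), add = TRUE)
  writeLines(c(header, body), con)
  invisible(path)
}

#' Load a user-supplied PT to SOC mapping table
#'
#' MedDRA is licensed and cannot be bundled, so system-organ-class aggregation
#' relies on a user-supplied two-column tab-delimited file (PT, SOC). PT keys
#' are normalized (trimmed, case-folded) so lookups are casing-insensitive; a
#' PT mapped to two different SOCs is an error (primary-SOC convention),
#' exact duplicate rows are collapsed.
#'
#' @param path Path to a 2-column TSV. A first line whose cells are `pt` and
#'   `soc` (any case) is treated as a header and skipped.
#' @return Named character vector (class `pt_soc_map`): normalized PT key ->
#'   SOC name.
#' @export
load_pt_soc_map <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("PT->SOC map not found: %s", path), call. = FALSE)
  }
  con <- file(path, encoding = "latin1")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(structure(setNames(character(0), character(0)),
                     class = "pt_soc_map"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  first <- tolower(trimws(parts[[1]]))
  if (length(first) >= 2L && first[1] == "pt" && first[2] == "soc") {
    parts <- parts[-1]
  }
  short <- lengths(parts) < 2L
  if (any(short)) {
    stop(sprintf("PT->SOC map line %d does not have two tab-separated fields",
                 which(short)[1] + (length(lines) - length(parts))),
         call. = FALSE)
  }
  pt <- normalize_pt(vapply(parts, `[[`, "", 1L))
  soc <- trimws(vapply(parts, `[[`, "", 2L))
  pairs <- unique(data.frame(pt = pt, soc = soc, stringsAsFactors = FALSE))
  dup <- pairs$pt[duplicated(pairs$pt)]
  if (length(dup) > 0L) {
    stop(sprintf("PT mapped to more than one SOC: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  structure(setNames(pairs$soc, pairs$pt), class = "pt_soc_map")
}
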