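# End-to-end pipeline: parse -> dedup -> cohort -> descriptives ->
# disproportionality, with stage-tagged logging of the counts at every step
# (the audit trail a study flow chart shows) and a TSV/JSON report bundle.

.REQUIRED_TABLES <- c("DEMO", "DRUG", "REAC", "OUTC")

.find_table_file <- function(input_dir, kind) {
  cand <- file.path(input_dir, c(paste0(kind, ".txt"), paste0(tolower(kind), ".txt")))
  hit <- cand[file.exists(cand)]
  if (length(hit) > 0L) hit[1] else NA_character_
}

.read_input_tables <- function(input_dir) {
  tables <- list()
  for (kind in .FAERS_KINDS) {
    path <- .find_table_file(input_dir, kind)
    if (is.na(path)) {
      if (kind %in% .REQUIRED_TABLES) {
        abort_user(sprintf("stage parse: required %s table not found in %s",
                           kind, input_dir))
      }
      next
    }
    tables[[kind]] <- parse_faers_table(path, kind)
  }
  tables
}

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on a directory of FAERS tables
#'
#' Executes parse, deduplication, cohort extraction, descriptive tables and
#' disproportionality analysis in order, writing the report bundle (TSV
#' tables, `run.log`, `summary.json`) to `output_dir`. Any stage failure
#' aborts with a stage-named error and removes the partially written outputs.
#' No multiple-testing correction is applied to the signal tests; the run log
#' header carries the corresponding disclaimer.
#'
#' @param input_dir Directory holding `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `OUTC.txt` (required) and optionally `INDI.txt`, `THER.txt`, `RPSR.txt`.
#' @param output_dir Output directory (created if needed).
#' @param drug_names Drug search strings (default selinexor/XPOVIO).
#' @param role Cohort role code (default `"PS"`).
#' @param pt_soc_map Optional path to a PT->SOC TSV, or a loaded
#'   `pt_soc_map`; when absent the SOC table is skipped.
#' @param top_n Row limit for PT/SOC/signal tables (default 15).
#' @param min_a Minimum `a` cell for signal-table rows (default 1).
#' @param z CI quantile (default 1.96).
#' @param correction Haldane-Anscombe +0.5 for the ROR (default FALSE).
#' @param rank_key Signal ranking key (default `"ror"`).
#' @param what `"full"`, `"describe"` (skip signals) or `"signals"` (skip
#'   descriptive tables).
#' @param verbose Echo log lines with `message()` (default TRUE).
#' @return Invisibly, a list with the computed objects (`dedup`, `cohort`,
#'   `descriptives`, `signals`, `summary`).
#' @export
run_pipeline <- function(input_dir, output_dir,
                         drug_names = c("selinexor", "xpovio"),
                         role = "PS", pt_soc_map = NULL,
                         top_n = 15, min_a = 1, z = 1.96, correction = FALSE,
                         rank_key = "ror",
                         what = c("full", "describe", "signals"),
                         verbose = TRUE) {
  what <- match.arg(what)
  if (!dir.exists(input_dir)) {
    abort_user(sprintf("stage parse: input directory not found: %s", input_dir))
  }
  if (length(drug_names) == 0L) {
    abort_user("stage cohort: drug_names must be non-empty")
  }

  log_lines <- c(
    paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
           " [config] no multiple-testing correction is applied;",
           " disproportionality signals are hypothesis-generating only"))
  log_ <- function(stage, fmt, ...) {
    line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "faersignal_user_error")) stop(e)
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  tables <- stage("parse", .read_input_tables(input_dir))
  n_bad <- sum(vapply(tables, function(t) nrow(attr(t, "parse_report")),
                      integer(1)))
  log_("parse", "read %d tables (%d invalid lines skipped)",
       length(tables), n_bad)

  dedup <- stage("dedup", deduplicate_demo(tables$DEMO))
  log_("dedup", "input=%d kept=%d removed=%d",
       dedup$input_count, nrow(dedup$kept), dedup$removed_count)

  cohort <- stage("cohort", build_cohort(dedup, tables$DRUG, tables$REAC,
                                         drug_names, role = role))
  log_("cohort", "cohort reports=%d target events=%d background events=%d unmatched reactions=%d",
       length(cohort$cohort_ids), sum(cohort$events$is_target_drug),
       sum(!cohort$events$is_target_drug), cohort$n_unmatched_reactions)

  map <- NULL
  if (!is.null(pt_soc_map)) {
    map <- stage("soc_map", if (inherits(pt_soc_map, "pt_soc_map")) pt_soc_map
                            else load_pt_soc_map(pt_soc_map))
  }

  cohort_demo <- dedup$kept[dedup$kept$primary_id %in% cohort$cohort_ids, ,
                            drop = FALSE]
  desc <- NULL
  if (what %in% c("full", "describe")) {
    desc <- stage("descriptives", {
      cohort_outc <- tables$OUTC[tables$OUTC$primary_id %in% cohort$cohort_ids, ,
                                 drop = FALSE]
      list(
        demographics = if (nrow(cohort_demo) > 0L)
          demographic_table(cohort_demo) else NULL,
        outcomes = outcome_table(cohort_outc),
        pt = pt_frequency(cohort$events, top_n = top_n),
        soc = if (!is.null(map)) soc_frequency(cohort$events, map,
                                               top_n = top_n) else NULL,
        annual = annual_distribution(cohort_demo))
    })
    log_("descriptives", "pt rows=%d outcome instances=%d",
         nrow(desc$pt), attr(desc$outcomes, "denominator"))
  }

  signals <- ranked <- NULL
  if (what %in% c("full", "signals")) {
    signals <- stage("signals", signal_table(cohort$events, min_a = min_a,
                                             z = z, correction = correction))
    ranked <- stage("signals", rank_signals(signals, key = rank_key,
                                            top_n = top_n))
    log_("signals", "PTs tested=%d flagged=%d (either rule)",
         nrow(signals), sum(signals$ror_signal | signals$prr_signal))
  }

  summary <- list(
    input_dir = input_dir,
    drug_names = drug_names, role = role,
    demo_input = dedup$input_count,
    demo_kept = nrow(dedup$kept),
    demo_removed = dedup$removed_count,
    cohort_reports = length(cohort$cohort_ids),
    target_events = sum(cohort$events$is_target_drug),
    background_events = sum(!cohort$events$is_target_drug),
    unmatched_reactions = cohort$n_unmatched_reactions,
    pts_tested = if (is.null(signals)) NA_integer_ else nrow(signals),
    signals_flagged = if (is.null(signals)) NA_integer_
                      else sum(signals$ror_signal | signals$prr_signal))

  # all computation succeeded; write the bundle, removing it on any failure
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wr <- function(obj, file) {
    path <- file.path(output_dir, file)
    .write_tsv(obj, path)
    written <<- c(written, path)
  }
  stage("write", tryCatch({
    parse_reports <- bind_rows(lapply(tables, attr, "parse_report"))
    wr(parse_reports, "parse_report.tsv")
    wr(tibble(input = dedup$input_count, kept = nrow(dedup$kept),
              removed = dedup$removed_count), "dedup_summary.tsv")
    wr(tibble(primary_id = cohort$cohort_ids), "cohort_reports.tsv")
    wr(cohort$events, "events.tsv")
    if (!is.null(desc)) {
      if (!is.null(desc$demographics)) {
        demo_rows <- bind_rows(lapply(names(desc$demographics), function(v) {
          cbind(variable = v, desc$demographics[[v]])
        }))
        wr(demo_rows, "demographics.tsv")
      }
      wr(desc$outcomes, "outcomes.tsv")
      wr(desc$pt, "pt_frequency.tsv")
      if (!is.null(desc$soc)) wr(desc$soc, "soc_frequency.tsv")
      wr(desc$annual, "annual_distribution.tsv")
    }
    if (!is.null(signals)) {
      wr(signals, "signals.tsv")
      wr(ranked, "signals_ranked.tsv")
    }
    log_path <- file.path(output_dir, "run.log")
    writeLines(log_lines, log_path)
    written <- c(written, log_path)
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, error = function(e) {
    unlink(written)
    stop(e)
  }))

  invisible(list(dedup = dedup, cohort = cohort, descriptives = desc,
                 signals = signals, ranked = ranked, summary = summary))
}

.CLI_USAGE <- paste(
  "usage: faers-dispro <simulate|describe|signals|full> [options]",
  "",
  "subcommands:",
  "  simulate  --out-dir DIR [--n-cases N] [--seed S] [--target-prob P]",
  "            [--duplicate-prob P]",
  "  describe  --input-dir DIR --output-dir DIR [--drug-names a,b]",
  "            [--pt-soc-map FILE] [--top-n N]",
  "  signals   --input-dir DIR --output-dir DIR [--drug-names a,b]",
  "            [--min-a N] [--z Z] [--correction] [--rank-key ror|prr|a]",
  "            [--top-n N]",
  "  full      all of the above options",
  sep = "\n")

.parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      abort_user(sprintf("unexpected argument: %s", a))
    }
    key <- sub("^--", "", a)
    if (key == "correction") {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) abort_user(sprintf("flag --%s needs a value", key))
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `describe`, `signals` and `full` subcommands
#' (see `inst/exec/faers-dispro` for the Rscript wrapper). Returns the process
#' exit status: 0 on success, 1 on a user error (bad flags, missing inputs),
#' 2 on an internal error.
#'
#' @param args Character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
faersignal_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L ||
        !args[1] %in% c("simulate", "describe", "signals", "full")) {
      message(.CLI_USAGE)
      return(invisible(1L))
    }
    cmd <- args[1]
    flags <- .parse_cli_flags(args[-1])
    num <- function(key, default) {
      if (is.null(flags[[key]])) default else as.numeric(flags[[key]])
    }
    if (cmd == "simulate") {
      if (is.null(flags[["out-dir"]])) abort_user("simulate: --out-dir is required")
      config <- synthetic_config(
        n_cases = num("n-cases", 5000),
        seed = num("seed", 1),
        target_drug_prob = num("target-prob", 0.05),
        duplicate_prob = num("duplicate-prob", 0.26))
      write_synthetic_dataset(generate_faers(config), flags[["out-dir"]],
                              config = config)
      message(sprintf("wrote synthetic dataset (%d cases) to %s",
                      config$n_cases, flags[["out-dir"]]))
    } else {
      if (is.null(flags[["input-dir"]]) || is.null(flags[["output-dir"]])) {
        abort_user(sprintf("%s: --input-dir and --output-dir are required", cmd))
      }
      drug_names <- if (is.null(flags[["drug-names"]])) c("selinexor", "xpovio")
                    else strsplit(flags[["drug-names"]], ",", fixed = TRUE)[[1]]
      run_pipeline(
        input_dir = flags[["input-dir"]],
        output_dir = flags[["output-dir"]],
        drug_names = drug_names,
        pt_soc_map = flags[["pt-soc-map"]],
        top_n = num("top-n", 15),
        min_a = num("min-a", 1),
        z = num("z", 1.96),
        correction = isTRUE(flags[["correction"]]),
        rank_key = flags[["rank-key"]] %||% "ror",
        what = if (cmd == "full") "full" else cmd)
    }
    0L
  },
  faersignal_user_error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  },
  error = function(e) {
    message("internal error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
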