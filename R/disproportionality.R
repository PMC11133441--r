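# Disproportionality statistics on per-PT 2x2 contingency tables.
#
# Cell layout (events = distinct case-PT pairs):
#          target PT   other PTs
# target      a            b        a + b = total target-drug events
# others      c            d        c + d = total background events
#
# ROR = ad/(bc) with Woolf-type 95% CI on the log scale; PRR in the standard
# orientation [a/(a+b)]/[c/(c+d)]; Pearson chi-squared without continuity
# correction. Signal rules: ROR rule = (a >= 3 and CI lower bound > 1);
# PRR rule = (a >= 3 and PRR > 2 and chi2 > 4); strict ">" throughout, ">="
# only for a.

#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d Nonnegative integer cell counts (see the layout in the
#'   package source: a = target drug & target PT events, b = target drug &
#'   other PTs, c = other drugs & target PT, d = other drugs & other PTs).
#' @param pt Optional PT label.
#' @return Object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, pt = NA_character_) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("contingency_table(): cells must be nonnegative integers",
         call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d, pt = pt),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table%s: a=%d b=%d c=%d d=%d\n",
              if (is.na(x$pt)) "" else paste0(" [", x$pt, "]"),
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Build the 2x2 table for one preferred term
#'
#' Counts events (distinct case-PT pairs) from a [build_cohort()] event list:
#' a = target events with this PT, b = other target events, c = background
#' events with this PT, d = other background events.
#'
#' @param events Event tibble from [build_cohort()].
#' @param pt PT name (matched after normalization).
#' @return A [contingency_table()].
#' @export
build_contingency <- function(events, pt) {
  key <- normalize_pt(events$pt)
  target <- events$is_target_drug
  this <- key == normalize_pt(pt)
  contingency_table(
    a = sum(target & this), b = sum(target & !this),
    c = sum(!target & this), d = sum(!target & !this),
    pt = pt)
}

# vectorised core shared by the scalar API and signal_table()
.dispro_stats <- function(a, b, c, d, z = 1.96, correction = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)

  if (correction) {
    ar <- a + 0.5; br <- b + 0.5; cr <- c + 0.5; dr <- d + 0.5
    ror_ok <- rep(TRUE, length(a))
  } else {
    ar <- a; br <- b; cr <- c; dr <- d
    ror_ok <- a > 0 & b > 0 & c > 0 & d > 0
  }
  ror <- ifelse(ror_ok, (ar * dr) / (br * cr), NA_real_)
  se <- ifelse(ror_ok, sqrt(1 / ar + 1 / br + 1 / cr + 1 / dr), NA_real_)
  ci_low <- exp(log(ror) - z * se)
  ci_high <- exp(log(ror) + z * se)

  prr_ok <- (a + b) > 0 & (c + d) > 0 & c > 0
  prr <- ifelse(prr_ok, (a / (a + b)) / (c / (c + d)), NA_real_)

  m_ok <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  n_tot <- a + b + c + d
  chi2 <- ifelse(m_ok,
                 (a * d - b * c)^2 * n_tot /
                   ((a + b) * (c + d) * (a + c) * (b + d)),
                 NA_real_)

  tibble(ror = ror, ror_ci_low = ci_low, ror_ci_high = ci_high,
         prr = prr, chi2 = chi2)
}

#' Reporting odds ratio with Woolf-type confidence interval
#'
#' `ROR = ad/(bc)`; the CI is `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c +
#' 1/d))`. With any zero cell the estimate is undefined (`NA`) unless
#' `correction = TRUE`, which applies the Haldane-Anscombe +0.5 to every cell.
#'
#' @param table A [contingency_table()].
#' @param z Normal quantile for the CI (default 1.96, a 95% interval).
#' @param correction Apply the +0.5 continuity correction (default FALSE).
#' @return Named numeric vector `c(estimate, ci_low, ci_high)` (NA when
#'   undefined).
#' @export
ror <- function(table, z = 1.96, correction = FALSE) {
  stopifnot(inherits(table, "contingency_table"))
  s <- .dispro_stats(table$a, table$b, table$c, table$d, z, correction)
  c(estimate = s$ror, ci_low = s$ror_ci_low, ci_high = s$ror_ci_high)
}

#' Proportional reporting ratio
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`: the PT's share among the target drug's
#' events over its share among all other drugs' events. Undefined (`NA`) when
#' `c = 0` or a margin is empty.
#'
#' @param table A [contingency_table()].
#' @return Numeric scalar (NA when undefined).
#' @export
prr <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  .dispro_stats(table$a, table$b, table$c, table$d)$prr
}

#' Pearson chi-squared statistic of a 2x2 table
#'
#' `chi2 = (ad - bc)^2 (a+b+c+d) / [(a+b)(c+d)(a+c)(b+d)]`, without Yates
#' continuity correction. Undefined (`NA`) when any margin is zero.
#'
#' @param table A [contingency_table()].
#' @return Numeric scalar (NA when undefined).
#' @export
chi_square <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  .dispro_stats(table$a, table$b, table$c, table$d)$chi2
}

#' Apply the ROR and PRR signal thresholds
#'
#' ROR rule: `a >= 3` and CI lower bound `> 1`. PRR rule: `a >= 3`, `PRR > 2`
#' and `chi2 > 4`. Inequalities are strict except the `a >= 3` gate; undefined
#' statistics never flag.
#'
#' @param a Cell-a counts (vectorised).
#' @param ror_ci_low ROR CI lower bounds.
#' @param prr PRR estimates.
#' @param chi2 Chi-squared statistics.
#' @return Tibble with logical columns `ror_signal`, `prr_signal`.
#' @export
flag_signals <- function(a, ror_ci_low, prr, chi2) {
  tibble(
    ror_signal = !is.na(ror_ci_low) & a >= 3 & ror_ci_low > 1,
    prr_signal = !is.na(prr) & !is.na(chi2) & a >= 3 & prr > 2 & chi2 > 4
  )
}

#' Disproportionality statistics for every target PT
#'
#' Builds the 2x2 table for each PT observed among target events and computes
#' ROR/CI, PRR, chi-squared and both threshold flags in one pass.
#'
#' @param events Event tibble from [build_cohort()].
#' @param min_a Keep only rows with `a >= min_a` (default 1).
#' @param z CI quantile (default 1.96).
#' @param correction Haldane-Anscombe +0.5 for the ROR (default FALSE).
#' @return Tibble with columns pt, a, b, c, d, ror, ror_ci_low, ror_ci_high,
#'   prr, chi2, ror_signal, prr_signal.
#' @export
signal_table <- function(events, min_a = 1, z = 1.96, correction = FALSE) {
  key <- normalize_pt(events$pt)
  target <- events$is_target_drug
  n_target <- sum(target)
  n_background <- sum(!target)

  tkey <- key[target]
  if (length(tkey) == 0L) {
    return(tibble(pt = character(0), a = integer(0), b = integer(0),
                  c = integer(0), d = integer(0), ror = numeric(0),
                  ror_ci_low = numeric(0), ror_ci_high = numeric(0),
                  prr = numeric(0), chi2 = numeric(0),
                  ror_signal = logical(0), prr_signal = logical(0)))
  }
  a_tab <- table(tkey)
  pts <- names(a_tab)
  a <- as.integer(a_tab)
  bkey <- key[!target]
  c_ <- as.integer(table(factor(bkey, levels = pts)))
  b <- n_target - a
  d <- n_background - c_

  display <- .display_casing(events$pt[target], tkey)
  stats <- .dispro_stats(a, b, c_, d, z = z, correction = correction)
  flags <- flag_signals(a, stats$ror_ci_low, stats$prr, stats$chi2)

  out <- tibble(pt = unname(display[pts]), a = a, b = b, c = c_, d = d)
  out <- dplyr::bind_cols(out, stats, flags)
  out <- out[out$a >= min_a, , drop = FALSE]
  out[order(-out$a, out$pt), , drop = FALSE]
}

#' Rank flagged signals
#'
#' Keeps rows where either the ROR or the PRR rule fired and sorts them by the
#' chosen key (descending), breaking ties by `a` descending then PT
#' alphabetical.
#'
#' @param signals Tibble from [signal_table()].
#' @param key Ranking key: `"ror"`, `"prr"` or `"a"`.
#' @param top_n Number of rows to keep (default all).
#' @return Reordered, filtered tibble.
#' @export
rank_signals <- function(signals, key = c("ror", "prr", "a"), top_n = Inf) {
  key <- match.arg(key)
  sig <- signals[signals$ror_signal | signals$prr_signal, , drop = FALSE]
  k <- sig[[key]]
  k[is.na(k)] <- -Inf
  sig <- sig[order(-k, -sig$a, sig$pt), , drop = FALSE]
  if (is.finite(top_n)) sig <- head(sig, top_n)
  sig
}
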