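# Validation report: cohort condition frequencies and their distance to
# literature reference ranges.

#' Round half-up
#'
#' Presentation rounding for the report's percent column: ties away from
#' zero at the given number of decimals (base `round()` uses banker's
#' rounding, which the report deliberately avoids).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Tabulate cohort condition frequencies
#'
#' Counts, per condition code, the number of distinct persons with at least
#' one `ConditionOnset` event of that code, and the percentage over the
#' cohort size (rounded half-up to one decimal; the raw fraction is retained
#' in `percent_raw`).
#'
#' @param cohort List of simulated `person_record`s.
#' @param conditions Data frame with columns `system`, `code`, `display`
#'   naming the conditions to tabulate; defaults to the 14 reported
#'   conditions of [default_reference_ranges()].
#' @return Data frame with `system`, `code`, `display`, `count`, `percent`,
#'   `percent_raw`.
#' @export
tabulate_conditions <- function(cohort,
                                conditions =
                                  default_reference_ranges()[,
                                    c("system", "code", "display")]) {
  if (length(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  n <- length(cohort)
  ev <- cohort_events(cohort)
  cond <- ev[kind == "ConditionOnset"]
  key <- paste(cond$system, cond$code)
  counts <- vapply(seq_len(nrow(conditions)), function(i) {
    k <- paste(conditions$system[i], conditions$code[i])
    length(unique(cond$person_id[key == k]))
  }, integer(1L))
  out <- conditions
  out$count <- counts
  out$percent_raw <- 100 * counts / n
  out$percent <- round_half_up(out$percent_raw, 1L)
  rownames(out) <- NULL
  out
}

#' Distance of an observed percentage to a literature reference range
#'
#' Sign convention: observed minus reference. For a range, `diff_lower` is
#' the distance to the lower bound and `diff_upper` to the upper bound; for a
#' point reference (`lower == upper`) the difference is computed directly and
#' `diff_upper` is `NA`.
#'
#' @param observed Observed percentage(s) in `[0, 100]`.
#' @param lower,upper Reference bounds in percent (vectorized; `upper` equal
#'   to `lower` marks a point reference).
#' @return Data frame with columns `diff_lower`, `diff_upper` (percentage
#'   points).
#' @examples
#' compare_to_reference(13.6, 4, 6)    # 9.6 / 7.6
#' compare_to_reference(5.6, 7.2, 7.2) # -1.6 / NA
#' @export
compare_to_reference <- function(observed, lower, upper = lower) {
  stopifnot(all(observed >= 0 & observed <= 100),
            all(lower <= upper))
  point <- upper == lower
  data.frame(diff_lower = observed - lower,
             diff_upper = ifelse(point, NA_real_, observed - upper))
}

#' Build the full frequency report
#'
#' Tabulates the cohort, joins the literature reference ranges, and computes
#' the observed-minus-reference distances — the cohort-level validation
#' comparison for the generator.
#'
#' @param cohort List of simulated `person_record`s.
#' @param references Reference ranges; default [default_reference_ranges()].
#' @return A `frequency_report` data frame: `system`, `code`, `display`,
#'   `count`, `percent`, `percent_raw`, `ref_lower`, `ref_upper`,
#'   `diff_lower`, `diff_upper`.
#' @export
frequency_report <- function(cohort, references = default_reference_ranges()) {
  tab <- tabulate_conditions(cohort,
                             references[, c("system", "code", "display")])
  out <- cbind(tab,
               ref_lower = references$lower,
               ref_upper = references$upper)
  d <- compare_to_reference(out$percent, out$ref_lower, out$ref_upper)
  out$diff_lower <- round_half_up(d$diff_lower, 1L)
  out$diff_upper <- round_half_up(d$diff_upper, 1L)
  class(out) <- c("frequency_report", "data.frame")
  out
}

format_range <- function(lower, upper) {
  ifelse(upper == lower, formatC(lower, format = "fg"),
         paste0(formatC(lower, format = "fg"), "-",
                formatC(upper, format = "fg")))
}

format_diff <- function(dl, du) {
  ifelse(is.na(du), sprintf("%.1f", dl),
         sprintf("%.1f a %.1f", dl, du))
}

#' @export
print.frequency_report <- function(x, ...) {
  txt <- data.frame(
    code = x$code,
    condition = x$display,
    `observed n (%)` = sprintf("%d (%.1f)", x$count, x$percent),
    `literature (%)` = format_range(x$ref_lower, x$ref_upper),
    `difference (%)` = format_diff(x$diff_lower, x$diff_upper),
    check.names = FALSE)
  print(txt, right = FALSE, row.names = FALSE)
  invisible(x)
}

#' Write a frequency report
#'
#' @param report A `frequency_report`.
#' @param path Output path; a `.csv` suffix writes CSV, anything else an
#'   aligned text table mirroring the printed layout.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.csv$", path)) {
    data.table::fwrite(as.data.frame(report), path, na = "")
  } else {
    writeLines(utils::capture.output(print(report)), path, useBytes = TRUE)
  }
  invisible(path)
}
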