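# Plate-level analysis: Z'-factor assay QC, per-plate neomycin-normalized
# percent binding, duplicate summarization, hit calling.

.WELL_ROLES <- c("probe_only", "negative", "positive", "compound")
.WELL_RE <- "^[A-H](1[0-2]|[1-9])$"

#' Plate set container
#'
#' Validates a long-format table of 96-well fluorescence reads. Required
#' columns: `plate_id`, `well` (A1-H12), `role` (one of `probe_only`,
#' `negative` = probe+RNA, `positive` = probe+RNA+neomycin, `compound`),
#' `compound` (name, may be empty for control wells) and `signal`
#' (finite, >= 0). Compound names are checked with [parse_compound_name()].
#'
#' @param df A data frame with the columns above.
#' @return The validated data frame with class `plate_set`.
#' @export
plate_set <- function(df) {
  if (!is.data.frame(df)) validation_error("'df' must be a data frame")
  need <- c("plate_id", "well", "role", "compound", "signal")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    schema_error(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  df <- as.data.frame(df)[need]
  df$plate_id <- as.character(df$plate_id)
  df$well <- as.character(df$well)
  df$role <- as.character(df$role)
  df$compound <- as.character(df$compound)
  bad_well <- !grepl(.WELL_RE, df$well)
  if (any(bad_well))
    validation_error(sprintf("invalid well id(s) for a 96-well plate: %s (row %d)",
                             df$well[bad_well][1L], which(bad_well)[1L]))
  bad_role <- !(df$role %in% .WELL_ROLES)
  if (any(bad_role))
    validation_error(sprintf("unknown role '%s' (row %d); expected one of %s",
                             df$role[bad_role][1L], which(bad_role)[1L],
                             paste(.WELL_ROLES, collapse = ", ")))
  if (!is.numeric(df$signal) || any(!is.finite(df$signal)) || any(df$signal < 0))
    validation_error("'signal' must be finite and >= 0")
  key <- paste(df$plate_id, df$well)
  if (anyDuplicated(key))
    validation_error(sprintf("well mapped twice: %s", key[duplicated(key)][1L]))
  cmp <- df$role == "compound"
  if (any(cmp & (is.na(df$compound) | df$compound == "")))
    validation_error("compound wells must carry a compound name")
  for (nm in unique(df$compound[cmp])) parse_compound_name(nm)
  class(df) <- c("plate_set", "data.frame")
  df
}

#' @export
print.plate_set <- function(x, ...) {
  cat(sprintf("Plate set: %d wells on %d plate(s)\n",
              nrow(x), length(unique(x$plate_id))))
  print(table(x$role))
  invisible(x)
}

#' Z'-factor of a screening assay window
#'
#' `Z' = 1 - 3 (sigma_p + sigma_n) / |mu_p - mu_n|` from replicate positive
#' (probe + RNA + neomycin) and negative (probe + RNA) control wells, with
#' sample standard deviations. Verdict on the conventional scale: > 0.5
#' excellent, 0 to 0.5 marginal, < 0 unacceptable.
#'
#' @param positive_signals Numeric vector of positive-control signals (n >= 2).
#' @param negative_signals Numeric vector of negative-control signals (n >= 2).
#' @return A `zfactor_result`: `z`, `mu_p`, `sigma_p`, `mu_n`, `sigma_n`,
#'   `n_pos`, `n_neg`, `verdict`.
#' @export
zfactor <- function(positive_signals, negative_signals) {
  check_numeric_finite(positive_signals, "positive_signals")
  check_numeric_finite(negative_signals, "negative_signals")
  if (length(positive_signals) < 2L || length(negative_signals) < 2L)
    validation_error("need >= 2 wells per control group")
  mu_p <- mean(positive_signals); sigma_p <- stats::sd(positive_signals)
  mu_n <- mean(negative_signals); sigma_n <- stats::sd(negative_signals)
  if (mu_p == mu_n)
    domain_error("undefined assay window: positive and negative means coincide")
  z <- 1 - 3 * (sigma_p + sigma_n) / abs(mu_p - mu_n)
  verdict <- if (z > 0.5) "excellent" else if (z > 0) "marginal" else "unacceptable"
  structure(list(z = z, mu_p = mu_p, sigma_p = sigma_p, mu_n = mu_n,
                 sigma_n = sigma_n, n_pos = length(positive_signals),
                 n_neg = length(negative_signals), verdict = verdict),
            class = "zfactor_result")
}

#' @export
print.zfactor_result <- function(x, ...) {
  cat(sprintf("Z' = %.3f (%s); mu_p = %.4g +/- %.3g (n=%d), mu_n = %.4g +/- %.3g (n=%d)\n",
              x$z, x$verdict, x$mu_p, x$sigma_p, x$n_pos,
              x$mu_n, x$sigma_n, x$n_neg))
  invisible(x)
}

#' Percent binding relative to the on-plate neomycin control
#'
#' `100 * (compound - baseline) / (neomycin - baseline)`: the compound's
#' displacement window as a percentage of neomycin's on the same plate.
#' Deltas are signed — values below 0% or above 100% are reported, not
#' clipped.
#'
#' @param compound_signal Mean fluorescence of the compound wells.
#' @param neomycin_signal Mean fluorescence of the positive (neomycin) wells.
#' @param baseline_signal Mean fluorescence of the negative (probe+RNA) wells.
#' @return Percent binding (vectorized over `compound_signal`).
#' @export
percent_binding <- function(compound_signal, neomycin_signal, baseline_signal) {
  check_numeric_finite(compound_signal, "compound_signal")
  check_scalar_finite(neomycin_signal, "neomycin_signal")
  check_scalar_finite(baseline_signal, "baseline_signal")
  if (neomycin_signal == baseline_signal)
    domain_error("zero neomycin window: neomycin and baseline signals coincide")
  100 * (compound_signal - baseline_signal) /
    (neomycin_signal - baseline_signal)
}

#' Summarize a displacement screen
#'
#' Per plate, computes the baseline (negative wells) and neomycin (positive
#' wells) means from that plate only, converts each compound replicate well to
#' percent binding against those plate controls, and averages replicates. The
#' spread is the sample SD of replicate percents (0 for a single well). A
#' compound appearing on more than one plate keeps one record per plate, with
#' `split_across_plates = TRUE`. The neomycin control itself is reported as a
#' `Neomycin` record at 100% by construction.
#'
#' @param plates A [plate_set()] (or coercible data frame).
#' @return A `screen_table` data frame: `compound`, `percent_binding`,
#'   `spread`, `n_replicates`, `plate_id`, `hit` (all `FALSE` until
#'   [call_hits()]), `split_across_plates`.
#' @export
summarize_screen <- function(plates) {
  plates <- if (inherits(plates, "plate_set")) plates else plate_set(plates)
  out <- list()
  for (pid in unique(plates$plate_id)) {
    pl <- plates[plates$plate_id == pid, ]
    neg <- pl$signal[pl$role == "negative"]
    pos <- pl$signal[pl$role == "positive"]
    if (length(neg) < 1L || length(pos) < 1L)
      validation_error(sprintf(
        "plate '%s' is missing %s control wells", pid,
        paste(c("negative", "positive")[c(length(neg) < 1L, length(pos) < 1L)],
              collapse = " and ")))
    baseline <- mean(neg); neo <- mean(pos)
    cmp <- pl[pl$role == "compound", ]
    groups <- c(split(cmp$signal, cmp$compound), list(Neomycin = pos))
    for (nm in names(groups)) {
      sig <- groups[[nm]]
      pct <- percent_binding(sig, neo, baseline)
      out[[length(out) + 1L]] <- data.frame(
        compound = nm,
        percent_binding = mean(pct),
        spread = if (length(pct) > 1L) stats::sd(pct) else 0,
        n_replicates = length(pct),
        plate_id = pid,
        hit = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  dup <- tab$compound %in% tab$compound[duplicated(tab$compound)]
  tab$split_across_plates <- dup & tab$compound != "Neomycin"
  class(tab) <- c("screen_table", "data.frame")
  tab
}

#' Flag hits in a screen table
#'
#' @param table A `screen_table` from [summarize_screen()].
#' @param threshold_percent Hit threshold on percent binding (default 110:
#'   at least ten percent more displacement than the parent neomycin).
#' @return The table with the `hit` column set.
#' @export
flag_hits <- function(table, threshold_percent = 110) {
  check_scalar_finite(threshold_percent, "threshold_percent")
  if (threshold_percent <= 0) validation_error("'threshold_percent' must be > 0")
  table$hit <- table$percent_binding >= threshold_percent
  table
}

#' Call hits from a screen table
#'
#' Flags records with `percent_binding >= threshold_percent` and returns the
#' hit subset sorted by descending percent binding.
#'
#' @inheritParams flag_hits
#' @return The hit subset of `table` (possibly empty), sorted descending.
#' @export
call_hits <- function(table, threshold_percent = 110) {
  if (is.null(table) || nrow(table) == 0L) return(table)
  table <- flag_hits(table, threshold_percent)
  hits <- table[table$hit, , drop = FALSE]
  hits[order(-hits$percent_binding), , drop = FALSE]
}
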