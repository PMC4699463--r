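# Positional amino-acid preference statistics (the sigma ledger): per-compound
# deviations from the library mean and positional class averages for
# peptidic-aminoglycoside (neomycin-amino acid conjugate) libraries.

# One-letter codes used in the conjugate library; beta-alanine is a distinct
# two-character token "bA" (rendered βA in Unicode), never collapsed to A.
.AA_CODES <- c("A", "R", "N", "D", "C", "H", "L", "K", "F", "P",
               "S", "T", "W", "Y", "V")
.BA_ASCII <- "bA"
.BA_UTF8 <- "βA"

.tokenize_positions <- function(body, raw, allow_x = FALSE) {
  toks <- character(0)
  while (nchar(body) > 0L) {
    if (startsWith(body, .BA_UTF8)) {
      toks <- c(toks, .BA_ASCII)
      body <- substring(body, nchar(.BA_UTF8) + 1L)
    } else if (startsWith(body, .BA_ASCII)) {
      toks <- c(toks, .BA_ASCII)
      body <- substring(body, 3L)
    } else {
      ch <- substring(body, 1L, 1L)
      if (!(ch %in% .AA_CODES || (allow_x && ch == "X")))
        parse_error(sprintf("unknown amino-acid code '%s' in '%s'", ch, raw))
      toks <- c(toks, ch)
      body <- substring(body, 2L)
    }
  }
  if (length(toks) > 2L)
    parse_error(sprintf("'%s' has more than two conjugation positions", raw))
  toks
}

#' Parse a conjugate compound name
#'
#' Names encode the amino acids conjugated to neomycin: `"Neomycin"` (or bare
#' `"Neo"`) is the unconjugated parent; `"NeoR"` carries arginine at position
#' 1; `"NeoRS"` arginine at position 1 and serine at position 2. Beta-alanine
#' is the two-character token `"βA"` (accepted in ASCII form `"bA"`).
#'
#' @param raw Compound name string.
#' @return A `compound_name`: `raw`, `pos1`, `pos2` (`NA` when absent;
#'   beta-alanine stored as `"bA"`).
#' @export
parse_compound_name <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || raw == "")
    parse_error("compound name must be a non-empty string")
  if (raw == "Neomycin" || raw == "Neo")
    return(structure(list(raw = raw, pos1 = NA_character_, pos2 = NA_character_),
                     class = "compound_name"))
  if (!startsWith(raw, "Neo"))
    parse_error(sprintf("'%s' does not start with 'Neo'", raw))
  toks <- .tokenize_positions(substring(raw, 4L), raw)
  if (length(toks) == 0L)
    parse_error(sprintf("'%s' names no conjugated amino acid", raw))
  structure(list(raw = raw, pos1 = toks[1L],
                 pos2 = if (length(toks) > 1L) toks[2L] else NA_character_),
            class = "compound_name")
}

#' Format a compound name from its parsed positions
#'
#' Round-trips with [parse_compound_name()]; `ascii = TRUE` serializes
#' beta-alanine as `"bA"` (lossless), `ascii = FALSE` as `"βA"`.
#'
#' @param x A `compound_name`.
#' @param ascii Use the ASCII beta-alanine spelling (default `TRUE`).
#' @param ... Unused.
#' @return The compound name string.
#' @export
format.compound_name <- function(x, ascii = TRUE, ...) {
  if (is.na(x$pos1)) return(if (x$raw == "Neo") "Neo" else "Neomycin")
  render <- function(tok) {
    if (is.na(tok)) "" else if (tok == .BA_ASCII && !ascii) .BA_UTF8 else tok
  }
  paste0("Neo", render(x$pos1), render(x$pos2))
}

#' @export
print.compound_name <- function(x, ...) {
  cat(sprintf("Compound %s: position 1 = %s, position 2 = %s\n",
              format(x), ifelse(is.na(x$pos1), "(none)", x$pos1),
              ifelse(is.na(x$pos2), "(none)", x$pos2)))
  invisible(x)
}

#' Library z-scores (sigma deviations) for one miRNA
#'
#' Expresses each library compound's percent binding as its deviation from the
#' library mean in units of the library sample SD:
#' `sigma_i = (b_i - mean(b)) / sd(b)`. Neomycin is the normalization anchor
#' (100% by construction), not a library member, and is excluded from both the
#' statistics and the output. A degenerate library (SD = 0) returns all-zero
#' deviations with a warning.
#'
#' @param table A `screen_table` from [summarize_screen()] for one miRNA, or a
#'   data frame with `compound` and `percent_binding` columns.
#' @param mirna_id Identifier of the assayed miRNA carried into the output.
#' @return A `preference_scores` data frame: `compound`, `mirna_id`,
#'   `percent_binding`, `sigma_dev`; attributes `library_mean`, `library_sd`.
#' @export
library_zscores <- function(table, mirna_id = "miRNA") {
  if (!is.data.frame(table) ||
      !all(c("compound", "percent_binding") %in% names(table)))
    validation_error("'table' needs columns 'compound' and 'percent_binding'")
  tab <- table[!(table$compound %in% c("Neomycin", "Neo")), , drop = FALSE]
  if (nrow(tab) < 3L) validation_error("need >= 3 library compounds")
  b <- tab$percent_binding
  mu <- mean(b)
  sdev <- stats::sd(b)
  if (sdev == 0) {
    warning("degenerate library: SD of percent binding is 0; all sigma set to 0",
            call. = FALSE)
    z <- rep(0, length(b))
  } else {
    z <- (b - mu) / sdev
  }
  out <- data.frame(compound = tab$compound, mirna_id = mirna_id,
                    percent_binding = b, sigma_dev = z,
                    stringsAsFactors = FALSE)
  attr(out, "library_mean") <- mu
  attr(out, "library_sd") <- sdev
  class(out) <- c("preference_scores", "data.frame")
  out
}

# Does a parsed compound match a class pattern? Patterns use X as the
# positional wildcard: at position 1, X matches any amino acid (the parent has
# none); at position 2, X matches any amino acid or none ("NeoRX, where X is
# any or no amino acid in position 2"). "NeoX" is the mono-conjugate class.
.matches_class <- function(cn, spec_toks) {
  n <- length(spec_toks)
  if (n == 0L) return(is.na(cn$pos1))          # parent neomycin
  if (is.na(cn$pos1)) return(FALSE)
  p1 <- spec_toks[1L]
  if (p1 != "X" && !identical(cn$pos1, p1)) return(FALSE)
  if (n == 1L) {
    if (p1 == "X") return(is.na(cn$pos2))      # NeoX: mono-conjugates only
    return(is.na(cn$pos2))                     # NeoR: the single compound
  }
  p2 <- spec_toks[2L]
  if (p2 == "X") return(TRUE)                  # any or no amino acid at pos 2
  identical(cn$pos2, p2)
}

.parse_class_spec <- function(class_spec) {
  if (!is.character(class_spec) || length(class_spec) != 1L ||
      !startsWith(class_spec, "Neo"))
    validation_error("class spec must be a 'Neo...' pattern string")
  .tokenize_positions(substring(class_spec, 4L), class_spec, allow_x = TRUE)
}

#' Average sigma deviation of a positional compound class
#'
#' Averages `sigma_dev` over the members of a class pattern. Supported
#' patterns: `NeoRX` (fixed position 1, any or no position 2), `NeoXS` (any
#' position 1, fixed position 2), `NeoX` (mono-conjugates), `NeoRS` (a single
#' compound). Members are weighted equally.
#'
#' @param scores A `preference_scores` data frame from [library_zscores()].
#' @param class_spec Class pattern string.
#' @return A `class_average`: `class_spec`, `mirna_id`, `mean_sigma`,
#'   `n_members`, `members`.
#' @export
class_average <- function(scores, class_spec) {
  if (!is.data.frame(scores) ||
      !all(c("compound", "sigma_dev") %in% names(scores)))
    validation_error("'scores' must come from library_zscores()")
  toks <- .parse_class_spec(class_spec)
  parsed <- lapply(scores$compound, parse_compound_name)
  keep <- vapply(parsed, .matches_class, logical(1), spec_toks = toks)
  if (!any(keep))
    validation_error(sprintf("class '%s' has no members in the score table",
                             class_spec))
  structure(list(
    class_spec = class_spec,
    mirna_id = if (!is.null(scores$mirna_id)) scores$mirna_id[1L] else NA,
    mean_sigma = mean(scores$sigma_dev[keep]),
    n_members = sum(keep),
    members = scores$compound[keep]
  ), class = "class_average")
}

#' @export
print.class_average <- function(x, ...) {
  cat(sprintf("%s (%s): mean sigma = %+.3f over %d compound(s)\n",
              x$class_spec, x$mirna_id, x$mean_sigma, x$n_members))
  invisible(x)
}

#' Positional preference ledger across class patterns and miRNAs
#'
#' Builds the familiar classes-by-miRNA table of mean sigma deviations.
#'
#' @param scores_by_mirna Named list of `preference_scores` (one per miRNA).
#' @param class_specs Character vector of class patterns (rows).
#' @return A data frame, rows = class specs, one column per miRNA.
#' @export
preference_table <- function(scores_by_mirna, class_specs) {
  if (!is.list(scores_by_mirna) || is.null(names(scores_by_mirna)))
    validation_error("'scores_by_mirna' must be a named list")
  cols <- lapply(scores_by_mirna, function(sc)
    vapply(class_specs, function(cs) class_average(sc, cs)$mean_sigma,
           numeric(1)))
  out <- data.frame(class_spec = class_specs, stringsAsFactors = FALSE)
  for (nm in names(scores_by_mirna)) out[[nm]] <- unname(cols[[nm]])
  out
}

#' Cross-miRNA specificity deltas for one compound
#'
#' Pairwise differences of a compound's sigma deviation between miRNAs:
#' `delta[i, j] = sigma(miRNA_i) - sigma(miRNA_j)`. A large positive entry
#' means the conjugation helps binding of miRNA i more than miRNA j relative
#' to the rest of the library — a specificity gain. The matrix is
#' antisymmetric by construction.
#'
#' @param scores_by_mirna Named list of `preference_scores`.
#' @param compound Compound name present in at least two score sets.
#' @return Antisymmetric numeric matrix of sigma differences.
#' @export
specificity_delta <- function(scores_by_mirna, compound) {
  if (!is.list(scores_by_mirna) || is.null(names(scores_by_mirna)))
    validation_error("'scores_by_mirna' must be a named list")
  sig <- vapply(scores_by_mirna, function(sc) {
    i <- match(compound, sc$compound)
    if (is.na(i)) NA_real_ else sc$sigma_dev[i]
  }, numeric(1))
  if (any(is.na(sig)))
    validation_error(sprintf(
      "compound '%s' missing from score set(s): %s (searched: %s)",
      compound, paste(names(sig)[is.na(sig)], collapse = ", "),
      paste(names(sig), collapse = ", ")))
  if (length(sig) < 2L)
    validation_error("compound must appear in >= 2 miRNA score sets")
  outer(sig, sig, "-")
}
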