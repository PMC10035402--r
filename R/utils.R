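#' Round half away from zero
#'
#' Rounding convention used for all printed percentages and means: halves are
#' rounded away from zero (so 12.5 -> 13), unlike base R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clonality labels
#'
#' Ordered label set used throughout: CLONAL (all tumor biopsies carry the
#' variant), SUBCLONAL (more than one but not all), PRIVATE (exactly one),
#' NONE (aberrant cases: no presence after merging, or single-biopsy patients
#' where clonality is unassessable).
#' @export
CLONALITY_LEVELS <- c("CLONAL", "SUBCLONAL", "PRIVATE", "NONE")

#' TCGA gastric molecular subtypes
#' @export
SUBTYPE_LEVELS <- c("EBV", "MSI", "CIN", "GS")

stop_parse <- function(...) stop(sprintf(...), call. = FALSE)

# shared validation: a data.frame has the named columns
check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop_parse("%s: missing required column(s): %s", what,
               paste(miss, collapse = ", "))
  }
  invisible(df)
}
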