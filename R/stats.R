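## Cohort-level descriptive and inferential statistics: per-biopsy mutation
## rates over the targeted region, two-sample t tests, Freeman-Halton exact
## tests on r x c contingency tables, and the clinical-table summary.

#' Per-biopsy mutation rate over the targeted region
#'
#' @param nonsilent_count,silent_count Nonnegative mutation counts.
#' @param panel Panel definition (uses \code{target_mbp}).
#' @return List with \code{nonsilent}, \code{silent}, \code{total} rates in
#'   mutations per targeted Mbp.
#' @export
mutation_rate_per_biopsy <- function(nonsilent_count, silent_count, panel) {
  if (nonsilent_count < 0 || silent_count < 0) {
    stop_parse("mutation_rate_per_biopsy: negative count")
  }
  stopifnot(panel$target_mbp > 0)
  list(nonsilent = nonsilent_count / panel$target_mbp,
       silent = silent_count / panel$target_mbp,
       total = (nonsilent_count + silent_count) / panel$target_mbp)
}

#' Two-sample t test
#'
#' Student's two-sample t (pooled variance by default; Welch optional).
#' Missing values are dropped and counted.
#'
#' @param group_a,group_b Numeric vectors (each >= 2 non-missing values).
#' @param variant \code{"pooled"} (default) or \code{"welch"}.
#' @return List with \code{t}, \code{df}, \code{p} (two-sided),
#'   \code{mean_a}, \code{mean_b}, \code{n_missing}.
#' @export
two_sample_t <- function(group_a, group_b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  n_missing <- sum(is.na(group_a)) + sum(is.na(group_b))
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop_parse("two_sample_t: each group needs >= 2 non-missing values")
  }
  tt <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b),
       n_missing = n_missing)
}

.log_table_prob <- function(tab, lr, lc, ln) {
  # conditional probability of an r x c table given its margins
  lr + lc - ln - sum(lgamma(tab + 1))
}

.enumerate_tables <- function(rows, cols) {
  # all nonnegative integer matrices with the given margins
  r <- length(rows)
  out <- list()
  rec <- function(i, remaining_cols, acc) {
    if (i == r) {
      if (all(remaining_cols >= 0)) {
        out[[length(out) + 1L]] <<- rbind(acc, remaining_cols)
      }
      return(invisible())
    }
    cells <- .compositions(rows[i], remaining_cols)
    for (j in seq_len(nrow(cells))) {
      rec(i + 1L, remaining_cols - cells[j, ], rbind(acc, cells[j, ]))
    }
  }
  rec(1L, cols, matrix(numeric(0), nrow = 0, ncol = length(cols)))
  out
}

.compositions <- function(total, caps) {
  # nonnegative integer vectors summing to `total` with per-entry caps
  if (length(caps) == 1L) {
    if (total <= caps[1]) return(matrix(total, 1, 1))
    return(matrix(numeric(0), 0, 1))
  }
  res <- list()
  for (x in 0:min(total, caps[1])) {
    rest <- .compositions(total - x, caps[-1])
    if (nrow(rest) > 0) res[[length(res) + 1L]] <- cbind(x, rest)
  }
  if (length(res) == 0L) return(matrix(numeric(0), 0, length(caps)))
  out <- do.call(rbind, res)
  dimnames(out) <- NULL
  out
}

#' Freeman-Halton (Fisher) exact test for r x c tables
#'
#' Two-sided p-value by the probability-ordering rule: the total conditional
#' probability, over all tables with the observed margins, of tables whose
#' probability does not exceed that of the observed table (equality within a
#' relative slack of 1e-12). \code{enumerate} walks every table with the
#' observed margins (permitted for total n <= 40); \code{monte_carlo} samples
#' margin-preserving tables with base R's Patefield algorithm
#' (\code{r2dtable}) under a fixed seed. The 2 x 2 case agrees with the
#' classical two-sided Fisher test.
#'
#' @param table Integer matrix (at least 2 x 2) of counts.
#' @param method \code{"enumerate"} or \code{"monte_carlo"}.
#' @param n_draws Monte Carlo draws (default 1e6).
#' @param seed Seed for the Monte Carlo method.
#' @return The two-sided p-value, with attribute \code{method}.
#' @export
fisher_exact <- function(table, method = c("enumerate", "monte_carlo"),
                         n_draws = 1e6, seed = 1L) {
  method <- match.arg(method)
  tab <- as.matrix(table)
  if (any(tab != round(tab)) || any(tab < 0)) {
    stop_parse("fisher_exact: counts must be nonnegative integers")
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) stop_parse("fisher_exact: table must be at least 2x2")
  n <- sum(tab)
  if (n < 1) stop_parse("fisher_exact: empty table")
  rows <- rowSums(tab)
  cols <- colSums(tab)
  lr <- sum(lgamma(rows + 1))
  lc <- sum(lgamma(cols + 1))
  ln <- lgamma(n + 1)
  lp_obs <- .log_table_prob(tab, lr, lc, ln)
  slack <- 1e-12
  if (method == "enumerate") {
    if (n > 40) {
      stop_parse("fisher_exact: enumeration permitted only for n <= 40 (n = %d); use monte_carlo", n)
    }
    tabs <- .enumerate_tables(rows, cols)
    lps <- vapply(tabs, .log_table_prob, numeric(1), lr = lr, lc = lc, ln = ln)
    p <- sum(exp(lps[lps <= lp_obs + slack]))
    p <- min(p, 1)
  } else {
    set.seed(seed)
    chunk <- 1e5
    hits <- 0
    done <- 0
    while (done < n_draws) {
      b <- min(chunk, n_draws - done)
      draws <- stats::r2dtable(b, rows, cols)
      lps <- vapply(draws, .log_table_prob, numeric(1), lr = lr, lc = lc,
                    ln = ln)
      hits <- hits + sum(lps <= lp_obs + slack)
      done <- done + b
    }
    p <- hits / n_draws
  }
  attr(p, "method") <- method
  p
}

#' Summarize a cohort clinical table
#'
#' Percent male over all patients; mean age over non-missing ages, overall
#' and by country; percent advanced stage (stage III or IV) over patients
#' with known stage; subtype percentages (overall and Latino-only). Percents
#' and reported mean ages are rounded half-away-from-zero to integers; raw
#' means are also returned.
#'
#' @param patients Patient records data.frame (see
#'   \code{\link{read_cohort_table}}).
#' @param advanced_denominator \code{"known_stage"} (default) or
#'   \code{"all"}.
#' @return List of class \code{cohort_summary}.
#' @export
summarize_cohort <- function(patients,
                             advanced_denominator = c("known_stage", "all")) {
  advanced_denominator <- match.arg(advanced_denominator)
  stopifnot(nrow(patients) >= 1)
  n <- nrow(patients)
  pct_male <- round_half_up(100 * sum(patients$sex == "M", na.rm = TRUE) / n)
  ages <- patients$age
  mean_age <- mean(ages, na.rm = TRUE)
  by_country <- tapply(ages, patients$country,
                       function(x) mean(x, na.rm = TRUE))
  advanced <- !is.na(patients$stage) & grepl("^(III|IV)", patients$stage)
  denom <- if (advanced_denominator == "known_stage") {
    sum(!is.na(patients$stage))
  } else n
  pct_advanced <- round_half_up(100 * sum(advanced) / denom)
  out <- list(
    n_patients = n,
    percent_male = pct_male,
    mean_age = mean_age,
    mean_age_rounded = round_half_up(mean_age),
    mean_age_by_country = by_country,
    percent_advanced_stage = pct_advanced,
    subtype_percent = subtype_frequencies(patients),
    subtype_percent_latino = tryCatch(
      subtype_frequencies(patients, ethnicity = "Latino"),
      error = function(e) NULL)
  )
  class(out) <- "cohort_summary"
  out
}

#' Subtype-by-country contingency table
#'
#' Builds the r x c table of subtype counts by country for the selected
#' patients (rows = subtypes in EBV/MSI/CIN/GS order, columns = countries in
#' the given order).
#'
#' @param patients Patient records.
#' @param countries Countries to include, in column order.
#' @param ethnicity Optional ethnicity filter.
#' @return Integer matrix.
#' @export
subtype_country_table <- function(patients, countries = c("Colombia", "Mexico"),
                                  ethnicity = NULL) {
  p <- patients
  if (!is.null(ethnicity)) p <- p[p$ethnicity %in% ethnicity, , drop = FALSE]
  p <- p[p$country %in% countries, , drop = FALSE]
  tab <- vapply(countries, function(ct) {
    vapply(SUBTYPE_LEVELS, function(s) {
      sum(p$country == ct & p$subtype_assigned == s, na.rm = TRUE)
    }, numeric(1))
  }, numeric(length(SUBTYPE_LEVELS)))
  matrix(as.integer(tab), nrow = length(SUBTYPE_LEVELS),
         dimnames = list(SUBTYPE_LEVELS, countries))
}
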