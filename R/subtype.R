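## TCGA gastric molecular subtype assignment: EBV -> MSI -> CIN -> GS decision
## cascade over three evidence channels (EBV on-target read fraction, a
## simplified microsatellite-instability score, CNV-altered panel fraction).

#' Simplified microsatellite instability score
#'
#' For each assessable locus (tumor and normal histogram totals both at least
#' \code{min_locus_coverage}), tumor and normal repeat-length histograms are
#' compared by a chi-square homogeneity test on the 2 x L table, after pooling
#' adjacent length bins until every expected cell is at least 1. A locus is
#' unstable when its Benjamini-Hochberg adjusted p-value is below
#' \code{alpha}. The score is the percentage of assessable loci that are
#' unstable (the conventional MSI-high cutoff on this scale is 3.5).
#'
#' @param loci Long-format data.frame with columns \code{locus_id,
#'   sample_role, repeat_length, read_count} for one tumor/normal pair.
#' @param alpha Per-locus adjusted significance level (default 0.05).
#' @param min_locus_coverage Minimum reads per histogram for a locus to be
#'   assessable (default 20).
#' @param min_assessable_loci Minimum assessable loci required (default 20).
#' @return Percent of assessable loci unstable, with attributes
#'   \code{n_assessable} and \code{n_unstable}.
#' @export
msi_score <- function(loci, alpha = 0.05, min_locus_coverage = 20,
                      min_assessable_loci = 20) {
  stopifnot(is.data.frame(loci))
  ids <- unique(loci$locus_id)
  pvals <- numeric(0)
  for (id in ids) {
    sub <- loci[loci$locus_id == id, , drop = FALSE]
    lengths <- sort(unique(sub$repeat_length))
    tum <- stats::setNames(rep(0, length(lengths)), lengths)
    nor <- tum
    tt <- sub[sub$sample_role == "tumor", , drop = FALSE]
    nn <- sub[sub$sample_role == "normal", , drop = FALSE]
    tum[as.character(tt$repeat_length)] <- tum[as.character(tt$repeat_length)] + tt$read_count
    nor[as.character(nn$repeat_length)] <- nor[as.character(nn$repeat_length)] + nn$read_count
    if (sum(tum) < min_locus_coverage || sum(nor) < min_locus_coverage) next
    pvals <- c(pvals, .locus_chisq_p(tum, nor))
  }
  n_assessable <- length(pvals)
  if (n_assessable < min_assessable_loci) {
    stop_parse("msi_score: only %d assessable loci (need >= %d)",
               n_assessable, min_assessable_loci)
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  n_unstable <- sum(adj < alpha)
  score <- 100 * n_unstable / n_assessable
  attr(score, "n_assessable") <- n_assessable
  attr(score, "n_unstable") <- n_unstable
  score
}

# chi-square homogeneity p for a 2 x L table after pooling adjacent length
# bins so that every expected cell is >= 1; p = 1 when only one pooled bin
# remains or a margin is degenerate.
.locus_chisq_p <- function(tumor, normal) {
  counts <- rbind(tumor, normal)
  n <- sum(counts)
  # pool left to right until each pooled column's expected cells are all >= 1
  pooled <- list()
  acc <- c(0, 0)
  rowp <- rowSums(counts) / n
  for (j in seq_len(ncol(counts))) {
    acc <- acc + counts[, j]
    if (all(sum(acc) * rowp >= 1)) {
      pooled[[length(pooled) + 1L]] <- acc
      acc <- c(0, 0)
    }
  }
  if (sum(acc) > 0) {
    if (length(pooled) == 0L) {
      pooled[[1L]] <- acc
    } else {
      pooled[[length(pooled)]] <- pooled[[length(pooled)]] + acc
    }
  }
  tab <- do.call(cbind, pooled)
  if (ncol(tab) < 2L || any(rowSums(tab) == 0)) return(1)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Fraction of the panel altered by copy-number changes
#'
#' Panel bases covered by segments with |log2 ratio| at or above
#' \code{amp_del_log2}, divided by total panel bases. Overlapping qualifying
#' segments are counted once (interval union).
#'
#' @param segments Data.frame of CNV segments (\code{chrom, start, end,
#'   log2_ratio}; half-open 0-based).
#' @param panel Panel definition from \code{\link{read_panel_definition}}.
#' @param amp_del_log2 Absolute log2-ratio threshold (default 0.3).
#' @return Fraction in [0, 1].
#' @export
cnv_altered_fraction <- function(segments, panel, amp_del_log2 = 0.3) {
  if (nrow(segments) == 0L) return(0)
  if (any(segments$end <= segments$start)) {
    stop_parse("cnv_altered_fraction: segment with end <= start")
  }
  qual <- segments[abs(segments$log2_ratio) >= amp_del_log2, , drop = FALSE]
  if (nrow(qual) == 0L) return(0)
  tr <- panel$target_regions
  panel_gr <- GenomicRanges::GRanges(
    tr$chrom, IRanges::IRanges(start = tr$start + 1L, end = tr$end))
  panel_gr <- GenomicRanges::reduce(panel_gr)
  seg_gr <- GenomicRanges::GRanges(
    qual$chrom, IRanges::IRanges(start = qual$start + 1L, end = qual$end))
  seg_gr <- GenomicRanges::reduce(seg_gr)
  hit <- GenomicRanges::intersect(panel_gr, seg_gr)
  total <- sum(GenomicRanges::width(panel_gr))
  sum(GenomicRanges::width(hit)) / total
}

#' Subtype decision thresholds
#'
#' @param ebv_min Minimum EBV on-target read fraction for the EBV call
#'   (default 1e-4, separating real viral load from bleed-through).
#' @param msi_min Minimum MSI score (percent unstable loci; default 3.5, the
#'   conventional MSI-high cutoff).
#' @param cin_min Minimum CNV-altered panel fraction for CIN (default 0.20).
#' @return List of class \code{subtype_thresholds}.
#' @export
subtype_thresholds <- function(ebv_min = 1e-4, msi_min = 3.5, cin_min = 0.20) {
  structure(list(ebv_min = ebv_min, msi_min = msi_min, cin_min = cin_min),
            class = "subtype_thresholds")
}

#' Assign a TCGA gastric molecular subtype
#'
#' Decision cascade in TCGA order: EBV if the EBV read fraction reaches
#' \code{ebv_min}; else MSI if the MSI score reaches \code{msi_min}; else CIN
#' if the CNV-altered fraction reaches \code{cin_min}; else GS (genomically
#' stable).
#'
#' @param evidence List or one-row data.frame with \code{ebv_read_fraction},
#'   \code{msi_score} (percent), \code{cnv_altered_fraction}.
#' @param thresholds A \code{\link{subtype_thresholds}} object.
#' @param patient_id Optional id carried through to the result.
#' @return A list with \code{patient_id}, \code{subtype}, \code{evidence} and
#'   \code{thresholds}.
#' @export
assign_subtype <- function(evidence, thresholds = subtype_thresholds(),
                           patient_id = NA_character_) {
  stopifnot(all(c("ebv_read_fraction", "msi_score", "cnv_altered_fraction")
                %in% names(evidence)))
  subtype <- if (evidence$ebv_read_fraction >= thresholds$ebv_min) {
    "EBV"
  } else if (evidence$msi_score >= thresholds$msi_min) {
    "MSI"
  } else if (evidence$cnv_altered_fraction >= thresholds$cin_min) {
    "CIN"
  } else {
    "GS"
  }
  list(patient_id = patient_id, subtype = subtype,
       evidence = evidence[c("ebv_read_fraction", "msi_score",
                             "cnv_altered_fraction")],
       thresholds = thresholds)
}

#' Subtype frequencies in a (filtered) cohort
#'
#' Percent of patients per subtype, rounded half-away-from-zero to integers.
#'
#' @param patients Data.frame of patient records (needs
#'   \code{patient_id} plus any filter columns).
#' @param subtypes Named character vector patient_id -> subtype, or NULL to
#'   use the \code{subtype_assigned} column of \code{patients}.
#' @param ethnicity,country Optional filters on the patient records.
#' @return Named numeric vector of integer percentages over
#'   \code{EBV, MSI, CIN, GS}, with attribute \code{n} (patients counted).
#' @export
subtype_frequencies <- function(patients, subtypes = NULL, ethnicity = NULL,
                                country = NULL) {
  sel <- rep(TRUE, nrow(patients))
  if (!is.null(ethnicity)) sel <- sel & patients$ethnicity %in% ethnicity
  if (!is.null(country)) sel <- sel & patients$country %in% country
  p <- patients[sel, , drop = FALSE]
  if (nrow(p) == 0L) stop_parse("subtype_frequencies: no patients after filtering")
  st <- if (is.null(subtypes)) p$subtype_assigned else unname(subtypes[p$patient_id])
  counts <- vapply(SUBTYPE_LEVELS, function(s) sum(st == s, na.rm = TRUE),
                   numeric(1))
  pct <- round_half_up(100 * counts / nrow(p))
  attr(pct, "n") <- nrow(p)
  pct
}

#' Aggregate per-biopsy evidence into patient-level subtype evidence
#'
#' Multi-biopsy evidence is combined as: maximum EBV read fraction, maximum
#' MSI score, mean CNV-altered fraction across biopsies.
#'
#' @param ebv_fractions Numeric vector of per-biopsy EBV read fractions.
#' @param msi_scores Numeric vector of per-pair MSI scores (percent).
#' @param cnv_fractions Numeric vector of per-biopsy altered fractions.
#' @return Evidence list consumable by \code{\link{assign_subtype}}.
#' @export
aggregate_subtype_evidence <- function(ebv_fractions, msi_scores,
                                       cnv_fractions) {
  list(ebv_read_fraction = max(ebv_fractions, na.rm = TRUE),
       msi_score = max(msi_scores, na.rm = TRUE),
       cnv_altered_fraction = mean(cnv_fractions, na.rm = TRUE))
}
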