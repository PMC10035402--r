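## Per-patient variant merging, forced-call rescue of censored presences, and
## clonality labelling across spatially separated tumor biopsies.

#' Rescue parameters
#'
#' Thresholds used by \code{\link{forced_call_rescue}} to decide whether the
#' mutant-allele reads observed in a biopsy where the upstream caller did not
#' emit the variant are convincing evidence of presence. A biopsy is rescued
#' only when all of the following hold: coverage at least \code{min_depth},
#' at least \code{min_alt_reads} mutant reads, variant allele fraction at
#' least \code{min_vaf}, and an upper-tail binomial probability of seeing that
#' many mutant reads from sequencing error alone (per-base error
#' \code{error_rate}) no larger than \code{max_binomial_p}. Defaults are
#' conservative against error at ~336x panel depth.
#'
#' @param min_alt_reads Minimum mutant reads (default 3).
#' @param min_vaf Minimum variant allele fraction (default 0.01).
#' @param min_depth Minimum coverage for a biopsy to be evaluable (default 20).
#' @param max_binomial_p Maximum binomial upper-tail probability (default 0.01).
#' @param error_rate Assumed per-base sequencing error rate (default 0.001).
#' @return A list of class \code{rescue_params}.
#' @export
rescue_params <- function(min_alt_reads = 3L, min_vaf = 0.01, min_depth = 20L,
                          max_binomial_p = 0.01, error_rate = 0.001) {
  stopifnot(min_alt_reads >= 0, min_vaf >= 0, min_vaf <= 1, min_depth >= 0,
            max_binomial_p >= 0, error_rate >= 0)
  structure(list(min_alt_reads = min_alt_reads, min_vaf = min_vaf,
                 min_depth = min_depth, max_binomial_p = max_binomial_p,
                 error_rate = error_rate),
            class = "rescue_params")
}

#' Merge per-biopsy calls into per-patient variant records
#'
#' Collapses one patient's variant-biopsy rows into one record per distinct
#' variant key (chrom, pos, ref, alt), with an ordered presence vector over
#' the patient's tumor biopsies and per-biopsy read counts. Presence is taken
#' from the \code{called} flag. Exact duplicate rows within one biopsy are
#' collapsed with a warning. Read counts at biopsies without a row are
#' recorded as NA (depth unknown there).
#'
#' @param calls Data.frame of variant calls for one patient.
#' @param biopsy_order Character vector of the patient's tumor biopsy ids, in
#'   the order presence vectors should use; must cover every biopsy_id in
#'   \code{calls}.
#' @return A data.frame with one row per distinct variant key and columns
#'   \code{chrom, pos, ref, alt, patient_id, gene, effect,
#'   trinucleotide_context} plus list-columns \code{presence},
#'   \code{rescued}, \code{alt_reads}, \code{depth} (each a vector over
#'   \code{biopsy_order}) and a \code{clonality} column (NA until
#'   \code{\link{classify_clonality}} is applied).
#' @export
merge_patient_variants <- function(calls, biopsy_order) {
  stopifnot(is.data.frame(calls), length(biopsy_order) >= 1)
  if (nrow(calls) > 0 && length(unique(calls$patient_id)) > 1) {
    stop_parse("merge_patient_variants: calls span multiple patients: %s",
               paste(unique(calls$patient_id), collapse = ", "))
  }
  unknown <- setdiff(unique(calls$biopsy_id), biopsy_order)
  if (length(unknown) > 0) {
    stop_parse("merge_patient_variants: biopsy_id not in biopsy_order: %s",
               paste(unknown, collapse = ", "))
  }
  nb <- length(biopsy_order)
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  dup <- duplicated(paste(key, calls$biopsy_id))
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate variant-biopsy row(s)", sum(dup)),
            call. = FALSE)
    calls <- calls[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  out <- list()
  for (k in unique(key)) {
    rows <- calls[key == k, , drop = FALSE]
    idx <- match(rows$biopsy_id, biopsy_order)
    presence <- rep(FALSE, nb)
    altv <- rep(NA_integer_, nb)
    depv <- rep(NA_integer_, nb)
    presence[idx] <- rows$called
    altv[idx] <- rows$alt_reads
    depv[idx] <- rows$depth
    out[[length(out) + 1L]] <- data.frame(
      chrom = rows$chrom[1], pos = rows$pos[1], ref = rows$ref[1],
      alt = rows$alt[1],
      patient_id = rows$patient_id[1],
      gene = rows$gene[1], effect = rows$effect[1],
      trinucleotide_context = rows$trinucleotide_context[1],
      presence = I(list(presence)), rescued = I(list(rep(FALSE, nb))),
      alt_reads = I(list(altv)), depth = I(list(depv)),
      clonality = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               patient_id = character(0), gene = character(0),
               effect = character(0),
               trinucleotide_context = character(0),
               presence = I(list()), rescued = I(list()),
               alt_reads = I(list()), depth = I(list()),
               clonality = character(0), stringsAsFactors = FALSE)
  }
  attr(res, "biopsy_order") <- biopsy_order
  rownames(res) <- NULL
  res
}

#' Binomial upper-tail probability of mutant reads arising from error
#'
#' P(X >= alt_reads) for X ~ Binomial(depth, error_rate); the evidence test
#' used by the forced-call rescue.
#'
#' @param alt_reads Observed mutant reads.
#' @param depth Coverage.
#' @param error_rate Per-base error rate.
#' @return Upper-tail probability.
#' @export
binomial_tail_p <- function(alt_reads, depth, error_rate) {
  stats::pbinom(alt_reads - 1, size = depth, prob = error_rate,
                lower.tail = FALSE)
}

#' Forced-call rescue of censored presences
#'
#' When a variant was called in at least one sister biopsy, biopsies where the
#' caller emitted nothing are re-examined: if they carry mutant reads at
#' levels compatible with true presence but below the caller's sensitivity
#' (pseudoheterogeneity), presence is added and flagged as rescued. Biopsies
#' with coverage below \code{min_depth} are left absent and recorded as
#' unevaluable. Rescue never removes a called presence.
#'
#' @param merged One merged-variant row set (data.frame from
#'   \code{\link{merge_patient_variants}}); all rows are processed.
#' @param params A \code{\link{rescue_params}} object.
#' @return The input with updated \code{presence}/\code{rescued} list-columns
#'   and an added \code{unevaluable} list-column.
#' @export
forced_call_rescue <- function(merged, params = rescue_params()) {
  stopifnot(inherits(params, "rescue_params"))
  if (nrow(merged) == 0L) {
    merged$unevaluable <- I(list())
    return(merged)
  }
  uneval <- vector("list", nrow(merged))
  for (i in seq_len(nrow(merged))) {
    presence <- merged$presence[[i]]
    rescued <- merged$rescued[[i]]
    altv <- merged$alt_reads[[i]]
    depv <- merged$depth[[i]]
    un <- rep(FALSE, length(presence))
    if (!any(presence)) {
      warning("forced_call_rescue: variant with no called presence left unchanged",
              call. = FALSE)
      uneval[[i]] <- un
      next
    }
    for (b in which(!presence)) {
      d <- depv[b]
      a <- altv[b]
      if (is.na(d) || d < params$min_depth) {
        un[b] <- TRUE
        next
      }
      if (is.na(a)) a <- 0L
      ok <- a >= params$min_alt_reads &&
        (a / d) >= params$min_vaf &&
        binomial_tail_p(a, d, params$error_rate) <= params$max_binomial_p
      if (ok) {
        presence[b] <- TRUE
        rescued[b] <- TRUE
      }
    }
    merged$presence[[i]] <- presence
    merged$rescued[[i]] <- rescued
    uneval[[i]] <- un
  }
  merged$unevaluable <- I(uneval)
  merged
}

#' Clonality of a presence vector
#'
#' With k the number of biopsies carrying the variant out of n tumor
#' biopsies: CLONAL when k = n >= 2; SUBCLONAL when 1 < k < n; PRIVATE when
#' k = 1 and n >= 2; NONE for the aberrant cases (k = 0, or single-biopsy
#' patients where clonality is unassessable).
#'
#' @param presence Logical vector over the patient's tumor biopsies.
#' @param n_biopsies Number of tumor biopsies; must equal
#'   \code{length(presence)}.
#' @return One of \code{"CLONAL"}, \code{"SUBCLONAL"}, \code{"PRIVATE"},
#'   \code{"NONE"}.
#' @export
classify_clonality <- function(presence, n_biopsies = length(presence)) {
  if (length(presence) == 0L) stop_parse("classify_clonality: empty presence vector")
  if (length(presence) != n_biopsies) {
    stop_parse("classify_clonality: presence length %d != n_biopsies %d",
               length(presence), n_biopsies)
  }
  k <- sum(presence)
  if (k == 0L || n_biopsies == 1L) return("NONE")
  if (k == n_biopsies) return("CLONAL")
  if (k == 1L) return("PRIVATE")
  "SUBCLONAL"
}

#' Classify every merged variant of a patient
#'
#' @param merged Data.frame from \code{\link{merge_patient_variants}} (after
#'   optional \code{\link{forced_call_rescue}}).
#' @return The input with the \code{clonality} column filled.
#' @export
classify_merged <- function(merged) {
  if (nrow(merged) == 0L) return(merged)
  merged$clonality <- vapply(merged$presence, classify_clonality, character(1))
  merged
}

#' Cohort clonality summary
#'
#' Counts and fractions of CLONAL / SUBCLONAL / PRIVATE mutations, overall and
#' per molecular subtype, plus per-patient means. NONE-labelled variants are
#' excluded from the percentage denominator. Percentages are rounded
#' half-away-from-zero to integers.
#'
#' @param merged Data.frame of classified merged variants for the whole
#'   cohort (must carry \code{patient_id} and \code{clonality}).
#' @param patient_subtypes Optional named character vector mapping patient_id
#'   to subtype; when given, per-subtype breakdowns are included.
#' @param n_patients Number of patients for per-patient means (default: number
#'   of distinct patient_ids in \code{merged}).
#' @return A list with \code{counts}, \code{percent}, \code{per_patient_mean},
#'   \code{n_classified}, \code{n_patients} and (optionally)
#'   \code{by_subtype}.
#' @export
clonality_summary <- function(merged, patient_subtypes = NULL,
                              n_patients = NULL) {
  labels <- c("CLONAL", "SUBCLONAL", "PRIVATE")
  if (nrow(merged) == 0L) {
    z <- stats::setNames(rep(0, 3), labels)
    return(list(counts = z, percent = z, per_patient_mean = z,
                n_classified = 0L, n_patients = n_patients %||% 0L))
  }
  if (any(is.na(merged$clonality))) {
    stop_parse("clonality_summary: unclassified variants present")
  }
  np <- n_patients %||% length(unique(merged$patient_id))
  lab <- merged$clonality[merged$clonality != "NONE"]
  counts <- stats::setNames(vapply(labels, function(l) sum(lab == l), numeric(1)),
                            labels)
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * counts / total) else counts * 0
  ppm <- round_half_up(counts / max(np, 1L))
  out <- list(counts = counts, percent = pct, per_patient_mean = ppm,
              n_classified = total, n_patients = np)
  if (!is.null(patient_subtypes)) {
    st <- patient_subtypes[merged$patient_id]
    by <- lapply(unique(stats::na.omit(unname(patient_subtypes))), function(s) {
      sub <- merged[!is.na(st) & st == s, , drop = FALSE]
      clonality_summary(sub, NULL,
                        n_patients = sum(patient_subtypes == s, na.rm = TRUE))
    })
    names(by) <- unique(stats::na.omit(unname(patient_subtypes)))
    out$by_subtype <- by
  }
  out
}
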