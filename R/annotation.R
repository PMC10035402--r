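## Rule-based annotation: likely-pathogenic verdicts, long-gene flags,
## CDS-normalized gene burden, recurrence tables of clonally mutated genes,
## and the druggable-gene summary.

#' Annotation resources
#'
#' Exact-match lookup sets used by \code{\link{classify_pathogenic}} and the
#' summary tables. All sets may be empty; they are supplied by the user (e.g.
#' OncoKB-derived druggable genes, ClinVar pathogenic keys), never downloaded.
#'
#' @param hotspot_set Character vector of known hotspot keys, either
#'   \code{"gene:protein_change"} or \code{"chrom:pos:ref:alt"}.
#' @param clinvar_pathogenic_set Character vector of variant keys
#'   \code{"chrom:pos:ref:alt"} annotated pathogenic in ClinVar.
#' @param oncogene_set Gene symbols of known oncogenes.
#' @param druggable_set Gene symbols of druggable genes (the combined
#'   OncoKB + FDA gastric-therapy list in the study has 58).
#' @param driver_sets Optional named list of driver gene sets.
#' @return List of class \code{annotation_resources}.
#' @export
annotation_resources <- function(hotspot_set = character(0),
                                 clinvar_pathogenic_set = character(0),
                                 oncogene_set = character(0),
                                 druggable_set = character(0),
                                 driver_sets = list()) {
  structure(list(hotspot_set = hotspot_set,
                 clinvar_pathogenic_set = clinvar_pathogenic_set,
                 oncogene_set = oncogene_set,
                 druggable_set = druggable_set,
                 driver_sets = driver_sets),
            class = "annotation_resources")
}

LOF_EFFECTS <- c("nonsense", "frameshift", "splice")

#' Likely-pathogenic classification
#'
#' A change is likely pathogenic when any of five clauses fires:
#' loss-of-function effect (nonsense, frameshift, splice), known cancer
#' hotspot, annotated pathogenic in ClinVar, amplification of a known
#' oncogene, or complete deletion of the gene or its wild-type allele.
#'
#' @param event List or one-row data.frame. For SNVs/indels supply
#'   \code{effect}, optionally \code{gene}, \code{protein_change} and the key
#'   fields \code{chrom, pos, ref, alt}. For CNV events supply \code{gene} and
#'   \code{cnv_call} in \code{c("gain", "loss")}, plus logical
#'   \code{full_gene_deletion} or \code{wt_allele_loss} flags for the
#'   complete-deletion clause (LOH is an upstream call, never inferred here).
#' @param resources An \code{\link{annotation_resources}} object.
#' @return List with \code{is_likely_pathogenic} and \code{reasons} (subset of
#'   LOF, HOTSPOT, CLINVAR, ONCOGENE_AMP, COMPLETE_DELETION).
#' @export
classify_pathogenic <- function(event, resources = annotation_resources()) {
  reasons <- character(0)
  eff <- event$effect %||% NA_character_
  if (!is.na(eff) && eff %in% LOF_EFFECTS) reasons <- c(reasons, "LOF")
  key <- if (!is.null(event$chrom)) {
    paste(event$chrom, event$pos, event$ref, event$alt, sep = ":")
  } else NA_character_
  pkey <- if (!is.null(event$gene) && !is.null(event$protein_change)) {
    paste(event$gene, event$protein_change, sep = ":")
  } else NA_character_
  if ((!is.na(key) && key %in% resources$hotspot_set) ||
      (!is.na(pkey) && pkey %in% resources$hotspot_set)) {
    reasons <- c(reasons, "HOTSPOT")
  }
  if (!is.na(key) && key %in% resources$clinvar_pathogenic_set) {
    reasons <- c(reasons, "CLINVAR")
  }
  cnv_call <- event$cnv_call %||% NA_character_
  gene <- event$gene %||% NA_character_
  if (!is.na(cnv_call) && cnv_call == "gain" && !is.na(gene) &&
      gene %in% resources$oncogene_set) {
    reasons <- c(reasons, "ONCOGENE_AMP")
  }
  if (isTRUE(event$full_gene_deletion) || isTRUE(event$wt_allele_loss)) {
    reasons <- c(reasons, "COMPLETE_DELETION")
  }
  list(is_likely_pathogenic = length(reasons) > 0, reasons = reasons)
}

#' Long-gene threshold and flags
#'
#' The threshold is the 75th percentile of panel gene CDS lengths
#' (type-7 linear interpolation between order statistics); a gene is flagged
#' long when its CDS length is strictly above the threshold.
#'
#' @param gene_cds_kbp Named numeric vector of CDS lengths in kbp (>= 4 genes).
#' @param probs Percentile (default 0.75).
#' @return List with \code{threshold_kbp} and logical named vector
#'   \code{is_long}.
#' @export
long_gene_threshold <- function(gene_cds_kbp, probs = 0.75) {
  if (length(gene_cds_kbp) == 0L) stop_parse("long_gene_threshold: empty mapping")
  if (length(gene_cds_kbp) < 4L) {
    stop_parse("long_gene_threshold: need >= 4 genes, got %d",
               length(gene_cds_kbp))
  }
  thr <- unname(stats::quantile(gene_cds_kbp, probs = probs, type = 7))
  list(threshold_kbp = thr, is_long = gene_cds_kbp > thr)
}

#' CDS-normalized per-gene mutation burden
#'
#' Burden = SNV count summed over biopsies, divided by the gene's CDS length
#' in kbp.
#'
#' @param gene_counts Named numeric vector of per-gene SNV counts.
#' @param gene_cds_kbp Named numeric vector of CDS lengths; must cover every
#'   counted gene.
#' @param include_zero Include panel genes with zero counts at burden 0.
#' @return Named numeric vector of mutations per kbp.
#' @export
normalized_gene_burden <- function(gene_counts, gene_cds_kbp,
                                   include_zero = FALSE) {
  miss <- setdiff(names(gene_counts), names(gene_cds_kbp))
  if (length(miss) > 0L) {
    stop_parse("normalized_gene_burden: no CDS length for gene(s): %s",
               paste(miss, collapse = ", "))
  }
  genes <- if (include_zero) names(gene_cds_kbp) else names(gene_counts)
  counts <- stats::setNames(rep(0, length(genes)), genes)
  counts[names(gene_counts)] <- gene_counts
  counts / gene_cds_kbp[genes]
}

#' Recurrently (clonally) mutated genes
#'
#' Counts, per gene, the number of patients carrying a qualifying nonsilent
#' SNV/indel: a patient counts once per gene regardless of mutation
#' multiplicity; silent effects are excluded; \code{clonal_only} restricts to
#' CLONAL labels; \code{population} restricts patients by MSI status.
#'
#' @param merged Classified merged variants, cohort-wide.
#' @param clonal_only Restrict to clonal mutations (default TRUE).
#' @param min_patients Minimum patients for a gene to be reported (default 2).
#' @param population \code{"all"}, \code{"MSS"} or \code{"MSI"}.
#' @param patient_msi Named character vector patient_id -> "MSI"/"MSS"
#'   (required unless \code{population == "all"}).
#' @return Data.frame \code{gene, n_patients}, sorted by descending count then
#'   gene name.
#' @export
recurrence_table <- function(merged, clonal_only = TRUE, min_patients = 2L,
                             population = c("all", "MSS", "MSI"),
                             patient_msi = NULL) {
  population <- match.arg(population)
  m <- merged
  if (population != "all") {
    if (is.null(patient_msi)) {
      stop_parse("recurrence_table: patient_msi required for population %s",
                 population)
    }
    m <- m[!is.na(patient_msi[m$patient_id]) &
             patient_msi[m$patient_id] == population, , drop = FALSE]
  }
  m <- m[!is.na(m$gene) & !m$effect %in% c("silent"), , drop = FALSE]
  if (clonal_only) m <- m[m$clonality == "CLONAL", , drop = FALSE]
  if (nrow(m) == 0L) return(data.frame(gene = character(0), n_patients = integer(0)))
  pairs <- unique(m[, c("gene", "patient_id")])
  tab <- table(pairs$gene)
  out <- data.frame(gene = names(tab), n_patients = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[out$n_patients >= min_patients, , drop = FALSE]
  out <- out[order(-out$n_patients, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-subtype druggable-gene summary
#'
#' For each molecular subtype: the fraction of patients with at least one
#' CLONAL likely-pathogenic change in a druggable gene.
#'
#' @param merged Classified merged variants with \code{gene}, \code{effect}.
#' @param subtype_by_patient Named character vector patient_id -> subtype.
#' @param resources \code{\link{annotation_resources}} with
#'   \code{druggable_set}.
#' @param extra_events Optional data.frame of clonal CNV events
#'   (\code{patient_id, gene, cnv_call, full_gene_deletion, wt_allele_loss}).
#' @return Data.frame \code{subtype, n_patients, n_with_druggable, percent}
#'   (percent rounded half-away-from-zero).
#' @export
druggable_summary <- function(merged, subtype_by_patient, resources,
                              extra_events = NULL) {
  qual_patients <- character(0)
  if (nrow(merged) > 0) {
    cl <- merged[merged$clonality == "CLONAL" & !is.na(merged$gene) &
                   merged$gene %in% resources$druggable_set, , drop = FALSE]
    if (nrow(cl) > 0) {
      patho <- vapply(seq_len(nrow(cl)), function(i) {
        classify_pathogenic(as.list(cl[i, c("chrom", "pos", "ref", "alt",
                                            "gene", "effect")]),
                            resources)$is_likely_pathogenic
      }, logical(1))
      qual_patients <- unique(cl$patient_id[patho])
    }
  }
  if (!is.null(extra_events) && nrow(extra_events) > 0) {
    ev <- extra_events[extra_events$gene %in% resources$druggable_set, ,
                       drop = FALSE]
    if (nrow(ev) > 0) {
      patho <- vapply(seq_len(nrow(ev)), function(i) {
        classify_pathogenic(as.list(ev[i, ]), resources)$is_likely_pathogenic
      }, logical(1))
      qual_patients <- unique(c(qual_patients, ev$patient_id[patho]))
    }
  }
  sts <- unique(unname(subtype_by_patient))
  rows <- lapply(sts, function(s) {
    ids <- names(subtype_by_patient)[subtype_by_patient == s]
    n_with <- sum(ids %in% qual_patients)
    data.frame(subtype = s, n_patients = length(ids),
               n_with_druggable = n_with,
               percent = round_half_up(100 * n_with / length(ids)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
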