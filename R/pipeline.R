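## End-to-end orchestration: fixed stage order
## merge -> rescue -> classify -> subtype -> phylogeny -> signatures ->
## annotation -> summary. Every output file carries the run seed and the MD5
## of the resolved configuration; a rerun with identical inputs is
## byte-identical.

#' Run configuration
#'
#' Collects input paths and stage parameters for \code{\link{run_all}}.
#' Any parameter left NULL uses the stage default.
#'
#' @param variants Path to the MAF-like variant TSV.
#' @param biopsies Optional path to a biopsy table TSV
#'   (\code{biopsy_id, patient_id}); when absent, biopsy order is derived
#'   from the variant table.
#' @param cnv,msi,ebv Paths to CNV segment, MSI histogram and EBV fraction
#'   TSVs (each optional; missing evidence defaults to zero).
#' @param panel_bed,panel_cds Panel definition paths.
#' @param catalog Signature catalog TSV path.
#' @param cohort_table Optional clinical table path (Table-1 layout).
#' @param rescue \code{\link{rescue_params}}.
#' @param thresholds \code{\link{subtype_thresholds}}.
#' @param sig_cutoff,sig_tol,sig_min_mutations Signature refit parameters.
#' @param seed Integer seed recorded in every output header.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(variants, biopsies = NULL, cnv = NULL, msi = NULL,
                       ebv = NULL, panel_bed = NULL, panel_cds = NULL,
                       catalog = NULL, cohort_table = NULL,
                       rescue = rescue_params(),
                       thresholds = subtype_thresholds(),
                       sig_cutoff = 0.06, sig_tol = 1e-3,
                       sig_min_mutations = 20, seed = 1L) {
  structure(list(variants = variants, biopsies = biopsies, cnv = cnv,
                 msi = msi, ebv = ebv, panel_bed = panel_bed,
                 panel_cds = panel_cds, catalog = catalog,
                 cohort_table = cohort_table, rescue = rescue,
                 thresholds = thresholds, sig_cutoff = sig_cutoff,
                 sig_tol = sig_tol, sig_min_mutations = sig_min_mutations,
                 seed = seed),
            class = "run_config")
}

.write_stage_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.presence_bits <- function(x) paste(as.integer(x), collapse = "")

#' Run the full pipeline
#'
#' Stages run in fixed order: per-patient merge, forced-call rescue,
#' clonality classification, patient subtype assignment, per-patient clonal
#' trees (Newick), clonality-stratified signature refitting grouped by
#' subtype, and the cohort summary. Fails fast on a missing required input.
#'
#' @param config A \code{\link{run_config}}.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the output
#'   paths.
#' @export
run_all <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  req <- c("variants", "panel_bed", "panel_cds", "catalog")
  for (r in req) {
    if (is.null(config[[r]]) || !file.exists(config[[r]])) {
      stop_parse("run_all: required input '%s' missing or not found (%s)",
                 r, config[[r]] %||% "NULL")
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(outdir, "run_config.yaml")
  yaml::write_yaml(.config_for_hash(config), cfg_path)
  cfg_md5 <- unname(tools::md5sum(cfg_path))
  header <- sprintf("# gastroITH seed=%d config_md5=%s", config$seed, cfg_md5)

  variants <- read_variant_table(config$variants, "maf_tsv")
  panel <- read_panel_definition(config$panel_bed, config$panel_cds)
  catalog <- read_signature_catalog(config$catalog)
  biopsy_map <- if (!is.null(config$biopsies)) {
    utils::read.delim(config$biopsies, stringsAsFactors = FALSE)
  } else {
    unique(variants[, c("biopsy_id", "patient_id")])
  }
  cnv <- if (!is.null(config$cnv)) read_cnv_segments(config$cnv) else NULL
  msi <- if (!is.null(config$msi)) read_msi_histograms(config$msi) else NULL
  ebv <- if (!is.null(config$ebv)) read_ebv_fractions(config$ebv) else NULL

  # merge -> rescue -> classify, per patient
  pids <- sort(unique(biopsy_map$patient_id))
  merged_all <- list()
  trees_dir <- file.path(outdir, "trees")
  dir.create(trees_dir, showWarnings = FALSE)
  conflict_rows <- list()
  for (pid in pids) {
    border <- sort(biopsy_map$biopsy_id[biopsy_map$patient_id == pid])
    calls <- variants[variants$patient_id == pid, , drop = FALSE]
    merged <- merge_patient_variants(calls, border)
    merged <- forced_call_rescue(merged, config$rescue)
    merged <- classify_merged(merged)
    merged_all[[pid]] <- merged
    # phylogeny
    patterns <- build_presence_patterns(merged)
    res <- resolve_conflicts(patterns)
    tree <- build_tree(res$kept, border)
    write_newick(tree, file.path(trees_dir, paste0(pid, ".nwk")))
    if (nrow(res$dropped) > 0) {
      conflict_rows[[pid]] <- data.frame(patient_id = pid, res$dropped)
    }
  }
  merged_df <- do.call(rbind, merged_all)

  # subtype assignment
  subtype_rows <- lapply(pids, function(pid) {
    border <- biopsy_map$biopsy_id[biopsy_map$patient_id == pid]
    ebv_f <- if (!is.null(ebv)) ebv$ebv_read_fraction[ebv$patient_id == pid] else 0
    if (length(ebv_f) == 0L) ebv_f <- 0
    msi_s <- if (!is.null(msi) && any(msi$patient_id == pid)) {
      msi_score(msi[msi$patient_id == pid, , drop = FALSE])
    } else 0
    cnv_f <- if (!is.null(cnv)) {
      vapply(border, function(b) {
        cnv_altered_fraction(cnv[cnv$biopsy_id == b, , drop = FALSE], panel)
      }, numeric(1))
    } else 0
    ev <- aggregate_subtype_evidence(ebv_f, msi_s, cnv_f)
    call <- assign_subtype(ev, config$thresholds, patient_id = pid)
    data.frame(patient_id = pid, subtype = call$subtype,
               ebv_read_fraction = ev$ebv_read_fraction,
               msi_score = as.numeric(ev$msi_score),
               cnv_altered_fraction = ev$cnv_altered_fraction,
               stringsAsFactors = FALSE)
  })
  subtypes_df <- do.call(rbind, subtype_rows)
  subtype_map <- stats::setNames(subtypes_df$subtype, subtypes_df$patient_id)

  # signatures, stratified by clonality, grouped by subtype
  sig_df <- stratified_signatures(merged_df, catalog,
                                  patient_groups = subtype_map,
                                  cutoff = config$sig_cutoff,
                                  tol = config$sig_tol,
                                  min_mutations = config$sig_min_mutations)

  # cohort summary
  clon <- clonality_summary(merged_df, patient_subtypes = subtype_map)
  summary_rows <- data.frame(
    key = c("n_patients", "n_classified",
            paste0("count_", names(clon$counts)),
            paste0("percent_", names(clon$percent)),
            paste0("per_patient_mean_", names(clon$per_patient_mean))),
    value = c(clon$n_patients, clon$n_classified, clon$counts, clon$percent,
              clon$per_patient_mean))

  # write bundle
  clon_out <- data.frame(
    chrom = merged_df$chrom, pos = merged_df$pos, ref = merged_df$ref,
    alt = merged_df$alt, patient_id = merged_df$patient_id,
    gene = merged_df$gene, effect = merged_df$effect,
    presence = vapply(merged_df$presence, .presence_bits, character(1)),
    rescued = vapply(merged_df$rescued, .presence_bits, character(1)),
    clonality = merged_df$clonality, stringsAsFactors = FALSE)
  .write_stage_tsv(clon_out, file.path(outdir, "clonality.tsv"), header)
  .write_stage_tsv(subtypes_df, file.path(outdir, "subtypes.tsv"), header)
  .write_stage_tsv(sig_df, file.path(outdir, "signatures.tsv"), header)
  .write_stage_tsv(summary_rows, file.path(outdir, "summary.tsv"), header)
  conflicts <- if (length(conflict_rows)) do.call(rbind, conflict_rows) else
    data.frame(patient_id = character(0), mask = integer(0), count = integer(0))
  .write_stage_tsv(conflicts, file.path(outdir, "conflicts.tsv"), header)

  invisible(list(merged = merged_df, subtypes = subtypes_df,
                 signatures = sig_df, clonality_summary = clon,
                 conflicts = conflicts, outdir = outdir,
                 config_md5 = cfg_md5))
}

.config_for_hash <- function(config) {
  x <- unclass(config)
  x$rescue <- unclass(x$rescue)
  x$thresholds <- unclass(x$thresholds)
  x
}

#' Simulate a cohort and write the input bundle
#'
#' Runs \code{\link{simulate_cohort}} and writes every file the pipeline
#' readers consume: variants (MAF-like TSV), biopsy table, CNV segments, MSI
#' histograms, EBV fractions, panel BED + CDS lengths, signature catalog and
#' the ground-truth table, plus a ready \code{run_config.yaml}.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param outdir Output directory.
#' @return Invisibly, a \code{\link{run_config}} pointing at the files.
#' @export
simulate_command <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config)
  paths <- list(
    variants = file.path(outdir, "variants.tsv"),
    biopsies = file.path(outdir, "biopsies.tsv"),
    cnv = file.path(outdir, "cnv.tsv"),
    msi = file.path(outdir, "msi.tsv"),
    ebv = file.path(outdir, "ebv.tsv"),
    panel_bed = file.path(outdir, "panel.bed"),
    panel_cds = file.path(outdir, "panel_cds.tsv"),
    catalog = file.path(outdir, "catalog.tsv"),
    truth = file.path(outdir, "truth.tsv")
  )
  write_variant_table(sim$variants, paths$variants)
  utils::write.table(sim$biopsies, paths$biopsies, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$cnv, paths$cnv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$msi, paths$msi, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$ebv, paths$ebv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$panel$target_regions, paths$panel_bed, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(gene = names(sim$panel$gene_cds_kbp),
                                cds_kbp = unname(sim$panel$gene_cds_kbp)),
                     paths$panel_cds, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_signature_catalog(config$catalog, paths$catalog)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rc <- run_config(variants = paths$variants, biopsies = paths$biopsies,
                   cnv = paths$cnv, msi = paths$msi, ebv = paths$ebv,
                   panel_bed = paths$panel_bed, panel_cds = paths$panel_cds,
                   catalog = paths$catalog, seed = config$seed)
  yaml::write_yaml(.config_for_hash(rc), file.path(outdir, "run_config.yaml"))
  invisible(rc)
}
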