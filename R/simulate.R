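## Synthetic multiregion cohort generator with known ground truth. Emulates
## the study conditions: 2-6 tumor biopsies per patient, subtype-specific
## mutation burdens and clonal fractions, purity-scaled diploid VAFs with
## binomial read sampling at ~336x mean depth, caller censoring by an
## alt-read threshold, subtype-specific signature mixtures per clonality
## stratum, shifted microsatellite length histograms for MSI patients,
## amplified/deleted CNV segments for CIN patients and elevated EBV read
## fractions for EBV patients.

#' Synthetic panel definition
#'
#' A deterministic stand-in capture panel: \code{n_intervals} targets of
#' \code{interval_bp} bases each on chr1 (3.75 targeted Mbp at the defaults),
#' plus a synthetic gene list with CDS lengths spanning 0.5-12 kbp.
#'
#' @param n_intervals Number of target intervals (default 375).
#' @param interval_bp Interval width (default 10000).
#' @param n_genes Number of panel genes (default 150).
#' @return A panel definition list (same shape as
#'   \code{\link{read_panel_definition}}).
#' @export
synthetic_panel <- function(n_intervals = 375L, interval_bp = 10000L,
                            n_genes = 150L) {
  starts <- (seq_len(n_intervals) - 1L) * 2L * interval_bp
  bed <- data.frame(chrom = "chr1", start = starts, end = starts + interval_bp)
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  # deterministic spread of CDS lengths, right-skewed like a real panel
  cds <- round(0.5 + 11.5 * (seq_len(n_genes) / n_genes)^2, 3)
  list(target_regions = bed,
       target_mbp = sum(bed$end - bed$start) / 1e6,
       gene_cds_kbp = stats::setNames(cds, genes))
}

.default_sig_weights <- function() {
  mss_clonal <- c(SBS1 = 0.30, SBS3 = 0.20, SBS4 = 0.15, SBS5 = 0.25,
                  SBS10b = 0.10)
  mss_nonclonal <- c(SBS3 = 0.15, SBS4 = 0.15, SBS5 = 0.20, SBS6 = 0.15,
                     SBS15 = 0.15, SBS18 = 0.10, SBS24 = 0.10)
  msi_clonal <- c(SBS1 = 0.30, SBS15 = 0.40, SBS26 = 0.30)
  msi_nonclonal <- c(SBS1 = 0.20, SBS4 = 0.15, SBS6 = 0.20, SBS15 = 0.20,
                     SBS21 = 0.15, SBS26 = 0.10)
  list(
    clonal = list(EBV = mss_clonal, MSI = msi_clonal, CIN = mss_clonal,
                  GS = mss_clonal),
    nonclonal = list(EBV = mss_nonclonal, MSI = msi_nonclonal,
                     CIN = mss_nonclonal, GS = mss_nonclonal)
  )
}

#' Simulation configuration
#'
#' Defaults encode the study conditions: subtype mix as observed in the
#' 32-patient cohort, per-subtype mean mutation burdens (MSI 170, EBV 25,
#' CIN 26, GS 22), per-subtype clonal fractions (EBV 0.34, MSI 0.36,
#' CIN 0.27, GS 0.27) with the nonclonal remainder split
#' subclonal:private = 16:52, tumor purity uniform in (0.3, 0.7), mean
#' sequencing depth 336x, per-base error rate 0.001 and a caller that emits a
#' carried variant once it has at least 8 supporting reads.
#'
#' @param n_patients Number of patients (default 32).
#' @param biopsies_per_patient Inclusive range (default c(2, 6)).
#' @param subtype_probs Probabilities over EBV/MSI/CIN/GS (default
#'   2/32, 4/32, 12/32, 14/32).
#' @param burden_per_subtype Mean mutation count per patient per subtype.
#' @param clonal_fraction_per_subtype Probability a mutation is clonal.
#' @param subclonal_private_ratio Two nonnegative numbers giving the
#'   subclonal:private split of the nonclonal remainder (default c(16, 52)).
#' @param purity_range Tumor purity range (default c(0.3, 0.7)).
#' @param mean_depth Mean per-site coverage (default 336).
#' @param error_rate Per-base sequencing error rate (default 0.001).
#' @param caller_min_alt Alt reads needed for the emulated caller to call a
#'   carried variant (default 8).
#' @param vaf_suppression_prob Probability that a carrier biopsy's expected
#'   VAF is suppressed by allele-specific imbalance or heterogeneous
#'   amplification (default 0.15). Suppressed sites are the
#'   pseudoheterogeneity the forced-call rescue targets: mutant reads are
#'   present but often below the caller threshold.
#' @param vaf_suppression_factor Multiplier applied to the expected VAF at
#'   suppressed sites (default 0.1).
#' @param indel_fraction Fraction of mutations simulated as short indels
#'   (default 0.1).
#' @param signature_weights List with \code{clonal}/\code{nonclonal}
#'   per-subtype weight vectors over the catalog (default
#'   \code{.default_sig_weights()}).
#' @param catalog Signature catalog matrix (default
#'   \code{\link{synthetic_signature_catalog}()}).
#' @param msi_n_loci Microsatellite loci simulated per patient (default 100).
#' @param msi_reads_per_locus Reads per histogram (default 100).
#' @param msi_unstable_fraction Fraction of loci shifted in MSI patients
#'   (default 0.2).
#' @param cin_altered_fraction Panel fraction covered by high-|log2| segments
#'   in CIN patients (default 0.4).
#' @param background_altered_fraction Same for non-CIN patients, at low
#'   |log2| (default 0.05).
#' @param ebv_fraction_positive,ebv_fraction_background EBV on-target read
#'   fraction for EBV patients (1e-2) and bleed-through for others (1e-6).
#' @param panel Panel definition (default \code{\link{synthetic_panel}()}).
#' @param seed Integer seed; the generator consumes a single seeded stream.
#' @return List of class \code{simulation_config}.
#' @export
simulation_config <- function(n_patients = 32L,
                              biopsies_per_patient = c(2L, 6L),
                              subtype_probs = c(EBV = 2, MSI = 4, CIN = 12,
                                                GS = 14) / 32,
                              burden_per_subtype = c(EBV = 25, MSI = 170,
                                                     CIN = 26, GS = 22),
                              clonal_fraction_per_subtype = c(EBV = 0.34,
                                                              MSI = 0.36,
                                                              CIN = 0.27,
                                                              GS = 0.27),
                              subclonal_private_ratio = c(16, 52),
                              purity_range = c(0.3, 0.7),
                              mean_depth = 336,
                              error_rate = 0.001,
                              caller_min_alt = 8L,
                              vaf_suppression_prob = 0.15,
                              vaf_suppression_factor = 0.1,
                              indel_fraction = 0.1,
                              signature_weights = .default_sig_weights(),
                              catalog = synthetic_signature_catalog(),
                              msi_n_loci = 100L,
                              msi_reads_per_locus = 100L,
                              msi_unstable_fraction = 0.2,
                              cin_altered_fraction = 0.4,
                              background_altered_fraction = 0.05,
                              ebv_fraction_positive = 1e-2,
                              ebv_fraction_background = 1e-6,
                              panel = synthetic_panel(),
                              seed = 1L) {
  if (n_patients < 1) stop_parse("simulation_config: n_patients must be >= 1")
  if (biopsies_per_patient[1] < 1) {
    stop_parse("simulation_config: zero biopsies requested")
  }
  if (abs(sum(subtype_probs) - 1) > 1e-9) {
    stop_parse("simulation_config: subtype_probs must sum to 1")
  }
  if (purity_range[1] <= 0 || purity_range[2] > 1) {
    stop_parse("simulation_config: purity_range must lie within (0, 1]")
  }
  stopifnot(all(burden_per_subtype > 0), mean_depth > 0, error_rate >= 0,
            caller_min_alt >= 0)
  structure(as.list(environment()), class = "simulation_config")
}

# uniform draw of a biopsy subset for a nonclonal mutation
.draw_subset <- function(n, label) {
  if (label == "PRIVATE" || n == 2L) {
    idx <- sample.int(n, 1L)
    return(list(idx = idx, label = "PRIVATE"))
  }
  sizes <- 2:(n - 1L)
  k <- sizes[sample.int(length(sizes), 1L)]  # avoid sample()'s scalar gotcha
  list(idx = sort(sample.int(n, k)), label = "SUBCLONAL")
}

#' Simulate a multiregion cohort with ground truth
#'
#' Deterministic given \code{config$seed}. Draw order per patient: subtype,
#' biopsy count, per-biopsy purity, mutation count, then per mutation label,
#' carrier subset, context/effect/position, then per-biopsy depth and read
#' draws; MSI, CNV and EBV evidence follow. The emitted variant table has one
#' row per (mutation, biopsy), carrying read counts everywhere so the
#' forced-call rescue has sister-biopsy pileups to inspect; \code{called} is
#' TRUE where the emulated caller emitted the variant (a carrier biopsy with
#' at least \code{caller_min_alt} supporting reads).
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{variants} (per variant-biopsy calls),
#'   \code{truth} (per-variant labels, strata, per-biopsy CCFs),
#'   \code{patients} (patient_id, subtype_true, n_biopsies),
#'   \code{biopsies} (biopsy_id, patient_id, purity),
#'   \code{cnv}, \code{msi}, \code{ebv}, \code{panel}, \code{config}.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  panel <- config$panel
  genes <- names(panel$gene_cds_kbp)
  classes <- context_classes()
  subtypes <- names(config$subtype_probs)
  p_sub <- config$subclonal_private_ratio[1] / sum(config$subclonal_private_ratio)

  patients <- biopsies <- variants <- truth <- cnv <- msi <- ebv <- list()
  vid <- 0L
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", p)
    subtype <- sample(subtypes, 1L, prob = config$subtype_probs)
    nb_range <- config$biopsies_per_patient[1]:config$biopsies_per_patient[2]
    nb <- nb_range[sample.int(length(nb_range), 1L)]
    bids <- sprintf("%s_B%d", pid, seq_len(nb))
    purity <- stats::runif(nb, config$purity_range[1], config$purity_range[2])
    n_mut <- stats::rpois(1L, config$burden_per_subtype[[subtype]])
    patients[[p]] <- data.frame(patient_id = pid, subtype_true = subtype,
                                n_biopsies = nb)
    biopsies[[p]] <- data.frame(biopsy_id = bids, patient_id = pid,
                                purity = purity)
    if (n_mut > 0) {
      pos_pool <- sample(nrow(panel$target_regions), n_mut, replace = TRUE)
      offs <- sample.int(panel$target_regions$end[1] -
                           panel$target_regions$start[1], n_mut, replace = TRUE)
      for (m in seq_len(n_mut)) {
        vid <- vid + 1L
        is_clonal <- stats::runif(1) < config$clonal_fraction_per_subtype[[subtype]]
        if (is_clonal || nb == 1L) {
          idx <- seq_len(nb)    # single-biopsy patients: every mutation fills the set
          label <- "CLONAL"
          stratum <- "clonal"
        } else {
          want <- if (stats::runif(1) < p_sub) "SUBCLONAL" else "PRIVATE"
          ds <- .draw_subset(nb, want)
          idx <- ds$idx
          label <- ds$label
          stratum <- "nonclonal"
        }
        w <- config$signature_weights[[stratum]][[subtype]]
        wfull <- stats::setNames(rep(0, ncol(config$catalog)),
                                 colnames(config$catalog))
        wfull[names(w)] <- w
        probs <- as.vector(config$catalog %*% (wfull / sum(wfull)))
        is_indel <- stats::runif(1) < config$indel_fraction
        gene <- sample(genes, 1L)
        chrom <- panel$target_regions$chrom[pos_pool[m]]
        pos <- panel$target_regions$start[pos_pool[m]] + offs[m]
        if (is_indel) {
          ref <- sample(c("AT", "CG", "TAA"), 1L)
          alt <- substr(ref, 1, 1)
          ctx <- NA_character_
          effect <- sample(c("frameshift", "inframe_indel"), 1L,
                           prob = c(0.7, 0.3))
        } else {
          cls <- classes[sample.int(96L, 1L, prob = probs)]
          ref <- substr(cls, 3, 3)
          alt <- substr(cls, 5, 5)
          ctx <- paste0(substr(cls, 1, 1), ref, substr(cls, 7, 7))
          if (stats::runif(1) < 0.5) {  # purine-strand representation
            ref2 <- unname(REV_COMP[ref])
            alt2 <- unname(REV_COMP[alt])
            ctx <- revcomp(ctx)
            ref <- ref2
            alt <- alt2
          }
          effect <- sample(c("missense", "silent", "nonsense", "splice"), 1L,
                           prob = c(0.45, 0.45, 0.07, 0.03))
        }
        ccf <- rep(0, nb)
        ccf[idx] <- 1
        depth <- pmax(1L, stats::rpois(nb, config$mean_depth))
        vaf <- purity * ccf / 2
        suppressed <- ccf > 0 &
          stats::runif(nb) < config$vaf_suppression_prob
        vaf[suppressed] <- vaf[suppressed] * config$vaf_suppression_factor
        alt_reads <- integer(nb)
        for (b in seq_len(nb)) {
          alt_reads[b] <- if (ccf[b] > 0) {
            stats::rbinom(1L, depth[b], vaf[b])
          } else {
            stats::rbinom(1L, depth[b], config$error_rate)
          }
        }
        called <- ccf > 0 & alt_reads >= config$caller_min_alt
        variants[[vid]] <- data.frame(
          biopsy_id = bids, patient_id = pid, chrom = chrom, pos = pos,
          ref = ref, alt = alt, gene = gene, effect = effect,
          trinucleotide_context = ctx, alt_reads = alt_reads, depth = depth,
          called = called, stringsAsFactors = FALSE)
        truth[[vid]] <- data.frame(
          chrom = chrom, pos = pos, ref = ref, alt = alt, patient_id = pid,
          true_label = label, stratum = stratum,
          true_ccf = paste(ccf, collapse = ","), stringsAsFactors = FALSE)
      }
    }
    # CNV evidence (per biopsy)
    tr <- panel$target_regions
    frac <- if (subtype == "CIN") config$cin_altered_fraction else
      config$background_altered_fraction
    lg2 <- if (subtype == "CIN") sample(c(-1, 0.8, 1), 1L) else
      sample(c(-0.1, 0.1), 1L)
    k <- max(1L, round(frac * nrow(tr)))
    for (b in seq_len(nb)) {
      cnv[[length(cnv) + 1L]] <- data.frame(
        biopsy_id = bids[b], patient_id = pid,
        chrom = tr$chrom[seq_len(k)], start = tr$start[seq_len(k)],
        end = tr$end[seq_len(k)], log2_ratio = lg2, stringsAsFactors = FALSE)
    }
    # MSI evidence (one tumor/normal histogram pair per patient)
    shape <- c(0.1, 0.2, 0.4, 0.2, 0.1)
    n_unstable <- if (subtype == "MSI") {
      round(config$msi_unstable_fraction * config$msi_n_loci)
    } else 0L
    for (l in seq_len(config$msi_n_loci)) {
      normal_lengths <- 13:17
      tumor_lengths <- if (l <= n_unstable) 10:14 else 13:17
      nh <- as.integer(stats::rmultinom(1, config$msi_reads_per_locus, shape))
      th <- as.integer(stats::rmultinom(1, config$msi_reads_per_locus, shape))
      msi[[length(msi) + 1L]] <- data.frame(
        patient_id = pid, locus_id = sprintf("MS%03d", l),
        sample_role = rep(c("normal", "tumor"), each = 5L),
        repeat_length = c(normal_lengths, tumor_lengths),
        read_count = c(nh, th), stringsAsFactors = FALSE)
    }
    # EBV evidence (per biopsy)
    ef <- if (subtype == "EBV") config$ebv_fraction_positive else
      config$ebv_fraction_background
    ebv[[length(ebv) + 1L]] <- data.frame(
      patient_id = pid, biopsy_id = bids,
      ebv_read_fraction = ef * stats::runif(nb, 0.8, 1.2),
      stringsAsFactors = FALSE)
  }
  list(
    variants = do.call(rbind, variants) %||%
      data.frame(),
    truth = do.call(rbind, truth) %||% data.frame(),
    patients = do.call(rbind, patients),
    biopsies = do.call(rbind, biopsies),
    cnv = do.call(rbind, cnv),
    msi = do.call(rbind, msi),
    ebv = do.call(rbind, ebv),
    panel = panel,
    config = config
  )
}

#' Simulate a 96-context spectrum from a signature mixture
#'
#' Multinomial draw of \code{n_mutations} contexts with probabilities equal to
#' the weighted mixture of catalog columns.
#'
#' @param weights Nonnegative vector over catalog columns, summing to 1.
#' @param n_mutations Number of mutations (>= 1).
#' @param catalog 96 x K signature matrix.
#' @param seed Integer seed.
#' @return A \code{spectrum} (see \code{\link{count_contexts}}).
#' @export
simulate_spectrum <- function(weights, n_mutations, catalog, seed = 1L) {
  if (length(weights) != ncol(catalog)) {
    stop_parse("simulate_spectrum: weight vector length %d != catalog columns %d",
               length(weights), ncol(catalog))
  }
  if (n_mutations < 1) stop_parse("simulate_spectrum: n_mutations must be >= 1")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop_parse("simulate_spectrum: weights must be nonnegative and sum to 1")
  }
  set.seed(seed)
  probs <- as.vector(catalog %*% weights)
  counts <- as.integer(stats::rmultinom(1, n_mutations, probs))
  names(counts) <- rownames(catalog)
  structure(list(counts = counts, n_mutations = sum(counts), skipped = 0L),
            class = "spectrum")
}
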