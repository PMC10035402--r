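## 96-context mutation spectra and nonnegative signature refitting against a
## catalog, by iterative forward selection with a reporting cutoff, stratified
## by clonality and by patient grouping.

#' Count the 96-context spectrum of a set of SNVs
#'
#' Bins SNVs into the 96 pyrimidine-centered trinucleotide substitution
#' classes. Records with a purine reference base are reverse-complemented
#' before binning. Non-SNVs (ref or alt longer than one base) and records with
#' missing context are skipped and counted.
#'
#' @param variants Data.frame with columns \code{ref}, \code{alt},
#'   \code{trinucleotide_context} (reference-strand, middle base = ref).
#' @return A list of class \code{spectrum}: \code{counts} (named integer
#'   vector over the 96 classes), \code{n_mutations} (their sum),
#'   \code{skipped}.
#' @export
count_contexts <- function(variants) {
  classes <- context_classes()
  counts <- stats::setNames(rep(0L, 96L), classes)
  if (nrow(variants) == 0L) {
    return(structure(list(counts = counts, n_mutations = 0L, skipped = 0L),
                     class = "spectrum"))
  }
  is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref %in% names(REV_COMP) & variants$alt %in% names(REV_COMP)
  has_ctx <- !is.na(variants$trinucleotide_context) &
    nchar(variants$trinucleotide_context) == 3L
  use <- is_snv & has_ctx
  skipped <- sum(!use)
  if (any(use)) {
    cls <- canonical_context_class(variants$ref[use], variants$alt[use],
                                   variants$trinucleotide_context[use])
    tab <- table(factor(cls, levels = classes))
    counts <- counts + as.integer(tab)
    names(counts) <- classes
  }
  structure(list(counts = counts, n_mutations = sum(counts),
                 skipped = skipped), class = "spectrum")
}

.sse_for <- function(weights, catalog_m, freqs) {
  recon <- as.vector(catalog_m %*% weights)
  s <- sum(recon)
  if (s > 0) recon <- recon / s
  sum((recon - freqs)^2)
}

#' Refit signature weights to a spectrum by forward selection
#'
#' Starting from all-zero weights, each iteration scans every catalog
#' signature, finds the single-weight value in [0, 1] minimizing the
#' sum-of-squared-error between the re-normalized weighted reconstruction and
#' the observed context frequencies (one-dimensional golden-section line
#' search, absolute tolerance 1e-5), and adopts the signature with the
#' largest error decrease. Iteration stops when the best decrease in the
#' reconstruction error (the root of the SSE, the scale on which refitting
#' tools state their stopping threshold) falls below \code{tol}. Weights
#' below \code{cutoff} are then zeroed and the survivors renormalized to sum
#' to 1. Ties in candidate choice are broken by catalog order.
#'
#' @param spectrum A \code{spectrum} from \code{\link{count_contexts}}, or a
#'   plain 96-long count vector.
#' @param catalog 96 x K column-stochastic signature matrix.
#' @param cutoff Minimum reported weight (default 0.06).
#' @param tol Minimum decrease in reconstruction error (root-SSE) to continue
#'   (default 1e-3).
#' @param min_mutations Refuse spectra with fewer mutations than this
#'   (default 20): tiny spectra give unstable fits.
#' @param max_iter Iteration cap (default 100).
#' @return A list of class \code{signature_weights}: \code{weights} (named,
#'   summing to 1 or all zero, each >= cutoff), \code{residual_sse},
#'   \code{n_mutations}.
#' @export
refit_signatures <- function(spectrum, catalog, cutoff = 0.06, tol = 1e-3,
                             min_mutations = 20, max_iter = 100) {
  counts <- if (inherits(spectrum, "spectrum")) spectrum$counts else spectrum
  if (length(counts) != nrow(catalog)) {
    stop_parse("refit_signatures: spectrum length %d does not match catalog rows %d",
               length(counts), nrow(catalog))
  }
  n <- sum(counts)
  if (n < min_mutations) {
    stop_parse("refit_signatures: %d mutations is below the floor of %d",
               n, min_mutations)
  }
  freqs <- counts / n
  K <- ncol(catalog)
  w <- rep(0, K)
  sse <- .sse_for(w, catalog, freqs)
  for (iter in seq_len(max_iter)) {
    best_k <- 0L
    best_t <- 0
    best_sse <- sse
    for (k in seq_len(K)) {
      obj <- function(t) {
        wk <- w
        wk[k] <- t
        .sse_for(wk, catalog, freqs)
      }
      opt <- stats::optimize(obj, interval = c(0, 1), tol = 1e-5)
      # evaluate endpoints too: optimize never returns the exact boundary
      cand <- c(opt$minimum, 0, 1)
      vals <- vapply(cand, obj, numeric(1))
      j <- which.min(vals)
      if (vals[j] < best_sse - 1e-15) {
        best_sse <- vals[j]
        best_k <- k
        best_t <- cand[j]
      }
    }
    if (best_k == 0L || (sqrt(sse) - sqrt(best_sse)) < tol) break
    w[best_k] <- best_t
    stopifnot(best_sse <= sse + 1e-12)  # SSE is non-increasing by construction
    sse <- best_sse
  }
  if (sum(w) > 0) {
    w <- w / sum(w)
    w[w < cutoff] <- 0
    if (sum(w) > 0) w <- w / sum(w)
  }
  names(w) <- colnames(catalog)
  structure(list(weights = w,
                 residual_sse = .sse_for(w, catalog, freqs),
                 n_mutations = n),
            class = "signature_weights")
}

#' Clonality-stratified, group-wise signature refitting
#'
#' Pools the spectra of classified merged variants within each (group,
#' stratum) cell, then refits signature weights per cell. Strata are defined
#' on the clonality label (default: clonal vs nonclonal, i.e. subclonal +
#' private); groups on a per-patient covariate such as subtype or histology.
#' Cells below the mutation floor are reported as insufficient rather than
#' fitted.
#'
#' @param merged Classified merged variants for the cohort (NONE labels are
#'   excluded).
#' @param catalog 96 x K signature matrix.
#' @param patient_groups Named character vector patient_id -> group label, or
#'   NULL for a single group \code{"all"}.
#' @param strata Named list of clonality label sets (default
#'   \code{list(clonal = "CLONAL", nonclonal = c("SUBCLONAL", "PRIVATE"))});
#'   must partition the non-NONE labels.
#' @param cutoff,tol,min_mutations Passed to \code{\link{refit_signatures}}.
#' @return Data.frame with one row per (group, stratum): \code{group},
#'   \code{stratum}, \code{n_mutations}, \code{status}
#'   (\code{"fit"}/\code{"insufficient"}), and one column per signature.
#' @export
stratified_signatures <- function(merged, catalog, patient_groups = NULL,
                                  strata = list(clonal = "CLONAL",
                                                nonclonal = c("SUBCLONAL", "PRIVATE")),
                                  cutoff = 0.06, tol = 1e-3,
                                  min_mutations = 20) {
  all_labels <- sort(unique(unlist(strata)))
  if (anyDuplicated(unlist(strata)) ||
      !all(all_labels %in% setdiff(CLONALITY_LEVELS, "NONE"))) {
    stop_parse("stratified_signatures: strata must partition the non-NONE labels")
  }
  m <- merged[merged$clonality %in% all_labels, , drop = FALSE]
  groups <- if (is.null(patient_groups)) {
    stats::setNames(rep("all", length(unique(m$patient_id))),
                    unique(m$patient_id))
  } else {
    patient_groups
  }
  glabels <- sort(unique(stats::na.omit(unname(groups))))
  rows <- list()
  for (g in glabels) {
    in_g <- !is.na(groups[m$patient_id]) & groups[m$patient_id] == g
    for (s in names(strata)) {
      sub <- m[in_g & m$clonality %in% strata[[s]], , drop = FALSE]
      spec <- count_contexts(sub)
      wrow <- stats::setNames(rep(NA_real_, ncol(catalog)), colnames(catalog))
      status <- "insufficient"
      if (spec$n_mutations >= min_mutations) {
        fit <- refit_signatures(spec, catalog, cutoff = cutoff, tol = tol,
                                min_mutations = min_mutations)
        wrow[] <- fit$weights
        status <- "fit"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, stratum = s, n_mutations = spec$n_mutations,
        status = status, t(wrow), check.names = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
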