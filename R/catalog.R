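## A deterministic SYNTHETIC single-base-substitution signature catalog.
##
## The analysis targets a subset of COSMIC v3.2 SBS signatures relevant to
## gastric cancer (SBS1, 3, 4, 5, 6, 10b, 15, 18, 21, 24, 26). The COSMIC
## probability matrices are licensed reference data and are NOT bundled;
## instead this constructor builds synthetic stand-ins that carry the same
## names and qualitatively similar shapes (e.g. SBS1 peaks at [C>T]G,
## tobacco-like SBS4 loads C>A, MMRd-like signatures load C>T/T>C subsets,
## SBS3 is near-featureless). Swap in the real catalog with
## read_signature_catalog() for production analyses.

.block_index <- function(sub) {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  (match(sub, subs) - 1L) * 16L
}

.peak_set <- function(sub, left = NULL, right = NULL) {
  bases <- c("A", "C", "G", "T")
  idx <- integer(0)
  for (l in seq_len(4)) {
    for (r in seq_len(4)) {
      if ((is.null(left) || bases[l] %in% left) &&
          (is.null(right) || bases[r] %in% right)) {
        idx <- c(idx, .block_index(sub) + (l - 1L) * 4L + r)
      }
    }
  }
  idx
}

#' Synthetic signature catalog (stand-in for a COSMIC subset)
#'
#' Builds a deterministic 96 x 11 column-stochastic matrix with signature
#' names SBS1, SBS3, SBS4, SBS5, SBS6, SBS10b, SBS15, SBS18, SBS21, SBS24,
#' SBS26. Each signature places \code{peak_mass} of its probability on a
#' characteristic context subset and spreads the remainder uniformly. These
#' are synthetic shapes, not the published COSMIC probabilities; use them for
#' simulation and testing, and supply the real catalog TSV for real data.
#'
#' @param peak_mass Probability mass on the characteristic contexts
#'   (default 0.8).
#' @return 96 x 11 matrix with context rownames and signature colnames.
#' @export
synthetic_signature_catalog <- function(peak_mass = 0.8) {
  stopifnot(peak_mass >= 0, peak_mass <= 1)
  peaks <- list(
    SBS1   = .peak_set("C>T", right = "G"),          # deamination at CpG
    SBS3   = seq_len(96),                            # featureless (HRd-like)
    SBS4   = .peak_set("C>A"),                       # tobacco-like
    SBS5   = c(.peak_set("T>C"), .peak_set("C>T")),  # clock-like, broad
    SBS6   = .peak_set("C>T", left = "G"),           # MMRd-like
    SBS10b = .peak_set("C>T", left = "T"),           # POLE-like
    SBS15  = .peak_set("C>T", right = "T"),          # MMRd-like
    SBS18  = .peak_set("C>A", right = "A"),          # ROS-like
    SBS21  = .peak_set("T>C", left = "A"),           # MMRd-like
    SBS24  = .peak_set("C>A", left = "G"),           # aflatoxin-like
    SBS26  = .peak_set("T>C", right = "T")           # MMRd-like
  )
  m <- matrix(0, nrow = 96, ncol = length(peaks),
              dimnames = list(context_classes(), names(peaks)))
  for (k in seq_along(peaks)) {
    col <- rep((1 - peak_mass) / 96, 96)
    col[peaks[[k]]] <- col[peaks[[k]]] + peak_mass / length(peaks[[k]])
    m[, k] <- col / sum(col)
  }
  m
}
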