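#' The 96 trinucleotide substitution classes
#'
#' Pyrimidine-centered single-base-substitution classes in COSMIC
#' lexicographic order: substitutions ordered C>A, C>G, C>T, T>A, T>C, T>G,
#' and within each substitution the 16 flank combinations ordered
#' alphabetically (A, C, G, T on each side). Labels look like \code{"A[C>A]A"}.
#'
#' @return Character vector of length 96.
#' @export
context_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) {
    for (l in bases) {
      for (r in bases) {
        out <- c(out, paste0(l, "[", s, "]", r))
      }
    }
  }
  out
}

REV_COMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(b) paste(rev(unname(REV_COMP[b])), collapse = ""),
         character(1))
}

#' Canonical pyrimidine-centered class of an SNV
#'
#' Maps an SNV (ref, alt, reference-strand trinucleotide context) to its
#' pyrimidine-centered class label. Purine-reference substitutions are
#' reverse-complemented.
#'
#' @param ref,alt Single reference/alternate bases.
#' @param context Length-3 reference-strand context whose middle base must
#'   equal \code{ref}.
#' @return Class label such as \code{"A[C>A]A"}.
#' @export
canonical_context_class <- function(ref, alt, context) {
  stopifnot(length(ref) == length(alt), length(alt) == length(context))
  mid <- substr(context, 2, 2)
  bad <- !is.na(context) & mid != ref
  if (any(bad)) {
    stop_parse("context middle base differs from ref at record(s): %s",
               paste(which(bad), collapse = ", "))
  }
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, unname(REV_COMP[ref]), ref)
  a <- ifelse(flip, unname(REV_COMP[alt]), alt)
  ctx <- context
  ctx[flip] <- revcomp(context[flip])
  paste0(substr(ctx, 1, 1), "[", r, ">", a, "]", substr(ctx, 3, 3))
}
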