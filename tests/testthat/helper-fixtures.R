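# Shared fixtures built in code.

table1_path <- function() {
  system.file("extdata", "cohort_table1.tsv", package = "gastroITH")
}

# Build a classified merged-variant data.frame directly from presence vectors.
# `presences` is a list of logical vectors (one per variant, all same length).
make_merged <- function(presences, patient_id = "P1", gene = NA_character_,
                        effect = "missense", ref = "C", alt = "T",
                        context = "ACA") {
  n <- length(presences)
  df <- data.frame(
    chrom = "chr1", pos = seq_len(n) * 100L, ref = ref, alt = alt,
    patient_id = patient_id,
    gene = gene, effect = effect, trinucleotide_context = context,
    presence = I(presences),
    rescued = I(lapply(presences, function(p) rep(FALSE, length(p)))),
    alt_reads = I(lapply(presences, function(p) ifelse(p, 50L, 0L))),
    depth = I(lapply(presences, function(p) rep(300L, length(p)))),
    clonality = NA_character_, stringsAsFactors = FALSE)
  classify_merged(df)
}

# A tiny MAF-like variant TSV on disk; returns the path.
write_tiny_maf <- function(path = tempfile(fileext = ".tsv")) {
  df <- data.frame(
    biopsy_id = c("B1", "B2", "B1"), patient_id = "P1",
    chrom = "chr1", pos = c(100L, 100L, 200L),
    ref = c("C", "C", "T"), alt = c("T", "T", "G"),
    gene = c("TP53", "TP53", "CDH1"),
    effect = c("missense", "missense", "nonsense"),
    trinucleotide_context = c("ACA", "ACA", "ATG"),
    alt_reads = c(40L, 35L, 20L), depth = c(200L, 180L, 150L),
    called = TRUE, stringsAsFactors = FALSE)
  write_variant_table(df, path)
  path
}

# MSI histogram long data.frame: n_loci loci, of which n_shifted have the
# tumor mass moved down by 3 repeat units; n reads per histogram.
make_msi_loci <- function(n_loci = 100, n_shifted = 0, reads = 200) {
  shape <- c(0.1, 0.2, 0.4, 0.2, 0.1) * reads
  rows <- lapply(seq_len(n_loci), function(l) {
    tumor_lengths <- if (l <= n_shifted) 10:14 else 13:17
    data.frame(locus_id = sprintf("MS%03d", l),
               sample_role = rep(c("normal", "tumor"), each = 5L),
               repeat_length = c(13:17, tumor_lengths),
               read_count = as.integer(c(shape, shape)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
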