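## Readers and writers for every external representation the pipeline touches:
## cohort table (Table-1 layout), variant tables (MAF-like TSV, minimal VCF),
## panel definition (BED + CDS lengths), CNV segments, microsatellite
## histograms, EBV read fractions, signature catalogs, Newick trees.
##
## Coordinate conventions: variants are 1-based (VCF convention); panel BED
## intervals and CNV segments are half-open 0-based (BED convention).

COHORT_COLUMNS <- c("Indiv", "Type", "Hpy", "Ctry", "Eth", "Sex", "Age",
                    "Hist", "Anat", "Stage")

.cohort_maps <- list(
  Type = c(EBV = "EBV", MSI = "MSI", CIN = "CIN", GS = "GS"),
  Hpy  = c(Y = "yes", N = "no"),
  Ctry = c(Col = "Colombia", Mex = "Mexico", USA = "USA"),
  Eth  = c(Lat = "Latino", Wht = "White"),
  Sex  = c(M = "M", F = "F"),
  Hist = c(I = "intestinal", D = "diffuse", M = "mixed")
)

.map_token <- function(value, column, row) {
  if (is.na(value) || value == "NA") return(NA_character_)
  map <- .cohort_maps[[column]]
  if (!value %in% names(map)) {
    stop_parse("cohort table row %d, column %s: unknown token '%s'",
               row, column, value)
  }
  unname(map[value])
}

#' Read a cohort clinical table
#'
#' Reads the 10-column clinical table (patient id, assigned molecular subtype,
#' H. pylori status, country, ethnicity, sex, age, histology, anatomic site,
#' AJCC stage). Cells containing the literal token \code{"NA"}
#' (case-sensitive) become missing; \code{Subtotal}/\code{Total} rows are
#' skipped. Abbreviated tokens (Col/Mex/USA, Lat/Wht, I/D/M, Y/N) are expanded.
#'
#' @param path Path to a TSV file with header
#'   \code{Indiv Type Hpy Ctry Eth Sex Age Hist Anat Stage}.
#' @return A data.frame with one row per patient and columns
#'   \code{patient_id}, \code{subtype_assigned}, \code{hpylori},
#'   \code{country}, \code{ethnicity}, \code{sex}, \code{age},
#'   \code{histology}, \code{anatomic_site}, \code{stage}.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop_parse("cohort table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_parse("cohort table is empty: %s", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header[seq_along(COHORT_COLUMNS)], COHORT_COLUMNS)) {
    stop_parse("cohort table header does not match expected columns (%s)",
               paste(COHORT_COLUMNS, collapse = " "))
  }
  if (length(lines) == 1L) stop_parse("cohort table has no data rows: %s", path)
  rows <- lapply(strsplit(lines[-1], "\t", fixed = TRUE), function(x) {
    length(x) <- length(COHORT_COLUMNS)
    x
  })
  out <- list()
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    id <- r[[1]]
    if (id %in% c("Subtotal", "Total")) next
    age <- r[[7]]
    if (!is.na(age) && age != "NA" && !grepl("^[0-9]+$", age)) {
      stop_parse("cohort table row %d, column Age: not an integer: '%s'", i, age)
    }
    age <- if (is.na(age) || age == "NA") NA_integer_ else as.integer(age)
    if (!is.na(age) && (age < 0 || age > 120)) {
      stop_parse("cohort table row %d: age %d outside [0, 120]", i, age)
    }
    stage <- r[[10]]
    if (is.na(stage) || stage == "NA") stage <- NA_character_
    if (!is.na(stage) && !grepl("^(I|II|III|IV)", stage)) {
      stop_parse("cohort table row %d, column Stage: unknown stage '%s'", i, stage)
    }
    anat <- r[[9]]
    if (is.na(anat) || anat == "NA") anat <- NA_character_
    out[[length(out) + 1L]] <- data.frame(
      patient_id = id,
      subtype_assigned = .map_token(r[[2]], "Type", i),
      hpylori = .map_token(r[[3]], "Hpy", i),
      country = .map_token(r[[4]], "Ctry", i),
      ethnicity = .map_token(r[[5]], "Eth", i),
      sex = .map_token(r[[6]], "Sex", i),
      age = age,
      histology = .map_token(r[[8]], "Hist", i),
      anatomic_site = anat,
      stage = stage,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) stop_parse("cohort table has no patient rows: %s", path)
  res <- do.call(rbind, out)
  if (anyDuplicated(res$patient_id)) {
    stop_parse("duplicate patient_id in cohort table: %s",
               paste(unique(res$patient_id[duplicated(res$patient_id)]),
                     collapse = ", "))
  }
  rownames(res) <- NULL
  res
}

VARIANT_COLUMNS <- c("biopsy_id", "patient_id", "chrom", "pos", "ref", "alt",
                     "gene", "effect", "trinucleotide_context", "alt_reads",
                     "depth", "called")

EFFECT_LEVELS <- c("missense", "nonsense", "frameshift", "splice",
                   "inframe_indel", "silent", "other")

validate_variant_calls <- function(v, what = "variant table") {
  if (nrow(v) == 0L) return(v)
  if (any(is.na(v$pos)) || any(v$pos < 1)) {
    stop_parse("%s: malformed position (must be integer >= 1)", what)
  }
  if (any(v$depth <= 0)) stop_parse("%s: depth must be positive", what)
  if (any(v$alt_reads < 0)) stop_parse("%s: alt_reads must be nonnegative", what)
  if (any(v$alt_reads > v$depth)) {
    stop_parse("%s: alt_reads exceeds depth at row(s) %s", what,
               paste(which(v$alt_reads > v$depth), collapse = ", "))
  }
  if (any(v$ref == v$alt)) stop_parse("%s: ref equals alt", what)
  v
}

#' Read a per-biopsy somatic variant table
#'
#' Two dialects are supported. \code{maf_tsv} is one variant-biopsy row per
#' line with columns \code{chrom, pos, ref, alt, biopsy_id, alt_reads, depth}
#' (required) plus optional \code{patient_id, gene, effect,
#' trinucleotide_context, called}. \code{vcf_minimal} is VCF 4.2 with
#' \code{GT:AD:DP} FORMAT fields, one sample column per biopsy;
#' multi-allelic rows are split into one record per alternate allele, and
#' \code{PATIENT}/\code{GENE}/\code{EFFECT}/\code{CTX} INFO keys are honoured.
#'
#' @param path File path.
#' @param dialect \code{"maf_tsv"} or \code{"vcf_minimal"}.
#' @return A data.frame of variant calls (one row per variant-biopsy) with the
#'   full column set; positions are 1-based.
#' @export
read_variant_table <- function(path, dialect = c("maf_tsv", "vcf_minimal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_parse("variant table not found: %s", path)
  if (dialect == "maf_tsv") .read_variants_maf(path) else .read_variants_vcf(path)
}

.read_variants_maf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  check_columns(df, c("chrom", "pos", "ref", "alt", "biopsy_id",
                      "alt_reads", "depth"), "MAF-like TSV")
  if (any(!grepl("^[0-9]+$", df$pos))) {
    stop_parse("MAF-like TSV: malformed position '%s'",
               df$pos[!grepl("^[0-9]+$", df$pos)][1])
  }
  out <- data.frame(
    biopsy_id = df$biopsy_id,
    patient_id = if ("patient_id" %in% names(df)) df$patient_id else NA_character_,
    chrom = df$chrom,
    pos = as.integer(df$pos),
    ref = df$ref,
    alt = df$alt,
    gene = if ("gene" %in% names(df)) ifelse(df$gene == "NA", NA, df$gene) else NA_character_,
    effect = if ("effect" %in% names(df)) df$effect else "other",
    trinucleotide_context = if ("trinucleotide_context" %in% names(df))
      ifelse(df$trinucleotide_context == "NA", NA, df$trinucleotide_context)
      else NA_character_,
    alt_reads = as.integer(df$alt_reads),
    depth = as.integer(df$depth),
    called = if ("called" %in% names(df)) as.logical(df$called) else TRUE,
    stringsAsFactors = FALSE
  )
  validate_variant_calls(out, "MAF-like TSV")
}

.read_variants_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop_parse("minimal VCF: missing #CHROM header line")
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  if (length(samples) == 0L) stop_parse("minimal VCF: no sample columns")
  body <- lines[seq_along(lines) > hdr]
  body <- body[nzchar(body)]
  recs <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (!grepl("^[0-9]+$", f[2])) stop_parse("minimal VCF: malformed POS '%s'", f[2])
    info <- f[8]
    info_kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    info_map <- stats::setNames(
      vapply(info_kv, function(x) if (length(x) == 2) x[2] else "", character(1)),
      vapply(info_kv, `[`, character(1), 1))
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    for (s in seq_along(samples)) {
      sv <- strsplit(f[9 + s], ":", fixed = TRUE)[[1]]
      if (length(sv) == 1L && sv == ".") next
      gt <- sv[match("GT", fmt)]
      ad <- strsplit(sv[match("AD", fmt)], ",", fixed = TRUE)[[1]]
      dp <- suppressWarnings(as.integer(sv[match("DP", fmt)]))
      if (is.na(dp)) next
      for (ai in seq_along(alts)) {
        altn <- suppressWarnings(as.integer(ad[ai + 1L]))
        if (is.na(altn)) altn <- 0L
        called <- grepl(as.character(ai), gt, fixed = TRUE)
        recs[[length(recs) + 1L]] <- data.frame(
          biopsy_id = samples[s],
          patient_id = unname(info_map["PATIENT"]) %na% NA_character_,
          chrom = f[1], pos = as.integer(f[2]), ref = f[4], alt = alts[ai],
          gene = unname(info_map["GENE"]) %na% NA_character_,
          effect = unname(info_map["EFFECT"]) %na% "other",
          trinucleotide_context = unname(info_map["CTX"]) %na% NA_character_,
          alt_reads = altn, depth = dp, called = called,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(VARIANT_COLUMNS))),
                    VARIANT_COLUMNS)
  validate_variant_calls(out, "minimal VCF")
}

`%na%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Write a variant table in the MAF-like TSV dialect
#'
#' Inverse of \code{read_variant_table(dialect = "maf_tsv")}: writing then
#' re-reading reproduces the records field by field.
#'
#' @param variants Data.frame of variant calls.
#' @param path Output path.
#' @export
write_variant_table <- function(variants, path) {
  v <- variants[, VARIANT_COLUMNS]
  utils::write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a panel definition
#'
#' @param bed_path BED file of capture target intervals (half-open 0-based).
#' @param cds_path Two-column TSV \code{gene<TAB>cds_kbp} of coding-sequence
#'   lengths in kilobases.
#' @return A list with \code{target_regions} (data.frame chrom/start/end),
#'   \code{target_mbp} (total targeted megabases) and \code{gene_cds_kbp}
#'   (named numeric vector).
#' @export
read_panel_definition <- function(bed_path, cds_path) {
  bed <- utils::read.table(bed_path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end"))
  if (any(bed$end < bed$start)) stop_parse("panel BED: interval with end < start")
  cds <- utils::read.delim(cds_path, stringsAsFactors = FALSE)
  check_columns(cds, c("gene", "cds_kbp"), "CDS length table")
  if (any(cds$cds_kbp <= 0)) stop_parse("CDS length table: nonpositive length")
  panel <- list(
    target_regions = bed,
    target_mbp = sum(bed$end - bed$start) / 1e6,
    gene_cds_kbp = stats::setNames(as.numeric(cds$cds_kbp), cds$gene)
  )
  if (panel$target_mbp <= 0) stop_parse("panel BED: zero targeted bases")
  panel
}

#' Read CNV segments
#'
#' @param path TSV with columns \code{biopsy_id, chrom, start, end,
#'   log2_ratio} (half-open 0-based coordinates).
#' @return Data.frame of segments.
#' @export
read_cnv_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("biopsy_id", "chrom", "start", "end", "log2_ratio"),
                "CNV segment table")
  if (any(df$end <= df$start)) stop_parse("CNV segment with end <= start")
  df
}

#' Read microsatellite locus read-length histograms
#'
#' @param path Long TSV with columns \code{locus_id, sample_role,
#'   repeat_length, read_count} and optionally \code{patient_id};
#'   \code{sample_role} is \code{tumor} or \code{normal}.
#' @return Data.frame in long format.
#' @export
read_msi_histograms <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("locus_id", "sample_role", "repeat_length", "read_count"),
                "MSI histogram table")
  if (!all(df$sample_role %in% c("tumor", "normal"))) {
    stop_parse("MSI histogram table: sample_role must be tumor/normal")
  }
  if (any(df$read_count < 0)) stop_parse("MSI histogram table: negative count")
  df
}

#' Read per-patient EBV on-target read fractions
#'
#' @param path TSV with columns \code{patient_id, biopsy_id,
#'   ebv_read_fraction}.
#' @return Data.frame.
#' @export
read_ebv_fractions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("patient_id", "biopsy_id", "ebv_read_fraction"),
                "EBV fraction table")
  if (any(df$ebv_read_fraction < 0 | df$ebv_read_fraction > 1)) {
    stop_parse("EBV fraction outside [0, 1]")
  }
  df
}

#' Read a single-base-substitution signature catalog
#'
#' @param path TSV whose first column (\code{context}) lists the 96 classes in
#'   COSMIC lexicographic order and whose remaining columns are
#'   column-stochastic signature probability vectors.
#' @return A numeric 96 x K matrix with context rownames and signature
#'   colnames.
#' @export
read_signature_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, "context", "signature catalog")
  if (!identical(df$context, context_classes())) {
    stop_parse("signature catalog rows must be the 96 contexts in COSMIC lexicographic order")
  }
  m <- as.matrix(df[, setdiff(names(df), "context"), drop = FALSE])
  rownames(m) <- df$context
  if (any(m < 0)) stop_parse("signature catalog: negative entry")
  sums <- colSums(m)
  if (any(abs(sums - 1) > 1e-6)) {
    stop_parse("signature catalog: column(s) not summing to 1: %s",
               paste(colnames(m)[abs(sums - 1) > 1e-6], collapse = ", "))
  }
  m
}

#' Write a signature catalog TSV
#' @param catalog 96 x K matrix with context rownames.
#' @param path Output path.
#' @export
write_signature_catalog <- function(catalog, path) {
  df <- data.frame(context = rownames(catalog), catalog, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a clonal tree to Newick
#'
#' Branch lengths are mutation counts; leaf names are biopsy ids; the trunk
#' (full-presence) edge is written as the root branch length. The string is
#' terminated by \code{";"}.
#'
#' @param tree A \code{clonal_tree} from \code{\link{build_tree}}.
#' @param path Output file path.
#' @return The Newick string, invisibly.
#' @export
write_newick <- function(tree, path) {
  s <- format_newick(tree)
  writeLines(s, path)
  invisible(s)
}
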