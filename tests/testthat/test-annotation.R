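test_that("likely-pathogenic verdicts follow the five-clause disjunction", {
  res <- annotation_resources(
    hotspot_set = c("KRAS:G12D"),
    clinvar_pathogenic_set = c("chr17:7675088:C:T"),
    oncogene_set = c("ERBB2"))
  v <- classify_pathogenic(list(effect = "nonsense"), res)
  expect_true(v$is_likely_pathogenic)
  expect_equal(v$reasons, "LOF")
  v <- classify_pathogenic(list(effect = "missense", gene = "KRAS",
                                protein_change = "G12D"), res)
  expect_equal(v$reasons, "HOTSPOT")
  v <- classify_pathogenic(list(effect = "missense", chrom = "chr17",
                                pos = 7675088, ref = "C", alt = "T"), res)
  expect_equal(v$reasons, "CLINVAR")
  v <- classify_pathogenic(list(gene = "ERBB2", cnv_call = "gain"), res)
  expect_equal(v$reasons, "ONCOGENE_AMP")
  v <- classify_pathogenic(list(gene = "X", cnv_call = "loss",
                                full_gene_deletion = TRUE), res)
  expect_equal(v$reasons, "COMPLETE_DELETION")
  v <- classify_pathogenic(list(effect = "missense", gene = "NOPE"), res)
  expect_false(v$is_likely_pathogenic)
  expect_equal(length(v$reasons), 0)
})

test_that("verdict equals the brute-force disjunction over all clause settings", {
  # rule-table oracle: construct events firing each subset of the 5 clauses
  res <- annotation_resources(hotspot_set = "G:p", clinvar_pathogenic_set = "c:1:A:T",
                              oncogene_set = "ONC")
  for (bits in 0:31) {
    on <- as.logical(bitwAnd(bits, 2^(0:4)))
    ev <- list(
      effect = if (on[1]) "frameshift" else "missense",
      gene = if (on[2]) "G" else if (on[4]) "ONC" else "ZZZ",
      protein_change = if (on[2]) "p" else "q",
      chrom = if (on[3]) "c" else "x", pos = 1, ref = "A", alt = "T",
      cnv_call = if (on[4]) "gain" else NA_character_,
      full_gene_deletion = on[5])
    # firing HOTSPOT requires gene G; ONCOGENE_AMP requires gene ONC; the two
    # clauses cannot fire together in one event, so skip that combination
    if (on[2] && on[4]) next
    v <- classify_pathogenic(ev, res)
    expect_equal(v$is_likely_pathogenic, any(on), info = paste("bits", bits))
    expect_setequal(v$reasons,
                    c("LOF", "HOTSPOT", "CLINVAR", "ONCOGENE_AMP",
                      "COMPLETE_DELETION")[on])
  }
})

test_that("long-gene threshold interpolates the 75th percentile", {
  lg <- long_gene_threshold(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(lg$threshold_kbp, 3.25)
  expect_equal(unname(lg$is_long), c(FALSE, FALSE, FALSE, TRUE))
  # equal lengths: nothing strictly above
  eq <- long_gene_threshold(c(a = 2, b = 2, c = 2, d = 2))
  expect_false(any(eq$is_long))
  # permutation invariance
  x <- c(a = 5, b = 1, c = 9, d = 3, e = 7)
  expect_equal(long_gene_threshold(x)$threshold_kbp,
               long_gene_threshold(rev(x))$threshold_kbp)
  expect_error(long_gene_threshold(c(a = 1)), ">= 4 genes")
  expect_error(long_gene_threshold(numeric(0)), "empty")
})

test_that("gene burden normalizes by CDS length", {
  cds <- c(TP53 = 1.5, MUC16 = 3)
  expect_equal(unname(normalized_gene_burden(c(MUC16 = 12), cds)), 4)
  b <- normalized_gene_burden(c(MUC16 = 12), cds, include_zero = TRUE)
  expect_equal(unname(b["TP53"]), 0)
  expect_error(normalized_gene_burden(c(NOPE = 2), cds), "NOPE")
})

test_that("recurrence tables count each patient once per gene", {
  presences <- replicate(6, c(TRUE, TRUE), simplify = FALSE)
  m <- make_merged(presences, patient_id = "P1", gene = "TP53")
  m$patient_id <- c("P1", "P1", "P2", "P3", "P4", "P5")
  m$gene <- c("TP53", "TP53", "TP53", "TP53", "APC", "APC")
  m$clonality <- c("CLONAL", "CLONAL", "CLONAL", "SUBCLONAL", "CLONAL", "CLONAL")
  msi <- c(P1 = "MSS", P2 = "MSS", P3 = "MSS", P4 = "MSS", P5 = "MSI")
  tab <- recurrence_table(m, clonal_only = TRUE, min_patients = 2,
                          population = "all")
  # P1 has two clonal TP53 mutations but counts once; P3 is subclonal-only
  expect_equal(tab$n_patients[tab$gene == "TP53"], 2)
  expect_equal(tab$n_patients[tab$gene == "APC"], 2)
  mss <- recurrence_table(m, clonal_only = TRUE, min_patients = 1,
                          population = "MSS", patient_msi = msi)
  expect_equal(mss$n_patients[mss$gene == "APC"], 1)
  # silent mutations never count
  m$effect <- "silent"
  expect_equal(nrow(recurrence_table(m, min_patients = 1)), 0)
})

test_that("removing a patient never increases a recurrence count", {
  set.seed(8)
  presences <- replicate(40, c(TRUE, TRUE), simplify = FALSE)
  m <- make_merged(presences, gene = "X")
  m$patient_id <- sample(sprintf("P%d", 1:8), 40, replace = TRUE)
  m$gene <- sample(c("A", "B", "C"), 40, replace = TRUE)
  full <- recurrence_table(m, min_patients = 1)
  drop <- recurrence_table(m[m$patient_id != "P1", ], min_patients = 1)
  for (g in drop$gene) {
    expect_lte(drop$n_patients[drop$gene == g],
               full$n_patients[full$gene == g])
  }
})

test_that("druggable summary fractions count qualifying patients per subtype", {
  res <- annotation_resources(druggable_set = c("ERBB2", "PIK3CA"))
  presences <- replicate(4, c(TRUE, TRUE), simplify = FALSE)
  m <- make_merged(presences, gene = "ERBB2", effect = "nonsense")
  m$patient_id <- c("M1", "M2", "C1", "C2")
  m$clonality <- c("CLONAL", "CLONAL", "CLONAL", "SUBCLONAL")
  m$effect <- c("nonsense", "frameshift", "missense", "nonsense")
  subtype <- c(M1 = "MSI", M2 = "MSI", C1 = "CIN", C2 = "CIN", C3 = "CIN")
  tab <- druggable_summary(m, subtype, res)
  expect_equal(tab$percent[tab$subtype == "MSI"], 100)
  # C1 clonal but missense (no clause), C2 LOF but subclonal, C3 nothing
  expect_equal(tab$percent[tab$subtype == "CIN"], 0)
  # 5 of 12 rounds to 42, the printed convention
  expect_equal(round_half_up(100 * 5 / 12), 42)
})
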