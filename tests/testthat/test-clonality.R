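test_that("clonality labels match the definition on hand cases", {
  expect_equal(classify_clonality(c(TRUE, TRUE, TRUE)), "CLONAL")
  expect_equal(classify_clonality(c(TRUE, FALSE, FALSE, FALSE)), "PRIVATE")
  expect_equal(classify_clonality(c(TRUE, TRUE, FALSE)), "SUBCLONAL")
  expect_equal(classify_clonality(c(FALSE, FALSE)), "NONE")
  expect_equal(classify_clonality(TRUE, 1), "NONE")  # unassessable
  expect_error(classify_clonality(logical(0)), "empty")
})

test_that("clonality classifier agrees with exhaustive enumeration, n <= 6", {
  # independent oracle: count carriers and apply the definition literally
  oracle <- function(presence) {
    n <- length(presence)
    k <- sum(presence)
    if (n == 1L || k == 0L) return("NONE")
    if (k == n) return("CLONAL")
    if (k == 1L) return("PRIVATE")
    "SUBCLONAL"
  }
  for (n in 1:6) {
    for (code in 0:(2^n - 1)) {
      presence <- as.logical(bitwAnd(code, 2^(seq_len(n) - 1L)))
      expect_equal(classify_clonality(presence, n), oracle(presence),
                   info = sprintf("n=%d code=%d", n, code))
    }
  }
})

test_that("merging collapses to one record per variant key", {
  calls <- data.frame(
    biopsy_id = c("B1", "B2", "B1", "B1"), patient_id = "P1",
    chrom = "chr1", pos = c(100L, 100L, 100L, 100L),
    ref = "C", alt = c("T", "T", "G", "T"),
    gene = "TP53", effect = "missense", trinucleotide_context = "ACA",
    alt_reads = c(40L, 30L, 10L, 40L), depth = 200L, called = TRUE,
    stringsAsFactors = FALSE)
  expect_warning(
    m <- merge_patient_variants(calls, c("B1", "B2", "B3")),
    "duplicate")
  expect_equal(nrow(m), 2)  # C>T and C>G are distinct keys
  ct <- m[m$alt == "T", ]
  expect_equal(ct$presence[[1]], c(TRUE, TRUE, FALSE))
  expect_equal(ct$alt_reads[[1]], c(40L, 30L, NA))
  expect_error(merge_patient_variants(calls, c("B1")), "biopsy_order")
})

test_that("forced-call rescue applies the binomial evidence gate", {
  presences <- list(c(TRUE, FALSE))
  m <- make_merged(presences)
  # absent biopsy with 4/200 reads: binomial tail at error 0.001 well below 0.01
  m$alt_reads[[1]] <- c(50L, 4L)
  m$depth[[1]] <- c(200L, 200L)
  expect_equal(binomial_tail_p(4, 200, 0.001),
               pbinom(3, 200, 0.001, lower.tail = FALSE))
  r <- forced_call_rescue(m)
  expect_true(r$presence[[1]][2])
  expect_true(r$rescued[[1]][2])
  # 1 alt read fails min_alt_reads
  m$alt_reads[[1]] <- c(50L, 1L)
  m$depth[[1]] <- c(200L, 300L)
  r <- forced_call_rescue(m)
  expect_false(r$presence[[1]][2])
  # low depth -> unevaluable, untouched
  m$alt_reads[[1]] <- c(50L, 4L)
  m$depth[[1]] <- c(200L, 10L)
  r <- forced_call_rescue(m)
  expect_false(r$presence[[1]][2])
  expect_true(r$unevaluable[[1]][2])
  # no called presence anywhere -> warning, unchanged
  m2 <- make_merged(list(c(FALSE, FALSE)))
  expect_warning(forced_call_rescue(m2), "no called presence")
})

test_that("rescue is monotone in its thresholds and never drops calls", {
  set.seed(42)
  base <- rescue_params()
  stricter <- rescue_params(min_alt_reads = 6, max_binomial_p = 1e-4)
  for (i in 1:50) {
    nb <- sample(2:5, 1)
    presence <- rep(FALSE, nb)
    presence[sample(nb, 1)] <- TRUE
    m <- make_merged(list(presence))
    m$alt_reads[[1]] <- ifelse(presence, 60L, sample(0:8, nb, replace = TRUE))
    m$depth[[1]] <- sample(c(10L, 50L, 200L, 400L), nb, replace = TRUE)
    r1 <- forced_call_rescue(m, base)$presence[[1]]
    r2 <- forced_call_rescue(m, stricter)$presence[[1]]
    expect_true(all(r1[presence]), info = "called presences retained")
    expect_true(all(r2 <= r1), info = "stricter params never add presences")
  }
})

test_that("rescue recovers censored truth-clonal labels on synthetic cohorts", {
  cfg <- simulation_config(n_patients = 20, seed = 11)
  sim <- simulate_cohort(cfg)
  classify_all <- function(use_rescue) {
    out <- list()
    for (pid in sim$patients$patient_id) {
      border <- sim$biopsies$biopsy_id[sim$biopsies$patient_id == pid]
      m <- merge_patient_variants(
        sim$variants[sim$variants$patient_id == pid, ], border)
      if (use_rescue) m <- forced_call_rescue(m)
      out[[pid]] <- classify_merged(m)
    }
    do.call(rbind, out)
  }
  with_rescue <- suppressWarnings(classify_all(TRUE))
  without <- suppressWarnings(classify_all(FALSE))
  key <- function(m) paste(m$chrom, m$pos, m$ref, m$alt, m$patient_id)
  tkey <- key(sim$truth)
  truth_of <- function(m) sim$truth$true_label[match(key(m), tkey)]
  clonal_recall <- function(m) {
    tl <- truth_of(m)
    mean(m$clonality[tl == "CLONAL"] == "CLONAL")
  }
  expect_gt(clonal_recall(with_rescue), clonal_recall(without))
  # in an error-free simulation rescue never promotes a truth-private
  # variant to clonal
  cfg0 <- simulation_config(n_patients = 10, error_rate = 0, seed = 12)
  sim0 <- simulate_cohort(cfg0)
  out <- list()
  for (pid in sim0$patients$patient_id) {
    border <- sim0$biopsies$biopsy_id[sim0$biopsies$patient_id == pid]
    m <- merge_patient_variants(
      sim0$variants[sim0$variants$patient_id == pid, ], border)
    out[[pid]] <- classify_merged(suppressWarnings(forced_call_rescue(m)))
  }
  m0 <- do.call(rbind, out)
  tkey0 <- paste(sim0$truth$chrom, sim0$truth$pos, sim0$truth$ref,
                 sim0$truth$alt, sim0$truth$patient_id)
  tl0 <- sim0$truth$true_label[match(
    paste(m0$chrom, m0$pos, m0$ref, m0$alt, m0$patient_id), tkey0)]
  expect_false(any(tl0 == "PRIVATE" & m0$clonality == "CLONAL"))
})

test_that("cohort summary reproduces fractions, means and rounding", {
  # 428 clonal / 213 subclonal / 685 private of 1,326 over 32 patients
  labels <- rep(c("CLONAL", "SUBCLONAL", "PRIVATE"), c(428, 213, 685))
  merged <- data.frame(patient_id = rep(sprintf("P%02d", 1:32), length.out = 1326),
                       clonality = labels, stringsAsFactors = FALSE)
  s <- clonality_summary(merged, n_patients = 32)
  expect_equal(unname(s$percent), c(32, 16, 52))
  expect_equal(unname(s$per_patient_mean), c(13, 7, 21))
  # empty cohort: zeros, not an error
  empty <- clonality_summary(merged[0, ], n_patients = 0)
  expect_equal(unname(empty$counts), c(0, 0, 0))
  expect_equal(unname(empty$percent), c(0, 0, 0))
})

test_that("NONE labels are excluded from the percentage denominator", {
  m <- make_merged(list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, FALSE)))
  s <- clonality_summary(m)
  expect_equal(s$n_classified, 2)
  expect_equal(unname(s$percent), c(50, 0, 50))
})
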