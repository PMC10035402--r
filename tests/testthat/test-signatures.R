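test_that("context counting bins on the pyrimidine strand", {
  v <- data.frame(ref = c("C", "G", "A"), alt = c("A", "T", "G"),
                  trinucleotide_context = c("ACA", "TGT", "CAG"),
                  stringsAsFactors = FALSE)
  sp <- count_contexts(v)
  # C>A at ACA stays; G>T at TGT reverse-complements to A[C>A]A too
  expect_equal(unname(sp$counts["A[C>A]A"]), 2)
  # A>G at CAG reverse-complements to C[T>C]G
  expect_equal(unname(sp$counts["C[T>C]G"]), 1)
  expect_equal(sp$n_mutations, 3)
  expect_equal(sp$skipped, 0)
})

test_that("context counting skips non-SNVs and conserves totals", {
  v <- data.frame(ref = c("C", "AT", "C", "C"), alt = c("T", "A", "G", "A"),
                  trinucleotide_context = c("ACG", NA, "TCT", NA),
                  stringsAsFactors = FALSE)
  sp <- count_contexts(v)
  expect_equal(sp$n_mutations + sp$skipped, 4)
  expect_equal(sp$skipped, 2)  # the indel and the missing-context SNV
  # context inconsistent with ref is a validation error
  bad <- data.frame(ref = "C", alt = "T", trinucleotide_context = "ATA")
  expect_error(count_contexts(bad), "middle base")
})

test_that("refitting an exact catalog column returns weight 1 and zero residual", {
  cat_m <- synthetic_signature_catalog()
  spectrum <- round(cat_m[, "SBS4"] * 1e6)
  fit <- refit_signatures(spectrum, cat_m)
  expect_equal(unname(fit$weights["SBS4"]), 1, tolerance = 1e-6)
  expect_lt(fit$residual_sse, 1e-9)
})

test_that("refitting recovers simulated mixtures within tolerance", {
  cat_m <- synthetic_signature_catalog()
  w <- setNames(rep(0, ncol(cat_m)), colnames(cat_m))
  w[c("SBS1", "SBS18")] <- c(0.7, 0.3)
  sp <- simulate_spectrum(w, 10000, cat_m, seed = 2)
  fit <- refit_signatures(sp, cat_m)
  expect_lt(abs(fit$weights["SBS1"] - 0.7), 0.03)
  expect_lt(abs(fit$weights["SBS18"] - 0.3), 0.03)
  # components below the 6% cutoff are absorbed: single signature at 1.0
  w2 <- setNames(rep(0, ncol(cat_m)), colnames(cat_m))
  w2[c("SBS1", "SBS24")] <- c(0.97, 0.03)
  sp2 <- simulate_spectrum(w2, 10000, cat_m, seed = 3)
  fit2 <- refit_signatures(sp2, cat_m)
  expect_equal(unname(fit2$weights["SBS1"]), 1)
  expect_equal(sum(fit2$weights > 0), 1)
})

test_that("asymptotic consistency on noiseless three-signature mixtures", {
  cat_m <- synthetic_signature_catalog()
  w <- setNames(rep(0, ncol(cat_m)), colnames(cat_m))
  w[c("SBS1", "SBS4", "SBS26")] <- c(0.5, 0.3, 0.2)
  mix <- as.vector(cat_m %*% w)
  spectrum <- round(mix * 1e5)
  fit <- refit_signatures(spectrum, cat_m)
  expect_true(all(abs(fit$weights[c("SBS1", "SBS4", "SBS26")] -
                        c(0.5, 0.3, 0.2)) < 0.02))
})

test_that("reported weights respect the cutoff and normalization invariants", {
  cat_m <- synthetic_signature_catalog()
  set.seed(4)
  for (i in 1:5) {
    k <- sample(2:4, 1)
    sigs <- sample(colnames(cat_m), k)
    raw <- stats::runif(k)
    w <- setNames(rep(0, ncol(cat_m)), colnames(cat_m))
    w[sigs] <- raw / sum(raw)
    sp <- simulate_spectrum(w, 5000, cat_m, seed = 100 + i)
    fit <- refit_signatures(sp, cat_m)
    nz <- fit$weights[fit$weights > 0]
    expect_equal(sum(nz), 1, tolerance = 1e-9)
    expect_true(all(nz >= 0.06))
  }
})

test_that("refit refuses tiny spectra and mismatched catalogs", {
  cat_m <- synthetic_signature_catalog()
  expect_error(refit_signatures(round(cat_m[, 1] * 10), cat_m), "below the floor")
  expect_error(refit_signatures(rep(1, 95), cat_m), "does not match")
})

test_that("stratified refitting recovers distinct clonal vs nonclonal mixtures", {
  cat_m <- synthetic_signature_catalog()
  w_clonal <- setNames(rep(0, ncol(cat_m)), colnames(cat_m))
  w_clonal[c("SBS1", "SBS5")] <- c(0.6, 0.4)
  w_non <- setNames(rep(0, ncol(cat_m)), colnames(cat_m))
  w_non[c("SBS4", "SBS15")] <- c(0.5, 0.5)
  sp_c <- simulate_spectrum(w_clonal, 6000, cat_m, seed = 5)
  sp_n <- simulate_spectrum(w_non, 6000, cat_m, seed = 6)
  make_rows <- function(spec, presence) {
    idx <- rep(seq_len(96), spec$counts)
    cls <- context_classes()[idx]
    data.frame(
      chrom = "chr1", pos = seq_along(idx), patient_id = "P1",
      ref = substr(cls, 3, 3), alt = substr(cls, 5, 5),
      gene = NA_character_, effect = "missense",
      trinucleotide_context = paste0(substr(cls, 1, 1), substr(cls, 3, 3),
                                     substr(cls, 7, 7)),
      presence = I(replicate(length(idx), presence, simplify = FALSE)),
      rescued = I(replicate(length(idx), rep(FALSE, 3), simplify = FALSE)),
      alt_reads = I(replicate(length(idx), c(50L, 50L, 50L), simplify = FALSE)),
      depth = I(replicate(length(idx), rep(300L, 3), simplify = FALSE)),
      clonality = NA_character_, stringsAsFactors = FALSE)
  }
  merged <- classify_merged(rbind(make_rows(sp_c, c(TRUE, TRUE, TRUE)),
                                  make_rows(sp_n, c(TRUE, FALSE, FALSE))))
  tab <- stratified_signatures(merged, cat_m)
  cl <- tab[tab$stratum == "clonal", ]
  nc <- tab[tab$stratum == "nonclonal", ]
  expect_equal(cl$status, "fit")
  expect_lt(abs(cl$SBS1 - 0.6), 0.05)
  expect_lt(abs(cl$SBS5 - 0.4), 0.05)
  expect_lt(abs(nc$SBS4 - 0.5), 0.05)
  expect_lt(abs(nc$SBS15 - 0.5), 0.05)
})

test_that("strata below the mutation floor are marked insufficient", {
  m <- make_merged(replicate(30, c(TRUE, TRUE), simplify = FALSE),
                   ref = "C", alt = "T", context = "ACG")
  tab <- stratified_signatures(m, synthetic_signature_catalog())
  expect_equal(tab$status[tab$stratum == "clonal"], "fit")
  expect_equal(tab$status[tab$stratum == "nonclonal"], "insufficient")
  expect_equal(tab$n_mutations[tab$stratum == "nonclonal"], 0)
})
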