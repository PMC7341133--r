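test_that("classify_fixation covers the fixed/unfixed/absent cases", {
  fixed <- classify_fixation(c(S = 110L), "A", 1.0)
  expect_identical(fixed$status, "fixed")
  expect_identical(fixed$residue, "S")
  expect_true(fixed$derived)

  unfixed <- classify_fixation(c(A = 8L, S = 5L), "A", 1.0)
  expect_identical(unfixed$status, "unfixed")

  allanc <- classify_fixation(c(A = 12L), "A", 1.0)
  expect_identical(allanc$status, "fixed")
  expect_false(allanc$derived)

  absent <- classify_fixation(integer(0), "A", 1.0)
  expect_identical(absent$status, "absent")
  expect_error(classify_fixation(c(A = 1L), "A", 0.4), "threshold")
})

test_that("the set of fixed clades shrinks monotonically as threshold rises", {
  set.seed(41)
  spectra <- lapply(1:40, function(i) {
    k <- sample(1:4, 1)
    stats::setNames(as.integer(sample(1:50, k)), sample(aa20, k))
  })
  thresholds <- c(0.6, 0.75, 0.9, 0.99, 1.0)
  fixed_sets <- lapply(thresholds, function(th) {
    which(vapply(spectra, function(sp) {
      classify_fixation(sp, "A", th)$status == "fixed"
    }, logical(1)))
  })
  for (i in seq_len(length(thresholds) - 1)) {
    expect_true(all(fixed_sets[[i + 1]] %in% fixed_sets[[i]]),
                label = paste("threshold", thresholds[i + 1]))
  }
})

make_ref <- function(seed = 99, len = 260, focal = 153, residue = "A") {
  set.seed(seed)
  ref <- paste(sample(aa20, len, replace = TRUE), collapse = "")
  substr(ref, focal, focal) <- residue
  ref
}

test_that("survey recovers a paper-shaped 914/915 spectrum exactly", {
  ref <- make_ref()
  map <- reference_map_from_sequence(ref, "bos")
  panel <- make_barcode_panel(ref, 153,
                              list(hummingbird = c(S = 914L, A = 1L),
                                   swift = c(A = 110L)),
                              coverage = 1, seed = 19)
  rep <- survey_position(panel$barcodes, panel$annotations, map, 153,
                         ancestral_residue = "A", threshold = 1.0)
  hb <- rep[rep$clade == "hummingbird", ]
  expect_identical(hb$n_total, 915L)
  expect_identical(hb$n_informative, 915L)
  expect_identical(hb$spectrum[[1]], c(S = 914L, A = 1L))
  expect_identical(hb$fixation_state, "unfixed")
  sw <- rep[rep$clade == "swift", ]
  expect_identical(sw$spectrum[[1]], c(A = 110L))
  expect_identical(sw$fixation_state, "fixed(A)")

  # at threshold 0.99 the 914/915 spectrum counts as (derived-)fixed
  rep99 <- survey_position(panel$barcodes, panel$annotations, map, 153,
                           ancestral_residue = "A", threshold = 0.99)
  hb99 <- rep99[rep99$clade == "hummingbird", ]
  expect_identical(hb99$fixation_state, "fixed(S)")
  expect_true(hb99$derived)
})

test_that("non-covering samples count toward totals but not informativeness", {
  ref <- make_ref()
  map <- reference_map_from_sequence(ref, "bos")
  panel <- make_barcode_panel(ref, 153, list(hb = c(S = 12L)), coverage = 0,
                              seed = 7)
  rep <- survey_position(panel$barcodes, panel$annotations, map, 153,
                         ancestral_residue = "A")
  expect_identical(rep$n_total, 12L)
  expect_identical(rep$n_informative, 0L)
  expect_identical(rep$fixation_state, "absent")

  panel2 <- make_barcode_panel(ref, 153, list(hb = c(S = 10L)), coverage = 0.5,
                               seed = 8)
  rep2 <- survey_position(panel2$barcodes, panel2$annotations, map, 153,
                          ancestral_residue = "A")
  expect_identical(rep2$n_total, 10L)
  expect_identical(rep2$n_informative, 5L)
  expect_identical(rep2$spectrum[[1]], panel2$truth$observed_spectra$hb)
})

test_that("surveys can run on pre-aligned rows and respect exclusions", {
  aln_rows <- c(s1 = "MA-KV", s2 = "MASKV", s3 = "MATKV", s4 = "MAXKV")
  ref_aln <- as_msa(c(bos = "MA-KV", s1 = aln_rows[[1]], s2 = aln_rows[[2]],
                      s3 = aln_rows[[3]], s4 = aln_rows[[4]]))
  map <- build_reference_map(ref_aln, "bos")
  ann <- data.frame(id = paste0("s", 1:4), genus = "g1")
  rep <- survey_position(aln_rows, ann, map, ref_position = 3,
                         ancestral_residue = "K", aligned = TRUE)
  # reference position 3 is column 4 ("K"); all four samples carry K there
  expect_identical(rep$n_informative, 4L)
  expect_identical(rep$fixation_state, "fixed(K)")

  # the aligned column 3 is reference-gapped; surveying ref position 2 uses col 2
  rep2 <- survey_position(aln_rows, ann, map, ref_position = 2,
                          ancestral_residue = "A", aligned = TRUE,
                          exclude = "s4")
  expect_identical(rep2$n_total, 3L)
  expect_error(survey_position(aln_rows, ann, map, 99, aligned = TRUE),
               "unmapped")
})

test_that("merging disjoint reports adds totals and spectra componentwise", {
  ref <- make_ref()
  map <- reference_map_from_sequence(ref, "bos")
  p1 <- make_barcode_panel(ref, 153, list(hb = c(S = 20L, A = 1L)), seed = 1)
  p2 <- make_barcode_panel(ref, 153, list(hb = c(S = 5L, T = 2L),
                                          other = c(A = 7L)), seed = 2)
  r1 <- survey_position(p1$barcodes, p1$annotations, map, 153,
                        ancestral_residue = "A")
  r2 <- survey_position(p2$barcodes, p2$annotations, map, 153,
                        ancestral_residue = "A")
  m <- merge_fixation_reports(r1, r2)
  hb <- m[m$clade == "hb", ]
  expect_identical(hb$n_total, 28L)
  expect_identical(hb$n_informative, 28L)
  expect_identical(hb$spectrum[[1]][sort(names(hb$spectrum[[1]]))],
                   c(A = 1L, S = 25L, T = 2L))
  expect_identical(m[m$clade == "other", ]$n_total, 7L)
})

test_that("rank_substituted_clades reports divergent fractions and totals", {
  ref <- make_ref()
  map <- reference_map_from_sequence(ref, "bos")
  # a small panel shaped like a rare-divergence survey: 3 of 60 divergent
  panel <- make_barcode_panel(ref, 153,
                              list(g1 = c(A = 30L), g2 = c(A = 25L, S = 2L),
                                   g3 = c(A = 2L, V = 1L)),
                              seed = 5)
  rep <- survey_position(panel$barcodes, panel$annotations, map, 153,
                         ancestral_residue = "A")
  rk <- rank_substituted_clades(rep)
  expect_identical(rk$clade, c("g3", "g2"))  # descending derived fraction
  expect_identical(attr(rk, "overall_divergent"), 3L)
  expect_identical(attr(rk, "overall_informative"), 60L)
  expect_equal(attr(rk, "overall_fraction"), 3 / 60)

  # no divergent samples -> empty table, fraction 0
  panel0 <- make_barcode_panel(ref, 153, list(g1 = c(A = 10L)), seed = 6)
  rep0 <- survey_position(panel0$barcodes, panel0$annotations, map, 153,
                          ancestral_residue = "A")
  rk0 <- rank_substituted_clades(rep0)
  expect_identical(nrow(rk0), 0L)
  expect_equal(attr(rk0, "overall_fraction"), 0)
})

test_that("fixation reports serialise with per-residue count columns", {
  ref <- make_ref()
  map <- reference_map_from_sequence(ref, "bos")
  panel <- make_barcode_panel(ref, 153, list(hb = c(S = 9L, A = 1L)), seed = 3)
  rep <- survey_position(panel$barcodes, panel$annotations, map, 153,
                         ancestral_residue = "A")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fixation_report(rep, f)
  tab <- utils::read.delim(f)
  expect_identical(tab$S, 9L)
  expect_identical(tab$A, 1L)
  expect_identical(tab$n_informative, 10L)
})
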