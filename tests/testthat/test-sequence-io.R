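test_that("read_fasta parses records and enforces preconditions", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a extra header words", "MKV", ">b", "MK-"), f)
  recs <- read_fasta(f, "aa")
  expect_identical(recs, c(a = "MKV", b = "MK-"))

  writeLines(c(">a", "MKV", ">a", "MKC"), f)
  expect_error(read_fasta(f), "duplicate.*a")

  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")

  writeLines(c(">a", "MK9"), f)
  expect_error(read_fasta(f, "aa"), "illegal.*'9'.*'a'")
})

test_that("FASTA round-trip is the identity on random record sets", {
  set.seed(42)
  for (rep in 1:5) {
    recs <- random_records(50)
    f <- withr::local_tempfile(fileext = ".fasta")
    write_fasta(recs, f, width = 17)  # force wrapping
    expect_identical(read_fasta(f, "aa"), recs)
  }
})

test_that("embedded genetic codes match the published NCBI tables", {
  # independent oracle: Biostrings ships the NCBI genetic code registry
  for (id in c("1", "2", "5")) {
    mine <- genetic_code(id)$table
    ref <- Biostrings::getGeneticCode(id)
    expect_identical(unname(mine[names(ref)]), as.vector(ref),
                     label = paste("table", id))
  }
})

test_that("translate obeys the codon rules", {
  vmt <- genetic_code("vertebrate-mitochondrial")
  expect_identical(translate("GCC", vmt), "A")
  expect_identical(translate("AGA", vmt), "*")
  expect_identical(translate("AGA", genetic_code("standard")), "R")
  expect_identical(translate("GCNTCN", vmt), "XX")
  expect_identical(translate("GC-GCA", vmt), "XA")
  expect_error(genetic_code("martian"), "unknown genetic code")

  # length law: floor((len - frame + 1)/3) residues
  set.seed(7)
  for (i in 1:20) {
    len <- sample(3:40, 1)
    frame <- sample(1:3, 1)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    if ((len - frame + 1) < 3) next
    expect_identical(nchar(translate(s, vmt, frame)),
                     (len - frame + 1L) %/% 3L)
  }
})

test_that("best_frame_translation picks the frame with fewest internal stops", {
  vmt <- genetic_code("vertebrate-mitochondrial")
  # frame 2 reads KKVLAT cleanly; frame 1 opens with the stop TAA and frame 3
  # hits AGA and TAG stops
  nt <- "TAAGAAAGTACTAGCTACA"
  res <- best_frame_translation(nt, vmt)
  expect_identical(res$frame, 2L)
  expect_identical(res$protein, "KKVLAT")
})

test_that("min_codon_distance matches brute force and is a metric", {
  vmt <- genetic_code("vertebrate-mitochondrial")
  expect_identical(min_codon_distance("A", "S", vmt), 1L)
  expect_identical(min_codon_distance("A", "A", vmt), 0L)
  expect_error(min_codon_distance("A", "B", vmt), "not encoded")

  # brute-force oracle over the full codon grid via the Biostrings registry
  ref <- Biostrings::getGeneticCode("2")
  codons <- names(ref)
  ham <- function(c1, c2) sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  for (aa in aa20) {
    cw <- codons[ref == "W"]
    ca <- codons[ref == aa]
    expected <- min(outer(cw, ca, Vectorize(ham)))
    expect_identical(min_codon_distance("W", aa, vmt), as.integer(expected),
                     label = paste("W vs", aa))
  }

  # symmetry and triangle inequality over a random triple sample
  set.seed(11)
  for (i in 1:25) {
    abc <- sample(aa20, 3)
    dab <- min_codon_distance(abc[1], abc[2], vmt)
    expect_identical(dab, min_codon_distance(abc[2], abc[1], vmt))
    expect_lte(min_codon_distance(abc[1], abc[3], vmt),
               dab + min_codon_distance(abc[2], abc[3], vmt))
  }
})

test_that("concatenate_proteomes tracks offsets and the missing-gene policy", {
  per_species <- list(
    sp1 = list(g1 = "MKV", g2 = "ACDE"),
    sp2 = list(g1 = "MRV", g2 = "ACD-"))
  out <- concatenate_proteomes(per_species, c("g1", "g2"))
  expect_identical(unname(nchar(out$records)), c(7L, 7L))
  expect_identical(out$records[["sp1"]], "MKVACDE")
  expect_identical(out$offsets,
                   data.frame(gene = c("g1", "g2"), start = c(1L, 4L),
                              end = c(3L, 7L), stringsAsFactors = FALSE))

  # permuted gene order: same residues, offsets permuted consistently
  out2 <- concatenate_proteomes(per_species, c("g2", "g1"))
  expect_identical(out2$records[["sp2"]], "ACD-MRV")
  expect_identical(out2$offsets$gene, c("g2", "g1"))
  expect_identical(out2$offsets$start, c(1L, 5L))

  per_species$sp2$g2 <- NULL
  expect_error(concatenate_proteomes(per_species, c("g1", "g2")),
               "sp2.*missing gene 'g2'")
  pad <- concatenate_proteomes(per_species, c("g1", "g2"), missing = "pad")
  expect_identical(pad$records[["sp2"]], "MRV----")
})

test_that("13-gene concatenation length equals the sum of gene lengths", {
  set.seed(5)
  genes <- paste0("mt", 1:13)
  lens <- sample(20:60, 13)
  per_species <- lapply(1:4, function(i) {
    stats::setNames(lapply(lens, function(L) {
      paste(sample(aa20, L, replace = TRUE), collapse = "")
    }), genes)
  })
  names(per_species) <- paste0("sp", 1:4)
  out <- concatenate_proteomes(per_species, genes)
  expect_true(all(nchar(out$records) == sum(lens)))
  expect_identical(out$offsets$end[13], sum(lens))
})
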