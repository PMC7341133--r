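test_that("simulate_tree is deterministic and honours the clade spec", {
  t1 <- simulate_tree(20, c(focal = 6), seed = 12)
  t2 <- simulate_tree(20, c(focal = 6), seed = 12)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  t3 <- simulate_tree(20, c(focal = 6), seed = 13)
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))

  expect_identical(length(t1$tip.label), 20L)
  expect_true("outgroup" %in% t1$tip.label)
  focal_tips <- paste0("focal_", 1:6)
  expect_true(ape::is.monophyletic(t1, focal_tips))
  # the focal clade's ancestor carries the clade label
  node <- ape::getMRCA(t1, focal_tips)
  expect_identical(t1$node.label[node - 20L], "focal")
  # the outgroup subtends the root
  root <- setdiff(unique(t1$edge[, 1]), t1$edge[, 2])
  kids <- t1$edge[t1$edge[, 1] == root, 2]
  expect_true(which(t1$tip.label == "outgroup") %in% kids)

  expect_identical(length(simulate_tree(3, c(focal = 1), seed = 1)$tip.label), 3L)
  expect_error(simulate_tree(5, c(focal = 9), seed = 1), "exceed")
})

test_that("evolve_alignment is seed-deterministic and records exact truth", {
  tr <- simulate_tree(12, c(focal = 4), seed = 2)
  s1 <- evolve_alignment(tr, 50, background_rate = 0.05, seed = 3)
  s2 <- evolve_alignment(tr, 50, background_rate = 0.05, seed = 3)
  expect_identical(s1$aln, s2$aln)
  expect_identical(s1$truth$events, s2$truth$events)

  # the last recorded event per (child, column) matches the truth matrix
  # (a column may be hit more than once on one edge at high rates)
  ev <- s1$truth$events
  last <- !duplicated(ev[, c("child", "column")], fromLast = TRUE)
  for (i in which(last)) {
    expect_identical(unname(s1$truth$states[ev$child[i], ev$column[i]]),
                     ev$to[i])
  }
  # and chains are consistent: each event starts from the previous 'to'
  for (key in unique(paste(ev$child, ev$column))) {
    chain <- ev[paste(ev$child, ev$column) == key, ]
    if (nrow(chain) > 1) {
      expect_identical(chain$from[-1], chain$to[-nrow(chain)])
    }
  }
})

test_that("rate 0 with one planted event yields the single-event limit", {
  tr <- simulate_tree(12, c(focal = 4), seed = 21)
  planted <- data.frame(child = "focal", column = 7L, from = "A", to = "S")
  sim <- evolve_alignment(tr, 20, background_rate = 0, planted_events = planted,
                          seed = 22)
  expect_identical(nrow(sim$truth$events), 1L)
  aln <- unclass(sim$aln)
  focal_tips <- paste0("focal_", 1:4)
  expect_true(all(aln[focal_tips, 7] == "S"))
  expect_true(all(aln[setdiff(rownames(aln), focal_tips), 7] == "A"))
  # all other columns are untouched (constant across leaves)
  expect_true(all(apply(aln[, -7], 2, function(cc) length(unique(cc)) == 1L)))

  # inconsistent planted 'from' residues at one column -> error up front
  bad <- data.frame(child = "focal_1", column = 7L, from = "W", to = "C")
  expect_error(evolve_alignment(tr, 20, background_rate = 0,
                                planted_events = rbind(planted, bad),
                                seed = 22),
               "conflicting 'from'")

  # a planted event below another one sees the derived state, not 'from'
  nested <- rbind(planted,
                  data.frame(child = "focal_1", column = 7L, from = "A",
                             to = "C"))
  expect_error(evolve_alignment(tr, 20, background_rate = 0,
                                planted_events = nested, seed = 22),
               "expects ancestral 'A' but found 'S'")
})

test_that("background event counts follow the Poisson expectation", {
  tr <- simulate_tree(24, c(focal = 5), seed = 31)
  rate <- 0.01
  n_col <- 200
  sim <- evolve_alignment(tr, n_col, background_rate = rate, seed = 32)
  n_edges <- nrow(tr$edge)
  expected <- n_edges * n_col * rate
  observed <- nrow(sim$truth$events)
  expect_lt(abs(observed - expected), 3 * sqrt(expected))
})

test_that("homoplasy-free pipelines recover the planted event set exactly", {
  b <- simulate_scan_bundle(n_leaves = 28, focal_size = 6, n_columns = 150,
                            n_planted = 8, background_rate = 0.01, seed = 41)
  asg <- reconstruct(b$tree, b$aln)
  tab <- build_edge_table(asg)
  hits <- which(tab$indicator == 1L, arr.ind = TRUE)
  recovered <- data.frame(parent = tab$edges$parent[hits[, 1]],
                          child = tab$edges$child[hits[, 1]],
                          column = as.integer(hits[, 2]),
                          stringsAsFactors = FALSE)
  truth <- b$truth$events[, c("parent", "child", "column")]
  o1 <- order(recovered$column, recovered$child)
  o2 <- order(truth$column, truth$child)
  expect_identical(recovered[o1, ], truth[o2, ], ignore_attr = TRUE)
  expect_identical(nrow(recovered), nrow(truth))
})

test_that("barcode panels are deterministic and invert through translation", {
  ref <- paste(rep(aa20, length.out = 240), collapse = "")
  p1 <- make_barcode_panel(ref, 153, list(hb = c(S = 5L, A = 2L)),
                           coverage = 1, seed = 51)
  p2 <- make_barcode_panel(ref, 153, list(hb = c(S = 5L, A = 2L)),
                           coverage = 1, seed = 51)
  expect_identical(p1$barcodes, p2$barcodes)
  expect_identical(p1$annotations, p2$annotations)

  # back-translation then translation is the identity on the fragment
  vmt <- genetic_code("vertebrate-mitochondrial")
  for (id in names(p1$barcodes)) {
    prot <- translate(p1$barcodes[[id]], vmt)
    expect_identical(substr(prot, 1, 1), substr(ref, 33, 33))  # window start
    focal_at <- 153 - 33 + 1
    expect_identical(substr(prot, focal_at, focal_at),
                     unname(p1$truth$residues[id]))
  }
})
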