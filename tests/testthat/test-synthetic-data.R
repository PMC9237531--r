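test_that("planting at rate 1 is always recovered and truth spans verify", {
  sp <- synthetic_spec(seed = 51, n_proteins = 30, p_overlap = 0,
                       motif_plan = data.frame(
                         notation = c("RRIL", "LxLSIxGA"),
                         rate = c(1.0, 1.0),
                         window = c("tail_opposite_tffd", "tmd")),
                       n_background = 0, n_membrane_background = 0)
  co <- generate_cohort(sp)
  rril <- compile_pattern("RRIL")
  for (i in seq_len(30)) {
    rec <- co$records[i, ]
    expect_true(protein_has_motif(rec, co$annotations[[i]], rril,
                                  windows = "full"))
    # every planted instance is verifiable against the emitted sequence
    for (pm in co$truth[[rec$id]]$planted_motifs) {
      pep <- substr(rec$sequence, pm$span[1], pm$span[2])
      expect_equal(pep, pm$peptide)
      pat <- compile_pattern(pm$notation)
      expect_equal(nrow(scan_window(rec, pat,
        ripscan:::search_window("w", pm$span[1], pm$span[2]))), 1L)
    }
  }
  # planted-in-TMD motif is absent from the TMD-only scan iff planted in tail
  tail_ids <- vapply(co$truth, function(t)
    any(vapply(t$planted_motifs, function(m)
      m$notation == "RRIL" && m$window == "tail_opposite_tffd",
      logical(1))), logical(1))
  expect_true(all(tail_ids))
  for (i in which(tail_ids)[1:5]) {
    expect_false(protein_has_motif(co$records[i, ], co$annotations[[i]],
                                   rril, windows = "tmd"))
  }
})

test_that("at rate 0 motif occurrence matches the analytic chance rate", {
  sp <- synthetic_spec(seed = 53, n_proteins = 150, p_overlap = 0,
                       length_range = c(400, 400),
                       n_background = 0, n_membrane_background = 0)
  co <- generate_cohort(sp)
  p <- compile_pattern("Rx[LIT][KL]")
  # TMD residues are hydrophobicity-biased, so count matches outside the TMD
  # neighbourhood where residues are i.i.d. uniform
  n_pos <- 0L
  n_hit <- 0L
  for (i in seq_len(nrow(co$records))) {
    rec <- co$records[i, ]
    tmd <- co$annotations[[rec$id]]$tmds[1, ]
    w <- ripscan:::search_window("pre", 1L, tmd$start - 1L)
    if (ripscan:::window_length(w) < 4) next
    n_pos <- n_pos + ripscan:::window_length(w) - 3L
    n_hit <- n_hit + nrow(scan_window(rec, p, w))
  }
  pr <- match_probability(p)
  ci <- qbinom(c(0.005, 0.995), n_pos, pr)
  expect_gte(n_hit, ci[1])
  expect_lte(n_hit, ci[2])
})

test_that("generation is reproducible to the byte", {
  sp <- synthetic_spec(seed = 57, n_proteins = 10,
                       motif_plan = data.frame(notation = "RRIL", rate = 0.5,
                                               window = "tail_opposite_tffd"),
                       n_background = 20, n_membrane_background = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(sp), d1)
  write_cohort(generate_cohort(sp), d2)
  for (f in c("proteins.fasta", "annotations.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the output
  sp2 <- sp; sp2$seed <- 58
  expect_false(identical(generate_cohort(sp2)$records$sequence,
                         generate_cohort(sp)$records$sequence))
})

test_that("backgrounds have controlled sizes, TMDs and feature rates", {
  sp <- synthetic_spec(seed = 59, n_background = 600,
                       n_membrane_background = 200,
                       motif_plan = data.frame(notation = "RRIL", rate = 1,
                                               window = "tmd"),
                       background_motif_rate = 0.10)
  bg <- generate_background(sp)
  expect_equal(nrow(bg$proteome$records), 600L)
  expect_equal(nrow(bg$membrane_proteome$records), 200L)
  expect_true(all(vapply(bg$membrane_proteome$records$id, function(id)
    nrow(bg$membrane_proteome$tmds[[id]]) >= 1, logical(1))))
  rril <- compile_pattern("RRIL")
  rate <- mean(vapply(seq_len(600), function(i)
    protein_has_motif(bg$proteome$records[i, ], NULL, rril, "full"),
    logical(1)))
  # planted 10% plus a small analytic chance-match contribution
  p_chance <- 1 - (1 - match_probability(rril))^mean(bg$proteome$records$length)
  lo <- qbinom(0.005, 600, 0.10) / 600
  hi <- qbinom(0.995, 600, 0.10 + p_chance) / 600
  expect_gte(rate, lo)
  expect_lte(rate, hi)
})

test_that("zero-size background requests give empty but valid sets", {
  sp <- synthetic_spec(seed = 61, n_background = 0, n_membrane_background = 0)
  bg <- generate_background(sp)
  expect_equal(nrow(bg$proteome$records), 0L)
  expect_equal(nrow(bg$membrane_proteome$records), 0L)
  expect_s3_class(bg$proteome, "background_set")
})

test_that("infeasible planting plans fail before generation", {
  sp <- synthetic_spec(seed = 63, n_proteins = 2, p_overlap = 0,
                       motif_plan = data.frame(
                         notation = "[ILMF]xx[GAS][AHS][IMLF]AAAAAAAAAAAAAAA",
                         rate = 1, window = "flank_tffd_side", k = 5),
                       n_background = 0, n_membrane_background = 0)
  expect_error(generate_cohort(sp), "infeasible")
})

test_that("fully wired networks put every target in the TF's block", {
  sp <- synthetic_spec(seed = 65, network = list(
    n_tfs = 8, n_blocks = 4, targets_per_tf = 10, n_genes = 200,
    wiring_rate = 1.0))
  nw <- generate_network(sp)
  for (tf in unique(nw$network$edges$tf_id)) {
    targets <- nw$network$edges$target_id[nw$network$edges$tf_id == tf]
    expect_true(all(nw$truth$gene_block[targets] ==
                      nw$truth$tf_block[[tf]]))
  }
  # reproducible
  nw2 <- generate_network(sp)
  expect_identical(nw$network$edges, nw2$network$edges)
})

test_that("the full pipeline recovers planted truth end to end", {
  sp <- synthetic_spec(seed = 67, n_proteins = 40, p_overlap = 0,
                       motif_plan = data.frame(notation = "Rx[LIT][KL]",
                                               rate = 1.0,
                                               window = "flank_tffd_side"),
                       n_background = 0, n_membrane_background = 0)
  co <- generate_cohort(sp)
  p <- compile_pattern("Rx[LIT][KL]")
  # sensitivity: every planted instance is found by the windowed scan
  found <- vapply(seq_len(40), function(i)
    protein_has_motif(co$records[i, ], co$annotations[[i]], p,
                      windows = "tmd_plus_flank", k = 20), logical(1))
  expect_equal(mean(found), 1.0)
  # topology classification reproduces the generator's truth exactly
  for (i in seq_len(40)) {
    tc <- classify_topology(co$annotations[[i]])
    tr <- co$truth[[i]]
    expect_equal(tc$position_class, tr$position_class)
    expect_equal(tc$tffd_side, tr$tffd_side)
  }
})
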