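test_that("motif notation compiles to the expected token classes", {
  p <- compile_pattern("Rx[LIT][KL]")
  expect_length(p$tokens, 4L)
  expect_equal(vapply(p$tokens, `[[`, character(1), "type"),
               c("literal", "any", "set", "set"))
  expect_equal(p$tokens[[3]]$residues, c("L", "I", "T"))
  expect_equal(p$tokens[[4]]$residues, c("K", "L"))

  q <- compile_pattern("[^WP]A")
  expect_equal(q$tokens[[1]]$type, "complement")
  expect_equal(q$tokens[[1]]$residues, c("W", "P"))
  expect_equal(q$tokens[[2]]$type, "literal")

  expect_error(compile_pattern("R[x"), "parse error")
  expect_error(compile_pattern("R[LI"), "unbalanced")
  expect_error(compile_pattern("RB"), "column 2")
  expect_error(compile_pattern("R"), "at least 2")
})

test_that("window scanning finds degenerate matches in both orientations", {
  rec <- list(id = "T1", sequence = "MARSILKQ")
  hits <- scan_window(rec, compile_pattern("Rx[LIT][KL]"))
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$start, hits$end), c(3L, 6L))
  expect_equal(hits$matched_peptide, "RSIL")

  # reverse orientation = reversed token order, scanned forward
  rec2 <- list(id = "T2", sequence = "APNA")
  rev_hits <- scan_window(rec2, compile_pattern("NP"), orientation = "reverse")
  expect_equal(c(rev_hits$start, rev_hits$end), c(2L, 3L))
  expect_equal(rev_hits$matched_peptide, "PN")

  expect_equal(nrow(scan_window(list(id = "T3", sequence = "MKVAAA"),
                                compile_pattern("RRIL"))), 0L)
})

test_that("the wildcard matches X but literal and set tokens never do", {
  rec <- list(id = "T", sequence = "RXIL")
  expect_equal(nrow(scan_window(rec, compile_pattern("Rx[LIT][KL]"))), 1L)
  rec2 <- list(id = "T", sequence = "RAXL")
  expect_equal(nrow(scan_window(rec2, compile_pattern("Rx[LIT][KL]"))), 0L)
  rec3 <- list(id = "T", sequence = "XA")
  expect_equal(nrow(scan_window(rec3, compile_pattern("[^WP]A"))), 0L)
})

test_that("overlapping matches are all reported", {
  rec <- list(id = "T", sequence = "GAGAGA")
  hits <- scan_window(rec, compile_pattern("GA"))
  expect_equal(hits$start, c(1L, 3L, 5L))
})

test_that("the default catalog carries every published pattern", {
  cat14 <- motif_catalog()
  expect_length(cat14, 14L)
  notations <- vapply(cat14, `[[`, character(1), "notation")
  expect_true(all(c("RRIL", "Rx[LIT][KL]", "LxLSIxGA", "[LF]xLSIxGA",
                    "[ILMF]xx[GAS][AHS][IMLF]", "[ILMF]x[GAS][AHS][IMLF]",
                    "[^WP][IMYFWLV][^WPD][^WF][AGCS][^P][FIMVACLTW]",
                    "NP", "NxxP", "PxxP", "GxxN", "PxxN", "PN", "GA")
                  %in% notations))
  helix <- Filter(function(p) p$category == "helix_destabilizing", cat14)
  expect_length(helix, 7L)
  expect_true(all(vapply(helix, function(p)
    identical(attr(p, "orientations"), c("forward", "reverse")), logical(1))))
  # the Spitz-derived dual cleavage site is carried as metadata
  expect_equal(cat14$rhomboid_NTL$cleavage_offsets, c(3L, 7L))
})

test_that("scanner agrees with the positional-membership oracle", {
  set.seed(11)
  cat14 <- motif_catalog()
  seqs <- replicate(60, random_protein(200))
  for (p in cat14) {
    for (ori in c("forward", "reverse")) {
      for (s in seqs) {
        rec <- list(id = "R", sequence = s)
        got <- scan_window(rec, p, orientation = ori)$start
        want <- oracle_scan(s, p$notation, reverse = (ori == "reverse"))
        expect_equal(got, as.integer(want), info = paste(p$name, ori))
      }
    }
  }
})

test_that("reverse scan equals forward scan for symmetric token patterns", {
  set.seed(7)
  for (notation in c("PxxP", "GxxG")) {
    p <- compile_pattern(notation)
    for (i in 1:20) {
      rec <- list(id = "R", sequence = random_protein(150))
      expect_equal(scan_window(rec, p, orientation = "forward")$start,
                   scan_window(rec, p, orientation = "reverse")$start)
    }
  }
})

test_that("restricting the window can only remove hits", {
  set.seed(13)
  p <- compile_pattern("Rx[LIT][KL]")
  for (i in 1:25) {
    s <- random_protein(300)
    rec <- list(id = "R", sequence = s)
    full <- scan_window(rec, p)$start
    lo <- sample(1:100, 1); hi <- sample(200:300, 1)
    w <- ripscan:::search_window("sub", lo, hi)
    sub <- scan_window(rec, p, w)$start
    expect_true(all(sub %in% full))
    expect_setequal(sub, full[full >= lo & full + 3L <= hi])
  }
})

test_that("observed hit frequency matches the analytic per-position product", {
  # i.i.d. uniform residues: P(match at a position) = prod(|class|/20)
  set.seed(29)
  p <- compile_pattern("Rx[LIT][KL]")
  expect_equal(match_probability(p), (1 / 20) * 1 * (3 / 20) * (2 / 20))
  n_pos <- 1e5
  L <- length(p$tokens)
  s <- random_protein(n_pos + L - 1)
  hits <- length(scan_window(list(id = "S", sequence = s), p)$start)
  pr <- match_probability(p)
  ci <- qbinom(c(0.005, 0.995), n_pos, pr)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("protein_has_motif honours window choice and TMD policy", {
  # RRIL planted in the tail beyond the TMD, TFFD N-terminal
  seq <- paste0(strrep("A", 100), strrep("L", 21), strrep("G", 30), "RRIL",
                strrep("G", 30))
  rec <- list(id = "P", sequence = seq)
  ann <- annotation("P", c(10, 60),
                    data.frame(start = 101, end = 121, topology = "I"),
                    seq_length = nchar(seq))
  p <- compile_pattern("RRIL")
  expect_true(protein_has_motif(rec, ann, p, windows = "full"))
  expect_false(protein_has_motif(rec, ann, p, windows = "tmd"))
  expect_false(protein_has_motif(rec, ann, p,
                                 windows = c("tmd", "tmd_plus_flank")))
  # a second TMD next to the motif is only seen under policy "all"
  ann2 <- annotation("P", c(10, 60),
                     data.frame(start = c(101, 130), end = c(121, 150),
                                topology = c("I", "I")),
                     seq_length = nchar(seq))
  expect_false(protein_has_motif(rec, ann2, p, windows = "tmd_plus_flank",
                                 tmd_policy = "first"))
  expect_true(protein_has_motif(rec, ann2, p, windows = "tmd_plus_flank",
                                tmd_policy = "all"))
})
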