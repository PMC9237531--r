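mk_ann <- function(tffd, tmd, topology = NA, len = NA) {
  suppressWarnings(annotation("P", tffd,
    data.frame(start = tmd[1], end = tmd[2], topology = topology),
    seq_length = len))
}

test_that("TFFD-side flank windows resolve to the published coordinates", {
  # TFFD N-terminal of the TMD: left flank
  bzip28 <- mk_ann(c(192, 237), c(321, 344), "I", len = 675)
  w <- resolve_window(bzip28, "flank_tffd_side", k = 20)
  expect_equal(c(w$start, w$end), c(301L, 320L))
  # TFFD C-terminal of the TMD: right flank
  ail6 <- mk_ann(c(389, 440), c(301, 321), "I", len = 500)
  w2 <- resolve_window(ail6, "flank_tffd_side", k = 20)
  expect_equal(c(w2$start, w2$end), c(322L, 341L))
})

test_that("windows clip at sequence bounds and degenerate to empty on overlap", {
  ann <- mk_ann(c(1, 3), c(5, 25), "I", len = 30)
  w <- resolve_window(ann, "tmd_plus_flank", k = 10)
  expect_equal(c(w$start, w$end), c(1L, 30L))
  ov <- mk_ann(c(50, 100), c(60, 80), "I", len = 200)
  wf <- resolve_window(ov, "flank_tffd_side", k = 20)
  expect_equal(window_length(wf), 0L)
})

test_that("flank windows nest with increasing k and resolution is idempotent", {
  set.seed(5)
  for (i in 1:30) {
    len <- sample(60:400, 1)
    ts <- sample(25:(len - 25), 1)
    te <- min(len, ts + sample(12:25, 1))
    tffd <- if (runif(1) < 0.5 && ts > 2) c(1, max(1, ts - sample(1:20, 1)))
            else c(min(len, te + 1), len)
    if (tffd[1] > tffd[2]) tffd <- rev(tffd)
    ann <- mk_ann(tffd, c(ts, te), len = len)
    prev <- NULL
    for (k in c(5, 10, 15, 20)) {
      w <- resolve_window(ann, "flank_tffd_side", k = k, seq_length = len)
      expect_gte(w$start, 1L)
      expect_lte(w$end, len)
      if (!is.null(prev) && window_length(prev) > 0) {
        expect_gte(prev$start, w$start)
        expect_lte(prev$end, w$end)
      }
      prev <- w
    }
  }
})

test_that("charge profiles count K and R exactly", {
  seq <- paste0("MM", "LLKLLARLL", "QQ")
  ann <- mk_ann(c(12, 13), c(3, 11), len = 13)
  prof <- charge_profile(list(id = "P", sequence = seq), ann, ks = c(5, 10))
  tmd <- prof[prof$window == "tmd", ]
  expect_equal(tmd$K, 1L)
  expect_equal(tmd$R, 1L)
  expect_equal(tmd$width, 9L)
  # overlap-class proteins have no TFFD-side flank: zero-width, zero counts
  ov <- mk_ann(c(1, 13), c(3, 11), len = 13)
  pov <- charge_profile(list(id = "P", sequence = seq), ov, ks = 5)
  fl <- pov[pov$window == "flank_tffd_side(5)", ]
  expect_equal(fl$width, 0L)
  expect_equal(fl$K + fl$R, 0L)
})

test_that("charge counts equal the per-position indicator sum on random data", {
  set.seed(17)
  for (i in 1:20) {
    len <- sample(80:300, 1)
    s <- random_protein(len)
    ts <- sample(30:(len - 30), 1); te <- min(len, ts + 20)
    ann <- mk_ann(c(1, 5), c(ts, te), len = len)
    prof <- charge_profile(list(id = "P", sequence = s), ann)
    chars <- strsplit(s, "")[[1]]
    for (j in seq_len(nrow(prof))) {
      if (prof$width[j] == 0) next
      idx <- prof$start[j]:prof$end[j]
      expect_equal(prof$K[j], sum(chars[idx] == "K"))
      expect_equal(prof$R[j], sum(chars[idx] == "R"))
    }
  }
})

test_that("helix breakers are found in the TMD only, both orientations, deduplicated", {
  seq <- paste0(strrep("A", 20), "LLLGALLLPLLPLLLLLLLLL", strrep("A", 20),
                "GA", strrep("A", 10))
  ann <- mk_ann(c(1, 10), c(21, 41), len = nchar(seq))
  hits <- find_helix_breakers(list(id = "P", sequence = seq), ann)
  expect_true("GA" %in% hits$motif_name)
  expect_true("PxxP" %in% hits$motif_name)
  # the GA outside the TMD is not reported
  expect_true(all(hits$start >= 21 & hits$end <= 41))
  expect_false(any(duplicated(hits[, c("motif_name", "start", "end")])))

  polyL <- paste0(strrep("A", 20), strrep("L", 21), strrep("A", 20))
  ann2 <- mk_ann(c(1, 10), c(21, 41), len = nchar(polyL))
  expect_equal(nrow(find_helix_breakers(list(id = "P", sequence = polyL),
                                        ann2)), 0L)
})

test_that("topology classification combines position class and type-I/II", {
  # C-terminal TMD + type II: N-terminal TFFD in the cytosol
  bzip60 <- classify_topology(mk_ann(c(141, 183), c(217, 240), "II"))
  expect_equal(bzip60$position_class, "C")
  expect_equal(bzip60$tffd_side, "cytosolic")
  # C-terminal TMD + type I: TFFD in the lumen
  ntl1 <- classify_topology(mk_ann(c(10, 135), c(497, 520), "I"))
  expect_equal(ntl1$tffd_side, "luminal")
  # overlap: side undefined
  ov <- classify_topology(mk_ann(c(50, 100), c(60, 80), "I"))
  expect_equal(ov$position_class, "overlap")
  expect_true(is.na(ov$tffd_side))
  # unknown topology: class known, side unknown
  unk <- classify_topology(mk_ann(c(1, 50), c(100, 120)))
  expect_equal(unk$position_class, "C")
  expect_true(is.na(unk$tffd_side))
})

test_that("topology classification partitions all annotations into one class", {
  set.seed(23)
  for (i in 1:50) {
    len <- 300
    ts <- sample(30:250, 1); te <- ts + 20
    f1 <- sample(1:280, 1); f2 <- min(len, f1 + sample(5:60, 1))
    ann <- mk_ann(c(f1, f2), c(ts, te), len = len)
    cls <- classify_topology(ann)$position_class
    expect_true(cls %in% c("N", "C", "overlap"))
    expect_equal(cls == "C", ts > f2)
    expect_equal(cls == "N", te < f1)
  }
})

test_that("on the packaged inventory all NTLs except NTL1 have a cytosolic TFFD", {
  fx <- load_table1_fixture()
  ntl <- fx[grep("^NTL", names(fx))]
  side <- vapply(ntl, function(a) classify_topology(a)$tffd_side, character(1))
  expect_equal(unname(side["NTL1"]), "luminal")
  expect_true(all(side[setdiff(names(side), "NTL1")] == "cytosolic"))
})

test_that("PTMs between the domains are selected by the open interval", {
  ptms <- data.frame(kind = c("phosphorylation", "phosphorylation",
                              "phosphorylation"),
                     position = c(150L, 50L, 100L))
  ann <- suppressWarnings(annotation("P", c(10, 100),
    data.frame(start = 200, end = 220), ptms = ptms, seq_length = 300))
  sel <- ptm_between_tffd_and_tmd(ann)
  expect_equal(sel$position, 150L)  # 50 and 100 are inside the TFFD
  # boundary residues belong to their domains
  ptms2 <- data.frame(kind = "phosphorylation", position = c(101L, 199L))
  ann2 <- annotation("P", c(10, 100), data.frame(start = 200, end = 220),
                     ptms = ptms2, seq_length = 300)
  expect_equal(nrow(ptm_between_tffd_and_tmd(ann2)), 2L)
})

test_that("a proteolytic N-terminus within 41 residues of the TMD is RIP-consistent", {
  mk <- function(pos) suppressWarnings(annotation("P", c(1, 100),
    data.frame(start = 200, end = 220),
    ptms = data.frame(kind = "proteolytic N-terminus", position = pos),
    seq_length = 300))
  expect_true(proteolytic_nterm_near_tmd(mk(170L)))   # 30 residues away
  expect_true(proteolytic_nterm_near_tmd(mk(159L)))   # exactly 41
  expect_false(proteolytic_nterm_near_tmd(mk(158L)))  # 42
  expect_false(proteolytic_nterm_near_tmd(mk(250L)))  # wrong side
})
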