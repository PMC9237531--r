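HYDROPHOBIC <- c("A", "F", "G", "I", "L", "M", "V", "W")

# sample one element of x (never the 1:n expansion of a scalar)
pick1 <- function(x) x[sample.int(length(x), 1L)]
pick <- function(x, size) x[sample.int(length(x), size)]
NEUTRAL_FILL <- c("A", "L", "S", "T", "V")

#' Specify a synthetic cohort
#'
#' Bundles every knob of the synthetic-data generator: cohort size, protein
#' length range, residue model, TMD model, TFFD placement mix, motif and
#' charge planting plans, background sizes and the regulatory-network plan.
#' The defaults emulate the statistical structure the pipeline assumes: a
#' membrane-bound TF cohort of 57 proteins against a 2,000-protein
#' background, i.i.d. uniform residues (which makes analytic per-position
#' match probabilities exact), hydrophobicity-biased TMDs of 18-25 residues,
#' and a TFFD on the N- or C-terminal side of the TMD with a small
#' overlap-class fraction.
#'
#' @param seed Integer seed; every generator call derives all randomness
#'   from it.
#' @param n_proteins Cohort size (default 57, the analysis-set size of the
#'   motivating inventory).
#' @param length_range Protein length min/max (default c(300, 700)).
#' @param residue_freq Named numeric vector of residue frequencies over the
#'   20-letter alphabet, or `NULL` for uniform.
#' @param tmd_length_range TMD length min/max (default c(18, 25)).
#' @param tmd_hydrophobic_bias Probability that a TMD residue is drawn from
#'   the hydrophobic alphabet (default 0.9).
#' @param p_tffd_nterm Probability that the TFFD lies N-terminal of the TMD
#'   (default 0.4; the inventory is C-TMD-heavy).
#' @param p_overlap Fraction of overlap-class decoys (default 0.1).
#' @param p_type_II Probability of a type-II topology call (default 0.6).
#' @param motif_plan Data frame with columns `notation`, `rate`, `window`
#'   (one of `tmd`, `flank_tffd_side`, `tail_opposite_tffd`, `full`) and
#'   optionally `k` (flank size, default 20): each motif is planted with the
#'   given per-protein rate at a uniform legal offset inside the window.
#' @param charge_plan `NULL`, or a list with `count` (K/R residues to plant)
#'   and `k` (flank size of the target `flank_tffd_side` window); K/R
#'   elsewhere in the TMD neighborhood is scrubbed so the planted window
#'   carries the signal.
#' @param n_background,n_membrane_background Background set sizes.
#' @param background_motif_rate Planting rate of `motif_plan` motifs in the
#'   background (default 0, i.e. chance occurrences only).
#' @param network Network plan: list with `n_tfs`, `n_blocks`,
#'   `targets_per_tf`, `n_genes`, `wiring_rate` (probability that a target
#'   is drawn from the TF's own block).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1, n_proteins = 57,
                           length_range = c(300, 700), residue_freq = NULL,
                           tmd_length_range = c(18, 25),
                           tmd_hydrophobic_bias = 0.9, p_tffd_nterm = 0.4,
                           p_overlap = 0.1, p_type_II = 0.6,
                           motif_plan = NULL, charge_plan = NULL,
                           n_background = 2000,
                           n_membrane_background = 1000,
                           background_motif_rate = 0,
                           network = list(n_tfs = 20, n_blocks = 4,
                                          targets_per_tf = 15,
                                          n_genes = 400,
                                          wiring_rate = 0.9)) {
  if (!is.null(residue_freq)) {
    stopifnot(setequal(names(residue_freq), AA20))
    residue_freq <- residue_freq[AA20] / sum(residue_freq)
  }
  if (!is.null(motif_plan)) {
    stopifnot(all(c("notation", "rate", "window") %in% names(motif_plan)),
              all(motif_plan$rate >= 0 & motif_plan$rate <= 1))
    if (is.null(motif_plan$k)) motif_plan$k <- 20
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

draw_residues <- function(n, freq = NULL) {
  if (is.null(freq)) sample(AA20, n, replace = TRUE)
  else sample(AA20, n, replace = TRUE, prob = freq)
}

realize_pattern <- function(pattern) {
  paste(vapply(pattern$tokens, function(tok) switch(tok$type,
    any = sample(AA20, 1),
    literal = tok$residues,
    set = sample(tok$residues, 1)[[1]],
    complement = sample(setdiff(AA20, tok$residues), 1)), character(1)),
    collapse = "")
}

plant_window <- function(spec_entry, ann, seq_length) {
  w <- spec_entry$window
  tmd <- ann$tmds[1, ]
  if (w == "full") return(c(1L, seq_length))
  if (w == "tmd") return(c(tmd$start, tmd$end))
  cls <- position_class(ann$tffd, c(tmd$start, tmd$end))
  if (cls == "overlap") return(NULL)
  k <- spec_entry$k
  if (w == "flank_tffd_side") {
    if (cls == "C") c(max(1L, tmd$start - k), tmd$start - 1L)
    else c(tmd$end + 1L, min(seq_length, tmd$end + k))
  } else if (w == "tail_opposite_tffd") {
    if (cls == "C") {
      if (tmd$end + 1L > seq_length) NULL else c(tmd$end + 1L, seq_length)
    } else {
      if (tmd$start - 1L < 1L) NULL else c(1L, tmd$start - 1L)
    }
  } else stop("unknown planting window '", w, "'")
}

plant_motif <- function(chars, pattern, win, occupied, max_retry = 100) {
  L <- length(pattern$tokens)
  lo <- win[1]; hi <- win[2] - L + 1L
  if (is.null(win) || hi < lo)
    stop("planting plan infeasible: motif '", pattern$notation,
         "' (length ", L, ") does not fit window [", win[1], ",", win[2], "]")
  for (r in seq_len(max_retry)) {
    start <- if (hi == lo) lo else lo + sample.int(hi - lo + 1L, 1) - 1L
    span <- start:(start + L - 1L)
    if (!any(span %in% occupied)) {
      chars[span] <- strsplit(realize_pattern(pattern), "")[[1]]
      return(list(chars = chars, span = c(start, start + L - 1L),
                  occupied = c(occupied, span)))
    }
  }
  stop("planting plan infeasible: could not place '", pattern$notation,
       "' without collision after ", max_retry, " retries")
}

#' Generate a synthetic MB-TF cohort with recorded ground truth
#'
#' Draws i.i.d.-residue proteins, plants a hydrophobicity-biased TMD with an
#' assigned type-I/II topology, places the TFFD N-terminal, C-terminal or
#' overlapping per the spec's mix, writes the planned motifs into their
#' target windows at the planned rates (resampling offsets on collision),
#' optionally plants a controlled K/R count in one flank window, and records
#' everything in a truth table. Identical spec and seed give identical
#' output.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_cohort`: `records` (`protein_set`),
#'   `annotations` (named list of `domain_annotation`s), `truth` (list with
#'   per-protein planted motif instances, planted charge counts, true
#'   topology class and TFFD side).
#' @export
generate_cohort <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_proteins
  ids <- sprintf("SYN%03d", seq_len(n))
  seqs <- character(n)
  anns <- vector("list", n)
  names(anns) <- ids
  truth <- vector("list", n)
  names(truth) <- ids
  plan <- spec$motif_plan
  patterns <- if (!is.null(plan))
    lapply(plan$notation, compile_pattern) else list()
  for (i in seq_len(n)) {
    L <- pick1(spec$length_range[1]:spec$length_range[2])
    chars <- draw_residues(L, spec$residue_freq)
    tmd_len <- pick1(spec$tmd_length_range[1]:spec$tmd_length_range[2])
    u <- runif(1)
    cls <- if (u < spec$p_overlap) "overlap"
    else if (u < spec$p_overlap + spec$p_tffd_nterm) "C"  # TFFD N-terminal
    else "N"                                              # TFFD C-terminal
    margin <- 60L  # room for a TFFD and full flanks on the TFFD side
    if (cls == "C") {
      tmd_start <- pick1((margin + 21L):(L - tmd_len - 25L))
      tffd <- c(10L, tmd_start - 40L)
    } else if (cls == "N") {
      tmd_start <- pick1(26L:(L - tmd_len - margin - 20L))
      tffd <- c(tmd_start + tmd_len + 40L, L - 9L)
    } else {
      tmd_start <- pick1(margin:(L - tmd_len - margin))
      tffd <- c(tmd_start - 20L, tmd_start + tmd_len - 1L + 20L)
    }
    tmd_end <- tmd_start + tmd_len - 1L
    hydro <- runif(tmd_len) < spec$tmd_hydrophobic_bias
    chars[tmd_start:tmd_end][hydro] <- sample(HYDROPHOBIC, sum(hydro),
                                              replace = TRUE)
    topology <- if (runif(1) < spec$p_type_II) "II" else "I"
    ann <- suppressWarnings(annotation(
      ids[i], tffd = tffd,
      tmds = data.frame(start = tmd_start, end = tmd_end,
                        score = round(mean(hydro), 3), topology = topology),
      seq_length = L))
    planted <- list()
    occupied <- integer()
    if (!is.null(plan)) {
      for (j in seq_len(nrow(plan))) {
        if (runif(1) >= plan$rate[j]) next
        win <- plant_window(plan[j, ], ann, L)
        if (is.null(win)) next
        res <- plant_motif(chars, patterns[[j]], win, occupied)
        chars <- res$chars
        occupied <- res$occupied
        planted[[length(planted) + 1L]] <- list(
          notation = plan$notation[j], window = plan$window[j],
          span = res$span,
          peptide = paste(chars[res$span[1]:res$span[2]], collapse = ""))
      }
    }
    charge_count <- NA_integer_
    if (!is.null(spec$charge_plan) && cls != "overlap") {
      ck <- spec$charge_plan$k
      scrub <- c(max(1L, tmd_start - 20L):min(L, tmd_end + 20L))
      scrub <- setdiff(scrub, occupied)
      is_kr <- chars[scrub] %in% c("K", "R")
      chars[scrub][is_kr] <- sample(NEUTRAL_FILL, sum(is_kr), replace = TRUE)
      win <- plant_window(list(window = "flank_tffd_side", k = ck), ann, L)
      slots <- setdiff(win[1]:win[2], occupied)
      count <- min(spec$charge_plan$count, length(slots))
      pos <- pick(slots, count)
      chars[pos] <- sample(c("K", "R"), count, replace = TRUE)
      charge_count <- count
    }
    seqs[i] <- paste(chars, collapse = "")
    anns[[i]] <- ann
    side <- classify_topology(ann)$tffd_side
    truth[[i]] <- list(position_class = cls, topology = topology,
                       tffd_side = side, planted_motifs = planted,
                       planted_charge = charge_count)
  }
  structure(list(records = protein_set(ids, seqs), annotations = anns,
                 truth = truth, spec = spec), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$records), " proteins (seed ",
      x$spec$seed, ")\n", sep = "")
  invisible(x)
}

#' Generate synthetic background sets
#'
#' Produces the pair of backgrounds the enrichment module expects: a whole
#' proteome (no TMD annotations) and a membrane proteome (every entry with a
#' planted TMD span). Motifs from the spec's plan are planted at
#' `background_motif_rate` at uniform positions, so feature base-rates are
#' controlled up to chance matches.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `proteome` and `membrane_proteome`, both
#'   [background_set()]s.
#' @export
generate_background <- function(spec) {
  set.seed(spec$seed + 1L)
  plan <- spec$motif_plan
  patterns <- if (!is.null(plan))
    lapply(plan$notation, compile_pattern) else list()
  make_set <- function(n, prefix, with_tmd) {
    if (n == 0) {
      recs <- protein_set(character(), character())
      return(background_set(if (with_tmd) "membrane_proteome" else "proteome",
                            recs, tmds = if (with_tmd) list() else NULL))
    }
    ids <- sprintf("%s%05d", prefix, seq_len(n))
    seqs <- character(n)
    tmds <- if (with_tmd) vector("list", n) else NULL
    if (with_tmd) names(tmds) <- ids
    for (i in seq_len(n)) {
      L <- pick1(spec$length_range[1]:spec$length_range[2])
      chars <- draw_residues(L, spec$residue_freq)
      if (with_tmd) {
        tmd_len <- pick1(spec$tmd_length_range[1]:spec$tmd_length_range[2])
        ts <- pick1(30L:(L - tmd_len - 30L))
        hydro <- runif(tmd_len) < spec$tmd_hydrophobic_bias
        chars[ts:(ts + tmd_len - 1L)][hydro] <-
          sample(HYDROPHOBIC, sum(hydro), replace = TRUE)
        tmds[[i]] <- data.frame(start = ts, end = ts + tmd_len - 1L)
      }
      if (!is.null(plan) && spec$background_motif_rate > 0) {
        for (j in seq_len(nrow(plan))) {
          if (runif(1) >= spec$background_motif_rate) next
          res <- plant_motif(chars, patterns[[j]], c(1L, L), integer())
          chars <- res$chars
        }
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    recs <- protein_set(ids, seqs)
    background_set(if (with_tmd) "membrane_proteome" else "proteome",
                   recs, tmds = tmds)
  }
  list(proteome = make_set(spec$n_background, "BG", FALSE),
       membrane_proteome = make_set(spec$n_membrane_background, "MB", TRUE))
}

#' Generate a synthetic regulatory network with block structure
#'
#' Genes are partitioned into blocks, each block carries its own GO term,
#' and each TF is assigned a block and wired to genes of that block with the
#' spec's wiring rate (uniformly otherwise).
#'
#' @param spec A [synthetic_spec()].
#' @return List: `network` (a [regulatory_network()]) and `truth` (list with
#'   `tf_block`, `gene_block`, `block_term`).
#' @export
generate_network <- function(spec) {
  set.seed(spec$seed + 2L)
  np <- spec$network
  genes <- sprintf("G%05d", seq_len(np$n_genes))
  gene_block <- rep_len(seq_len(np$n_blocks), np$n_genes)
  block_term <- sprintf("GO:BLOCK%02d", seq_len(np$n_blocks))
  tfs <- sprintf("TF%03d", seq_len(np$n_tfs))
  tf_block <- rep_len(seq_len(np$n_blocks), np$n_tfs)
  edges <- list()
  for (i in seq_len(np$n_tfs)) {
    own <- genes[gene_block == tf_block[i]]
    pick <- vapply(seq_len(np$targets_per_tf), function(j) {
      if (runif(1) < np$wiring_rate) pick1(own) else pick1(genes)
    }, character(1))
    edges[[i]] <- data.frame(tf_id = tfs[i], target_id = unique(pick),
                             stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  go <- data.frame(gene_id = genes, term_id = block_term[gene_block],
                   stringsAsFactors = FALSE)
  net <- regulatory_network(edges, go, universe = genes)
  list(network = net,
       truth = list(tf_block = setNames(tf_block, tfs),
                    gene_block = setNames(gene_block, genes),
                    block_term = block_term))
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort as the pipeline's exchange formats: `proteins.fasta`,
#' `annotations.tsv` and `truth.json`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(cohort$records, file.path(dir, "proteins.fasta"))
  write_annotations(cohort$annotations, file.path(dir, "annotations.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
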