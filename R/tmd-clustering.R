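#' Align TMD peptides
#'
#' Progressive global multiple alignment of short transmembrane-domain
#' peptides using MAFFT (G-INS-1 style: global pairwise guide alignments, a
#' BLOSUM substitution matrix and affine gap penalties). Deterministic for a
#' fixed input order.
#'
#' @param peptides Named character vector (id -> TMD peptide), at least 3
#'   entries, each at least 12 residues.
#' @return Object of class `tmd_alignment`: list with `ids`, `aligned`
#'   (named character vector of equal-length gapped rows, uppercase) and
#'   `params`.
#' @export
align_tmds <- function(peptides) {
  if (length(peptides) < 3)
    stop("need at least 3 peptides to align, got ", length(peptides))
  if (any(nchar(peptides) < 12))
    stop("TMD peptides shorter than 12 residues: ",
         paste(names(peptides)[nchar(peptides) < 12], collapse = ","))
  if (is.null(names(peptides)) || anyDuplicated(names(peptides)))
    stop("peptides must have unique names")
  mafft <- Sys.which("mafft")
  if (mafft == "") stop("MAFFT binary not found on PATH")
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste0(">", names(peptides), "\n", unname(peptides)), fin)
  status <- system2(mafft, c("--globalpair", "--maxiterate", "0", "--quiet",
                             "--anysymbol", shQuote(fin)),
                    stdout = fout, stderr = FALSE)
  if (!identical(status, 0L)) stop("mafft failed with status ", status)
  aln <- Biostrings::readAAStringSet(fout)
  aligned <- toupper(as.character(aln))
  # mafft preserves input order for these sizes, but do not rely on it
  aligned <- aligned[names(peptides)]
  stopifnot(length(unique(nchar(aligned))) == 1)
  structure(list(ids = names(peptides), aligned = aligned,
                 params = list(tool = "mafft", mode = "globalpair",
                               columns = nchar(aligned[[1]]))),
            class = "tmd_alignment")
}

#' @export
print.tmd_alignment <- function(x, ...) {
  cat("<tmd_alignment> ", length(x$ids), " peptides, ",
      x$params$columns, " columns\n", sep = "")
  invisible(x)
}

#' Write a gapped alignment to FASTA
#' @param alignment A `tmd_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  writeLines(paste0(">", names(alignment$aligned), "\n",
                    unname(alignment$aligned)), path)
  invisible(path)
}

alignment_matrix <- function(alignment) {
  do.call(rbind, strsplit(unname(alignment$aligned), ""))
}

blosum_distance <- function(mat) {
  # normalized substitution-matrix dissimilarity; gaps scored as the worst
  # BLOSUM62 mismatch. d(i,j) = 1 - S_ij / min(S_ii, S_jj), clipped at 0;
  # identical rows get distance 0, unrelated rows approach/exceed 1.
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  gap_score <- min(B)
  n <- nrow(mat)
  score_pair <- function(a, b) {
    both_gap <- a == "-" & b == "-"
    one_gap <- (a == "-" | b == "-") & !both_gap
    res <- !both_gap & !one_gap
    sum(B[cbind(a[res], b[res])]) + gap_score * sum(one_gap)
  }
  D <- matrix(0, n, n)
  self <- vapply(seq_len(n), function(i) score_pair(mat[i, ], mat[i, ]),
                 numeric(1))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- score_pair(mat[i, ], mat[j, ])
    d <- 1 - s / min(self[i], self[j])
    D[i, j] <- D[j, i] <- max(0, d)
  }
  D
}

nj_tree <- function(D, labels) {
  dimnames(D) <- list(labels, labels)
  ape::nj(stats::as.dist(D))
}

#' Bootstrap consensus tree of aligned TMD peptides
#'
#' Resamples alignment columns with replacement, builds a neighbor-joining
#' tree per replicate from the normalized substitution-matrix distance, and
#' summarizes the replicates in a majority-rule (>50%) consensus tree with
#' bipartition supports in percent on the internal nodes. Reproducible for a
#' fixed seed (per-replicate substreams are derived deterministically).
#'
#' @param alignment A [align_tmds()] result.
#' @param replicates Bootstrap replicate count (>= 100).
#' @param seed Integer RNG seed.
#' @return Object of class `tmd_consensus`: list with `tree` (an `ape`
#'   `phylo`; `node.label` holds supports in \[0,100\], `""` for the root),
#'   `replicates`, `seed` and `star` (TRUE when the alignment carried no
#'   variable signal and the consensus is a star).
#' @export
bootstrap_consensus <- function(alignment, replicates = 1000, seed = 1) {
  stopifnot(replicates >= 100)
  mat <- alignment_matrix(alignment)
  ids <- alignment$ids
  ncol_aln <- ncol(mat)
  if (max(blosum_distance(mat)) == 0) {
    # no resolving signal at all: every pair is indistinguishable
    star_tree <- ape::stree(length(ids), type = "star", tip.label = ids)
    star_tree$node.label <- rep("", star_tree$Nnode)
    message("alignment columns carry no resolving signal; consensus is a star tree")
    return(structure(list(tree = star_tree, replicates = replicates,
                          seed = seed, star = TRUE,
                          params = list(distance = "normalized BLOSUM62, gaps as worst mismatch",
                                        method = "nj + majority-rule consensus")),
                     class = "tmd_consensus"))
  }
  trees <- vector("list", replicates)
  set.seed(seed)
  col_draws <- matrix(sample.int(ncol_aln, ncol_aln * replicates,
                                 replace = TRUE), nrow = replicates)
  for (b in seq_len(replicates)) {
    cols <- col_draws[b, ]
    D <- blosum_distance(mat[, cols, drop = FALSE])
    trees[[b]] <- nj_tree(D, ids)
  }
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5, check.labels = TRUE)
  star <- cons$Nnode <= 1
  if (!star) {
    counts <- ape::prop.clades(cons, trees, rooted = FALSE)
    counts[is.na(counts)] <- 0
    cons$node.label <- as.character(round(100 * counts / replicates, 1))
  } else {
    cons$node.label <- rep("", cons$Nnode)
    message("alignment columns carry no resolving signal; consensus is a star tree")
  }
  structure(list(tree = cons, replicates = replicates, seed = seed,
                 star = star,
                 params = list(distance = "normalized BLOSUM62, gaps as worst mismatch",
                               method = "nj + majority-rule consensus")),
            class = "tmd_consensus")
}

#' @export
print.tmd_consensus <- function(x, ...) {
  cat("<tmd_consensus> ", length(x$tree$tip.label), " TMDs, ",
      x$replicates, " bootstrap replicates",
      if (x$star) " (star: no resolved clusters)", "\n", sep = "")
  invisible(x)
}

#' Serialize a consensus tree to Newick with supports as node labels
#' @param consensus A `tmd_consensus`.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to file).
#' @export
write_consensus_newick <- function(consensus, path = NULL) {
  if (is.null(path)) {
    ape::write.tree(consensus$tree)
  } else {
    ape::write.tree(consensus$tree, file = path)
    invisible(ape::write.tree(consensus$tree))
  }
}

#' @export
plot.tmd_consensus <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  if (!x$star) ape::nodelabels(x$tree$node.label, frame = "none", adj = -0.2)
  invisible(x)
}

#' Extract high-support clusters from a consensus tree
#'
#' Returns the maximal clades whose subtending bootstrap support exceeds the
#' threshold: a clade is reported only if no ancestor clade also exceeds the
#' threshold, so the reported leaf sets are disjoint.
#'
#' @param consensus A `tmd_consensus`.
#' @param threshold Support threshold in percent (strictly exceeded).
#' @return List of character vectors of leaf ids (possibly empty).
#' @export
clusters_above <- function(consensus, threshold) {
  tree <- consensus$tree
  if (consensus$star) return(list())
  n_tip <- length(tree$tip.label)
  supports <- suppressWarnings(as.numeric(tree$node.label))
  node_ids <- n_tip + seq_len(tree$Nnode)
  # the root "clade" is the whole leaf set, not a cluster
  keep <- which(!is.na(supports) & supports > threshold &
                  node_ids != n_tip + 1L)
  if (!length(keep)) return(list())
  clades <- lapply(keep, function(i)
    sort(ape::extract.clade(tree, node_ids[i])$tip.label))
  # keep maximal clades only
  maximal <- rep(TRUE, length(clades))
  for (i in seq_along(clades)) for (j in seq_along(clades)) {
    if (i != j && maximal[i] && all(clades[[i]] %in% clades[[j]]) &&
        length(clades[[i]]) < length(clades[[j]]))
      maximal[i] <- FALSE
  }
  clades[maximal]
}
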