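search_window <- function(label, start, end) {
  structure(list(label = label, start = as.integer(start),
                 end = as.integer(end)), class = "search_window")
}

full_window <- function(len) search_window("full", 1L, len)

window_empty <- function(w) {
  is.na(w$start) || is.na(w$end) || w$start > w$end
}

#' @export
print.search_window <- function(x, ...) {
  if (window_empty(x)) cat("<search_window> ", x$label, " (empty)\n", sep = "")
  else cat("<search_window> ", x$label, " [", x$start, ",", x$end, "]\n",
           sep = "")
  invisible(x)
}

#' Length of a resolved search window in residues
#' @param w A `search_window`.
#' @return Integer (0 for an empty window).
#' @export
window_length <- function(w) {
  if (window_empty(w)) 0L else w$end - w$start + 1L
}

select_tmds <- function(annotation, tmd_policy = c("first", "all")) {
  tmd_policy <- match.arg(tmd_policy)
  if (tmd_policy == "first") annotation$tmds[1, , drop = FALSE]
  else annotation$tmds
}

#' Resolve a TMD-anchored search window to protein coordinates
#'
#' Window labels: `"full"` (whole protein); `"tmd"` (the TMD span);
#' `"tmd_plus_flank"` (`[tmd_start - k, tmd_end + k]`); `"flank_tffd_side"`
#' (the k residues abutting the TMD on the side facing the TFFD, excluding
#' the TMD itself: the left flank when the TFFD is N-terminal of the TMD,
#' the right flank when it is C-terminal). All windows are clipped to
#' `[1, seq_length]`; the clipped length, not the nominal k, is what
#' downstream enrichment denominators use. For a protein whose TMD overlaps
#' its TFFD, `flank_tffd_side` is defined-degenerate: an empty window.
#'
#' @param annotation A `domain_annotation`.
#' @param spec Window label.
#' @param k Flank size in residues (one of 5, 10, 15, 20 in the pipeline's
#'   charge analysis; any positive integer is accepted).
#' @param tmd_policy `"first"` (default) or `"all"` (see Details of
#'   [protein_has_motif()]); `resolve_window` uses the first selected TMD,
#'   `resolve_windows` returns one window per selected TMD.
#' @param seq_length Protein length for clipping; defaults to the
#'   annotation's recorded length, or no upper clipping when unknown.
#' @return A `search_window` (possibly empty).
#' @export
resolve_window <- function(annotation,
                           spec = c("full", "tmd", "tmd_plus_flank",
                                    "flank_tffd_side"),
                           k = 20, tmd_policy = "first", seq_length = NULL) {
  resolve_windows(annotation, spec, k, tmd_policy, seq_length)[[1]]
}

#' @rdname resolve_window
#' @export
resolve_windows <- function(annotation,
                            spec = c("full", "tmd", "tmd_plus_flank",
                                     "flank_tffd_side"),
                            k = 20, tmd_policy = "first", seq_length = NULL) {
  spec <- match.arg(spec)
  if (is.null(seq_length)) seq_length <- annotation$seq_length
  if (is.na(seq_length)) seq_length <- .Machine$integer.max
  if (spec == "full")
    return(list(full_window(seq_length)))
  tmds <- select_tmds(annotation, tmd_policy)
  lapply(seq_len(nrow(tmds)), function(i) {
    ts <- tmds$start[i]; te <- tmds$end[i]
    tffd <- annotation$tffd
    if (spec == "tmd") {
      search_window("tmd", max(1L, ts), min(seq_length, te))
    } else if (spec == "tmd_plus_flank") {
      search_window(sprintf("tmd_plus_flank(%d)", k),
                    max(1L, ts - k), min(seq_length, te + k))
    } else {
      label <- sprintf("flank_tffd_side(%d)", k)
      cls <- position_class(tffd, c(ts, te))
      if (cls == "overlap") {
        search_window(label, 1L, 0L)  # empty: no flank exists
      } else if (cls == "C") {
        # TFFD N-terminal of the TMD: left flank
        search_window(label, max(1L, ts - k), ts - 1L)
      } else {
        # TFFD C-terminal of the TMD: right flank
        search_window(label, te + 1L, min(seq_length, te + k))
      }
    }
  })
}

position_class <- function(tffd, tmd) {
  if (tmd[1] > tffd[2]) "C"
  else if (tmd[2] < tffd[1]) "N"
  else "overlap"
}

#' Lysine/arginine counts in the TMD and its TFFD-side flanks
#'
#' Counts K and R exactly, per window: inside the TMD, and inside each
#' `flank_tffd_side(k)` window for the requested flank sizes. Windows are
#' clipped at sequence termini and the clipped lengths are recorded, since
#' they are the sampling frame for residue-level enrichment.
#'
#' @param record Protein record (one-row `protein_set`).
#' @param annotation A `domain_annotation`.
#' @param ks Flank window sizes (default `c(5, 10, 15, 20)`).
#' @param tmd_policy TMD selection policy (default `"first"`).
#' @return Object of class `charge_profile`: a data frame with one row per
#'   window (`tmd`, then `flank_tffd_side(k)` for each k) and columns
#'   `window`, `start`, `end`, `width`, `K`, `R`.
#' @export
charge_profile <- function(record, annotation, ks = c(5, 10, 15, 20),
                           tmd_policy = "first") {
  len <- nchar(record$sequence)
  wins <- c(resolve_windows(annotation, "tmd", tmd_policy = tmd_policy,
                            seq_length = len)[1],
            lapply(ks, function(k)
              resolve_windows(annotation, "flank_tffd_side", k = k,
                              tmd_policy = tmd_policy, seq_length = len)[[1]]))
  count_res <- function(w, res) {
    if (window_empty(w)) return(0L)
    chars <- strsplit(substr(record$sequence, w$start, w$end), "")[[1]]
    sum(chars == res)
  }
  out <- data.frame(
    window = vapply(wins, `[[`, character(1), "label"),
    start = vapply(wins, function(w) if (window_empty(w)) NA_integer_ else
      w$start, integer(1)),
    end = vapply(wins, function(w) if (window_empty(w)) NA_integer_ else
      w$end, integer(1)),
    width = vapply(wins, window_length, integer(1)),
    K = vapply(wins, count_res, integer(1), res = "K"),
    R = vapply(wins, count_res, integer(1), res = "R"),
    stringsAsFactors = FALSE)
  attr(out, "protein_id") <- record$id
  class(out) <- c("charge_profile", "data.frame")
  out
}

#' Find helix-destabilization motifs inside the TMD
#'
#' Scans the helix-breaker catalog (NP, NxxP, PxxP, GxxN, PxxN, PN, GA) in
#' the TMD window only, in both forward and reverse orientation (the
#' orientation of the protease relative to the substrate is not fixed), and
#' deduplicates hits by motif and span.
#'
#' @param record Protein record.
#' @param annotation A `domain_annotation`.
#' @param catalog Motif catalog (default [motif_catalog()]); only
#'   helix-destabilizing entries are scanned.
#' @param tmd_policy TMD selection policy.
#' @return Data frame of hits (see [scan_window()]).
#' @export
find_helix_breakers <- function(record, annotation, catalog = motif_catalog(),
                                tmd_policy = "first") {
  helix <- Filter(function(p) p$category == "helix_destabilizing", catalog)
  len <- nchar(record$sequence)
  wins <- resolve_windows(annotation, "tmd", tmd_policy = tmd_policy,
                          seq_length = len)
  hits <- list()
  for (w in wins) for (p in helix) for (ori in c("forward", "reverse"))
    hits[[length(hits) + 1L]] <- scan_window(record, p, w, ori)
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits)) return(empty_hits())
  hits[!duplicated(hits[, c("motif_name", "start", "end")]), , drop = FALSE]
}

#' Classify TMD position and infer the membrane side of the TFFD
#'
#' The TMD-position class is `C` when the TMD lies C-terminal of the TFFD,
#' `N` when N-terminal, `overlap` otherwise. Combined with the type-I/II
#' topology call (type I: C-terminus cytosolic; type II: N-terminus
#' cytosolic) this fixes the membrane side of the TFFD: cytosolic for (C,
#' II) or (N, I); luminal for (C, I) or (N, II); `NA` when the topology is
#' unknown or the domains overlap.
#'
#' @param annotation A `domain_annotation`.
#' @param tmd_policy TMD selection policy (default `"first"`: the
#'   first-listed TMD determines the call).
#' @return List of class `topology_class` with `protein_id`,
#'   `position_class`, `topology`, `tffd_side`.
#' @export
classify_topology <- function(annotation, tmd_policy = "first") {
  tmd <- select_tmds(annotation, tmd_policy)[1, ]
  cls <- position_class(annotation$tffd, c(tmd$start, tmd$end))
  topo <- tmd$topology
  side <- if (cls == "overlap" || is.na(topo)) NA_character_
  else if ((cls == "C" && topo == "II") || (cls == "N" && topo == "I"))
    "cytosolic"
  else "luminal"
  structure(list(protein_id = annotation$protein_id, position_class = cls,
                 topology = if (is.na(topo)) NA_character_ else topo,
                 tffd_side = side),
            class = "topology_class")
}

#' @export
print.topology_class <- function(x, ...) {
  cat("<topology_class> ", x$protein_id, ": TMD ", x$position_class,
      "-terminal of TFFD, type ",
      if (is.na(x$topology)) "?" else x$topology, ", TFFD ",
      if (is.na(x$tffd_side)) "side unknown" else x$tffd_side, "\n", sep = "")
  invisible(x)
}

between_interval <- function(tffd, tmd) {
  # open interval strictly between the two domains; NULL if none exists
  cls <- position_class(tffd, tmd)
  if (cls == "C") {
    lo <- tffd[2] + 1L; hi <- tmd[1] - 1L
  } else if (cls == "N") {
    lo <- tmd[2] + 1L; hi <- tffd[1] - 1L
  } else return(NULL)
  if (lo > hi) return(NULL)
  c(lo, hi)
}

#' PTMs located strictly between the TFFD and the TMD
#'
#' Returns the PTM records whose (known) position lies strictly between the
#' TFFD span and the TMD span, on whichever side that interval exists.
#' Boundary residues belong to their domains. Overlap-class proteins have no
#' such interval and yield an empty result.
#'
#' @param annotation A `domain_annotation`.
#' @param tmd_policy TMD selection policy.
#' @return Data frame with columns `kind`, `position` (subset of the
#'   annotation's PTM table).
#' @export
ptm_between_tffd_and_tmd <- function(annotation, tmd_policy = "first") {
  tmd <- select_tmds(annotation, tmd_policy)[1, ]
  iv <- between_interval(annotation$tffd, c(tmd$start, tmd$end))
  ptms <- annotation$ptms
  if (is.null(iv) || !nrow(ptms))
    return(ptms[0, , drop = FALSE])
  keep <- !is.na(ptms$position) & ptms$position >= iv[1] & ptms$position <= iv[2]
  ptms[keep, , drop = FALSE]
}

#' Flag a RIP-consistent proteolytic N-terminus
#'
#' A proteolytic N-terminus (from N-terminomics) is consistent with
#' regulated intramembrane proteolysis when it lies on the TFFD side of the
#' TMD within `proximity` residues of the TMD boundary (default 41, the
#' distance at which such an N-terminus was observed for ANAC028).
#'
#' @param annotation A `domain_annotation`.
#' @param proximity Maximum distance in residues from the TMD boundary.
#' @param tmd_policy TMD selection policy.
#' @return Logical scalar.
#' @export
proteolytic_nterm_near_tmd <- function(annotation, proximity = 41,
                                       tmd_policy = "first") {
  ptms <- annotation$ptms
  nt <- ptms[ptms$kind == "proteolytic N-terminus" & !is.na(ptms$position), ,
             drop = FALSE]
  if (!nrow(nt)) return(FALSE)
  tmd <- select_tmds(annotation, tmd_policy)[1, ]
  cls <- position_class(annotation$tffd, c(tmd$start, tmd$end))
  if (cls == "overlap") return(FALSE)
  if (cls == "C") {
    any(nt$position < tmd$start & tmd$start - nt$position <= proximity)
  } else {
    any(nt$position > tmd$end & nt$position - tmd$end <= proximity)
  }
}

#' Per-protein feature table for a cohort
#'
#' Convenience wrapper producing one row per protein x window x feature with
#' counts and hit flags, suitable for TSV export.
#'
#' @param records `protein_set` for the cohort.
#' @param annotations Named list of `domain_annotation`s.
#' @param catalog Motif catalog.
#' @param ks Charge-window sizes.
#' @return Data frame with columns `protein_id`, `feature`, `window`,
#'   `value` (count or 0/1 flag).
#' @export
feature_table <- function(records, annotations, catalog = motif_catalog(),
                          ks = c(5, 10, 15, 20)) {
  rows <- list()
  for (id in names(annotations)) {
    ann <- annotations[[id]]
    if (!id %in% records$id) next
    rec <- get_record(records, id)
    cp <- charge_profile(rec, ann, ks = ks)
    for (i in seq_len(nrow(cp)))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, feature = "KR_count", window = cp$window[i],
        value = cp$K[i] + cp$R[i], stringsAsFactors = FALSE)
    for (p in catalog) {
      oris <- attr(p, "orientations")
      hit <- protein_has_motif(rec, ann, p,
                               windows = c("tmd", "tmd_plus_flank"),
                               orientations = oris)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, feature = p$name, window = "tmd_plus_flank(20)",
        value = as.integer(hit), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
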