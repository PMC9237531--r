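#' Upper-tail hypergeometric probability
#'
#' P(X >= k) when drawing `n` items without replacement from a background of
#' `N` items of which `K` carry the feature. This is the one-sided
#' overrepresentation test used throughout the pipeline.
#'
#' @param k Observed feature-positive count in the sample.
#' @param n Sample size.
#' @param K Feature-positive count in the background.
#' @param N Background size.
#' @return Probability in \[0, 1\].
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  stopifnot(k >= 0, k <= n, n <= N, K >= 0, K <= N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fold enrichment of a sample rate over a background proportion
#'
#' @param k Feature-positive count in the sample.
#' @param n Sample size (> 0).
#' @param background_proportion Background feature rate (> 0).
#' @return `(k/n) / background_proportion`.
#' @export
fold_enrichment <- function(k, n, background_proportion) {
  stopifnot(n > 0)
  if (background_proportion <= 0)
    stop("fold enrichment undefined for background proportion <= 0")
  (k / n) / background_proportion
}

#' Bonferroni correction
#'
#' Multiplies each raw p-value by the family size and caps at 1. The family
#' size may exceed the number of p-values supplied (tests skipped for empty
#' windows still count toward the family).
#'
#' @param p_values Numeric vector of raw p-values.
#' @param family_size Number of hypotheses in the family (defaults to
#'   `length(p_values)`).
#' @return Adjusted p-values, order preserved.
#' @export
bonferroni <- function(p_values, family_size = length(p_values)) {
  stopifnot(family_size >= length(p_values))
  pmin(1, p_values * family_size)
}

enrichment_result <- function(feature, window, k, n, K, N, p_raw,
                              p_adjusted = p_raw, background = NA_character_,
                              mode = "hypergeometric") {
  fold <- if (!is.na(K) && !is.na(N) && n > 0 && N > 0 && K > 0)
    (k / n) / (K / N) else NA_real_
  out <- data.frame(feature = feature, window = window, k = k, n = n,
                    K = K, N = N, fold = fold, p_raw = p_raw,
                    p_adjusted = p_adjusted, background = background,
                    mode = mode, stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>\n")
  y <- as.data.frame(x)
  y$fold <- round(y$fold, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Protein-level presence/absence enrichment of a feature
#'
#' Computes the feature on every sample protein and every background
#' protein, then tests overrepresentation of feature-positive proteins in
#' the sample with the upper-tail hypergeometric test. The sampling frame
#' treats the background set as the urn. When the requested window is
#' TMD-anchored, the background must carry TMD spans (a membrane-proteome
#' background); requesting such a window against a TMD-less background is a
#' configuration error.
#'
#' @param sample_records `protein_set` of the sample cohort.
#' @param sample_annotations Named list of `domain_annotation`s for the
#'   sample (may be `NULL` for full-sequence features).
#' @param background A [background_set()].
#' @param feature Predicate `function(record, annotation)` returning a
#'   logical; for background proteome entries `annotation` is `NULL`, for
#'   membrane-proteome entries it is a minimal annotation carrying the TMD
#'   spans.
#' @param window_label Label recorded in the result (documentation only; the
#'   predicate itself decides where it looks).
#' @param tmd_needed Set `TRUE` when the predicate uses TMD-anchored windows,
#'   to enforce the background contract.
#' @param feature_name Label for the result row.
#' @return An `enrichment_result` (one row) echoing k, n, K, N.
#' @export
protein_level_enrichment <- function(sample_records, sample_annotations,
                                     background, feature,
                                     window_label = "full",
                                     tmd_needed = FALSE,
                                     feature_name = "feature") {
  if (tmd_needed && background$label != "membrane_proteome")
    stop("TMD-anchored windows need a membrane_proteome background with TMD spans")
  sample_flags <- vapply(seq_len(nrow(sample_records)), function(i) {
    rec <- sample_records[i, , drop = FALSE]
    ann <- if (is.null(sample_annotations)) NULL else
      sample_annotations[[rec$id]]
    isTRUE(feature(rec, ann))
  }, logical(1))
  bg_flags <- vapply(seq_len(nrow(background$records)), function(i) {
    rec <- background$records[i, , drop = FALSE]
    ann <- NULL
    if (!is.null(background$tmds) && !is.null(background$tmds[[rec$id]])) {
      spans <- background$tmds[[rec$id]]
      ann <- suppressWarnings(annotation(
        rec$id, tffd = c(1L, 1L), tmds = spans, seq_length = rec$length))
    }
    isTRUE(feature(rec, ann))
  }, logical(1))
  k <- sum(sample_flags); n <- length(sample_flags)
  K <- sum(bg_flags); N <- length(bg_flags)
  # the urn is the background; when the sample is disjoint from it, pool the
  # sample into the urn so the draw is well defined
  if (!all(sample_records$id %in% background$records$id)) {
    K_urn <- K + k; N_urn <- N + n
  } else {
    K_urn <- K; N_urn <- N
  }
  p <- hypergeom_upper_tail(k, n, K_urn, N_urn)
  enrichment_result(feature_name, window_label, k, n, K, N, p_raw = p,
                    background = background$label)
}

#' Residue-level K/R enrichment of one charge window
#'
#' Tests whether the lysine+arginine count of a protein's window is higher
#' than expected from the background residue composition: `k` = K+R in the
#' window, `n` = clipped window length, `K` = K+R residues in the background
#' scope, `N` = total residues in the background scope. The Bonferroni
#' family defaults to (proteins tested) x (window sizes) and must be passed
#' in by the caller orchestrating the cohort.
#'
#' @param profile A [charge_profile()].
#' @param window Window label present in the profile (e.g.
#'   `"flank_tffd_side(15)"` or `"tmd"`).
#' @param background_K K+R residue count in the background scope.
#' @param background_N Total residue count in the background scope.
#' @param family_size Bonferroni family size (default 1, i.e. no
#'   correction).
#' @param background Background label for the result.
#' @return An `enrichment_result`, or `NULL` with a message when the window
#'   is empty (the test is skipped; it still counts toward the family).
#' @export
residue_level_enrichment <- function(profile, window, background_K,
                                     background_N, family_size = 1,
                                     background = NA_character_) {
  row <- profile[profile$window == window, , drop = FALSE]
  if (!nrow(row)) stop("window '", window, "' not in profile")
  n <- row$width[1]
  if (n == 0) {
    message(attr(profile, "protein_id"), ": window '", window,
            "' is empty after clipping; test skipped")
    return(NULL)
  }
  k <- row$K[1] + row$R[1]
  p <- hypergeom_upper_tail(k, n, background_K, background_N)
  enrichment_result("KR", window, k, n, background_K, background_N,
                    p_raw = p, p_adjusted = bonferroni(p, family_size),
                    background = background)
}

#' Proportion-mode binomial enrichment
#'
#' When only a background proportion is known (e.g. a printed 50% membrane
#' background rate) the finite-urn counts are unavailable; the test falls
#' back to an upper-tail binomial with that proportion, and the fold uses
#' the proportion directly. Results are flagged `mode = "proportion"`.
#'
#' @param k Feature-positive count in the sample.
#' @param n Sample size.
#' @param background_proportion Background feature rate in (0, 1\].
#' @param feature_name,window_label,background Labels for the result.
#' @return An `enrichment_result`.
#' @export
proportion_enrichment <- function(k, n, background_proportion,
                                  feature_name = "feature",
                                  window_label = "full",
                                  background = NA_character_) {
  stopifnot(n > 0, background_proportion > 0, background_proportion <= 1)
  p <- pbinom(k - 1, n, background_proportion, lower.tail = FALSE)
  out <- enrichment_result(feature_name, window_label, k, n,
                           K = NA_integer_, N = NA_integer_, p_raw = p,
                           background = background, mode = "proportion")
  out$fold <- fold_enrichment(k, n, background_proportion)
  out
}

#' Cohort-wide residue-level K/R enrichment
#'
#' Runs [residue_level_enrichment()] for every protein and every requested
#' charge window against a common background scope, with a Bonferroni family
#' of (number of proteins) x (number of windows) per the most conservative
#' reading of a per-feature family.
#'
#' @param records `protein_set` of the cohort.
#' @param annotations Named list of `domain_annotation`s.
#' @param background_K,background_N Background K+R and total residue counts.
#' @param windows Window labels to test (default the TMD-side flanks at
#'   k = 5, 10, 15, 20).
#' @param background Background label.
#' @return Data frame of stacked `enrichment_result` rows with a
#'   `protein_id` column; skipped (empty) windows are absent but counted in
#'   the family.
#' @export
cohort_charge_enrichment <- function(records, annotations, background_K,
                                     background_N,
                                     windows = sprintf("flank_tffd_side(%d)",
                                                       c(5, 10, 15, 20)),
                                     background = NA_character_) {
  ids <- intersect(names(annotations), records$id)
  family <- length(ids) * length(windows)
  rows <- list()
  for (id in ids) {
    prof <- charge_profile(get_record(records, id), annotations[[id]])
    for (w in windows) {
      res <- suppressMessages(residue_level_enrichment(
        prof, w, background_K, background_N, family_size = family,
        background = background))
      if (!is.null(res)) {
        res$protein_id <- id
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "family_size") <- family
  out
}

#' K+R and total residue counts of a background scope
#'
#' For a whole-proteome background, counts residues over the full sequences;
#' for a membrane-proteome background, counts within the TFFD-side-agnostic
#' TMD-flanking scope: each protein's TMD spans extended by `k` residues on
#' both sides (clipped), excluding the TMD itself when `flanks_only`.
#'
#' @param background A [background_set()].
#' @param scope `"full"` or `"tmd_flank"`.
#' @param k Flank size for the `tmd_flank` scope.
#' @param flanks_only Exclude the TMD interior from the flank scope.
#' @return Named integer vector `c(K = <K+R residues>, N = <residues>)`.
#' @export
background_residue_counts <- function(background,
                                      scope = c("full", "tmd_flank"),
                                      k = 20, flanks_only = TRUE) {
  scope <- match.arg(scope)
  total <- 0L; kr <- 0L
  for (i in seq_len(nrow(background$records))) {
    rec <- background$records[i, , drop = FALSE]
    if (scope == "full") {
      segs <- rec$sequence
    } else {
      spans <- background$tmds[[rec$id]]
      if (is.null(spans)) next
      segs <- character()
      for (j in seq_len(nrow(spans))) {
        lo <- max(1L, spans$start[j] - k); hi <- min(rec$length, spans$end[j] + k)
        if (flanks_only) {
          if (lo <= spans$start[j] - 1L)
            segs <- c(segs, substr(rec$sequence, lo, spans$start[j] - 1L))
          if (spans$end[j] + 1L <= hi)
            segs <- c(segs, substr(rec$sequence, spans$end[j] + 1L, hi))
        } else {
          segs <- c(segs, substr(rec$sequence, lo, hi))
        }
      }
    }
    for (s in segs) {
      total <- total + nchar(s)
      chars <- strsplit(s, "")[[1]]
      kr <- kr + sum(chars %in% c("K", "R"))
    }
  }
  c(K = kr, N = total)
}
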