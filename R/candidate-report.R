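RIP_FLAGS <- c("s1p_site_exact", "s1p_site_degenerate", "rhomboid_site",
               "pan_rhomboid_site", "helix_breaker_in_tmd", "kr_in_tmd",
               "kr_flank_enriched", "ptm_between_domains",
               "proteolytic_nterm_near_tmd", "tffd_cytosolic", "nls_present",
               "alt_transcript_lacking_tmd")

#' Assign the evidence tier of a candidate report
#'
#' The tier is a pure function of the evidence flags. The decision table
#' (configurable through the `rules` argument) is:
#' \itemize{
#'   \item `RIP-candidate`: cytosolic TFFD and (a protease-site flag, or a
#'     helix breaker in the TMD together with charged residues in or next to
#'     the TMD);
#'   \item `RIP-possible`: any single RIP-consistent flag (including the
#'     case where topology is unknown, which caps the tier here);
#'   \item `splicing-candidate`: a TMD-lacking alternative transcript with no
#'     RIP-consistent evidence at all — the alternative-transcript route is
#'     the fallback explanation when nothing points at proteolysis;
#'   \item `uninformative`: otherwise.
#' }
#' This precedence (proteolysis evidence before the splicing fallback) keeps
#' tier assignment monotone: adding evidence never demotes a protein.
#' Protease-site flags are the exact S1P site, the degenerate S1P site and
#' the rhomboid site; the pan-rhomboid consensus is too degenerate to count
#' (it matches most membrane proteins) and is reported but never drives the
#' tier. NLS presence is reported, not used as a veto.
#'
#' @param flags Named logical vector over (a subset of) the flag set; `NA`
#'   is treated as `FALSE` except for `tffd_cytosolic`, where `NA` means
#'   unknown topology and caps the tier at `RIP-possible`.
#' @return One of `"RIP-candidate"`, `"RIP-possible"`,
#'   `"splicing-candidate"`, `"uninformative"`.
#' @export
assign_tier <- function(flags) {
  get <- function(name) isTRUE(flags[[name]])
  cytosolic_known <- !is.null(flags[["tffd_cytosolic"]]) &&
    !is.na(flags[["tffd_cytosolic"]])
  protease_site <- get("s1p_site_exact") || get("s1p_site_degenerate") ||
    get("rhomboid_site")
  structural <- get("helix_breaker_in_tmd") &&
    (get("kr_in_tmd") || get("kr_flank_enriched"))
  rip_consistent <- protease_site || get("helix_breaker_in_tmd") ||
    get("kr_in_tmd") || get("kr_flank_enriched") ||
    get("ptm_between_domains") || get("proteolytic_nterm_near_tmd")
  if (cytosolic_known && get("tffd_cytosolic") && (protease_site || structural))
    return("RIP-candidate")
  if (rip_consistent) return("RIP-possible")
  if (get("alt_transcript_lacking_tmd")) return("splicing-candidate")
  "uninformative"
}

#' Build a per-protein RIP candidate report
#'
#' Integrates motif, structural, topological and PTM evidence for one
#' protein into a flag vector with provenance and an evidence tier (see
#' [assign_tier()]). Proteins whose TMD overlaps the TFFD carry no
#' TMD-anchored evidence (they are excluded from feature scans) and can only
#' be splicing candidates or uninformative.
#'
#' @param record Protein record (one-row `protein_set`), or `NULL` when only
#'   annotation-level evidence is available (sequence-dependent flags are
#'   then taken from the annotation's helix/K-R columns).
#' @param annotation A `domain_annotation`.
#' @param catalog Motif catalog (default [motif_catalog()]).
#' @param kr_flank_enrichment Optional row subset of
#'   [cohort_charge_enrichment()] output for this protein (drives
#'   `kr_flank_enriched`).
#' @param tmd_policy TMD selection policy.
#' @return Object of class `candidate_report`: list with `protein_id`,
#'   `flags` (named logical), `tier`, `provenance` (list of per-flag
#'   evidence: hits, windows, adjusted p).
#' @export
build_report <- function(record, annotation, catalog = motif_catalog(),
                         kr_flank_enrichment = NULL, tmd_policy = "first") {
  topo <- classify_topology(annotation, tmd_policy)
  overlap <- topo$position_class == "overlap"
  flags <- setNames(rep(FALSE, length(RIP_FLAGS)), RIP_FLAGS)
  prov <- list()

  flags["tffd_cytosolic"] <- if (is.na(topo$tffd_side)) NA else
    topo$tffd_side == "cytosolic"
  prov$tffd_cytosolic <- topo
  flags["nls_present"] <- isTRUE(annotation$nls)
  flags["alt_transcript_lacking_tmd"] <-
    !is.na(annotation$n_alt_transcripts) && annotation$n_alt_transcripts > 0

  if (is.null(record)) {
    # annotation-only mode: the inventory's helix/K-R columns are transcribed
    # evidence and count even when the printed spans marginally overlap
    tmds <- annotation$tmds
    flags["helix_breaker_in_tmd"] <- any(!is.na(tmds$helix_motif))
    prov$helix_breaker_in_tmd <- tmds$helix_motif
    kr <- parse_kr(tmds$kr_tmd)
    flags["kr_in_tmd"] <- any(rowSums(kr) > 0, na.rm = TRUE)
    prov$kr_in_tmd <- tmds$kr_tmd
  }

  if (!overlap) {
    if (!is.null(record)) {
      scan_in <- function(pat_name, windows) {
        p <- catalog[[pat_name]]
        hits <- list()
        for (wlab in windows)
          for (w in resolve_windows(annotation, wlab, k = 20,
                                    tmd_policy = tmd_policy,
                                    seq_length = nchar(record$sequence)))
            for (ori in attr(p, "orientations"))
              hits[[length(hits) + 1L]] <- scan_window(record, p, w, ori)
        do.call(rbind, hits)
      }
      wins <- c("tmd", "tmd_plus_flank")
      h_exact <- scan_in("RRIL", "full")
      h_degen <- scan_in("S1P_degenerate", wins)
      h_rhom <- rbind(scan_in("rhomboid_NTL", wins),
                      scan_in("rhomboid_NTL_relaxed", wins))
      h_pan <- scan_in("pan_rhomboid", wins)
      flags["s1p_site_exact"] <- nrow(h_exact) > 0
      flags["s1p_site_degenerate"] <- nrow(h_degen) > 0
      flags["rhomboid_site"] <- nrow(h_rhom) > 0
      flags["pan_rhomboid_site"] <- nrow(h_pan) > 0
      prov$s1p_site_exact <- h_exact
      prov$s1p_site_degenerate <- h_degen
      prov$rhomboid_site <- h_rhom
      helix_hits <- find_helix_breakers(record, annotation, catalog,
                                        tmd_policy)
      flags["helix_breaker_in_tmd"] <- nrow(helix_hits) > 0
      prov$helix_breaker_in_tmd <- helix_hits
      cp <- charge_profile(record, annotation, tmd_policy = tmd_policy)
      tmd_row <- cp[cp$window == "tmd", ]
      flags["kr_in_tmd"] <- (tmd_row$K + tmd_row$R) > 0
      prov$kr_in_tmd <- cp
    }
    if (!is.null(kr_flank_enrichment) && nrow(kr_flank_enrichment)) {
      sig <- kr_flank_enrichment$p_adjusted < 0.05
      flags["kr_flank_enriched"] <- any(sig)
      prov$kr_flank_enriched <- kr_flank_enrichment[sig, , drop = FALSE]
    }
    ptms_between <- ptm_between_tffd_and_tmd(annotation, tmd_policy)
    flags["ptm_between_domains"] <- nrow(ptms_between) > 0
    prov$ptm_between_domains <- ptms_between
    flags["proteolytic_nterm_near_tmd"] <-
      proteolytic_nterm_near_tmd(annotation, tmd_policy = tmd_policy)
  }

  structure(list(protein_id = annotation$protein_id, flags = flags,
                 tier = assign_tier(flags), position_class =
                   topo$position_class, provenance = prov),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  on <- names(x$flags)[!is.na(x$flags) & x$flags]
  cat("<candidate_report> ", x$protein_id, " [", x$tier, "]\n  evidence: ",
      if (length(on)) paste(on, collapse = ", ") else "none", "\n", sep = "")
  invisible(x)
}

#' Cohort summary statistics
#'
#' Counts and percentages over a set of candidate reports and their
#' annotations: TMD-position-class distribution, topology distribution,
#' cytosolic-TFFD count, helix-breaker count, per-flag counts, tier
#' distribution. Percentages are reported to one decimal with their
#' denominators.
#'
#' @param reports List of `candidate_report`s.
#' @param annotations Named list of `domain_annotation`s (same proteins).
#' @return Data frame of class `cohort_summary` with columns `statistic`,
#'   `count`, `denominator`, `percent`.
#' @export
summarize_cohort <- function(reports, annotations) {
  n <- length(reports)
  row <- function(stat, count, denom = n) data.frame(
    statistic = stat, count = count, denominator = denom,
    percent = if (denom > 0) round(100 * count / denom, 1) else NA_real_,
    stringsAsFactors = FALSE)
  topo <- lapply(annotations, classify_topology)
  pos <- vapply(topo, `[[`, character(1), "position_class")
  side <- vapply(topo, function(t)
    if (is.na(t$tffd_side)) "unknown" else t$tffd_side, character(1))
  tt <- vapply(topo, function(t)
    if (is.na(t$topology)) "unknown" else t$topology, character(1))
  out <- list()
  for (cl in c("C", "N", "overlap"))
    out[[length(out) + 1L]] <- row(paste0("position_class_", cl),
                                   sum(pos == cl))
  for (ty in c("I", "II", "unknown"))
    out[[length(out) + 1L]] <- row(paste0("topology_", ty), sum(tt == ty))
  out[[length(out) + 1L]] <- row("tffd_cytosolic", sum(side == "cytosolic"))
  flag_mat <- if (n > 0)
    do.call(rbind, lapply(reports, function(r) r$flags)) else
    matrix(FALSE, 0, length(RIP_FLAGS), dimnames = list(NULL, RIP_FLAGS))
  for (f in RIP_FLAGS)
    out[[length(out) + 1L]] <- row(paste0("flag_", f),
                                   sum(flag_mat[, f], na.rm = TRUE))
  tiers <- vapply(reports, `[[`, character(1), "tier")
  for (tier in c("RIP-candidate", "RIP-possible", "splicing-candidate",
                 "uninformative"))
    out[[length(out) + 1L]] <- row(paste0("tier_", tier), sum(tiers == tier))
  res <- do.call(rbind, out)
  class(res) <- c("cohort_summary", "data.frame")
  res
}

#' Run the candidate pipeline over a cohort
#'
#' @param records `protein_set`, or `NULL` for annotation-only mode.
#' @param annotations Named list of `domain_annotation`s.
#' @param catalog Motif catalog.
#' @param kr_flank_enrichment Output of [cohort_charge_enrichment()]
#'   (optional).
#' @return Named list of `candidate_report`s.
#' @export
build_reports <- function(records, annotations, catalog = motif_catalog(),
                          kr_flank_enrichment = NULL) {
  out <- vector("list", length(annotations))
  names(out) <- names(annotations)
  for (id in names(annotations)) {
    rec <- if (!is.null(records) && id %in% records$id)
      get_record(records, id) else NULL
    enr <- if (!is.null(kr_flank_enrichment))
      kr_flank_enrichment[kr_flank_enrichment$protein_id == id, , drop = FALSE]
    else NULL
    out[[id]] <- build_report(rec, annotations[[id]], catalog, enr)
  }
  out
}

#' Export candidate reports as a flat table
#'
#' @param reports Named list of `candidate_report`s.
#' @return Data frame with one row per protein: `protein_id`, `tier`,
#'   `position_class` and one logical column per evidence flag.
#' @export
reports_table <- function(reports) {
  flag_mat <- do.call(rbind, lapply(reports, function(r) r$flags))
  data.frame(protein_id = vapply(reports, `[[`, character(1), "protein_id"),
             tier = vapply(reports, `[[`, character(1), "tier"),
             position_class = vapply(reports, `[[`, character(1),
                                     "position_class"),
             flag_mat, stringsAsFactors = FALSE, row.names = NULL)
}
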