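#' @importFrom stats phyper pbinom setNames
#' @importFrom utils read.delim write.table
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PTM_CODES <- c(
  ph = "phosphorylation",
  na = "N-terminal acetylation",
  nt = "proteolytic N-terminus",
  ng = "N-glycosylation",
  ac = "lysine acetylation",
  ro = "cysteine oxidation",
  sm = "SUMOylation",
  ub = "ubiquitination",
  my = "myristoylation"
)

LOCALIZATION_LABELS <- c("nuc", "ER", "PM", "Golgi", "mt", "pl", "sec", "cyt")

#' Read protein sequences from a FASTA file
#'
#' Reads amino-acid FASTA into a protein-record table. Record ids are taken
#' from the header up to the first whitespace; the remainder of the header, if
#' any, becomes the display name. Sequences are uppercased and validated
#' against the 20-letter amino-acid alphabet plus `X` (unknown residue).
#'
#' @param path Path to a FASTA file.
#' @return A data frame of class `protein_set` with columns `id`, `name`,
#'   `sequence` and `length` (one row per record; empty file gives zero rows).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  nm <- trimws(sub("^\\S+\\s*", "", headers))
  nm[nm == ""] <- ids[nm == ""]
  seqs <- toupper(as.character(aa))
  recs <- protein_set(ids, seqs, name = nm)
  recs
}

#' Construct a protein-record table
#'
#' @param id Character vector of accessions (must be unique).
#' @param sequence Character vector of amino-acid sequences.
#' @param name Optional display names (defaults to `id`).
#' @return A `protein_set` data frame with columns `id`, `name`, `sequence`,
#'   `length`.
#' @export
protein_set <- function(id, sequence, name = id) {
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id))
    stop("duplicate protein ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  sequence <- toupper(sequence)
  bad <- vapply(sequence, function(s) {
    res <- strsplit(s, "")[[1]]
    any(!res %in% c(AA20, "X"))
  }, logical(1))
  if (any(bad)) {
    off <- strsplit(sequence[bad][1], "")[[1]]
    ill <- setdiff(unique(off), c(AA20, "X"))
    stop("illegal residue(s) ", paste(ill, collapse = ","), " in record ",
         id[bad][1])
  }
  out <- data.frame(id = as.character(id), name = as.character(name),
                    sequence = sequence, length = nchar(sequence),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Write protein records to FASTA
#'
#' @param records A `protein_set` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

get_record <- function(records, id) {
  i <- match(id, records$id)
  if (is.na(i)) stop("no sequence record for protein ", id)
  records[i, , drop = FALSE]
}

#' Construct a domain annotation
#'
#' A domain annotation carries everything known about one membrane-bound
#' transcription factor apart from its sequence: the transcription factor
#' family domain (TFFD) span, one or more transmembrane-domain (TMD) spans
#' with hydrophobicity scores and type-I/II topology calls, an NLS flag,
#' subcellular localization labels, posttranslational modification records
#' and a few per-protein summary columns.
#'
#' Coordinates are 1-based and inclusive at both ends. Topology type I means
#' the C-terminus is cytosolic; type II means the N-terminus is cytosolic.
#'
#' @param protein_id Accession.
#' @param tffd Length-2 integer vector `(start, end)`.
#' @param tmds Data frame with columns `start`, `end` and optionally `score`
#'   (mean hydrophobicity in \[0,1\] or `NA`), `topology` (`"I"`, `"II"` or
#'   `NA`), `helix_motif` (bracketed motif annotation or `NA`), `kr_tmd`,
#'   `kr_flank` (compact K/R count strings such as `"K3R1"`, or `NA`).
#' @param name Display name.
#' @param nls `TRUE`, `FALSE` or `NA` (unknown).
#' @param localizations Character vector of localization labels (subset of
#'   nuc, ER, PM, Golgi, mt, pl, sec, cyt).
#' @param ptms Data frame with columns `kind` (long PTM names, see
#'   [ptm_kinds()]) and `position` (residue index or `NA`).
#' @param n_alt_transcripts Number of annotated TMD-lacking alternative
#'   transcripts (`NA` if none reported).
#' @param seq_length Protein length if known, for bounds validation.
#' @return An object of class `domain_annotation`.
#' @export
annotation <- function(protein_id, tffd, tmds, name = protein_id, nls = NA,
                       localizations = character(), ptms = NULL,
                       n_alt_transcripts = NA_integer_, seq_length = NA_integer_) {
  tmds <- as.data.frame(tmds, stringsAsFactors = FALSE)
  for (col in c("score", "topology", "helix_motif", "kr_tmd", "kr_flank"))
    if (is.null(tmds[[col]])) tmds[[col]] <- rep(NA, nrow(tmds))
  if (is.null(ptms))
    ptms <- data.frame(kind = character(), position = integer(),
                       stringsAsFactors = FALSE)
  obj <- structure(list(
    protein_id = protein_id, name = name,
    tffd = as.integer(tffd), tmds = tmds, nls = nls,
    localizations = localizations, ptms = ptms,
    n_alt_transcripts = as.integer(n_alt_transcripts),
    seq_length = as.integer(seq_length)
  ), class = "domain_annotation")
  validate_annotation(obj)
  obj
}

validate_annotation <- function(x) {
  if (length(x$tffd) != 2 || any(is.na(x$tffd)))
    stop(x$protein_id, ": TFFD span must be two known coordinates")
  if (x$tffd[1] > x$tffd[2])
    stop(x$protein_id, ": TFFD start > end (", x$tffd[1], "-", x$tffd[2], ")")
  if (nrow(x$tmds) < 1)
    stop(x$protein_id, ": an MB-TF annotation needs at least one TMD span")
  if (any(x$tmds$start > x$tmds$end))
    stop(x$protein_id, ": TMD start > end")
  if (any(x$tffd < 1) || any(x$tmds$start < 1))
    stop(x$protein_id, ": spans are 1-based; coordinates must be >= 1")
  len <- x$tmds$end - x$tmds$start + 1L
  if (any(len < 12 | len > 40))
    warning(x$protein_id, ": TMD length ", paste(len[len < 12 | len > 40],
            collapse = ","), " outside the typical 12-40 residue range")
  if (!is.na(x$seq_length)) {
    if (x$tffd[2] > x$seq_length || any(x$tmds$end > x$seq_length))
      stop(x$protein_id, ": span exceeds sequence length ", x$seq_length)
    if (nrow(x$ptms) && any(!is.na(x$ptms$position) &
        (x$ptms$position < 1 | x$ptms$position > x$seq_length)))
      stop(x$protein_id, ": PTM position outside [1, length]")
  }
  bad_topo <- !is.na(x$tmds$topology) & !x$tmds$topology %in% c("I", "II")
  if (any(bad_topo)) stop(x$protein_id, ": topology must be I, II or NA")
  bad_loc <- setdiff(x$localizations, LOCALIZATION_LABELS)
  if (length(bad_loc))
    stop(x$protein_id, ": unknown localization label(s) ",
         paste(bad_loc, collapse = ","))
  invisible(x)
}

#' @export
print.domain_annotation <- function(x, ...) {
  cat("<domain_annotation> ", x$protein_id,
      "  TFFD ", x$tffd[1], "-", x$tffd[2],
      "  TMDs: ", paste(sprintf("%d-%d(%s)", x$tmds$start, x$tmds$end,
                                ifelse(is.na(x$tmds$topology), "?",
                                       x$tmds$topology)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' PTM code table
#'
#' Mapping of the compact PTM codes used in annotation tables to the long
#' modification names (ph = phosphorylation, na = N-terminal acetylation,
#' nt = proteolytic N-terminus, ng = N-glycosylation, ac = lysine acetylation,
#' ro = cysteine oxidation, sm = SUMOylation, ub = ubiquitination,
#' my = myristoylation).
#'
#' @return Named character vector, names are codes.
#' @export
ptm_kinds <- function() PTM_CODES

#' Parse a compact K/R count string
#'
#' Strings such as `"K3R1"` or `"K1"` encode lysine and arginine counts;
#' `"0"` encodes zero of both; `NA`/empty means not reported.
#'
#' @param x Character vector.
#' @return Integer matrix with columns `K` and `R` (NA rows for unreported).
#' @export
parse_kr <- function(x) {
  out <- matrix(NA_integer_, nrow = length(x), ncol = 2,
                dimnames = list(NULL, c("K", "R")))
  for (i in seq_along(x)) {
    s <- x[i]
    if (is.na(s) || s == "") next
    if (s == "0") { out[i, ] <- c(0L, 0L); next }
    k <- regmatches(s, regexec("K(\\d+)", s))[[1]]
    r <- regmatches(s, regexec("R(\\d+)", s))[[1]]
    out[i, "K"] <- if (length(k)) as.integer(k[2]) else 0L
    out[i, "R"] <- if (length(r)) as.integer(r[2]) else 0L
  }
  out
}

ANNOTATION_COLUMNS <- c("protein_id", "name", "tffd_start", "tffd_end",
  "tmd_index", "tmd_start", "tmd_end", "tmd_score", "topology", "nls",
  "localizations", "ptm_kind", "ptm_position", "helix_motif", "kr_tmd",
  "kr_flank", "n_alt_transcripts")

#' Read a domain-annotation table
#'
#' Reads the tab-separated annotation schema: one row per TMD (ordered by
#' `tmd_index`; the first row of a protein also carries the TFFD span, NLS
#' flag, localizations and alternative-transcript count) plus one row per
#' PTM instance (with `tmd_index` empty and `ptm_kind` set to a code from
#' [ptm_kinds()]).
#'
#' @param path Path to the TSV file.
#' @param sequences Optional `protein_set` used to validate span bounds.
#' @return Named list of [annotation()] objects, one per protein, in file
#'   order.
#' @export
read_annotations <- function(path, sequences = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    colClasses = "character")
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(tab))
  if (length(missing_cols))
    stop("annotation table lacks column(s): ", paste(missing_cols, collapse = ", "))
  num <- function(v) suppressWarnings(as.numeric(v))
  int <- function(v) suppressWarnings(as.integer(v))
  ids <- unique(tab$protein_id)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    rows <- tab[tab$protein_id == id, , drop = FALSE]
    tmd_rows <- rows[!is.na(rows$tmd_index), , drop = FALSE]
    tmd_rows <- tmd_rows[order(int(tmd_rows$tmd_index)), , drop = FALSE]
    ptm_rows <- rows[is.na(rows$tmd_index) & !is.na(rows$ptm_kind), , drop = FALSE]
    if (!nrow(tmd_rows)) stop(id, ": no TMD rows")
    head_row <- tmd_rows[1, ]
    locs <- if (is.na(head_row$localizations)) character() else
      strsplit(head_row$localizations, ";", fixed = TRUE)[[1]]
    kinds <- ptm_rows$ptm_kind
    unknown <- setdiff(kinds, names(PTM_CODES))
    if (length(unknown))
      stop(id, ": unknown PTM code(s) ", paste(unknown, collapse = ","))
    ptms <- data.frame(kind = unname(PTM_CODES[kinds]),
                       position = int(ptm_rows$ptm_position),
                       stringsAsFactors = FALSE)
    seq_length <- NA_integer_
    if (!is.null(sequences) && id %in% sequences$id)
      seq_length <- sequences$length[match(id, sequences$id)]
    out[[id]] <- annotation(
      protein_id = id,
      name = if (is.na(head_row$name)) id else head_row$name,
      tffd = c(int(head_row$tffd_start), int(head_row$tffd_end)),
      tmds = data.frame(
        start = int(tmd_rows$tmd_start), end = int(tmd_rows$tmd_end),
        score = num(tmd_rows$tmd_score), topology = tmd_rows$topology,
        helix_motif = tmd_rows$helix_motif, kr_tmd = tmd_rows$kr_tmd,
        kr_flank = tmd_rows$kr_flank, stringsAsFactors = FALSE),
      nls = c("TRUE" = TRUE, "FALSE" = FALSE)[toupper(head_row$nls)][[1]],
      localizations = locs,
      ptms = ptms,
      n_alt_transcripts = int(head_row$n_alt_transcripts),
      seq_length = seq_length)
  }
  out
}

#' Write domain annotations to the TSV schema read by [read_annotations()]
#'
#' @param annotations Named list of [annotation()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  rows <- list()
  code_of <- setNames(names(PTM_CODES), PTM_CODES)
  for (ann in annotations) {
    n_tmd <- nrow(ann$tmds)
    for (i in seq_len(n_tmd)) {
      first <- i == 1L
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = ann$protein_id, name = if (first) ann$name else NA,
        tffd_start = if (first) ann$tffd[1] else NA,
        tffd_end = if (first) ann$tffd[2] else NA,
        tmd_index = i, tmd_start = ann$tmds$start[i], tmd_end = ann$tmds$end[i],
        tmd_score = ann$tmds$score[i], topology = ann$tmds$topology[i],
        nls = if (first && !is.na(ann$nls)) ann$nls else NA,
        localizations = if (first && length(ann$localizations))
          paste(ann$localizations, collapse = ";") else NA,
        ptm_kind = NA, ptm_position = NA,
        helix_motif = ann$tmds$helix_motif[i], kr_tmd = ann$tmds$kr_tmd[i],
        kr_flank = ann$tmds$kr_flank[i],
        n_alt_transcripts = if (first) ann$n_alt_transcripts else NA,
        stringsAsFactors = FALSE)
    }
    if (nrow(ann$ptms)) {
      for (j in seq_len(nrow(ann$ptms))) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = ann$protein_id, name = NA, tffd_start = NA,
          tffd_end = NA, tmd_index = NA, tmd_start = NA, tmd_end = NA,
          tmd_score = NA, topology = NA, nls = NA, localizations = NA,
          ptm_kind = code_of[[ann$ptms$kind[j]]],
          ptm_position = ann$ptms$position[j],
          helix_motif = NA, kr_tmd = NA, kr_flank = NA,
          n_alt_transcripts = NA, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Load the packaged atMB-TF annotation table
#'
#' The package ships a transcription of the published inventory of
#' *Arabidopsis thaliana* membrane-bound transcription factors: 52 proteins
#' with TFFD and TMD coordinates, hydrophobicity scores, type-I/II topology
#' calls where predicted, subcellular localizations, PTM records (positions
#' unknown at this granularity), helix-breaking-motif annotations, compact
#' K/R counts for the TMD and its 20-residue flank, and counts of TMD-lacking
#' alternative transcripts. Protein sequences are not part of the fixture;
#' statistics computed from it use annotation columns only.
#'
#' @return Named list of [annotation()] objects (52 proteins).
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_annotations.tsv", package = "ripscan",
                      mustWork = TRUE)
  suppressWarnings(read_annotations(path))
}

#' Construct a background set
#'
#' @param label `"proteome"` or `"membrane_proteome"`.
#' @param records A `protein_set`.
#' @param tmds For the membrane proteome, a named list (by protein id) of
#'   data frames with `start`/`end` TMD spans; every membrane entry must have
#'   at least one span.
#' @return Object of class `background_set`.
#' @export
background_set <- function(label = c("proteome", "membrane_proteome"),
                           records, tmds = NULL) {
  label <- match.arg(label)
  if (label == "membrane_proteome") {
    if (is.null(tmds)) stop("membrane_proteome background needs TMD spans")
    n_spans <- vapply(records$id, function(id)
      if (is.null(tmds[[id]])) 0L else nrow(tmds[[id]]), integer(1))
    if (any(n_spans < 1))
      stop("membrane_proteome entries without a TMD span: ",
           paste(records$id[n_spans < 1][seq_len(min(5, sum(n_spans < 1)))],
                 collapse = ","))
  }
  structure(list(label = label, records = records, tmds = tmds),
            class = "background_set")
}

#' @export
print.background_set <- function(x, ...) {
  cat("<background_set> ", x$label, ": ", nrow(x$records), " proteins\n",
      sep = "")
  invisible(x)
}
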