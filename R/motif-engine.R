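#' Compile a degenerate motif notation into an executable pattern
#'
#' The notation used for intramembrane-protease recognition sites and
#' helix-destabilization motifs consists of literal residues, `x` for any
#' residue, `[SET]` for an allowed set, and `[^SET]` for the complement of a
#' set (any residue except those listed). Example: `"Rx[LIT][KL]"`, the
#' degenerate site-1 protease (S1P) consensus, matches an arginine, any
#' residue, then one of L/I/T and one of K/L.
#'
#' Matching semantics for the unknown residue `X`: the wildcard `x` matches
#' it, literal, set and complement tokens do not (conservative calling).
#'
#' @param notation Motif string.
#' @param name Label (defaults to the notation).
#' @param category `"protease_recognition"` or `"helix_destabilizing"`.
#' @param source Free-text provenance (e.g. "S1P", "Rho-1", "pan-rhomboid").
#' @param cleavage_offsets Optional integer vector of inter-residue cleavage
#'   positions within the match (recorded as metadata only; offset i means
#'   cleavage between matched residues i and i+1).
#' @return Object of class `motif_pattern` with fields `name`, `notation`,
#'   `tokens` (list of lists with `type` in literal/any/set/complement and
#'   `residues`), `category`, `source`, `cleavage_offsets`.
#' @export
compile_pattern <- function(notation, name = notation,
                            category = c("protease_recognition",
                                         "helix_destabilizing"),
                            source = NA_character_, cleavage_offsets = NULL) {
  category <- match.arg(category)
  chars <- strsplit(notation, "")[[1]]
  tokens <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      tokens[[length(tokens) + 1L]] <- list(type = "any", residues = NULL)
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      neg <- FALSE
      if (j <= length(chars) && chars[j] == "^") { neg <- TRUE; j <- j + 1L }
      set <- character()
      while (j <= length(chars) && chars[j] != "]") {
        if (!chars[j] %in% AA20)
          stop("parse error at column ", j, ": illegal residue '", chars[j],
               "' in set")
        set <- c(set, chars[j])
        j <- j + 1L
      }
      if (j > length(chars))
        stop("parse error at column ", i, ": unbalanced '['")
      if (!length(set))
        stop("parse error at column ", i, ": empty set")
      tokens[[length(tokens) + 1L]] <- list(
        type = if (neg) "complement" else "set", residues = set)
      i <- j + 1L
    } else if (ch %in% AA20) {
      tokens[[length(tokens) + 1L]] <- list(type = "literal", residues = ch)
      i <- i + 1L
    } else {
      stop("parse error at column ", i, ": unexpected character '", ch, "'")
    }
  }
  if (length(tokens) < 2)
    stop("motif must have at least 2 positions: ", notation)
  structure(list(name = name, notation = notation, tokens = tokens,
                 category = category, source = source,
                 cleavage_offsets = cleavage_offsets),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", x$name, " (", x$category, ", ",
      length(x$tokens), " positions)\n", sep = "")
  invisible(x)
}

#' @export
length.motif_pattern <- function(x) length(x$tokens)

token_regex <- function(tok) {
  switch(tok$type,
    any = paste0("[", paste(c(AA20, "X"), collapse = ""), "]"),
    literal = tok$residues,
    set = paste0("[", paste(tok$residues, collapse = ""), "]"),
    complement = paste0("[", paste(setdiff(AA20, tok$residues), collapse = ""),
                        "]"))
}

pattern_regex <- function(pattern, orientation = "forward") {
  toks <- pattern$tokens
  if (orientation == "reverse") toks <- rev(toks)
  paste0(vapply(toks, token_regex, character(1)), collapse = "")
}

#' Per-position match probability under i.i.d. uniform residues
#'
#' Product over tokens of (class size)/20, the analytic probability that a
#' random 20-letter peptide matches the pattern at a given position.
#'
#' @param pattern A `motif_pattern`.
#' @return Probability in \[0, 1\].
#' @export
match_probability <- function(pattern) {
  sizes <- vapply(pattern$tokens, function(tok) switch(tok$type,
    any = 20L, literal = 1L, set = length(tok$residues),
    complement = 20L - length(tok$residues)), integer(1))
  prod(sizes / 20)
}

#' The default motif catalog
#'
#' Loads the catalog of protease-recognition and helix-destabilization
#' motifs scanned by the pipeline: the exact S1P site RRIL and its degenerate
#' consensus Rx\[LIT\]\[KL\]; the rhomboid (Rho-1/Spitz-derived) sites
#' LxLSIxGA and \[LF\]xLSIxGA; the bacterial/metazoan rhomboid consensus
#' sites \[ILMF\]xx\[GAS\]\[AHS\]\[IMLF\] and \[ILMF\]x\[GAS\]\[AHS\]\[IMLF\];
#' the minimal pan-rhomboid consensus; and the helix-breaking motifs NP,
#' NxxP, PxxP, GxxN, PxxN, PN and GA. Helix motifs are flagged for scanning
#' in both orientations, protease motifs forward only.
#'
#' @param path Optional path to a catalog TSV with columns `name`,
#'   `notation`, `category`, `source`, `orientations`
#'   (`forward` or `both`); defaults to the packaged catalog.
#' @return Named list of `motif_pattern` objects; each carries an
#'   `orientations` attribute.
#' @export
motif_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "motif_catalog.tsv", package = "ripscan",
                        mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  out <- vector("list", nrow(tab))
  names(out) <- tab$name
  for (i in seq_len(nrow(tab))) {
    offs <- NULL
    if (!is.null(tab$cleavage_offsets) && !is.na(tab$cleavage_offsets[i]))
      offs <- as.integer(strsplit(tab$cleavage_offsets[i], ";")[[1]])
    p <- compile_pattern(tab$notation[i], name = tab$name[i],
                         category = tab$category[i], source = tab$source[i],
                         cleavage_offsets = offs)
    attr(p, "orientations") <- if (identical(tab$orientations[i], "both"))
      c("forward", "reverse") else "forward"
    out[[i]] <- p
  }
  out
}

empty_hits <- function() {
  data.frame(protein_id = character(), motif_name = character(),
             start = integer(), end = integer(), window_label = character(),
             orientation = character(), matched_peptide = character(),
             stringsAsFactors = FALSE)
}

#' Scan a search window of a protein for a motif
#'
#' Reports every match whose span lies entirely inside the window, including
#' overlapping matches. Reverse orientation reverses the token order of the
#' pattern (proteins have no strand complement) and scans forward.
#'
#' @param record One protein record (one-row `protein_set` or list with
#'   `id` and `sequence`).
#' @param pattern A `motif_pattern`.
#' @param window A `search_window` (see [resolve_window()]), or `NULL` for
#'   the full sequence.
#' @param orientation `"forward"` or `"reverse"`.
#' @return Data frame of hits with columns `protein_id`, `motif_name`,
#'   `start`, `end` (1-based inclusive, on the protein), `window_label`,
#'   `orientation`, `matched_peptide`.
#' @export
scan_window <- function(record, pattern, window = NULL,
                        orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  seq <- record$sequence
  len <- nchar(seq)
  if (is.null(window)) window <- full_window(len)
  if (window_empty(window)) return(empty_hits())
  if (window$start < 1 || window$end > len)
    stop("window [", window$start, ",", window$end,
         "] outside sequence of length ", len)
  sub <- substr(seq, window$start, window$end)
  L <- length(pattern$tokens)
  if (nchar(sub) < L) return(empty_hits())
  rx <- paste0("(?=", pattern_regex(pattern, orientation), ")")
  m <- gregexpr(rx, sub, perl = TRUE)[[1]]
  if (m[1] == -1) return(empty_hits())
  starts <- as.integer(m) + window$start - 1L
  ends <- starts + L - 1L
  data.frame(protein_id = record$id, motif_name = pattern$name,
             start = starts, end = ends, window_label = window$label,
             orientation = orientation,
             matched_peptide = substring(seq, starts, ends),
             stringsAsFactors = FALSE)
}

#' Presence/absence of a motif in a protein
#'
#' Collapses window scans into a single logical: `TRUE` iff the motif has at
#' least one hit across the selected windows, orientations, and all TMDs
#' under the TMD selection policy.
#'
#' @param record Protein record.
#' @param annotation A `domain_annotation`, or `NULL` when `windows` is
#'   `"full"` only.
#' @param pattern A `motif_pattern`.
#' @param windows Character vector of window labels (see [resolve_window()]):
#'   any of `"full"`, `"tmd"`, `"tmd_plus_flank"`, `"flank_tffd_side"`.
#' @param k Flank size for flank-bearing windows (default 20).
#' @param orientations Orientations to scan (default forward).
#' @param tmd_policy `"first"` (default) or `"all"`: which annotated TMD
#'   spans anchor TMD-relative windows.
#' @return Logical scalar.
#' @export
protein_has_motif <- function(record, annotation = NULL, pattern,
                              windows = "full", k = 20,
                              orientations = "forward",
                              tmd_policy = c("first", "all")) {
  tmd_policy <- match.arg(tmd_policy)
  len <- nchar(record$sequence)
  for (wlab in windows) {
    wins <- if (wlab == "full") list(full_window(len)) else
      resolve_windows(annotation, wlab, k = k, tmd_policy = tmd_policy,
                      seq_length = len)
    for (w in wins) {
      for (ori in orientations) {
        if (nrow(scan_window(record, pattern, w, ori)) > 0) return(TRUE)
      }
    }
  }
  FALSE
}
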