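# File formats: FASTA, GFF3, TSV reports, YAML threshold config.
#
# Dialect decisions (fixed, documented in the methods vignette):
#   * GFF3 is the only annotation dialect (no GTF); Parent links must resolve.
#   * All coordinates, in memory and on disk, are 1-based inclusive, the
#     GFF3 convention.
#   * Sequences are uppercased on load and U is folded to T in nucleotide
#     mode, so RNA-style morpholino sequences and DNA references share one
#     alphabet.

NT_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

#' Read a FASTA file
#'
#' Reads a (multi-record) FASTA file into a data frame of sequence records.
#' Sequences are uppercased; in nucleotide mode `U` is transliterated to `T`
#' and the alphabet is restricted to `A,C,G,T,N` (IUPAC ambiguity codes are
#' accepted when `strict = FALSE`). In protein mode the 20 amino acids plus
#' `X` and `*` are accepted.
#'
#' @param path Path to a FASTA file.
#' @param mode `"nucleotide"` or `"protein"`; controls alphabet validation
#'   and U-folding.
#' @param strict Reject IUPAC ambiguity codes other than N (nucleotide mode).
#' @return A `data.frame` with columns `id`, `description`, `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a demo", "ACGU"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, mode = c("nucleotide", "protein"), strict = FALSE) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  if (mode == "nucleotide") seqs <- chartr("U", "T", seqs)
  if (any(ids == "")) stop("empty record id in ", path)
  allowed <- if (mode == "nucleotide") {
    if (strict) NT_ALPHABET else
      c(NT_ALPHABET, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  } else AA_ALPHABET
  for (i in seq_along(seqs)) {
    if (nchar(seqs[[i]]) == 0L)
      stop("record '", ids[[i]], "' has an empty sequence")
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% allowed)
    if (length(bad))
      stop("illegal character '", ch[bad[1]], "' in record '", ids[[i]],
           "' at position ", bad[1])
  }
  data.frame(id = unname(ids), description = unname(desc),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequence records as FASTA
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `description`, as returned by [read_fasta()]; a named character vector
#'   is also accepted.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records) && !is.null(names(records)))
    records <- data.frame(id = names(records), description = "",
                          sequence = unname(records), stringsAsFactors = FALSE)
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else
    rep("", nrow(records))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

# Split one GFF3 attribute column into a named character vector.
parse_gff_attributes <- function(s) {
  if (is.na(s) || s == "." || s == "") return(character(0))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  kv <- regmatches(parts, regexpr("=", parts, fixed = TRUE), invert = TRUE)
  keys <- vapply(kv, function(x) trimws(x[[1]]), character(1))
  vals <- vapply(kv, function(x) if (length(x) > 1) x[[2]] else "", character(1))
  stats::setNames(vals, keys)
}

#' Read a GFF3 annotation file
#'
#' Parses a 9-column GFF3 file into a feature data frame. Comment and
#' directive lines (`#...`) are skipped; coordinates are kept 1-based
#' inclusive as in the file; the attribute column is split on `;` and `=`.
#' `ID`, `Parent` and `Name` are lifted into convenience columns (NA when
#' absent); the full attribute map is kept in the `attributes` list-column.
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` with columns `contig`, `source`, `ftype`, `start`,
#'   `end`, `score`, `strand`, `phase`, `id`, `parent`, `name`, `attributes`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(empty_gff())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    bad <- which(nf < 9L)[1]
    stop("GFF3 line ", lineno[bad], ": expected 9 tab-separated columns, got ",
         nf[bad])
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:9))
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end))
    stop("GFF3 line ", lineno[which(is.na(start) | is.na(end))[1]],
         ": non-integer coordinates")
  if (any(start > end))
    stop("GFF3 line ", lineno[which(start > end)[1]], ": start > end")
  if (any(!m[, 7] %in% c("+", "-", ".")))
    stop("GFF3 line ", lineno[which(!m[, 7] %in% c("+", "-", "."))[1]],
         ": strand must be +, - or .")
  attrs <- lapply(m[, 9], parse_gff_attributes)
  getattr <- function(key)
    vapply(attrs, function(a) if (key %in% names(a)) a[[key]] else NA_character_,
           character(1))
  df <- data.frame(
    contig = m[, 1], source = m[, 2], ftype = m[, 3],
    start = start, end = end, score = m[, 6], strand = m[, 7], phase = m[, 8],
    id = getattr("ID"), parent = getattr("Parent"), name = getattr("Name"),
    stringsAsFactors = FALSE)
  df$attributes <- attrs
  parents <- stats::na.omit(unique(df$parent))
  unresolved <- setdiff(parents, df$id)
  if (length(unresolved))
    stop("GFF3 Parent link(s) do not resolve: ",
         paste(unresolved, collapse = ", "))
  df
}

empty_gff <- function() {
  df <- data.frame(contig = character(0), source = character(0),
                   ftype = character(0), start = integer(0), end = integer(0),
                   score = character(0), strand = character(0),
                   phase = character(0), id = character(0),
                   parent = character(0), name = character(0),
                   stringsAsFactors = FALSE)
  df$attributes <- list()
  df
}

#' Write a feature data frame as GFF3
#'
#' Inverse of [read_gff3()]: attribute order is preserved, so a
#' read/write/read cycle reproduces the feature table exactly.
#'
#' @param features Feature data frame as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  attr_str <- vapply(features$attributes, function(a) {
    if (length(a) == 0) "." else paste(names(a), a, sep = "=", collapse = ";")
  }, character(1))
  lines <- paste(features$contig, features$source, features$ftype,
                 features$start, features$end, features$score,
                 features$strand, features$phase, attr_str, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

SCREEN_REPORT_COLS <- c("probe", "gene", "transcript", "molecule", "start",
                        "end", "orientation", "mismatches", "tm_celsius",
                        "step1_named_gene", "step2_orientation",
                        "step3_mechanism", "step4_tm_retained", "final_status")

#' Write a screening decision-trail report
#'
#' Writes one TSV row per candidate binding site with the full trail of the
#' five screening rules. Coordinates are 1-based inclusive in the named
#' molecule's coordinate system; `tm_celsius` is formatted with 2 decimals.
#'
#' @param verdicts Verdict data frame from [screen_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(verdicts, path) {
  rows <- data.frame(
    probe = verdicts$probe_id, gene = verdicts$gene_id,
    transcript = verdicts$transcript_id, molecule = verdicts$molecule,
    start = verdicts$start, end = verdicts$end,
    orientation = verdicts$orientation, mismatches = verdicts$mismatches,
    tm_celsius = sprintf("%.2f", verdicts$tm_celsius),
    step1_named_gene = verdicts$step1_named_gene,
    step2_orientation = verdicts$step2_orientation,
    step3_mechanism = verdicts$step3_mechanism,
    step4_tm_retained = verdicts$step4_tm_retained,
    final_status = verdicts$final_status,
    stringsAsFactors = FALSE)
  if (nrow(rows) == 0)
    rows <- rows[, SCREEN_REPORT_COLS, drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read back a screening report written by [write_screen_report()]
#'
#' @param path Path to a report TSV.
#' @return A data frame with the report columns; numeric and logical columns
#'   restored to their types.
#' @export
read_screen_report <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!identical(names(df), SCREEN_REPORT_COLS))
    stop("not a screen report: unexpected columns in ", path)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$mismatches <- as.integer(df$mismatches)
  df$tm_celsius <- as.numeric(df$tm_celsius)
  for (col in c("step1_named_gene", "step2_orientation", "step4_tm_retained"))
    df[[col]] <- as.logical(df[[col]])
  df
}

#' Read screening thresholds from a YAML config file
#'
#' Recognised keys: `start_window_nt`, `intron_edge_nt`, `exon_edge_nt`,
#' `tm_threshold_celsius`, `max_mismatches`, `min_perfect_run`. Missing keys
#' fall back to the defaults of [screen_config()] / [scan_params()].
#'
#' @param path Path to a YAML file.
#' @return A list with elements `screen` ([screen_config()]) and `scan`
#'   ([scan_params()]).
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  pick <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  list(
    screen = screen_config(
      start_window_nt = pick("start_window_nt", 25L),
      intron_edge_nt = pick("intron_edge_nt", 5L),
      exon_edge_nt = pick("exon_edge_nt", 2L),
      tm_threshold_celsius = pick("tm_threshold_celsius", 70)),
    scan = scan_params(
      max_mismatches = pick("max_mismatches", 5L),
      min_perfect_run = pick("min_perfect_run", 12L)))
}
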