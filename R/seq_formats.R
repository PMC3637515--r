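#' Sequence records
#'
#' A sequence record is a plain list with fields `id` (unique token),
#' `description` (free text, possibly empty) and `residues` (upper-case
#' string over the 20 canonical amino acids, optionally `X`). Collections of
#' records are unnamed lists; ids must be unique within a collection.
#'
#' @param id Non-empty identifier token.
#' @param residues Amino-acid string; upper-cased on construction.
#' @param description Optional free-text description.
#' @return A `seq_record` object.
#' @export
#' @examples
#' seq_record("a", "mkv")$residues
seq_record <- function(id, residues, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop_("sequence id must be a non-empty string")
  }
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) stop_("sequence '", id, "' is empty")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c(AA_ORDER, "X"))
  if (length(bad)) {
    stop_("sequence '", id, "': illegal character '", chars[bad[1]],
          "' at position ", bad[1])
  }
  structure(list(id = id, description = description, residues = residues),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat("<seq_record>", x$id,
      if (nzchar(x$description)) paste0("(", x$description, ")"),
      "-", nchar(x$residues), "aa\n")
  invisible(x)
}

check_unique_ids <- function(records) {
  ids <- vapply(records, `[[`, character(1), "id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop_("duplicate sequence id: '", dup[1], "'")
  ids
}

#' Read and write protein FASTA files
#'
#' `read_fasta()` parses a multi-record amino-acid FASTA file into a list of
#' [seq_record()] objects (order preserved, residues upper-cased); ids are
#' the header tokens before the first whitespace, the remainder becomes the
#' description. Duplicate ids, empty sequences and characters outside the
#' 20-letter alphabet plus `X` are errors. `write_fasta()` is its inverse.
#'
#' @param path File path.
#' @param records List of [seq_record()] objects.
#' @param width Line-wrap width for output.
#' @return `read_fasta()` returns a list of `seq_record`s; `write_fasta()`
#'   returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) stop_("no sequences in ", path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  records <- lapply(seq_along(aa), function(i) {
    seq_record(ids[i], as.character(aa[[i]]), desc[i])
  })
  check_unique_ids(records)
  records
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path, width = 70L) {
  check_unique_ids(records)
  lines <- unlist(lapply(records, function(r) {
    header <- paste0(">", r$id,
                     if (nzchar(r$description)) paste0(" ", r$description))
    body <- substring(r$residues,
                      seq(1L, nchar(r$residues), by = width),
                      pmin(seq(1L, nchar(r$residues), by = width) + width - 1L,
                           nchar(r$residues)))
    c(header, body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Domain-boundary tables and domain extraction
#'
#' Boundary tables are TSV files with a header line `id<TAB>start<TAB>end`
#' giving, per row, a region of a parent sequence in 0-based half-open
#' coordinates (`start` inclusive, `end` exclusive). `extract_domains()`
#' slices the referenced regions out of a record collection, one
#' `domain_region` per row, each holding `parent_id`, `start`, `end` and the
#' sliced `residues`.
#'
#' @param records List of [seq_record()]s.
#' @param boundaries Data frame with columns `id`, `start`, `end`.
#' @param path TSV file path.
#' @return `extract_domains()` returns a list of `domain_region` objects.
#' @export
#' @examples
#' recs <- list(seq_record("s1", "MKVLA"))
#' extract_domains(recs, data.frame(id = "s1", start = 1, end = 4))[[1]]$residues
extract_domains <- function(records, boundaries) {
  stopifnot(is.data.frame(boundaries))
  if (!all(c("id", "start", "end") %in% names(boundaries))) {
    stop_("boundary table needs columns id, start, end")
  }
  ids <- check_unique_ids(records)
  lapply(seq_len(nrow(boundaries)), function(i) {
    row <- boundaries[i, ]
    k <- match(row$id, ids)
    if (is.na(k)) stop_("boundary row ", i, ": unknown sequence id '",
                        row$id, "'")
    parent <- records[[k]]
    len <- nchar(parent$residues)
    s <- as.integer(row$start); e <- as.integer(row$end)
    if (is.na(s) || is.na(e) || s < 0L || s >= e || e > len) {
      stop_("boundary row ", i, " (", row$id, "): coordinates [", row$start,
            ", ", row$end, ") out of range for length ", len)
    }
    structure(list(parent_id = parent$id, start = s, end = e,
                   residues = substr(parent$residues, s + 1L, e)),
              class = "domain_region")
  })
}

#' @rdname extract_domains
#' @export
read_boundary_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("id", "start", "end") %in% names(df))) {
    stop_("boundary table ", path, " needs header id<TAB>start<TAB>end")
  }
  df[c("id", "start", "end")]
}

#' @rdname extract_domains
#' @param x Data frame of boundaries to write.
#' @export
write_boundary_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# 0-based half-open coordinates: [start, end)", con)
  utils::write.table(x[c("id", "start", "end")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Convert a domain_region (or seq_record) to a seq_record usable as a
# profile seed.
as_seq_record <- function(x, id = NULL) {
  if (inherits(x, "seq_record")) return(x)
  if (inherits(x, "domain_region")) {
    return(seq_record(id %||% x$parent_id, x$residues))
  }
  stop_("cannot interpret object of class ", class(x)[1], " as a sequence")
}
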