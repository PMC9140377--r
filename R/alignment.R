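# Coding alignments: aligned nucleotide records plus an annotation of coding
# intervals. Coordinates are 0-based half-open; `frame` is the offset of codon
# position 1 within the interval; strand is forward only.

#' Construct a coding alignment
#'
#' Container for an aligned set of nucleotide sequences together with the
#' annotation of protein-coding regions and their reading frames.
#'
#' @param seqs Named character vector of aligned sequences (gaps as `-`).
#'   All must have equal length and unique names.
#' @param coding_map `NULL` (fully non-coding) or a data frame with columns
#'   `start`, `end` (0-based half-open column interval), `frame` (0-2, offset
#'   of codon position 1 within the interval) and optionally `code_id`
#'   (genetic code per interval, default taken from `code_id`).
#' @param code_id Default genetic code id for intervals lacking their own
#'   (`"2"`, vertebrate mitochondrial, by default).
#' @return An object of class `coding_alignment` with fields `seqs`,
#'   `coding_map`, `length`.
#' @examples
#' aln <- coding_alignment(c(a = "ATGAAA", b = "ATGAAG"),
#'                         coding_map = data.frame(start = 0, end = 6, frame = 0))
#' @export
coding_alignment <- function(seqs, coding_map = NULL, code_id = "2") {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence id: ",
         names(seqs)[duplicated(names(seqs))][1])
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- names(seqs)[lens != lens[1]][1]
    stop("alignment records have unequal lengths (record '", bad, "')")
  }
  L <- lens[[1]]
  coding_map <- .normalize_coding_map(coding_map, L, code_id)
  structure(list(seqs = toupper(seqs), coding_map = coding_map, length = L),
            class = "coding_alignment")
}

.normalize_coding_map <- function(coding_map, L, code_id = "2") {
  if (is.null(coding_map) || NROW(coding_map) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), code_id = character(0)))
  }
  cm <- as.data.frame(coding_map)
  if (!all(c("start", "end", "frame") %in% names(cm))) {
    stop("coding_map needs columns start, end, frame")
  }
  if (is.null(cm$code_id)) cm$code_id <- as.character(code_id)
  cm$start <- as.integer(cm$start); cm$end <- as.integer(cm$end)
  cm$frame <- as.integer(cm$frame); cm$code_id <- as.character(cm$code_id)
  if (any(cm$start < 0L) || any(cm$end > L) || any(cm$start >= cm$end)) {
    stop("coding intervals must satisfy 0 <= start < end <= alignment length")
  }
  if (any(cm$frame < 0L | cm$frame > 2L)) stop("frame must be 0, 1 or 2")
  for (id in unique(cm$code_id)) get_genetic_code(id)  # validate
  cm <- cm[order(cm$start), , drop = FALSE]
  if (nrow(cm) > 1L && any(cm$start[-1L] < cm$end[-nrow(cm)])) {
    stop("coding intervals overlap")
  }
  rownames(cm) <- NULL
  cm
}

# Per-site codon annotation for a coding map. Returns a list with integer
# vectors of length L: codon_start (1-based site of codon position 1, NA for
# non-coding), codon_pos (1..3, NA), and a character vector code (code_id, NA).
# Partial codons at interval edges are treated as non-coding.
.site_codon_map <- function(coding_map, L) {
  codon_start <- rep(NA_integer_, L)
  codon_pos <- rep(NA_integer_, L)
  code <- rep(NA_character_, L)
  if (NROW(coding_map) == 0L) {
    return(list(codon_start = codon_start, codon_pos = codon_pos, code = code))
  }
  for (k in seq_len(nrow(coding_map))) {
    s0 <- coding_map$start[k] + coding_map$frame[k]  # 0-based first codon base
    n_codons <- (coding_map$end[k] - s0) %/% 3L
    if (n_codons <= 0L) next
    first <- s0 + 1L                          # 1-based
    last <- s0 + 3L * n_codons                # 1-based inclusive
    idx <- first:last
    codon_start[idx] <- first + 3L * ((idx - first) %/% 3L)
    codon_pos[idx] <- ((idx - first) %% 3L) + 1L
    code[idx] <- coding_map$code_id[k]
  }
  list(codon_start = codon_start, codon_pos = codon_pos, code = code)
}

#' @export
print.coding_alignment <- function(x, ...) {
  cat("coding_alignment:", length(x$seqs), "sequences x", x$length, "columns\n")
  nc <- if (nrow(x$coding_map)) sum(x$coding_map$end - x$coding_map$start) else 0L
  cat("  coding:", nrow(x$coding_map), "interval(s),", nc, "bp\n")
  cat("  ids:", paste(utils::head(names(x$seqs), 8), collapse = ", "),
      if (length(x$seqs) > 8) "..." else "", "\n")
  invisible(x)
}

# character matrix view (L x n), columns named by record id
.aln_matrix <- function(aln) {
  m <- vapply(aln$seqs, function(s) strsplit(s, "")[[1]],
              character(aln$length))
  if (is.null(dim(m))) m <- matrix(m, nrow = aln$length)
  dimnames(m) <- list(NULL, names(aln$seqs))
  m
}

# integer matrix view (L x n); non-ACGT (gap/ambiguity) -> NA
.aln_int_matrix <- function(aln) {
  m <- .aln_matrix(aln)
  im <- matrix(.base_to_int(m), nrow = nrow(m), dimnames = dimnames(m))
  im
}

#' Read a multi-FASTA alignment
#'
#' Tolerant of line wrapping and mixed case; fails loudly (with the line
#' number) on malformed input, duplicate ids or unequal record lengths.
#'
#' @param path File path.
#' @param coding_map,code_id Passed to [coding_alignment()].
#' @return A [coding_alignment()].
#' @export
read_fasta <- function(path, coding_map = NULL, code_id = "2") {
  lines <- readLines(path)
  ids <- character(0)
  parts <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^\\s*$", ln)) next
    if (startsWith(ln, ">")) {
      id <- sub("\\s.*$", "", sub("^>\\s*", "", ln))
      if (id == "") stop("FASTA: empty sequence id at line ", i)
      if (id %in% ids) stop("FASTA: duplicate id '", id, "' at line ", i)
      ids <- c(ids, id)
      cur <- id
      parts[[id]] <- character(0)
    } else {
      if (is.null(cur)) stop("FASTA: sequence data before any header at line ", i)
      ln2 <- gsub("\\s", "", ln)
      if (!grepl("^[A-Za-z.*-]*$", ln2)) {
        stop("FASTA: invalid sequence characters at line ", i)
      }
      parts[[cur]] <- c(parts[[cur]], ln2)
    }
  }
  if (!length(ids)) stop("FASTA: no records found in '", path, "'")
  seqs <- vapply(parts, paste, character(1), collapse = "")
  coding_alignment(seqs[ids], coding_map = coding_map, code_id = code_id)
}

#' Write a coding alignment as multi-FASTA
#'
#' @param aln A [coding_alignment()] (or named character vector).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 60L) {
  seqs <- if (inherits(aln, "coding_alignment")) aln$seqs else aln
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
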