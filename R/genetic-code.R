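# Genetic code tables, keyed by NCBI transl_table id ("1" standard,
# "2" vertebrate mitochondrial). Stops are carried as "*" and count as an
# amino-acid state: a change into or out of a stop is non-synonymous.

.CODE_BASE_ORDER <- c("T", "C", "A", "G")
.STANDARD_AA <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

.build_genetic_codes <- function() {
  b <- .CODE_BASE_ORDER
  g <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  codons <- paste0(g$b1, g$b2, g$b3)
  std <- strsplit(.STANDARD_AA, "")[[1]]
  names(std) <- codons
  mito <- std
  # vertebrate mitochondrial reassignments relative to the standard code
  mito["TGA"] <- "W"
  mito["ATA"] <- "M"
  mito["AGA"] <- "*"
  mito["AGG"] <- "*"
  list("1" = std, "2" = mito)
}

.GENETIC_CODES <- .build_genetic_codes()

#' Genetic code table
#'
#' Returns the codon -> amino-acid lookup for a supported NCBI translation
#' table. Stops are encoded as `"*"`.
#'
#' @param code_id Translation table id: `"1"` (standard) or `"2"` (vertebrate
#'   mitochondrial, the default throughout the package since NUMTs are
#'   mtDNA-derived). Numeric values are accepted.
#' @return Named character vector of length 64 (names are codons over
#'   `T`,`C`,`A`,`G`).
#' @examples
#' get_genetic_code("2")[["TGA"]]  # "W": Trp in the mitochondrial code
#' @export
get_genetic_code <- function(code_id = "2") {
  key <- as.character(code_id)
  if (!key %in% names(.GENETIC_CODES)) {
    stop("unknown genetic code id '", key, "'; supported: ",
         paste(names(.GENETIC_CODES), collapse = ", "))
  }
  .GENETIC_CODES[[key]]
}

#' Translate a single codon
#'
#' @param codon Three-letter nucleotide string (case-insensitive, `U` allowed).
#' @param code_id Genetic code id, see [get_genetic_code()].
#' @return Single-letter amino acid, `"*"` for stop, or `NA` if the codon
#'   contains a non-ACGT character.
#' @export
translate_codon <- function(codon, code_id = "2") {
  code <- get_genetic_code(code_id)
  codon <- chartr("u", "T", toupper(codon))
  if (nchar(codon) != 3L) stop("codon must have exactly 3 bases")
  if (!grepl("^[ACGT]{3}$", codon)) return(NA_character_)
  unname(code[codon])
}

# --- integer-coded fast path used by the simulator and mutation mapper ----
# Bases are coded A=1, C=2, G=3, T=4; codon index = (b1-1)*16 + (b2-1)*4 + b3.

.BASES <- c("A", "C", "G", "T")
.TS_PARTNER <- c(3L, 4L, 1L, 2L)  # A<->G, C<->T transitions

.base_to_int <- function(x) {
  # x: character vector of single bases; non-ACGT -> NA
  match(x, .BASES)
}

.int_to_base <- function(i) .BASES[i]

.seq_to_int <- function(s) {
  .base_to_int(strsplit(toupper(s), "")[[1]])
}

.int_to_seq <- function(v) paste(.BASES[v], collapse = "")

# amino-acid table indexed by integer codon index (ACGT order)
.aa_by_int <- local({
  cache <- list()
  function(code_id) {
    key <- as.character(code_id)
    if (!is.null(cache[[key]])) return(cache[[key]])
    code <- get_genetic_code(key)
    out <- character(64)
    for (codon in names(code)) {
      v <- .base_to_int(strsplit(codon, "")[[1]])
      out[(v[1] - 1L) * 16L + (v[2] - 1L) * 4L + v[3]] <- code[[codon]]
    }
    cache[[key]] <<- out
    out
  }
})
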