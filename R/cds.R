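# Coding-sequence container and standard-code translation.

#' The standard genetic code as a codon -> amino-acid lookup
#'
#' Named character vector mapping all 64 trinucleotides (DNA alphabet) to
#' single-letter amino acids, with `"*"` for the three stop codons. Only the
#' standard code is supported; alternative translation tables are out of scope
#' because the screens this package models use ordinary mammalian cDNA inserts.
#'
#' @format Named character vector of length 64.
#' @export
GENETIC_CODE_STANDARD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

DNA_BASES <- c("A", "C", "G", "T")

#' Translate codons under the standard genetic code
#'
#' @param codons Character vector of trinucleotides over `{A,C,G,T}`.
#' @return Character vector of single-letter amino acids (`"*"` = stop).
#' @export
translate_codons <- function(codons) {
  aa <- unname(GENETIC_CODE_STANDARD[codons])
  if (anyNA(aa)) {
    bad <- codons[is.na(aa)][1]
    stop("not a valid codon: '", bad, "'", call. = FALSE)
  }
  aa
}

#' Construct a validated coding sequence
#'
#' A `coding_sequence` is the substrate of variant-space enumeration and
#' library simulation: an in-frame DNA string over `{A,C,G,T}`.
#'
#' @param sequence DNA string; length must be a positive multiple of 3 and
#'   every character one of `A`, `C`, `G`, `T` (ambiguity codes are rejected).
#' @param id Text label for the sequence.
#' @param includes_stop Does the final codon encode the translation stop?
#'   If `NULL` (default) this is auto-detected from the final codon. When
#'   `TRUE`, the final codon must be a stop codon and no internal codon may
#'   be one.
#' @return An object of class `coding_sequence` with fields `id`, `sequence`,
#'   `includes_stop` and `n_codons`.
#' @examples
#' cds <- coding_sequence("ATGGCTTAA", id = "toy")
#' cds$includes_stop
#' @export
coding_sequence <- function(sequence, id = "cds", includes_stop = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L || n %% 3L != 0L) {
    stop("CDS length must be a positive multiple of 3, got ", n, call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% DNA_BASES)
  if (length(bad) > 0L) {
    stop("invalid base '", chars[bad[1]], "' at position ", bad[1],
         " (alphabet is A/C/G/T; ambiguity codes are rejected)", call. = FALSE)
  }
  codons <- substring(sequence, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aas <- translate_codons(codons)
  final_is_stop <- aas[length(aas)] == "*"
  if (is.null(includes_stop)) includes_stop <- final_is_stop
  if (includes_stop) {
    if (!final_is_stop) {
      stop("includes_stop = TRUE but final codon '", codons[length(codons)],
           "' is not a stop codon", call. = FALSE)
    }
    internal <- which(aas[-length(aas)] == "*")
    if (length(internal) > 0L) {
      stop("internal stop codon at codon ", internal[1], call. = FALSE)
    }
  }
  structure(
    list(id = id, sequence = sequence, includes_stop = includes_stop,
         n_codons = n %/% 3L),
    class = "coding_sequence"
  )
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("<coding_sequence> ", x$id, ": ", nchar(x$sequence), " bp (",
      x$n_codons, " codons), includes_stop = ", x$includes_stop, "\n", sep = "")
  invisible(x)
}

cds_bases <- function(cds) strsplit(cds$sequence, "", fixed = TRUE)[[1]]

cds_codons <- function(cds) {
  n <- nchar(cds$sequence)
  substring(cds$sequence, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Read a coding sequence from a FASTA file
#'
#' The file must contain exactly one record; multi-record files are rejected
#' so that the screened CDS is always unambiguous.
#'
#' @param path Path to a FASTA file with a single in-frame CDS record.
#' @param includes_stop Passed to [coding_sequence()]; `NULL` auto-detects.
#' @return A [coding_sequence()].
#' @export
read_cds_fasta <- function(path, includes_stop = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop("expected exactly one FASTA record, found ", length(set), call. = FALSE)
  }
  coding_sequence(as.character(set[[1]]), id = names(set)[1],
                  includes_stop = includes_stop)
}

#' Write a coding sequence to FASTA
#'
#' @param cds A [coding_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  set <- Biostrings::DNAStringSet(cds$sequence)
  names(set) <- cds$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Generate a random in-frame coding sequence
#'
#' Draws codons uniformly from the 61 sense codons, prepends an ATG start and
#' (optionally) appends a TAA stop. Used to build synthetic stand-ins for real
#' cDNA inserts whose exact sequence is not redistributable.
#'
#' @param n_codons Total codon count including start (and stop when
#'   `with_stop = TRUE`); must be at least 2 when a stop codon is requested.
#' @param id Sequence label.
#' @param with_stop Append a terminal TAA stop codon.
#' @param seed Optional integer seed for reproducibility.
#' @return A [coding_sequence()].
#' @export
random_cds <- function(n_codons, id = "synthetic_cds", with_stop = TRUE,
                       seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  sense <- names(GENETIC_CODE_STANDARD)[GENETIC_CODE_STANDARD != "*"]
  n_body <- n_codons - 1L - as.integer(with_stop)
  if (n_body < 0L) stop("n_codons too small", call. = FALSE)
  body <- sample(sense, n_body, replace = TRUE)
  seq <- paste(c("ATG", body, if (with_stop) "TAA"), collapse = "")
  coding_sequence(seq, id = id, includes_stop = with_stop)
}
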