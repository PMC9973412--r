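# Tabular interchange formats: per-variant count tables, results tables,
# annotated-variant imports, and the screen manifest.

#' Construct a validated per-variant count table
#'
#' The interchange object between sequencing (real or simulated) and
#' enrichment scoring: one row per observed substitution carrying the number
#' of reads supporting the variant and the total aligned reads at its locus.
#'
#' @param df Data frame with columns `pos`, `ref`, `alt`, `variant_reads`,
#'   `locus_total_reads`.
#' @param sample_id Sample label attached as an attribute.
#' @return A data frame of class `variant_count_table`, sorted by
#'   `(pos, alt)`.
#' @details Validation is strict: counts must satisfy
#'   `0 <= variant_reads <= locus_total_reads`, a `(pos, alt)` pair may occur
#'   only once, and all rows at the same position must agree on
#'   `locus_total_reads`. Violations are errors naming the offending row.
#' @export
variant_count_table <- function(df, sample_id = "sample") {
  required <- c("pos", "ref", "alt", "variant_reads", "locus_total_reads")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("count table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[, union(required, names(df)), drop = FALSE]
  df$pos <- as.integer(df$pos)
  df$variant_reads <- as.integer(df$variant_reads)
  df$locus_total_reads <- as.integer(df$locus_total_reads)

  check <- function(bad, what) {
    if (any(bad)) {
      stop("invalid count table row ", which(bad)[1], ": ", what,
           call. = FALSE)
    }
  }
  check(is.na(df$pos) | df$pos < 1L, "position must be a positive integer")
  check(!df$ref %in% DNA_BASES | !df$alt %in% DNA_BASES,
        "ref/alt must be one of A/C/G/T")
  check(df$ref == df$alt, "ref and alt must differ")
  check(is.na(df$variant_reads) | df$variant_reads < 0L,
        "variant_reads must be a non-negative integer")
  check(is.na(df$locus_total_reads) | df$locus_total_reads < 1L,
        "locus_total_reads must be a positive integer")
  check(df$variant_reads > df$locus_total_reads,
        "variant_reads exceeds locus_total_reads")
  key <- paste(df$pos, df$alt)
  check(duplicated(key), "duplicate (pos, alt) pair")
  tot_by_pos <- tapply(df$locus_total_reads, df$pos,
                       function(x) length(unique(x)))
  if (any(tot_by_pos > 1L)) {
    bad_pos <- names(tot_by_pos)[tot_by_pos > 1L][1]
    stop("inconsistent locus_total_reads at position ", bad_pos,
         call. = FALSE)
  }
  df <- df[order(df$pos, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, sample_id = sample_id,
            class = c("variant_count_table", "data.frame"))
}

#' Read a per-variant count table from TSV
#'
#' Expects a header line `pos ref alt variant_reads locus_total_reads`
#' (extra annotation columns are carried along). All validity violations are
#' hard errors with row numbers; readers reject rather than repair.
#'
#' @param path Path to the TSV file.
#' @param sample_id Sample label; defaults to the file name without extension.
#' @return A [variant_count_table()].
#' @export
read_counts <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("count table not found: ", path, call. = FALSE)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  variant_count_table(df, sample_id = sample_id)
}

#' Write a per-variant count table as TSV
#'
#' @param tbl A [variant_count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write enrichment results as TSV
#'
#' Columns `pos, ref, alt, aa_change, freq_library, freq_timepoint,
#' fold_change, p, q, hit` in stable `(pos, alt)` order; floating-point
#' values are rendered with at least six significant digits.
#'
#' @param records A `screen_result` from [score_screen()] (or a compatible
#'   data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  cols <- c("pos", "ref", "alt", "aa_change", "freq_library",
            "freq_timepoint", "fold_change", "p", "q", "hit")
  df <- as.data.frame(records)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("results missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$pos, df$alt), cols, drop = FALSE]
  for (col in c("freq_library", "freq_timepoint", "fold_change", "p", "q")) {
    df[[col]] <- formatC(df[[col]], digits = 8, format = "g")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read enrichment results written by [write_results()]
#'
#' @param path Path to a results TSV.
#' @return Data frame with typed columns.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$hit <- as.logical(df$hit)
  df
}

#' Read an annotated-variant table into CDS coordinates
#'
#' Two dialects are recognized. `minimal` expects columns `pos`, `ref`,
#' `alt`. `annovar_like` is a tolerant import of annotation-tool output:
#' it accepts `start` (or `pos`) for the CDS position and `ref`/`alt`
#' columns, matching case-insensitively and ignoring all other columns.
#'
#' @param path Path to a TSV file.
#' @param dialect `"minimal"` or `"annovar_like"`.
#' @param space Optional [enumerate_snv_space()] result; when supplied,
#'   variants whose coordinates fall outside the enumerated CDS are errors.
#' @return Data frame of unique variants with columns `pos`, `ref`, `alt`.
#' @export
read_annotated_variants <- function(path, dialect = c("minimal", "annovar_like"),
                                    space = NULL) {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  lower <- tolower(names(df))
  pick <- function(candidates) {
    idx <- match(candidates, lower)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) {
      stop("dialect '", dialect, "': no column matching ",
           paste(candidates, collapse = "/"), " in ", path, call. = FALSE)
    }
    df[[idx[1]]]
  }
  if (dialect == "minimal") {
    out <- data.frame(pos = as.integer(pick("pos")),
                      ref = toupper(pick("ref")),
                      alt = toupper(pick("alt")),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(pos = as.integer(pick(c("start", "pos"))),
                      ref = toupper(pick("ref")),
                      alt = toupper(pick("alt")),
                      stringsAsFactors = FALSE)
  }
  bad <- which(is.na(out$pos) | out$pos < 1L |
                 !out$ref %in% DNA_BASES | !out$alt %in% DNA_BASES)
  if (length(bad) > 0L) {
    stop("invalid variant at row ", bad[1], " of ", path, call. = FALSE)
  }
  if (!is.null(space)) {
    past <- which(out$pos > space$length_enumerated)
    if (length(past) > 0L) {
      stop("variant at row ", past[1], " lies past the enumerated CDS end (",
           out$pos[past[1]], " > ", space$length_enumerated, ")",
           call. = FALSE)
    }
  }
  unique(out)
}

#' Read a screen manifest (JSON)
#'
#' A manifest ties a screen's files together: exactly one library sample and
#' one or more timepoint samples with day labels, the CDS FASTA, and optional
#' hit-calling threshold overrides.
#'
#' @param path Path to a JSON manifest with fields `cds_fasta`,
#'   `library` (`{id, path}`), `timepoints` (array of `{id, day, path}`) and
#'   optional `params`.
#' @return Validated manifest list.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(m$cds_fasta)) stop("manifest missing 'cds_fasta'", call. = FALSE)
  if (is.null(m$library$id) || is.null(m$library$path)) {
    stop("manifest must name exactly one library sample (id + path)",
         call. = FALSE)
  }
  tp <- m$timepoints
  if (is.null(tp) || NROW(tp) < 1L) {
    stop("manifest must list at least one timepoint sample", call. = FALSE)
  }
  if (is.null(tp$id) || is.null(tp$day) || is.null(tp$path)) {
    stop("each timepoint needs id, day and path", call. = FALSE)
  }
  m
}
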