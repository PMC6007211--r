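# The curatable record schema and its JSONL/TSV serialization.

.RECORD_COLS <- c("pmid", "sentence_index", "sentence_text", "relation_type",
                  "entity_text", "entity_kind", "gene_id", "mirna_norm",
                  "level", "disease_text", "doid", "disease_sample",
                  "compared_sample", "frame_of_reference", "disease_source")

#' An empty record table
#' @return Zero-row tibble with the record schema.
#' @export
empty_records <- function() {
  tibble::tibble(pmid = character(0), sentence_index = integer(0),
                 sentence_text = character(0), relation_type = character(0),
                 entity_text = character(0), entity_kind = character(0),
                 gene_id = character(0), mirna_norm = character(0),
                 level = character(0), disease_text = character(0),
                 doid = character(0), disease_sample = character(0),
                 compared_sample = character(0),
                 frame_of_reference = character(0),
                 disease_source = character(0))
}

#' Write expression records
#'
#' JSONL: one JSON object per record with stable field names (missing values
#' become `null`). TSV: header row plus one row per record. Both round-trip
#' losslessly through [read_records()].
#'
#' @param records Record tibble.
#' @param path Output path.
#' @param format `"jsonl"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_records <- function(records, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  records <- records[, .RECORD_COLS]
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(records)), function(i)
      as.character(jsonlite::toJSON(as.list(records[i, ]), auto_unbox = TRUE,
                                    na = "null")), character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    tab <- as.data.frame(records)
    tab[] <- lapply(tab, function(x) ifelse(is.na(x), "", as.character(x)))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read expression records
#' @param path Input path.
#' @param format `"jsonl"` or `"tsv"`.
#' @return Record tibble.
#' @export
read_records <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(empty_records())
    rows <- lapply(lines, function(l) {
      x <- jsonlite::fromJSON(l)
      x <- lapply(x, function(v) if (is.null(v)) NA else v)
      tibble::as_tibble(x[.RECORD_COLS])
    })
    out <- do.call(rbind, rows)
  } else {
    tab <- utils::read.delim(path, sep = "\t", quote = "",
                             stringsAsFactors = FALSE,
                             colClasses = "character", encoding = "UTF-8")
    if (!nrow(tab)) return(empty_records())
    tab[tab == ""] <- NA_character_
    out <- tibble::as_tibble(tab[, .RECORD_COLS])
  }
  out$sentence_index <- as.integer(out$sentence_index)
  for (cl in setdiff(.RECORD_COLS, "sentence_index"))
    out[[cl]] <- as.character(out[[cl]])
  out
}
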