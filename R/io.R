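#' Read a 4-line FASTQ file
#'
#' Minimal strict FASTQ reader (Phred+33) used throughout the package. Every
#' record must be exactly four lines: `@id`, sequence, `+`, quality string of
#' the same length as the sequence.
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return A [data.table::data.table] with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ file ", path, " does not contain a multiple of 4 lines")
  }
  n <- length(lines) %/% 4L
  idx <- seq_len(n)
  hdr <- lines[4L * idx - 3L]
  seqs <- lines[4L * idx - 2L]
  plus <- lines[4L * idx - 1L]
  quals <- lines[4L * idx]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(quals))
  if (length(bad) > 0L) {
    stop("malformed FASTQ record at index ", bad[1L], " in ", path)
  }
  data.table(id = sub("^@", "", hdr), sequence = seqs, quality = quals)
}

#' Write reads as FASTQ
#'
#' @param reads A data.frame/data.table with columns `id`, `sequence`,
#'   `quality` (Phred+33 strings).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  out <- character(4L * nrow(reads))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$id)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- reads$sequence
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}

#' Read a tile library from TSV or FASTA
#'
#' TSV libraries have columns `tile_id`, `gene`, `sequence`; FASTA record
#' names are taken as tile ids (gene set to `NA`).
#'
#' @param path Path to the library file.
#' @param format `"tsv"`, `"fasta"`, or `"auto"` (by file extension).
#' @return A `tile_library`: data.table with columns `tile_id`, `gene`,
#'   `sequence`.
#' @export
read_tile_library <- function(path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "tsv") {
    lib <- fread(path, colClasses = list(character = c("tile_id", "sequence")))
    stopifnot(all(c("tile_id", "sequence") %in% names(lib)))
    if (!"gene" %in% names(lib)) lib$gene <- NA_character_
  } else {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    if (length(hdr) == 0L) stop("no FASTA records in ", path)
    ends <- c(hdr[-1L] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      paste(lines[seq(hdr[i] + 1L, ends[i])], collapse = "")
    }, character(1))
    lib <- data.table(
      tile_id = sub("^>\\s*(\\S+).*$", "\\1", lines[hdr]),
      gene = NA_character_,
      sequence = toupper(seqs)
    )
  }
  as_tile_library(lib[, c("tile_id", "gene", "sequence"), with = FALSE])
}

#' Write a tile library
#'
#' @param library A `tile_library`.
#' @param path Output path; extension picks the format (.tsv or .fa/.fasta).
#' @return `path`, invisibly.
#' @export
write_tile_library <- function(library, path) {
  if (grepl("\\.(fa|fasta)$", path, ignore.case = TRUE)) {
    writeLines(paste0(">", library$tile_id, "\n", library$sequence), path)
  } else {
    fwrite(library, path, sep = "\t")
  }
  invisible(path)
}

as_tile_library <- function(x) {
  x <- as.data.table(x)
  if (anyDuplicated(x$tile_id)) stop("duplicated tile ids in library")
  class(x) <- c("tile_library", class(x))
  x
}

#' Read a sample sheet
#'
#' A TSV with one row per sequencing sample; required column `sample_id`,
#' typical extra columns: `fastq`, `context`, `fraction`, `condition`,
#' `replicate`, `timepoint`.
#'
#' @param path Path to the TSV.
#' @return A data.table.
#' @export
read_sample_sheet <- function(path) {
  sheet <- fread(path)
  if (!"sample_id" %in% names(sheet)) stop("sample sheet needs a sample_id column")
  if (anyDuplicated(sheet$sample_id)) stop("duplicated sample_id in sample sheet")
  sheet
}
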