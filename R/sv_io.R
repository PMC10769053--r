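#' Construct a table of candidate SVs
#'
#' The SV table is the package's central record: one row per candidate with
#' 0-based half-open reference coordinates. For deletions and inversions
#' `length` defaults to `end - start`; for insertions `end` is the breakpoint
#' (`start + 1`) and `length` is the inserted length and must be given.
#'
#' @param chrom,start,end,sv_type,length,id vectors, recycled to a common
#'   length. `sv_type` must be one of DEL, INS, INV.
#' @return a `data.frame` with columns `id, chrom, start, end, sv_type,
#'   length`.
#' @export
sv_table <- function(chrom, start, end, sv_type, length = NA_integer_,
                     id = NA_character_) {
  df <- data.frame(
    id = as.character(id), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    sv_type = toupper(as.character(sv_type)),
    length = as.integer(length),
    stringsAsFactors = FALSE
  )
  bad <- !df$sv_type %in% SV_TYPES
  if (any(bad)) {
    stop("unknown sv_type: ", paste(unique(df$sv_type[bad]), collapse = ", "))
  }
  fill <- is.na(df$length) & df$sv_type != "INS"
  df$length[fill] <- df$end[fill] - df$start[fill]
  if (anyNA(df$length)) stop("INS records require an explicit length")
  if (any(df$length <= 0L)) stop("SV length must be positive")
  if (any(df$sv_type != "INS" & df$start >= df$end)) {
    stop("start must be < end for DEL/INV records")
  }
  synth <- is.na(df$id)
  df$id[synth] <- paste(df$chrom[synth], df$start[synth], df$sv_type[synth],
                        sep = "_")
  df
}

#' Read a BED-like SV list
#'
#' Accepts the common 4-6 column tab-separated dialect
#' `chrom, start, end, type[, length][, id]` with 0-based half-open
#' coordinates. A missing length column is derived as `end - start` for
#' DEL/INV; a missing id is synthesized as `chrom_start_type`. Records with
#' an unrecognized type are skipped (and reported), not fatal; malformed
#' coordinates are fatal with the offending line number.
#'
#' @param path path to the BED file.
#' @return SV table in file order, with skipped records (if any) attached as
#'   attribute `"skipped"` (a data.frame of line number, line text, reason).
#' @export
read_sv_bed <- function(path) {
  if (!file.exists(path)) stop("SV BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- seq_along(lines)[keep]
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)

  rows <- vector("list", length(lines))
  skipped <- list()
  for (i in seq_along(lines)) {
    f <- fields[[i]]
    if (length(f) < 4L) {
      stop(sprintf("line %d: expected >= 4 tab-separated columns, got %d",
                   lineno[i], length(f)))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("line %d: non-integer coordinate ('%s', '%s')",
                   lineno[i], f[2], f[3]))
    }
    type <- toupper(f[4])
    if (!type %in% SV_TYPES) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        line = lineno[i], text = lines[i],
        reason = paste0("unknown sv_type '", f[4], "'"),
        stringsAsFactors = FALSE
      )
      next
    }
    len <- if (length(f) >= 5L && nzchar(f[5])) {
      v <- suppressWarnings(as.integer(f[5]))
      if (is.na(v)) stop(sprintf("line %d: non-integer length '%s'",
                                 lineno[i], f[5]))
      v
    } else NA_integer_
    id <- if (length(f) >= 6L && nzchar(f[6])) f[6] else NA_character_
    rows[[i]] <- list(chrom = f[1], start = start, end = end, type = type,
                      length = len, id = id)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- sv_table(character(), integer(), integer(), character())
  } else {
    out <- sv_table(
      chrom = vapply(rows, `[[`, "", "chrom"),
      start = vapply(rows, `[[`, 0L, "start"),
      end = vapply(rows, `[[`, 0L, "end"),
      sv_type = vapply(rows, `[[`, "", "type"),
      length = vapply(rows, `[[`, 0L, "length"),
      id = vapply(rows, `[[`, "", "id")
    )
  }
  if (length(skipped)) attr(out, "skipped") <- do.call(rbind, skipped)
  out
}

#' Write an SV table as BED
#'
#' Emits the 6-column dialect read by [read_sv_bed()].
#' @param svs SV table.
#' @param path output path.
#' @export
write_sv_bed <- function(svs, path) {
  df <- data.frame(svs$chrom, svs$start, svs$end, svs$sv_type, svs$length,
                   svs$id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read SVs from a VCF (convenience adapter)
#'
#' Maps `SVTYPE`, `SVLEN` and `END` of an SV VCF into the package's SV
#' table. Only DEL/INS/INV records are kept. VCF positions are 1-based with
#' a padding base; the affected interval `[POS, END]` (1-based) becomes the
#' 0-based half-open `[POS, END)`.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @return SV table.
#' @export
read_sv_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the VCF adapter requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  svtype <- toupper(vcfR::extract.info(v, "SVTYPE"))
  svlen <- suppressWarnings(as.integer(vcfR::extract.info(v, "SVLEN")))
  endf <- suppressWarnings(as.integer(vcfR::extract.info(v, "END")))
  pos <- as.integer(fix[, "POS"])
  keep <- svtype %in% SV_TYPES
  chrom <- fix[keep, "CHROM"]
  pos <- pos[keep]; svtype <- svtype[keep]
  svlen <- svlen[keep]; endf <- endf[keep]
  start <- pos  # POS is the padding base; event starts at POS 0-based
  end <- ifelse(svtype == "INS", start + 1L,
                ifelse(!is.na(endf), endf, start + abs(svlen)))
  len <- ifelse(!is.na(svlen), abs(svlen), end - start)
  id <- fix[keep, "ID"]
  id[is.na(id) | id == "."] <- NA_character_
  sv_table(chrom, start, end, svtype, len, id)
}

#' Write validation results as TSV
#'
#' One row per input SV, in input order. `support_rate` is printed with 4
#' decimals; `corrected_length` is empty when absent. The file is
#' bit-identical across runs for identical inputs and seed.
#'
#' @param results data.frame from [validate_all()].
#' @param path output path.
#' @export
write_results <- function(results, path) {
  cols <- c("chrom", "start", "end", "sv_type", "length", "total_reads",
            "support_reads", "support_rate", "label", "corrected_length")
  hdr <- c("chrom", "start", "end", "type", "listed_length", "total_reads",
           "support_reads", "support_rate", "label", "corrected_length")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  if (nrow(results)) {
    fmt <- results[, cols]
    fmt$support_rate <- ifelse(is.na(fmt$support_rate), "NA",
                               sprintf("%.4f", fmt$support_rate))
    fmt$corrected_length <- ifelse(is.na(fmt$corrected_length), "",
                                   as.character(fmt$corrected_length))
    writeLines(do.call(paste, c(lapply(fmt, as.character), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#' @param path path to the TSV.
#' @return data.frame with the result columns.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(
                            chrom = "character", start = "integer",
                            end = "integer", type = "character",
                            listed_length = "integer",
                            total_reads = "integer",
                            support_reads = "integer",
                            support_rate = "numeric", label = "character",
                            corrected_length = "integer"),
                          stringsAsFactors = FALSE, fill = TRUE)
  names(df)[names(df) == "type"] <- "sv_type"
  names(df)[names(df) == "listed_length"] <- "length"
  df
}
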