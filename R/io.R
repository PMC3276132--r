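#' Read a FASTA file of nucleotide sequences
#'
#' Reads a (possibly gzip-compressed, multi-line) FASTA file into a
#' `DNAStringSet`.  Residues are uppercased; ids must be unique and
#' sequences may contain only A, C, G, T or N.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A [Biostrings::DNAStringSet] named by record id (first
#'   whitespace-delimited token of the header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) return(Biostrings::DNAStringSet())
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  names(seqs) <- ids
  up <- Biostrings::BStringSet(toupper(as.character(seqs)))
  bad <- grepl("[^ACGTN]", as.character(up))
  if (any(bad)) {
    stop("non-ACGTN residues in record(s): ",
         paste(ids[which(bad)[seq_len(min(5, sum(bad)))]], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(as.character(up))
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A named `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @param width Line width for wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(seqs, path, width = as.integer(width))
  invisible(path)
}

#' Read a genetic map table
#'
#' Expects a tab-separated file with header columns `marker_id`,
#' `linkage_group` and `position_cM`.
#'
#' @param path Path to the TSV file.
#' @return An object of class `genetic_map`: a data.frame of loci with an
#'   `lg_lengths` attribute (maximum cM per linkage group).
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genetic_map(df)
}

#' Construct a genetic map from a data.frame of loci
#'
#' @param loci data.frame with columns `marker_id`, `linkage_group`,
#'   `position_cM`.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(loci) {
  need <- c("marker_id", "linkage_group", "position_cM")
  if (!all(need %in% names(loci))) {
    stop("genetic map needs columns: ", paste(need, collapse = ", "))
  }
  loci <- as.data.frame(loci)[need]
  loci$marker_id <- as.character(loci$marker_id)
  loci$linkage_group <- as.character(loci$linkage_group)
  loci$position_cM <- as.numeric(loci$position_cM)
  if (anyNA(loci$position_cM) || any(loci$position_cM < 0)) {
    stop("position_cM must be numeric and >= 0")
  }
  if (anyDuplicated(loci$marker_id)) {
    stop("duplicate marker_id in genetic map: ",
         paste(unique(loci$marker_id[duplicated(loci$marker_id)]),
               collapse = ", "))
  }
  loci <- loci[order(loci$linkage_group, loci$position_cM, loci$marker_id), ]
  rownames(loci) <- NULL
  lg_lengths <- c(tapply(loci$position_cM, loci$linkage_group, max))
  structure(loci, lg_lengths = lg_lengths, class = c("genetic_map", "data.frame"))
}

#' Read gene positions from GFF3 or BED
#'
#' GFF3 coordinates (1-based, inclusive) and BED coordinates (0-based,
#' half-open) are both normalized to the internal 0-based half-open
#' convention.
#'
#' @param path Path to the file.
#' @param dialect `"gff3"` or `"bed"`; inferred from the file extension
#'   when `NULL`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @export
read_positions <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("position file not found: ", path)
  if (is.null(dialect)) {
    ext <- tolower(file_ext_nogz(path))
    dialect <- if (ext %in% c("bed")) "bed" else "gff3"
  }
  dialect <- match.arg(dialect, c("gff3", "bed"))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  if (!length(lineno)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (dialect == "gff3") {
    nf <- lengths(fields)
    if (any(nf < 9)) {
      stop("malformed GFF3 line ", lineno[which(nf < 9)[1]], " in ", path)
    }
    chrom <- vapply(fields, `[[`, "", 1L)
    start1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
    end1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
    strand <- vapply(fields, `[[`, "", 7L)
    attrs <- vapply(fields, `[[`, "", 9L)
    id <- gff3_attr(attrs, "ID")
    noid <- is.na(id)
    id[noid] <- gff3_attr(attrs[noid], "Name")
    if (anyNA(id)) {
      stop("GFF3 line ", lineno[which(keepNA <- is.na(id))[1]],
           " lacks an ID or Name attribute in ", path)
    }
    bad <- is.na(start1) | is.na(end1) | end1 < start1
    if (any(bad)) stop("invalid coordinates at line ", lineno[which(bad)[1]],
                       " in ", path)
    out <- data.frame(gene_id = id, chrom = chrom,
                      start = start1 - 1L, end = end1,
                      strand = strand, stringsAsFactors = FALSE)
  } else {
    nf <- lengths(fields)
    if (any(nf < 4)) {
      stop("BED line ", lineno[which(nf < 4)[1]], " needs >= 4 columns in ",
           path)
    }
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    id <- vapply(fields, `[[`, "", 4L)
    strand <- vapply(fields, function(f) if (length(f) >= 6) f[[6]] else "+", "")
    bad <- is.na(start0) | is.na(end0) | end0 < start0
    if (any(bad)) stop("invalid coordinates at line ", lineno[which(bad)[1]],
                       " in ", path)
    out <- data.frame(gene_id = id, chrom = chrom,
                      start = start0, end = end0,
                      strand = strand, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$gene_id)) {
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Write gene positions as GFF3
#'
#' Internal 0-based half-open coordinates are converted back to the GFF3
#' 1-based inclusive convention.
#'
#' @param positions data.frame as returned by [read_positions()].
#' @param path Output path.
#' @param source,type GFF3 source and feature-type columns.
#' @return `path`, invisibly.
#' @export
write_positions_gff3 <- function(positions, path, source = "legumap",
                                 type = "gene") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(positions)) {
    writeLines(paste(positions$chrom, source, type,
                     positions$start + 1L, positions$end, ".",
                     positions$strand, ".",
                     paste0("ID=", positions$gene_id), sep = "\t"), con)
  }
  invisible(path)
}

# file_ext that looks through a trailing .gz
file_ext_nogz <- function(path) tools::file_ext(sub("\\.gz$", "", path))

# pull one key=value attribute out of a GFF3 column-9 string (NA if absent)
gff3_attr <- function(attrs, key) {
  has <- grepl(paste0("(^|;)\\s*", key, "="), attrs)
  out <- rep(NA_character_, length(attrs))
  out[has] <- sub(paste0("(?:^|.*;)\\s*", key, "=([^;]+).*"), "\\1",
                  attrs[has])
  out
}

#' Write a data.frame as a deterministic TSV
#'
#' @param df data.frame.
#' @param path Output path.
#' @param digits Number of decimal places for numeric columns (`NULL` keeps
#'   full precision).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, digits = NULL) {
  df <- as.data.frame(df)
  if (!is.null(digits)) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(round(x, digits),
                                                   format = "f",
                                                   digits = digits))
    df[num] <- lapply(df[num], function(x) ifelse(grepl("NA", x), "NA", x))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}
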