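## Reading/writing barcodes and taxonomy metadata, and rank partitions.

## Unannotated-value convention: empty cells, "unidentified" (any case), NA,
## and species epithets that are only "sp." (e.g. "Candida sp.") all mean
## "unannotated at this rank".
.annotated <- function(values, rank) {
  v <- trimws(as.character(values))
  ok <- !is.na(v) & nzchar(v) & tolower(v) != "unidentified"
  if (rank == "species")
    ok <- ok & !grepl("^\\S+\\s+sp\\.?$", v)
  ok
}

#' Read barcode sequences from FASTA
#'
#' Reads a FASTA file into a [BarcodeSet-class]. The sequence id is the first
#' whitespace-delimited token of each header; residues are uppercased; input
#' order is preserved. Duplicate ids or an empty file are errors.
#'
#' @param path Path to a FASTA file.
#' @param marker Marker label attached to the set (reporting only).
#' @return A [BarcodeSet-class].
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a some description", "acgtACGT", ">b", "GGGTTT"), fa)
#' readBarcodes(fa, marker = "ITS")
readBarcodes <- function(path, marker = "other") {
  stopifnot(file.exists(path))
  seqs <- readDNAStringSet(path)
  if (length(seqs) == 0) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- ids
  new("BarcodeSet", seqs, marker = marker)
}

#' Write barcode sequences to FASTA
#'
#' @param x A [BarcodeSet-class] or named [Biostrings::DNAStringSet-class].
#' @param path Output path; lines wrapped at 80 columns.
#' @return \code{path}, invisibly.
#' @export
writeBarcodes <- function(x, path) {
  writeXStringSet(as(x, "DNAStringSet"), path, width = 80L)
  invisible(path)
}

## Detect the delimiter of a header line among tab, comma, semicolon.
.detect_sep <- function(line) {
  counts <- c("\t" = lengths(regmatches(line, gregexpr("\t", line))),
              "," = lengths(regmatches(line, gregexpr(",", line))),
              ";" = lengths(regmatches(line, gregexpr(";", line))))
  if (all(counts == 0)) stop("could not detect delimiter (tab/comma/semicolon)")
  names(counts)[which.max(counts)]
}

#' Read a taxonomy table
#'
#' Reads a delimited text table (tab, comma or semicolon; auto-detected) with
#' a header row into a [TaxonomyTable-class]. An \code{id} column and a
#' \code{species} column are required; missing rank columns are treated as
#' unannotated. Column names are matched case-insensitively and can be
#' remapped with \code{colMap}. The \code{is_new} flag, when not given as a
#' column, is derived from the id-prefix convention: ids beginning with
#' \code{"WI"} mark newly generated barcodes.
#'
#' @param path Path to the delimited table.
#' @param colMap Optional named character vector mapping standard column names
#'   (\code{id}, the seven ranks, \code{type}) to the file's actual headers,
#'   e.g. \code{c(id = "SequenceID", species = "Species name")}.
#' @return A [TaxonomyTable-class].
#' @export
readTaxonomy <- function(path, colMap = NULL) {
  stopifnot(file.exists(path))
  header <- readLines(path, n = 1L)
  sep <- .detect_sep(header)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  nm <- tolower(trimws(names(raw)))
  lookup <- function(std) {
    if (!is.null(colMap) && std %in% names(colMap)) {
      j <- match(tolower(colMap[[std]]), nm)
    } else {
      j <- match(std, nm)
    }
    if (is.na(j)) NULL else raw[[j]]
  }
  id <- lookup("id")
  if (is.null(id)) stop("taxonomy table has no 'id' column")
  if (is.null(lookup("species"))) stop("taxonomy table has no 'species' column")
  id <- trimws(id)
  if (anyDuplicated(id))
    stop("duplicate ids in taxonomy table: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  tb <- data.frame(id = id, stringsAsFactors = FALSE)
  for (r in .RANKS) {
    v <- lookup(r)
    tb[[r]] <- if (is.null(v)) "" else trimws(v)
  }
  ty <- lookup("type")
  tb$is_type <- if (is.null(ty)) NA else tolower(trimws(ty)) %in% c("yes", "true", "1")
  nw <- lookup("is_new")
  tb$is_new <- if (is.null(nw)) startsWith(id, "WI")
               else tolower(trimws(nw)) %in% c("yes", "true", "1")
  new("TaxonomyTable", tab = tb)
}

#' Construct a TaxonomyTable from a data.frame
#'
#' @param df data.frame with an \code{id} column and any subset of the rank
#'   columns; missing ranks are filled as unannotated.
#' @return A [TaxonomyTable-class].
#' @export
taxonomyTable <- function(df) {
  stopifnot("id" %in% names(df))
  tb <- data.frame(id = as.character(df$id), stringsAsFactors = FALSE)
  for (r in .RANKS)
    tb[[r]] <- if (r %in% names(df)) as.character(df[[r]]) else ""
  tb$is_type <- if ("is_type" %in% names(df)) df$is_type else NA
  tb$is_new <- if ("is_new" %in% names(df)) df$is_new else startsWith(tb$id, "WI")
  new("TaxonomyTable", tab = tb)
}

#' @describeIn taxonomyTable underlying data.frame accessor
#' @param x A TaxonomyTable.
#' @export
taxTable <- function(x) {
  stopifnot(is(x, "TaxonomyTable"))
  x@tab
}

#' @describeIn taxonomyTable sequence ids in the table
#' @export
taxIds <- function(x) {
  stopifnot(is(x, "TaxonomyTable"))
  x@tab$id
}

#' Write a taxonomy table
#'
#' Writes a tab-separated UTF-8 table with the standard columns. Reading the
#' file back with [readTaxonomy()] reproduces all non-empty cells exactly.
#'
#' @param x A [TaxonomyTable-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeTaxonomy <- function(x, path) {
  tb <- taxTable(x)
  out <- tb[, c("id", .RANKS)]
  out$type <- ifelse(is.na(tb$is_type), "", ifelse(tb$is_type, "yes", "no"))
  out$is_new <- ifelse(tb$is_new, "yes", "no")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Partition sequence ids at a taxonomic rank
#'
#' Groups the given ids by their taxon name at \code{rank}. Ids unannotated at
#' the rank are excluded; the partition's \code{covered} set holds the ids
#' retained. This is the ground truth used by clustering evaluation.
#'
#' @param tax A [TaxonomyTable-class].
#' @param ids Ids to partition (must be present in \code{tax}).
#' @param rank One of [taxRanks()].
#' @return A [RankPartition-class].
#' @export
#' @examples
#' tax <- taxonomyTable(data.frame(id = c("a", "b", "c", "d"),
#'                                 species = c("S1", "S1", "S2", "S2")))
#' partitionAtRank(tax, c("a", "b", "c", "d"), "species")
partitionAtRank <- function(tax, ids, rank) {
  if (!rank %in% .RANKS)
    stop("unknown rank '", rank, "'; expected one of: ", paste(.RANKS, collapse = ", "))
  tb <- taxTable(tax)
  miss <- setdiff(ids, tb$id)
  if (length(miss) > 0)
    stop("ids not in taxonomy table: ", paste(utils::head(miss, 5), collapse = ", "))
  rows <- tb[match(ids, tb$id), ]
  keep <- .annotated(rows[[rank]], rank)
  rows <- rows[keep, ]
  groups <- split(rows$id, rows[[rank]])
  groups <- lapply(groups, sort)
  groups <- groups[order(names(groups))]
  new("RankPartition", rank = rank, groups = groups,
      covered = sort(rows$id))
}
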