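# Readers and writers for the external formats the pipeline touches.
#
# Internal convention: 1-based inclusive coordinates everywhere; only
# BED/bedGraph boundaries are converted at the file boundary (standard
# 0-based half-open), and that conversion is its own inverse.

#' Read a single-record genome FASTA
#'
#' @param path FASTA file with exactly one record.
#' @return a DNAStringSet of length 1, sequence upper-cased.
#' @export
readGenomeFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1L)
    stop("multi-record FASTA not supported: found ", length(x),
         " records in ", path)
  s <- toupper(as.character(x[[1L]]))
  if (nchar(s) == 0L) stop("empty genome sequence in ", path)
  bad <- setdiff(unique(strsplit(s, "")[[1L]]), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("non-DNA characters in genome: ", paste(bad, collapse = ", "))
  out <- Biostrings::DNAStringSet(s)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a genome FASTA
#'
#' @param genome DNAStringSet of length 1 (or character scalar).
#' @param path output path.
#' @param accession record name when `genome` is a bare string.
#' @return invisibly, the path.
#' @export
writeGenomeFasta <- function(genome, path, accession = "genome") {
  if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(toupper(genome))
    names(genome) <- accession
  }
  if (length(genome) != 1L) stop("genome must contain a single record")
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read gene annotation from GFF3 or a PTT-like table
#'
#' Both dialects are normalized to 1-based inclusive coordinates. For GFF3,
#' CDS/rRNA/tRNA features are retained and `locus_tag` (falling back to ID)
#' names the gene; an optional `COG` attribute is carried through. The
#' PTT-like dialect is the tab-separated RefSeq protein table: Location
#' ("start..end"), Strand, Length, PID, Gene, Synonym, Code, COG, Product.
#'
#' @param path annotation file.
#' @param dialect \code{"gff3"} or \code{"ptt_like"}.
#' @return GRanges with mcols gene_id, feature_kind, cog_category, product.
#' @export
readAnnotation <- function(path, dialect = c("gff3", "ptt_like")) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    keep <- as.character(gr$type) %in% c("CDS", "rRNA", "tRNA", "gene")
    gr <- gr[keep]
    kind <- as.character(gr$type)
    kind[!kind %in% c("CDS", "rRNA", "tRNA")] <- "other"
    ids <- if (!is.null(gr$locus_tag)) gr$locus_tag else gr$ID
    if (is.null(ids)) stop("GFF3 features carry neither locus_tag nor ID")
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                  IRanges::ranges(gr),
                                  strand = GenomicRanges::strand(gr))
    S4Vectors::mcols(out)$gene_id <- as.character(ids)
    S4Vectors::mcols(out)$feature_kind <- kind
    cog <- if (!is.null(gr$COG)) as.character(gr$COG) else NA_character_
    cog[cog %in% c("", "-")] <- NA_character_
    S4Vectors::mcols(out)$cog_category <- cog
    S4Vectors::mcols(out)$product <-
      if (!is.null(gr$product)) as.character(gr$product) else NA_character_
  } else {
    lines <- readLines(path)
    # skip header lines until the column header containing "Location"
    hdr <- grep("^Location\t", lines)
    start_at <- if (length(hdr)) hdr[1L] + 1L else 1L
    body <- lines[seq(start_at, length(lines))]
    body <- body[nzchar(body)]
    rec <- vector("list", length(body))
    for (i in seq_along(body)) {
      f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
      if (length(f) < 2L)
        stop("malformed PTT-like line ", start_at + i - 1L, " in ", path)
      m <- regmatches(f[1L], regexec("^(\\d+)\\.\\.(\\d+)$", f[1L]))[[1L]]
      if (length(m) != 3L)
        stop("malformed location string on line ", start_at + i - 1L,
             " in ", path, ": ", f[1L])
      rec[[i]] <- data.frame(
        start = as.integer(m[2L]), end = as.integer(m[3L]),
        strand = f[2L],
        gene_id = if (length(f) >= 6L && nzchar(f[6L])) f[6L]
                  else paste0("gene_", i),
        cog = if (length(f) >= 8L) f[8L] else NA_character_,
        product = if (length(f) >= 9L) f[9L] else NA_character_,
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rec)
    if (any(!df$strand %in% c("+", "-")))
      stop("annotation without strand in ", path)
    df$cog[df$cog %in% c("", "-")] <- NA_character_
    out <- GenomicRanges::GRanges("genome",
                                  IRanges::IRanges(df$start, df$end),
                                  strand = df$strand)
    S4Vectors::mcols(out)$gene_id <- df$gene_id
    S4Vectors::mcols(out)$feature_kind <- "CDS"
    S4Vectors::mcols(out)$cog_category <- df$cog
    S4Vectors::mcols(out)$product <- df$product
  }
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene_id in annotation: ",
         out$gene_id[duplicated(out$gene_id)][1L])
  if (any(as.character(GenomicRanges::strand(out)) == "*"))
    stop("annotation without strand")
  out
}

#' Read a stranded pair of bedGraph files into a profile
#'
#' bedGraph intervals are 0-based half-open; they are converted to 1-based
#' positions and overlapping intervals are summed.
#'
#' @param path_fwd,path_rev bedGraph files for forward / reverse strand.
#' @param libraryKind \code{"TEX_PLUS"}, \code{"TEX_MINUS"}, \code{"SSRNA"}
#'   for a 5'-end count profile, or \code{"coverage"} for a real-valued
#'   coverage profile.
#' @param genomeLength genome length (defines the dense vector size).
#' @return \linkS4class{FivePrimeProfile} or \linkS4class{CoverageProfile}.
#' @export
readBedGraphPair <- function(path_fwd, path_rev, libraryKind, genomeLength) {
  readOne <- function(path) {
    v <- numeric(genomeLength)
    info <- file.info(path)
    if (is.na(info$size) || info$size == 0L) return(v)
    gr <- try(rtracklayer::import(path, format = "bedGraph"), silent = TRUE)
    if (inherits(gr, "try-error") || length(gr) == 0L) return(v)
    st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
    sc <- gr$score
    for (i in seq_along(gr)) {
      idx <- st[i]:en[i]
      idx <- idx[idx >= 1L & idx <= genomeLength]
      v[idx] <- v[idx] + sc[i]
    }
    v
  }
  fwd <- readOne(path_fwd)
  rev <- readOne(path_rev)
  if (libraryKind == "coverage") {
    if (any(fwd < 0) || any(rev < 0))
      warning("negative values in coverage bedGraph clamped to 0")
    return(CoverageProfile(pmax(fwd, 0), pmax(rev, 0)))
  }
  if (any(fwd < 0) || any(rev < 0))
    stop("negative values are not valid 5'-end counts")
  FivePrimeProfile(libraryKind, fwd, rev)
}

#' Write a profile as a stranded pair of bedGraph files
#'
#' @param profile a \linkS4class{FivePrimeProfile} or
#'   \linkS4class{CoverageProfile}.
#' @param prefix output prefix; writes `<prefix>.fwd.bedgraph` and
#'   `<prefix>.rev.bedgraph` (0-based half-open single-base intervals).
#' @param seqname chromosome name to write.
#' @return invisibly, the two paths.
#' @export
writeProfileBedGraph <- function(profile, prefix, seqname = "genome") {
  writeOne <- function(v, path) {
    nz <- which(v != 0)
    df <- data.frame(chrom = seqname, start = nz - 1L, end = nz,
                     score = v[nz])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    path
  }
  p1 <- writeOne(profile@fwd, paste0(prefix, ".fwd.bedgraph"))
  p2 <- writeOne(profile@rev, paste0(prefix, ".rev.bedgraph"))
  invisible(c(p1, p2))
}

#' Write / read a classified TSS table (TSV)
#'
#' Columns: tss_id, position (1-based), strand, category (P/S/I/A/N),
#' read_count, gene_id (empty for unlinked TSSs), utr_length (empty when
#' undefined).
#'
#' @param tss GRanges of classified TSSs (as from \code{\link{classifyTss}}).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTssTable <- function(tss, path) {
  dist <- tss$distance_to_start
  utr <- ifelse(tss$category == "P" & !is.na(dist) & dist <= 0L, -dist,
                NA_integer_)
  df <- data.frame(
    tss_id = tss$tss_id,
    position = GenomicRanges::start(tss),
    strand = as.character(GenomicRanges::strand(tss)),
    category = tss$category,
    read_count = tss$read_count,
    gene_id = ifelse(is.na(tss$gene_id), "", tss$gene_id),
    distance_to_start = ifelse(is.na(dist), "", dist),
    utr_length = ifelse(is.na(utr), "", utr),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTssTable
#' @param seqname chromosome name for the reconstructed GRanges.
#' @export
readTssTable <- function(path, seqname = "genome") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(tss_id = "character",
                                         gene_id = "character"))
  gr <- GenomicRanges::GRanges(seqname,
                               IRanges::IRanges(df$position, width = 1L),
                               strand = df$strand)
  S4Vectors::mcols(gr)$tss_id <- df$tss_id
  S4Vectors::mcols(gr)$read_count <- df$read_count
  S4Vectors::mcols(gr)$category <- df$category
  S4Vectors::mcols(gr)$gene_id <- ifelse(df$gene_id == "" |
                                           is.na(df$gene_id),
                                         NA_character_, df$gene_id)
  S4Vectors::mcols(gr)$distance_to_start <-
    suppressWarnings(as.integer(df$distance_to_start))
  gr
}

#' Write a classified TSS set as BED6
#'
#' Single-base intervals in 0-based half-open convention; the category is
#' placed in the name field, read count in the score field.
#'
#' @param tss GRanges of classified TSSs.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTssBed <- function(tss, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(tss)),
    start = GenomicRanges::start(tss) - 1L,
    end = GenomicRanges::start(tss),
    name = paste0(tss$tss_id, "_", tss$category),
    score = tss$read_count,
    strand = as.character(GenomicRanges::strand(tss)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
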