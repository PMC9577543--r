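#' Read a BED file of intervals
#'
#' Reads BED3/BED6 into a \code{GRanges}. BED is 0-based half-open on disk;
#' the returned object uses the 1-based closed GRanges convention. Strand is
#' taken from column 6 when present, else \code{*}.
#'
#' @param path path to a tab-separated BED file.
#' @return \code{GRanges}; column 4 (name), if present, is kept as mcol
#'   \code{name}.
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(GRanges())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop(sprintf("BED parse error at line %d: fewer than 3 fields",
                 which(nf < 3)[1]))
  chrom <- vapply(parts, `[[`, character(1), 1)
  s <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2)))
  e <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3)))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stop(sprintf("BED parse error at line %d: non-numeric coordinates", bad[1]))
  bad <- which(s >= e | s < 0)
  if (length(bad))
    stop(sprintf("BED validation error at line %d: need 0 <= start < end",
                 bad[1]))
  strand <- ifelse(nf >= 6, vapply(parts, function(p)
    if (length(p) >= 6) p[[6]] else "*", character(1)), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(chrom, IRanges(s + 1L, e), strand = strand)
  if (any(nf >= 4))
    mcols(gr)$name <- vapply(parts, function(p)
      if (length(p) >= 4) p[[4]] else NA_character_, character(1))
  gr
}

#' Write intervals to a BED file
#'
#' Inverse of \code{\link{readBed}}: \code{readBed(writeBed(gr))} returns the
#' same intervals.
#'
#' @param gr a \code{GRanges}.
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
  nm <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name)
        else rep(".", length(gr))
  str <- as.character(strand(gr))
  str[str == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   nm, str)
  writeLines(lines, path)
  invisible(path)
}

#' Read a RepeatMasker track table
#'
#' Expects the UCSC table-browser rmsk dialect: a tab-separated table with
#' (at least) columns \code{genoName}, \code{genoStart}, \code{genoEnd},
#' \code{strand}, \code{repName}, \code{repClass}. Repeat classes are
#' collapsed to \code{SINE}, \code{LINE}, \code{LTR} or \code{other}
#' (class strings like \code{"SINE/Alu"} collapse on the part before the
#' slash).
#'
#' @param path path to the table (with a header row).
#' @return \code{GRanges} with mcols \code{repName}, \code{repClass}.
#' @export
readRepeatMaskerTrack <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("genoName", "genoStart", "genoEnd", "strand", "repName",
            "repClass")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("rmsk schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0)
    return(GRanges(repName = character(0), repClass = character(0)))
  if (any(!nzchar(df$repName)))
    stop("rmsk schema error: empty repName")
  top <- toupper(sub("/.*$", "", df$repClass))
  cls <- ifelse(top %in% c("SINE", "LINE", "LTR"), top, "other")
  str <- ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  GRanges(df$genoName, IRanges(df$genoStart + 1L, df$genoEnd),
          strand = str, repName = df$repName, repClass = cls)
}

#' Write a RepeatMasker-style track table
#' @param gr \code{GRanges} with mcols \code{repName}, \code{repClass}.
#' @param path output path.
#' @export
writeRepeatMaskerTrack <- function(gr, path) {
  df <- data.frame(genoName = as.character(seqnames(gr)),
                   genoStart = start(gr) - 1L, genoEnd = end(gr),
                   strand = sub("\\*", "+", as.character(strand(gr))),
                   repName = mcols(gr)$repName,
                   repClass = mcols(gr)$repClass)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR text dialect: \code{>ID NAME} header followed by four
#' rows (A, C, G, T) of counts or frequencies, with or without the
#' \code{A [ ... ]} bracket decoration. Counts are pseudocounted and
#' normalized into \linkS4class{MotifModel} objects with exact p-value
#' machinery (see \code{\link{motifModel}}).
#'
#' @param path path to a JASPAR PFM file (may contain several motifs).
#' @param background base frequencies (default uniform).
#' @param pseudocount added to every PFM cell before normalization.
#' @param alpha default hit-calling p-value threshold.
#' @return named list of \linkS4class{MotifModel}.
#' @export
readJasparPfm <- function(path, background = rep(0.25, 4),
                          pseudocount = 0.1, alpha = 1e-4) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("JASPAR schema error: no '>' header")
  out <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(block) != 4L)
      stop("JASPAR schema error: motif must have exactly 4 matrix rows")
    nm <- sub("^>\\s*", "", lines[hdr[k]])
    nm <- gsub("\\s+", "_", nm)
    rows <- lapply(block, function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[][]", " ", l)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (anyNA(v)) stop("JASPAR schema error: non-numeric matrix entry")
      v
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("JASPAR schema error: matrix rows of unequal length")
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    out[[nm]] <- motifModel(nm, m, background = background,
                            pseudocount = pseudocount, alpha = alpha)
  }
  out
}

#' Write motifs as a JASPAR PFM file
#' @param models list of \linkS4class{MotifModel}.
#' @param path output path.
#' @param scale counts scale (frequencies are written as counts out of
#'   \code{scale}).
#' @export
writeJasparPfm <- function(models, path, scale = 100) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    writeLines(paste0(">", m@name), con)
    cnt <- round(m@pfm * scale)
    for (b in c("A", "C", "G", "T"))
      writeLines(paste0(b, " [ ", paste(cnt[b, ], collapse = " "), " ]"),
                 con)
  }
  invisible(path)
}

#' Read a region count table with its sample sheet
#'
#' The counts file is tab-separated with columns \code{chrom}, \code{start},
#' \code{end} (0-based half-open on disk) followed by one column per sample;
#' the sample sheet has columns \code{sample}, \code{species}, \code{assay}
#' (\code{ChIP} or \code{input}), \code{replicate}, \code{lib_size}.
#'
#' @param countsPath,samplesPath file paths.
#' @return a \code{SummarizedExperiment} with region \code{rowRanges} and the
#'   sample sheet as \code{colData}.
#' @export
readCountTable <- function(countsPath, samplesPath) {
  cdf <- utils::read.table(countsPath, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  sdf <- utils::read.table(samplesPath, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample", "species", "assay", "replicate", "lib_size")
  miss <- setdiff(need, colnames(sdf))
  if (length(miss))
    stop("sample sheet schema error: missing ", paste(miss, collapse = ", "))
  if (any(sdf$lib_size <= 0)) stop("library sizes must be positive")
  samples <- as.character(sdf$sample)
  miss <- setdiff(samples, colnames(cdf))
  if (length(miss))
    stop("count table missing sample column(s): ",
         paste(miss, collapse = ", "))
  counts <- as.matrix(cdf[, samples, drop = FALSE])
  if (any(counts < 0)) stop("counts must be non-negative")
  gr <- GRanges(cdf$chrom, IRanges(cdf$start + 1L, cdf$end))
  if ("label" %in% colnames(cdf)) mcols(gr)$trueLabel <- cdf$label
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = gr,
    colData = DataFrame(sdf, row.names = samples))
}

#' Write a region count table and its sample sheet
#' @param se \code{SummarizedExperiment} as built by
#'   \code{\link{simulatePeakCounts}} or \code{\link{readCountTable}}.
#' @param countsPath,samplesPath output paths.
#' @export
writeCountTable <- function(se, countsPath, samplesPath) {
  gr <- SummarizedExperiment::rowRanges(se)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(mcols(gr)$trueLabel)) df$label <- mcols(gr)$trueLabel
  df <- cbind(df, as.data.frame(SummarizedExperiment::assay(se, "counts")))
  utils::write.table(df, countsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  utils::write.table(cd, samplesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(countsPath)
}

#' Read a TPM expression table
#'
#' Tab-separated, first column \code{gene}, one column per sample.
#' @param path file path.
#' @return numeric matrix, genes in rows.
#' @export
readTpmTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0)) stop("TPM values must be non-negative")
  m
}

#' Write a TPM expression table
#' @param tpm numeric matrix (genes x samples).
#' @param path output path.
#' @export
writeTpmTable <- function(tpm, path) {
  df <- data.frame(gene = rownames(tpm), tpm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a simplified alignment table
#'
#' A light-weight TSV stand-in for per-read alignments, with columns
#' \code{read_id}, \code{chrom}, \code{start}, \code{end} (0-based half-open
#' on disk), \code{strand}, \code{mate_role} (\code{first}/\code{second}) and
#' \code{n_hits} (number of loci the read maps to). Optional column
#' \code{length} carries the read length for small-RNA filtering.
#'
#' @param path file path.
#' @return data.frame with 1-based \code{start} (GRanges convention).
#' @export
readAlignmentTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("read_id", "chrom", "start", "end", "strand", "mate_role",
            "n_hits")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("alignment table schema error: missing ",
         paste(miss, collapse = ", "))
  df$start <- df$start + 1L
  df
}

#' Count reads overlapping regions
#'
#' Counts alignment records with at least 1 bp of overlap per region, the
#' package's stand-in for coverage-based read counting over peak or window
#' sets.
#'
#' @param aln data.frame from \code{\link{readAlignmentTable}} (1-based
#'   \code{start}).
#' @param regions \code{GRanges}.
#' @param sameStrand if TRUE, count only records whose strand matches the
#'   region's annotated strand.
#' @return integer vector of counts, one per region.
#' @export
countReadsInRegions <- function(aln, regions, sameStrand = FALSE) {
  if (nrow(aln) == 0) return(integer(length(regions)))
  reads <- GRanges(aln$chrom, IRanges(aln$start, aln$end),
                   strand = ifelse(aln$strand %in% c("+", "-"), aln$strand,
                                   "*"))
  hits <- GenomicRanges::countOverlaps(regions, reads,
                                       ignore.strand = !sameStrand)
  as.integer(hits)
}
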