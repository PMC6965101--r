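## File formats: all tables are tab-separated with a header row; genomic
## annotation is BED (0-based half-open on disk, converted to the internal
## 1-based inclusive convention on read and back on write); genotypes are
## either a dosage TSV or a VCF with a DS FORMAT field; gene sets are GMT.

#' @name grpmIO
#' @title Readers and writers for the pipeline's file formats
#' @param path File path.
#' @param x Object to write (see each writer).
#' @description
#' Round-trip-safe readers/writers: dosage TSV (patients in rows), VCF with
#' a `DS` genotype field, survival TSV, BED gene annotation, two-column edge
#' lists, GMT gene sets, expression TSV and GWAS summary TSV.
NULL

#' @rdname grpmIO
#' @export
writeDosageTsv <- function(x, path) {
  df <- data.frame(patient_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname grpmIO
#' @export
readDosageTsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname grpmIO
#' @param variants Variant table (`variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`) aligned to the columns of the dosage matrix.
#' @export
writeVcfDosages <- function(x, variants, path) {
  stopifnot(all(colnames(x) == variants$variant_id))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(x)),
                     collapse = "\t")), con)
  body <- vapply(seq_len(ncol(x)), function(j) {
    paste(c(variants$chrom[j], variants$pos[j], variants$variant_id[j],
            variants$ref[j], variants$alt[j], ".", ".", ".", "DS",
            format(x[, j], trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname grpmIO
#' @export
readVcfDosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-variant file
  m <- t(ds)
  colnames(m) <- fix[, "ID"]
  variants <- data.frame(variant_id = fix[, "ID"], chrom = fix[, "CHROM"],
                         pos = as.numeric(fix[, "POS"]), ref = fix[, "REF"],
                         alt = fix[, "ALT"], stringsAsFactors = FALSE)
  list(dosages = m, variants = variants)
}

#' @rdname grpmIO
#' @param cohort A [SurvivalCohort-class].
#' @export
writeSurvivalTsv <- function(cohort, path) {
  write.table(cohortData(cohort), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname grpmIO
#' @export
readSurvivalTsv <- function(path) {
  SurvivalCohort(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname grpmIO
#' @param annotation data.frame `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive); written as BED (0-based half-open).
#' @export
writeBedAnnotation <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start, annotation$end),
    name = annotation$gene
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname grpmIO
#' @export
readBedAnnotation <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) grpmError(
                   paste("BED parse failure:", conditionMessage(e)),
                   "formatError"))
  data.frame(gene = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),  # rtracklayer yields 1-based
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' @rdname grpmIO
#' @param network Edge-list data.frame (`from`, `to`).
#' @export
writeEdgeList <- function(network, path) {
  write.table(network[, c("from", "to")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname grpmIO
#' @export
readEdgeList <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(df))) {
    grpmError("edge list needs 'from' and 'to' columns", "formatError")
  }
  df
}

#' @rdname grpmIO
#' @param geneSets Named list of character vectors.
#' @export
writeGmt <- function(geneSets, path) {
  lines <- vapply(names(geneSets), function(nm) {
    paste(c(nm, "na", geneSets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname grpmIO
#' @export
readGmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname grpmIO
#' @param expression Patients-by-genes matrix.
#' @export
writeExpressionTsv <- function(expression, path) {
  writeDosageTsv(expression, path)
}

#' @rdname grpmIO
#' @export
readExpressionTsv <- function(path) {
  readDosageTsv(path)
}

#' @rdname grpmIO
#' @param summary GWAS summary data.frame (from [runSurvivalGwas()]).
#' @export
writeGwasSummary <- function(summary, path) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname grpmIO
#' @export
readGwasSummary <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
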