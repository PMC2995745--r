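## Readers and writers for the text dialects the pipeline touches.
## Internal coordinates are 1-based inclusive everywhere; BED conversion
## (0-based half-open) happens only at the boundary, in one pair of
## utilities.

#' Coordinate conversion utilities
#'
#' All 1-based-inclusive <-> BED (0-based half-open) conversions go
#' through these two helpers so the convention lives in one place:
#' `toBedCoords()` subtracts 1 from the start; `fromBedCoords()` adds it
#' back.
#'
#' @param start,end interval boundaries.
#' @return A two-column data.frame `start`, `end` in the target
#'   convention.
#' @export
toBedCoords <- function(start, end) data.frame(start = start - 1L, end = end)

#' @rdname toBedCoords
#' @export
fromBedCoords <- function(start, end) data.frame(start = start + 1L, end = end)

.readTsv <- function(path, colNames, what) {
  if (!file.exists(path)) stop("missing ", what, " file: ", path)
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", what, " file ", path, ": ",
                             conditionMessage(e)))
  miss <- setdiff(colNames, colnames(df))
  if (length(miss))
    stop(what, " file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Read / write a SNP manifest
#'
#' Tab-delimited with header `Name  Chr  Position  GC` (1-based
#' positions); a `FreqB` column is carried through when present.
#'
#' @param path file path.
#' @return `readSnpManifest`: a [SnpManifest].
#' @export
readSnpManifest <- function(path) {
  df <- .readTsv(path, c("Name", "Chr", "Position", "GC"), "manifest")
  SnpManifest(df$Name, df$Chr, df$Position, df$GC, freqB = df$FreqB)
}

#' @rdname readSnpManifest
#' @param manifest a [SnpManifest].
#' @export
writeSnpManifest <- function(manifest, path) {
  df <- data.frame(Name = mcols(manifest)$Name,
                   Chr = as.character(seqnames(manifest)),
                   Position = start(manifest), GC = mcols(manifest)$GC)
  if (!is.null(mcols(manifest)$FreqB)) df$FreqB <- mcols(manifest)$FreqB
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-sample signal tracks
#'
#' The signal-file dialect is tab-delimited with header
#' `Name  <sample>.Log R Ratio  <sample>.B Allele Freq`, one file per
#' sample.
#'
#' @param path file path.
#' @return `readSignalFile`: `list(sample =, Name =, lrr =, baf =)`.
#' @export
readSignalFile <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(hdr) != 3L || hdr[1] != "Name" ||
      !grepl("\\.Log R Ratio$", hdr[2]) ||
      !grepl("\\.B Allele Freq$", hdr[3]))
    stop("not a signal file (header mismatch): ", path)
  sample <- sub("\\.Log R Ratio$", "", hdr[2])
  df <- read.table(path, header = FALSE, skip = 1L, sep = "\t",
                   col.names = c("Name", "lrr", "baf"),
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  list(sample = sample, Name = df$Name, lrr = df$lrr, baf = df$baf)
}

#' @rdname readSignalFile
#' @param sample sample id used in the column headers.
#' @param name probe names.
#' @param lrr,baf signal vectors aligned to `name`.
#' @export
writeSignalFile <- function(path, sample, name, lrr, baf) {
  hdr <- paste(c("Name", paste0(sample, ".Log R Ratio"),
                 paste0(sample, ".B Allele Freq")), collapse = "\t")
  body <- paste(name, format(lrr, trim = TRUE, digits = 6),
                format(baf, trim = TRUE, digits = 6), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write a PFB table
#'
#' Tab-delimited `Name  Chr  Position  PFB`.
#'
#' @param path file path.
#' @return `readPfb`: a data.frame with those columns.
#' @export
readPfb <- function(path) .readTsv(path, c("Name", "Chr", "Position", "PFB"),
                                   "PFB")

#' @rdname readPfb
#' @param manifest a [SnpManifest].
#' @param pfb per-probe PFB values aligned to the manifest.
#' @export
writePfb <- function(manifest, pfb, path) {
  write.table(data.frame(Name = mcols(manifest)$Name,
                         Chr = as.character(seqnames(manifest)),
                         Position = start(manifest), PFB = pfb),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an HMM model file
#'
#' A flat `key=value` text dialect holding every [CnvHmm] parameter
#' (`lrrMean`, `lrrSd`, `bafSd`, `transBase` row-major, `distScale`,
#' `outlierFrac`).
#'
#' @param path file path.
#' @return `readHmmModel`: a [CnvHmm].
#' @export
readHmmModel <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad))
    stop("malformed model line ", bad[1], " in ", path, ": ", ln[bad[1]])
  vals <- setNames(lapply(kv, function(x)
    as.numeric(strsplit(trimws(x[2]), ",", fixed = TRUE)[[1L]])),
    vapply(kv, function(x) trimws(x[1]), character(1)))
  cnvHmm(lrrMean = vals$lrrMean, lrrSd = vals$lrrSd, bafSd = vals$bafSd,
         transBase = matrix(vals$transBase, 6, 6, byrow = TRUE),
         distScale = vals$distScale, outlierFrac = vals$outlierFrac)
}

#' @rdname readHmmModel
#' @param model a [CnvHmm].
#' @export
writeHmmModel <- function(model, path) {
  num <- function(v) paste(format(v, digits = 15, trim = TRUE,
                                  scientific = FALSE), collapse = ",")
  writeLines(c(
    "# cnvarray HMM model",
    paste0("lrrMean=", num(model@lrrMean)),
    paste0("lrrSd=", num(model@lrrSd)),
    paste0("bafSd=", num(model@bafSd)),
    paste0("transBase=", num(as.vector(t(model@transBase)))),
    paste0("distScale=", num(model@distScale)),
    paste0("outlierFrac=", num(model@outlierFrac))), path)
  invisible(path)
}

#' Read / write CNV calls in the rawcnv line dialect
#'
#' One call per line:
#' `chr5:168423758-169070607  numsnp=198  length=646,850  state=5,cn=3
#' <sample>  startsnp=<name>  endsnp=<name>  conf=<x>` — whitespace
#' delimited, 1-based inclusive coordinates, length with thousands
#' commas.  State codes follow the 1..6 ordering of [CnvHmm] states.
#'
#' @param path file path.
#' @return `readRawCnv`: a [CnvCalls].
#' @export
readRawCnv <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  if (!length(ln))
    return(new("CnvCalls", GRanges(sample = character(), state = character(),
                                   cn = integer(), numsnp = integer(),
                                   startSnp = character(),
                                   endSnp = character(), conf = numeric())))
  parse1 <- function(s, lineNo) {
    f <- strsplit(trimws(s), "\\s+")[[1L]]
    m <- regmatches(f[1], regexec("^([^:]+):([0-9]+)-([0-9]+)$", f[1]))[[1L]]
    if (length(f) < 8L || length(m) != 4L)
      stop("malformed rawcnv line ", lineNo, ": ", s)
    grab <- function(key) {
      hit <- grep(paste0("^", key, "="), f, value = TRUE)
      if (!length(hit)) stop("rawcnv line ", lineNo, " lacks ", key)
      sub(paste0("^", key, "="), "", hit[1])
    }
    stCn <- strsplit(grab("state"), ",", fixed = TRUE)[[1L]]
    st <- as.integer(stCn[1])
    GRanges(m[2], IRanges(as.integer(m[3]), as.integer(m[4])),
            sample = f[5], state = HMM_STATES[st],
            cn = as.integer(sub("^cn=", "", stCn[2])),
            numsnp = as.integer(grab("numsnp")),
            startSnp = grab("startsnp"), endSnp = grab("endsnp"),
            conf = as.numeric(grab("conf")))
  }
  new("CnvCalls",
      do.call(c, mapply(parse1, ln, seq_along(ln), SIMPLIFY = FALSE,
                        USE.NAMES = FALSE)))
}

#' @rdname readRawCnv
#' @param calls a [CnvCalls].
#' @export
writeRawCnv <- function(calls, path) {
  mc <- mcols(calls)
  st <- match(mc$state, HMM_STATES)
  ln <- sprintf("%s:%d-%d\tnumsnp=%d\tlength=%s\tstate=%d,cn=%d\t%s\tstartsnp=%s\tendsnp=%s\tconf=%.4f",
                as.character(seqnames(calls)), start(calls), end(calls),
                mc$numsnp, formatC(width(calls), big.mark = ",", format = "d"),
                st, mc$cn, mc$sample, mc$startSnp, mc$endSnp, mc$conf)
  writeLines(ln, path)
  invisible(path)
}

#' CNV calls as BED intervals
#'
#' BED-like tab-delimited interchange: `chrom  start  end  sample  cn`
#' with 0-based half-open coordinates (conversion through
#' [toBedCoords()]).
#'
#' @param calls a [CnvCalls].
#' @param path file path.
#' @export
writeCnvBed <- function(calls, path) {
  bed <- toBedCoords(start(calls), end(calls))
  write.table(data.frame(chrom = as.character(seqnames(calls)),
                         start = bed$start, end = bed$end,
                         sample = mcols(calls)$sample,
                         cn = mcols(calls)$cn),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeCnvBed
#' @return `readCnvBed`: a `GRanges` (1-based inclusive) with `sample`
#'   and `cn` columns.
#' @export
readCnvBed <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "sample", "cn"))
  co <- fromBedCoords(df$start, df$end)
  GRanges(df$chrom, IRanges(co$start, co$end), sample = df$sample,
          cn = as.integer(df$cn))
}

#' Read a UCSC cytoband table
#'
#' The standard 5-column cytoBand dialect (`chrom  chromStart  chromEnd
#' name  gieStain`, BED-style 0-based half-open starts), with or without
#' header.
#'
#' @param path file path.
#' @return A `GRanges` with `name` and `gieStain` columns (1-based
#'   inclusive internally).
#' @export
readCytoband <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("chrom", first, ignore.case = TRUE)
  df <- read.table(path, sep = "\t", header = hasHeader,
                   stringsAsFactors = FALSE,
                   col.names = c("chrom", "chromStart", "chromEnd", "name",
                                 "gieStain"))
  co <- fromBedCoords(df$chromStart, df$chromEnd)
  GRanges(df$chrom, IRanges(co$start, co$end), name = df$name,
          gieStain = df$gieStain)
}

#' Read / write case-control labels
#'
#' Tab-delimited `Sample  Label` with labels `case` or `control`.
#'
#' @param path file path.
#' @return `readLabels`: a named character vector.
#' @export
readLabels <- function(path) {
  df <- .readTsv(path, c("Sample", "Label"), "labels")
  bad <- which(!df$Label %in% c("case", "control"))
  if (length(bad))
    stop("labels file line ", bad[1] + 1L, ": label must be case/control, got '",
         df$Label[bad[1]], "'")
  setNames(df$Label, df$Sample)
}

#' @rdname readLabels
#' @param labels named `"case"`/`"control"` vector.
#' @export
writeLabels <- function(labels, path) {
  write.table(data.frame(Sample = names(labels), Label = unname(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the raw cohort as one intensity file per sample
#'
#' Tab-delimited `Name  X_raw  Y_raw  Genotype  Confidence` with genotype
#' strings AA/AB/BB/NC, plus the truth intervals as a BED-like file
#' (`chrom  start  end  sample  copy_number`, 0-based half-open).
#'
#' @param x a [SnpSignalSet] from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
writeRawCohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- assay(x, "X"); Y <- assay(x, "Y")
  g <- assay(x, "genotype"); cf <- assay(x, "genoConf")
  files <- character()
  for (j in seq_len(ncol(x))) {
    gs <- ifelse(is.na(g[, j]), "NC", GENOTYPE_LEVELS[g[, j] + 1L])
    f <- file.path(dir, paste0(colnames(x)[j], ".txt"))
    write.table(data.frame(Name = rownames(x), X_raw = X[, j],
                           Y_raw = Y[, j], Genotype = gs,
                           Confidence = cf[, j]),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  truth <- metadata(x)$truth
  if (!is.null(truth) && length(truth$intervals)) {
    iv <- truth$intervals
    bed <- toBedCoords(start(iv), end(iv))
    f <- file.path(dir, "truth_cnv.bed")
    write.table(data.frame(chrom = as.character(seqnames(iv)),
                           start = bed$start, end = bed$end,
                           sample = mcols(iv)$sample,
                           copy_number = mcols(iv)$copyNumber),
                f, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a raw cohort directory into a SnpSignalSet
#'
#' Counterpart of [writeRawCohort()]: reads every `*.txt` per-sample
#' intensity file in `dir`, aligns probes to the manifest, and attaches
#' labels.
#'
#' @param dir directory of per-sample files.
#' @param manifest a [SnpManifest].
#' @param labels named `"case"`/`"control"` vector.
#' @return A [SnpSignalSet] with `X`, `Y`, `genotype`, `genoConf` assays.
#' @export
readRawCohort <- function(dir, manifest, labels) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no per-sample .txt files in ", dir)
  ids <- sub("\\.txt$", "", basename(files))
  m <- length(manifest)
  X <- Y <- cf <- matrix(NA_real_, m, length(files),
                         dimnames = list(mcols(manifest)$Name, ids))
  g <- matrix(NA_integer_, m, length(files),
              dimnames = list(mcols(manifest)$Name, ids))
  for (j in seq_along(files)) {
    df <- .readTsv(files[j], c("Name", "X_raw", "Y_raw", "Genotype",
                               "Confidence"), "raw intensity")
    idx <- match(df$Name, mcols(manifest)$Name)
    if (anyNA(idx))
      stop("probe(s) absent from manifest in ", files[j], ": ",
           paste(head(df$Name[is.na(idx)]), collapse = ", "))
    X[idx, j] <- df$X_raw; Y[idx, j] <- df$Y_raw
    g[idx, j] <- match(df$Genotype, GENOTYPE_LEVELS) - 1L  # NC -> NA
    cf[idx, j] <- df$Confidence
  }
  SnpSignalSet(manifest,
               assays = list(X = X, Y = Y, genotype = g, genoConf = cf),
               colData = DataFrame(label = unname(labels[ids]),
                                   row.names = ids))
}
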