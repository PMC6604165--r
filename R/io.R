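# Readers and writers for the on-disk formats the tool touches: BED/BEDPE
# fragment files, DANPOS-style nucleosome tables, gene annotations (BED or
# GTF), expression tables, and the extended-BED peak output. Fragment and
# map coordinates are normalized to 0-based half-open on read.

.read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

.split_cols <- function(lines) strsplit(lines, "[ \t]+")

.numify <- function(x, what, line_no) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v))
  if (length(bad))
    stop("malformed ", what, " at line ", line_no[bad[1]],
         ": non-numeric coordinate '", x[bad[1]], "'")
  v
}

#' Read a fragment file (BED or BEDPE)
#'
#' BED records (>= 3 columns) become one fragment each. BEDPE records (>= 6
#' columns with a second chromosome in column 4) are merged to one fragment
#' spanning `min(start)` to `max(end)` of the two ends; mates on different
#' chromosomes are rejected. Parsing is fail-fast: the first malformed
#' record aborts with its line number. The returned table carries the
#' library size (total fragments) as attribute `library_size`.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"bed"`, `"bedpe"`. `"auto"` sniffs BEDPE
#'   by a chromosome name in column 4.
#' @return Fragment `data.frame` (see [fragments()]) with attribute
#'   `library_size`.
#' @export
read_fragments <- function(path, format = c("auto", "bed", "bedpe")) {
  format <- match.arg(format)
  lines <- .read_lines_checked(path)
  if (length(lines) == 0L) stop("zero fragments in ", path)
  cols <- .split_cols(lines)
  ncol1 <- length(cols[[1]])
  if (format == "auto") {
    format <- if (ncol1 >= 6 &&
                  is.na(suppressWarnings(as.numeric(cols[[1]][4])))) "bedpe" else "bed"
  }
  n <- length(cols)
  line_no <- seq_len(n)
  if (format == "bed") {
    short <- which(lengths(cols) < 3L)
    if (length(short)) stop("malformed BED at line ", short[1], ": fewer than 3 fields")
    chrom <- vapply(cols, `[`, "", 1L)
    start <- .numify(vapply(cols, `[`, "", 2L), "BED", line_no)
    end <- .numify(vapply(cols, `[`, "", 3L), "BED", line_no)
  } else {
    short <- which(lengths(cols) < 6L)
    if (length(short)) stop("malformed BEDPE at line ", short[1], ": fewer than 6 fields")
    c1 <- vapply(cols, `[`, "", 1L); c2 <- vapply(cols, `[`, "", 4L)
    diff <- which(c1 != c2)
    if (length(diff)) stop("malformed BEDPE at line ", diff[1],
                           ": mates on different chromosomes")
    s1 <- .numify(vapply(cols, `[`, "", 2L), "BEDPE", line_no)
    e1 <- .numify(vapply(cols, `[`, "", 3L), "BEDPE", line_no)
    s2 <- .numify(vapply(cols, `[`, "", 5L), "BEDPE", line_no)
    e2 <- .numify(vapply(cols, `[`, "", 6L), "BEDPE", line_no)
    chrom <- c1; start <- pmin(s1, s2); end <- pmax(e1, e2)
  }
  bad <- which(!(start >= 0 & end > start))
  if (length(bad)) stop("malformed record at line ", bad[1],
                        ": requires 0 <= start < end")
  out <- fragments(chrom, start, end)
  attr(out, "library_size") <- nrow(out)
  out
}

#' Library size of a fragment table
#' @param frags Fragment table from [read_fragments()] or [fragments()].
#' @return Total fragment count.
#' @export
library_size <- function(frags) {
  n <- attr(frags, "library_size")
  if (is.null(n)) nrow(frags) else n
}

#' Read a nucleosome map file
#'
#' Understands two dialects: a DANPOS-style tab table with a header row
#' naming at least chromosome/start/end columns (1-based inclusive
#' coordinates, converted to 0-based half-open; a summit column supplies the
#' dyad, otherwise the interval midpoint is used), and headerless BED
#' (already 0-based). The result is sorted, overlap-trimmed, and carries
#' stable ids (see [nucleosome_map()]).
#'
#' @param path File path.
#' @param chrom_col,start_col,end_col,summit_col,occ_col Column names of the
#'   DANPOS-style dialect; defaults match DANPOS positions output
#'   (`chr`, `start`, `end`, `smt_pos`, `smt_value`).
#' @return A `nuc_map`.
#' @export
read_nucleosome_map <- function(path, chrom_col = "chr", start_col = "start",
                                end_col = "end", summit_col = "smt_pos",
                                occ_col = "smt_value") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  fields <- strsplit(first, "[ \t]+")[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(fields[2])))
  if (has_header) {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
    need <- c(chrom_col, start_col, end_col)
    if (!all(need %in% names(tab)))
      stop("unknown nucleosome-map dialect; detected columns: ",
           paste(names(tab), collapse = ", "))
    start <- tab[[start_col]] - 1  # 1-based inclusive -> 0-based half-open
    end <- tab[[end_col]]
    dyad <- if (summit_col %in% names(tab)) tab[[summit_col]] - 1 else NULL
    occ <- if (occ_col %in% names(tab)) tab[[occ_col]] else NA_real_
    nucleosome_map(tab[[chrom_col]], start, end, dyad = dyad, occupancy = occ)
  } else {
    b <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(b) < 3) stop("unknown nucleosome-map dialect; detected ",
                          ncol(b), " unnamed columns")
    nucleosome_map(b[[1]], b[[2]], b[[3]])
  }
}

#' Read a gene annotation (BED6/BED12 or GTF)
#'
#' Reduces each gene to a single TSS: `start` on the plus strand, `end - 1`
#' on the minus strand. For GTF (read via \pkg{rtracklayer}) transcripts are
#' collapsed per `gene_id` to the 5'-most transcript start on the gene
#' strand.
#'
#' @param path File path; `.gtf`/`.gff` extensions select GTF parsing.
#' @return `data.frame` with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("GTF input requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type %in% c("transcript", "mRNA", "gene")]
    g <- as.data.frame(gr)
    df <- data.frame(gene_id = as.character(g$gene_id),
                     chrom = as.character(g$seqnames),
                     start = g$start - 1,  # GRanges 1-based -> 0-based
                     end = g$end,
                     strand = as.character(g$strand),
                     stringsAsFactors = FALSE)
  } else {
    lines <- .read_lines_checked(path)
    cols <- .split_cols(lines)
    short <- which(lengths(cols) < 6L)
    if (length(short)) stop("gene BED needs >= 6 columns (line ", short[1], ")")
    df <- data.frame(gene_id = vapply(cols, `[`, "", 4L),
                     chrom = vapply(cols, `[`, "", 1L),
                     start = as.numeric(vapply(cols, `[`, "", 2L)),
                     end = as.numeric(vapply(cols, `[`, "", 3L)),
                     strand = vapply(cols, `[`, "", 6L),
                     stringsAsFactors = FALSE)
  }
  if (any(!df$strand %in% c("+", "-")))
    stop("gene records must carry strand + or -")
  # 5'-most transcript start per gene on the gene strand
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  pick <- function(d) {
    i <- if (d$strand[1] == "+") which.min(d$tss) else which.max(d$tss)
    d[i, c("gene_id", "chrom", "tss", "strand")]
  }
  out <- do.call(rbind, lapply(split(df, df$gene_id), pick))
  out <- out[order(out$chrom, out$tss), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a two-column expression table
#'
#' @param path TSV with columns gene id and RPKM (header optional).
#' @return `data.frame` with columns `gene_id`, `rpkm`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t")[[1]]
  header <- is.na(suppressWarnings(as.numeric(first[2])))
  tab <- read.table(path, header = header, sep = "\t", stringsAsFactors = FALSE)
  data.frame(gene_id = as.character(tab[[1]]), rpkm = as.numeric(tab[[2]]),
             stringsAsFactors = FALSE)
}

.peak_num_cols <- c("input_count_scaled", "fold_local", "fold_input",
                    "p_local", "p_input", "fdr_local", "fdr_input")
.peak_cols <- c("chrom", "start", "end", "name", "score", "strand",
                "chip_count", .peak_num_cols, "status", "reject_reason")

#' Write peak calls as extended BED
#'
#' One row per nucleosome-mark call: the six BED fields (`name` is
#' `mark:nucleosome_id`, `score` is `-10 log10(max(p_local, p_input))`
#' capped at 1000, strand "."), followed by counts, fold changes, p-values,
#' FDRs, status and reject reason. Rows are ordered by (chrom, start, mark)
#' and numerics are printed at full precision so [read_peaks()] round-trips
#' exactly.
#'
#' @param peaks Peak table from [call_peaks()] (element `peaks`).
#' @param path Output path.
#' @return Invisibly, the written table.
#' @export
write_peaks <- function(peaks, path) {
  df <- peaks[order(peaks$chrom, peaks$start, peaks$mark), , drop = FALSE]
  p_worst <- pmax(df$p_local, df$p_input)
  score <- ifelse(is.na(p_worst), 0, pmin(1000, -10 * log10(p_worst)))
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = sprintf("%s:%d", df$mark,
                                   as.integer(df$nucleosome_id)),
                    score = sprintf("%.6g", score),
                    strand = rep(".", nrow(df)),
                    chip_count = df$chip_count,
                    stringsAsFactors = FALSE)
  for (cc in .peak_num_cols) out[[cc]] <- sprintf("%.17g", df[[cc]])
  out$status <- df$status
  out$reject_reason <- df$reject_reason
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(.peak_cols, collapse = "\t")), con)
  if (nrow(out))
    write.table(out, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(out)
}

#' Read peak calls written by [write_peaks()]
#'
#' @param path File path.
#' @return Peak table with `mark` and `nucleosome_id` split back out of the
#'   BED name field.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      nucleosome_id = integer(), mark = character(),
                      chip_count = numeric(), input_count_scaled = numeric(),
                      fold_local = numeric(), fold_input = numeric(),
                      p_local = numeric(), p_input = numeric(),
                      fdr_local = numeric(), fdr_input = numeric(),
                      status = character(), reject_reason = character(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  tab <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE,
                    col.names = .peak_cols, na.strings = c("NA", "nan"))
  nm <- strsplit(tab$name, ":", fixed = TRUE)
  df <- data.frame(chrom = tab$chrom, start = as.numeric(tab$start),
                   end = as.numeric(tab$end),
                   nucleosome_id = as.integer(vapply(nm, `[`, "", 2L)),
                   mark = vapply(nm, `[`, "", 1L),
                   chip_count = tab$chip_count,
                   stringsAsFactors = FALSE)
  for (cc in .peak_num_cols) df[[cc]] <- as.numeric(tab[[cc]])
  df$status <- tab$status
  df$reject_reason <- as.character(tab$reject_reason)
  df
}
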