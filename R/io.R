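#' Read a FASTA file
#'
#' @param path FASTA path (gzip transparent).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTQ file (plain or gzip)
#'
#' @param path FASTQ(.gz) path.
#' @return data.frame with `id`, `seq`, `qual` (phred+33 strings).
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ (", path, "): ", length(lines),
         " lines is not a multiple of 4")
  if (length(lines) == 0)
    return(data.frame(id = character(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  idx <- seq(1, length(lines), by = 4)
  bad_hdr <- which(!startsWith(lines[idx], "@"))
  if (length(bad_hdr) > 0)
    stop("malformed FASTQ (", path, "): missing '@' header at line ",
         idx[bad_hdr[1]])
  seqs <- lines[idx + 1]; quals <- lines[idx + 3]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad) > 0)
    stop("malformed FASTQ (", path, "): sequence/quality length mismatch at line ",
         idx[bad[1]] + 1)
  data.frame(id = sub("^@", "", sub("[[:space:]].*$", "", lines[idx])),
             seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (gzip when the path ends in .gz)
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  txt <- paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual, "\n",
                collapse = "")
  writeChar(txt, con, eos = NULL)
  invisible(path)
}

#' TSV helpers (UTF-8, tab-separated, header, no quoting)
#'
#' @param x data.frame to write.
#' @param path File path.
#' @return The data.frame (reader) / `path` invisibly (writer).
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = NA, check.names = FALSE, comment.char = "")
}

#' Read and validate a run manifest
#'
#' The manifest describes one sequencing run: one row per library with columns
#' `sample_id`, `role` (sample / positive_control / ntc), `fastq_r1`,
#' `fastq_r2`, `spacer_f`, `spacer_r`. Relative FASTQ paths are resolved
#' against the manifest's directory.
#'
#' @param path Manifest TSV path.
#' @return data.frame with resolved paths.
#' @export
read_manifest <- function(path) {
  m <- read_tsv(path)
  required <- c("sample_id", "role", "fastq_r1", "fastq_r2", "spacer_f", "spacer_r")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0)
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id in manifest")
  bad_role <- setdiff(unique(m$role), c("sample", "positive_control", "ntc"))
  if (length(bad_role) > 0)
    stop("unknown role(s) in manifest: ", paste(bad_role, collapse = ", "))
  if (any(!nzchar(m$spacer_f)) || any(!nzchar(m$spacer_r)))
    stop("manifest spacers must be non-empty")
  if (any(grepl("[^ACGT]", c(m$spacer_f, m$spacer_r))))
    stop("manifest spacers must be ACGT strings")
  if (anyDuplicated(paste(m$spacer_f, m$spacer_r)))
    stop("spacer (forward, reverse) pairs must be unique per library")
  dir <- dirname(path)
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(dir, p))
  m$fastq_r1 <- fix(m$fastq_r1); m$fastq_r2 <- fix(m$fastq_r2)
  m
}

#' Read primers from a TSV (columns name, orientation, sequence)
#'
#' @param path Primer TSV path.
#' @return List with `forward` and `reverse` [degenerate_primer()]s.
#' @export
read_primers <- function(path) {
  p <- read_tsv(path)
  required <- c("name", "orientation", "sequence")
  if (!all(required %in% names(p)))
    stop("primer TSV needs columns: ", paste(required, collapse = ", "))
  fw <- p[p$orientation == "forward", ]
  rv <- p[p$orientation == "reverse", ]
  if (nrow(fw) != 1 || nrow(rv) != 1)
    stop("primer TSV must contain exactly one forward and one reverse primer")
  list(forward = degenerate_primer(fw$name, fw$sequence, "forward"),
       reverse = degenerate_primer(rv$name, rv$sequence, "reverse"))
}

#' Serialise / restore an ASV table as TSV
#'
#' Columns: `asv_id`, `sequence`, one count column per sample. The filter
#' ledger travels separately (see [write_tsv()] on `tab$ledger`).
#'
#' @param tab An `asv_table`.
#' @param path Output TSV.
#' @export
write_asv_table <- function(tab, path) {
  df <- data.frame(asv_id = rownames(tab$counts), sequence = tab$seq,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(tab$counts, check.names = FALSE))
  write_tsv(df, path)
}

#' @rdname write_asv_table
#' @return An `asv_table` (counts + sequences; no ledger).
#' @export
read_asv_table <- function(path) {
  df <- read_tsv(path)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$asv_id
  asv_table(seq = setNames(df$sequence, df$asv_id), counts = counts)
}
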