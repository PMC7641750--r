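# Repertoire-level processing: annotated reads, out-of-frame filtering,
# V/J/CDR3-length classing and single-linkage clonal clustering.

#' Construct a table of annotated IgH rearrangements
#'
#' An annotated read is one IgH rearrangement with its gene calls and CDR3
#' coordinates. CDR3 coordinates are 0-based, half-open on `sequence`.
#' Gene labels are compared at gene level: allele suffixes (`"*01"`) are
#' stripped.
#'
#' @param read_id character vector of unique identifiers.
#' @param sequence gapless nucleotide strings over A/C/G/T/N.
#' @param v_gene,j_gene gene labels (allele suffixes are stripped).
#' @param cdr3_start,cdr3_end 0-based half-open CDR3 (junction) bounds.
#' @param productive logical productivity flags.
#' @return A `data.frame` of class `annotated_reads`.
#' @export
annotated_reads <- function(read_id, sequence, v_gene, j_gene,
                            cdr3_start, cdr3_end, productive) {
  sequence <- toupper(sequence)
  df <- data.frame(read_id = as.character(read_id),
                   sequence = sequence,
                   v_gene = strip_allele(v_gene),
                   j_gene = strip_allele(j_gene),
                   cdr3_start = as.integer(cdr3_start),
                   cdr3_end = as.integer(cdr3_end),
                   productive = as.logical(productive),
                   stringsAsFactors = FALSE)
  bad <- grepl("[^ACGTN]", df$sequence)
  if (any(bad))
    stop("invalid nucleotide alphabet in read(s): ",
         paste(df$read_id[bad], collapse = ", "))
  len <- nchar(df$sequence)
  bad <- !(df$cdr3_start >= 0 & df$cdr3_start < df$cdr3_end &
             df$cdr3_end <= len)
  if (any(bad))
    stop("invalid CDR3 coordinates in read(s): ",
         paste(df$read_id[bad], collapse = ", "))
  if (anyDuplicated(df$read_id))
    stop("duplicated read_id values")
  class(df) <- c("annotated_reads", "data.frame")
  df
}

strip_allele <- function(x) sub("\\*.*$", "", as.character(x))

junction_length <- function(reads) reads$cdr3_end - reads$cdr3_start

cdr3_sequence <- function(reads) {
  substr(reads$sequence, reads$cdr3_start + 1L, reads$cdr3_end)
}

#' Read annotated rearrangements from disk
#'
#' Two dialects are supported. `"airr_tsv"` is an AIRR-style rearrangement
#' TSV with columns `sequence_id`, `sequence`, `v_call`, `j_call`,
#' `junction`, `productive` (and optionally `cdr3_start`, `cdr3_end`,
#' 1-based closed as in AIRR; otherwise the junction is located as its first
#' occurrence in `sequence`). `"fasta_with_sidecar"` reads sequences from a
#' FASTA file and all other columns from a sidecar TSV (same path with
#' extension `.tsv`) keyed by `sequence_id`.
#'
#' @param path input file.
#' @param format `"airr_tsv"` or `"fasta_with_sidecar"`.
#' @return An [annotated_reads()] table, in file order.
#' @export
read_annotated_reads <- function(path, format = c("airr_tsv",
                                                  "fasta_with_sidecar")) {
  format <- match.arg(format)
  if (format == "airr_tsv") {
    tab <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character")
  } else {
    fa <- read_fasta(path)
    sidecar <- sub("\\.[^.]*$", ".tsv", path)
    tab <- read.delim(sidecar, stringsAsFactors = FALSE,
                      colClasses = "character")
    need <- setdiff(c("sequence_id"), names(tab))
    if (length(need)) stop("sidecar is missing column: ", need[1])
    tab <- tab[match(names(fa), tab$sequence_id), , drop = FALSE]
    tab$sequence <- unname(fa)
  }
  required <- c("sequence_id", "sequence", "v_call", "j_call", "junction",
                "productive")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("missing required column: ", paste(missing, collapse = ", "))
  if (nrow(tab) == 0L) {
    return(annotated_reads(character(), character(), character(),
                           character(), integer(), integer(), logical()))
  }
  if (all(c("cdr3_start", "cdr3_end") %in% names(tab))) {
    start <- as.integer(tab$cdr3_start) - 1L      # AIRR is 1-based closed
    end <- as.integer(tab$cdr3_end)
  } else {
    start <- as.integer(regexpr(tab$junction, tab$sequence, fixed = TRUE)) - 1L
    if (any(start < 0))
      stop("junction not found in sequence for read(s): ",
           paste(tab$sequence_id[start < 0], collapse = ", "))
    end <- start + nchar(tab$junction)
  }
  annotated_reads(tab$sequence_id, tab$sequence, tab$v_call, tab$j_call,
                  start, end,
                  toupper(tab$productive) %in% c("T", "TRUE", "1"))
}

#' Write annotated rearrangements as AIRR-style TSV
#' @param reads an [annotated_reads()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotated_reads <- function(reads, path) {
  out <- data.frame(sequence_id = reads$read_id,
                    sequence = reads$sequence,
                    v_call = reads$v_gene,
                    j_call = reads$j_gene,
                    junction = cdr3_sequence(reads),
                    junction_length = junction_length(reads),
                    cdr3_start = reads$cdr3_start + 1L,
                    cdr3_end = reads$cdr3_end,
                    productive = ifelse(reads$productive, "TRUE", "FALSE"),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  setNames(unname(seqs), ids)
}

write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}

#' Select out-of-frame rearrangements
#'
#' Keeps reads that are flagged nonproductive and whose junction (CDR3)
#' length is not a multiple of 3, i.e. rearrangements carrying a CDR3
#' frameshift. These sequences are passengers of affinity maturation and
#' mutate free of selection on the receptor protein.
#'
#' @param reads an [annotated_reads()] table.
#' @return The retained subset, order preserved.
#' @export
filter_out_of_frame <- function(reads) {
  keep <- !reads$productive & (junction_length(reads) %% 3L != 0L)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition reads into (V gene, J gene, CDR3 length) classes
#'
#' @param reads an [annotated_reads()] table.
#' @return A named list of `annotated_reads` subsets; names are
#'   `"<v>|<j>|<cdr3 length>"`. Every read appears in exactly one class.
#' @export
partition_into_classes <- function(reads) {
  key <- paste(reads$v_gene, reads$j_gene, junction_length(reads), sep = "|")
  idx <- split(seq_len(nrow(reads)), key)
  lapply(idx, function(i) {
    out <- reads[i, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Single-linkage clonal families within a class
#'
#' Links two reads when their CDR3 identity, `1 - hamming / length` on the
#' equal-length junctions (N counts as a mismatch), is at least `threshold`;
#' families are the connected components. Family identifiers are assigned in
#' order of each family's smallest member `read_id`, so the result is
#' deterministic.
#'
#' @param class_members an [annotated_reads()] table whose reads share
#'   V gene, J gene and CDR3 length.
#' @param threshold identity threshold in (0, 1]; default 0.90.
#' @return A list of `clonal_family` objects with fields `family_id`,
#'   `members` (annotated_reads), `v_gene`, `j_gene`, `cdr3_length`.
#' @export
cluster_clonal_families <- function(class_members, threshold = 0.90) {
  stopifnot(threshold > 0, threshold <= 1)
  n <- nrow(class_members)
  if (n == 0L) return(list())
  cdr3 <- cdr3_sequence(class_members)
  len <- unique(nchar(cdr3))
  if (length(len) != 1L)
    stop("class members must share CDR3 length")
  if (length(unique(class_members$v_gene)) != 1L ||
      length(unique(class_members$j_gene)) != 1L)
    stop("class members must share V and J gene")
  # encoded CDR3 matrix; N -> distinct negative codes so N mismatches all
  m <- matrix(0L, n, len)
  for (i in seq_len(n)) {
    e <- encode_seq(cdr3[i])
    e[is.na(e)] <- -i
    m[i, ] <- e
  }
  # union-find over pairs meeting the identity threshold
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  max_mismatch <- floor((1 - threshold) * len + 1e-9)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      if (sum(m[i, ] != m[j, ]) <= max_mismatch) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  ord <- order(vapply(groups, function(i) min(class_members$read_id[i]),
                      character(1)))
  groups <- groups[ord]
  lapply(seq_along(groups), function(k) {
    members <- class_members[groups[[k]], , drop = FALSE]
    rownames(members) <- NULL
    structure(list(
      family_id = sprintf("%s|%s|%d|F%03d", members$v_gene[1],
                          members$j_gene[1], len, k),
      members = members,
      v_gene = members$v_gene[1],
      j_gene = members$j_gene[1],
      cdr3_length = len), class = "clonal_family")
  })
}

#' Full clustering pass: filter, class, cluster
#'
#' Convenience wrapper running [filter_out_of_frame()],
#' [partition_into_classes()] and [cluster_clonal_families()] over all
#' classes.
#'
#' @param reads an [annotated_reads()] table.
#' @param threshold CDR3 identity threshold.
#' @param filter if `TRUE` (default), keep only out-of-frame reads first.
#' @return A list of `clonal_family` objects.
#' @export
infer_clonal_families <- function(reads, threshold = 0.90, filter = TRUE) {
  if (filter) reads <- filter_out_of_frame(reads)
  classes <- partition_into_classes(reads)
  unlist(lapply(classes, cluster_clonal_families, threshold = threshold),
         recursive = FALSE, use.names = FALSE)
}

#' Write family assignments as TSV
#' @param families list of `clonal_family` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_families <- function(families, path) {
  out <- do.call(rbind, lapply(families, function(f)
    data.frame(read_id = f$members$read_id, family_id = f$family_id,
               stringsAsFactors = FALSE)))
  if (is.null(out))
    out <- data.frame(read_id = character(), family_id = character())
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
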