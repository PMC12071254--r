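# End-motif extraction: fragments + reference genome -> 256-motif profiles.
#
# Coordinates are BED-style 0-based half-open throughout; BAM template
# positions are converted on load.

#' Load cfDNA fragment spans from a BED or BAM file
#'
#' Reads fragment spans and applies the standard cfDNA fragment filter:
#' spans longer than `max_insert` are dropped. For BAM input only proper,
#' same-chromosome, correctly oriented pairs are used (one fragment per
#' read pair, taken from the forward-strand mate), records flagged as
#' duplicates or secondary are skipped, and reads below `min_mapq` are
#' discarded. Duplicate removal itself is assumed to have happened
#' upstream; this function only honours the flags.
#'
#' @param path path to a BED file (>= 3 columns: chrom, start, end;
#'   0-based half-open) or a coordinate-sorted, indexed BAM file.
#' @param max_insert maximum fragment length in bp (default 600).
#' @param min_mapq minimum mapping quality for BAM records (default 20).
#' @param format `"auto"` (by extension), `"bed"` or `"bam"`.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), one row per retained fragment.
#' @export
load_fragments <- function(path, max_insert = 600, min_mapq = 20,
                           format = c("auto", "bed", "bam")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read fragment file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  }
  fr <- if (format == "bam") load_fragments_bam(path, min_mapq) else
    load_fragments_bed(path)
  keep <- (fr$end - fr$start) <= max_insert
  fr <- fr[keep, , drop = FALSE]
  if (nrow(fr) == 0L) warning("no fragments retained from ", path)
  rownames(fr) <- NULL
  fr
}

load_fragments_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  parts <- strsplit(lines, "[\t ]+")
  ncol_ok <- vapply(parts, length, integer(1)) >= 3L
  if (any(!ncol_ok)) {
    stop("BED line ", which(!ncol_ok)[1], " has fewer than 3 columns")
  }
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(end <= start)
  if (length(bad)) {
    stop("BED line ", bad[1], ": end (", end[bad[1]],
         ") must exceed start (", start[bad[1]], ")")
  }
  data.frame(chrom = chrom, start = start, end = end)
}

load_fragments_bam <- function(path, min_mapq) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("BAM input requires the Rsamtools package")
  }
  flags <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isProperPair = TRUE, isUnmappedQuery = FALSE,
    hasUnmappedMate = FALSE, isMinusStrand = FALSE,
    isSecondaryAlignment = FALSE, isDuplicate = FALSE,
    isNotPassingQualityControls = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags, what = c("rname", "pos", "isize", "mapq"))
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !is.na(rec$pos) & !is.na(rec$isize) & rec$isize > 0 &
    (is.na(rec$mapq) | rec$mapq >= min_mapq)
  # forward mate of a proper pair: fragment spans [pos-1, pos-1+isize)
  data.frame(chrom = as.character(rec$rname)[keep],
             start = rec$pos[keep] - 1L,
             end = rec$pos[keep] - 1L + rec$isize[keep])
}

# Normalise a reference to a named character vector of sequences.
as_reference <- function(ref) {
  if (inherits(ref, "DNAStringSet")) {
    out <- as.character(ref)
    names(out) <- sub("\\s.*$", "", names(ref))
    return(out)
  }
  if (is.character(ref) && length(ref) >= 1) {
    if (length(ref) == 1 && file.exists(ref)) {
      seqs <- Biostrings::readDNAStringSet(ref)
      return(as_reference(seqs))
    }
    if (is.null(names(ref))) names(ref) <- paste0("chr", seq_along(ref))
    return(toupper(ref))
  }
  stop("reference must be a FASTA path, DNAStringSet, or named character")
}

#' 5' end motifs of a fragment on both strands
#'
#' The Watson-strand motif is the reference 4-mer at the fragment's left
#' end; the Crick-strand motif is the reverse complement of the reference
#' 4-mer at the right end, i.e. the 4-mer read 5'-to-3' from the minus
#' strand. Both are taken from the reference, not from read bases.
#'
#' @param chrom,start,end fragment span (0-based half-open).
#' @param ref reference: FASTA path, `DNAStringSet`, or named character.
#' @return list with `watson` and `crick` 4-mers, or `NULL` if either
#'   window falls off the chromosome or contains a non-ACGT base.
#' @export
end_motifs_of_fragment <- function(chrom, start, end, ref) {
  ref <- as_reference(ref)
  if (!chrom %in% names(ref)) stop("chromosome not in reference: ", chrom)
  seqlen <- nchar(ref[[chrom]])
  if (start < 0 || end > seqlen || end - start < 4) return(NULL)
  watson <- substr(ref[[chrom]], start + 1L, start + 4L)
  crick <- revcomp(substr(ref[[chrom]], end - 3L, end))
  if (grepl("[^ACGT]", watson) || grepl("[^ACGT]", crick)) return(NULL)
  list(watson = watson, crick = crick)
}

#' Build a 256-motif end-motif profile from fragments
#'
#' Each retained fragment contributes two motif counts, one per 5' end
#' (Watson and Crick). Fragments whose 4-mer windows fall off the
#' chromosome or contain non-ACGT reference bases are skipped and
#' counted, never fatal.
#'
#' @param fragments data.frame from [load_fragments()].
#' @param ref reference genome (FASTA path, `DNAStringSet`, or named
#'   character vector).
#' @param sample_id sample identifier.
#' @return object of class `end_motif_profile`: list with `sample_id`,
#'   `counts` (named integer, 256 motifs), `frequencies` (named numeric
#'   summing to 1) and `n_skipped`.
#' @export
build_profile <- function(fragments, ref, sample_id = "sample") {
  ref <- as_reference(ref)
  motifs <- all_motifs()
  counts <- integer(256)
  names(counts) <- motifs
  n_skipped <- 0L
  for (chrom in unique(fragments$chrom)) {
    if (!chrom %in% names(ref)) stop("chromosome not in reference: ", chrom)
    sub <- fragments[fragments$chrom == chrom, , drop = FALSE]
    seq <- ref[[chrom]]
    seqlen <- nchar(seq)
    ok <- sub$start >= 0 & sub$end <= seqlen & (sub$end - sub$start) >= 4
    n_skipped <- n_skipped + sum(!ok)
    if (sum(!ok) > 0) {
      warning(sum(!ok), " fragment(s) on ", chrom,
              " skipped: 4-mer window off chromosome")
    }
    sub <- sub[ok, , drop = FALSE]
    if (nrow(sub) == 0L) next
    watson <- substring(seq, sub$start + 1L, sub$start + 4L)
    crick <- revcomp(substring(seq, sub$end - 3L, sub$end))
    valid <- !grepl("[^ACGT]", watson) & !grepl("[^ACGT]", crick)
    n_skipped <- n_skipped + sum(!valid)
    tab <- table(factor(c(watson[valid], crick[valid]), levels = motifs))
    counts <- counts + as.integer(tab)
  }
  if (sum(counts) == 0L) stop("empty profile: no fragment ends retained")
  structure(list(sample_id = sample_id,
                 counts = counts,
                 frequencies = counts / sum(counts),
                 n_skipped = n_skipped),
            class = "end_motif_profile")
}

#' @export
print.end_motif_profile <- function(x, ...) {
  cat("End-motif profile:", x$sample_id, "\n")
  cat("  fragment ends counted:", sum(x$counts),
      " (skipped:", x$n_skipped, ")\n")
  top <- sort(x$frequencies, decreasing = TRUE)[1:5]
  cat("  top motifs:", paste(sprintf("%s=%.4f", names(top), top),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Assemble a profile matrix from per-sample profiles or a numeric matrix
#'
#' A profile matrix is the package's container for a cohort: a samples x
#' 256 matrix of motif frequencies in lexicographic motif order, with
#' optional binary labels (1 = cancer).
#'
#' @param x a numeric matrix (samples x 256, columns in motif order or
#'   named by motif) or a list of `end_motif_profile` objects.
#' @param labels optional binary vector (0 = control, 1 = cancer).
#' @param sample_ids optional sample identifiers.
#' @return object of class `profile_matrix`: list with `x` (the matrix),
#'   `sample_ids` and `labels`.
#' @export
profile_matrix <- function(x, labels = NULL, sample_ids = NULL) {
  motifs <- all_motifs()
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    stopifnot(all(vapply(x, inherits, logical(1), "end_motif_profile")))
    sample_ids <- sample_ids %||% vapply(x, `[[`, character(1), "sample_id")
    x <- do.call(rbind, lapply(x, `[[`, "frequencies"))
  }
  x <- as.matrix(x)
  if (ncol(x) != 256L) stop("profile matrix must have 256 motif columns")
  if (!is.null(colnames(x))) {
    missing <- setdiff(motifs, colnames(x))
    if (length(missing)) stop("missing motif column(s): ",
                              paste(head(missing, 3), collapse = ", "))
    x <- x[, motifs, drop = FALSE]
  } else {
    colnames(x) <- motifs
  }
  sample_ids <- sample_ids %||% rownames(x) %||%
    paste0("S", seq_len(nrow(x)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample_id")
  rownames(x) <- sample_ids
  rs <- rowSums(x)
  off <- abs(rs - 1) > 1e-6
  if (any(off)) {
    warning(sum(off), " row(s) did not sum to 1; renormalized")
    x[off, ] <- x[off, , drop = FALSE] / rs[off]
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    stopifnot(length(labels) == nrow(x), all(labels %in% 0:1))
  }
  structure(list(x = x, sample_ids = sample_ids, labels = labels),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("Profile matrix:", nrow(x$x), "samples x 256 motifs\n")
  if (!is.null(x$labels)) {
    cat("  labels: ", sum(x$labels == 1), " cancer / ",
        sum(x$labels == 0), " control\n", sep = "")
  }
  invisible(x)
}

#' Read / write a profile matrix as TSV
#'
#' The on-disk format is a TSV with a `sample_id` column, the 256 motif
#' columns AAAA...TTTT, and an optional `label` column in \{0, 1\}.
#' Writing then reading reproduces the matrix to within 1e-12.
#'
#' @param path TSV path.
#' @return [read_profile_matrix()] returns a `profile_matrix`.
#' @export
read_profile_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("missing sample_id column")
  motifs <- all_motifs()
  missing <- setdiff(motifs, names(df))
  if (length(missing)) stop("missing motif column(s): ",
                            paste(head(missing, 3), collapse = ", "))
  m <- as.matrix(df[, motifs])
  if (!is.numeric(m)) stop("non-numeric motif frequency cell in ", path)
  labels <- if ("label" %in% names(df)) df$label else NULL
  profile_matrix(m, labels = labels, sample_ids = df$sample_id)
}

#' @param pm a `profile_matrix`.
#' @rdname read_profile_matrix
#' @export
write_profile_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "profile_matrix"))
  df <- data.frame(sample_id = pm$sample_ids, pm$x,
                   check.names = FALSE)
  if (!is.null(pm$labels)) df$label <- pm$labels
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
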