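#' Read per-locus alignments
#'
#' Reads one alignment per file, as FASTA or (sequential or interleaved)
#' NEXUS.  Taxon labels have surrounding whitespace trimmed and states are
#' upper-cased.  Files whose sequences differ in length raise a format error
#' naming the file and offending row.
#'
#' @param paths character vector of file paths.
#' @param format `"fasta"` or `"nexus"`.
#' @param ids locus ids (default: file base names without extension).
#' @return a named list of [locus_aln()] objects.
#' @export
read_loci <- function(paths, format = c("fasta", "nexus"), ids = NULL) {
  format <- match.arg(format)
  if (is.null(ids)) ids <- sub("\\.[^.]*$", "", basename(paths))
  if (anyDuplicated(ids)) stop("read_loci: duplicate locus ids")
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) out[[i]] <- .read_locus(paths[i], format, ids[i])
  names(out) <- ids
  out
}

.read_locus <- function(path, format, id) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("format error: empty file ", path)
  if (format == "fasta") {
    lines <- readLines(path, warn = FALSE)
    hdr <- grep("^>", lines)
    if (!length(hdr)) stop("format error: no FASTA headers in ", path)
    labs <- trimws(sub("^>", "", lines[hdr]))
    ends <- c(hdr[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(k) {
      paste(lines[(hdr[k] + 1L):ends[k]], collapse = "")
    }, "")
    seqs <- gsub("[[:space:]]", "", seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1)
      stop(sprintf("format error in %s: row '%s' has %d sites, expected %d",
                   path, labs[which(lens != lens[1])[1]],
                   lens[lens != lens[1]][1], lens[1]))
    mat <- do.call(rbind, strsplit(seqs, ""))
    rownames(mat) <- labs
  } else {
    nx <- ape::read.nexus.data(path)
    lens <- lengths(nx)
    if (length(unique(lens)) != 1)
      stop(sprintf("format error in %s: row '%s' has %d sites, expected %d",
                   path, names(nx)[which(lens != lens[1])[1]],
                   lens[lens != lens[1]][1], lens[1]))
    mat <- do.call(rbind, nx)
    rownames(mat) <- trimws(names(nx))
  }
  locus_aln(mat, id = id)
}

#' Write one locus alignment
#'
#' @param locus a [locus_aln()].
#' @param path output file.
#' @param format `"fasta"` or `"nexus"` (sequential).
#' @return `path`, invisibly.
#' @export
write_locus <- function(locus, path, format = c("fasta", "nexus")) {
  format <- match.arg(format)
  if (format == "fasta") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(locus$seq))) {
      writeLines(paste0(">", rownames(locus$seq)[i]), con)
      writeLines(paste(locus$seq[i, ], collapse = ""), con)
    }
  } else {
    dat <- stats::setNames(lapply(seq_len(nrow(locus$seq)),
                                  function(i) locus$seq[i, ]),
                           rownames(locus$seq))
    ape::write.nexus.data(dat, path, interleaved = FALSE)
  }
  invisible(path)
}

#' Filter loci by taxon completeness
#'
#' Retains exactly the loci whose fraction of the `total_taxa` present is at
#' least `threshold` (inclusive, matching a "at least 75% of the taxa"
#' reading); order is preserved.  The conventional 75p and 90p regimes are
#' `threshold = 0.75` and `0.90`.
#'
#' @param loci list of [locus_aln()].
#' @param total_taxa total number of taxa in the study.
#' @param threshold completeness fraction in (0, 1].
#' @return the retained sub-list.
#' @export
filter_by_completeness <- function(loci, total_taxa, threshold = 0.75) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  nmax <- max(vapply(loci, function(x) nrow(x$seq), 0L))
  if (total_taxa < nmax) stop("total_taxa below the largest locus taxon count")
  keep <- vapply(loci, function(x) nrow(x$seq) / total_taxa >= threshold, NA)
  loci[keep]
}

#' Concatenate loci into a supermatrix
#'
#' Taxa absent from a locus receive all-gap rows for that block.  Character
#' sets are emitted per locus, or per core/flank segment when partition
#' schemes are supplied; internally coordinates are 0-based half-open, but
#' all emitted charsets are 1-based inclusive (the NEXUS convention).
#'
#' @param loci list of [locus_aln()].
#' @param schemes optional named list of [partition_scheme()]s (one per locus
#'   id) splitting each locus into left flank / core / right flank charsets.
#' @return an object of class `supermatrix`: list with `seq` (taxa x sites
#'   character matrix) and `charsets` (data.frame name/start/end, 1-based
#'   inclusive).
#' @export
concatenate <- function(loci, schemes = NULL) {
  stopifnot(length(loci) >= 1)
  taxa <- unique(unlist(lapply(loci, locus_taxa)))
  if (anyDuplicated(tolower(taxa)))
    stop("taxon labels differing only by case: ",
         paste(taxa[duplicated(tolower(taxa)) |
                      duplicated(tolower(taxa), fromLast = TRUE)], collapse = ", "))
  lens <- vapply(loci, n_sites, 0L)
  total <- sum(lens)
  seq <- matrix("-", length(taxa), total, dimnames = list(taxa, NULL))
  pos <- 0L
  cs <- list()
  for (loc in loci) {
    rng <- (pos + 1L):(pos + n_sites(loc))
    seq[locus_taxa(loc), rng] <- loc$seq
    sch <- if (!is.null(schemes)) schemes[[loc$id]] else NULL
    if (!is.null(sch) && !isTRUE(sch$unpartitionable)) {
      stopifnot(sch$L == n_sites(loc))
      cs[[length(cs) + 1]] <- data.frame(
        name = paste0(loc$id, c("_Lflank", "_core", "_Rflank")),
        start = pos + c(1L, sch$l + 1L, sch$r + 1L),
        end = pos + c(sch$l, sch$r, n_sites(loc)))
    } else {
      cs[[length(cs) + 1]] <- data.frame(name = loc$id, start = pos + 1L,
                                         end = pos + n_sites(loc))
    }
    pos <- pos + n_sites(loc)
  }
  structure(list(seq = seq, charsets = do.call(rbind, cs)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d sites, %d charsets\n",
              nrow(x$seq), ncol(x$seq), nrow(x$charsets)))
  invisible(x)
}

#' Write a supermatrix as NEXUS with a sets block
#'
#' @param sm a [concatenate()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_supermatrix_nexus <- function(sm, path) {
  dat <- stats::setNames(lapply(seq_len(nrow(sm$seq)), function(i) sm$seq[i, ]),
                         rownames(sm$seq))
  ape::write.nexus.data(dat, path, interleaved = FALSE)
  sets <- c("begin sets;",
            sprintf("  charset %s = %d-%d;", sm$charsets$name,
                    sm$charsets$start, sm$charsets$end),
            "end;")
  cat(paste(sets, collapse = "\n"), "\n", file = path, append = TRUE)
  invisible(path)
}

#' Write RAxML-style partition definitions
#'
#' One `MODEL, name = start-end` line per charset.
#'
#' @param charsets data.frame with `name`, `start`, `end` (1-based inclusive).
#' @param path output file.
#' @param model partition model label.
#' @return `path`, invisibly.
#' @export
write_raxml_partitions <- function(charsets, path, model = "DNA") {
  writeLines(sprintf("%s, %s = %d-%d", model, charsets$name, charsets$start,
                     charsets$end), path)
  invisible(path)
}
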