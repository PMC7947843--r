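#' UCE-like locus alignment
#'
#' A lightweight container for one locus: a taxa x sites character matrix of
#' nucleotide states (upper case, IUPAC ambiguity codes and `-` gaps allowed)
#' plus a locus identifier.
#'
#' @param seq character matrix (rows = taxa, named; columns = sites), or an
#'   object coercible to one.
#' @param id single string, the locus identifier.
#' @return an object of class `locus_aln`.
#' @export
locus_aln <- function(seq, id = "locus") {
  seq <- as.matrix(seq)
  if (is.null(rownames(seq))) stop("locus_aln: sequence matrix must have taxon rownames")
  if (anyDuplicated(rownames(seq))) stop("locus_aln: duplicated taxon labels")
  mode(seq) <- "character"
  seq[] <- toupper(seq)
  structure(list(id = as.character(id)[1], seq = seq), class = "locus_aln")
}

#' @export
print.locus_aln <- function(x, ...) {
  cat(sprintf("<locus_aln> %s: %d taxa x %d sites\n", x$id, nrow(x$seq), ncol(x$seq)))
  invisible(x)
}

#' Number of sites in a locus
#' @param locus a `locus_aln`.
#' @return integer site count.
#' @export
n_sites <- function(locus) ncol(locus$seq)

#' Taxa present in a locus
#' @param locus a `locus_aln`.
#' @return character vector of taxon labels.
#' @export
locus_taxa <- function(locus) rownames(locus$seq)

# IUPAC nucleotide -> 4-bit mask (A=1, C=2, G=4, T=8); gaps/unknown -> 15
.iupac_mask <- local({
  m <- rep(15L, 256)
  codes <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
             R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
             B = 14L, D = 13L, H = 11L, V = 7L, N = 15L, `-` = 15L, `?` = 15L)
  m[utf8ToInt(paste(names(codes), collapse = "")) + 1L] <- unname(codes)
  m
})

# character matrix -> integer mask matrix (same dim)
.encode_masks <- function(seq) {
  ints <- utf8ToInt(paste(t(seq), collapse = ""))
  matrix(.iupac_mask[ints + 1L], nrow = nrow(seq), byrow = TRUE,
         dimnames = dimnames(seq))
}

# is the state an unambiguous base?
.is_base <- function(x) x %in% c("A", "C", "G", "T")
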