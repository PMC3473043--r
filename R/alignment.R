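#' Canonical 21-symbol residue alphabet
#'
#' The fixed symbol ordering used throughout the package: the 20 standard
#' amino acids in alphabetical one-letter order followed by the gap
#' character \code{"-"} as the 21st symbol.  Every alignment cell is one of
#' these 21 symbols; ambiguous or non-standard letters (B, J, O, U, X, Z)
#' and the alternative gap characters \code{"."} and \code{"*"} are mapped
#' to the gap on input.
#'
#' @format Character vector of length 21.
#' @export
MSA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")

#' @rdname MSA_ALPHABET
#' @export
MSA_GAP <- "-"

## Number of symbols (20 aa + gap); the block width of the global binary
## expansion.
ALPHA_N <- 21L

normalize_symbols <- function(x) {
  x <- toupper(x)
  x[!(x %in% MSA_ALPHABET)] <- MSA_GAP
  x
}

#' Construct an alignment object
#'
#' An \code{msa} is a list with a character matrix \code{seqs} (rows =
#' sequences, columns = alignment positions, cells drawn from
#' \code{\link{MSA_ALPHABET}}) and a character vector \code{ids}.
#'
#' @param seqs Character matrix of residue symbols, or an object coercible
#'   to one.  Symbols are normalized: lower case is uppercased and any
#'   character outside the canonical alphabet becomes a gap.
#' @param ids Sequence identifiers; defaults to rownames or
#'   \code{seq1..seqN}.
#' @return Object of class \code{msa}.
#' @export
as_msa <- function(seqs, ids = NULL) {
  seqs <- as.matrix(seqs)
  if (nrow(seqs) < 2L || ncol(seqs) < 2L)
    stop("alignment must have at least 2 sequences and 2 positions")
  seqs[] <- normalize_symbols(seqs)
  if (is.null(ids)) ids <- rownames(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(seqs)))
  dimnames(seqs) <- NULL
  structure(list(ids = as.character(ids), seqs = seqs), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d positions\n",
              nrow(x$seqs), ncol(x$seqs)))
  invisible(x)
}

#' @export
dim.msa <- function(x) dim(x$seqs)

## Integer encoding 1..21 in MSA_ALPHABET order.
encode_msa <- function(aln) {
  m <- matrix(match(aln$seqs, MSA_ALPHABET), nrow = nrow(aln$seqs))
  storage.mode(m) <- "integer"
  m
}

decode_msa <- function(codes, ids = NULL) {
  seqs <- matrix(MSA_ALPHABET[codes], nrow = nrow(codes))
  as_msa(seqs, ids = ids)
}

#' Read an aligned FASTA file
#'
#' Records must all have the same length after parsing; identifiers are
#' kept in file order and symbols are normalized to the canonical
#' 21-letter alphabet.
#'
#' @param path Path to an aligned FASTA file.
#' @return An \code{\link{as_msa}} object.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", set.attributes = FALSE)
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L)
    stop("unequal record lengths (", paste(unique(lens), collapse = ", "),
         "): input is not an alignment")
  seqs <- do.call(rbind, recs)
  as_msa(seqs, ids = names(recs))
}

#' Write an alignment to FASTA
#'
#' @param aln An \code{msa} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_msa <- function(aln, path) {
  stopifnot(inherits(aln, "msa"))
  seqinr::write.fasta(
    sequences = lapply(seq_len(nrow(aln$seqs)), function(i) aln$seqs[i, ]),
    names = aln$ids, file.out = path, nbchar = 80)
  invisible(path)
}

#' Per-column relative entropy profile
#'
#' Kullback-Leibler divergence, in bits, of each column's amino-acid
#' frequencies from a background distribution.  Gaps are excluded from the
#' frequency counts; an all-gap column has relative entropy 0 by
#' convention.
#'
#' @param aln An \code{msa} object.
#' @param background Probability vector of length 20 over the amino acids
#'   in \code{MSA_ALPHABET} order (gap excluded).  Default uniform 1/20.
#' @return Numeric vector of length \code{n_pos} (bits), class
#'   \code{entropy_profile}.
#' @export
relative_entropy <- function(aln, background = rep(1 / 20, 20)) {
  stopifnot(inherits(aln, "msa"))
  if (length(background) != 20L)
    stop("background must have length 20")
  if (abs(sum(background) - 1) > 1e-8)
    stop("background must sum to 1")
  codes <- encode_msa(aln)
  re <- apply(codes, 2L, function(col) {
    col <- col[col != ALPHA_N]            # drop gaps
    if (length(col) == 0L) return(0)
    f <- tabulate(col, nbins = 20L) / length(col)
    keep <- f > 0
    if (any(background[keep] == 0))
      stop("background assigns probability 0 to an observed residue")
    sum(f[keep] * log2(f[keep] / background[keep]))
  })
  structure(re, class = "entropy_profile")
}

#' Residue-residue contact map from a PDB structure
#'
#' Builds a symmetric boolean contact map for one chain: a pair of
#' residues is a contact when the distance between their centroids is
#' strictly less than \code{cutoff} Angstrom.  The centroid is the
#' unweighted mean of all non-hydrogen atom coordinates (optionally
#' side-chain atoms only).  Only ATOM records of the first model with
#' altloc blank or \code{"A"} are used.
#'
#' @param pdb Path to a PDB file, or a \code{bio3d} \code{pdb} object.
#' @param chain Chain identifier.
#' @param cutoff Centroid distance cutoff in Angstrom (default 8).
#' @param offset Added to the PDB residue numbers to obtain 1-based
#'   alignment column indices (default 0: columns match residue numbers).
#' @param n_pos Number of alignment positions; defaults to the largest
#'   mapped index.
#' @param side_chain_only If \code{TRUE}, centroids use side-chain atoms
#'   only (backbone N, CA, C, O excluded; glycine falls back to CA).
#' @return \code{n_pos x n_pos} logical matrix of class \code{contact_map}
#'   with attributes \code{cutoff} and \code{positions} (mapped residue
#'   indices).
#' @export
contact_map <- function(pdb, chain, cutoff = 8, offset = 0,
                        n_pos = NULL, side_chain_only = FALSE) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain &
             (is.na(at$alt) | at$alt %in% c("", "A")) &
             !(at$elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records for chain ", chain)
  if (side_chain_only) {
    side <- !(at$elety %in% c("N", "CA", "C", "O", "OXT"))
    ## glycine (no side chain): keep CA
    has_side <- tapply(side, at$resno, any)
    keep <- side | (!has_side[as.character(at$resno)] & at$elety == "CA")
    at <- at[keep, , drop = FALSE]
  }
  resno <- sort(unique(at$resno))
  if (length(resno) < 2L) stop("chain ", chain, " has fewer than 2 residues")
  cent <- t(vapply(resno, function(r) {
    m <- at[at$resno == r, c("x", "y", "z"), drop = FALSE]
    colMeans(as.matrix(m))
  }, numeric(3)))
  pos <- resno + offset
  bad <- pos < 1L
  if (any(bad)) {
    warning(sum(bad), " residues map to non-positive columns; skipped")
    cent <- cent[!bad, , drop = FALSE]
    pos <- pos[!bad]
  }
  if (is.null(n_pos)) n_pos <- max(pos)
  d <- as.matrix(stats::dist(cent))
  map <- matrix(FALSE, n_pos, n_pos)
  map[pos, pos] <- d < cutoff
  diag(map) <- FALSE
  structure(map, class = c("contact_map", "matrix"),
            cutoff = cutoff, positions = pos)
}

#' Write a symmetric score or contact matrix as sparse TSV
#'
#' Serializes the upper triangle (i < j, 1-based) as three columns
#' \code{i}, \code{j}, \code{value}.
#'
#' @param m Symmetric matrix (numeric or logical).
#' @param path Output path.
#' @param all If \code{FALSE} (default) zero entries are dropped.
#' @return \code{path}, invisibly.
#' @export
write_pair_tsv <- function(m, path, all = TRUE) {
  m <- as.matrix(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  v <- as.numeric(m[ut])
  if (!all) {
    keep <- v != 0
    ut <- ut[keep, , drop = FALSE]
    v <- v[keep]
  }
  df <- data.frame(i = ut[, 1], j = ut[, 2], value = v)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sparse pair TSV back into a symmetric matrix
#'
#' @param path Path written by \code{\link{write_pair_tsv}}.
#' @param n_pos Matrix dimension; defaults to the largest index present.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
read_pair_tsv <- function(path, n_pos = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (is.null(n_pos)) n_pos <- max(df$i, df$j)
  m <- matrix(0, n_pos, n_pos)
  m[cbind(df$i, df$j)] <- df$value
  m[cbind(df$j, df$i)] <- df$value
  m
}
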