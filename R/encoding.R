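# Sequence encodings: one-hot, BLOSUM62, middle padding, peptide + pseudo-sequence
# pair inputs consumed by the network.

#' Amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes in the conventional
#' A,R,N,D,... order, plus `"-"` as the padding symbol. Non-canonical
#' residues (B, J, O, U, X, Z) are rejected everywhere to keep encodings
#' injective.
#'
#' @format Character vector of length 20 (`aa_alphabet`) or 1 (`aa_pad`).
#' @export
aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @rdname aa_alphabet
#' @export
aa_pad <- "-"

.enc_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' Returns the standard published BLOSUM62 matrix (half-bit scores) over the
#' 20 canonical residues, read from the data file shipped with the package.
#'
#' @return A symmetric 20 x 20 integer matrix with residue dimnames.
#' @export
blosum62_matrix <- function() {
  if (is.null(.enc_cache$blosum62)) {
    path <- system.file("extdata", "blosum62.tsv", package = "mhcbind")
    m <- as.matrix(utils::read.delim(path, comment.char = "#", row.names = 1,
                                     check.names = FALSE))
    storage.mode(m) <- "integer"
    stopifnot(identical(rownames(m), aa_alphabet), all(m == t(m)))
    .enc_cache$blosum62 <- m
  }
  .enc_cache$blosum62
}

# Split a sequence string into residues and map to indices 1..20, pad -> 21.
# Errors name the first offending position.
.residue_index <- function(seq, allow_pad = TRUE, what = "sequence") {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  alphabet <- c(aa_alphabet, aa_pad)
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1]
    stop(sprintf("invalid character '%s' at position %d of %s '%s'",
                 chars[pos], pos, what, seq), call. = FALSE)
  }
  if (!allow_pad && any(idx == 21L)) {
    pos <- which(idx == 21L)[1]
    stop(sprintf("padding symbol not allowed at position %d of %s '%s'",
                 pos, what, seq), call. = FALSE)
  }
  idx
}

#' One-hot encode a peptide or pseudo-sequence
#'
#' Each residue becomes a row of length 21 with a single 1 at the residue's
#' alphabet index; the padding symbol `"-"` maps to an all-zero row.
#'
#' @param seq Character scalar over the 20-letter alphabet, optionally
#'   containing the padding symbol.
#' @return Numeric matrix of dimension `nchar(seq)` x 21.
#' @export
#' @examples
#' encode_one_hot("ACD")
encode_one_hot <- function(seq) {
  idx <- .residue_index(seq)
  L <- length(idx)
  m <- matrix(0, L, 21L, dimnames = list(NULL, c(aa_alphabet, aa_pad)))
  keep <- idx != 21L
  if (any(keep)) m[cbind(which(keep), idx[keep])] <- 1
  m
}

#' BLOSUM62-encode a peptide
#'
#' Row i is the BLOSUM62 substitution-score row of residue i; the padding
#' symbol maps to an all-zero row.
#'
#' @inheritParams encode_one_hot
#' @return Numeric matrix of dimension `nchar(seq)` x 20.
#' @export
encode_blosum62 <- function(seq) {
  idx <- .residue_index(seq)
  B <- blosum62_matrix()
  m <- matrix(0, length(idx), 20L, dimnames = list(NULL, aa_alphabet))
  keep <- idx != 21L
  if (any(keep)) m[keep, ] <- B[idx[keep], , drop = FALSE]
  m
}

#' Middle-pad a peptide to a fixed length
#'
#' Pads with `"-"` inserted after position `ceiling(L/2)` so that both the
#' N-terminal and the C-terminal anchor positions keep their offsets from the
#' respective sequence ends, which is where class-I binding motifs live.
#'
#' @param seq Peptide string (no padding symbols).
#' @param target_length Final length; must be `>= nchar(seq)`.
#' @return The padded string of exactly `target_length` characters.
#' @export
#' @examples
#' pad_sequence("ACDEFGHI", 10) # "ACDE--FGHI"
pad_sequence <- function(seq, target_length) {
  .residue_index(seq, allow_pad = FALSE, what = "peptide")
  L <- nchar(seq)
  if (L > target_length) {
    stop(sprintf("peptide '%s' (length %d) exceeds target length %d",
                 seq, L, target_length), call. = FALSE)
  }
  if (L == target_length) return(toupper(seq))
  cut <- ceiling(L / 2)
  seq <- toupper(seq)
  paste0(substr(seq, 1L, cut),
         strrep(aa_pad, target_length - L),
         substr(seq, cut + 1L, L))
}

#' Read an allele pseudo-sequence table
#'
#' Two-column TSV `allele<TAB>pseudo_sequence`; lines starting with `#` and
#' blank lines are skipped. All pseudo-sequences must share one length and
#' allele names must be unique.
#'
#' @param path Path to the TSV file.
#' @return Named character vector: `names` are allele names, values the
#'   fixed-length pseudo-sequences (upper-cased).
#' @export
read_pseudo_table <- function(path) {
  df <- read_table(path, schema = "pseudo")
  seqs <- toupper(df$pseudo_sequence)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop("pseudo-sequences have mixed lengths: ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$allele)) {
    stop("duplicate allele name in pseudo-sequence table: ",
         df$allele[duplicated(df$allele)][1], call. = FALSE)
  }
  for (s in seqs) .residue_index(s, allow_pad = FALSE, what = "pseudo-sequence")
  stats::setNames(seqs, df$allele)
}

#' Build the fused peptide + allele network input
#'
#' Middle-pads the peptide to `max_pep_len`, concatenates it with the allele
#' pseudo-sequence, and returns the one-hot pair matrix (also usable as the
#' single-channel 2D image view) together with the BLOSUM62 encoding of the
#' padded peptide.
#'
#' @param peptide Peptide string.
#' @param pseudo Allele pseudo-sequence string (no padding).
#' @param max_pep_len Fixed padded peptide length (14 for class I, 21 for
#'   class II by default elsewhere).
#' @return An object of class `encoded_pair`: list with `onehot_pair`
#'   (`(max_pep_len + nchar(pseudo))` x 21), `blosum_peptide`
#'   (`max_pep_len` x 20), `image_view` (identical values to `onehot_pair`),
#'   and the padded sequences.
#' @export
build_pair_input <- function(peptide, pseudo, max_pep_len) {
  padded <- pad_sequence(peptide, max_pep_len)
  .residue_index(pseudo, allow_pad = FALSE, what = "pseudo-sequence")
  pair <- paste0(padded, toupper(pseudo))
  onehot <- encode_one_hot(pair)
  structure(list(
    onehot_pair    = onehot,
    blosum_peptide = encode_blosum62(padded),
    image_view     = onehot,
    padded_peptide = padded,
    pair_sequence  = pair
  ), class = "encoded_pair")
}

# Batched integer encoding of a peptide/allele table for the network engine.
# Returns residue-index matrix (n x T, pad = 21) and flattened BLOSUM block
# (n x max_pep_len*20, row-major per position).
encode_dataset <- function(peptide, allele, pseudo_table, max_pep_len) {
  missing <- setdiff(unique(allele), names(pseudo_table))
  if (length(missing)) {
    stop("no pseudo-sequence for allele(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pseudo_len <- nchar(pseudo_table[[1]])
  n <- length(peptide)
  T_len <- max_pep_len + pseudo_len
  idx <- matrix(21L, n, T_len)
  blosum <- matrix(0, n, max_pep_len * 20L)
  B <- blosum62_matrix()
  # encode unique peptides once
  up <- unique(peptide)
  pep_rows <- match(peptide, up)
  pep_idx <- matrix(21L, length(up), max_pep_len)
  for (i in seq_along(up)) {
    pep_idx[i, ] <- .residue_index(pad_sequence(up[i], max_pep_len))
  }
  idx[, seq_len(max_pep_len)] <- pep_idx[pep_rows, , drop = FALSE]
  ua <- unique(allele)
  al_idx <- t(vapply(pseudo_table[ua], function(s)
    .residue_index(s, allow_pad = FALSE, what = "pseudo-sequence"),
    integer(pseudo_len)))
  idx[, max_pep_len + seq_len(pseudo_len)] <-
    al_idx[match(allele, ua), , drop = FALSE]
  # BLOSUM block: position-major flattening (residue scores contiguous per position)
  Bpad <- rbind(B, rep(0L, 20L)) # row 21 = padding
  for (p in seq_len(max_pep_len)) {
    blosum[, (p - 1L) * 20L + seq_len(20L)] <- Bpad[idx[, p], , drop = FALSE]
  }
  list(idx = idx, blosum = blosum, T_len = T_len,
       max_pep_len = max_pep_len, pseudo_len = pseudo_len)
}
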