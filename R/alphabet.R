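#' The 20-letter amino-acid alphabet, alphabetical order
#'
#' Fixed ordering used for one-hot columns and the skip-gram vocabulary.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Conjoint-triad grouping of the 20 residues into 7 classes by dipole and
# side-chain volume; class 7 (cysteine) stands alone for its covalent bonds.
AA_CLASSES <- list(
  c("A", "G", "V"),
  c("I", "L", "F", "P"),
  c("Y", "M", "T", "S"),
  c("H", "N", "Q", "W"),
  c("R", "K"),
  c("D", "E"),
  c("C")
)

# residue letter -> class index 1..7 (NA for non-standard letters)
.aa_class_map <- local({
  m <- rep(NA_integer_, 26)
  for (k in seq_along(AA_CLASSES)) {
    m[utf8ToInt(paste(AA_CLASSES[[k]], collapse = "")) - 64L] <- k
  }
  names(m) <- LETTERS
  m
})

# residue letter -> alphabet index 1..20 (NA for non-standard letters)
.aa_index_map <- local({
  m <- rep(NA_integer_, 26)
  m[utf8ToInt(paste(AA_ALPHABET, collapse = "")) - 64L] <- seq_along(AA_ALPHABET)
  names(m) <- LETTERS
  m
})

.residue_indices <- function(residues) {
  .aa_index_map[utf8ToInt(residues) - 64L]
}

.residue_classes <- function(residues) {
  .aa_class_map[utf8ToInt(residues) - 64L]
}

# 7-class composition frequency vector of a residue string; non-standard
# residues are ignored in the tally.
.class_composition <- function(residues) {
  cl <- .residue_classes(residues)
  v <- tabulate(cl[!is.na(cl)], nbins = 7L)
  tot <- sum(v)
  if (tot == 0L) rep(0, 7L) else v / tot
}
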