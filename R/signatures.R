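#' Construct a signature set
#'
#' A signature set is a 96 x K column-stochastic matrix: each column holds one
#' predefined mutational signature's probability over the 96
#' pyrimidine-centered substitution channels.
#'
#' @param matrix Numeric 96 x K matrix; rownames must be a permutation of
#'   [sbs_channels()] (rows are reordered to the canonical layout), colnames
#'   are the signature names.
#' @return A `signature_set` object (the canonical-ordered matrix).
#' @export
signature_set <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) != 96L) stop("signature matrix must have 96 rows")
  chans <- sbs_channels()
  if (is.null(rownames(m)) || !setequal(rownames(m), chans))
    stop("rownames must be the 96 substitution channels, e.g. 'A[C>T]G'")
  if (is.null(colnames(m))) stop("signature columns must be named")
  m <- m[chans, , drop = FALSE]
  if (any(m < 0)) stop("signature probabilities must be nonnegative")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6))
    stop("each signature column must sum to 1 (tolerance 1e-6)")
  structure(m, class = c("signature_set", "matrix"))
}

#' Read / write a signature matrix in the COSMIC text layout
#'
#' The COSMIC probabilities layout is a tab-separated table with one row per
#' channel and label columns (`Substitution Type`, `Trinucleotide` and/or
#' `Somatic Mutation Type`, e.g. `A[C>A]A`) followed by one numeric column
#' per signature. Row order is normalized to the canonical channel order on
#' read, regardless of input order.
#'
#' @param path TSV path.
#' @param sigs A `signature_set`.
#' @return `read_signature_matrix()` returns a `signature_set`;
#'   `write_signature_matrix()` returns `path` invisibly.
#' @export
read_signature_matrix <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  chans <- sbs_channels()
  lab_col <- which(vapply(d, function(col)
    is.character(col) && all(col %in% chans) && anyDuplicated(col) == 0L,
    logical(1)))[1]
  if (is.na(lab_col)) {
    # fall back to Substitution Type + Trinucleotide columns
    st <- which(vapply(d, function(col)
      is.character(col) && all(grepl("^[CT]>[ACGT]$", col)), logical(1)))[1]
    tr <- which(vapply(d, function(col)
      is.character(col) && all(grepl("^[ACGT]{3}$", col)), logical(1)))[1]
    if (is.na(st) || is.na(tr))
      stop("cannot locate channel labels in ", path)
    labels <- paste0(substr(d[[tr]], 1, 1), "[", d[[st]], "]", substr(d[[tr]], 3, 3))
  } else labels <- d[[lab_col]]
  num <- vapply(d, is.numeric, logical(1))
  m <- as.matrix(d[, num, drop = FALSE])
  rownames(m) <- labels
  signature_set(m)
}

#' @rdname read_signature_matrix
#' @export
write_signature_matrix <- function(sigs, path) {
  stopifnot(inherits(sigs, "signature_set"))
  chans <- rownames(sigs)
  d <- data.frame(
    `Substitution Type` = substr(chans, 3, 5),
    Trinucleotide = paste0(substr(chans, 1, 1), substr(chans, 3, 3),
                           substr(chans, 7, 7)),
    `Somatic Mutation Type` = chans,
    check.names = FALSE, stringsAsFactors = FALSE)
  d <- cbind(d, as.data.frame(unclass(sigs)))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Deterministic synthetic signature set
#'
#' A small set of synthetic signature profiles with the qualitative character
#' of well-known COSMIC signatures, for simulation and testing when the
#' reference signature file is not available as an input artifact:
#'
#' * `SBS1`: C>T concentrated at NpCpG contexts (spontaneous deamination
#'   character);
#' * `SBS5`: flat, clock-like background over all channels;
#' * `SBS7a`, `SBS7b`: C>T at dipyrimidines (5' pyrimidine), the UV-damage
#'   character, with different context weighting;
#' * `SBS18`: C>A dominated (reactive-oxygen character).
#'
#' The profiles are fixed numeric constructions (no randomness) and are
#' clearly synthetic stand-ins, not COSMIC estimates.
#'
#' @return A `signature_set` with columns SBS1, SBS5, SBS7a, SBS7b, SBS18.
#' @export
synthetic_signature_set <- function() {
  chans <- sbs_channels()
  p5 <- substr(chans, 1, 1)
  ref <- substr(chans, 3, 3)
  alt <- substr(chans, 5, 5)
  p3 <- substr(chans, 7, 7)
  w <- function(x) x / sum(x)

  sbs1 <- rep(0.10 / 92, 96)
  sbs1[ref == "C" & alt == "T" & p3 == "G"] <- 0.90 / 4

  sbs5 <- rep(1, 96)
  sbs5[ref == "C" & alt == "T"] <- 2
  sbs5[ref == "T" & alt == "C"] <- 2
  sbs5 <- w(sbs5)

  sbs7a <- rep(0.06 / 88, 96)
  uv <- ref == "C" & alt == "T" & p5 %in% c("C", "T")
  sbs7a[uv] <- w(ifelse(p3[uv] %in% c("C", "T"), 2, 1)) * 0.94

  sbs7b <- rep(0.10 / 88, 96)
  sbs7b[uv] <- w(ifelse(p5[uv] == "T", 2.5, 1)) * 0.90

  sbs18 <- rep(0.12 / 80, 96)
  ca <- ref == "C" & alt == "A"
  sbs18[ca] <- w(ifelse(p5[ca] %in% c("A", "G"), 2, 1)) * 0.88

  m <- cbind(SBS1 = w(sbs1), SBS5 = sbs5, SBS7a = sbs7a,
             SBS7b = sbs7b, SBS18 = sbs18)
  rownames(m) <- chans
  signature_set(m)
}
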