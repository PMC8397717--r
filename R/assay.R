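#' Define a hotspot amplicon assay
#'
#' An amplicon assay describes one hairpin-barcoded amplicon: the fixed
#' primer-proximal anchor used to assign reads to the assay, the degenerate
#' molecular barcode, the hairpin stem whose expected position anchors barcode
#' extraction, and the amplified target region with its hotspot variant(s).
#' Reads are expected to have the structure
#' `anchor + barcode + stem + insert`, where `insert` aligns to
#' `reference_seq`.
#'
#' @param name Assay identifier, e.g. `"GNAQ_Q209"`.
#' @param anchor_seq Fixed anchor sequence expected at the very start of the
#'   read; used to assign a read to at most one assay by exact match.
#' @param stem_seq Hairpin stem sequence; must match exactly (up to
#'   `max_stem_mismatch` in [tag_reads()]) at `stem_offset`.
#' @param reference_seq Reference sequence of the amplified insert that
#'   follows the stem.
#' @param barcode_length Length of the degenerate barcode in nucleotides
#'   (default 12).
#' @param target_position 0-based offset of the hotspot base(s) within
#'   `reference_seq`.
#' @param target_ref Reference allele at the hotspot (one or more bases).
#' @param target_alts Character vector of alternate alleles, each the same
#'   length as `target_ref`.
#'
#' @return An object of class `amplicon_assay`.
#' @examples
#' assay <- amplicon_assay(
#'   name = "GNAQ_Q209", anchor_seq = "ACGTACGT", stem_seq = "GGCCGGCC",
#'   reference_seq = "ACCTGATCAGGTACTTGGACCGTA",
#'   target_position = 10, target_ref = "G", target_alts = c("T", "C"))
#' assay
#' @export
amplicon_assay <- function(name, anchor_seq, stem_seq, reference_seq,
                           barcode_length = 12L, target_position,
                           target_ref, target_alts) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  anchor_seq <- toupper(anchor_seq)
  stem_seq <- toupper(stem_seq)
  reference_seq <- toupper(reference_seq)
  target_ref <- toupper(target_ref)
  target_alts <- toupper(target_alts)
  if (!is_dna(anchor_seq)) stop("anchor_seq must be a non-empty ACGT string")
  if (!is_dna(stem_seq)) stop("stem_seq must be a non-empty ACGT string")
  if (!is_dna(reference_seq)) stop("reference_seq must be a non-empty ACGT string")
  barcode_length <- as.integer(barcode_length)
  if (barcode_length <= 0L) stop("barcode_length must be positive")
  target_position <- as.integer(target_position)
  if (target_position < 0L ||
      target_position + nchar(target_ref) > nchar(reference_seq))
    stop("target_position + nchar(target_ref) must fit inside reference_seq")
  if (substr(reference_seq, target_position + 1L,
             target_position + nchar(target_ref)) != target_ref)
    stop("target_ref disagrees with reference_seq at target_position")
  if (any(nchar(target_alts) != nchar(target_ref)) || !all(is_dna(target_alts)))
    stop("target_alts must be ACGT strings the same length as target_ref")
  if (any(target_alts == target_ref)) stop("target_alts must differ from target_ref")
  structure(list(
    name = name,
    anchor_seq = anchor_seq,
    stem_seq = stem_seq,
    reference_seq = reference_seq,
    barcode_length = barcode_length,
    # 0-based position in the read where the stem starts
    stem_offset = nchar(anchor_seq) + barcode_length,
    target_position = target_position,
    target_ref = target_ref,
    target_alts = target_alts
  ), class = "amplicon_assay")
}

#' @export
print.amplicon_assay <- function(x, ...) {
  cat(sprintf("<amplicon_assay> %s\n", x$name))
  cat(sprintf("  anchor %s | barcode %dnt | stem %s @ offset %d\n",
              x$anchor_seq, x$barcode_length, x$stem_seq, x$stem_offset))
  cat(sprintf("  insert %dnt; hotspot %s>%s at 0-based position %d\n",
              nchar(x$reference_seq), x$target_ref,
              paste(x$target_alts, collapse = "/"), x$target_position))
  invisible(x)
}

#' Read or write an assay panel configuration
#'
#' Assay panels are stored as YAML: a list of assay records with the fields of
#' [amplicon_assay()]. `read_assay_panel()` validates each record through the
#' constructor.
#'
#' @param path Path to a YAML file.
#' @param panel A named list of `amplicon_assay` objects.
#' @return `read_assay_panel()` returns a named list of `amplicon_assay`
#'   objects; `write_assay_panel()` returns `path` invisibly.
#' @seealso [synthetic_assay_panel()] for the bundled synthetic stand-in panel.
#' @export
read_assay_panel <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!length(cfg)) stop("empty assay panel: ", path)
  panel <- lapply(cfg, function(a)
    amplicon_assay(name = a$name, anchor_seq = a$anchor_seq,
                   stem_seq = a$stem_seq, reference_seq = a$reference_seq,
                   barcode_length = a$barcode_length %||% 12L,
                   target_position = a$target_position,
                   target_ref = a$target_ref,
                   target_alts = unlist(a$target_alts)))
  names(panel) <- vapply(panel, `[[`, character(1), "name")
  panel
}

#' @rdname read_assay_panel
#' @export
write_assay_panel <- function(panel, path) {
  recs <- lapply(unname(panel), function(a)
    list(name = a$name, anchor_seq = a$anchor_seq, stem_seq = a$stem_seq,
         reference_seq = a$reference_seq, barcode_length = a$barcode_length,
         target_position = a$target_position, target_ref = a$target_ref,
         target_alts = as.list(a$target_alts)))
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' Synthetic stand-in assay panel for the four uveal melanoma hotspots
#'
#' Hotspot assays targeting the recurrently mutated positions of the uveal
#' melanoma drivers GNAQ (Q209L/P), GNA11 (Q209L), CYSLTR2 (L129Q) and PLCB4
#' (D630Y). The anchor, stem and flanking sequences are synthetic stand-ins
#' with the geometry of hairpin-barcoded amplicon libraries; they are not the
#' proprietary assay oligos. Suitable for simulation and testing.
#'
#' @param barcode_length Barcode length in nucleotides (default 12).
#' @return Named list of [amplicon_assay()] objects.
#' @export
synthetic_assay_panel <- function(barcode_length = 12L) {
  mk <- function(name, anchor, stem, insert, pos, ref, alts)
    amplicon_assay(name, anchor, stem, insert, barcode_length, pos, ref, alts)
  panel <- list(
    # hotspot codon placed mid-insert; one-base substitutions emulating the
    # Q209L (A>T type) and Q209P changes
    mk("GNAQ_Q209",  "ACTGGTCA", "GCGCATGCGC",
       "TTCAGGTCCTTAGAAACGGGTATCTCGATGTAGCCA", 14L, "A", c("T", "C")),
    mk("GNA11_Q209", "TGACCAGT", "GCGCATGCGC",
       "CCATTGACGTTAACAGGGTCATAGGCTTTCAGACTG", 14L, "A", "T"),
    mk("CYSLTR2_L129", "GATCGTTG", "GCGCATGCGC",
       "AGGTCTTGAACCTGACATGATTCGCCTAGAGTTACC", 12L, "T", "A"),
    mk("PLCB4_D630", "CTAGGACT", "GCGCATGCGC",
       "GTTACCAGATTCGAAGACTGGTCTTAGCACGTATTG", 15L, "G", "T")
  )
  names(panel) <- vapply(panel, `[[`, character(1), "name")
  panel
}
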