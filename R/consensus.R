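#' Read amplicon FASTQ records
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning the plain
#' data frame representation used throughout the consensus module.
#'
#' @param path Path to a FASTQ file (optionally gzip-compressed).
#' @return A data frame with columns `read_id`, `sequence`, `qualities`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    read_id = names(x),
    sequence = as.character(x),
    qualities = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write amplicon reads to FASTQ
#'
#' @param reads Data frame with columns `read_id`, `sequence`, `qualities`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "qualities") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  q <- Biostrings::PhredQuality(reads$qualities)
  qx <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(qx, path)
  invisible(path)
}

#' Tag reads with assay assignment and molecular barcode
#'
#' Valid reads within each amplicon are those containing a barcode sequence in
#' the correct position relative to the hairpin stem. A read is assigned to at
#' most one assay by exact match of the assay's anchor sequence at the read
#' start; the barcode is the `barcode_length` bases between the anchor and the
#' stem. A read is invalid when no assay anchor matches, when the stem does
#' not match at its expected offset (within `max_stem_mismatch`
#' substitutions; default 0, the strictest reading), when the barcode
#' contains an ambiguous base, or when the read is too short to contain the
#' full insert.
#'
#' @param reads Data frame from [read_fastq()] (columns `read_id`,
#'   `sequence`, `qualities`).
#' @param assays List of [amplicon_assay()] objects.
#' @param max_stem_mismatch Number of substitutions tolerated in the stem
#'   (default 0).
#' @return A data frame of tagged reads: `read_id`, `assay`, `barcode`,
#'   `insert` (the reference-aligned portion after the stem) and `valid`.
#'   Invalid reads keep `NA` barcodes/inserts.
#' @export
tag_reads <- function(reads, assays, max_stem_mismatch = 0L) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence") %in% names(reads)))
  if (!is.null(reads$qualities) &&
      any(nchar(reads$qualities) != nchar(reads$sequence)))
    stop("malformed FASTQ record: sequence and quality lengths differ")
  if (inherits(assays, "amplicon_assay")) assays <- list(assays)
  n <- nrow(reads)
  seqs <- toupper(reads$sequence)

  assay_idx <- rep(NA_integer_, n)
  for (i in seq_along(assays)) {
    hit <- startsWith(seqs, assays[[i]]$anchor_seq)
    clash <- hit & !is.na(assay_idx)
    if (any(clash))
      stop("ambiguous assay assignment: anchors of more than one assay ",
           "match the same read (first read: ",
           reads$read_id[which(clash)[1]], ")")
    assay_idx[hit] <- i
  }

  barcode <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)
  valid <- rep(FALSE, n)
  for (i in seq_along(assays)) {
    a <- assays[[i]]
    sel <- which(assay_idx == i)
    if (!length(sel)) next
    s <- seqs[sel]
    stem_start <- a$stem_offset + 1L            # 1-based
    stem_end <- a$stem_offset + nchar(a$stem_seq)
    ins_end <- stem_end + nchar(a$reference_seq)
    long_enough <- nchar(s) >= ins_end
    stem_obs <- substr(s, stem_start, stem_end)
    if (max_stem_mismatch == 0L) {
      stem_ok <- stem_obs == a$stem_seq
    } else {
      stem_ok <- mismatch_count(stem_obs, a$stem_seq) <= max_stem_mismatch
    }
    bc <- substr(s, nchar(a$anchor_seq) + 1L, a$stem_offset)
    bc_ok <- is_dna(bc) & nchar(bc) == a$barcode_length
    ok <- long_enough & stem_ok & bc_ok
    barcode[sel] <- ifelse(ok, bc, NA_character_)
    insert[sel] <- ifelse(ok, substr(s, stem_end + 1L, ins_end), NA_character_)
    valid[sel] <- ok
  }

  data.frame(
    read_id = reads$read_id,
    assay = ifelse(is.na(assay_idx), NA_character_,
                   vapply(assays, `[[`, character(1), "name")[assay_idx]),
    barcode = barcode,
    insert = insert,
    valid = valid,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

mismatch_count <- function(x, ref) {
  rs <- strsplit(ref, NULL)[[1]]
  vapply(strsplit(x, NULL), function(s) {
    if (length(s) != length(rs)) return(length(rs))
    sum(s != rs)
  }, integer(1))
}

#' Group tagged reads into barcode families
#'
#' Reads are grouped into families by (amplicon, barcode): every valid tagged
#' read lands in exactly one family; invalid reads are dropped.
#'
#' @param tagged Data frame from [tag_reads()].
#' @return A list of `read_family` objects, each with fields `assay`,
#'   `barcode`, `size` and `inserts` (member insert sequences).
#' @export
build_families <- function(tagged) {
  stopifnot(is.data.frame(tagged),
            all(c("assay", "barcode", "insert", "valid") %in% names(tagged)))
  tv <- tagged[tagged$valid, , drop = FALSE]
  if (!nrow(tv)) return(list())
  key <- paste(tv$assay, tv$barcode, sep = "\r")
  idx <- split(seq_len(nrow(tv)), key)
  fams <- lapply(idx, function(ii) {
    structure(list(assay = tv$assay[ii[1]],
                   barcode = tv$barcode[ii[1]],
                   size = length(ii),
                   inserts = tv$insert[ii]),
              class = "read_family")
  })
  names(fams) <- NULL
  fams
}

# Family-size dependent threshold for reporting a nonreference base:
# all reads must agree for families of 3-20 reads; at least 90% for >20.
nonref_threshold <- function(size) ifelse(size > 20L, 0.9, 1.0)

#' Per-base consensus of one read family
#'
#' For reads within a family a consensus base is determined at each position.
#' A nonreference base is reported only if it composes 100% of the reads in
#' families with 3–20 reads, or at least 90% of reads in families with more
#' than 20 reads; otherwise the reference base is called. When several
#' distinct nonreference bases are present the threshold is applied to the
#' single most frequent one (ties broken alphabetically); if it fails and no
#' read supports the reference either, the position is a no-call. Families
#' below `min_family_size` are excluded (return `NULL`).
#'
#' @param family A `read_family` from [build_families()].
#' @param assay The corresponding [amplicon_assay()].
#' @param min_family_size Minimum usable family size (default 3, the lower
#'   bound of the 100% rule).
#' @return A `consensus_seq` object (fields `assay`, `barcode`,
#'   `family_size`, `bases` — the called sequence —, `support` — per-position
#'   support fraction —, `no_call` — positions without a call), or `NULL` for
#'   families below `min_family_size`.
#' @export
consensus_call <- function(family, assay, min_family_size = 3L) {
  stopifnot(inherits(family, "read_family"), inherits(assay, "amplicon_assay"))
  if (family$assay != assay$name)
    stop("family does not belong to assay ", assay$name)
  if (family$size < min_family_size) return(NULL)
  L <- nchar(assay$reference_seq)
  if (any(nchar(family$inserts) != L))
    stop("consensus error: reads of unequal aligned length within a family")
  cc <- consensus_core(family$inserts, rep(1L, family$size), 1L, assay)
  structure(list(assay = assay$name, barcode = family$barcode,
                 family_size = family$size,
                 bases = cc$called[1, ], support = cc$support[1, ],
                 no_call = which(is.na(cc$called[1, ]))),
            class = "consensus_seq")
}

# Vectorized consensus over many families of one assay.
# inserts: character vector of equal-length insert sequences;
# fam: integer family index per read (1..nfam). Returns called base matrix
# (nfam x L, NA = no call) and support fraction matrix.
consensus_core <- function(inserts, fam, nfam, assay) {
  L <- nchar(assay$reference_seq)
  n <- length(inserts)
  m <- matrix(unlist(strsplit(inserts, NULL), use.names = FALSE),
              nrow = L, ncol = n)
  counts <- array(0, dim = c(nfam, L, 4L))
  for (b in seq_along(DNA_BASES)) {
    hit <- t(m == DNA_BASES[b]) + 0    # n x L
    counts[, , b] <- rowsum(hit, fam, reorder = TRUE)
  }
  size <- as.vector(rowsum(rep(1, n), fam, reorder = TRUE))
  ref <- match(strsplit(assay$reference_seq, NULL)[[1]], DNA_BASES)

  refcnt <- matrix(0, nfam, L)
  for (j in seq_len(L)) refcnt[, j] <- counts[, j, ref[j]]
  # modal nonreference base per (family, position), alphabetical tie-break
  best_nr_cnt <- matrix(0, nfam, L)
  best_nr_base <- matrix(NA_integer_, nfam, L)
  for (b in seq_along(DNA_BASES)) {
    cb <- counts[, , b]
    isref <- matrix(rep(ref == b, each = nfam), nfam, L)
    cb[isref] <- -1
    better <- cb > best_nr_cnt
    best_nr_base[better] <- b
    best_nr_cnt[better] <- cb[better]
  }
  tot <- matrix(size, nfam, L)
  nr_frac <- best_nr_cnt / tot
  thr <- matrix(nonref_threshold(size), nfam, L)
  call_nr <- nr_frac >= thr & best_nr_cnt > 0
  called <- matrix(rep(ref, each = nfam), nfam, L)
  called[call_nr] <- best_nr_base[call_nr]
  support <- refcnt / tot
  support[call_nr] <- nr_frac[call_nr]
  # no reference support and threshold not met: no call
  nocall <- !call_nr & refcnt == 0
  called[nocall] <- NA_integer_
  support[nocall] <- NA_real_
  list(called = matrix(DNA_BASES[called], nfam, L),
       support = support, size = size)
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat(sprintf("<consensus_seq> %s barcode %s (family of %d)\n",
              x$assay, x$barcode, x$family_size))
  seq <- x$bases; seq[is.na(seq)] <- "N"
  cat(" ", paste(seq, collapse = ""), "\n")
  invisible(x)
}

#' Quantify variant allele frequency from consensus families
#'
#' Classifies every consensus family at the assay's hotspot as mutant
#' (matches one of `target_alts`), wildtype (matches `target_ref`) or no-call
#' (anything else, including no-call positions), and computes
#' VAF = mutant / (mutant + wildtype) — the fraction of mutant families among
#' families with a classifiable allele, reported in percent in exported
#' tables. No-call families enter neither numerator nor denominator.
#'
#' @param consensuses List of `consensus_seq` objects for one assay (as from
#'   [consensus_call()]); `NULL` entries (excluded families) are ignored.
#' @param assay The [amplicon_assay()] the consensuses belong to.
#' @return A `variant_call` object: one-row data frame with columns `assay`,
#'   `position` (1-based), `ref`, `alt`, `mutant_families`,
#'   `wildtype_families`, `nocall_families`, `vaf` (fraction, `NA` when no
#'   classifiable family exists) and `vaf_percent`.
#' @export
quantify_vaf <- function(consensuses, assay) {
  stopifnot(inherits(assay, "amplicon_assay"))
  consensuses <- Filter(Negate(is.null), consensuses)
  if (length(consensuses)) {
    bad <- vapply(consensuses, function(cs) cs$assay != assay$name, logical(1))
    if (any(bad)) stop("consensus families from a different assay than ", assay$name)
  }
  w <- nchar(assay$target_ref)
  pos <- assay$target_position + seq_len(w)     # 1-based columns
  allele <- vapply(consensuses, function(cs) {
    b <- cs$bases[pos]
    if (anyNA(b)) NA_character_ else paste(b, collapse = "")
  }, character(1))
  mut <- sum(allele %in% assay$target_alts, na.rm = TRUE)
  wt <- sum(allele == assay$target_ref, na.rm = TRUE)
  nocall <- length(allele) - mut - wt
  vaf <- if (mut + wt > 0) mut / (mut + wt) else NA_real_
  if (mut + wt == 0 && length(allele))
    warning("no classifiable family for assay ", assay$name,
            ": VAF undetectable (NA)")
  out <- data.frame(
    assay = assay$name,
    position = assay$target_position + 1L,
    ref = assay$target_ref,
    alt = paste(assay$target_alts, collapse = ","),
    mutant_families = mut,
    wildtype_families = wt,
    nocall_families = nocall,
    vaf = vaf,
    vaf_percent = 100 * vaf,
    stringsAsFactors = FALSE
  )
  class(out) <- c("variant_call", class(out))
  out
}

#' End-to-end consensus variant calling
#'
#' Runs the full pipeline — tagging, family grouping, per-base consensus with
#' the family-size dependent thresholds, and VAF quantification — over a set
#' of reads for a panel of assays. The consensus step uses a vectorized
#' implementation of the same rule as [consensus_call()].
#'
#' @param reads FASTQ records as a data frame ([read_fastq()]) or a path to a
#'   FASTQ file.
#' @param assays List of [amplicon_assay()] objects (or a single assay).
#' @param min_family_size Minimum family size used in consensus (default 3).
#' @param max_stem_mismatch Stem matching tolerance (default 0).
#' @return A data frame with one `variant_call` row per assay. Attributes:
#'   `n_valid_reads`, `n_families`, `family_sizes` (table).
#' @export
call_variants <- function(reads, assays, min_family_size = 3L,
                          max_stem_mismatch = 0L) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  if (inherits(assays, "amplicon_assay")) assays <- list(assays)
  tagged <- tag_reads(reads, assays, max_stem_mismatch = max_stem_mismatch)
  tv <- tagged[tagged$valid, , drop = FALSE]
  rows <- vector("list", length(assays))
  nfam_total <- 0L
  all_sizes <- integer(0)
  for (i in seq_along(assays)) {
    a <- assays[[i]]
    ta <- tv[tv$assay == a$name, , drop = FALSE]
    if (!nrow(ta)) {
      rows[[i]] <- quantify_vaf(list(), a)
      next
    }
    fam <- match(ta$barcode, unique(ta$barcode))
    nfam <- max(fam)
    cc <- consensus_core(ta$insert, fam, nfam, a)
    keep <- cc$size >= min_family_size
    all_sizes <- c(all_sizes, cc$size)
    nfam_total <- nfam_total + nfam
    w <- nchar(a$target_ref)
    pos <- a$target_position + seq_len(w)
    alle <- apply(cc$called[keep, pos, drop = FALSE], 1,
                  function(b) if (anyNA(b)) NA_character_ else paste(b, collapse = ""))
    mut <- sum(alle %in% a$target_alts, na.rm = TRUE)
    wt <- sum(alle == a$target_ref, na.rm = TRUE)
    nocall <- length(alle) - mut - wt
    vaf <- if (mut + wt > 0) mut / (mut + wt) else NA_real_
    rows[[i]] <- data.frame(
      assay = a$name, position = a$target_position + 1L, ref = a$target_ref,
      alt = paste(a$target_alts, collapse = ","), mutant_families = mut,
      wildtype_families = wt, nocall_families = nocall, vaf = vaf,
      vaf_percent = 100 * vaf, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("variant_call", class(out))
  attr(out, "n_valid_reads") <- nrow(tv)
  attr(out, "n_families") <- nfam_total
  attr(out, "family_sizes") <- table(all_sizes)
  out
}

#' Export variant calls as TSV
#'
#' Writes the per-sample variant table (VAF in percent, 1-based positions).
#'
#' @param calls A `variant_call` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_calls <- function(calls, path) {
  cols <- c("assay", "position", "ref", "alt", "mutant_families",
            "wildtype_families", "nocall_families", "vaf_percent")
  write.table(as.data.frame(calls)[, cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
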