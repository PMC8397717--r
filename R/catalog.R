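#' The canonical 96 single-base-substitution channels
#'
#' Pyrimidine-centered channel labels in the standard order: substitution
#' classes C>A, C>G, C>T, T>A, T>C, T>G, each crossed with the 16 flanking
#' contexts (5' base A,C,G,T by 3' base A,C,G,T), written e.g. `A[C>T]G`.
#'
#' @return Character vector of length 96.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1, 1)
    for (p5 in DNA_BASES) for (p3 in DNA_BASES)
      out <- c(out, paste0(p5, "[", s, "]", p3))
  }
  out
}

#' Build a 96-channel mutation catalog from somatic SNVs
#'
#' Applies the catalog inclusion filters — autosomal mutations only
#' (chromosomes 1–22), not present in any population variant resource,
#' alternate-allele read support of at least 5, single-nucleotide ref and alt
#' — and bins the survivors into the 96 pyrimidine-centered trinucleotide
#' channels. Mutations with a purine reference base (A or G) are
#' reverse-complemented into their pyrimidine-centered channel.
#'
#' @param mutations Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `t_alt_count` (alt-supporting reads) and `in_population_resource`
#'   (logical). A `context` column (reference trinucleotide centered on the
#'   site) may be supplied instead of `context_provider`.
#' @param context_provider Either `NULL` (use the `context` column) or a
#'   function `(chrom, pos) -> trinucleotide` vectorized over its arguments.
#' @param sample_id Optional sample identifier stored on the catalog.
#' @param min_alt_reads Minimum alt-supporting read count (default 5).
#' @return A `mutation_catalog`: named integer vector of length 96 (names
#'   from [sbs_channels()]), with attributes `sample_id` and `n_excluded`.
#' @examples
#' mut <- data.frame(chrom = "1", pos = 100, ref = "C", alt = "T",
#'                   t_alt_count = 12, in_population_resource = FALSE,
#'                   context = "ACA")
#' build_catalog(mut)
#' @export
build_catalog <- function(mutations, context_provider = NULL,
                          sample_id = NA_character_, min_alt_reads = 5L) {
  req <- c("chrom", "pos", "ref", "alt", "t_alt_count", "in_population_resource")
  stopifnot(is.data.frame(mutations), all(req %in% names(mutations)))
  m <- mutations
  m$chrom <- sub("^chr", "", as.character(m$chrom))
  keep <- m$chrom %in% as.character(1:22) &
    !m$in_population_resource &
    m$t_alt_count >= min_alt_reads &
    nchar(m$ref) == 1L & nchar(m$alt) == 1L &
    m$ref %in% DNA_BASES & m$alt %in% DNA_BASES & m$ref != m$alt
  m <- m[keep, , drop = FALSE]

  counts <- setNames(integer(96), sbs_channels())
  if (nrow(m)) {
    ctx <- if (is.null(context_provider)) {
      if (is.null(mutations$context))
        stop("supply a `context` column or a context_provider function")
      toupper(m$context)
    } else toupper(context_provider(m$chrom, m$pos))
    if (any(nchar(ctx) != 3L))
      stop("contexts must be trinucleotides centered on the mutated base")
    if (any(substr(ctx, 2, 2) != m$ref))
      stop("data-consistency error: context center base disagrees with ref")
    flip <- m$ref %in% c("A", "G")
    ctx[flip] <- revcomp(ctx[flip])
    alt <- m$alt
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    ref <- substr(ctx, 2, 2)
    chan <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
    tab <- table(factor(chan, levels = sbs_channels()))
    counts[] <- as.integer(tab)
  }
  structure(counts, sample_id = sample_id,
            n_excluded = nrow(mutations) - nrow(m),
            class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat(sprintf("<mutation_catalog> %s: %d mutations over 96 channels (%d excluded by filters)\n",
              attr(x, "sample_id"), sum(x), attr(x, "n_excluded") %||% NA))
  invisible(x)
}

#' Read a MAF-like somatic mutation table
#'
#' Expects a tab-separated file with columns `chrom`, `pos`, `ref`, `alt`,
#' `t_alt_count`, `in_population_resource` and optionally `context`.
#'
#' @param path TSV path.
#' @return Data frame suitable for [build_catalog()].
#' @export
read_maf_like <- function(path) {
  # read everything as character first: "T" alleles must not become logicals
  m <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("chrom", "pos", "ref", "alt", "t_alt_count", "in_population_resource")
  missing_cols <- setdiff(req, names(m))
  if (length(missing_cols))
    stop("MAF-like table misses columns: ", paste(missing_cols, collapse = ", "))
  m$pos <- as.integer(m$pos)
  m$t_alt_count <- as.numeric(m$t_alt_count)
  m$in_population_resource <- as.logical(m$in_population_resource)
  m
}
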