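#' Specification for simulated hairpin-barcoded amplicon reads
#'
#' @param assay An [amplicon_assay()].
#' @param true_vaf True variant allele fraction among template molecules.
#' @param n_molecules Number of template molecules.
#' @param reads_per_family_mean Mean of the per-molecule read-count
#'   distribution (Poisson truncated at >= 1; default 10).
#' @param per_base_error Per-base substitution error probability applied
#'   independently to barcode and insert bases (default 1e-3). Errors
#'   substitute uniformly to the three alternative bases.
#' @param stem_corruption_prob Probability that a read's stem carries a
#'   substitution (making the read invalid; default 0).
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, seed).
#' @return A `read_sim_spec` object.
#' @export
read_sim_spec <- function(assay, true_vaf, n_molecules,
                          reads_per_family_mean = 10,
                          per_base_error = 1e-3,
                          stem_corruption_prob = 0, seed = 1L) {
  stopifnot(inherits(assay, "amplicon_assay"),
            true_vaf >= 0, true_vaf <= 1, n_molecules >= 1,
            reads_per_family_mean > 0,
            per_base_error >= 0, per_base_error <= 1,
            stem_corruption_prob >= 0, stem_corruption_prob <= 1)
  structure(list(assay = assay, true_vaf = true_vaf,
                 n_molecules = as.integer(n_molecules),
                 reads_per_family_mean = reads_per_family_mean,
                 per_base_error = per_base_error,
                 stem_corruption_prob = stem_corruption_prob,
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

# collapse the columns of a character matrix into strings (fast row-wise paste)
paste_cols <- function(m) do.call(paste0, lapply(seq_len(nrow(m)), function(i) m[i, ]))

# substitute positions of a character base matrix (L x n) uniformly to one of
# the three alternative bases
substitute_errors <- function(m, idx) {
  if (!length(idx)) return(m)
  cur <- m[idx]
  shift <- sample.int(3L, length(idx), replace = TRUE)
  m[idx] <- DNA_BASES[((match(cur, DNA_BASES) - 1L + shift) %% 4L) + 1L]
  m
}

#' Simulate hairpin-barcoded amplicon reads with truth labels
#'
#' Draws each template molecule's allele (mutant with probability
#' `true_vaf`; mutant molecules carry one of the assay's alternate alleles,
#' chosen uniformly), a random barcode, and a family size from a
#' zero-truncated Poisson; then emits reads structured
#' `anchor + barcode + stem + insert` with independent per-base substitution
#' errors on barcode and insert, and optional per-read stem corruption (one
#' substituted stem base). The truth table records every molecule's allele,
#' barcode and emitted read count, and the summary attributes record the
#' per-read corruption bookkeeping needed to score the tagging stage.
#'
#' @param spec A `read_sim_spec` from [read_sim_spec()].
#' @param fastq_path Optional path; when given, reads are also written as
#'   FASTQ via [write_fastq()].
#' @return List with `reads` (data frame: `read_id`, `sequence`,
#'   `qualities`), `truth` (data frame per molecule: `molecule`, `allele`
#'   ("ref" or the alt string), `barcode`, `n_reads`) and `stats` (list:
#'   `n_reads`, `n_stem_corrupted`, `n_barcode_collisions`).
#' @export
simulate_reads <- function(spec, fastq_path = NULL) {
  stopifnot(inherits(spec, "read_sim_spec"))
  a <- spec$assay
  with_seed(spec$seed, {
    nmol <- spec$n_molecules
    mutant <- runif(nmol) < spec$true_vaf
    alt <- sample(a$target_alts, nmol, replace = TRUE)
    allele <- ifelse(mutant, alt, "ref")
    bc <- matrix(sample(DNA_BASES, nmol * a$barcode_length, replace = TRUE),
                 nrow = a$barcode_length)
    barcode <- paste_cols(bc)
    lambda <- spec$reads_per_family_mean
    # zero-truncated Poisson via quantile transform
    nreads <- qpois(runif(nmol, ppois(0, lambda), 1), lambda)

    mol_of_read <- rep.int(seq_len(nmol), nreads)
    n <- length(mol_of_read)
    L <- nchar(a$reference_seq)
    w <- nchar(a$target_ref)

    # insert bases per read (L x n), mutants carry their alt at the hotspot
    ins <- matrix(rep(strsplit(a$reference_seq, NULL)[[1]], n), nrow = L)
    mut_reads <- which(mutant[mol_of_read])
    if (length(mut_reads)) {
      altmat <- matrix(unlist(strsplit(alt[mol_of_read[mut_reads]], NULL),
                              use.names = FALSE), nrow = w)
      ins[a$target_position + seq_len(w), mut_reads] <- altmat
    }
    # per-base errors on insert and barcode
    bcr <- bc[, mol_of_read, drop = FALSE]
    if (spec$per_base_error > 0) {
      ins <- substitute_errors(ins, which(runif(L * n) < spec$per_base_error))
      bcr <- substitute_errors(bcr, which(runif(a$barcode_length * n) <
                                            spec$per_base_error))
    }
    # stem corruption: one substituted base in the stem of affected reads
    stem <- rep(a$stem_seq, n)
    corrupted <- runif(n) < spec$stem_corruption_prob
    if (any(corrupted)) {
      sl <- nchar(a$stem_seq)
      ci <- which(corrupted)
      pos <- sample.int(sl, length(ci), replace = TRUE)
      old <- substr(rep(a$stem_seq, length(ci)), pos, pos)
      new <- DNA_BASES[((match(old, DNA_BASES) - 1L +
                           sample.int(3L, length(ci), TRUE)) %% 4L) + 1L]
      s <- strsplit(stem[ci], NULL)
      stem[ci] <- vapply(seq_along(ci), function(k) {
        v <- s[[k]]; v[pos[k]] <- new[k]; paste(v, collapse = "")
      }, character(1))
    }
    seqs <- paste0(a$anchor_seq, paste_cols(bcr), stem, paste_cols(ins))
    reads <- data.frame(
      read_id = sprintf("%s_mol%06d_r%03d", a$name, mol_of_read,
                        sequence(nreads)),
      sequence = seqs,
      qualities = strrep("I", nchar(seqs)),
      stringsAsFactors = FALSE)
    truth <- data.frame(molecule = seq_len(nmol), allele = allele,
                        barcode = barcode, n_reads = nreads,
                        stringsAsFactors = FALSE)
    stats <- list(n_reads = n,
                  n_stem_corrupted = sum(corrupted),
                  n_barcode_collisions = nmol - length(unique(barcode)))
    if (!is.null(fastq_path)) write_fastq(reads, fastq_path)
    list(reads = reads, truth = truth, stats = stats)
  })
}

#' Simulate a 96-channel catalog from a signature mixture
#'
#' Multinomial draw of `n_mutations` over the 96 channels from the mixture
#' distribution `signatures %*% weights`.
#'
#' @param weights Named nonnegative vector of mixture weights over (a subset
#'   of) the signature set's columns, summing to 1.
#' @param n_mutations Number of mutations to draw.
#' @param signatures A `signature_set`.
#' @param seed Integer seed.
#' @return A `mutation_catalog` with attribute `truth_weights`.
#' @export
simulate_catalog <- function(weights, n_mutations, signatures, seed = 1L) {
  stopifnot(inherits(signatures, "signature_set"))
  if (any(weights < 0)) stop("parameter error: negative mixture weight")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (is.null(names(weights)) ||
      !all(names(weights) %in% colnames(signatures)))
    stop("weights must be named after signature set columns")
  p <- as.numeric(unclass(signatures)[, names(weights), drop = FALSE] %*% weights)
  counts <- with_seed(seed, as.integer(rmultinom(1, n_mutations, p)))
  structure(setNames(counts, rownames(signatures)),
            sample_id = "simulated", n_excluded = 0L,
            truth_weights = weights, class = "mutation_catalog")
}

#' Specification for a simulated clinical cohort
#'
#' @param n_patients Number of patients (default 29, a typical two-stage
#'   phase II cohort).
#' @param baseline_hazard Exponential event rate per month for a patient
#'   with favorable biomarkers (default `log(2) / 13.4`, i.e. a 13.4-month
#'   median in the favorable stratum).
#' @param log_hr Named numeric vector of log hazard ratios for
#'   `ctdna_high`, `ldh_above_uln` and `bap1_mutant` (defaults 0.9, 0.8,
#'   0.7).
#' @param censor_time Administrative censoring time in months from first
#'   dose (default 22).
#' @param accrual_months Accrual window; each patient's follow-up is
#'   `censor_time - U(0, accrual_months)` (default 10).
#' @param response_probs Probabilities of best overall response
#'   `c(PR, SD, PD, NE)` (defaults 4/29, 4/29, 20/29, 1/29).
#' @param seed Integer seed.
#' @return A `cohort_sim_spec` object.
#' @export
cohort_sim_spec <- function(n_patients = 29L,
                            baseline_hazard = log(2) / 13.4,
                            log_hr = c(ctdna_high = 0.9,
                                       ldh_above_uln = 0.8,
                                       bap1_mutant = 0.7),
                            censor_time = 22,
                            accrual_months = 10,
                            response_probs = c(PR = 4, SD = 4, PD = 20,
                                               NE = 1) / 29,
                            seed = 1L) {
  stopifnot(n_patients >= 2L, baseline_hazard > 0, censor_time > 0,
            accrual_months >= 0, accrual_months < censor_time,
            all(response_probs >= 0), abs(sum(response_probs) - 1) < 1e-8,
            all(c("ctdna_high", "ldh_above_uln", "bap1_mutant") %in%
                  names(log_hr)))
  structure(list(n_patients = as.integer(n_patients),
                 baseline_hazard = baseline_hazard, log_hr = log_hr,
                 censor_time = censor_time, accrual_months = accrual_months,
                 response_probs = response_probs, seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' Simulate a clinical cohort table with truth parameters
#'
#' Draws per-patient biomarkers (log-normal ctDNA copies and LDH, driver
#' gene, BAP1 status, rare UV flag), then exponential event times whose
#' hazard multiplies the baseline by the configured hazard ratios for
#' ctDNA above the cohort median, LDH above the upper limit of normal and
#' BAP1-mutant status. Administrative censoring reflects staggered accrual.
#' Best overall response is sampled independently of survival.
#'
#' @param spec A `cohort_sim_spec`.
#' @param tsv_path Optional path; when given the table is also written as
#'   TSV.
#' @param ldh_uln Upper limit of normal used for the LDH flag (default 250).
#' @return Data frame (one row per patient) with columns `patient_id`,
#'   `time`, `event`, `ctdna_copies`, `ldh`, `ldh_above_uln`, `driver`,
#'   `bap1`, `uv`, `response`; attribute `truth` holds the generating
#'   parameters and per-patient linear predictors.
#' @export
simulate_cohort <- function(spec, tsv_path = NULL, ldh_uln = 250) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    ctdna <- stats::rlnorm(n, meanlog = 5, sdlog = 1.6)
    ldh <- stats::rlnorm(n, meanlog = log(ldh_uln) - 0.1, sdlog = 0.35)
    driver <- sample(c("GNAQ", "GNA11", "other"), n, replace = TRUE,
                     prob = c(0.5, 0.4, 0.1))
    bap1 <- sample(c("mutant", "wildtype", NA), n, replace = TRUE,
                   prob = c(0.55, 0.35, 0.10))
    uv <- runif(n) < 0.05
    ctdna_high <- ctdna > median(ctdna)
    ldh_high <- ldh > ldh_uln
    lp <- spec$log_hr["ctdna_high"] * ctdna_high +
      spec$log_hr["ldh_above_uln"] * ldh_high +
      spec$log_hr["bap1_mutant"] * (!is.na(bap1) & bap1 == "mutant")
    tev <- rexp(n, rate = spec$baseline_hazard * exp(lp))
    cens <- spec$censor_time - runif(n, 0, spec$accrual_months)
    time <- pmin(tev, cens)
    event <- as.integer(tev <= cens)
    response <- sample(names(spec$response_probs), n, replace = TRUE,
                       prob = spec$response_probs)
    d <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                    time = time, event = event,
                    ctdna_copies = ctdna, ldh = ldh,
                    ldh_above_uln = ldh_high, driver = driver,
                    bap1 = bap1, uv = uv, response = response,
                    stringsAsFactors = FALSE)
    attr(d, "truth") <- list(spec = spec, linear_predictor = as.numeric(lp),
                             event_time = tev, censor_time = cens,
                             ldh_uln = ldh_uln)
    if (!is.null(tsv_path))
      write.table(d, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
    d
  })
}
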