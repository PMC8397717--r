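sigs <- synthetic_signature_set()

mut_row <- function(chrom = "1", pos = 100L, ref = "C", alt = "T",
                    alt_reads = 10L, pop = FALSE, context = "ACA") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             t_alt_count = alt_reads, in_population_resource = pop,
             context = context, stringsAsFactors = FALSE)
}

test_that("catalog channels follow the pyrimidine-centered convention", {
  cl <- build_catalog(mut_row(ref = "C", alt = "T", context = "ACA"))
  expect_equal(sum(cl), 1L)
  expect_equal(unname(cl["A[C>T]A"]), 1L)
  # purine reference is reverse-complemented: G>A in TGA -> T[C>T]A
  cl2 <- build_catalog(mut_row(ref = "G", alt = "A", context = "TGA"))
  expect_equal(unname(cl2["T[C>T]A"]), 1L)
  expect_equal(sum(cl2), 1L)
  expect_equal(length(cl), 96L)
  expect_identical(names(cl), sbs_channels())
})

test_that("catalog filters drop low-support, population and non-autosomal mutations", {
  m <- rbind(mut_row(alt_reads = 4L),                 # support below 5
             mut_row(alt_reads = 5L),                 # exactly 5: included
             mut_row(chrom = "X"),                    # not autosomal
             mut_row(pop = TRUE),                     # population variant
             mut_row(ref = "C", alt = "CT"),          # not an SNV
             mut_row(chrom = "chr7"))                 # chr prefix accepted
  cl <- build_catalog(m)
  expect_equal(sum(cl), 2L)
  expect_equal(attr(cl, "n_excluded"), 4L)
})

test_that("a context center disagreeing with ref raises a consistency error", {
  expect_error(build_catalog(mut_row(ref = "C", context = "ATA")),
               "consistency")
})

test_that("NNLS matches the reference active-set solver on random instances", {
  skip_if_not_installed("pracma")
  set.seed(42)
  for (i in 1:20) {
    A <- matrix(abs(rnorm(30 * 4)), 30, 4)
    b <- abs(rnorm(30))
    ours <- nnls_lawson_hanson(A, b)
    ref <- pracma::lsqnonneg(A, b)
    expect_equal(ours$x, ref$x, tolerance = 1e-6)
    expect_equal(ours$residual, ref$resid.norm, tolerance = 1e-8)
  }
})

test_that("NNLS beats single-signature and projected unconstrained fits", {
  set.seed(7)
  W <- unclass(sigs)
  for (i in 1:10) {
    w <- runif(2); w <- w / sum(w)
    pick <- sample(colnames(W), 2)
    m <- as.numeric(rmultinom(1, 3000, W[, pick] %*% w))
    fit <- nnls_lawson_hanson(W, m)
    # any single-signature least-squares fit has residual >= NNLS residual
    for (k in seq_len(ncol(W))) {
      ck <- max(sum(W[, k] * m) / sum(W[, k]^2), 0)
      expect_gte(sum((m - ck * W[, k])^2) + 1e-8, fit$residual)
    }
    # unconstrained LS projected to nonnegativity is no better
    xls <- pmax(qr.coef(qr(W), m), 0)
    expect_gte(sum((m - W %*% xls)^2) + 1e-8, fit$residual)
    # brute-force grid over the generating 2-signature mixture
    grid <- seq(0, 1, by = 0.01)
    tot <- sum(m)
    gres <- vapply(grid, function(g)
      sum((m - tot * (g * W[, pick[1]] + (1 - g) * W[, pick[2]]))^2),
      numeric(1))
    expect_lte(fit$residual, min(gres) + 1e-8)
  }
})

test_that("an exactly representable mixture is recovered with near-zero residual", {
  m <- 100 * unclass(sigs)[, "SBS7a"]
  e <- fit_signatures(structure(m, class = "mutation_catalog"), sigs)
  expect_equal(unname(e$absolute["SBS7a"]), 100, tolerance = 1e-8)
  expect_lt(e$residual, 1e-12)
  expect_equal(unname(e$relative["SBS7a"]), 1, tolerance = 1e-8)
})

test_that("multinomial catalogs recover their mixture weights", {
  truth <- c(SBS1 = 0.6, SBS7b = 0.4)
  cl <- simulate_catalog(truth, 5000, sigs, seed = 123L)
  e <- fit_signatures(cl, sigs)
  expect_lt(abs(e$relative["SBS1"] - 0.6), 0.05)
  expect_lt(abs(e$relative["SBS7b"] - 0.4), 0.05)
})

test_that("empty catalogs give zero exposures and flagged relative contributions", {
  empty <- structure(setNames(integer(96), sbs_channels()),
                     class = "mutation_catalog")
  e <- fit_signatures(empty, sigs)
  expect_equal(unname(e$absolute), rep(0, 5))
  expect_equal(e$residual, 0)
  expect_true(all(is.na(e$relative)))
  expect_warning(uv <- flag_uv(e), "undefined")
  expect_false(as.logical(uv))
})

test_that("fitting a scaled catalog scales the exposures", {
  cl <- simulate_catalog(c(SBS5 = 0.5, SBS18 = 0.5), 2000, sigs, seed = 3L)
  e1 <- fit_signatures(cl, sigs)
  e7 <- fit_signatures(structure(7 * as.numeric(cl), names = names(cl),
                                 class = "mutation_catalog"), sigs)
  expect_equal(e7$absolute, 7 * e1$absolute, tolerance = 1e-6)
  expect_equal(e7$relative, e1$relative, tolerance = 1e-6)
})

test_that("catalog total equals the number of mutations passing filters", {
  set.seed(5)
  n <- 200
  ctx <- paste0(sample(c("A", "C", "G", "T"), n, TRUE), "C",
                sample(c("A", "C", "G", "T"), n, TRUE))
  m <- data.frame(chrom = sample(c(1:22, "X"), n, TRUE), pos = seq_len(n),
                  ref = "C", alt = sample(c("A", "G", "T"), n, TRUE),
                  t_alt_count = sample(1:20, n, TRUE),
                  in_population_resource = runif(n) < 0.2,
                  context = ctx, stringsAsFactors = FALSE)
  cl <- build_catalog(m)
  n_pass <- sum(m$chrom %in% as.character(1:22) & !m$in_population_resource &
                  m$t_alt_count >= 5)
  expect_equal(sum(cl), n_pass)
})

test_that("the UV flag applies its threshold inclusively", {
  e <- structure(list(sample_id = "s", residual = 0, n_mutations = 100,
                      absolute = c(SBS1 = 50, SBS7a = 30, SBS7b = 20),
                      relative = c(SBS1 = 0.5, SBS7a = 0.3, SBS7b = 0.2)),
                 class = "signature_exposure")
  expect_true(as.logical(flag_uv(e, threshold = 0.5)))    # exactly at threshold
  expect_false(as.logical(flag_uv(e, threshold = 0.51)))
  expect_false(as.logical(flag_uv(e, uv_signature_names = "SBS7a",
                                  threshold = 0.5)))
  expect_error(flag_uv(e, uv_signature_names = "SBS99"), "unknown")
  zero <- e; zero$relative <- c(SBS1 = 1, SBS7a = 0, SBS7b = 0)
  expect_false(as.logical(flag_uv(zero)))
})

test_that("MAF-like tables keep T alleles as strings, not logicals", {
  path <- withr::local_tempfile(fileext = ".tsv")
  m <- data.frame(chrom = c("1", "2"), pos = c(10L, 20L), ref = c("C", "T"),
                  alt = c("T", "A"), t_alt_count = c(9, 6),
                  in_population_resource = c(FALSE, FALSE),
                  context = c("ACA", "TTA"), stringsAsFactors = FALSE)
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_maf_like(path)
  expect_identical(back$alt, c("T", "A"))
  expect_identical(back$ref, c("C", "T"))
  cl <- build_catalog(back)
  expect_equal(sum(cl), 2L)
  expect_equal(unname(cl["A[C>T]A"]), 1L)
  expect_equal(unname(cl["T[T>A]A"]), 1L)
})

test_that("signature matrices round-trip through the COSMIC text layout", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature_matrix(sigs, path)
  back <- read_signature_matrix(path)
  expect_equal(unclass(back), unclass(sigs), tolerance = 1e-12)
  # shuffled row order is normalized back to canonical
  d <- read.delim(path, check.names = FALSE)
  set.seed(1); d <- d[sample(nrow(d)), ]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(d, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_signature_matrix(path2)
  expect_equal(unclass(back2), unclass(sigs), tolerance = 1e-12)
})
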