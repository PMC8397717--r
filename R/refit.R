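#' Nonnegative least squares by the Lawson-Hanson active-set method
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0` with the classical
#' active-set algorithm: starting from `x = 0`, variables enter the passive
#' set by largest positive gradient of the residual (ties broken by lowest
#' column index), and an inner feasibility loop removes variables whose
#' unconstrained subproblem solution turns nonpositive. Deterministic for
#' fixed inputs.
#'
#' @param A Numeric matrix (m x n).
#' @param b Numeric vector of length m.
#' @param tol Convergence tolerance on the gradient (default 1e-10 relative
#'   to the problem scale).
#' @return List with `x` (solution), `residual` (sum of squared residuals)
#'   and `fitted` (`A %*% x`).
#' @export
nnls_lawson_hanson <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  stopifnot(nrow(A) == length(b))
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  scale <- max(abs(crossprod(A, b)), 1)
  w <- as.numeric(crossprod(A, b))       # gradient at x = 0
  iter_max <- 30L * n
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol * scale)) {
    iter <- iter + 1L
    if (iter > iter_max) break
    cand <- which(!passive)
    j <- cand[which.max(w[cand])]        # which.max -> lowest index on ties
    passive[j] <- TRUE
    inner <- 0L
    repeat {
      inner <- inner + 1L
      P <- which(passive)
      z <- numeric(n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > 0) || inner > iter_max) { x <- pmax(z, 0); break }
      neg <- P[z[P] <= 0]
      alpha <- suppressWarnings(min(x[neg] / (x[neg] - z[neg]), na.rm = TRUE))
      if (!is.finite(alpha)) alpha <- 0
      x <- x + alpha * (z - x)
      passive[P[x[P] <= tol * max(x, 1)]] <- FALSE
      x[!passive] <- 0
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  fitted <- as.numeric(A %*% x)
  list(x = x, residual = sum((b - fitted)^2), fitted = fitted)
}

#' Refit predefined mutational signatures to a catalog
#'
#' Searches for the nonnegative linear combination of the predefined
#' signatures that best explains the observed 96-channel catalog, by solving
#' a nonnegative least-squares problem (see [nnls_lawson_hanson()]). Returns
#' absolute contributions (in mutation counts) and relative contributions
#' (fractions of the total fitted contribution).
#'
#' @param catalog A `mutation_catalog` (or plain 96-vector of counts).
#' @param signatures A `signature_set`.
#' @return A `signature_exposure` object: list with `sample_id`, `absolute`
#'   (named vector), `relative` (named vector summing to 1; all `NA` for an
#'   all-zero catalog), `residual` (sum of squares) and `n_mutations`.
#' @examples
#' sigs <- synthetic_signature_set()
#' catalog <- simulate_catalog(c(SBS1 = 0.6, SBS7a = 0.4), 2000, sigs, seed = 1)
#' fit_signatures(catalog, sigs)
#' @export
fit_signatures <- function(catalog, signatures) {
  stopifnot(inherits(signatures, "signature_set"))
  m <- as.numeric(catalog)
  if (length(m) != 96L) stop("catalog must have exactly 96 channels")
  if (any(m < 0)) stop("catalog counts must be nonnegative")
  if (!is.null(names(catalog))) m <- as.numeric(catalog[rownames(signatures)])
  fit <- nnls_lawson_hanson(unclass(signatures), m)
  absolute <- setNames(fit$x, colnames(signatures))
  total <- sum(absolute)
  relative <- if (total > 0) absolute / total else setNames(
    rep(NA_real_, length(absolute)), names(absolute))
  structure(list(
    sample_id = attr(catalog, "sample_id") %||% NA_character_,
    absolute = absolute,
    relative = relative,
    residual = fit$residual,
    n_mutations = sum(m)
  ), class = "signature_exposure")
}

#' @export
print.signature_exposure <- function(x, ...) {
  cat(sprintf("<signature_exposure> %s (%d mutations, residual %.3g)\n",
              x$sample_id, x$n_mutations, x$residual))
  print(round(rbind(absolute = x$absolute, relative = x$relative), 3))
  invisible(x)
}

#' Flag a UV-damaged genome from signature exposures
#'
#' A sample is flagged as UV-damaged when the summed relative contribution of
#' the UV signatures (the SBS7 family by default) reaches `threshold`
#' (inclusive). An exposure with undefined relative contributions (all-zero
#' catalog) is flagged `FALSE` with a warning.
#'
#' @param exposure A `signature_exposure` from [fit_signatures()].
#' @param uv_signature_names Signature names counted as UV damage; default:
#'   every fitted signature whose name starts with "SBS7".
#' @param threshold Minimum summed relative UV contribution (default 0.5).
#' @return Logical flag with attribute `uv_contribution`.
#' @export
flag_uv <- function(exposure, uv_signature_names = NULL, threshold = 0.5) {
  stopifnot(inherits(exposure, "signature_exposure"))
  if (is.null(uv_signature_names))
    uv_signature_names <- grep("^SBS7", names(exposure$relative), value = TRUE)
  missing_sig <- setdiff(uv_signature_names, names(exposure$relative))
  if (length(missing_sig))
    stop("unknown signature name(s): ", paste(missing_sig, collapse = ", "))
  if (anyNA(exposure$relative)) {
    warning("relative contributions undefined (empty catalog); UV flag FALSE")
    return(structure(FALSE, uv_contribution = NA_real_))
  }
  contrib <- sum(exposure$relative[uv_signature_names])
  structure(contrib >= threshold, uv_contribution = contrib)
}

#' Write signature exposures as TSV
#'
#' @param exposures A `signature_exposure` or list of them.
#' @param path Output TSV path.
#' @param uv_threshold UV flag threshold passed to [flag_uv()].
#' @return `path`, invisibly.
#' @export
write_exposures <- function(exposures, path, uv_threshold = 0.5) {
  if (inherits(exposures, "signature_exposure")) exposures <- list(exposures)
  rows <- lapply(exposures, function(e) {
    uv <- suppressWarnings(flag_uv(e, threshold = uv_threshold))
    data.frame(sample_id = e$sample_id,
               signature = names(e$absolute),
               absolute = as.numeric(e$absolute),
               relative = as.numeric(e$relative),
               uv_flag = as.logical(uv),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
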