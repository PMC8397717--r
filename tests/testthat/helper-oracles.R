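# Independent oracles kept deliberately naive: scalar loops and direct
# probability sums, structurally unlike the package implementations.

# Brute-force search over all two-stage designs (r1/n1, r/n), n <= n_max.
# Returns the design minimizing EN0 among those with type I error <= alpha
# and power >= 1 - beta; ties resolved as (EN0, n, n1, -r1, r) ascending.
simon_bruteforce <- function(p0, p1, alpha, beta, n_max) {
  best <- NULL
  for (n in 2:n_max) {
    for (n1 in 1:(n - 1)) {
      n2 <- n - n1
      for (r1 in 0:(n1 - 1)) {
        PET0 <- sum(dbinom(0:r1, n1, p0))
        EN0 <- n1 + (1 - PET0) * n2
        if (!is.null(best) && EN0 > best$EN0 + 1e-12) next
        for (r in (r1 + 1):n) {
          a <- 0; pw <- 0
          for (x1 in (r1 + 1):n1) {
            a <- a + dbinom(x1, n1, p0) * sum(dbinom(max(r - x1 + 1, 0):n2, n2, p0))
            pw <- pw + dbinom(x1, n1, p1) * sum(dbinom(max(r - x1 + 1, 0):n2, n2, p1))
          }
          if (a <= alpha) {
            # the smallest alpha-feasible r has the best power for this r1
            if (pw >= 1 - beta &&
                (is.null(best) || EN0 < best$EN0 - 1e-12))
              best <- list(n1 = n1, r1 = r1, n = n, r = r, EN0 = EN0)
            break
          }
        }
      }
    }
  }
  best
}

# Two-sided Fisher p by explicit enumeration of all 2x2 tables with the
# observed margins, using factorials directly.
fisher_enumeration <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); c2 <- sum(m[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  ntot <- r1 + r2
  tab_prob <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    if (min(b, c, d) < 0) return(0)
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
          lfactorial(ntot) - lfactorial(a) - lfactorial(b) - lfactorial(c) -
          lfactorial(d))
  }
  p_obs <- tab_prob(m[1, 1])
  p <- 0
  for (a in 0:min(r1, c1)) {
    pa <- tab_prob(a)
    if (pa <= p_obs * (1 + 1e-7)) p <- p + pa
  }
  min(p, 1)
}

# Product-limit estimate computed as an explicit product over risk sets.
km_by_hand <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    died <- sum(time == ut[i] & event == 1)
    s <- s * (1 - died / at_risk)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# Two-group log-rank statistic by per-event-time 2x2 enumeration.
logrank_by_hand <- function(tA, eA, tB, eB) {
  time <- c(tA, tB); event <- c(eA, eB)
  grp <- rep(c(0, 1), c(length(tA), length(tB)))
  ut <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    nA <- sum(tA >= t); nB <- sum(tB >= t); n <- nA + nB
    dA <- sum(tA == t & eA == 1); dB <- sum(tB == t & eB == 1); d <- dA + dB
    O <- O + dA
    E <- E + d * nA / n
    if (n > 1) V <- V + d * (nA / n) * (nB / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Build a read_family object directly (bypasses tagging) for threshold tests.
make_family <- function(assay, inserts, barcode = "ACGTACGTACGT") {
  structure(list(assay = assay$name, barcode = barcode,
                 size = length(inserts), inserts = inserts),
            class = "read_family")
}

# Insert sequence carrying a given allele at the assay hotspot.
insert_with_allele <- function(assay, allele) {
  s <- assay$reference_seq
  if (identical(allele, "ref")) return(s)
  w <- nchar(assay$target_ref)
  paste0(substr(s, 1, assay$target_position),
         allele,
         substr(s, assay$target_position + w + 1, nchar(s)))
}
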